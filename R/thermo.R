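# Equilibrium thermodynamics of ion-coupled transport.
#
# Conventions used throughout:
#   * voltage = psi_in - psi_out, outside is ground;
#   * slope = RT ln(10)/F approximated as exactly 60 mV per decade;
#   * activities are taken equal to concentrations (ideal solutions);
#   * free energies are expressed in "mV-equivalents" per cycle, i.e. divided
#     by F and by one elementary charge, so they live on the same scale as
#     membrane voltages.

#' Per-cycle free energy of a coupled transport reaction
#'
#' The free energy of moving one full transport cycle inward, expressed in
#' mV-equivalents: `G = slope * sum(nu_i * log10(c_in_i/c_out_i)) + Q * voltage`
#' where Q is the net charge per cycle. `G < 0` means the inward cycle is
#' spontaneous (net influx), `G > 0` means net efflux, and `G = 0` is
#' equilibrium -- which defines the reversal potential.
#'
#' @param cycle A [transport_cycle()].
#' @param gradients A [gradient_set()] containing every cycle species.
#' @param voltage Membrane voltage in mV (psi_in - psi_out).
#' @param slope mV per tenfold concentration change; 60 by default.
#' @return Free energy per cycle in mV-equivalents.
#' @examples
#' g <- vcindy_gradients()
#' cycle_free_energy(vcindy_cycle(), g, voltage = 84) # > 0: efflux
#' @export
cycle_free_energy <- function(cycle, gradients, voltage, slope = 60) {
  stopifnot(is.numeric(voltage), length(voltage) == 1L, is.finite(voltage),
            is.numeric(slope), slope > 0)
  chem <- sum(.weighted_log_ratios(cycle, gradients))
  slope * chem + net_charge(cycle) * voltage
}

#' Reversal potential of an electrogenic transport cycle
#'
#' The membrane voltage at which the electrochemical driving forces on the
#' cycle sum to zero, so no net substrate flux occurs:
#' `E_rev = -slope * sum(nu_i * log10(c_in_i/c_out_i)) / Q`.
#' Only electrogenic cycles (net charge Q != 0) have a finite reversal
#' potential; electroneutral cycles raise an error.
#'
#' @inheritParams cycle_free_energy
#' @return Reversal potential in mV.
#' @examples
#' reversal_potential(vcindy_cycle(), vcindy_gradients()) # ~ +48.4 mV
#' @export
reversal_potential <- function(cycle, gradients, slope = 60) {
  q <- net_charge(cycle)
  if (abs(q) < 1e-12)
    stop("electroneutral cycle: net charge per cycle is zero, so the reversal ",
         "potential is undefined", call. = FALSE)
  chem <- sum(.weighted_log_ratios(cycle, gradients))
  -slope * chem / q
}

#' Reversal potential for an n Na+ : m divalent-anion symporter
#'
#' Closed form for a symporter co-transporting `n` Na+ ions (valence +1) with
#' `m` substrate molecules of valence -2:
#' `E_rev = -slope/(n/m - 2) * ((n/m) * log10(r_Na) + log10(r_S))`
#' with `r = c_in/c_out`. Reduces to [reversal_potential()] on the equivalent
#' two-term cycle. `n/m = 2` is electroneutral and raises an error.
#'
#' @param n,m Positive ion and substrate stoichiometries (rationals allowed).
#' @param na_ratio `[Na+]_in / [Na+]_out`, > 0.
#' @param s_ratio `[S]_in / [S]_out`, > 0.
#' @param slope mV per decade, 60 by default.
#' @return Reversal potential in mV.
#' @examples
#' reversal_potential_eq1(3, 1, 0.25, 10) # ~ +48.4 mV
#' @export
reversal_potential_eq1 <- function(n, m, na_ratio, s_ratio, slope = 60) {
  stopifnot(is.numeric(n), n > 0, is.numeric(m), m > 0,
            is.numeric(na_ratio), na_ratio > 0,
            is.numeric(s_ratio), s_ratio > 0)
  r <- n / m
  if (abs(r - 2) < 1e-12)
    stop("electroneutral cycle: n/m = 2 carries no net charge, so the ",
         "reversal potential is undefined", call. = FALSE)
  -slope / (r - 2) * (r * log10(na_ratio) + log10(s_ratio))
}

#' Reversal potential for an n Na+ : m neutral-substrate symporter
#'
#' For a neutral substrate (e.g. a sugar) all the transported charge rides on
#' the Na+ ions: `E_rev = -slope * ((m/n) * log10(r_G) + log10(r_Na))`.
#' Agrees with [reversal_potential()] for the cycle {Na+ nu = n, z = +1;
#' G nu = m, z = 0}.
#'
#' @inheritParams reversal_potential_eq1
#' @param g_ratio `[G]_in / [G]_out` for the neutral substrate, > 0.
#' @return Reversal potential in mV.
#' @examples
#' reversal_potential_neutral_substrate(2, 1, 1, 100) # -60 mV
#' @export
reversal_potential_neutral_substrate <- function(n, m, na_ratio, g_ratio,
                                                 slope = 60) {
  stopifnot(is.numeric(n), n > 0, is.numeric(m), m > 0,
            is.numeric(na_ratio), na_ratio > 0,
            is.numeric(g_ratio), g_ratio > 0)
  -slope * ((m / n) * log10(g_ratio) + log10(na_ratio))
}

#' Nernst potential of a single permeant ion
#'
#' `E = -(slope/z) * log10(c_in/c_out)`, using the same voltage sign
#' convention as the rest of the package (inside minus outside). With
#' valinomycin present and K+ as the only permeant ion, the membrane voltage
#' is clamped at the potassium Nernst potential.
#'
#' @param valence Nonzero integer ion valence.
#' @param ratio_in_out `c_in / c_out`, > 0.
#' @param slope mV per decade, 60 by default.
#' @return Equilibrium voltage in mV.
#' @examples
#' nernst_potential(+1, 0.1) # +60 mV
#' @export
nernst_potential <- function(valence, ratio_in_out, slope = 60) {
  if (!is.numeric(valence) || length(valence) != 1L || valence == 0)
    stop("`valence` must be a nonzero integer", call. = FALSE)
  stopifnot(is.numeric(ratio_in_out), ratio_in_out > 0)
  -(slope / valence) * log10(ratio_in_out)
}

#' Substrate ratio at which a cycle is at equilibrium
#'
#' Solves the zero-free-energy condition of [cycle_free_energy()] for the
#' substrate in/out ratio, holding all other (ion) ratios and the voltage
#' fixed: the concentration ratio the transporter can hold at steady state.
#' This is the accumulation-ratio calculation behind statements such as
#' "physiological ion gradients let a glutamate transporter hold a
#' million-fold glutamate gradient".
#'
#' @inheritParams cycle_free_energy
#' @param ion_gradients A [gradient_set()] containing every *non-substrate*
#'   cycle species (a substrate entry, if present, is ignored).
#' @param substrate Name of the substrate term to solve for; defaults to the
#'   unique term with role `"substrate"`.
#' @return The equilibrium `c_in/c_out` ratio of the substrate.
#' @examples
#' # equal Na+ on both sides, 0 mV: no concentrating power
#' equilibrium_substrate_ratio(vcindy_cycle(),
#'   gradient_set(Na = c(0.1, 0.1)), voltage = 0) # 1
#' @export
equilibrium_substrate_ratio <- function(cycle, ion_gradients, voltage,
                                        substrate = NULL, slope = 60) {
  stopifnot(inherits(cycle, "transport_cycle"),
            inherits(ion_gradients, "gradient_set"),
            is.numeric(voltage), length(voltage) == 1L)
  terms <- cycle$terms
  if (is.null(substrate)) {
    subs <- terms$name[terms$role == "substrate"]
    if (length(subs) != 1L)
      stop("`substrate` must be named when the cycle has several substrate terms",
           call. = FALSE)
    substrate <- subs
  }
  i <- match(substrate, terms$name)
  if (is.na(i) || terms$stoichiometry[i] == 0)
    stop(sprintf("'%s' is not a species of this cycle", substrate), call. = FALSE)
  others <- terms[terms$name != substrate, , drop = FALSE]
  conc <- ion_gradients$concentrations
  idx <- match(others$name, conc$name)
  if (anyNA(idx)) {
    missing <- others$name[is.na(idx)]
    stop(sprintf("ion gradients missing for species: %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  chem_others <- sum(others$stoichiometry * log10(conc$c_in[idx] / conc$c_out[idx]))
  q <- net_charge(cycle)
  log_rs <- (-q * voltage / slope - chem_others) / terms$stoichiometry[i]
  10^log_rs
}

#' Static-head ion gradient balancing a substrate gradient
#'
#' At zero voltage a cycle with ion:substrate stoichiometry n:m is at
#' equilibrium when `n*log10(r_ion) + m*log10(r_S) = 0`, so the ion gradient
#' required to hold a given substrate gradient is
#' `r_ion = r_S^(-m/n) = (1/r_S)^(1/(n/m))`.
#' Each substrate molecule draws on n/m ion translocations, so the more ions
#' per substrate, the *smaller* the opposing ion gradient needed -- the flip
#' side of the familiar amplification of concentrating power,
#' `r_S = (1/r_ion)^(n/m)`.
#'
#' @param n_over_m Ion:substrate stoichiometric ratio, > 0.
#' @param substrate_ratio_in_out Substrate `c_in/c_out` to be balanced, > 0.
#' @return The ion `c_in/c_out` ratio giving zero net flux at 0 mV.
#' @examples
#' # a tenfold outward substrate gradient, 3 ions per substrate:
#' static_head_ion_gradient(3, 10) # ~0.464, i.e. about a 1:2.15 inward gradient
#' @export
static_head_ion_gradient <- function(n_over_m, substrate_ratio_in_out) {
  stopifnot(is.numeric(n_over_m), n_over_m > 0,
            is.numeric(substrate_ratio_in_out), substrate_ratio_in_out > 0)
  substrate_ratio_in_out^(-1 / n_over_m)
}

#' Direction of net substrate flux at a given voltage
#'
#' Maps the sign of [cycle_free_energy()] to a flux direction: negative free
#' energy drives the inward cycle ("influx"), positive drives "efflux", and
#' magnitudes below `tol` are called "equilibrium". For a cycle with positive
#' net charge, flux is inward at all voltages below the reversal potential
#' and outward above it.
#'
#' @inheritParams cycle_free_energy
#' @param tol Equilibrium tolerance in mV-equivalents.
#' @return One of `"influx"`, `"efflux"`, `"equilibrium"`.
#' @examples
#' flux_direction(vcindy_cycle(), vcindy_gradients(), 12) # influx
#' flux_direction(vcindy_cycle(), vcindy_gradients(), 84) # efflux
#' @export
flux_direction <- function(cycle, gradients, voltage, slope = 60, tol = 1e-6) {
  g <- cycle_free_energy(cycle, gradients, voltage, slope = slope)
  if (abs(g) < tol) "equilibrium" else if (g < 0) "influx" else "efflux"
}
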