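# Synthetic proteoliposome radiotracer flux assays.
#
# The generator mimics the data shape of a reversal-potential flux
# experiment: triplicate internalized-CPM time courses at several clamped
# voltages, a t = 0 baseline taken before dilution, optional late-onset
# protein-mediated substrate leak, per-course baseline jitter and Poisson
# scintillation counting noise.

.AVOGADRO <- 6.02214076e23
.DPM_PER_CI <- 2.22e12

#' Proteoliposome population
#'
#' @param diameter Internal vesicle diameter in nm (default 400, the
#'   extrusion pore size).
#' @param vesicle_count Number of vesicles contributing to each filter
#'   (default 1e10).
#' @param lipid_mg Lipid mass metadata (mg), optional.
#' @return A list of class `vesicle_population`.
#' @export
vesicle_population <- function(diameter = 400, vesicle_count = 1e10,
                               lipid_mg = NA_real_) {
  stopifnot(is.numeric(diameter), diameter > 0,
            is.numeric(vesicle_count), vesicle_count >= 1)
  structure(list(diameter = diameter, vesicle_count = vesicle_count,
                 lipid_mg = lipid_mg),
            class = "vesicle_population")
}

#' Expected substrate molecules per vesicle
#'
#' For a spherical vesicle of internal diameter `diameter` nm holding
#' substrate at `concentration` mol/L, the expected occupancy is
#' `concentration * N_A * (pi/6) * d^3` with the diameter converted to dm.
#' At 1 uM in a 400 nm vesicle this is about 20 molecules, small enough that
#' per-vesicle occupancy is strongly Poisson-distributed.
#'
#' @param concentration Substrate concentration in mol/L, >= 0.
#' @param diameter Internal vesicle diameter in nm, > 0.
#' @return Expected molecule count (not rounded).
#' @examples
#' expected_molecules_per_vesicle(1e-6, 400) # ~20.2
#' @export
expected_molecules_per_vesicle <- function(concentration, diameter) {
  stopifnot(is.numeric(concentration), all(concentration >= 0),
            is.numeric(diameter), all(diameter > 0))
  volume_l <- (pi / 6) * (diameter * 1e-8)^3  # nm -> dm; dm^3 = L
  concentration * .AVOGADRO * volume_l
}

#' Draw Poisson vesicle occupancies
#'
#' @param n Number of vesicles to draw.
#' @param concentration Substrate concentration (mol/L).
#' @param diameter Vesicle diameter (nm).
#' @return Integer vector of per-vesicle molecule counts.
#' @export
draw_vesicle_occupancy <- function(n, concentration, diameter = 400) {
  stats::rpois(n, expected_molecules_per_vesicle(concentration, diameter))
}

#' Simulator parameters for the flux-assay generator
#'
#' Defaults describe the succinate-transport conditions used throughout the
#' package: 1 uM internal tritiated substrate at 60 Ci/mmol counted at 30%
#' efficiency, no leak and no baseline jitter.
#'
#' @param rate_scale Turnover scale of the population-mean flux law, in
#'   mol/L/s of internal-concentration change (default 5e-9).
#' @param km_substrate Optional Michaelis constant (mol/L) applying a
#'   saturation factor `S/(S + km)` on the cis-side substrate; `NULL` (the
#'   default) disables saturation.
#' @param leak_rate First-order leak rate constant (1/s) on internal
#'   substrate, representing a protein-mediated leak; 0 disables it.
#' @param leak_onset Time (s) after which the leak switches on.
#' @param counting_efficiency Scintillation counting efficiency in (0, 1];
#'   about 0.3 for tritium, 0.9 for carbon-14.
#' @param specific_activity Radiolabel specific activity in Ci/mmol.
#' @param baseline_jitter_cv Coefficient of variation of a lognormal scale
#'   factor applied per time course (mimicking vesicle-recovery variation in
#'   the starting counts between voltages); 0 disables it.
#' @param seed Integer RNG seed; required by [simulate_experiment()].
#' @return A list of class `flux_params`.
#' @export
flux_params <- function(rate_scale = 5e-9, km_substrate = NULL,
                        leak_rate = 0, leak_onset = 30,
                        counting_efficiency = 0.3, specific_activity = 60,
                        baseline_jitter_cv = 0, seed = NULL) {
  stopifnot(rate_scale >= 0, leak_rate >= 0, leak_onset >= 0,
            counting_efficiency > 0, counting_efficiency <= 1,
            specific_activity >= 0, baseline_jitter_cv >= 0)
  if (!is.null(km_substrate)) stopifnot(km_substrate > 0)
  if (!is.null(seed)) stopifnot(is.numeric(seed), seed == round(seed))
  structure(list(rate_scale = rate_scale, km_substrate = km_substrate,
                 leak_rate = leak_rate, leak_onset = leak_onset,
                 counting_efficiency = counting_efficiency,
                 specific_activity = specific_activity,
                 baseline_jitter_cv = baseline_jitter_cv, seed = seed),
            class = "flux_params")
}

#' Replicate CPM measurements over time at one clamped voltage
#'
#' Container for the data shape of a flux assay: internalized counts per
#' minute for each replicate at each timepoint, at one membrane voltage.
#'
#' @param voltage Clamped membrane voltage (mV); may be `NA` for a
#'   pre-dilution baseline course.
#' @param time Strictly increasing timepoints in seconds (may include 0).
#' @param cpm Numeric matrix, `length(time)` rows by one column per
#'   replicate; all values >= 0.
#' @param metadata Optional list (isotope, gradient labels, experiment id).
#' @return An object of class `flux_time_course`.
#' @export
flux_time_course <- function(voltage, time, cpm, metadata = list()) {
  cpm <- as.matrix(cpm)
  if (is.unsorted(time, strictly = TRUE))
    stop("`time` must be strictly increasing", call. = FALSE)
  if (nrow(cpm) != length(time))
    stop("`cpm` must have one row per timepoint", call. = FALSE)
  if (any(cpm < 0)) stop("CPM values must be nonnegative", call. = FALSE)
  structure(list(voltage = voltage, time = as.numeric(time), cpm = cpm,
                 metadata = metadata),
            class = "flux_time_course")
}

#' @export
print.flux_time_course <- function(x, ...) {
  cat(sprintf("Flux time course at %s mV: %d timepoints x %d replicates\n",
              format(x$voltage), length(x$time), ncol(x$cpm)))
  df <- data.frame(time_s = x$time, round(x$cpm))
  names(df)[-1] <- paste0("rep", seq_len(ncol(x$cpm)), "_cpm")
  print(df, row.names = FALSE)
  invisible(x)
}

# Total internal volume (L) of the population and the moles -> CPM factor.
.population_volume_l <- function(population) {
  population$vesicle_count * (pi / 6) * (population$diameter * 1e-8)^3
}

.cpm_per_molar <- function(population, params) {
  # CPM = [S]_in * V_total * SA(Ci/mmol) * 1e3 mmol/mol * dpm/Ci * efficiency
  .population_volume_l(population) * params$specific_activity * 1e3 *
    .DPM_PER_CI * params$counting_efficiency
}

#' Noise-free expected CPM trajectory
#'
#' Integrates the population-mean flux law
#' `d[S]_in/dt = -rate_scale * sat * (1 - exp(-G/slope)) - leak(t) * [S]_in`
#' where `G = cycle_free_energy(cycle, gradients, voltage)` is recomputed
#' along the trajectory as the internal substrate concentration evolves (ion
#' gradients and external substrate are treated as clamped by the much larger
#' external volume). The law vanishes at `G = 0`, has the sign of `-G`, and
#' is bounded for efflux, so a course simulated exactly at the reversal
#' potential stays constant. The result is converted to counts per minute via
#' the population's internal volume, the label's specific activity and the
#' counting efficiency.
#'
#' @inheritParams cycle_free_energy
#' @param population A [vesicle_population()].
#' @param params A [flux_params()].
#' @param timepoints Sampling times in seconds.
#' @param substrate Substrate species name; defaults to the cycle's unique
#'   substrate term.
#' @return Data frame with columns `time` (s), `s_in` (mol/L) and `cpm`
#'   (expected counts per minute).
#' @export
expected_time_course <- function(cycle, gradients, voltage,
                                 population = vesicle_population(),
                                 params = flux_params(),
                                 timepoints = c(0, 15, 30, 45, 60, 90, 120),
                                 substrate = NULL, slope = 60) {
  stopifnot(inherits(population, "vesicle_population"),
            inherits(params, "flux_params"))
  if (is.unsorted(timepoints, strictly = TRUE))
    stop("`timepoints` must be strictly increasing", call. = FALSE)
  if (is_electroneutral(cycle))
    stop("electroneutral cycle: the clamped voltage cannot influence flux, ",
         "so a voltage-series experiment is not meaningful", call. = FALSE)
  terms <- cycle$terms
  if (is.null(substrate)) {
    subs <- terms$name[terms$role == "substrate"]
    if (length(subs) != 1L)
      stop("`substrate` must be named when the cycle has several substrate terms",
           call. = FALSE)
    substrate <- subs
  }
  conc <- gradients$concentrations
  i_sub <- match(substrate, conc$name)
  if (is.na(i_sub))
    stop(sprintf("species missing from the gradient set: %s", substrate),
         call. = FALSE)
  s_out <- conc$c_out[i_sub]
  s_in0 <- conc$c_in[i_sub]
  nu_s <- terms$stoichiometry[match(substrate, terms$name)]
  others <- terms[terms$name != substrate, , drop = FALSE]
  idx <- match(others$name, conc$name)
  if (anyNA(idx))
    stop(sprintf("species missing from the gradient set: %s",
                 paste(others$name[is.na(idx)], collapse = ", ")),
         call. = FALSE)
  chem_ions <- sum(others$stoichiometry * log10(conc$c_in[idx] / conc$c_out[idx]))
  q <- net_charge(cycle)
  km <- params$km_substrate
  deriv <- function(t, y, parms) {
    s_in <- max(y[[1L]], 1e-30)
    g <- slope * (chem_ions + nu_s * log10(s_in / s_out)) + q * voltage
    g <- min(max(g, -600), 600)  # guard the exponential near depletion
    sat <- if (is.null(km)) 1 else {
      cis <- if (g > 0) s_in else s_out  # substrate on the donor side
      cis / (cis + km)
    }
    list(-params$rate_scale * sat * (1 - exp(-g / slope)) - parms * s_in)
  }
  # the leak switches on discontinuously at leak_onset, so integrate the two
  # regimes separately rather than letting the solver step across the switch
  onset <- params$leak_onset
  grid <- sort(unique(c(0, timepoints, if (params$leak_rate > 0) onset)))
  s_grid <- stats::setNames(numeric(length(grid)), sprintf("%.15g", grid))
  run_leg <- function(times, y0, leak) {
    if (length(times) < 2L) {
      s_grid[sprintf("%.15g", times)] <<- y0
      return(y0)
    }
    sol <- deSolve::ode(y = c(s_in = y0), times = times, func = deriv,
                        parms = leak)
    s_grid[sprintf("%.15g", times)] <<- sol[, "s_in"]
    unname(sol[nrow(sol), "s_in"])
  }
  if (params$leak_rate > 0) {
    y_mid <- run_leg(grid[grid <= onset], s_in0, 0)
    run_leg(grid[grid >= onset], y_mid, params$leak_rate)
  } else {
    run_leg(grid, s_in0, 0)
  }
  s_in <- unname(s_grid[sprintf("%.15g", timepoints)])
  if (any(s_in < 0)) {
    warning("internal substrate reached zero; concentrations clipped at 0",
            call. = FALSE)
    s_in <- pmax(s_in, 0)
  }
  data.frame(time = timepoints, s_in = s_in,
             cpm = s_in * .cpm_per_molar(population, params))
}

#' Simulate replicate CPM time courses at one clamped voltage
#'
#' Wraps [expected_time_course()] with the generator's noise model: one
#' lognormal scale factor per course (mean 1, coefficient of variation
#' `baseline_jitter_cv`) emulating between-voltage variation in recovered
#' counts, then independent Poisson draws around the scaled expected CPM for
#' every replicate and timepoint. With the seed fixed the output is
#' reproducible bit for bit.
#'
#' @inheritParams expected_time_course
#' @param n_replicates Number of replicate filters per timepoint (default 3).
#' @return A [flux_time_course()].
#' @examples
#' p <- flux_params(seed = 7)
#' simulate_time_course(vcindy_cycle(), vcindy_gradients(), 12, params = p)
#' @export
simulate_time_course <- function(cycle, gradients, voltage,
                                 population = vesicle_population(),
                                 params = flux_params(),
                                 timepoints = c(0, 15, 30, 45, 60, 90, 120),
                                 n_replicates = 3, substrate = NULL,
                                 slope = 60) {
  if (!is.null(params$seed)) set.seed(params$seed)
  mean_course <- expected_time_course(cycle, gradients, voltage,
                                      population = population, params = params,
                                      timepoints = timepoints,
                                      substrate = substrate, slope = slope)
  cv <- params$baseline_jitter_cv
  scale <- if (cv > 0) {
    sdlog <- sqrt(log1p(cv^2))
    stats::rlnorm(1L, meanlog = -sdlog^2 / 2, sdlog = sdlog)
  } else 1
  lambda <- scale * mean_course$cpm
  cpm <- matrix(stats::rpois(length(lambda) * n_replicates, rep(lambda, n_replicates)),
                nrow = length(lambda), ncol = n_replicates)
  flux_time_course(voltage, timepoints, cpm,
                   metadata = list(expected_cpm = mean_course$cpm,
                                   scale = scale))
}

#' Simulate a full voltage-series flux experiment
#'
#' One [flux_time_course()] per clamped voltage plus a shared pre-dilution
#' t = 0 baseline course, all drawn from a single proteoliposome batch (one
#' common expected t = 0 level). Deterministic under a fixed seed, which is
#' mandatory here.
#'
#' @inheritParams simulate_time_course
#' @param voltages Clamp voltages in mV (nonempty).
#' @param gradients A [gradient_set()], or a list of gradient sets, one per
#'   voltage.
#' @return A list of class `flux_experiment` with elements `courses` (named
#'   by voltage), `baseline` (a one-timepoint course at t = 0) and `manifest`
#'   (seed and parameters for reproducibility).
#' @examples
#' simulate_experiment(c(12, 48, 84), vcindy_cycle(), vcindy_gradients(),
#'                     params = flux_params(seed = 1))
#' @export
simulate_experiment <- function(voltages, cycle, gradients,
                                population = vesicle_population(),
                                params = flux_params(),
                                timepoints = c(0, 15, 30, 45, 60, 90, 120),
                                n_replicates = 3, substrate = NULL,
                                slope = 60) {
  if (length(voltages) == 0L)
    stop("`voltages` must be nonempty", call. = FALSE)
  if (is.null(params$seed))
    stop("`params$seed` must be set: simulation is a stochastic stage",
         call. = FALSE)
  grad_list <- if (inherits(gradients, "gradient_set"))
    rep(list(gradients), length(voltages))
  else gradients
  if (length(grad_list) != length(voltages))
    stop("`gradients` must be one gradient set or one per voltage",
         call. = FALSE)
  set.seed(params$seed)
  inner <- params
  inner$seed <- NULL  # one seeding for the whole experiment, not per course
  baseline_mean <- expected_time_course(cycle, grad_list[[1L]], voltages[[1L]],
                                        population = population, params = inner,
                                        timepoints = c(0, 1),
                                        substrate = substrate,
                                        slope = slope)$cpm[1L]
  baseline <- flux_time_course(NA_real_, 0,
                               matrix(stats::rpois(n_replicates, baseline_mean),
                                      nrow = 1L),
                               metadata = list(role = "t0_baseline"))
  courses <- vector("list", length(voltages))
  for (i in seq_along(voltages)) {
    courses[[i]] <- simulate_time_course(cycle, grad_list[[i]], voltages[[i]],
                                         population = population,
                                         params = inner,
                                         timepoints = timepoints,
                                         n_replicates = n_replicates,
                                         substrate = substrate, slope = slope)
  }
  names(courses) <- as.character(voltages)
  structure(list(courses = courses, baseline = baseline,
                 manifest = list(seed = params$seed, voltages = voltages,
                                 timepoints = timepoints,
                                 n_replicates = n_replicates,
                                 params = unclass(params))),
            class = "flux_experiment")
}

#' @export
print.flux_experiment <- function(x, ...) {
  cat(sprintf("Flux experiment: %d voltages (%s mV), seed %s\n",
              length(x$courses), paste(names(x$courses), collapse = ", "),
              format(x$manifest$seed)))
  invisible(x)
}
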