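# Domain types: species terms, transport cycles, gradient sets.

#' Define one chemical species of a transport cycle
#'
#' A transport cycle is a fixed-stoichiometry reaction moving ions and
#' substrate across a membrane. Each participating species carries an integer
#' valence and a signed stoichiometric coefficient: positive coefficients mean
#' the species moves in the same direction as the substrate each cycle
#' (cotransport), negative coefficients mean counter-transport (antiport).
#'
#' @param name Species label (e.g. `"Na"`, `"succinate"`). Must be unique
#'   within a cycle.
#' @param valence Integer charge of the species; 0 is allowed for a neutral
#'   substrate such as galactose.
#' @param stoichiometry Signed, nonzero stoichiometric coefficient per
#'   transport cycle. Rational values are permitted.
#' @param role Either `"coupling_ion"` or `"substrate"`.
#' @return An object of class `species_term`.
#' @examples
#' species_term("Na", valence = +1, stoichiometry = 3, role = "coupling_ion")
#' species_term("succinate", valence = -2, stoichiometry = 1, role = "substrate")
#' @export
species_term <- function(name, valence, stoichiometry,
                         role = c("coupling_ion", "substrate")) {
  role <- match.arg(role)
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    stop("`name` must be a single non-empty string", call. = FALSE)
  if (!is.numeric(valence) || length(valence) != 1L || !is.finite(valence) ||
      valence != round(valence))
    stop("`valence` must be a single integer (0 is allowed for a neutral substrate)",
         call. = FALSE)
  if (!is.numeric(stoichiometry) || length(stoichiometry) != 1L ||
      !is.finite(stoichiometry) || stoichiometry == 0)
    stop("`stoichiometry` must be a single nonzero number; ",
         "negative values denote counter-transport", call. = FALSE)
  structure(
    list(name = name, valence = as.integer(valence),
         stoichiometry = as.numeric(stoichiometry), role = role),
    class = "species_term"
  )
}

#' Assemble a transport cycle from species terms
#'
#' @param ... `species_term` objects (or a single list of them). At least one
#'   term must have role `"substrate"`; coupling ions are optional so that
#'   uniporters can be represented.
#' @param label Optional text label for the cycle.
#' @return An object of class `transport_cycle` holding a `terms` data frame
#'   with columns `name`, `valence`, `stoichiometry`, `role`.
#' @examples
#' transport_cycle(
#'   species_term("Na", +1, 3, "coupling_ion"),
#'   species_term("succinate", -2, 1, "substrate"),
#'   label = "3 Na+ : 1 succinate(2-)"
#' )
#' @seealso [vcindy_cycle()], [vsglt_cycle()], [eaat3_cycle()] for ready-made
#'   cycles; [net_charge()] for the charge moved per cycle.
#' @export
transport_cycle <- function(..., label = "") {
  terms <- list(...)
  if (length(terms) == 1L && is.list(terms[[1L]]) &&
      !inherits(terms[[1L]], "species_term"))
    terms <- terms[[1L]]
  if (length(terms) == 0L)
    stop("a transport cycle needs at least one species term", call. = FALSE)
  ok <- vapply(terms, inherits, logical(1L), what = "species_term")
  if (!all(ok))
    stop("all arguments must be `species_term` objects", call. = FALSE)
  df <- data.frame(
    name = vapply(terms, `[[`, character(1L), "name"),
    valence = vapply(terms, `[[`, integer(1L), "valence"),
    stoichiometry = vapply(terms, `[[`, numeric(1L), "stoichiometry"),
    role = vapply(terms, `[[`, character(1L), "role"),
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(df$name))
    stop("species names must be unique within a cycle", call. = FALSE)
  if (!any(df$role == "substrate"))
    stop("a transport cycle needs at least one substrate term", call. = FALSE)
  structure(list(terms = df, label = label), class = "transport_cycle")
}

#' Net charge moved per transport cycle
#'
#' The charge Q = sum of valence times stoichiometry over all species moved in
#' one cycle. Q = 0 identifies an electroneutral cycle, which has no finite
#' reversal potential.
#'
#' @param cycle A [transport_cycle()].
#' @return The (signed) net charge per cycle.
#' @examples
#' net_charge(vcindy_cycle()) # 3*(+1) + 1*(-2) = +1
#' @export
net_charge <- function(cycle) {
  stopifnot(inherits(cycle, "transport_cycle"))
  sum(cycle$terms$stoichiometry * cycle$terms$valence)
}

#' Is a transport cycle electroneutral?
#'
#' @inheritParams net_charge
#' @param tol Tolerance on the net charge for rational stoichiometries.
#' @return `TRUE` if the net charge per cycle is (numerically) zero.
#' @export
is_electroneutral <- function(cycle, tol = 1e-12) {
  abs(net_charge(cycle)) < tol
}

#' @export
print.transport_cycle <- function(x, ...) {
  lab <- if (nzchar(x$label)) x$label else "(unlabelled)"
  cat("Transport cycle:", lab, "\n")
  df <- x$terms
  df$valence <- sprintf("%+d", df$valence)
  print(df, row.names = FALSE)
  q <- net_charge(x)
  cat(sprintf("Net charge per cycle: %+g%s\n", q,
              if (abs(q) < 1e-12) " (electroneutral)" else ""))
  invisible(x)
}

#' Inside/outside concentrations for a set of species
#'
#' Concentrations are stored internally in mol/L. The sign convention
#' throughout the package is membrane voltage = psi_in - psi_out with the
#' outside as ground, so an "inwardly directed" gradient of a species means a
#' higher concentration outside (in/out ratio < 1).
#'
#' @param ... Named length-2 numeric vectors `c(c_in, c_out)`, one per
#'   species, strictly positive.
#' @param unit Unit of the supplied values: `"M"` (default), `"mM"` or `"uM"`.
#' @return An object of class `gradient_set`.
#' @examples
#' gradient_set(Na = c(25, 100), succinate = c(1e-3, 1e-4), unit = "mM")
#' @export
gradient_set <- function(..., unit = c("M", "mM", "uM")) {
  unit <- match.arg(unit)
  f <- c(M = 1, mM = 1e-3, uM = 1e-6)[[unit]]
  entries <- list(...)
  if (length(entries) == 0L)
    stop("a gradient set needs at least one species", call. = FALSE)
  nms <- names(entries)
  if (is.null(nms) || any(!nzchar(nms)))
    stop("every gradient entry must be named by its species", call. = FALSE)
  if (anyDuplicated(nms))
    stop("species names must be unique in a gradient set", call. = FALSE)
  for (nm in nms) {
    v <- entries[[nm]]
    if (!is.numeric(v) || length(v) != 2L || any(!is.finite(v)) || any(v <= 0))
      stop(sprintf("gradient entry '%s' must be c(c_in, c_out) with both values > 0", nm),
           call. = FALSE)
  }
  conc <- data.frame(
    name = nms,
    c_in = vapply(entries, function(v) v[[1L]] * f, numeric(1L)),
    c_out = vapply(entries, function(v) v[[2L]] * f, numeric(1L)),
    stringsAsFactors = FALSE
  )
  structure(list(concentrations = conc), class = "gradient_set")
}

#' @export
print.gradient_set <- function(x, ...) {
  cat("Gradient set (mol/L):\n")
  df <- x$concentrations
  df$in_out_ratio <- df$c_in / df$c_out
  print(df, row.names = FALSE)
  invisible(x)
}

#' In/out concentration ratio of one species
#'
#' @param gradients A [gradient_set()].
#' @param species Species name.
#' @return `c_in / c_out` for that species.
#' @export
ratio_in_out <- function(gradients, species) {
  stopifnot(inherits(gradients, "gradient_set"))
  conc <- gradients$concentrations
  i <- match(species, conc$name)
  if (is.na(i))
    stop(sprintf("species '%s' is missing from the gradient set", species),
         call. = FALSE)
  conc$c_in[i] / conc$c_out[i]
}

# nu_i * log10(c_in/c_out) per cycle species, with a named error for any
# species absent from the gradient set.
.weighted_log_ratios <- function(cycle, gradients) {
  stopifnot(inherits(cycle, "transport_cycle"),
            inherits(gradients, "gradient_set"))
  terms <- cycle$terms
  conc <- gradients$concentrations
  idx <- match(terms$name, conc$name)
  if (anyNA(idx)) {
    missing <- terms$name[is.na(idx)]
    stop(sprintf("species missing from the gradient set: %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  terms$stoichiometry * log10(conc$c_in[idx] / conc$c_out[idx])
}

#' Ready-made transport cycles
#'
#' Convenience constructors for the transport cycles used throughout the
#' package documentation and tests: the bacterial Na+-coupled succinate
#' symporter VcINDY (3 Na+ : 1 succinate(2-), net charge +1 per cycle), the
#' bacterial Na+/galactose symporter vSGLT (1 Na+ : 1 neutral galactose), and
#' a mammalian glutamate-transporter-like cycle (3 Na+ and 1 H+ in, 1 K+
#' counter-transported, with one glutamate(-); net charge +2).
#'
#' @return A [transport_cycle()].
#' @examples
#' net_charge(vcindy_cycle()) # +1
#' net_charge(eaat3_cycle())  # +2
#' @name example_cycles
NULL

#' @rdname example_cycles
#' @export
vcindy_cycle <- function() {
  transport_cycle(
    species_term("Na", +1, 3, "coupling_ion"),
    species_term("succinate", -2, 1, "substrate"),
    label = "VcINDY (3 Na+ : 1 succinate2-)"
  )
}

#' @rdname example_cycles
#' @export
vsglt_cycle <- function() {
  transport_cycle(
    species_term("Na", +1, 1, "coupling_ion"),
    species_term("galactose", 0, 1, "substrate"),
    label = "vSGLT (1 Na+ : 1 galactose)"
  )
}

#' @rdname example_cycles
#' @export
eaat3_cycle <- function() {
  transport_cycle(
    species_term("Na", +1, 3, "coupling_ion"),
    species_term("H", +1, 1, "coupling_ion"),
    species_term("K", +1, -1, "coupling_ion"),
    species_term("glutamate", -1, 1, "substrate"),
    label = "EAAT3-like (3 Na+, 1 H+ in; 1 K+ out; 1 glutamate-)"
  )
}

#' Demonstration gradients for the succinate-transport experiments
#'
#' A fourfold inwardly directed Na+ gradient ([Na+]in:out = 1:4; 25 mM inside,
#' 100 mM outside) and a tenfold outwardly directed radiolabelled succinate
#' gradient ([S]in:out = 10:1; 1 uM inside, 0.1 uM outside). With the
#' [vcindy_cycle()] these gradients put the 3:1 reversal potential at +48 mV.
#'
#' @return A [gradient_set()].
#' @export
vcindy_gradients <- function() {
  gradient_set(Na = c(0.025, 0.100), succinate = c(1e-6, 1e-7), unit = "M")
}
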