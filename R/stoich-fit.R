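# The fitting front end: courses in, classed fit object out, with the
# standard modelling methods.

#' Fit a coupling stoichiometry to voltage-series flux data
#'
#' The package's central estimator. Given replicate CPM time courses at
#' several clamped voltages, it (1) optionally normalizes each course by an
#' early timepoint, (2) classifies the flux direction at every voltage by an
#' OLS slope test ([classify_flux()]), (3) builds a voltage-deltaCPM table
#' ([delta_cpm()]), (4) estimates and brackets the reversal potential
#' ([estimate_reversal_potential()]), and (5) assigns or excludes candidate
#' n:m stoichiometries ([assign_stoichiometry()]).
#'
#' @param courses A `flux_experiment` from [simulate_experiment()], or a list
#'   of [flux_time_course()] objects.
#' @inheritParams predict_candidate_potentials
#' @param alpha Detection level of the per-voltage slope test.
#' @param tolerance_mV Assignment/exclusion tolerance (default 10 mV).
#' @param exclusion_alpha Evidence level required to exclude a candidate.
#' @param leak Set `TRUE` when a late-onset substrate leak is present: the
#'   analysis window and deltaCPM evaluation time are then restricted to the
#'   first 30 s, before the leak contributes.
#' @param window Explicit analysis window (s); overrides the `leak` default.
#' @param normalize Normalize each course by its `t_norm` timepoint first.
#' @param t_norm Normalization timepoint (s), default 5.
#' @param delta_initial,delta_eval Timepoints (s) for the deltaCPM table;
#'   default to the first timepoint and the latest timepoint at or before
#'   60 s (30 s under `leak`).
#' @return An object of class `stoich_fit` (which inherits from
#'   `stoich_inference`), with methods for [print()], [summary()], [coef()],
#'   [predict()], [plot()], [residuals()] and [simulate()].
#' @examples
#' expt <- simulate_experiment(c(12, 48, 84), vcindy_cycle(),
#'                             vcindy_gradients(), params = flux_params(seed = 1))
#' fit <- fit_stoichiometry(expt, candidates = lapply(1:4, c, 1),
#'                          gradients = vcindy_gradients())
#' coef(fit)
#' @export
fit_stoichiometry <- function(courses, candidates, gradients = NULL,
                              substrate_valence = -2,
                              na_ratio = NULL, s_ratio = NULL,
                              ion = "Na", substrate = NULL,
                              alpha = 0.05, tolerance_mV = 10,
                              exclusion_alpha = 0.01,
                              leak = FALSE, window = NULL,
                              normalize = FALSE, t_norm = 5,
                              delta_initial = NULL, delta_eval = NULL,
                              slope = 60) {
  if (inherits(courses, "flux_experiment")) courses <- courses$courses
  stopifnot(is.list(courses), length(courses) >= 1L)
  ok <- vapply(courses, inherits, logical(1L), what = "flux_time_course")
  if (!all(ok))
    stop("`courses` must be flux_time_course objects", call. = FALSE)
  if (is.null(window)) window <- if (leak) c(0, 30) else c(0, Inf)
  if (normalize)
    courses <- lapply(courses, normalize_by_early_timepoint, t_norm = t_norm)
  calls <- lapply(courses, classify_flux, alpha = alpha, window = window)

  horizon <- if (leak) 30 else 60
  deltas <- lapply(courses, function(tc) {
    t0 <- if (is.null(delta_initial)) tc$time[1L] else delta_initial
    t1 <- if (is.null(delta_eval)) {
      cand <- tc$time[tc$time <= horizon & tc$time > t0]
      if (length(cand)) max(cand) else tc$time[length(tc$time)]
    } else delta_eval
    delta_cpm(tc, t0, t1)
  })
  delta_tab <- data.frame(
    voltage = vapply(deltas, `[[`, numeric(1L), "voltage"),
    mean = vapply(deltas, `[[`, numeric(1L), "mean"),
    sem = vapply(deltas, `[[`, numeric(1L), "sem"),
    eval_time = vapply(deltas, `[[`, numeric(1L), "eval_time")
  )
  delta_tab <- delta_tab[order(delta_tab$voltage), , drop = FALSE]
  rownames(delta_tab) <- NULL

  preds <- predict_candidate_potentials(candidates, gradients = gradients,
                                        substrate_valence = substrate_valence,
                                        na_ratio = na_ratio, s_ratio = s_ratio,
                                        ion = ion, substrate = substrate,
                                        slope = slope)
  est <- estimate_reversal_potential(calls, delta_cpm_by_voltage = delta_tab)
  inf <- assign_stoichiometry(preds, calls, est,
                              tolerance_mV = tolerance_mV,
                              exclusion_alpha = exclusion_alpha)
  inf$delta <- delta_tab
  inf$courses <- courses
  inf$gradients <- gradients
  inf$options <- list(alpha = alpha, window = window, leak = leak,
                      normalize = normalize, t_norm = t_norm,
                      substrate_valence = substrate_valence, slope = slope,
                      ion = ion)
  class(inf) <- c("stoich_fit", class(inf))
  inf
}

#' @export
print.stoich_fit <- function(x, ...) {
  cat("Coupling stoichiometry from reversal-potential flux analysis\n\n")
  NextMethod()
  invisible(x)
}

#' @export
summary.stoich_fit <- function(object, ...) {
  structure(list(fit = object), class = "summary.stoich_fit")
}

#' @export
print.summary.stoich_fit <- function(x, ...) {
  f <- x$fit
  print(f)
  cat("\nVoltage-deltaCPM table (initial minus later; + = efflux):\n")
  print(f$delta, row.names = FALSE, digits = 4)
  cat("\nCandidate predictions:\n")
  print(f$predictions)
  cat(sprintf("\nOptions: alpha = %g, window = [%g, %g] s, tolerance = %g mV\n",
              f$options$alpha, f$options$window[1L], f$options$window[2L],
              f$tolerance_mV))
  invisible(x)
}

#' Extract the fitted reversal potential and assigned stoichiometry
#'
#' @param object A `stoich_fit`.
#' @param ... Unused.
#' @return Named vector `c(e_rev, n, m)`; `n` and `m` are `NA` when no
#'   candidate was assigned.
#' @export
coef.stoich_fit <- function(object, ...) {
  est <- if (inherits(object$e_rev, "erev_estimate"))
    object$e_rev$estimate else as.numeric(object$e_rev)
  c(e_rev = est,
    n = if (is.null(object$assigned)) NA_real_ else object$assigned$n,
    m = if (is.null(object$assigned)) NA_real_ else object$assigned$m)
}

#' Predicted reversal potentials under the fitted gradients
#'
#' @param object A `stoich_fit`.
#' @param candidates Optional new candidate set; defaults to the fitted one.
#' @param ... Unused.
#' @return A `candidate_predictions` table.
#' @export
predict.stoich_fit <- function(object, candidates = NULL, ...) {
  if (is.null(candidates))
    candidates <- object$predictions[, c("n", "m")]
  predict_candidate_potentials(
    candidates,
    na_ratio = attr(object$predictions, "na_ratio"),
    s_ratio = attr(object$predictions, "s_ratio"),
    substrate_valence = attr(object$predictions, "substrate_valence"),
    slope = object$options$slope)
}

#' Residuals of the per-voltage slope fits
#'
#' @param object A `stoich_fit`.
#' @param ... Unused.
#' @return A named list (by voltage) of residual vectors from the pooled
#'   OLS fits used by [classify_flux()].
#' @export
residuals.stoich_fit <- function(object, ...) {
  out <- lapply(object$calls, `[[`, "residuals")
  names(out) <- vapply(object$calls, function(x) format(x$voltage), character(1L))
  out
}

#' Voltage-deltaCPM plot of a stoichiometry fit
#'
#' The flux-assay analogue of a current-voltage relation: mean deltaCPM
#' (initial minus later counts, so positive = efflux) against clamp voltage
#' with standard-error bars, a zero-flux line, the estimated reversal
#' potential (dashed) and tick marks at the candidate predictions.
#'
#' @param x A `stoich_fit`.
#' @param ... Passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.stoich_fit <- function(x, ...) {
  d <- x$delta
  est <- coef(x)[["e_rev"]]
  preds <- x$predictions
  ylim <- range(c(d$mean - d$sem, d$mean + d$sem, 0), finite = TRUE)
  graphics::plot(d$voltage, d$mean, pch = 19, ylim = ylim,
                 xlab = "membrane voltage (mV)",
                 ylab = expression(Delta * "CPM (initial - later)"), ...)
  keep <- is.finite(d$sem) & d$sem > 0
  if (any(keep))
    graphics::arrows(d$voltage[keep], d$mean[keep] - d$sem[keep],
                     d$voltage[keep], d$mean[keep] + d$sem[keep],
                     angle = 90, code = 3, length = 0.04)
  graphics::abline(h = 0, col = "grey50")
  graphics::abline(v = est, lty = 2)
  fin <- is.finite(preds$e_rev)
  if (any(fin)) {
    graphics::axis(3, at = preds$e_rev[fin],
                   labels = sprintf("%g:%g", preds$n[fin], preds$m[fin]),
                   tick = TRUE, cex.axis = 0.8)
  }
  invisible(x)
}

#' Simulate new flux experiments from a fitted stoichiometry
#'
#' Parametric-bootstrap style: regenerates synthetic voltage-series
#' experiments using the *assigned* transport cycle under the gradients the
#' fit was performed with. Requires the fit to have been given a
#' [gradient_set()] (absolute concentrations) and to have an assigned
#' candidate.
#'
#' @param object A `stoich_fit` with a non-`NULL` assignment.
#' @param nsim Number of experiments to simulate.
#' @param seed Integer seed (required).
#' @param population A [vesicle_population()].
#' @param params A [flux_params()]; its seed field is overridden.
#' @param timepoints,n_replicates Passed to [simulate_experiment()].
#' @param ... Unused.
#' @return A `flux_experiment`, or a list of them when `nsim > 1`.
#' @export
simulate.stoich_fit <- function(object, nsim = 1, seed = NULL,
                                population = vesicle_population(),
                                params = flux_params(),
                                timepoints = c(0, 15, 30, 45, 60, 90, 120),
                                n_replicates = 3, ...) {
  if (is.null(object$assigned))
    stop("cannot simulate from an unassigned fit", call. = FALSE)
  if (is.null(object$gradients))
    stop("the fit carries no gradient_set with absolute concentrations",
         call. = FALSE)
  if (is.null(seed)) stop("`seed` is required", call. = FALSE)
  zs <- object$options$substrate_valence
  ion <- object$options$ion
  grads <- object$gradients
  sub_name <- setdiff(grads$concentrations$name, ion)[1L]
  cyc <- transport_cycle(
    species_term(ion, +1, object$assigned$n, "coupling_ion"),
    species_term(sub_name, zs, object$assigned$m, "substrate"),
    label = sprintf("assigned %g:%g", object$assigned$n, object$assigned$m)
  )
  voltages <- vapply(object$calls, `[[`, numeric(1L), "voltage")
  sims <- lapply(seq_len(nsim), function(i) {
    p <- params
    p$seed <- seed + i - 1L
    simulate_experiment(voltages, cyc, grads, population = population,
                        params = p, timepoints = timepoints,
                        n_replicates = n_replicates,
                        slope = object$options$slope)
  })
  if (nsim == 1L) sims[[1L]] else sims
}
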