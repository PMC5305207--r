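# Analysis stage: per-voltage flux calls, voltage-deltaCPM curves, reversal
# potential estimation and candidate stoichiometry assignment/exclusion.

.match_time <- function(course, t, tol = 1e-8) {
  i <- which(abs(course$time - t) <= tol)
  if (length(i) != 1L)
    stop(sprintf("timepoint %g s is not present in the course", t),
         call. = FALSE)
  i
}

#' Change in internalized counts between two timepoints
#'
#' Computes `deltaCPM = CPM(initial) - CPM(eval)` per replicate, plus mean and
#' standard error. With internalized counts, a *positive* deltaCPM means
#' counts were lost (net efflux) and a negative deltaCPM means counts were
#' gained (net influx); plotted against voltage this is the flux-assay
#' analogue of a current-voltage relation.
#'
#' @param course A [flux_time_course()].
#' @param initial_time Reference timepoint (s); defaults to the first.
#' @param eval_time Evaluation timepoint (s); defaults to the last.
#' @return A list with `replicates` (per-replicate deltaCPM), `mean`, `sem`,
#'   `initial_time`, `eval_time` and `voltage`.
#' @examples
#' tc <- flux_time_course(12, c(0, 60), rbind(c(1000, 1000), c(1400, 1400)))
#' delta_cpm(tc)$mean # -400: influx
#' @export
delta_cpm <- function(course, initial_time = NULL, eval_time = NULL) {
  stopifnot(inherits(course, "flux_time_course"))
  if (is.null(initial_time)) initial_time <- course$time[1L]
  if (is.null(eval_time)) eval_time <- course$time[length(course$time)]
  i0 <- .match_time(course, initial_time)
  i1 <- .match_time(course, eval_time)
  d <- course$cpm[i0, ] - course$cpm[i1, ]
  list(replicates = as.numeric(d), mean = mean(d),
       sem = stats::sd(d) / sqrt(length(d)),
       initial_time = initial_time, eval_time = eval_time,
       voltage = course$voltage)
}

#' Normalize a time course by an early timepoint
#'
#' Divides every CPM value by the replicate-mean CPM at `t_norm`, so the
#' course reads 1.0 there on average. This removes between-course variation
#' in recovered counts (differing baselines) while preserving relative
#' trajectories, and therefore never changes a flux-direction call.
#'
#' @param course A [flux_time_course()].
#' @param t_norm Normalization timepoint in seconds (default 5 s).
#' @return The normalized [flux_time_course()].
#' @export
normalize_by_early_timepoint <- function(course, t_norm = 5) {
  stopifnot(inherits(course, "flux_time_course"))
  i <- .match_time(course, t_norm)
  ref <- mean(course$cpm[i, ])
  if (!is.finite(ref) || ref <= 0)
    stop(sprintf("mean CPM at t = %g s must be positive to normalize", t_norm),
         call. = FALSE)
  out <- course
  out$cpm <- course$cpm / ref
  out$metadata$normalized_by <- t_norm
  out
}

#' Construct a flux call
#'
#' Container for a per-voltage flux-direction decision, normally produced by
#' [classify_flux()] but constructible directly (e.g. to encode calls read
#' off a published figure).
#'
#' @param voltage Clamped voltage (mV).
#' @param direction `"influx"`, `"efflux"` or `"none"`.
#' @param slope Fitted CPM/s slope (optional).
#' @param se,p Slope standard error and two-sided p-value (optional).
#' @param ci Confidence interval on the slope (length 2, optional).
#' @param window Time window used (length 2, optional).
#' @return An object of class `flux_call`.
#' @export
flux_call <- function(voltage, direction = c("none", "influx", "efflux"),
                      slope = NA_real_, se = NA_real_, p = NA_real_,
                      ci = c(NA_real_, NA_real_), window = c(NA_real_, NA_real_)) {
  direction <- match.arg(direction)
  structure(list(voltage = voltage, direction = direction, slope = slope,
                 se = se, p = p, ci = ci, window = window,
                 residuals = NULL),
            class = "flux_call")
}

#' @export
print.flux_call <- function(x, ...) {
  cat(sprintf("%+g mV: %s (slope %.3g CPM/s, p = %.3g)\n",
              x$voltage, x$direction, x$slope, x$p))
  invisible(x)
}

#' Classify the direction of flux in a time course
#'
#' Fits an ordinary least-squares line to CPM against time, pooling all
#' replicates within the analysis window, and tests the slope against zero
#' (two-sided, level `alpha`). A significantly positive CPM slope is called
#' influx (internal counts rising), a significantly negative slope efflux,
#' and a non-significant slope "none" -- the no-net-flux call that marks a
#' candidate reversal potential. The direction is `"none"` exactly when the
#' `1 - alpha` confidence interval on the slope contains zero.
#'
#' @param course A [flux_time_course()].
#' @param alpha Two-sided test level (default 0.05).
#' @param window Length-2 time window (s) of points used; defaults to the
#'   whole course. Restrict to `c(0, 30)` when a late-onset leak is present.
#' @return A [flux_call()] carrying the fitted slope, its standard error,
#'   confidence interval, p-value and the residuals of the pooled fit.
#' @export
classify_flux <- function(course, alpha = 0.05, window = c(0, Inf)) {
  stopifnot(inherits(course, "flux_time_course"),
            is.numeric(alpha), alpha > 0, alpha < 1,
            length(window) == 2L)
  keep <- course$time >= window[1L] & course$time <= window[2L]
  if (sum(keep) < 3L)
    stop("need at least 3 timepoints inside the analysis window", call. = FALSE)
  if (ncol(course$cpm) < 2L)
    stop("need at least 2 replicates to classify flux", call. = FALSE)
  tt <- rep(course$time[keep], times = ncol(course$cpm))
  yy <- as.vector(course$cpm[keep, ])
  fit <- stats::lm(yy ~ tt)
  est <- summary(fit)$coefficients["tt", ]
  ci <- stats::confint(fit, "tt", level = 1 - alpha)
  p <- unname(est[["Pr(>|t|)"]])
  slope <- unname(est[["Estimate"]])
  direction <- if (p < alpha) {
    if (slope > 0) "influx" else "efflux"
  } else "none"
  call <- flux_call(course$voltage, direction, slope = slope,
                    se = unname(est[["Std. Error"]]), p = p,
                    ci = as.numeric(ci), window = window)
  call$residuals <- stats::residuals(fit)
  call
}

.calls_df <- function(calls) {
  if (inherits(calls, "flux_call")) calls <- list(calls)
  stopifnot(is.list(calls), length(calls) >= 1L)
  df <- data.frame(
    voltage = vapply(calls, `[[`, numeric(1L), "voltage"),
    direction = vapply(calls, `[[`, character(1L), "direction"),
    slope = vapply(calls, function(x) as.numeric(x$slope[1L]), numeric(1L)),
    p = vapply(calls, function(x) as.numeric(x$p[1L]), numeric(1L)),
    stringsAsFactors = FALSE
  )
  df[order(df$voltage), , drop = FALSE]
}

#' Estimate the reversal potential from per-voltage flux calls
#'
#' The reversal potential must be *bracketed*: flux in both directions has to
#' be observed so that the absence of flux reflects equilibrium rather than
#' inactive protein. If a no-flux call sits between opposite-direction calls,
#' its voltage is the point estimate; otherwise, when a mean-deltaCPM table
#' is supplied, the estimate is the zero crossing linearly interpolated
#' between the adjacent voltages where the deltaCPM changes sign; failing
#' that, the midpoint between the nearest opposite-direction calls is used.
#' The bracket is always (nearest flux call below, nearest flux call above).
#'
#' @param calls A list of [flux_call()] objects (or a single one).
#' @param delta_cpm_by_voltage Optional data frame with columns `voltage` and
#'   `mean` (mean deltaCPM, initial minus later).
#' @return A list of class `erev_estimate` with `estimate` (mV), `bracket`
#'   (length 2, mV) and `method`.
#' @examples
#' calls <- list(flux_call(12, "influx"), flux_call(48, "none"),
#'               flux_call(84, "efflux"))
#' estimate_reversal_potential(calls) # 48 mV, bracketed by 12 and 84
#' @export
estimate_reversal_potential <- function(calls, delta_cpm_by_voltage = NULL) {
  df <- .calls_df(calls)
  dirs <- unique(df$direction[df$direction != "none"])
  if (length(dirs) < 2L)
    stop("cannot estimate the reversal potential: flux was ",
         if (length(dirs)) sprintf("%s-only", dirs[1L]) else "never detected",
         " across the measured voltages, so the system is not bracketed ",
         "around equilibrium", call. = FALSE)
  est <- NA_real_
  method <- NA_character_
  none_v <- df$voltage[df$direction == "none"]
  for (v in none_v) {
    below <- df$direction[df$voltage < v & df$direction != "none"]
    above <- df$direction[df$voltage > v & df$direction != "none"]
    bracketed <- (any(below == "influx") && any(above == "efflux")) ||
                 (any(below == "efflux") && any(above == "influx"))
    if (bracketed) { est <- v; method <- "no-flux voltage"; break }
  }
  if (is.na(est) && !is.null(delta_cpm_by_voltage)) {
    dd <- delta_cpm_by_voltage[order(delta_cpm_by_voltage$voltage), , drop = FALSE]
    s <- sign(dd$mean)
    flip <- which(s[-1L] * s[-length(s)] < 0)
    if (length(flip)) {
      i <- flip[1L]
      v1 <- dd$voltage[i]; v2 <- dd$voltage[i + 1L]
      m1 <- dd$mean[i]; m2 <- dd$mean[i + 1L]
      est <- v1 + (0 - m1) * (v2 - v1) / (m2 - m1)
      method <- "deltaCPM interpolation"
    }
  }
  if (is.na(est)) {
    flux <- df[df$direction != "none", , drop = FALSE]
    # midpoint of the closest opposite-direction pair
    best <- Inf
    for (i in seq_len(nrow(flux) - 1L)) {
      if (flux$direction[i] != flux$direction[i + 1L] &&
          diff(flux$voltage[i + 0:1]) < best) {
        best <- diff(flux$voltage[i + 0:1])
        est <- mean(flux$voltage[i + 0:1])
      }
    }
    method <- "midpoint"
  }
  flux_v <- df$voltage[df$direction != "none"]
  lower <- suppressWarnings(max(flux_v[flux_v < est]))
  upper <- suppressWarnings(min(flux_v[flux_v > est]))
  if (!is.finite(lower)) lower <- min(df$voltage)
  if (!is.finite(upper)) upper <- max(df$voltage)
  structure(list(estimate = est, bracket = c(lower, upper), method = method),
            class = "erev_estimate")
}

#' @export
print.erev_estimate <- function(x, ...) {
  cat(sprintf("Reversal potential estimate: %+d mV (bracketed by %+d and %+d mV; %s)\n",
              round(x$estimate), round(x$bracket[1L]), round(x$bracket[2L]),
              x$method))
  invisible(x)
}

#' Assign a coupling stoichiometry from predictions and flux calls
#'
#' Implements the elimination logic of a reversal-potential experiment: a
#' candidate whose predicted reversal potential coincides (within
#' `tolerance_mV`) with a voltage where flux was decisively observed cannot
#' be the true stoichiometry and is excluded; electroneutral candidates are
#' flagged and excluded since no finite reversal potential can confirm them.
#' Among the survivors, the candidate whose prediction lies nearest the
#' estimated reversal potential -- and within `tolerance_mV` of it -- is
#' assigned; "unassigned" is a valid outcome.
#'
#' Exclusion is a strong claim, so it requires decisive evidence of flux:
#' a call with p below `exclusion_alpha` (default 0.01), stricter than the
#' detection level used by [classify_flux()]. Calls constructed by hand
#' without a p-value are taken at face value.
#'
#' @param predictions A `candidate_predictions` table
#'   (see [predict_candidate_potentials()]).
#' @param calls List of [flux_call()] objects.
#' @param e_rev_estimate An `erev_estimate` or a numeric voltage (mV).
#' @param tolerance_mV Assignment/exclusion tolerance (default 10 mV).
#' @param exclusion_alpha Evidence level required for exclusion.
#' @return A list of class `stoich_inference` with `predictions`, `calls`,
#'   `e_rev`, `assigned` (list with `n`, `m`, or `NULL`), and `excluded`
#'   (data frame of candidates with reasons).
#' @export
assign_stoichiometry <- function(predictions, calls, e_rev_estimate,
                                 tolerance_mV = 10, exclusion_alpha = 0.01) {
  stopifnot(is.data.frame(predictions), nrow(predictions) >= 1L)
  est <- if (inherits(e_rev_estimate, "erev_estimate"))
    e_rev_estimate$estimate else as.numeric(e_rev_estimate)
  df <- .calls_df(calls)
  decisive <- df$direction != "none" & (is.na(df$p) | df$p < exclusion_alpha)
  flux_v <- df$voltage[decisive]
  reasons <- character(nrow(predictions))
  for (i in seq_len(nrow(predictions))) {
    if (isTRUE(predictions$electroneutral[i])) {
      reasons[i] <- "electroneutral cycle: no finite reversal potential"
    } else {
      hit <- flux_v[abs(flux_v - predictions$e_rev[i]) <= tolerance_mV]
      if (length(hit))
        reasons[i] <- sprintf(
          "net flux observed at %s mV, within %g mV of its predicted E_rev (%.1f mV)",
          paste(hit, collapse = "/"), tolerance_mV, predictions$e_rev[i])
    }
  }
  excluded <- data.frame(n = predictions$n, m = predictions$m,
                         reason = reasons,
                         stringsAsFactors = FALSE)[nzchar(reasons), , drop = FALSE]
  survivors <- predictions[!nzchar(reasons), , drop = FALSE]
  assigned <- NULL
  if (nrow(survivors)) {
    dist <- abs(survivors$e_rev - est)
    j <- which.min(dist)
    if (length(j) && is.finite(dist[j]) && dist[j] <= tolerance_mV)
      assigned <- list(n = survivors$n[j], m = survivors$m[j],
                       predicted_e_rev = survivors$e_rev[j])
  }
  structure(list(predictions = predictions, calls = calls,
                 e_rev = e_rev_estimate, assigned = assigned,
                 excluded = excluded, tolerance_mV = tolerance_mV,
                 exclusion_alpha = exclusion_alpha),
            class = "stoich_inference")
}

#' @export
print.stoich_inference <- function(x, ...) {
  cat("Stoichiometry inference\n")
  df <- .calls_df(x$calls)
  cat("Flux calls:\n")
  print(df, row.names = FALSE, digits = 3)
  if (inherits(x$e_rev, "erev_estimate")) print(x$e_rev)
  else cat(sprintf("Reversal potential estimate: %+g mV\n", x$e_rev))
  if (is.null(x$assigned)) {
    cat("Assigned stoichiometry: unassigned\n")
  } else {
    cat(sprintf("Assigned stoichiometry: %g : %g (ion : substrate), predicted E_rev %+.1f mV\n",
                x$assigned$n, x$assigned$m, x$assigned$predicted_e_rev))
  }
  if (nrow(x$excluded)) {
    cat("Excluded candidates:\n")
    for (i in seq_len(nrow(x$excluded)))
      cat(sprintf("  %g:%g -- %s\n", x$excluded$n[i], x$excluded$m[i],
                  x$excluded$reason[i]))
  }
  invisible(x)
}
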