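# Forward and inverse design of reversal-potential experiments.

# Accept candidates as a 2-column matrix/data.frame or a list of c(n, m).
.normalize_candidates <- function(candidates) {
  if (is.data.frame(candidates) || is.matrix(candidates)) {
    cand <- as.data.frame(candidates)
    if (ncol(cand) < 2L)
      stop("`candidates` needs two columns: n (ions) and m (substrates)",
           call. = FALSE)
    cand <- cand[, 1:2]
  } else if (is.list(candidates)) {
    cand <- as.data.frame(do.call(rbind, lapply(candidates, function(x) x[1:2])))
  } else if (is.numeric(candidates) && length(candidates) == 2L) {
    cand <- as.data.frame(rbind(candidates[1:2]))
  } else {
    stop("`candidates` must be a list of c(n, m) pairs or a 2-column table",
         call. = FALSE)
  }
  names(cand) <- c("n", "m")
  if (nrow(cand) == 0L) stop("`candidates` is empty", call. = FALSE)
  if (any(cand$n <= 0) || any(cand$m <= 0))
    stop("candidate stoichiometries must be positive", call. = FALSE)
  rownames(cand) <- NULL
  cand
}

# Resolve (na_ratio, s_ratio) either from explicit ratios or a gradient_set.
.design_ratios <- function(gradients, na_ratio, s_ratio, ion, substrate) {
  if (!is.null(gradients)) {
    stopifnot(inherits(gradients, "gradient_set"))
    nms <- gradients$concentrations$name
    if (!(ion %in% nms))
      stop(sprintf("coupling ion '%s' is missing from the gradient set", ion),
           call. = FALSE)
    if (is.null(substrate)) {
      rest <- setdiff(nms, ion)
      if (length(rest) != 1L)
        stop("`substrate` must be named when the gradient set has more than ",
             "one non-ion species", call. = FALSE)
      substrate <- rest
    }
    na_ratio <- ratio_in_out(gradients, ion)
    s_ratio <- ratio_in_out(gradients, substrate)
  }
  if (is.null(na_ratio) || is.null(s_ratio))
    stop("supply either `gradients` or both `na_ratio` and `s_ratio`",
         call. = FALSE)
  stopifnot(na_ratio > 0, s_ratio > 0)
  list(na_ratio = na_ratio, s_ratio = s_ratio, substrate = substrate)
}

#' Predicted reversal potentials for candidate stoichiometries
#'
#' Computes, for each candidate n:m, the reversal potential of the two-term
#' cycle {ion nu = n, z = +1; substrate nu = m, z = `substrate_valence`} under
#' one set of gradients. Electroneutral candidates (n + m * z_S = 0) are
#' flagged rather than dropped: they predict no finite reversal potential and
#' can never be confirmed by a no-flux voltage.
#'
#' @param candidates Candidate stoichiometries: a list of `c(n, m)` pairs or a
#'   two-column table.
#' @param gradients Optional [gradient_set()] holding the coupling ion and the
#'   substrate; alternatively give `na_ratio` and `s_ratio` directly.
#' @param substrate_valence Integer substrate charge (default -2, a divalent
#'   anion; use 0 for a neutral sugar).
#' @param na_ratio,s_ratio In/out concentration ratios, used when `gradients`
#'   is `NULL`.
#' @param ion,substrate Species names used to look ratios up in `gradients`.
#' @param slope mV per decade, 60 by default.
#' @return A data frame of class `candidate_predictions` with columns `n`,
#'   `m`, `e_rev` (mV, `NA` for electroneutral candidates) and
#'   `electroneutral`.
#' @examples
#' predict_candidate_potentials(list(c(1, 1), c(3, 1), c(4, 1)),
#'                              na_ratio = 0.25, s_ratio = 10)
#' @export
predict_candidate_potentials <- function(candidates, gradients = NULL,
                                         substrate_valence = -2,
                                         na_ratio = NULL, s_ratio = NULL,
                                         ion = "Na", substrate = NULL,
                                         slope = 60) {
  cand <- .normalize_candidates(candidates)
  rat <- .design_ratios(gradients, na_ratio, s_ratio, ion, substrate)
  e_rev <- numeric(nrow(cand))
  neutral <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    q <- cand$n[i] + cand$m[i] * substrate_valence
    if (abs(q) < 1e-12) {
      e_rev[i] <- NA_real_
      neutral[i] <- TRUE
    } else {
      e_rev[i] <- -slope * (cand$n[i] * log10(rat$na_ratio) +
                            cand$m[i] * log10(rat$s_ratio)) / q
    }
  }
  out <- data.frame(n = cand$n, m = cand$m, e_rev = e_rev,
                    electroneutral = neutral)
  attr(out, "na_ratio") <- rat$na_ratio
  attr(out, "s_ratio") <- rat$s_ratio
  attr(out, "substrate_valence") <- substrate_valence
  class(out) <- c("candidate_predictions", "data.frame")
  out
}

#' @export
print.candidate_predictions <- function(x, ...) {
  cat("Candidate reversal potentials",
      sprintf("(z_S = %+g, [ion]in/out = %.4g, [S]in/out = %.4g):\n",
              attr(x, "substrate_valence"), attr(x, "na_ratio"),
              attr(x, "s_ratio")))
  df <- as.data.frame(x)
  df$E_rev_mV <- ifelse(df$electroneutral, "electroneutral",
                        sprintf("%+d", round(df$e_rev)))
  print(df[, c("n", "m", "E_rev_mV")], row.names = FALSE)
  invisible(x)
}

#' Are candidate predictions separable by the voltage clamp?
#'
#' The K+/valinomycin "chemical patch clamp" sets voltages only coarsely, so
#' candidate reversal potentials must differ by more than the clamp's
#' resolution to be distinguished experimentally. Fails when any pair of
#' electrogenic predictions lies closer than `min_separation_mV`.
#'
#' @param predictions A `candidate_predictions` table (or any data frame with
#'   an `e_rev` column), or a numeric vector of predicted potentials.
#' @param min_separation_mV Minimum resolvable separation, default 15 mV.
#' @return A list of class `separability_check` with elements `pass`,
#'   `min_separation_mV` (the closest observed pair distance, `NA` when fewer
#'   than two electrogenic predictions) and `pair` (indices of that pair).
#' @examples
#' check_separability(c(0, 62, 46.5))   # pass (closest pair 15.5 mV)
#' check_separability(c(48.4, 42.2))    # fail (6.2 mV)
#' @export
check_separability <- function(predictions, min_separation_mV = 15) {
  e <- if (is.data.frame(predictions)) predictions$e_rev else as.numeric(predictions)
  e <- e[is.finite(e)]
  if (length(e) < 1L)
    stop("at least one electrogenic prediction is required", call. = FALSE)
  if (length(e) < 2L) {
    out <- list(pass = TRUE, min_separation_mV = NA_real_, pair = NULL,
                threshold_mV = min_separation_mV)
  } else {
    d <- abs(outer(e, e, "-"))
    d[upper.tri(d, diag = TRUE)] <- Inf
    i <- which(d == min(d), arr.ind = TRUE)[1L, ]
    out <- list(pass = min(d) >= min_separation_mV,
                min_separation_mV = min(d),
                pair = sort(unname(i)), threshold_mV = min_separation_mV)
  }
  class(out) <- "separability_check"
  out
}

#' @export
print.separability_check <- function(x, ...) {
  cat(sprintf("Separability (threshold %g mV): %s", x$threshold_mV,
              if (x$pass) "pass" else "FAIL"))
  if (!is.na(x$min_separation_mV))
    cat(sprintf(" -- closest pair %g and %g, %.1f mV apart",
                x$pair[1], x$pair[2], x$min_separation_mV))
  cat("\n")
  invisible(x)
}

#' Solve gradients placing two candidate reversal potentials at chosen targets
#'
#' Inverse design: given two distinct electrogenic candidates and the voltages
#' their reversal potentials should sit at, solves the 2x2 linear system in
#' `log10(na_ratio)` and `log10(s_ratio)` so that both targets are met
#' simultaneously. This is how experimental gradients are chosen to spread
#' candidate predictions far enough apart to be resolved.
#'
#' @param candidate_a,candidate_b Candidate stoichiometries `c(n, m)`; both
#'   must be electrogenic and must not constrain the same gradient direction.
#' @param target_a,target_b Target reversal potentials in mV.
#' @param substrate_valence Integer substrate charge, default -2.
#' @param slope mV per decade, 60 by default.
#' @return Named numeric vector `c(na_ratio, s_ratio)`.
#' @examples
#' # put 1:1 at 0 mV and 3:1 at +62 mV
#' solve_gradients_for_targets(c(1, 1), 0, c(3, 1), 62)
#' @export
solve_gradients_for_targets <- function(candidate_a, target_a,
                                        candidate_b, target_b,
                                        substrate_valence = -2, slope = 60) {
  row_for <- function(cand, target) {
    n <- cand[[1L]]; m <- cand[[2L]]
    stopifnot(n > 0, m > 0)
    q <- n + m * substrate_valence
    if (abs(q) < 1e-12)
      stop(sprintf("candidate %g:%g is electroneutral and cannot have a ",
                   n, m), "target reversal potential", call. = FALSE)
    list(coef = c(n, m), rhs = -target * q / slope)
  }
  a <- row_for(candidate_a, target_a)
  b <- row_for(candidate_b, target_b)
  A <- rbind(a$coef, b$coef)
  if (abs(det(A)) < 1e-10)
    stop("degenerate candidate pair: both candidates constrain the same ",
         "combination of gradients", call. = FALSE)
  sol <- solve(A, c(a$rhs, b$rhs))
  c(na_ratio = 10^sol[[1L]], s_ratio = 10^sol[[2L]])
}

#' External potassium for a target clamp voltage
#'
#' With valinomycin the membrane voltage sits at the potassium Nernst
#' potential, so the external K+ that clamps the membrane at `target_mV` given
#' internal K+ is `k_out = k_in * 10^(target_mV/slope)`.
#'
#' @param k_in Internal K+ concentration (mM), > 0.
#' @param target_mV Desired clamp voltage in mV.
#' @param slope mV per decade, 60 by default.
#' @return External K+ concentration in mM.
#' @examples
#' potassium_for_voltage(100, +60) # 1000 mM
#' @export
potassium_for_voltage <- function(k_in, target_mV, slope = 60) {
  stopifnot(is.numeric(k_in), k_in > 0, is.numeric(target_mV))
  k_in * 10^(target_mV / slope)
}

#' K+/valinomycin clamp composition
#'
#' @param k_in Internal K+ (mM), > 0.
#' @param target_voltage Desired clamp voltage (mV).
#' @param slope mV per decade.
#' @return A list of class `clamp_spec` with `k_in`, `k_out`, `valinomycin`
#'   and `target_voltage`; `nernst_potential(+1, k_in/k_out)` equals the
#'   target.
#' @export
clamp_spec <- function(k_in, target_voltage, slope = 60) {
  k_out <- potassium_for_voltage(k_in, target_voltage, slope = slope)
  structure(list(k_in = k_in, k_out = k_out, valinomycin = TRUE,
                 target_voltage = target_voltage),
            class = "clamp_spec")
}

#' Buffer composition with ideal osmotic accounting
#'
#' Describes one side of the membrane: named salt concentrations (mM) with a
#' per-salt osmotic particle count (2 for a fully dissociating monovalent salt
#' such as NaCl, KCl or choline chloride), a choline chloride filler used to
#' balance osmolarity between sides, and a fixed 20 mM Tris/HEPES pH 7.5
#' background common to all solutions.
#'
#' @param salts Named numeric vector of salt concentrations in mM (all >= 0).
#' @param particles Osmotic particles per formula unit: a single number
#'   recycled over salts, or a named vector; default 2.
#' @param choline_cl Choline chloride filler concentration (mM).
#' @param background_mM Buffer background concentration (mM), default 20.
#' @param background_particles Osmotic particles counted for the background
#'   (identical on both sides, so its value never affects balancing).
#' @return A list of class `buffer_spec`.
#' @examples
#' inside <- buffer_spec(c(KCl = 199, NaCl = 1))
#' osmolarity(inside) # 420 mOsm including the 20 mM background
#' @export
buffer_spec <- function(salts = numeric(), particles = 2, choline_cl = 0,
                        background_mM = 20, background_particles = 1) {
  salts <- unlist(salts)
  if (length(salts) && (is.null(names(salts)) || any(!nzchar(names(salts)))))
    stop("`salts` must be a named vector of mM concentrations", call. = FALSE)
  if (any(salts < 0) || choline_cl < 0)
    stop("salt concentrations must be nonnegative", call. = FALSE)
  if (length(particles) == 1L)
    particles <- setNames(rep(particles, length(salts)), names(salts))
  if (length(salts) && !all(names(salts) %in% names(particles)))
    stop("`particles` must cover every salt", call. = FALSE)
  structure(list(salts = salts, particles = particles[names(salts)],
                 choline_cl = choline_cl, background_mM = background_mM,
                 background_particles = background_particles),
            class = "buffer_spec")
}

#' Ideal (van 't Hoff) osmolarity of a buffer
#'
#' @param buffer A [buffer_spec()].
#' @return Osmolarity in mOsm, counting `conc * particles` for each salt, two
#'   particles per mM of choline chloride filler, and the buffer background.
#' @export
osmolarity <- function(buffer) {
  stopifnot(inherits(buffer, "buffer_spec"))
  sum(buffer$salts * buffer$particles) + 2 * buffer$choline_cl +
    buffer$background_mM * buffer$background_particles
}

#' Balance a buffer against a reference with choline chloride
#'
#' Adds choline chloride filler to `adjustable` so its ideal osmolarity equals
#' that of `reference`. Errors when `adjustable` is already hyperosmotic
#' relative to the reference (filler cannot be negative).
#'
#' @param reference,adjustable [buffer_spec()] objects.
#' @param tol Numerical tolerance on the osmotic deficit (mOsm).
#' @return `adjustable` with its `choline_cl` filler increased so both sides
#'   are isosmotic.
#' @examples
#' ref <- buffer_spec(c(KCl = 199, NaCl = 1))
#' balance_osmolarity(ref, buffer_spec(c(NaCl = 100)))$choline_cl # 100 mM
#' @export
balance_osmolarity <- function(reference, adjustable, tol = 1e-9) {
  deficit <- osmolarity(reference) - osmolarity(adjustable)
  if (deficit < -tol)
    stop(sprintf("adjustable buffer is hyperosmotic by %.3g mOsm; ",
                 -deficit), "cannot add negative filler", call. = FALSE)
  adjustable$choline_cl <- adjustable$choline_cl + max(deficit, 0) / 2
  adjustable
}

#' Design a reversal-potential experiment
#'
#' Bundles the forward design steps: candidate predictions under the chosen
#' gradients (or gradients solved from two target voltages), a separability
#' check, K+/valinomycin clamp compositions for each finite predicted voltage,
#' and osmotically balanced internal/external buffer compositions.
#'
#' @inheritParams predict_candidate_potentials
#' @param targets Optional inverse-design specification: a list
#'   `list(candidate_a =, target_a =, candidate_b =, target_b =)` passed to
#'   [solve_gradients_for_targets()]; overrides `gradients`/ratios.
#' @param k_in Internal K+ (mM) for the clamp, default 10.
#' @param na_in_mM Internal Na+ (mM); external Na+ is `na_in_mM / na_ratio`.
#' @param internal Optional [buffer_spec()] for the internal solution;
#'   defaults to NaCl/KCl at the above concentrations plus 300 mM choline
#'   chloride headroom so external solutions can be balanced up to it.
#' @param extra_voltages Additional clamp voltages (mV) to include, e.g. a
#'   proof-of-reversal voltage beyond every candidate's prediction.
#' @param min_separation_mV Separability threshold.
#' @return A list of class `transport_design` with elements `predictions`,
#'   `separability`, `clamps` (data frame), `buffers` (data frame, one row per
#'   solution) and `ratios`.
#' @export
design_experiment <- function(candidates, gradients = NULL,
                              substrate_valence = -2,
                              na_ratio = NULL, s_ratio = NULL,
                              targets = NULL,
                              k_in = 10, na_in_mM = 25, internal = NULL,
                              extra_voltages = numeric(),
                              min_separation_mV = 15, slope = 60) {
  if (!is.null(targets)) {
    sol <- solve_gradients_for_targets(targets$candidate_a, targets$target_a,
                                       targets$candidate_b, targets$target_b,
                                       substrate_valence = substrate_valence,
                                       slope = slope)
    na_ratio <- sol[["na_ratio"]]
    s_ratio <- sol[["s_ratio"]]
    gradients <- NULL
  }
  preds <- predict_candidate_potentials(candidates, gradients = gradients,
                                        substrate_valence = substrate_valence,
                                        na_ratio = na_ratio, s_ratio = s_ratio,
                                        slope = slope)
  sep <- check_separability(preds, min_separation_mV = min_separation_mV)
  # report clamp voltages to the nearest integer mV, halves away from zero
  round_mv <- function(x) sign(x) * floor(abs(x) + 0.5)
  voltages <- sort(unique(c(round_mv(preds$e_rev[is.finite(preds$e_rev)]),
                            round_mv(extra_voltages))))
  if (is.null(internal))
    internal <- buffer_spec(c(NaCl = na_in_mM, KCl = k_in), choline_cl = 300)
  na_out <- na_in_mM / attr(preds, "na_ratio")
  clamps <- data.frame(voltage_mV = voltages, k_in_mM = k_in,
                       k_out_mM = potassium_for_voltage(k_in, voltages,
                                                        slope = slope))
  buf_rows <- list(data.frame(side = "internal", voltage_mV = NA_real_,
                              NaCl_mM = na_in_mM, KCl_mM = k_in,
                              CholineCl_mM = internal$choline_cl,
                              TrisHEPES_mM = internal$background_mM,
                              mOsm = osmolarity(internal)))
  for (i in seq_len(nrow(clamps))) {
    ext <- buffer_spec(c(NaCl = na_out, KCl = clamps$k_out_mM[i]))
    ext <- balance_osmolarity(internal, ext)
    buf_rows[[length(buf_rows) + 1L]] <-
      data.frame(side = "external", voltage_mV = clamps$voltage_mV[i],
                 NaCl_mM = na_out, KCl_mM = clamps$k_out_mM[i],
                 CholineCl_mM = ext$choline_cl,
                 TrisHEPES_mM = ext$background_mM, mOsm = osmolarity(ext))
  }
  structure(list(predictions = preds, separability = sep, clamps = clamps,
                 buffers = do.call(rbind, buf_rows),
                 ratios = c(na_ratio = attr(preds, "na_ratio"),
                            s_ratio = attr(preds, "s_ratio")),
                 substrate_valence = substrate_valence),
            class = "transport_design")
}

#' @export
print.transport_design <- function(x, ...) {
  print(x$predictions)
  print(x$separability)
  cat("Clamp compositions (mM):\n")
  df <- x$clamps
  df$k_out_mM <- round(df$k_out_mM, 1)
  print(df, row.names = FALSE)
  invisible(x)
}
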