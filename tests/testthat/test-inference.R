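test_that("deltaCPM is initial minus later counts, positive for efflux", {
  tc <- flux_time_course(12, c(0, 60), rbind(c(1000, 1000), c(1400, 1400)))
  d <- delta_cpm(tc, 0, 60)
  expect_equal(d$mean, -400) # counts gained: influx
  expect_equal(d$replicates, c(-400, -400))
  flat <- flux_time_course(48, c(0, 30), rbind(c(500, 500), c(500, 500)))
  expect_equal(delta_cpm(flat, 0, 30)$mean, 0)
  out <- flux_time_course(84, c(0, 30), rbind(c(1000, 1000), c(600, 600)))
  expect_equal(delta_cpm(out, 0, 30)$mean, 400) # counts lost: efflux
  expect_error(delta_cpm(tc, 0, 45), "not present")
})

test_that("deltaCPM sign is always opposite to the fitted slope sign", {
  for (seed in 1:5) {
    expt <- succinate_experiment(seed)
    for (tc in expt$courses) {
      sl <- classify_flux(tc)$slope
      d <- delta_cpm(tc, 0, 60)$mean
      if (abs(sl) > 1) expect_lt(sl * d, 0)
    }
  }
})

test_that("early-timepoint normalization rescales to 1 and is shape-preserving", {
  tc <- flux_time_course(10, c(5, 30, 60),
                         rbind(c(2000, 2200), c(2400, 2600), c(2800, 3000)))
  norm <- normalize_by_early_timepoint(tc, 5)
  expect_equal(mean(norm$cpm[1, ]), 1.0)
  # a twofold brighter course normalizes to the identical trajectory
  tc2 <- flux_time_course(10, c(5, 30, 60), tc$cpm * 2)
  expect_equal(normalize_by_early_timepoint(tc2, 5)$cpm, norm$cpm)
  expect_error(normalize_by_early_timepoint(tc, 4), "not present")
  zero <- flux_time_course(10, c(5, 30, 60), matrix(0, 3, 2))
  expect_error(normalize_by_early_timepoint(zero, 5), "positive")
})

test_that("flux classification calls the simulated directions", {
  expt <- succinate_experiment(seed = 7)
  expect_equal(classify_flux(expt$courses[["12"]])$direction, "influx")
  expect_equal(classify_flux(expt$courses[["84"]])$direction, "efflux")
  call48 <- classify_flux(expt$courses[["48"]])
  # direction is "none" exactly when the CI contains zero
  for (call in lapply(expt$courses, classify_flux)) {
    contains0 <- call$ci[1] <= 0 && call$ci[2] >= 0
    expect_equal(call$direction == "none", contains0)
  }
  short <- flux_time_course(0, c(0, 30), rbind(c(1, 1), c(2, 2)))
  expect_error(classify_flux(short), "3 timepoints")
  lone <- flux_time_course(0, c(0, 30, 60), matrix(1:3, ncol = 1))
  expect_error(classify_flux(lone), "2 replicates")
})

test_that("the no-flux test is roughly calibrated on null courses", {
  # courses simulated exactly at the reversal potential carry no signal
  e <- reversal_potential(vcindy_cycle(), vcindy_gradients())
  hits <- vapply(1:200, function(s) {
    tc <- simulate_time_course(vcindy_cycle(), vcindy_gradients(), e,
                               params = flux_params(seed = 1000 + s))
    classify_flux(tc)$direction != "none"
  }, logical(1))
  expect_lt(mean(hits), 0.12) # coarse bound; full calibration in acceptance
})

test_that("direction calls are invariant under early-timepoint normalization", {
  expt <- simulate_experiment(c(12, 48, 84), vcindy_cycle(), vcindy_gradients(),
                              params = flux_params(baseline_jitter_cv = 0.2,
                                                   seed = 13),
                              timepoints = c(5, 15, 30, 45, 60, 90, 120))
  for (tc in expt$courses) {
    raw <- classify_flux(tc)$direction
    norm <- classify_flux(normalize_by_early_timepoint(tc, 5))$direction
    expect_equal(norm, raw)
  }
})

test_that("reversal potential estimation uses no-flux voltages and interpolation", {
  calls <- list(flux_call(12, "influx"), flux_call(48, "none"),
                flux_call(84, "efflux"))
  est <- estimate_reversal_potential(calls)
  expect_equal(est$estimate, 48)
  expect_equal(est$bracket, c(12, 84))
  # zero crossing of the deltaCPM curve when no clean no-flux call exists
  calls2 <- list(flux_call(40, "influx"), flux_call(60, "efflux"))
  dd <- data.frame(voltage = c(40, 60), mean = c(-200, 200))
  est2 <- estimate_reversal_potential(calls2, dd)
  expect_equal(est2$estimate, 50)
  expect_equal(est2$bracket, c(40, 60))
  expect_error(estimate_reversal_potential(
    list(flux_call(12, "influx"), flux_call(84, "influx"))), "bracketed")
  expect_error(estimate_reversal_potential(
    list(flux_call(12, "none"), flux_call(84, "none"))), "bracketed")
})

test_that("the bracket always contains the point estimate", {
  for (seed in 1:5) {
    fit <- fit_stoichiometry(succinate_experiment(seed), succinate_candidates,
                             gradients = vcindy_gradients())
    est <- fit$e_rev
    expect_gte(est$estimate, est$bracket[1])
    expect_lte(est$estimate, est$bracket[2])
  }
})

test_that("candidates are excluded where flux was seen and assigned where it was not", {
  # gradients placing 1:1 at 0 mV and 3:1 at +62 mV (4:1 then lands at 46.5)
  sol <- solve_gradients_for_targets(c(1, 1), 0, c(3, 1), 62)
  preds <- predict_candidate_potentials(list(c(1, 1), c(3, 1), c(4, 1)),
                                        na_ratio = sol[["na_ratio"]],
                                        s_ratio = sol[["s_ratio"]])
  calls <- list(flux_call(0, "influx"), flux_call(47, "influx"),
                flux_call(62, "none"), flux_call(80, "efflux"))
  res <- assign_stoichiometry(preds, calls, estimate_reversal_potential(calls))
  expect_equal(res$assigned$n, 3)
  expect_equal(res$assigned$m, 1)
  expect_equal(sort(res$excluded$n), c(1, 4))
  expect_match(res$excluded$reason[res$excluded$n == 1], "net flux")
  # flux observed at every candidate's prediction: everything excluded
  calls_all <- list(flux_call(0, "influx"), flux_call(47, "influx"),
                    flux_call(62, "influx"), flux_call(80, "efflux"))
  res2 <- assign_stoichiometry(preds, calls_all, 70)
  expect_null(res2$assigned)
  expect_equal(nrow(res2$excluded), 3)
  # nearest-candidate rule under the 1:4 / 10:1 gradients, estimate 48
  preds3 <- predict_candidate_potentials(list(c(1, 1), c(3, 1), c(4, 1)),
                                         na_ratio = 0.25, s_ratio = 10)
  calls3 <- list(flux_call(12, "influx"), flux_call(48, "none"),
                 flux_call(84, "efflux"))
  res3 <- assign_stoichiometry(preds3, calls3, 48)
  expect_equal(res3$assigned$n, 3)
  # electroneutral candidates are flagged and excluded, never assigned
  preds4 <- predict_candidate_potentials(succinate_candidates,
                                         na_ratio = 0.25, s_ratio = 10)
  res4 <- assign_stoichiometry(preds4, calls3, 48)
  expect_true(any(res4$excluded$n == 2))
  expect_match(res4$excluded$reason[res4$excluded$n == 2], "electroneutral")
})

test_that("marginal flux calls do not exclude, decisive ones do", {
  preds <- predict_candidate_potentials(list(c(3, 1)), na_ratio = 0.25,
                                        s_ratio = 10) # 48.4 mV
  weak <- list(flux_call(12, "influx", p = 1e-6),
               flux_call(48, "influx", p = 0.03), # marginal
               flux_call(84, "efflux", p = 1e-6))
  dd <- data.frame(voltage = c(12, 48, 84), mean = c(-3000, -100, 1700))
  est <- estimate_reversal_potential(weak, dd)
  res <- assign_stoichiometry(preds, weak, est)
  expect_equal(res$assigned$n, 3) # not excluded by a p = 0.03 call
  strong <- weak
  strong[[2]] <- flux_call(48, "influx", p = 1e-4)
  res2 <- assign_stoichiometry(preds, strong, est)
  expect_null(res2$assigned)
})

test_that("the full fit recovers 3:1 and exposes the modelling methods", {
  expt <- succinate_experiment(seed = 1)
  fit <- fit_stoichiometry(expt, succinate_candidates,
                           gradients = vcindy_gradients())
  expect_s3_class(fit, "stoich_fit")
  co <- coef(fit)
  expect_equal(unname(co[c("n", "m")]), c(3, 1))
  expect_equal(unname(co[["e_rev"]]), 48, tolerance = 0.1)
  expect_output(print(fit), "3 : 1")
  expect_output(print(summary(fit)), "deltaCPM")
  # predict: same gradients, new candidates
  p5 <- predict(fit, candidates = list(c(5, 1)))
  expect_equal(p5$e_rev, reversal_potential_eq1(5, 1, 0.25, 10))
  # residuals: one vector per voltage, zero mean by OLS construction
  res <- residuals(fit)
  expect_named(res, c("12", "48", "84"))
  for (r in res) expect_equal(mean(r), 0, tolerance = 1e-9)
  # plot runs silently on a null device
  grDevices::pdf(NULL)
  on.exit(grDevices::dev.off())
  expect_silent(plot(fit))
  # simulate: parametric regeneration from the assigned cycle
  sim <- simulate(fit, seed = 99)
  expect_s3_class(sim, "flux_experiment")
  expect_named(sim$courses, c("12", "48", "84"))
  refit <- fit_stoichiometry(sim, succinate_candidates,
                             gradients = vcindy_gradients())
  expect_equal(coef(refit)[["n"]], 3)
})

test_that("leak handling restricts the analysis window to early timepoints", {
  e <- reversal_potential(vcindy_cycle(), vcindy_gradients())
  p <- flux_params(leak_rate = 0.02, leak_onset = 30, seed = 17)
  expt <- simulate_experiment(c(12, round(e), 84), vcindy_cycle(),
                              vcindy_gradients(), params = p)
  # with the full window the leak masquerades as efflux at the no-flux voltage
  full <- classify_flux(expt$courses[[2]])
  expect_equal(full$direction, "efflux")
  fit <- fit_stoichiometry(expt, succinate_candidates,
                           gradients = vcindy_gradients(), leak = TRUE)
  expect_equal(fit$options$window, c(0, 30))
  expect_equal(coef(fit)[["n"]], 3)
  expect_true(all(fit$delta$eval_time <= 30))
})

test_that("the pipeline recovers 3:1 reliably and never calls 1:1", {
  assigned <- vapply(1:20, function(seed) {
    fit <- fit_stoichiometry(succinate_experiment(seed), succinate_candidates,
                             gradients = vcindy_gradients())
    n <- coef(fit)[["n"]]
    if (is.na(n)) -1 else n
  }, numeric(1))
  expect_gte(mean(assigned == 3), 0.9)
  expect_false(any(assigned == 1))
})
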