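test_that("objective is zero at an exact fit and positive definite around it", {
  refs <- get_refs()
  # targets generated from the model itself
  tg <- rbind(
    calibration_target("cortisol", "stressed", refs$panel_stressed$cortisol),
    calibration_target("cortisol", "combined", refs$panel_combined$cortisol))
  expect_lt(objective(c(), tg), 1e-10)
  v0 <- default_parameters()$theta[["v_cort"]]
  expect_gt(objective(c(v_cort = 1.1 * v0), tg), 1e-4)
  expect_error(objective(c(), tg[0, ]), "non-empty")
  expect_error(objective(c(bogus = 1), tg), "bogus")
})

test_that("optimizer loss equals an independent residual re-evaluation", {
  refs <- get_refs()
  tg <- rbind(
    calibration_target("ros", "stressed", 180, weight = 2),
    calibration_target("tnfa", "stressed", 2.0e-3, weight = 0.5))
  got <- objective(c(), tg)
  # hand-computed weighted sum of squared relative residuals
  ros <- refs$panel_stressed$ros_percent
  tnf <- refs$panel_stressed$tnfa
  want <- 2 * ((ros - 180) / 180)^2 + 0.5 * ((tnf - 2.0e-3) / 2.0e-3)^2
  expect_equal(got, want, tolerance = 1e-12)
})

test_that("calibrate recovers a perturbed parameter from self-generated targets", {
  refs <- get_refs()
  tg <- rbind(
    calibration_target("cortisol", "stressed", refs$panel_stressed$cortisol,
                       tolerance = 0.01),
    calibration_target("cortisol", "combined", refs$panel_combined$cortisol,
                       tolerance = 0.01))
  v_true <- default_parameters()$theta[["v_cort"]]
  fit <- calibrate(c(v_cort = 1.15 * v_true), tg, budget = 60, n_starts = 2,
                   seed = 4)
  expect_lt(fit$loss, 1e-4)
  expect_lt(abs(fit$par[["v_cort"]] / v_true - 1), 0.02)
  expect_true(fit$converged)
  # the report is reproducible from the returned parameters
  re <- objective(fit$par, tg)
  expect_equal(re, sum(tg$weight * fit$report$residual^2), tolerance = 1e-10)
  expect_error(calibrate(c(v_cort = v_true), tg[0, ]), "non-empty")
  expect_error(calibrate(c(v_cort = v_true), tg, budget = 0), "budget")
})

test_that("the shipped defaults pass every packaged calibration target", {
  tg <- default_calibration_targets()
  refs <- get_refs()
  form <- get_form()
  for (i in seq_len(nrow(tg))) {
    val <- stressnet:::eval_condition(tg$condition[i], tg$marker[i],
                                      refs$params_healthy, form, refs)
    expect_lt(abs(val - tg$value[i]) / tg$value[i], tg$tolerance[i])
  }
})

test_that("literature fixtures are well-formed and dose-monotone", {
  fx <- literature_fixtures()
  expect_true(all(fx$dose_ug_ml > 0))
  expect_true(all(is.finite(fx$effect)))
  g <- fx[fx$source == "gotukola", ]
  expect_true(all(diff(g$effect[order(g$dose_ug_ml)]) > 0))
})
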