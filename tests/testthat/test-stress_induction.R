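test_that("zero severity is the exact identity and apply_stress is pure", {
  p <- default_parameters()
  snap <- p$theta
  p2 <- apply_stress(p, stress_scenario(0, 0, 0))
  expect_identical(p2$theta, p$theta)
  p3 <- apply_stress(p, stressed_scenario())
  expect_identical(p$theta, snap)  # input untouched
  expect_gt(p3$theta[["g_inf"]], 1)
  expect_gt(p3$theta[["g_aox"]], 1)
})

test_that("severities outside the unit interval are rejected", {
  expect_error(stress_scenario(-0.1, 0, 0), "\\[0, 1\\]")
  expect_error(stress_scenario(0, 1.2, 0), "\\[0, 1\\]")
  expect_error(apply_stress(default_parameters(),
                            list(inflammatory = 2, oxidative = 0,
                                 insulin = 0)),
               "\\[0, 1\\]")
})

test_that("full-severity stress pushes every biomarker past its threshold", {
  refs <- get_refs()
  th <- default_thresholds()
  pan <- refs$panel_stressed
  expect_gt(pan$ros_percent, th$ros_percent)
  expect_gt(pan$tnfa, th$tnfa)
  expect_gt(pan$sbp, th$sbp)
  expect_gt(pan$pss, th$pss)
})

test_that("steady-state markers increase monotonically in their severity", {
  refs <- get_refs()
  p <- refs$params_healthy
  grid <- seq(0, 1, by = 0.2)
  ros <- vapply(grid, function(s) {
    ss <- steady_state(apply_stress(p, stress_scenario(0, s, 0)),
                       init = refs$healthy)
    ss[["ros"]]
  }, numeric(1))
  expect_true(all(diff(ros) > -1e-9))
  tnf <- vapply(grid, function(s) {
    ss <- steady_state(apply_stress(p, stress_scenario(s, 0, 0)),
                       init = refs$healthy)
    ss[["tnfa"]]
  }, numeric(1))
  expect_true(all(diff(tnf) > -1e-12))
})

test_that("confirm_stressed flags axes against the healthy baseline", {
  refs <- get_refs()
  expect_false(any(confirm_stressed(refs$healthy, refs$healthy)))
  expect_true(all(confirm_stressed(refs$stressed, refs$healthy)))
  # only cortisol elevated -> only the mental axis
  y <- as.numeric(refs$healthy)
  names(y) <- species_names()
  y["cortisol"] <- 106.7
  flags <- confirm_stressed(species_state(y), refs$healthy)
  expect_identical(unname(flags), c(FALSE, FALSE, FALSE, TRUE))
})
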