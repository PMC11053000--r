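test_that("panel at the healthy baseline carries no stress signal", {
  refs <- get_refs()
  pan <- derive_panel(refs$healthy, refs$healthy)
  expect_equal(pan$ros_percent, 0)
  cls <- classify(pan)
  expect_equal(cls$count, 0)
  expect_equal(cls$category, "none")
})

test_that("the stressed reference panel matches the calibrated anchors", {
  pan <- get_refs()$panel_stressed
  expect_equal(pan$ros_percent, 171.92, tolerance = 1e-3)
  expect_equal(pan$cortisol, 106.7, tolerance = 1e-3)
  expect_equal(pan$tnfa, 2.2e-3, tolerance = 1e-3)
  cls <- classify(pan)
  expect_equal(cls$count, 4)
  expect_equal(cls$category, "four")
})

test_that("classification combinatorics are exact on enumerated panels", {
  th <- default_thresholds()
  lo <- list(ros_percent = 2, tnfa = 1e-5, sbp = 112, pss = 6)
  hi <- list(ros_percent = 50, tnfa = 3e-3, sbp = 150, pss = 30)
  for (mask in 0:15) {
    f <- as.logical(bitwAnd(mask, c(1L, 2L, 4L, 8L)) > 0)
    panel <- data.frame(
      ros_percent = if (f[1]) hi$ros_percent else lo$ros_percent,
      tnfa = if (f[2]) hi$tnfa else lo$tnfa,
      sbp = if (f[3]) hi$sbp else lo$sbp,
      dbp = 70,
      cortisol = 10,
      pss = if (f[4]) hi$pss else lo$pss)
    cls <- classify(panel, th)
    expect_identical(c(cls$oxidative, cls$inflammatory, cls$physical,
                       cls$mental), f)
    expect_equal(cls$count, sum(f))
  }
})

test_that("classification is threshold-monotone", {
  th <- default_thresholds()
  base <- data.frame(ros_percent = 5, tnfa = 1e-4, sbp = 115, dbp = 75,
                     cortisol = 9, pss = 9)
  for (col in c("ros_percent", "tnfa", "sbp", "pss")) {
    up <- base
    up[[col]] <- base[[col]] * 100
    flag <- c(ros_percent = "oxidative", tnfa = "inflammatory",
              sbp = "physical", pss = "mental")[[col]]
    expect_false(classify(base, th)[[flag]])
    expect_true(classify(up, th)[[flag]])
  }
})

test_that("the cortisol-to-PSS map is monotone, bounded and banded", {
  grid <- seq(0, 500, length.out = 400)
  pss <- cortisol_to_pss(grid)
  expect_true(all(diff(pss) >= 0))
  expect_true(all(pss >= 0 & pss <= 40))
  expect_equal(cortisol_to_pss(0), 0)
  expect_gte(floor(cortisol_to_pss(106.7) + 0.5), 27)  # high band
  expect_lte(cortisol_to_pss(8.57), 13)                    # low band
  expect_error(cortisol_to_pss(-1), "non-negative")
})

test_that("SBP increases strictly with the pressor drive", {
  a <- seq(0, 8, length.out = 200)
  sbp <- sbp_from_aldosterone(a)
  expect_true(all(diff(sbp) > 0))
  expect_true(all(sbp >= 90 & sbp <= 200))
  # doubling aldosterone raises SBP
  expect_gt(sbp_from_aldosterone(2), sbp_from_aldosterone(1))
})

test_that("phenotype distribution uses exact count arithmetic", {
  counts <- c(rep(0, 5), rep(1, 3), rep(4, 2))
  d <- phenotype_distribution(counts)
  expect_identical(sum(d), 1)
  expect_equal(unname(d["none"]), 0.5)
  expect_equal(unname(d["four"]), 0.2)
  all_healthy <- rep(0, 10)
  expect_equal(unname(phenotype_distribution(all_healthy)),
               c(0, 0, 0, 0, 1))
  expect_error(phenotype_distribution(integer(0)), "empty")
})

test_that("remission statistics behave at the boundaries", {
  pre <- pop_arm("stressed")
  # post = pre: about half the individuals sit below the arm mean
  rem <- remission_stats(pre, pre)
  expect_true(all(rem$below_stressed_mean > 0.25 &
                    rem$below_stressed_mean < 0.75))
  # fully recovered panels: every fraction is 1
  zero <- pre
  zero$ros_percent <- 0; zero$tnfa <- 1e-6; zero$sbp <- 100; zero$pss <- 3
  rem0 <- remission_stats(pre, zero)
  expect_true(all(rem0$below_stressed_mean == 1))
  expect_true(all(rem0$healthy_band == 1))
  expect_error(remission_stats(pre[0, ], pre[0, ]), "non-empty")
  expect_error(remission_stats(pre, pre[-1, ]), "paired")
})

test_that("healthy-band remission never exceeds the below-mean fraction", {
  pre <- pop_arm("stressed")
  post <- pop_arm("combined")
  rem <- remission_stats(pre, post)
  expect_true(all(rem$healthy_band <= rem$below_stressed_mean + 1e-12))
  expect_true(all(rem$below_stressed_mean >= 0 & rem$below_stressed_mean <= 1))
})
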