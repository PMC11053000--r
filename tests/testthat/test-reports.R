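test_that("the steady-state report reproduces the printed ROS row", {
  out <- tempfile()
  cfg <- run_config(n = 10, out_dir = out)
  tab <- run_steady_state(cfg)
  ros_pre <- tab$value[tab$arm == "stressed" & tab$marker == "ros_percent"]
  ros_post <- tab$value[tab$arm == "combined" & tab$marker == "ros_percent"]
  expect_equal(ros_pre, 171.92, tolerance = 2e-3)
  expect_equal(ros_post, 5.58, tolerance = 2e-3)
  # the fold column equals fold_change() applied to the table's own cells
  fold <- tab$value[tab$arm == "combined" & tab$marker == "fold_ros_percent"]
  expect_equal(fold, fold_change(ros_pre, ros_post), tolerance = 1e-12)
  expect_true(file.exists(file.path(out, "steady_state.csv")))
})

test_that("zero-severity stress collapses every arm onto the healthy row", {
  cfg <- run_config(stress = c(inflammatory = 0, oxidative = 0, insulin = 0),
                    arms = c("stressed", "combined"), n = 10,
                    out_dir = tempfile())
  tab <- run_steady_state(cfg)
  h <- tab[tab$arm == "healthy" & !startsWith(tab$marker, "fold"), ]
  s <- tab[tab$arm == "stressed" & !startsWith(tab$marker, "fold"), ]
  expect_equal(s$value, h$value, tolerance = 1e-6)
})

test_that("reports are byte-identical for identical config and seed", {
  d1 <- tempfile(); d2 <- tempfile()
  run_steady_state(run_config(n = 5, out_dir = d1))
  run_steady_state(run_config(n = 5, out_dir = d2))
  f1 <- file.path(d1, "steady_state.csv")
  f2 <- file.path(d2, "steady_state.csv")
  expect_identical(readLines(f1), readLines(f2))
  # header embeds the seed and config digest
  expect_match(readLines(f1)[1], "seed=1 \\| config=")
})

test_that("population report computes paired statistics per arm", {
  cfg <- run_config(n = 40, seed = 5, arms = c("stressed", "combined"),
                    out_dir = tempfile())
  res <- run_population(cfg)
  expect_true(all(c("population_panels.csv", "population_summary.csv",
                    "population_tests.csv") %in% list.files(cfg$out_dir)))
  # sd uses the n-1 denominator
  pre <- res$panels[res$panels$arm == "stressed", ]
  manual_sd <- sqrt(sum((pre$pss - mean(pre$pss))^2) / (nrow(pre) - 1))
  expect_equal(res$summary$sd[res$summary$arm == "stressed" &
                                res$summary$marker == "pss"],
               manual_sd, tolerance = 1e-12)
  # every marker falls under the combined arm: negative paired t
  expect_true(all(res$tests$t_statistic < 0))
  expect_true(all(res$tests$p_value < 0.005))
  # responder and remission percentages are reported for intervened arms
  comb <- res$summary[res$summary$arm == "combined", ]
  expect_true(all(is.finite(comb$responder_pct)))
  expect_true(all(comb$remission_pct >= 0 & comb$remission_pct <= 100))
})

test_that("phenotype report is consistent and handles the no-stress limit", {
  cfg <- run_config(n = 40, seed = 5, arms = c("stressed", "combined"),
                    out_dir = tempfile())
  pan <- run_population(cfg)$panels
  ph <- run_phenotypes(cfg, panels = pan)
  expect_equal(sum(ph$pre), 1)
  expect_equal(sum(ph$post), 1)
  expect_true(all(ph$residual >= 0 & ph$residual <= 100))
  # all-healthy population: both timepoints are fully stress-free
  cfg0 <- run_config(n = 6, seed = 5, arms = c("stressed", "combined"),
                     out_dir = tempfile())
  pan0 <- pan[pan$id <= 6, ]
  pan0$ros_percent <- 0; pan0$tnfa <- 1e-6; pan0$sbp <- 110; pan0$pss <- 5
  pan0 <- classify_panels(pan0)
  ph0 <- run_phenotypes(cfg0, panels = pan0)
  expect_equal(unname(ph0$pre["none"]), 1)
  expect_equal(unname(ph0$post["none"]), 1)
})

test_that("run configs validate fields and round-trip through JSON", {
  expect_error(run_config(stress = c(bogus = 1)), "unknown stress")
  expect_error(run_config(arms = "placebo"), "arms must be")
  expect_error(run_config(thresholds = list(nope = 1)), "unknown threshold")
  cfg <- run_config(n = 25, seed = 3)
  tmp <- tempfile(fileext = ".json")
  jsonlite::write_json(list(n = 25, seed = 3), tmp, auto_unbox = TRUE)
  cfg2 <- read_run_config(tmp)
  expect_equal(cfg2$n, cfg$n)
  expect_equal(cfg2$seed, cfg$seed)
})
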