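test_that("trivial fixed points of the kinetics hold exactly", {
  p <- default_parameters()
  # empty system: all basal productions zero, all-zero state
  th0 <- p$theta
  th0[startsWith(names(th0), "b_")] <- 0
  th0[["v_ros"]] <- 0  # ROS generation is ungated basal production
  p0 <- new_parameters(th0, p$totals)
  zero <- species_state(setNames(rep(0, 34), species_names()))
  expect_equal(max(abs(rhs(zero, p0))), 0)

  # isolated linear species at production/degradation
  st <- species_state(setNames(rep(1, 34), species_names()))
  st["insulin"] <- p$theta[["b_insulin"]] / p$theta[["d_insulin"]]
  expect_equal(unname(rhs(st, p)["insulin"]), 0)
})

test_that("fast kernel matches the reference rate law on random states", {
  p <- default_parameters()
  th <- list2env(as.list(p$theta))
  set.seed(42)
  for (i in 1:20) {
    y <- random_state()
    expect_lt(max(abs(rhs(y, p) - rhs_kernel(as.numeric(y), th))), 1e-12)
  }
})

test_that("rhs agrees with a finite difference of the integrated trajectory", {
  refs <- get_refs()
  p <- refs$params_stressed
  y0 <- refs$healthy
  dt <- 2.5e-4
  tr <- simulate(y0, p, duration = 2 * dt, output_grid = c(0, dt, 2 * dt),
                 rtol = 1e-10, atol = 1e-12)
  mid <- state_from_row(tr[2, ])
  fd <- (as.numeric(tr[3, species_names()]) -
           as.numeric(tr[1, species_names()])) / (2 * dt)
  an <- rhs(mid, p)
  scale <- max(abs(an))
  expect_lt(max(abs(fd - an)) / scale, 1e-6)
})

test_that("invalid inputs are rejected with the offending field named", {
  p <- default_parameters()
  st <- get_refs()$healthy
  bad <- st
  bad[["ros"]] <- NaN
  expect_error(rhs(bad, p), "ros")
  th <- p$theta
  th[["d_tnfa"]] <- -1
  expect_error(validate_parameters(new_parameters(th, p$totals)), "d_tnfa")
  expect_error(kinetic_parameters(c(no_such_constant = 1)), "no_such_constant")
})

test_that("zero-interaction system follows the analytic exponential decay", {
  p <- linear_limit_parameters()
  th <- p$theta
  th[startsWith(names(th), "b_")] <- 0
  p0 <- new_parameters(th, p$totals)
  y0 <- species_state(setNames(rep(2, 34), species_names()))
  tt <- c(0.2, 0.5, 1)
  tr <- simulate(y0, p0, duration = 1, output_grid = tt,
                 rtol = 1e-10, atol = 1e-14)
  dmap <- c(lps = "d_lps", tnfa = "d_tnfa", cortisol = "d_cort",
            glucose = "d_glucose")
  for (sp in names(dmap)) {
    d <- p0$theta[[dmap[[sp]]]]
    expect_equal(tr[[sp]][match(tt, tr$time)], 2 * exp(-d * tt),
                 tolerance = 1e-6)
  }
})

test_that("linear-limit steady state equals production over degradation", {
  p <- linear_limit_parameters()
  ss <- steady_state(p)
  th <- p$theta
  for (sp in c("lps", "nfkb", "il6", "mda", "crh", "cortisol", "renin")) {
    nm <- sub("cortisol", "cort", sp)
    expect_equal(unname(ss[[sp]]), th[[paste0("b_", nm)]] / th[[paste0("d_", nm)]],
                 tolerance = 1e-9)
  }
  expect_equal(unname(ss[["pirs"]]), 0, tolerance = 1e-9)
  expect_equal(unname(ss[["irs"]]), p$totals[["irs"]], tolerance = 1e-9)
})

test_that("stressed trajectories are non-negative and conserve the pools", {
  set.seed(7)
  for (i in 1:15) {
    p <- random_parameters()
    y0 <- random_state()
    tr <- simulate(y0, p, duration = 15, output_grid = seq(0, 15, by = 0.5),
                   rtol = 1e-8, atol = 1e-10)
    expect_gt(min(as.matrix(tr[, species_names()])), -1e-9)
    expect_lt(max(abs(tr$irs + tr$pirs - p$totals[["irs"]])), 1e-8)
    expect_lt(max(abs(tr$akt + tr$pakt - p$totals[["akt"]])), 1e-8)
  }
})

test_that("cortisol approaches its stressed steady state without oscillation", {
  refs <- get_refs()
  ss <- refs$stressed[["cortisol"]]
  tr <- simulate(refs$healthy, refs$params_stressed, duration = 120,
                 output_grid = seq(0, 120, by = 1))
  gap <- abs(tr$cortisol - ss)
  after <- gap[tr$time >= 5]
  expect_true(all(diff(after) <= 1e-6))
  expect_lt(tail(gap, 1) / ss, 1e-4)
})

test_that("a 35-day intervention run reaches the intervened steady state", {
  refs <- get_refs()
  p_cmb <- apply_intervention(refs$params_stressed, get_form())
  tr <- simulate(refs$stressed, p_cmb, duration = 35,
                 output_grid = c(17.5, 35))
  final <- state_from_row(tr[nrow(tr), ])
  ss <- steady_state(p_cmb, init = refs$healthy)
  big <- as.numeric(ss) > 1e-6
  expect_lt(max(abs((as.numeric(final) - as.numeric(ss))[big] /
                      as.numeric(ss)[big])), 0.005)
})

test_that("the healthy steady state is locally stable and deterministic", {
  refs <- get_refs()
  p <- refs$params_healthy
  ss <- refs$healthy
  y <- as.numeric(ss) * 1.01
  names(y) <- species_names()
  # perturb within the conserved IRS/AKT manifolds (pool sums are neutral
  # directions and cannot relax)
  y["irs"] <- p$totals[["irs"]] - y["pirs"]
  y["akt"] <- p$totals[["akt"]] - y["pakt"]
  pert <- species_state(y)
  tr <- simulate(pert, p, duration = 60, output_grid = c(30, 60))
  final <- as.numeric(tr[nrow(tr), species_names()])
  expect_lt(max(abs(final - as.numeric(ss)) / pmax(as.numeric(ss), 1e-8)),
            1e-4)
  expect_identical(as.numeric(steady_state(p)), as.numeric(steady_state(p)))
})

test_that("fold_change is plain division with domain checks", {
  expect_equal(fold_change(171.92, 5.58), 30.81, tolerance = 1e-3)
  expect_equal(fold_change(106.7, 8.57), 12.45, tolerance = 1e-3)
  expect_equal(fold_change(3.3, 3.3), 1)
  expect_error(fold_change(1, 0), "post_value = 0")
  expect_error(fold_change(-1, 2), "positive")
})

test_that("the packaged topology carries the required signed edges", {
  topo <- network_topology()
  req <- stressnet:::required_edges()
  key <- function(d) paste(d$from, d$to, d$sign)
  expect_true(all(key(req) %in% key(topo)))
  expect_error(network_topology(data.frame(from = "nfkb", to = "wat",
                                           sign = "activate")),
               "unknown species|missing")
  expect_error(network_topology(req[-1, ]), "missing required")
})

test_that("model serialization round-trips", {
  p <- default_parameters()
  tmp <- tempfile(fileext = ".json")
  write_model_json(p, tmp)
  p2 <- read_model_json(tmp)
  expect_equal(p2$theta, p$theta)
  expect_equal(p2$totals, p$totals)
})
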