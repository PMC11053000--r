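test_that("population generation is deterministic and well-formed", {
  a <- generate_population(101, 7)
  b <- generate_population(101, 7)
  expect_identical(a$individuals, b$individuals)
  expect_identical(a$multipliers, b$multipliers)
  ind <- a$individuals
  expect_equal(nrow(ind), 101)
  expect_lte(abs(sum(ind$sex == "male") - sum(ind$sex == "female")), 1)
  expect_true(all(ind$age >= 20 & ind$age <= 80))
  expect_true(all(a$multipliers > 0))
  sev <- as.matrix(ind[, c("sev_inflammatory", "sev_oxidative",
                           "sev_insulin")])
  expect_true(all(sev >= 0 & sev <= 1))
  expect_true(all(ind$response > 0 & ind$response <= 1))
  expect_equal(nrow(generate_population(0, 1)$individuals), 0)
  expect_error(generate_population(-3, 1), "non-negative")
})

test_that("different seeds give different draws; RNG state is restored", {
  set.seed(123)
  before <- .Random.seed
  a <- generate_population(50, 1)
  expect_identical(before, .Random.seed)
  b <- generate_population(50, 2)
  expect_false(identical(a$individuals$sev_inflammatory,
                         b$individuals$sev_inflammatory))
})

test_that("generated severity means converge with population size", {
  cfg <- population_config()
  small <- generate_population(200, 5, cfg)$individuals
  large <- generate_population(2000, 5, cfg)$individuals
  for (ax in c("sev_inflammatory", "sev_oxidative", "sev_insulin",
               "response")) {
    mu_s <- mean(small[[ax]])
    mu_l <- mean(large[[ax]])
    se <- sd(large[[ax]]) * sqrt(1 / 200 + 1 / 2000)
    expect_lt(abs(mu_s - mu_l), 4 * se + 0.01)
  }
})

test_that("arms share individuals so paired differences are defined", {
  pre <- pop_arm("stressed")
  post <- pop_arm("combined")
  expect_identical(pre$id, post$id)
  expect_equal(nrow(pre), 300)
  # paired decline is overwhelmingly positive under the full formulation
  expect_gt(mean(post$ros_percent < pre$ros_percent), 0.99)
})

test_that("population simulation is bit-stable for a fixed seed", {
  pop <- generate_population(12, 99)
  arms <- list(stressed = list(scenario = NULL, formulation = NULL),
               combined = list(scenario = NULL, formulation = get_form()))
  r1 <- simulate_population(pop, arms)
  r2 <- simulate_population(pop, arms)
  expect_identical(r1$panels, r2$panels)
  expect_equal(nrow(r1$failures), 0)
})

test_that("an unstressed, untreated individual stays at the healthy panel", {
  cfg <- population_config()
  cfg$severity <- lapply(cfg$severity, function(x) list(w = 1, lo = 0, hi = 0))
  pop <- generate_population(1, 3, cfg)
  pop$multipliers[] <- 1
  res <- simulate_population(pop, list(base = list(scenario = NULL,
                                                   formulation = NULL)))
  pan <- res$panels
  healthy_pan <- get_refs()$panel_healthy
  expect_equal(pan$ros_percent, healthy_pan$ros_percent, tolerance = 1e-6)
  expect_equal(pan$cortisol, healthy_pan$cortisol, tolerance = 1e-6)
  expect_equal(pan$sbp, healthy_pan$sbp, tolerance = 1e-6)
})

test_that("responder fractions respect their criterion", {
  pre <- pop_arm("stressed")
  post <- pop_arm("combined")
  expect_equal(responder_fraction(pre, pre, "pss"), 0)
  f_all <- responder_fraction(pre, post, "pss", criterion = 1e-9)
  f_deep <- responder_fraction(pre, post, "pss", criterion = 0.95)
  expect_gte(f_all, responder_fraction(pre, post, "pss"))
  expect_gte(responder_fraction(pre, post, "pss"), f_deep)
  expect_error(responder_fraction(pre[0, ], post[0, ], "pss"), "non-empty")
  expect_error(responder_fraction(pre, post, "shoe_size"), "unknown marker")
})
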