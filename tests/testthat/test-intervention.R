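test_that("the packaged formulation has the stated composition", {
  form <- get_form()
  meta <- unique(as.data.frame(form)[, c("ingredient", "class")])
  expect_equal(sum(meta$class == "botanical"), 4)
  expect_equal(sum(meta$class == "vitamin"), 13)
  expect_equal(sum(meta$class == "mineral"), 11)
  expect_false(anyDuplicated(meta$ingredient) > 0)
  expect_true(all(form$potency >= 0 & form$potency < 1))
  expect_true(all(form$node %in% names(stressnet:::node_levers())))
})

test_that("empty formulation is the exact identity", {
  p <- default_parameters()
  empty <- formulation(get_form()[0, ])
  expect_identical(apply_intervention(p, empty)$theta, p$theta)
  # inert ingredient: zero potencies -> zero efficacy
  inert <- ingredient("inert", "vitamin",
                      data.frame(node = "tnfa", direction = "down",
                                 potency = 0))
  eff <- single_ingredient_efficacy(get_refs()$params_stressed,
                                    formulation(inert), "tnfa",
                                    healthy_baseline = get_refs()$healthy)
  expect_equal(eff, 0, tolerance = 1e-6)
})

test_that("ingredient composition is order-independent and multiplicative", {
  p <- default_parameters()
  form <- get_form()
  set.seed(11)
  shuffled <- formulation(as.data.frame(form)[sample(nrow(form)), ])
  expect_equal(apply_intervention(p, form)$theta,
               apply_intervention(p, shuffled)$theta, tolerance = 1e-15)
  # two ingredients on one node compose as a product of (1 - p) factors
  two <- formulation(rbind(
    ingredient("a", "vitamin", data.frame(node = "tnfa", direction = "down",
                                          potency = 0.3)),
    ingredient("b", "mineral", data.frame(node = "tnfa", direction = "down",
                                          potency = 0.5))))
  expect_equal(apply_intervention(p, two)$theta[["m_tnfa"]], 0.7 * 0.5)
})

test_that("unknown target nodes are rejected naming the ingredient", {
  expect_error(ingredient("mystery", "mineral",
                          data.frame(node = "unobtainium",
                                     direction = "down", potency = 0.1)),
               "mystery")
  expect_error(ingredient("hot", "vitamin",
                          data.frame(node = "tnfa", direction = "down",
                                     potency = 1.0)),
               "potency")
})

test_that("efficacy decreases weakly when all potencies are scaled down", {
  refs <- get_refs()
  form <- get_form()
  effs <- vapply(c(0.25, 0.5, 1), function(lam) {
    efficacy_percent(refs$params_stressed, scale_formulation(form, lam),
                     "ros", healthy_baseline = refs$healthy)
  }, numeric(1))
  expect_true(all(diff(effs) > 0))
  expect_equal(efficacy_percent(refs$params_stressed,
                                scale_formulation(form, 0), "ros",
                                healthy_baseline = refs$healthy),
               0, tolerance = 1e-6)
})

test_that("unknown efficacy markers raise a domain error", {
  refs <- get_refs()
  expect_error(single_ingredient_efficacy(refs$params_stressed, "zinc",
                                          "bmi"),
               "unknown marker")
  expect_error(single_ingredient_efficacy(refs$params_stressed,
                                          "not_an_ingredient", "ros"),
               "not found")
})

test_that("formulation serialization round-trips", {
  form <- get_form()
  tmp <- tempfile(fileext = ".json")
  write_formulation_json(form, tmp)
  form2 <- read_formulation_json(tmp)
  expect_equal(as.data.frame(form2), as.data.frame(form), tolerance = 1e-12)
})

test_that("combined efficacy at individual level exceeds every single", {
  refs <- get_refs()
  comb <- combined_efficacy(refs$params_stressed, get_form(), "ros",
                            level = "individual",
                            healthy_baseline = refs$healthy)
  singles <- vapply(c("gotukola", "acerola", "zinc", "vitamin_c"),
                    function(ing) {
    single_ingredient_efficacy(refs$params_stressed, ing, "ros",
                               healthy_baseline = refs$healthy)
  }, numeric(1))
  expect_gt(comb, max(singles))
  expect_gt(comb, 90)  # near-complete reversal of the ROS excess
  expect_error(combined_efficacy(refs$params_stressed, get_form(), "bmi",
                                 level = "individual"),
               "unknown marker")
})
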