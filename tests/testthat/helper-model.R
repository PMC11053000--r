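# Shared fixtures, computed once per test run.

.fixtures <- new.env(parent = emptyenv())

get_refs <- function() {
  if (is.null(.fixtures$refs)) .fixtures$refs <- reference_states()
  .fixtures$refs
}

get_form <- function() {
  if (is.null(.fixtures$form)) .fixtures$form <- default_formulation()
  .fixtures$form
}

# population of 300 with the stressed and combined arms (the CI-scale run
# shared by the acceptance criteria)
get_pop_run <- function() {
  if (is.null(.fixtures$pop_run)) {
    pop <- generate_population(300, 1)
    res <- simulate_population(pop, list(
      stressed = list(scenario = NULL, formulation = NULL),
      combined = list(scenario = NULL, formulation = get_form())))
    .fixtures$pop_run <- list(pop = pop, panels = res$panels)
  }
  .fixtures$pop_run
}

pop_arm <- function(arm) {
  pr <- get_pop_run()
  p <- pr$panels[pr$panels$arm == arm, ]
  p[order(p$id), ]
}

# parameter set with every regulated input disabled: each species relaxes
# to basal production / degradation
linear_limit_parameters <- function() {
  p <- default_parameters()
  th <- p$theta
  th[startsWith(names(th), "v_")] <- 0
  th[c("k_keap", "k_gshros", "k_sodros", "k_catros", "k_gpxros", "k_gshc",
       "k_ampkros", "k_mda", "k_glc_g", "k_glc_i", "kp_irs", "kp_akt")] <- 0
  new_parameters(th, p$totals)
}

# random valid parameter draw: lognormal jitter of the calibrated defaults
random_parameters <- function(sd = 0.15) {
  p <- default_parameters()
  th <- p$theta
  jitter_names <- names(th)[startsWith(names(th), "b_") |
                              startsWith(names(th), "v_") |
                              startsWith(names(th), "d_") |
                              startsWith(names(th), "k")]
  th[jitter_names] <- th[jitter_names] * rlnorm(length(jitter_names), 0, sd)
  new_parameters(th, p$totals)
}

random_state <- function() {
  y <- runif(length(species_names()), 0.05, 3)
  names(y) <- species_names()
  y["tnfa"] <- runif(1, 1e-5, 3e-3)
  y["cortisol"] <- runif(1, 2, 120)
  y["pirs"] <- runif(1, 0, 1); y["irs"] <- 1 - y["pirs"]
  y["pakt"] <- runif(1, 0, 1); y["akt"] <- 1 - y["pakt"]
  species_state(y)
}
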