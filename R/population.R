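#' Virtual-population generation settings
#'
#' Defaults define the study conditions: 1000 adults aged 20-80, equal
#' male:female ratio, per-axis stress severities drawn from calibrated
#' mixtures placing most individuals at high multi-axis stress, lognormal
#' kinetic heterogeneity, and a per-individual intervention-response
#' factor (mixture over full, partial and poor responders). Severity and
#' response mixtures and the multiplier spreads are calibration constants
#' fitted once against the population-level outcome structure (see the
#' methods vignette).
#'
#' @return Named list of generation parameters.
#' @export
population_config <- function() {
  list(
    age_range = c(20, 80),
    # per-axis severity mixtures: weights + samplers over [0,1]
    severity = list(
      inflammatory = list(w = c(0.77, 0.155, 0.06, 0.015),
                          lo = c(0.78, 0.35, 0.15, 0.00),
                          hi = c(1.00, 0.60, 0.30, 0.05)),
      oxidative = list(w = c(0.96, 0.04),
                       lo = c(0.78, 0.00), hi = c(1.00, 0.25)),
      insulin = list(w = c(0.90, 0.10),
                     lo = c(0.70, 0.20), hi = c(1.00, 0.50))
    ),
    # intervention-response factor mixture (full -> poor responders)
    response = list(w = c(0.716, 0.030, 0.240, 0.006, 0.008),
                    lo = c(0.950, 0.800, 0.715, 0.450, 0.300),
                    hi = c(1.000, 0.830, 0.755, 0.550, 0.350)),
    # lognormal multipliers (sdlog) on heterogeneous pathway outputs;
    # each scales the basal and regulated production of its pathway jointly
    multiplier_sdlog = c(tnfa = 0.35, ros = 0.12, cortisol = 0.135,
                         il6 = 0.12, sod = 0.08, aldosterone = 0.06,
                         nfkb = 0.08),
    # responder criterion: relative decline cutoffs per marker (calibrated)
    responder_cutoff = c(ros = 0.85, tnfa = 0.969, pss = 0.655, sbp = 0.50)
  )
}

draw_mixture <- function(n, w, lo, hi) {
  comp <- sample.int(length(w), n, replace = TRUE, prob = w)
  runif(n, lo[comp], hi[comp])
}

#' Generate the in-silico population
#'
#' Deterministic for fixed `(n, seed, config)`. Ages are uniform on
#' 20-80 years; sexes are exactly balanced (+/- 1 for odd `n`); kinetic
#' multipliers are lognormal; per-axis severities and the
#' intervention-response factor are drawn from the configured mixtures.
#'
#' @param n Number of individuals (>= 0).
#' @param seed Integer RNG seed.
#' @param config See [population_config()].
#' @return Object of class `stress_population`: list with `individuals`
#'   (data.frame), `multipliers` (matrix), `seed`, `config`.
#' @export
generate_population <- function(n, seed = 1, config = population_config()) {
  if (!is.numeric(n) || length(n) != 1 || n < 0 || n != round(n)) {
    stop("n must be a non-negative integer")
  }
  n <- as.integer(n)
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  }, add = TRUE)
  set.seed(seed)
  sexes <- rep(c("male", "female"), length.out = n)
  sex <- if (n > 0) sample(sexes) else character(0)
  indiv <- data.frame(
    id = seq_len(n),
    age = if (n > 0) runif(n, config$age_range[1], config$age_range[2])
          else numeric(0),
    sex = sex,
    stringsAsFactors = FALSE
  )
  for (axis in names(config$severity)) {
    mx <- config$severity[[axis]]
    indiv[[paste0("sev_", axis)]] <-
      if (n > 0) draw_mixture(n, mx$w, mx$lo, mx$hi) else numeric(0)
  }
  # individuals with near-zero inflammatory severity form a mild-stress
  # subgroup whose insulin-axis perturbation is correspondingly low
  mild <- indiv$sev_inflammatory < 0.05
  if (any(mild)) {
    indiv$sev_insulin[mild] <- pmin(indiv$sev_insulin[mild],
                                    runif(sum(mild), 0, 0.2))
  }
  rs <- config$response
  indiv$response <- if (n > 0) draw_mixture(n, rs$w, rs$lo, rs$hi)
                    else numeric(0)
  sdl <- config$multiplier_sdlog
  mult <- matrix(1, nrow = n, ncol = length(sdl),
                 dimnames = list(NULL, names(sdl)))
  if (n > 0) {
    for (j in names(sdl)) mult[, j] <- rlnorm(n, meanlog = 0, sdlog = sdl[[j]])
  }
  structure(list(individuals = indiv, multipliers = mult, seed = seed,
                 config = config),
            class = "stress_population")
}

#' @export
print.stress_population <- function(x, ...) {
  cat("<stress_population> n =", nrow(x$individuals), " seed =", x$seed, "\n")
  invisible(x)
}

# pathway multiplier -> jointly scaled production constants
multiplier_map <- function() {
  list(tnfa = c("b_tnfa", "v_tnfa"), ros = c("b_ros", "v_ros"),
       cortisol = c("b_cort", "v_cort"), il6 = c("b_il6", "v_il6"),
       sod = c("b_sod", "v_sod"), aldosterone = c("b_aldo", "v_aldo"),
       nfkb = c("b_nfkb", "v_nfkb"))
}

individual_parameters <- function(pop, i, base_params) {
  th <- base_params$theta
  mm <- multiplier_map()
  m <- pop$multipliers[i, ]
  for (nm in intersect(names(m), names(mm))) {
    th[mm[[nm]]] <- th[mm[[nm]]] * m[[nm]]
  }
  new_parameters(th, base_params$totals)
}

individual_scenario <- function(pop, i) {
  ind <- pop$individuals[i, ]
  stress_scenario(inflammatory = ind$sev_inflammatory,
                  oxidative = ind$sev_oxidative,
                  insulin = ind$sev_insulin)
}

#' Simulate a population across intervention arms
#'
#' For each arm and individual: applies that individual's stress
#' severities (or the arm's override scenario), applies the arm's
#' formulation scaled by the individual's response factor, solves to
#' steady state and derives the biomarker panel. Arms share individuals
#' (paired design). A per-individual solver failure is recorded as a
#' flagged missing row; the run aborts only if more than 1% of
#' individuals fail.
#'
#' @param pop `stress_population`.
#' @param arms Named list; each element a list with `scenario`
#'   (`stress_scenario` or `NULL` for the individual's own severities)
#'   and `formulation` (`formulation` or `NULL` for none).
#' @param params Healthy `kinetic_parameters`.
#' @param thresholds See [default_thresholds()].
#' @return List with `panels` (data.frame: arm, id, markers, flags) and
#'   `failures` (data.frame of arm/id), carrying the population seed.
#' @export
simulate_population <- function(pop, arms, params = default_parameters(),
                                thresholds = default_thresholds()) {
  stopifnot(inherits(pop, "stress_population"))
  if (!is.list(arms) || length(arms) == 0) stop("arms must be a non-empty list")
  if (is.null(names(arms)) || any(names(arms) == "")) {
    names(arms) <- paste0("arm", seq_along(arms))
  }
  refs <- reference_states(params)
  n <- nrow(pop$individuals)
  out <- vector("list", length(arms) * max(n, 1))
  fails <- list()
  k <- 0L
  for (i in seq_len(n)) {
    p_i <- individual_parameters(pop, i, params)
    # each individual's biomarkers are referenced to their own healthy state
    healthy_i <- tryCatch(steady_state(p_i, init = refs$healthy),
                          error = function(e) refs$healthy)
    scen_i <- individual_scenario(pop, i)
    for (arm_name in names(arms)) {
      arm <- arms[[arm_name]]
      k <- k + 1L
      scen <- if (is.null(arm$scenario)) scen_i else arm$scenario
      p_arm <- apply_stress(p_i, scen)
      has_form <- !is.null(arm$formulation) && nrow(arm$formulation) > 0
      if (has_form) {
        rho <- pop$individuals$response[i]
        p_arm <- apply_intervention(p_arm,
                                    scale_formulation(arm$formulation, rho))
      }
      init <- if (has_form) refs$combined else refs$stressed
      st <- tryCatch(steady_state(p_arm, init = init),
                     error = function(e) NULL)
      if (is.null(st)) {
        st <- tryCatch(steady_state(p_arm, init = NULL),
                       error = function(e) NULL)
      }
      if (is.null(st)) {
        fails[[length(fails) + 1L]] <- data.frame(arm = arm_name, id = i)
        next
      }
      panel <- derive_panel(st, healthy_i, thresholds)
      out[[k]] <- data.frame(arm = arm_name, id = pop$individuals$id[i],
                             panel,
                             ros = as.numeric(st[["ros"]]),
                             aldosterone = as.numeric(st[["aldosterone"]]),
                             stringsAsFactors = FALSE)
    }
  }
  failures <- if (length(fails)) do.call(rbind, fails)
              else data.frame(arm = character(0), id = integer(0))
  if (n > 0 && nrow(failures) > 0.01 * n * length(arms)) {
    stop("more than 1% of individual simulations failed (",
         nrow(failures), " of ", n * length(arms), ")")
  }
  panels <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  panels <- classify_panels(panels, thresholds)
  structure(list(panels = panels, failures = failures, seed = pop$seed),
            class = "population_result")
}

#' Vectorised classification of a panel table
#'
#' @param panels data.frame with the biomarker panel columns.
#' @param thresholds See [default_thresholds()].
#' @return `panels` with added logical flag columns and `count`.
#' @export
classify_panels <- function(panels, thresholds = default_thresholds()) {
  panels$oxidative <- panels$ros_percent > thresholds$ros_percent
  panels$inflammatory <- panels$tnfa > thresholds$tnfa
  panels$physical <- panels$sbp > thresholds$sbp
  panels$mental <- round_half_up(panels$pss) > thresholds$pss
  panels$count <- panels$oxidative + panels$inflammatory +
    panels$physical + panels$mental
  panels
}

#' Responder fraction under a relative-decline criterion
#'
#' @param pre_panels,post_panels Paired panel data.frames (same ids).
#' @param marker One of `"ros"`, `"tnfa"`, `"pss"`, `"sbp"`.
#' @param criterion Relative-decline cutoff in (0, 1); defaults to the
#'   calibrated per-marker cutoff in [population_config()].
#' @return Fraction of individuals in [0, 1] whose marker declined by
#'   more than the cutoff.
#' @export
responder_fraction <- function(pre_panels, post_panels, marker,
                               criterion = NULL) {
  if (NROW(pre_panels) == 0 || NROW(post_panels) == 0) {
    stop("responder_fraction requires non-empty paired panels")
  }
  if (NROW(pre_panels) != NROW(post_panels)) {
    stop("pre/post panels must be paired")
  }
  col <- switch(marker, ros = "ros_percent", tnfa = "tnfa", pss = "pss",
                sbp = "aldosterone",
                stop("unknown marker '", marker, "'"))
  if (is.null(criterion)) {
    criterion <- population_config()$responder_cutoff[[marker]]
  }
  pre <- pre_panels[[col]]
  post <- post_panels[[col]]
  decline <- ifelse(pre > 0, (pre - post) / pre, 0)
  mean(decline > criterion)
}
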