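#' Run configuration
#'
#' A fully serializable description of an analysis run: model/formulation
#' sources, stress scenario, population settings, arms and thresholds. A
#' run is reproducible from its config and seed alone.
#'
#' @param model Path to a model JSON (or `NULL` for the packaged
#'   calibrated model).
#' @param formulation Path to a formulation JSON (or `NULL` for the
#'   packaged one).
#' @param stress Named list/vector of severities (inflammatory,
#'   oxidative, insulin), each in `[0, 1]`.
#' @param n Population size.
#' @param seed RNG seed.
#' @param arms Character vector of arm names among `"stressed"`,
#'   `"micronutrients"`, `"botanicals"`, `"combined"`.
#' @param out_dir Output directory for CSV reports.
#' @param thresholds Threshold overrides (merged over
#'   [default_thresholds()]).
#' @return List of class `run_config`.
#' @export
run_config <- function(model = NULL, formulation = NULL,
                       stress = c(inflammatory = 1, oxidative = 1,
                                  insulin = 1),
                       n = 1000, seed = 1,
                       arms = c("stressed", "micronutrients", "botanicals",
                                "combined"),
                       out_dir = "results", thresholds = list()) {
  stress <- as.list(stress)
  bad <- setdiff(names(stress), c("inflammatory", "oxidative", "insulin"))
  if (length(bad)) stop("unknown stress field(s): ", paste(bad, collapse = ", "))
  known_arms <- c("stressed", "micronutrients", "botanicals", "combined")
  if (!all(arms %in% known_arms)) {
    stop("arms must be among: ", paste(known_arms, collapse = ", "))
  }
  th <- default_thresholds()
  bad <- setdiff(names(thresholds), names(th))
  if (length(bad)) stop("unknown threshold field(s): ",
                        paste(bad, collapse = ", "))
  th[names(thresholds)] <- thresholds
  structure(list(model = model, formulation = formulation, stress = stress,
                 n = n, seed = seed, arms = arms, out_dir = out_dir,
                 thresholds = th),
            class = "run_config")
}

#' Read a run configuration from YAML or JSON
#'
#' @param path File path (`.yaml`/`.yml` requires the yaml package).
#' @return `run_config`.
#' @export
read_run_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  doc <- if (ext %in% c("yaml", "yml")) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("reading YAML configs requires the yaml package")
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  do.call(run_config, doc)
}

config_objects <- function(config) {
  params <- if (is.null(config$model)) default_parameters()
            else read_model_json(config$model)
  form <- if (is.null(config$formulation)) default_formulation()
          else read_formulation_json(config$formulation)
  list(params = params, form = form)
}

config_digest <- function(config) {
  cfg <- unclass(config)
  cfg$out_dir <- NULL  # the digest identifies the analysis, not its location
  s <- jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA)
  sprintf("%08x", sum(utf8ToInt(s) * (seq_len(nchar(s)) %% 251)) %% .Machine$integer.max)
}

arm_specs <- function(form) {
  list(
    stressed = list(scenario = NULL, formulation = NULL),
    micronutrients = list(scenario = NULL,
                          formulation = formulation_subset(
                            form, classes = c("vitamin", "mineral"))),
    botanicals = list(scenario = NULL,
                      formulation = formulation_subset(
                        form, classes = "botanical")),
    combined = list(scenario = NULL, formulation = form)
  )
}

write_report_csv <- function(df, path, config) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# stressnet report | seed=%s | config=%s",
                     config$seed, config_digest(config)), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Steady-state analysis report
#'
#' Computes the four-arm steady states of the reference individual
#' (healthy parameters, configured stress severities, each arm's
#' formulation), derives the biomarker panels and fold changes between
#' the stressed and each intervened arm, and writes
#' `steady_state.csv` under the configured output directory.
#'
#' @param config `run_config`.
#' @return data.frame (one row per arm per marker), invisibly the file
#'   path as attribute `path`.
#' @export
run_steady_state <- function(config = run_config()) {
  obj <- config_objects(config)
  th <- config$thresholds
  scen <- do.call(stress_scenario, config$stress)
  p_str <- apply_stress(obj$params, scen)
  healthy <- steady_state(obj$params)
  arms <- arm_specs(obj$form)[config$arms]
  states <- list(healthy = healthy)
  for (a in names(arms)) {
    p_a <- p_str
    if (!is.null(arms[[a]]$formulation)) {
      p_a <- apply_intervention(p_str, arms[[a]]$formulation)
    }
    states[[a]] <- steady_state(p_a, init = healthy)
  }
  rows <- list()
  for (a in names(states)) {
    pan <- derive_panel(states[[a]], healthy, th)
    rows[[a]] <- data.frame(
      arm = a, marker = c("ros_percent", "tnfa", "sbp", "pss", "cortisol"),
      value = c(pan$ros_percent, pan$tnfa, pan$sbp, pan$pss, pan$cortisol))
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  # fold changes of stressed vs each intervened arm (positive markers only)
  folds <- list()
  if ("stressed" %in% names(states)) {
    for (a in setdiff(names(states), c("healthy", "stressed"))) {
      for (mk in c("ros_percent", "tnfa", "cortisol")) {
        pre <- tab$value[tab$arm == "stressed" & tab$marker == mk]
        post <- tab$value[tab$arm == a & tab$marker == mk]
        if (pre > 0 && post > 0) {
          folds[[paste(a, mk)]] <- data.frame(
            arm = a, marker = paste0("fold_", mk),
            value = fold_change(pre, post))
        }
      }
    }
  }
  tab <- rbind(tab, do.call(rbind, folds))
  rownames(tab) <- NULL
  path <- file.path(config$out_dir, "steady_state.csv")
  write_report_csv(tab, path, config)
  attr(tab, "path") <- path
  invisible(tab)
}

#' Population analysis report
#'
#' Generates the configured in-silico population, simulates the
#' configured arms, and writes per-individual panels
#' (`population_panels.csv`) and per-arm summaries with responder and
#' remission fractions and a paired t-statistic of each marker between
#' the stressed and combined arms (`population_summary.csv`).
#'
#' @param config `run_config`.
#' @return List with `panels`, `summary`, `tests` data.frames.
#' @export
run_population <- function(config = run_config()) {
  obj <- config_objects(config)
  th <- config$thresholds
  pop <- generate_population(config$n, config$seed)
  arms <- arm_specs(obj$form)[config$arms]
  res <- simulate_population(pop, arms, obj$params, th)
  panels <- res$panels
  pre <- panels[panels$arm == "stressed", ]
  markers <- c(ros = "ros_percent", tnfa = "tnfa", sbp = "sbp", pss = "pss")
  summary_rows <- list()
  for (a in unique(panels$arm)) {
    pa <- panels[panels$arm == a, ]
    for (m in names(markers)) {
      col <- markers[[m]]
      row <- data.frame(arm = a, marker = col, mean = mean(pa[[col]]),
                        sd = stats::sd(pa[[col]]),
                        responder_pct = NA_real_, remission_pct = NA_real_)
      if (a != "stressed" && nrow(pre) == nrow(pa)) {
        row$responder_pct <- 100 * responder_fraction(pre, pa, m)
        rem <- remission_stats(pre, pa, thresholds = th)
        row$remission_pct <- 100 * rem$healthy_band[rem$marker == col]
      }
      summary_rows[[paste(a, m)]] <- row
    }
  }
  summ <- do.call(rbind, summary_rows)
  rownames(summ) <- NULL
  tests <- NULL
  if (all(c("stressed", "combined") %in% panels$arm)) {
    post <- panels[panels$arm == "combined", ]
    tests <- do.call(rbind, lapply(unname(markers), function(col) {
      tt <- stats::t.test(post[[col]], pre[[col]], paired = TRUE)
      data.frame(marker = col, t_statistic = unname(tt$statistic),
                 p_value = tt$p.value)
    }))
  }
  write_report_csv(panels, file.path(config$out_dir, "population_panels.csv"),
                   config)
  write_report_csv(summ, file.path(config$out_dir, "population_summary.csv"),
                   config)
  if (!is.null(tests)) {
    write_report_csv(tests, file.path(config$out_dir, "population_tests.csv"),
                     config)
  }
  invisible(list(panels = panels, summary = summ, tests = tests))
}

#' Stress-phenotype analysis report
#'
#' Classifies every individual before and after the combined
#' intervention, writes the five-category distributions and the per-axis
#' residual-stress percentages (`phenotypes.csv`).
#'
#' @param config `run_config`.
#' @param panels Optional precomputed [run_population()] panels (must
#'   contain `stressed` and `combined` arms); avoids re-simulation.
#' @return List with `pre`, `post` (category fractions) and `residual`
#'   (per-axis post-intervention flag percentages).
#' @export
run_phenotypes <- function(config = run_config(), panels = NULL) {
  if (is.null(panels)) {
    cfg2 <- config
    cfg2$arms <- c("stressed", "combined")
    panels <- run_population(cfg2)$panels
  }
  pre <- panels[panels$arm == "stressed", ]
  post <- panels[panels$arm == "combined", ]
  dist_pre <- phenotype_distribution(pre$count)
  dist_post <- phenotype_distribution(post$count)
  residual <- 100 * c(oxidative = mean(post$oxidative),
                      inflammatory = mean(post$inflammatory),
                      physical = mean(post$physical),
                      mental = mean(post$mental))
  tab <- rbind(
    data.frame(timepoint = "pre", category = names(dist_pre),
               fraction = as.numeric(dist_pre)),
    data.frame(timepoint = "post", category = names(dist_post),
               fraction = as.numeric(dist_post)),
    data.frame(timepoint = "post", category = paste0("residual_",
                                                     names(residual)),
               fraction = as.numeric(residual) / 100)
  )
  write_report_csv(tab, file.path(config$out_dir, "phenotypes.csv"), config)
  invisible(list(pre = dist_pre, post = dist_post, residual = residual))
}
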