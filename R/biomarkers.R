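#' Default thresholds and biomarker map constants
#'
#' Classification cutoffs follow the clinical conventions used throughout:
#' oxidative stress at ROS production > 10% over healthy, physical stress
#' at SBP > 120 mmHg, mental stress at PSS > 13 (low band 0-13, moderate
#' 14-26, high 27-40), and inflammatory stress when TNF-alpha exceeds the
#' model-scale threshold (1.5e-3 pg/mL; the clinical serum band 0-1.5
#' pg/mL is retained as metadata — the model's TNF-alpha scale sits three
#' orders of magnitude below it). The SBP and PSS maps are calibrated
#' saturating (Hill) transforms of the aldosterone pressor drive and of
#' cortisol respectively.
#'
#' @return Named list of thresholds and map constants.
#' @export
default_thresholds <- function() {
  list(
    ros_percent = 10,          # % over healthy baseline
    tnfa = 1.5e-3,             # pg/mL, model scale (calibrated)
    sbp = 120,                 # mmHg
    pss = 13,                  # upper edge of the low-stress band
    pss_high = 27,             # lower edge of the high-stress band
    tnfa_clinical_band = c(0, 1.5),      # pg/mL, serum assay (metadata)
    cortisol_healthy_nmol = c(140, 690), # nmol/L (metadata, unused)
    sbp_floor = 90, sbp_ceiling = 200,   # mmHg
    sbp_K = 2.8518, sbp_n = 1.1477,      # aldosterone -> SBP Hill map
    pss_K = 28.2, pss_n = 1.0824,      # cortisol -> PSS Hill map
    dbp_ratio = 0.65
  )
}

#' Systolic blood pressure from the pressor drive
#'
#' Saturating (Hill) map of aldosterone to SBP with floor 90 and ceiling
#' 200 mmHg; strictly increasing in aldosterone.
#'
#' @param aldosterone Aldosterone level (model units), >= 0.
#' @param thresholds See [default_thresholds()].
#' @return SBP in mmHg.
#' @export
sbp_from_aldosterone <- function(aldosterone, thresholds = default_thresholds()) {
  if (any(aldosterone < 0)) stop("aldosterone must be non-negative")
  f <- hill(aldosterone, thresholds$sbp_K, thresholds$sbp_n)
  thresholds$sbp_floor + (thresholds$sbp_ceiling - thresholds$sbp_floor) * f
}

#' Perceived-stress score from cortisol
#'
#' Monotone non-decreasing saturating map of cortisol (ng/mL) into the
#' 0-40 PSS range, calibrated so the stressed population means map to the
#' high band and post-intervention means to the low band. The score is
#' returned as a real value; banding rounds half-up to the instrument's
#' integer scale.
#'
#' @param cortisol Cortisol in ng/mL, >= 0.
#' @param thresholds See [default_thresholds()].
#' @return PSS score in [0, 40].
#' @export
cortisol_to_pss <- function(cortisol, thresholds = default_thresholds()) {
  if (any(!is.finite(cortisol)) || any(cortisol < 0)) {
    stop("cortisol must be finite and non-negative")
  }
  40 * hill(cortisol, thresholds$pss_K, thresholds$pss_n)
}

round_half_up <- function(x) floor(x + 0.5)

#' Derive the clinical biomarker panel from a model state
#'
#' @param state `species_state`.
#' @param healthy_baseline Healthy reference `species_state` (calibrated
#'   healthy steady state); its ROS level anchors the ROS production
#'   percentage.
#' @param thresholds See [default_thresholds()].
#' @return A one-row data.frame of class `biomarker_panel` with columns
#'   `ros_percent`, `tnfa`, `sbp`, `dbp`, `cortisol`, `pss`.
#' @export
derive_panel <- function(state, healthy_baseline,
                         thresholds = default_thresholds()) {
  ros_h <- as.numeric(healthy_baseline[["ros"]])
  if (!is.finite(ros_h) || ros_h <= 0) {
    stop("healthy baseline must have strictly positive ROS")
  }
  ros_percent <- max(100 * (as.numeric(state[["ros"]]) - ros_h) / ros_h, 0)
  sbp <- sbp_from_aldosterone(as.numeric(state[["aldosterone"]]), thresholds)
  panel <- data.frame(
    ros_percent = ros_percent,
    tnfa = as.numeric(state[["tnfa"]]),
    sbp = sbp,
    dbp = thresholds$dbp_ratio * sbp,
    cortisol = as.numeric(state[["cortisol"]]),
    pss = cortisol_to_pss(as.numeric(state[["cortisol"]]), thresholds)
  )
  class(panel) <- c("biomarker_panel", "data.frame")
  panel
}

#' Classify a biomarker panel into stress phenotypes
#'
#' Deterministic threshold classification; the PSS value is rounded
#' half-up to the instrument's integer scale before banding. Raising any
#' marker never clears its flag (threshold-monotone).
#'
#' @param panel `biomarker_panel` (or one-row data.frame with its columns).
#' @param thresholds See [default_thresholds()].
#' @return List with logical `oxidative`, `inflammatory`, `physical`,
#'   `mental`, integer `count` (0-4) and `category` in
#'   `c("none","one","two","three","four")`.
#' @export
classify <- function(panel, thresholds = default_thresholds()) {
  flags <- c(
    oxidative = panel$ros_percent > thresholds$ros_percent,
    inflammatory = panel$tnfa > thresholds$tnfa,
    physical = panel$sbp > thresholds$sbp,
    mental = round_half_up(panel$pss) > thresholds$pss
  )
  count <- sum(flags)
  category <- c("none", "one", "two", "three", "four")[count + 1]
  c(as.list(flags), list(count = count, category = category))
}

#' Phenotype distribution over a set of classifications
#'
#' @param classifications List of [classify()] results (or an integer
#'   vector of flag counts).
#' @return Named numeric fractions over `four`, `three`, `two`, `one`,
#'   `none`; sums to 1 exactly (computed from integer counts).
#' @export
phenotype_distribution <- function(classifications) {
  if (length(classifications) == 0) stop("empty classification list")
  counts <- if (is.numeric(classifications)) as.integer(classifications)
            else vapply(classifications, function(x) x$count, integer(1))
  if (any(counts < 0 | counts > 4)) stop("flag counts must be in 0..4")
  tab <- tabulate(counts + 1L, nbins = 5L)  # none, one, two, three, four
  frac <- tab / length(counts)
  c(four = frac[5], three = frac[4], two = frac[3], one = frac[2],
    none = frac[1])
}

#' Remission statistics for paired pre/post panels
#'
#' For each marker (ROS production %, TNF-alpha, SBP, PSS) reports the
#' fraction of individuals whose post-intervention value fell below the
#' stressed-population mean, and the fraction that remitted into the
#' healthy band (ROS 0-10%, TNF-alpha within the configured normal band,
#' SBP <= 120 mmHg, PSS 0-13).
#'
#' @param pre_panels,post_panels data.frames of panels (equal rows > 0).
#' @param stressed_means Named means (`ros_percent`, `tnfa`, `sbp`, `pss`)
#'   of the stressed arm; defaults to the column means of `pre_panels`.
#' @param thresholds See [default_thresholds()].
#' @return data.frame with one row per marker: `below_stressed_mean`,
#'   `healthy_band` (fractions in [0, 1]).
#' @export
remission_stats <- function(pre_panels, post_panels, stressed_means = NULL,
                            thresholds = default_thresholds()) {
  if (NROW(pre_panels) == 0 || NROW(post_panels) == 0) {
    stop("pre/post panel lists must be non-empty")
  }
  if (NROW(pre_panels) != NROW(post_panels)) {
    stop("pre/post panel lists must be paired (equal length)")
  }
  markers <- c("ros_percent", "tnfa", "sbp", "pss")
  if (is.null(stressed_means)) {
    stressed_means <- vapply(markers, function(m) mean(pre_panels[[m]]),
                             numeric(1))
  }
  in_band <- list(
    ros_percent = function(x) x <= thresholds$ros_percent,
    tnfa = function(x) x <= thresholds$tnfa,
    sbp = function(x) x <= thresholds$sbp,
    pss = function(x) round_half_up(x) <= thresholds$pss
  )
  out <- lapply(markers, function(m) {
    post <- post_panels[[m]]
    data.frame(marker = m,
               below_stressed_mean = mean(post < stressed_means[[m]]),
               healthy_band = mean(in_band[[m]](post)))
  })
  do.call(rbind, out)
}
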