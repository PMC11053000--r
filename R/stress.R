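#' Stress scenario
#'
#' A severity-parameterised perturbation of the network. Severities are in
#' `[0, 1]`: the inflammatory axis scales the LPS -> NF-kB activation gain,
#' the oxidative axis strengthens KEAP1-mediated NRF2 degradation,
#' suppresses antioxidant production (SOD/CAT/GPx/GSH) and amplifies ROS
#' generation, and the insulin axis amplifies the perturbed
#' PI3K/AKT -> FOXO1 -> LPS route. The all-zero scenario is the identity.
#'
#' @param inflammatory,oxidative,insulin Severities in `[0, 1]`.
#' @return Object of class `stress_scenario`.
#' @export
stress_scenario <- function(inflammatory = 0, oxidative = 0, insulin = 0) {
  sev <- c(inflammatory = inflammatory, oxidative = oxidative,
           insulin = insulin)
  if (any(!is.finite(sev)) || any(sev < 0) || any(sev > 1)) {
    stop("severities must lie in [0, 1]; got: ",
         paste(sprintf("%s=%.3g", names(sev), sev), collapse = ", "))
  }
  structure(as.list(sev), class = "stress_scenario")
}

#' Full-severity stressed condition
#'
#' The reference stressed arm perturbs all three axes at severity 1.
#' @return `stress_scenario` with all severities 1.
#' @export
stressed_scenario <- function() stress_scenario(1, 1, 1)

#' Apply a stress scenario to parameters
#'
#' Returns a new parameter set whose stress gains `g_*` are set from the
#' severities via the calibrated coupling constants `stress_*`
#' (gain = 1 + constant * severity, or its reciprocal for the suppressed
#' antioxidant production). The input is never modified; zero severity
#' returns an identical parameter set.
#'
#' @param params `kinetic_parameters`.
#' @param scenario `stress_scenario`.
#' @return New `kinetic_parameters`.
#' @export
apply_stress <- function(params, scenario) {
  validate_parameters(params)
  if (!inherits(scenario, "stress_scenario")) {
    scenario <- do.call(stress_scenario, as.list(scenario))
  }
  th <- params$theta
  si <- scenario$inflammatory
  so <- scenario$oxidative
  sn <- scenario$insulin
  th[["g_inf"]] <- th[["g_inf"]] * (1 + th[["stress_alpha_inf"]] * si)
  th[["g_keap"]] <- th[["g_keap"]] * (1 + th[["stress_beta_keap"]] * so)
  th[["g_aox"]] <- th[["g_aox"]] * (1 + th[["stress_beta_aox"]] * so)
  th[["g_rosgen"]] <- th[["g_rosgen"]] * (1 + th[["stress_beta_ros"]] * so)
  th[["g_ins"]] <- th[["g_ins"]] * (1 + th[["stress_gamma_ins"]] * sn)
  out <- new_parameters(th, params$totals)
  validate_parameters(out)
  out
}

#' Confirm stressed condition per axis
#'
#' Compares a state against the healthy baseline and reports, per stress
#' axis, whether the biomarker elevation criterion holds (oxidative:
#' ROS production above the +10% band; inflammatory: TNF-alpha above the
#' model-scale threshold; physical: SBP > 120 mmHg; mental: PSS > 13).
#'
#' @param state `species_state` to test.
#' @param healthy_baseline Healthy reference `species_state`.
#' @param thresholds See [default_thresholds()].
#' @return Named logical vector (oxidative, inflammatory, physical, mental).
#' @export
confirm_stressed <- function(state, healthy_baseline,
                             thresholds = default_thresholds()) {
  panel <- derive_panel(state, healthy_baseline, thresholds)
  cls <- classify(panel, thresholds)
  c(oxidative = cls$oxidative, inflammatory = cls$inflammatory,
    physical = cls$physical, mental = cls$mental)
}
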