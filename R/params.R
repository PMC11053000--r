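#' Kinetic parameters
#'
#' Parameters are stored as a flat named numeric vector wrapped in a list
#' with pool totals and metadata. Naming convention:
#' \itemize{
#'   \item `b_<sp>` basal production (units/day), `d_<sp>` first-order
#'     degradation (1/day), `v_<sp>` regulated production amplitude;
#'   \item `K_<sp>_<src>` half-saturation of the edge from `<src>` into
#'     `<sp>`, `n_<sp>` Hill exponent where not 2;
#'   \item `k_*` mass-action constants (phosphorylation, ROS clearance);
#'   \item `g_*` stress gains (set by [apply_stress()], default 1);
#'   \item `m_<node>` intervention multipliers on the regulated production
#'     of `<node>` (set by [apply_intervention()], default 1);
#'   \item `stress_*` severity-to-gain calibration constants.
#' }
#'
#' @param values Named numeric vector of parameter values; entries replace
#'   the packaged calibrated defaults.
#' @return Object of class `kinetic_parameters`.
#' @export
kinetic_parameters <- function(values = NULL) {
  p <- default_parameters()
  if (!is.null(values)) {
    unknown <- setdiff(names(values), names(p$theta))
    if (length(unknown)) {
      stop("unknown parameter(s): ", paste(unknown, collapse = ", "))
    }
    p$theta[names(values)] <- as.numeric(values)
  }
  validate_parameters(p)
  p
}

new_parameters <- function(theta, totals = c(irs = 1, akt = 1)) {
  structure(list(theta = theta, totals = totals), class = "kinetic_parameters")
}

#' @export
print.kinetic_parameters <- function(x, ...) {
  cat("<kinetic_parameters> ", length(x$theta), " constants; pool totals: irs=",
      x$totals[["irs"]], ", akt=", x$totals[["akt"]], "\n", sep = "")
  invisible(x)
}

#' Validate a parameter set
#'
#' Rates, amplitudes, half-saturations and pool totals must be strictly
#' positive (basal productions may be zero); Hill exponents >= 1; gain and
#' intervention multipliers non-negative.
#'
#' @param p A `kinetic_parameters` object.
#' @return `p`, invisibly; errors name the offending field.
#' @export
validate_parameters <- function(p) {
  stopifnot(inherits(p, "kinetic_parameters"))
  th <- p$theta
  if (any(!is.finite(th))) {
    stop("non-finite parameter value for field(s): ",
         paste(names(th)[!is.finite(th)], collapse = ", "), call. = FALSE)
  }
  pre <- function(prefix) th[startsWith(names(th), prefix)]
  neg <- function(x) names(x)[x < 0]
  nonpos <- function(x) names(x)[x <= 0]
  bad <- c(
    neg(pre("b_")), nonpos(pre("d_")), neg(pre("v_")),
    nonpos(pre("K_")), neg(pre("k_")), neg(pre("m_")), neg(pre("g_")),
    neg(pre("stress_")),
    names(pre("n_"))[pre("n_") < 1]
  )
  if (length(bad)) {
    stop("invalid (non-positive or negative) parameter value for field(s): ",
         paste(unique(bad), collapse = ", "), call. = FALSE)
  }
  if (any(p$totals <= 0)) stop("pool totals must be strictly positive", call. = FALSE)
  invisible(p)
}

#' Calibrated default parameters
#'
#' Loads the packaged calibrated parameter set (the result of the staged
#' calibration against the reference healthy, stressed and intervened
#' steady states; see the methods vignette).
#'
#' @return A `kinetic_parameters` object.
#' @export
default_parameters <- function() {
  path <- system.file("extdata", "params_default.json", package = "stressnet")
  if (path == "" || !file.exists(path)) {
    stop("packaged parameter file not found; reinstall the package")
  }
  read_model_json(path)
}

#' Write a model definition to JSON
#'
#' Serializes species registry, topology edge list and kinetic parameters
#' to a structured JSON document.
#'
#' @param params `kinetic_parameters`.
#' @param path Output file path.
#' @param topology A `network_topology` (defaults to the packaged network).
#' @return `path`, invisibly.
#' @export
write_model_json <- function(params, path, topology = network_topology()) {
  validate_parameters(params)
  doc <- list(
    format = "stressnet-model",
    version = 1L,
    species = species_names(),
    edges = as.data.frame(topology),
    totals = as.list(params$totals),
    parameters = as.list(params$theta)
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a model definition from JSON
#'
#' @param path Path to a JSON file written by [write_model_json()].
#' @return A `kinetic_parameters` object (topology available via
#'   `attr(, "topology")`).
#' @export
read_model_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(doc$format, "stressnet-model")) {
    stop("not a stressnet model definition: ", path)
  }
  theta <- unlist(doc$parameters)
  totals <- unlist(doc$totals)
  p <- new_parameters(theta, totals)
  validate_parameters(p)
  attr(p, "topology") <- network_topology(as.data.frame(doc$edges))
  p
}
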