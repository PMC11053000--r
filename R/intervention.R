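#' Ingredient definition
#'
#' An ingredient maps to one or more network nodes with a direction
#' (`"down"` suppresses the node's regulated production, `"up"` enhances
#' it) and a fractional potency in `[0, 1)` defined at formulation dose.
#'
#' @param name Ingredient name.
#' @param class One of `"botanical"`, `"vitamin"`, `"mineral"`.
#' @param targets data.frame with columns `node`, `direction`, `potency`.
#' @param dose_mg Label dose in mg (metadata only; `NA` if not stated).
#' @return data.frame of ingredient target edges.
#' @export
ingredient <- function(name, class, targets, dose_mg = NA_real_) {
  class <- match.arg(class, c("botanical", "vitamin", "mineral"))
  stopifnot(is.data.frame(targets),
            all(c("node", "direction", "potency") %in% names(targets)))
  if (any(targets$potency < 0 | targets$potency >= 1)) {
    stop("potency must lie in [0, 1) for ingredient ", name)
  }
  if (!all(targets$direction %in% c("up", "down"))) {
    stop("direction must be 'up' or 'down' for ingredient ", name)
  }
  bad <- setdiff(targets$node, names(node_levers()))
  if (length(bad)) {
    stop("ingredient ", name, " targets unknown node(s): ",
         paste(bad, collapse = ", "))
  }
  data.frame(ingredient = name, class = class, node = targets$node,
             direction = targets$direction, potency = targets$potency,
             dose_mg = dose_mg, stringsAsFactors = FALSE)
}

# Intervention levers: node name -> parameter multiplier entry.
node_levers <- function() {
  c(lps = "m_lps", nfkb = "m_nfkb", tnfa = "m_tnfa", il6 = "m_il6",
    il10 = "m_il10", nrf2 = "m_nrf2", keap1 = "m_keap1", sod = "m_sod",
    cat = "m_cat", gpx = "m_gpx", gsh = "m_gsh", ros = "m_ros",
    foxo1_cyt = "m_foxo1", pakt = "m_pakt", ampk = "m_ampk", crh = "m_crh",
    acth = "m_acth", cortisol = "m_cortisol", renin = "m_renin",
    ang2 = "m_ang2", aldosterone = "m_aldosterone")
}

#' Formulation
#'
#' A set of ingredients with a multiplicative combination rule: all
#' potencies targeting one node compose as products of `(1 - p)` (down)
#' and `(1 + p)` (up) factors, which is commutative and bounded.
#'
#' @param edges data.frame of ingredient target edges (rows as produced by
#'   [ingredient()], rbind-ed).
#' @param rule Combination rule identifier (only `"multiplicative"`).
#' @return Object of class `formulation` (a data.frame of edges).
#' @export
formulation <- function(edges, rule = "multiplicative") {
  rule <- match.arg(rule, "multiplicative")
  stopifnot(is.data.frame(edges),
            all(c("ingredient", "class", "node", "direction", "potency")
                %in% names(edges)))
  meta <- unique(edges[, c("ingredient", "class")])
  if (anyDuplicated(meta$ingredient)) {
    stop("ingredient names must be unique within a formulation")
  }
  bad <- setdiff(edges$node, names(node_levers()))
  if (length(bad)) stop("unknown target node(s): ", paste(bad, collapse = ", "))
  structure(edges, class = c("formulation", "data.frame"), rule = rule)
}

#' The packaged default formulation
#'
#' Four botanical extracts (Gotukola/Centella asiatica with 15%
#' triterpenoids, acerola cherry, elderberry, purple carrot), thirteen
#' vitamins (A, D, E, K, C and eight B vitamins) and eleven minerals
#' (iodine, copper, manganese, molybdenum, selenium, zinc, chromium, iron,
#' magnesium, calcium, phosphorus), with node targets assigned from their
#' reported anti-inflammatory/antioxidant/adaptogenic actions and
#' potencies fitted by the staged calibration.
#'
#' @return A `formulation`.
#' @export
default_formulation <- function() {
  path <- system.file("extdata", "formulation_default.json",
                      package = "stressnet")
  if (path == "" || !file.exists(path)) {
    stop("packaged formulation file not found; reinstall the package")
  }
  read_formulation_json(path)
}

#' Write / read a formulation as JSON
#' @param form A `formulation`.
#' @param path File path.
#' @return `path` (write) or a `formulation` (read), invisibly for write.
#' @export
write_formulation_json <- function(form, path) {
  stopifnot(inherits(form, "formulation"))
  jsonlite::write_json(list(format = "stressnet-formulation",
                            rule = attr(form, "rule"),
                            edges = as.data.frame(form)),
                       path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_formulation_json
#' @export
read_formulation_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(doc$format, "stressnet-formulation")) {
    stop("not a stressnet formulation: ", path)
  }
  formulation(as.data.frame(doc$edges), rule = doc$rule)
}

#' Subset a formulation by ingredient class or name
#'
#' @param form A `formulation`.
#' @param classes Classes to keep (e.g. `"botanical"`), or `NULL`.
#' @param ingredients Ingredient names to keep, or `NULL`.
#' @return A `formulation` (possibly with zero rows = inert).
#' @export
formulation_subset <- function(form, classes = NULL, ingredients = NULL) {
  keep <- rep(TRUE, nrow(form))
  if (!is.null(classes)) keep <- keep & form$class %in% classes
  if (!is.null(ingredients)) keep <- keep & form$ingredient %in% ingredients
  formulation(as.data.frame(form)[keep, , drop = FALSE], attr(form, "rule"))
}

#' Scale all potencies of a formulation
#'
#' Multiplies every potency by `lambda` in `[0, 1]` (used for response
#' heterogeneity and for the potency-monotonicity property).
#'
#' @param form A `formulation`.
#' @param lambda Scale factor in `[0, 1]`.
#' @return A `formulation`.
#' @export
scale_formulation <- function(form, lambda) {
  stopifnot(is.numeric(lambda), length(lambda) == 1, lambda >= 0, lambda <= 1)
  out <- as.data.frame(form)
  out$potency <- out$potency * lambda
  formulation(out, attr(form, "rule"))
}

#' Apply an intervention to model parameters
#'
#' Multiplies each targeted node's intervention multiplier by
#' `(1 - potency)` for down-edges and `(1 + potency)` for up-edges;
#' ingredients sharing a node compose multiplicatively (order-independent).
#' The empty formulation is the identity. The input is not modified.
#'
#' @param params `kinetic_parameters`.
#' @param form A `formulation`.
#' @return New `kinetic_parameters`.
#' @export
apply_intervention <- function(params, form) {
  validate_parameters(params)
  if (!inherits(form, "formulation")) stop("form must be a formulation")
  th <- params$theta
  if (nrow(form)) {
    lever <- node_levers()[form$node]
    fac <- ifelse(form$direction == "down", 1 - form$potency,
                  1 + form$potency)
    for (i in seq_along(lever)) th[[lever[i]]] <- th[[lever[i]]] * fac[i]
  }
  out <- new_parameters(th, params$totals)
  validate_parameters(out)
  out
}
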