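#' Species registry for the stress network
#'
#' The model tracks 34 molecular species spanning LPS-driven inflammation
#' (NF-kB, TNF-alpha, IL-6, IL-10, JAK1/STAT3, MAPK), the NRF2-KEAP1
#' antioxidant axis (SOD, CAT, GPx, GSH, ROS, MDA), hypoxia signalling
#' (HIF-1alpha), insulin signalling (IRS/pIRS and AKT/pAKT pools, PI3K,
#' mTOR, AMPK, FOXO1), the HPA axis (CRH, ACTH, cortisol) and the
#' renin-angiotensin system (renin, Ang II, aldosterone), plus insulin,
#' glucagon and glucose. Units are model units except TNF-alpha (pg/mL)
#' and cortisol (ng/mL); time is in days.
#'
#' @return Character vector of species names in canonical order.
#' @export
species_names <- function() {
  c("lps", "nfkb", "tnfa", "il6", "il10", "jak1", "stat3", "mapk",
    "nrf2", "keap1", "sod", "cat", "gpx", "gsh", "ros", "mda", "hif1a",
    "foxo1_cyt", "irs", "pirs", "akt", "pakt", "pi3k", "mtor", "ampk",
    "crh", "acth", "cortisol", "renin", "ang2", "aldosterone",
    "insulin", "glucagon", "glucose")
}

#' Construct a species state
#'
#' @param x Named numeric vector with one non-negative entry per species
#'   (any order; names must match [species_names()] exactly as a set).
#' @return A named numeric vector of class `species_state`, in canonical
#'   species order.
#' @export
species_state <- function(x) {
  nm <- species_names()
  if (is.null(names(x)) || !setequal(names(x), nm)) {
    missing <- setdiff(nm, names(x))
    extra <- setdiff(names(x), nm)
    stop("species_state: names must match the species registry",
         if (length(missing)) paste0("; missing: ", paste(missing, collapse = ", ")),
         if (length(extra)) paste0("; unknown: ", paste(extra, collapse = ", ")),
         call. = FALSE)
  }
  x <- as.numeric(x[nm])
  names(x) <- nm
  validate_state(x)
  structure(x, class = c("species_state", "numeric"))
}

validate_state <- function(x, what = "state") {
  if (any(!is.finite(x))) {
    stop(sprintf("non-finite %s value for field(s): %s", what,
                 paste(names(x)[!is.finite(x)], collapse = ", ")), call. = FALSE)
  }
  if (any(x < 0)) {
    stop(sprintf("negative %s value for field(s): %s", what,
                 paste(names(x)[x < 0], collapse = ", ")), call. = FALSE)
  }
  invisible(x)
}

#' @export
print.species_state <- function(x, ...) {
  cat("<species_state> (", length(x), " species)\n", sep = "")
  print(signif(unclass(x), 4), ...)
  invisible(x)
}
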