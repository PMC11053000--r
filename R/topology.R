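#' Signed network topology
#'
#' The directed, signed edge list of the stress network. The topology is
#' fixed at construction; [rhs()] implements exactly these influences.
#' `activate` edges enter as Hill activation (or mass-action drive for the
#' phosphorylation and clearance reactions), `inhibit` edges as repression
#' or enhanced clearance.
#'
#' @param edges Optional data.frame with columns `from`, `to`, `sign`
#'   (one of `"activate"`, `"inhibit"`). Defaults to the packaged network.
#' @return A data.frame of class `network_topology`.
#' @export
network_topology <- function(edges = default_edges()) {
  stopifnot(is.data.frame(edges), all(c("from", "to", "sign") %in% names(edges)))
  nm <- c(species_names(), "sbp")  # sbp is a derived output node
  bad <- setdiff(unique(c(edges$from, edges$to)), nm)
  if (length(bad)) stop("unknown species in topology: ", paste(bad, collapse = ", "))
  if (!all(edges$sign %in% c("activate", "inhibit"))) {
    stop("edge sign must be 'activate' or 'inhibit'")
  }
  req <- required_edges()
  key <- function(d) paste(d$from, d$to, d$sign)
  miss <- !(key(req) %in% key(edges))
  if (any(miss)) {
    stop("topology is missing required edges: ",
         paste(key(req)[miss], collapse = "; "))
  }
  class(edges) <- c("network_topology", "data.frame")
  edges
}

# Minimum signed edges the model must contain, each traceable to a stated
# mechanism (LPS-driven NF-kB, cytokine-HPA coupling, NRF2 antioxidant arm,
# ROS-HIF1a-CRH-ACTH-cortisol cascade, TNF-driven RAS hypertension).
required_edges <- function() {
  e <- rbind(
    c("lps", "nfkb", "activate"),
    c("nfkb", "tnfa", "activate"),
    c("nfkb", "il6", "activate"),
    c("tnfa", "il6", "activate"),
    c("il6", "crh", "activate"),
    c("ros", "hif1a", "activate"),
    c("hif1a", "crh", "activate"),
    c("crh", "acth", "activate"),
    c("acth", "cortisol", "activate"),
    c("nrf2", "sod", "activate"),
    c("keap1", "nrf2", "inhibit"),
    c("sod", "ros", "inhibit"),
    c("gsh", "ros", "inhibit"),
    c("ros", "mda", "activate"),
    c("pakt", "foxo1_cyt", "activate"),
    c("foxo1_cyt", "lps", "activate"),
    c("il10", "nfkb", "inhibit"),
    c("stat3", "il10", "activate"),
    c("tnfa", "renin", "activate"),
    c("ang2", "aldosterone", "activate"),
    c("aldosterone", "sbp", "activate")
  )
  data.frame(from = e[, 1], to = e[, 2], sign = e[, 3])
}

default_edges <- function() {
  extra <- rbind(
    c("insulin", "pi3k", "activate"),
    c("pi3k", "pakt", "activate"),
    c("mapk", "pirs", "activate"),
    c("lps", "mapk", "activate"),
    c("mapk", "il6", "activate"),
    c("il6", "jak1", "activate"),
    c("jak1", "stat3", "activate"),
    c("nrf2", "cat", "activate"),
    c("nrf2", "gpx", "activate"),
    c("ros", "gsh", "inhibit"),
    c("cat", "ros", "inhibit"),
    c("gpx", "ros", "inhibit"),
    c("nfkb", "ros", "activate"),
    c("pakt", "mtor", "activate"),
    c("mtor", "ampk", "inhibit"),
    c("ampk", "ros", "inhibit"),
    c("renin", "ang2", "activate"),
    c("glucagon", "glucose", "activate"),
    c("insulin", "glucose", "inhibit")
  )
  rbind(required_edges(),
        data.frame(from = extra[, 1], to = extra[, 2], sign = extra[, 3]))
}
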