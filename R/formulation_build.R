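#' Base ingredient-to-node potency assignments
#'
#' Literature-guided target map for the 4 botanicals, 13 vitamins and 11
#' minerals: botanicals act on NF-kB/TNF/IL-6 and the NRF2-KEAP1 axis
#' (Gotukola's signature is KEAP1 relief of NRF2), vitamins A/D/E/K on
#' the pro-inflammatory cytokine block, vitamin C and the B vitamins on
#' glutathione, cortisol and antioxidant enzymes, and minerals on their
#' cognate enzymes (selenium -> GPx, copper/manganese/zinc -> SOD,
#' iron -> catalase) plus the pressor axis (calcium, magnesium and
#' vitamin D on renin). Base potencies are starting values; the packaged
#' formulation carries the calibrated ones.
#'
#' @return data.frame of edges with a `group` column used by the fitter
#'   (`fit` groups are scaled to printed single-ingredient efficacies;
#'   `free` edges are renormalised to the required combined multipliers).
#' @keywords internal
base_potency_table <- function() {
  e <- function(ing, cls, node, dir, p, grp = "free", cap = 0.93) {
    data.frame(ingredient = ing, class = cls, node = node, direction = dir,
               potency = p, group = grp, cap = cap, stringsAsFactors = FALSE)
  }
  rbind(
    # botanicals
    e("gotukola", "botanical", "keap1", "down", 0.38, "gotukola_redox", cap = 0.60),
    e("gotukola", "botanical", "nrf2", "up", 0.10, "gotukola_redox"),
    e("gotukola", "botanical", "gsh", "up", 0.18, "gotukola_redox"),
    e("gotukola", "botanical", "ampk", "up", 0.04, "gotukola_redox"),
    e("gotukola", "botanical", "nfkb", "down", 0.07, "gotukola_inflam"),
    e("gotukola", "botanical", "tnfa", "down", 0.06, "gotukola_inflam"),
    e("gotukola", "botanical", "il6", "down", 0.03, "gotukola_inflam"),
    e("acerola", "botanical", "ros", "down", 0.06, "acerola_redox"),
    e("acerola", "botanical", "cat", "up", 0.18, "acerola_redox"),
    e("acerola", "botanical", "ampk", "up", 0.12, "acerola_redox"),
    e("acerola", "botanical", "gsh", "up", 0.12, "acerola_redox"),
    e("acerola", "botanical", "cortisol", "down", 0.11, "acerola_hpa"),
    e("acerola", "botanical", "acth", "down", 0.035, "acerola_hpa"),
    e("acerola", "botanical", "crh", "down", 0.02, "acerola_hpa"),
    e("acerola", "botanical", "il6", "down", 0.03, "acerola_hpa"),
    e("elderberry", "botanical", "ros", "down", 0.08),
    e("elderberry", "botanical", "nfkb", "down", 0.10),
    e("elderberry", "botanical", "lps", "down", 0.15),
    e("elderberry", "botanical", "keap1", "down", 0.10),
    e("elderberry", "botanical", "nrf2", "up", 0.05),
    e("purple_carrot", "botanical", "tnfa", "down", 0.36),
    e("purple_carrot", "botanical", "nfkb", "down", 0.05),
    e("purple_carrot", "botanical", "il6", "down", 0.02),
    # vitamins
    e("vitamin_a", "vitamin", "tnfa", "down", 0.24, "vita_inflam"),
    e("vitamin_a", "vitamin", "nfkb", "down", 0.05, "vita_inflam"),
    e("vitamin_a", "vitamin", "il6", "down", 0.02, "vita_inflam"),
    e("vitamin_c", "vitamin", "gsh", "up", 0.55, "vitc_redox"),
    e("vitamin_c", "vitamin", "ros", "down", 0.03, "vitc_redox"),
    e("vitamin_c", "vitamin", "cortisol", "down", 0.012),
    e("vitamin_d", "vitamin", "tnfa", "down", 0.17),
    e("vitamin_d", "vitamin", "nfkb", "down", 0.08),
    e("vitamin_d", "vitamin", "il6", "down", 0.03),
    e("vitamin_d", "vitamin", "lps", "down", 0.15),
    e("vitamin_d", "vitamin", "renin", "down", 0.40),
    e("vitamin_e", "vitamin", "ros", "down", 0.04),
    e("vitamin_e", "vitamin", "tnfa", "down", 0.15),
    e("vitamin_e", "vitamin", "nfkb", "down", 0.03),
    e("vitamin_e", "vitamin", "sod", "up", 0.05),
    e("vitamin_k", "vitamin", "nfkb", "down", 0.07),
    e("vitamin_k", "vitamin", "il6", "down", 0.02),
    e("vitamin_b1", "vitamin", "cortisol", "down", 0.025),
    e("vitamin_b1", "vitamin", "nfkb", "down", 0.02),
    e("vitamin_b2", "vitamin", "cat", "up", 0.15),
    e("vitamin_b2", "vitamin", "cortisol", "down", 0.02),
    e("vitamin_b3", "vitamin", "cortisol", "down", 0.025),
    e("vitamin_b3", "vitamin", "nfkb", "down", 0.02),
    e("vitamin_b5", "vitamin", "cortisol", "down", 0.03),
    e("vitamin_b6", "vitamin", "cortisol", "down", 0.03),
    e("vitamin_b6", "vitamin", "lps", "down", 0.07),
    e("vitamin_b7", "vitamin", "cortisol", "down", 0.02),
    e("vitamin_b7", "vitamin", "il6", "down", 0.01),
    e("vitamin_b9", "vitamin", "cortisol", "down", 0.025),
    e("vitamin_b9", "vitamin", "lps", "down", 0.05),
    e("vitamin_b12", "vitamin", "cortisol", "down", 0.025),
    e("vitamin_b12", "vitamin", "crh", "down", 0.012),
    # minerals
    e("iodine", "mineral", "gpx", "up", 0.20),
    e("iodine", "mineral", "sod", "up", 0.22),
    e("iodine", "mineral", "cat", "up", 0.15),
    e("iodine", "mineral", "il6", "down", 0.02),
    e("copper", "mineral", "sod", "up", 0.20),
    e("copper", "mineral", "cortisol", "down", 0.015),
    e("manganese", "mineral", "sod", "up", 0.20),
    e("molybdenum", "mineral", "cortisol", "down", 0.015),
    e("selenium", "mineral", "gpx", "up", 0.50),
    e("selenium", "mineral", "gsh", "up", 0.15),
    e("selenium", "mineral", "nfkb", "down", 0.03),
    e("zinc", "mineral", "sod", "up", 0.24, "zinc_redox"),
    e("zinc", "mineral", "nfkb", "down", 0.05),
    e("zinc", "mineral", "il6", "down", 0.02),
    e("zinc", "mineral", "lps", "down", 0.10),
    e("chromium", "mineral", "il6", "down", 0.02),
    e("chromium", "mineral", "ros", "down", 0.02),
    e("iron", "mineral", "cat", "up", 0.30),
    e("iron", "mineral", "gpx", "up", 0.10),
    e("calcium", "mineral", "renin", "down", 0.45),
    e("magnesium", "mineral", "renin", "down", 0.40),
    e("magnesium", "mineral", "acth", "down", 0.04),
    e("magnesium", "mineral", "cortisol", "down", 0.03),
    e("magnesium", "mineral", "il6", "down", 0.02),
    e("phosphorus", "mineral", "gsh", "up", 0.05),
    e("phosphorus", "mineral", "ampk", "up", 0.03)
  )
}

# printed single-ingredient efficacy constraints (percent declines)
single_constraints <- function() {
  data.frame(
    group = c("vita_inflam", "gotukola_inflam", "gotukola_redox",
              "acerola_redox", "zinc_redox", "vitc_redox", "acerola_hpa"),
    ingredient = c("vitamin_a", "gotukola", "gotukola", "acerola", "zinc",
                   "vitamin_c", "acerola"),
    marker = c("tnfa", "tnfa", "ros", "ros", "ros", "ros", "cortisol"),
    target = c(25, 11, 24, 21, 11, 11, 22),
    stringsAsFactors = FALSE
  )
}

#' Build the calibrated default formulation
#'
#' Stage 3 of the calibration: (1) each constrained ingredient's edge
#' group is scaled (1-D secant search on the full model) until its
#' printed single-ingredient efficacy is met; (2) the remaining free
#' edges on every node are rescaled so the combined products equal the
#' node multipliers required by the combined-arm steady-state anchors.
#'
#' @param params Healthy `kinetic_parameters` from [build_reference_model()]
#'   (must carry the `m_required` attribute).
#' @param verbose Print fit progress.
#' @return A `formulation` whose combined application reproduces the
#'   anchored steady state exactly.
#' @export
build_default_formulation <- function(params = build_reference_model(),
                                      verbose = FALSE) {
  mreq <- attr(params, "m_required")
  if (is.null(mreq)) stop("params must carry the m_required attribute")
  tab <- base_potency_table()
  p_str <- apply_stress(params, stressed_scenario())
  healthy <- steady_state(params)

  eff_for <- function(tab_i, marker) {
    sub <- formulation(tab_i[, c("ingredient", "class", "node", "direction",
                                 "potency")])
    efficacy_percent(p_str, sub, marker, healthy_baseline = healthy)
  }

  cons <- single_constraints()
  for (ci in seq_len(nrow(cons))) {
    grp <- cons$group[ci]
    idx <- tab$group == grp
    own <- tab$ingredient == cons$ingredient[ci]
    base <- tab$potency[idx]
    f <- function(lam) {
      tt <- tab[own, ]
      sel <- tt$group == grp
      tt$potency[sel] <- pmin(lam * base, tt$cap[sel])
      eff_for(tt, cons$marker[ci]) - cons$target[ci]
    }
    lam <- uniroot_scale(f, verbose = verbose, label = grp)
    tab$potency[idx] <- pmin(lam * base, tab$cap[idx])
    if (verbose) {
      message(sprintf("  %-16s lambda=%.3f  efficacy=%.2f (target %g)",
                      grp, lam, eff_for(tab[own, ], cons$marker[ci]),
                      cons$target[ci]))
    }
  }

  # renormalise free edges so node products match the required multipliers
  lever_nodes <- names(node_levers())
  for (node in lever_nodes) {
    req <- unname(mreq[node_levers()[[node]]])
    if (length(req) != 1 || is.na(req)) next
    rows <- tab$node == node
    if (!any(rows)) {
      if (abs(req - 1) > 0.02) {
        stop(sprintf("no edges available for node %s (required %.3f)",
                     node, req))
      }
      next
    }
    fixed <- rows & tab$group != "free"
    free <- rows & tab$group == "free"
    prod_fixed <- prod(ifelse(tab$direction[fixed] == "down",
                              1 - tab$potency[fixed], 1 + tab$potency[fixed]))
    if (!any(free)) {
      if (abs(prod_fixed - req) / req > 0.02) {
        stop(sprintf("node %s over-constrained: fixed product %.3f vs required %.3f",
                     node, prod_fixed, req))
      }
      next
    }
    target <- req / prod_fixed
    pf <- tab$potency[free]
    dirf <- tab$direction[free]
    capf <- tab$cap[free]
    g <- function(phi) {
      prod(ifelse(dirf == "down", 1 - pmin(phi * pf, capf),
                  1 + phi * pf)) - target
    }
    lo <- 0; hi <- 1
    if (g(0) * g(hi) > 0) {
      while (g(hi) * g(0) > 0 && hi < 40) hi <- hi * 1.6
      if (g(0) * g(hi) > 0) {
        stop(sprintf("cannot renormalise node %s to %.3f (fixed %.3f)",
                     node, req, prod_fixed))
      }
    }
    phi <- stats::uniroot(g, c(lo, hi), tol = 1e-12)$root
    tab$potency[free] <- pmin(phi * pf, tab$cap[free])
    if (verbose) {
      message(sprintf("  node %-12s phi=%.3f (required %.4f)", node, phi, req))
    }
  }
  formulation(tab[, c("ingredient", "class", "node", "direction", "potency")])
}

# secant/bisection hybrid for the 1-D efficacy fits (monotone in lambda)
uniroot_scale <- function(f, lo = 0.05, hi = 3, verbose = FALSE, label = "") {
  flo <- f(lo)
  fhi <- f(hi)
  tries <- 0
  while (flo * fhi > 0 && tries < 6) {
    hi <- hi * 1.7
    fhi <- f(hi)
    tries <- tries + 1
  }
  if (flo * fhi > 0) {
    stop("efficacy fit cannot bracket target for group ", label)
  }
  stats::uniroot(f, c(lo, hi), tol = 1e-4)$root
}
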