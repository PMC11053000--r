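#' Integrate the stress network
#'
#' Solves the ODE system with a stiff solver (lsoda) and returns the
#' trajectory on the requested output grid. Integration tolerances are
#' recorded in the result's attributes.
#'
#' @param state0 Initial `species_state`.
#' @param params `kinetic_parameters`.
#' @param topology `network_topology`.
#' @param duration Simulated time (days), > 0.
#' @param output_grid Output times within `[0, duration]`; defaults to 201
#'   equally spaced points.
#' @param rtol,atol Relative/absolute integration tolerances.
#' @return A data.frame with a `time` column and one column per species;
#'   attributes `rtol`, `atol`, `solver`.
#' @export
simulate <- function(state0, params, topology = network_topology(),
                     duration, output_grid = NULL,
                     rtol = 1e-8, atol = 1e-10) {
  if (!is.numeric(duration) || length(duration) != 1 || duration <= 0) {
    stop("duration must be a positive scalar (days)")
  }
  if (is.null(output_grid)) output_grid <- seq(0, duration, length.out = 201)
  if (any(output_grid < 0) || any(output_grid > duration + 1e-12)) {
    stop("output_grid must lie within [0, duration]")
  }
  y0 <- as.numeric(state0)[seq_along(species_names())]
  names(y0) <- species_names()
  validate_state(y0)
  validate_parameters(params)
  th <- list2env(as.list(params$theta))
  f <- function(t, y, parms) {
    list(rhs_kernel(pmax(y, 0), th))
  }
  times <- sort(unique(c(0, output_grid)))
  sol <- deSolve::ode(y = y0, times = times, func = f, parms = NULL,
                      method = "lsoda", rtol = rtol, atol = atol)
  if (attr(sol, "istate")[1] < 0) {
    last_t <- max(sol[, "time"], na.rm = TRUE)
    stop(sprintf("integration failed; last valid time %.4g days", last_t))
  }
  out <- as.data.frame(sol)
  names(out)[1] <- "time"
  out <- out[out$time %in% output_grid | seq_len(nrow(out)) == 1, ]
  rownames(out) <- NULL
  attr(out, "rtol") <- rtol
  attr(out, "atol") <- atol
  attr(out, "solver") <- "lsoda"
  out
}

#' Extract a species state from a trajectory row
#'
#' @param traj_row One row of a [simulate()] result.
#' @return `species_state`.
#' @export
state_from_row <- function(traj_row) {
  x <- as.numeric(traj_row[species_names()])
  names(x) <- species_names()
  species_state(pmax(x, 0))
}

#' Steady state of the network
#'
#' Finds the steady state by integrating towards the attractor and
#' polishing with a damped Newton iteration on the algebraic system
#' rhs = 0 (finite-difference Jacobian). Deterministic for fixed
#' parameters; the returned state carries the final residual as an
#' attribute.
#'
#' @param params `kinetic_parameters`.
#' @param topology `network_topology`.
#' @param init Optional warm-start state (skips most of the transient).
#' @param horizon Integration horizon in days used to approach the
#'   attractor before polishing (default 200).
#' @param tol Convergence criterion: `max|rhs| < tol * max(|state|, 1)`.
#' @return `species_state` with attributes `residual` and `iterations`.
#' @export
steady_state <- function(params, topology = network_topology(), init = NULL,
                         horizon = 200, tol = 1e-10) {
  validate_parameters(params)
  th <- list2env(as.list(params$theta))
  fvec <- function(y) rhs_kernel(pmax(y, 0), th)
  warm <- !is.null(init)
  if (!warm) {
    init <- rep(1, length(species_names()))
    names(init) <- species_names()
    init["tnfa"] <- 1e-4
    init["cortisol"] <- 10
  }
  y0 <- as.numeric(init)[seq_along(species_names())]
  names(y0) <- species_names()
  # enforce pool consistency of the start
  y0["pirs"] <- min(y0["pirs"], params$totals[["irs"]])
  y0["irs"] <- params$totals[["irs"]] - y0["pirs"]
  y0["pakt"] <- min(y0["pakt"], params$totals[["akt"]])
  y0["akt"] <- params$totals[["akt"]] - y0["pakt"]
  y <- if (warm) newton_steady(fvec, y0, params) else NULL
  if (is.null(y)) {
    # pseudo-transient continuation towards the attractor, then polish
    y1 <- ptc_steady(fvec, y0, params)
    y <- if (!is.null(y1)) newton_steady(fvec, y1, params) else NULL
  }
  if (is.null(y)) {
    tr <- simulate(species_state(y0), params, topology, duration = horizon,
                   output_grid = c(horizon / 2, horizon), rtol = 1e-8,
                   atol = 1e-12)
    y1 <- as.numeric(tr[nrow(tr), species_names()])
    names(y1) <- species_names()
    y <- newton_steady(fvec, y1, params)
    if (is.null(y)) y <- y1
  }
  finish_steady(y, fvec, params, tol)
}

finish_steady <- function(y, fvec, params, tol) {
  res <- max(abs(fvec(y)))
  scale <- max(max(abs(y)), 1)
  if (res >= tol * scale) {
    stop(sprintf(
      "steady state did not converge: residual %.3g (tolerance %.3g)",
      res, tol * scale))
  }
  st <- species_state(pmax(y, 0))
  attr(st, "residual") <- res
  st
}

# Damped chord Newton with finite-difference Jacobian (refreshed only when
# progress stalls); returns NULL on failure. The conserved IRS/AKT pools
# make the full Jacobian singular, so the iteration runs in the reduced
# space with irs = total_irs - pirs and akt = total_akt - pakt.
newton_steady <- function(fvec_full, y0_full, params, max_iter = 80) {
  i_irs <- .SP[["irs"]]; i_pirs <- .SP[["pirs"]]
  i_akt <- .SP[["akt"]]; i_pakt <- .SP[["pakt"]]
  keep <- setdiff(seq_along(y0_full), c(i_irs, i_akt))
  tot_irs <- params$totals[["irs"]]; tot_akt <- params$totals[["akt"]]
  expand <- function(yr) {
    y <- numeric(length(y0_full))
    y[keep] <- yr
    y[i_pirs] <- min(max(y[i_pirs], 0), tot_irs)
    y[i_pakt] <- min(max(y[i_pakt], 0), tot_akt)
    y[i_irs] <- tot_irs - y[i_pirs]
    y[i_akt] <- tot_akt - y[i_pakt]
    y
  }
  fvec <- function(yr) fvec_full(expand(yr))[keep]
  y <- pmax(y0_full[keep], 0)
  n <- length(y)
  fy <- fvec(y)
  Jlu <- NULL
  fresh <- FALSE
  refresh <- function() {
    J <- matrix(0, n, n)
    h <- pmax(abs(y), 1e-8) * 1e-7
    for (j in seq_len(n)) {
      yp <- y
      yp[j] <- yp[j] + h[j]
      J[, j] <- (fvec(yp) - fy) / h[j]
    }
    tryCatch(lu_factor(J), error = function(e) NULL)
  }
  for (it in seq_len(max_iter)) {
    nf <- max(abs(fy))
    if (nf < 1e-13 * max(max(abs(y)), 1)) break
    if (is.null(Jlu)) {
      Jlu <- refresh()
      fresh <- TRUE
      if (is.null(Jlu)) return(NULL)
    }
    step <- lu_solve(Jlu, -fy)
    if (any(!is.finite(step))) return(NULL)
    lambda <- 1
    improved <- FALSE
    for (k in 1:6) {
      y_new <- y + lambda * step
      if (all(y_new > -1e-12)) {
        f_new <- fvec(pmax(y_new, 0))
        if (max(abs(f_new)) < nf * (1 - 1e-4 * lambda) ||
            max(abs(f_new)) < 1e-13) {
          y <- pmax(y_new, 0); fy <- f_new; improved <- TRUE
          break
        }
      }
      lambda <- lambda / 2
    }
    if (!improved || max(abs(fy)) > 0.25 * nf) {
      # stalled or slow contraction: refresh the Jacobian once
      if (fresh && !improved) return(NULL)
      Jlu <- NULL
      fresh <- FALSE
      if (!improved) next
    } else {
      fresh <- FALSE
    }
  }
  if (max(abs(fy)) > 1e-9 * max(max(abs(y)), 1)) return(NULL)
  out <- expand(y)
  names(out) <- species_names()
  out
}

lu_factor <- function(J) list(qr = qr(J))
lu_solve <- function(f, b) solve(f$qr, b)

# Pseudo-transient continuation (switched-evolution relaxation): implicit
# Euler steps with a growing pseudo-timestep, robust far from the fixed
# point where undamped Newton fails.
ptc_steady <- function(fvec_full, y0_full, params, max_iter = 200) {
  i_irs <- .SP[["irs"]]; i_pirs <- .SP[["pirs"]]
  i_akt <- .SP[["akt"]]; i_pakt <- .SP[["pakt"]]
  keep <- setdiff(seq_along(y0_full), c(i_irs, i_akt))
  tot_irs <- params$totals[["irs"]]; tot_akt <- params$totals[["akt"]]
  expand <- function(yr) {
    y <- numeric(length(y0_full))
    y[keep] <- yr
    y[i_pirs] <- min(max(y[i_pirs], 0), tot_irs)
    y[i_pakt] <- min(max(y[i_pakt], 0), tot_akt)
    y[i_irs] <- tot_irs - y[i_pirs]
    y[i_akt] <- tot_akt - y[i_pakt]
    y
  }
  fvec <- function(yr) fvec_full(expand(yr))[keep]
  y <- pmax(y0_full[keep], 0)
  n <- length(y)
  fy <- fvec(y)
  nf0 <- max(abs(fy))
  if (nf0 < 1e-12) return(expand(y))
  delta <- 0.2
  J <- NULL
  age <- 0L
  for (it in seq_len(max_iter)) {
    if (is.null(J) || age >= 5L) {
      J <- matrix(0, n, n)
      h <- pmax(abs(y), 1e-8) * 1e-7
      for (j in seq_len(n)) {
        yp <- y
        yp[j] <- yp[j] + h[j]
        J[, j] <- (fvec(yp) - fy) / h[j]
      }
      age <- 0L
    }
    A <- diag(1 / delta, n) - J
    step <- tryCatch(solve(A, fy), error = function(e) NULL)
    if (is.null(step) || any(!is.finite(step))) return(NULL)
    y_new <- pmax(y + step, 0)
    f_new <- fvec(y_new)
    nf_new <- max(abs(f_new))
    nf <- max(abs(fy))
    if (nf_new <= nf * 1.05) {
      y <- y_new; fy <- f_new
      delta <- min(delta * max(nf / max(nf_new, 1e-15), 1.2), 1e6)
      age <- age + 1L
      if (nf_new < 1e-10 * max(max(abs(y)), 1)) break
    } else {
      delta <- delta / 4
      age <- 5L  # force refresh on next failure recovery
      if (delta < 1e-8) return(NULL)
    }
  }
  expand(y)
}

#' Fold change between two positive values
#'
#' @param pre_value,post_value Positive scalars.
#' @return `pre_value / post_value`.
#' @export
fold_change <- function(pre_value, post_value) {
  if (!is.numeric(pre_value) || !is.numeric(post_value)) {
    stop("fold_change expects numeric inputs")
  }
  if (any(post_value == 0)) stop("fold_change undefined for post_value = 0")
  if (any(pre_value <= 0) || any(post_value < 0)) {
    stop("fold_change requires positive values")
  }
  pre_value / post_value
}
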