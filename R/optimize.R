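#' Optimization settings
#'
#' Shared settings for the quasi-Newton minimizer and the dimer
#' transition-state search.  The gradient convergence criterion is the
#' maximum absolute gradient component in atomic units; the default 1e-4
#' hartree/bohr is the working criterion for all stationary-point searches
#' in this package.
#'
#' @param gradient_convergence max abs gradient component (hartree/bohr,
#'   > 0; default 1e-4).
#' @param max_steps maximum optimizer steps (>= 1).
#' @param max_step_length largest allowed displacement of any single
#'   coordinate per step (bohr); caps the quasi-Newton step.
#' @param dimer_separation half-distance between the dimer images (bohr).
#' @param rotation_tol rotational-force convergence threshold for the dimer
#'   rotation loop (hartree/bohr).
#' @param max_rotations rotation iterations per translation step.
#' @param curvature_tol eigenvalues with |lambda| below this (hartree/
#'   bohr^2) are treated as zero modes when classifying stationary points.
#' @param seed integer seed for any randomized choice (currently only the
#'   dimer's fallback initial orientation).
#' @return a list of class `opt_settings`.
#' @export
opt_settings <- function(gradient_convergence = 1e-4, max_steps = 500L,
                         max_step_length = 0.3, dimer_separation = 1e-3,
                         rotation_tol = 1e-4, max_rotations = 25L,
                         curvature_tol = 1e-6, seed = 1L) {
  stopifnot(gradient_convergence > 0, max_steps >= 1, max_step_length > 0,
            dimer_separation > 0, rotation_tol > 0, curvature_tol > 0)
  structure(list(gradient_convergence = gradient_convergence,
                 max_steps = as.integer(max_steps),
                 max_step_length = max_step_length,
                 dimer_separation = dimer_separation,
                 rotation_tol = rotation_tol,
                 max_rotations = as.integer(max_rotations),
                 curvature_tol = curvature_tol,
                 seed = as.integer(seed)),
            class = "opt_settings")
}

## free-coordinate bookkeeping: frozen atoms contribute no optimization dofs
.free_index <- function(geom) {
  frozen <- geom$frozen_mask
  if (is.null(frozen)) frozen <- rep(FALSE, n_atoms(geom))
  which(!rep(frozen, times = 3))  # column-major over N x 3
}

#' Minimize a geometry on a (modified) potential energy surface
#'
#' BFGS quasi-Newton minimization with backtracking (Armijo) line search.
#' Converged means the maximum absolute gradient component over the free
#' coordinates is at or below `settings$gradient_convergence`.  Frozen
#' atoms never move.  Energy is non-increasing across accepted steps, and
#' the trajectory is deterministic for identical settings and start.
#'
#' @param geom starting [geometry()].
#' @param pes a [potential_backend()] or [compose_modified_pes()] surface.
#' @param settings an [opt_settings()] list.
#' @param characterize if TRUE (default) compute the Hessian at the end
#'   point and classify it; set FALSE to skip the (3N)^2 gradient calls.
#' @return a `stationary_point` object; `converged = FALSE` (with the
#'   diagnostics retained) if `max_steps` was exhausted.
#' @examples
#' sp <- minimize(geometry("X", c(1.5, 0, 0)),
#'                quartic_double_well_backend(1, 2))
#' sp$geometry$coords[1, 1]  # close to +1 = sqrt(b / 2a)
#' @export
minimize <- function(geom, pes, settings = opt_settings(),
                     characterize = TRUE) {
  x_full <- .working_coords(geom, pes)
  free <- .free_index(geom)
  nfree <- length(free)
  if (nfree == 0) stop("all atoms are frozen; nothing to optimize",
                       call. = FALSE)
  x <- as.vector(x_full)
  efun <- function(v) {
    xf <- x; xf[free] <- v
    pes$energy(matrix(xf, ncol = 3))
  }
  gfun <- function(v) {
    xf <- x; xf[free] <- v
    as.vector(.grad_matrix(pes, matrix(xf, ncol = 3)))[free]
  }
  v <- x[free]
  e <- efun(v)
  g <- gfun(v)
  h_inv <- diag(nfree)
  converged <- max(abs(g)) <= settings$gradient_convergence
  steps <- 0L
  while (!converged && steps < settings$max_steps) {
    p <- -as.vector(h_inv %*% g)
    if (sum(p * g) >= 0) {   # not a descent direction: reset to steepest
      h_inv <- diag(nfree)
      p <- -g
    }
    ## cap the raw step so no coordinate moves more than max_step_length
    cap <- max(abs(p))
    t_step <- if (cap > settings$max_step_length) {
      settings$max_step_length / cap
    } else 1
    gp <- sum(g * p)
    repeat {
      e_new <- efun(v + t_step * p)
      if (is.finite(e_new) && e_new <= e + 1e-4 * t_step * gp) break
      t_step <- t_step / 2
      if (t_step < 1e-14) break
    }
    if (t_step < 1e-14) break  # line search failed; report non-convergence
    s <- t_step * p
    v_new <- v + s
    g_new <- gfun(v_new)
    y <- g_new - g
    sy <- sum(s * y)
    if (sy > 1e-12) {
      rho <- 1 / sy
      i_m <- diag(nfree)
      left <- i_m - rho * outer(s, y)
      h_inv <- left %*% h_inv %*% t(left) + rho * outer(s, s)
    }
    v <- v_new; e <- e_new; g <- g_new
    steps <- steps + 1L
    converged <- max(abs(g)) <= settings$gradient_convergence
  }
  x[free] <- v
  out_geom <- .working_geom(matrix(x, ncol = 3), geom, pes)
  .make_stationary_point(out_geom, pes, settings, energy = e,
                         max_grad = max(abs(g)), converged = converged,
                         n_steps = steps, characterize = characterize)
}

## gradient as N x 3 on working coordinates (analytic or finite differences)
.grad_matrix <- function(pes, x) {
  if (!is.null(pes$gradient)) pes$gradient(x)
  else .fd_gradient(pes$energy, x, 1e-4)
}

.make_stationary_point <- function(geom, pes, settings, energy, max_grad,
                                   converged, n_steps, characterize,
                                   status = NULL) {
  eig <- NULL
  cls <- "unknown"
  if (characterize) {
    sig <- .hessian_signature(geom, pes, settings)
    eig <- sig$eigenvalues
    cls <- sig$classification
  }
  structure(list(geometry = geom, energy = energy,
                 classification = cls, hessian_eigenvalues = eig,
                 converged = converged, n_steps = n_steps,
                 max_gradient = max_grad,
                 pes_signature = pes$name,
                 settings = settings, status = status),
            class = "stationary_point")
}

## Rigid-mode vectors (column-major over the N x 3 coordinate layout) for
## the symmetries the active external terms leave intact.  A free molecular
## surface built from internal coordinates is invariant under all 3
## translations and 3 rotations; the uniaxial compression term breaks
## z-translation and the two tilting rotations, leaving xy-translations and
## the z-rotation; a constant pulling force depends on an interatomic
## distance only and breaks nothing.  Low-dimensional ("internal") backends
## have no rigid symmetries to project.
.rigid_modes <- function(x, pes) {
  if (pes$coord_unit != "angstrom") return(NULL)
  has_uniaxial <- any(vapply(pes$terms %||% list(),
                             function(tm) tm$type == "uniaxial", logical(1)))
  n <- nrow(x)
  xc <- sweep(x, 2, colMeans(x))
  tr <- function(axis) {
    m <- matrix(0, n, 3); m[, axis] <- 1; as.vector(m)
  }
  rot <- function(axis) {
    a <- c(0, 0, 0); a[axis] <- 1
    m <- t(apply(xc, 1, function(r) c(a[2] * r[3] - a[3] * r[2],
                                      a[3] * r[1] - a[1] * r[3],
                                      a[1] * r[2] - a[2] * r[1])))
    as.vector(m)
  }
  vecs <- if (has_uniaxial) cbind(tr(1), tr(2), rot(3))
  else cbind(tr(1), tr(2), tr(3), rot(1), rot(2), rot(3))
  ## orthonormalize, dropping rank-deficient directions (linear molecules)
  q <- qr(vecs)
  qr.Q(q)[, seq_len(q$rank), drop = FALSE]
}

## Hessian eigenvalue signature with the term-dependent rigid modes
## projected out before counting; returns the raw sorted eigenvalues (for
## inspection) and the classification over the projected spectrum.
.hessian_signature <- function(geom, pes, settings) {
  h <- evaluate_hessian(geom, pes)
  raw <- sort(eigen(h, symmetric = TRUE, only.values = TRUE)$values)
  modes <- .rigid_modes(.working_coords(geom, pes), pes)
  used <- raw
  if (!is.null(modes)) {
    p <- diag(nrow(h)) - tcrossprod(modes)
    ph <- p %*% h %*% p
    ev <- sort(eigen((ph + t(ph)) / 2, symmetric = TRUE,
                     only.values = TRUE)$values)
    ## drop exactly the projected-out directions (eigenvalues pinned to 0)
    drop_idx <- order(abs(ev))[seq_len(ncol(modes))]
    used <- sort(ev[-drop_idx])
  }
  list(eigenvalues = raw, eigenvalues_used = used,
       classification = .classify_eigenvalues(used, settings$curvature_tol),
       n_projected = if (is.null(modes)) 0L else ncol(modes))
}

#' @export
print.stationary_point <- function(x, ...) {
  cat(sprintf("<stationary_point: %s, E = %.8f hartree, %s after %d steps (max |g| = %.2e)>\n",
              x$classification, x$energy,
              if (x$converged) "converged" else "NOT converged",
              x$n_steps, x$max_gradient))
  invisible(x)
}

## eigenvalue-signature rule: zero modes (|lambda| < tol) are excluded
## before counting.  For free 3-D molecules the 6 rigid-body modes (5 for
## linear) show up as zeros automatically since the built-in molecular
## surfaces depend on internal coordinates only; external terms that break
## a rigid symmetry (z-translation / tilt rotations under compression, the
## pulling axis modes) lift the corresponding zeros, so the count adapts to
## the active terms without an explicit projection step.
.classify_eigenvalues <- function(eig, tol) {
  n_neg <- sum(eig < -tol)
  if (n_neg == 0) "minimum"
  else if (n_neg == 1) "first_order_saddle"
  else "other"
}

#' Classify a stationary point by its Hessian eigenvalue signature
#'
#' Minima have a positive-definite Hessian over the non-zero modes; a
#' transition state shows exactly one negative eigenvalue.  Eigenvalues
#' with magnitude below `settings$curvature_tol` are treated as zero modes
#' (rigid-body motions or symmetry-protected directions) and excluded from
#' the count.
#'
#' Rigid modes that would show as exact zeros at a perfectly converged
#' stationary point (the active-term-dependent set described above) are
#' projected out before counting, so finite optimizer tolerances cannot
#' push a symmetry mode across the sign threshold.
#'
#' @param point a `stationary_point` or an [geometry()] at (near-)zero
#'   gradient.
#' @param pes the surface the point lives on.
#' @param settings an [opt_settings()] list (supplies the gradient
#'   threshold and curvature tolerance).
#' @return a list with `classification` (`"minimum"`,
#'   `"first_order_saddle"` or `"other"`), the sorted raw `eigenvalues`,
#'   the post-projection `eigenvalues_used`, `n_projected`, and
#'   `n_zero_modes` (raw eigenvalues below the curvature tolerance in
#'   magnitude).
#' @export
classify <- function(point, pes, settings = opt_settings()) {
  geom <- if (inherits(point, "stationary_point")) point$geometry else point
  g <- evaluate_gradient(geom, pes)
  if (max(abs(g)) > 10 * settings$gradient_convergence) {
    stop(sprintf(
      "not a stationary point: max |gradient| = %.3e exceeds 10 x threshold %.1e",
      max(abs(g)), settings$gradient_convergence), call. = FALSE)
  }
  sig <- .hessian_signature(geom, pes, settings)
  c(sig,
    list(n_zero_modes = sum(abs(sig$eigenvalues) < settings$curvature_tol)))
}
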