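#' Dimer-method transition-state search
#'
#' Walks a starting structure in a barrier region to a first-order saddle
#' point without ever computing a full Hessian during the walk: two closely
#' spaced replicas of the system estimate the lowest-curvature mode, the
#' dimer is rotated to align with that mode (Fourier-expansion rotation
#' steps on the rotational force), and the translation step reverses the
#' force component along the mode ("effective force") so the optimizer
#' climbs the mode while relaxing all others.
#'
#' The initial dimer orientation is the lowest-eigenvalue Hessian
#' eigenvector at the start when `init_orientation = "hessian"` (cheap on
#' every built-in analytic surface), or a seeded random unit vector.  After
#' convergence the Hessian at the end point is computed and the point is
#' classified; convergence to anything other than a first-order saddle is
#' reported honestly via the `classification` field and a `status` note,
#' never silently.
#'
#' @param geom starting [geometry()] near a barrier region (e.g. a midpoint
#'   interpolation between reactant and product).
#' @param pes a [potential_backend()] or [compose_modified_pes()] surface.
#' @param settings an [opt_settings()] list; `dimer_separation`,
#'   `rotation_tol`, `max_rotations` and `seed` belong to this search.
#' @param init_orientation `"hessian"` (default) or `"random"`.
#' @return a `stationary_point` object.
#' @examples
#' ts <- dimer_ts_search(geometry("X", c(0.3, 0, 0)),
#'                       quartic_double_well_backend(1, 2))
#' ts$classification  # "first_order_saddle"
#' @export
dimer_ts_search <- function(geom, pes, settings = opt_settings(),
                            init_orientation = c("hessian", "random")) {
  init_orientation <- match.arg(init_orientation)
  x_full <- .working_coords(geom, pes)
  free <- .free_index(geom)
  nfree <- length(free)
  x0 <- as.vector(x_full)
  gfun <- function(v) {
    xf <- x0; xf[free] <- v
    as.vector(.grad_matrix(pes, matrix(xf, ncol = 3)))[free]
  }
  v <- x0[free]

  if (init_orientation == "hessian") {
    h <- evaluate_hessian(geom, pes)[free, free, drop = FALSE]
    ev <- eigen((h + t(h)) / 2, symmetric = TRUE)
    tau <- ev$vectors[, which.min(ev$values)]
  } else {
    old_seed <- if (exists(".Random.seed", .GlobalEnv)) {
      get(".Random.seed", .GlobalEnv)
    }
    on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                           .GlobalEnv))
    set.seed(settings$seed)
    tau <- stats::rnorm(nfree)
  }
  tau <- tau / sqrt(sum(tau^2))

  efun <- function(vv) {
    xf <- x0; xf[free] <- vv
    pes$energy(matrix(xf, ncol = 3))
  }
  delta <- settings$dimer_separation
  g <- gfun(v)
  steps <- 0L
  converged <- max(abs(g)) <= settings$gradient_convergence
  while (!converged && steps < settings$max_steps) {
    rot <- .dimer_rotate(gfun, v, g, tau, delta, settings)
    tau <- rot$tau
    curv <- rot$curvature
    ## climb along the dimer axis: Newton step on the 1-D cut using the
    ## measured curvature (falls back to a capped push when the region is
    ## still convex along tau), then relax perpendicular to the axis with
    ## an Armijo-controlled descent step (valid: to first order the energy
    ## decreases along the projected gradient).
    g_par <- sum(g * tau)
    s_par <- if (curv < -settings$curvature_tol) {
      -g_par / curv
    } else {
      sign(g_par) * min(abs(g_par) / max(abs(curv), 1e-3),
                        settings$max_step_length)
    }
    s_par <- max(-settings$max_step_length,
                 min(settings$max_step_length, s_par))
    v <- v + s_par * tau
    g <- gfun(v)
    ## inner relaxation: BFGS with Armijo backtracking on the energy
    ## restricted to the hyperplane orthogonal to the dimer axis, until the
    ## transverse gradient is subdominant so the axis climb stays on track
    h_inv <- diag(nfree)
    g_perp <- g - sum(g * tau) * tau
    for (inner in seq_len(15L)) {
      ng <- sqrt(sum(g_perp^2))
      if (ng <= max(0.3 * abs(sum(g * tau)),
                    0.3 * settings$gradient_convergence)) break
      p <- -as.vector(h_inv %*% g_perp)
      p <- p - sum(p * tau) * tau
      if (sum(p * g_perp) >= 0) {
        h_inv <- diag(nfree)
        p <- -g_perp
      }
      t_step <- min(1, settings$max_step_length / max(abs(p)))
      e0 <- efun(v)
      gp <- sum(g_perp * p)
      repeat {
        e_new <- efun(v + t_step * p)
        if (is.finite(e_new) && e_new <= e0 + 1e-4 * t_step * gp) break
        t_step <- t_step / 2
        if (t_step < 1e-14) break
      }
      if (t_step < 1e-14) break
      s_in <- t_step * p
      v <- v + s_in
      g <- gfun(v)
      g_perp_new <- g - sum(g * tau) * tau
      y_in <- g_perp_new - g_perp
      sy <- sum(s_in * y_in)
      if (sy > 1e-14) {
        rho <- 1 / sy
        left <- diag(nfree) - rho * outer(s_in, y_in)
        h_inv <- left %*% h_inv %*% t(left) + rho * outer(s_in, s_in)
      }
      g_perp <- g_perp_new
    }
    steps <- steps + 1L
    converged <- max(abs(g)) <= settings$gradient_convergence
  }
  x0[free] <- v
  out_geom <- .working_geom(matrix(x0, ncol = 3), geom, pes)
  sp <- .make_stationary_point(out_geom, pes, settings,
                               energy = pes$energy(matrix(x0, ncol = 3)),
                               max_grad = max(abs(g)), converged = converged,
                               n_steps = steps, characterize = TRUE)
  if (sp$converged && sp$classification != "first_order_saddle") {
    sp$status <- sprintf("dimer search converged to a %s, not a saddle",
                         sp$classification)
    warning(sp$status, call. = FALSE)
  } else if (!sp$converged) {
    sp$status <- sprintf("dimer search not converged after %d steps", steps)
  }
  sp
}

## Rotate the dimer orientation tau at midpoint v to the lowest-curvature
## mode.  Curvature along tau: c(tau) = (g1 - g0) . tau / delta with g1 the
## gradient at v + delta * tau.  The rotational force is the transverse
## part of (g1 - g0); each iteration takes one Fourier-expansion rotation
## step (trial angle pi/8) in the plane spanned by tau and the normalized
## rotational force.
.dimer_rotate <- function(gfun, v, g0, tau, delta, settings) {
  curv <- NA_real_
  ## tighten the rotation as the translation converges: a residual axis
  ## error re-injects parallel force into the transverse relaxation and
  ## stalls the walk near the saddle
  tol_rot <- max(min(settings$rotation_tol, 0.1 * max(abs(g0))), 1e-10)
  ## central dimer images: curvature and rotational force accurate to
  ## O(separation^2), which the tight-convergence regime needs
  dcurv <- function(t_) (gfun(v + delta * t_) - gfun(v - delta * t_)) /
    (2 * delta)
  for (it in seq_len(settings$max_rotations)) {
    dg <- dcurv(tau)
    curv <- sum(dg * tau)
    f_rot <- -(dg - curv * tau)      # per unit rotation angle
    if (sqrt(sum(f_rot^2)) < tol_rot) break
    u <- f_rot - sum(f_rot * tau) * tau
    nu <- sqrt(sum(u^2))
    if (nu < 1e-14) break
    u <- u / nu
    dcdt <- 2 * sum(dg * u)          # dc/dtheta at theta = 0
    theta_t <- pi / 8
    tau_t <- cos(theta_t) * tau + sin(theta_t) * u
    c_t <- sum(dcurv(tau_t) * tau_t)
    b1 <- 0.5 * dcdt
    a1 <- (curv - c_t + b1 * sin(2 * theta_t)) / (1 - cos(2 * theta_t))
    theta_min <- 0.5 * atan2(b1, a1)
    ## pick the rotation that lowers the curvature
    c_min <- (curv - a1) + a1 * cos(2 * theta_min) + b1 * sin(2 * theta_min)
    if (c_min > curv) theta_min <- theta_min + pi / 2
    tau <- cos(theta_min) * tau + sin(theta_min) * u
    tau <- tau / sqrt(sum(tau^2))
  }
  list(tau = tau, curvature = curv)
}
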