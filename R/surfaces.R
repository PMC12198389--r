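#' Mueller-Brown benchmark surface
#'
#' The classic two-dimensional four-Gaussian benchmark with three minima and
#' two first-order saddles, widely used to exercise minimizers and
#' saddle-search algorithms.  Represented as a single pseudo-atom: the x and
#' y coordinates of atom 1 are the surface coordinates, z is ignored (its
#' gradient is identically zero).  Coordinates and energies are in the
#' surface's own units, treated as atomic units throughout.
#'
#' @return a [potential_backend()] with analytic gradient and Hessian.
#' @examples
#' mb <- muller_brown_backend()
#' evaluate_energy(geometry("X", c(-0.558, 1.442, 0)), mb)
#' @export
muller_brown_backend <- function() {
  A <- c(-200, -100, -170, 15)
  a <- c(-1, -1, -6.5, 0.7)
  b <- c(0, 0, 11, 0.6)
  cc <- c(-10, -10, -6.5, 0.7)
  x0 <- c(1, 0, -0.5, -1)
  y0 <- c(0, 0.5, 1.5, 1)
  terms <- function(x, y) {
    dx <- x - x0; dy <- y - y0
    A * exp(a * dx^2 + b * dx * dy + cc * dy^2)
  }
  potential_backend(
    name = "muller_brown",
    energy = function(xm) {
      sum(terms(xm[1, 1], xm[1, 2]))
    },
    gradient = function(xm) {
      x <- xm[1, 1]; y <- xm[1, 2]
      dx <- x - x0; dy <- y - y0
      tt <- terms(x, y)
      rbind(c(sum(tt * (2 * a * dx + b * dy)),
              sum(tt * (b * dx + 2 * cc * dy)), 0))
    },
    hessian = function(xm) {
      x <- xm[1, 1]; y <- xm[1, 2]
      dx <- x - x0; dy <- y - y0
      tt <- terms(x, y)
      u <- 2 * a * dx + b * dy
      v <- b * dx + 2 * cc * dy
      h <- matrix(0, 3, 3)
      h[1, 1] <- sum(tt * (u^2 + 2 * a))
      h[2, 2] <- sum(tt * (v^2 + 2 * cc))
      h[1, 2] <- h[2, 1] <- sum(tt * (u * v + b))
      h
    },
    n_atoms = 1, coord_unit = "internal"
  )
}

#' One-dimensional quartic double well
#'
#' V(x) = a x^4 - b x^2 on the x coordinate of a single pseudo-atom (y and z
#' ignored).  Closed forms used throughout the test suite: minima at
#' x = +/- sqrt(b / 2a), saddle at x = 0, barrier V_A = b^2 / (4a), second
#' derivative 12 a x^2 - 2 b.
#'
#' @param a,b positive well parameters (atomic units).
#' @return a [potential_backend()] with analytic gradient and Hessian.
#' @export
quartic_double_well_backend <- function(a = 1, b = 2) {
  stopifnot(a > 0, b > 0)
  potential_backend(
    name = sprintf("quartic_double_well(a=%g,b=%g)", a, b),
    energy = function(xm) {
      x <- xm[1, 1]
      a * x^4 - b * x^2
    },
    gradient = function(xm) {
      x <- xm[1, 1]
      rbind(c(4 * a * x^3 - 2 * b * x, 0, 0))
    },
    hessian = function(xm) {
      x <- xm[1, 1]
      h <- matrix(0, 3, 3)
      h[1, 1] <- 12 * a * x^2 - 2 * b
      h
    },
    n_atoms = 1, coord_unit = "internal"
  )
}

## --------------------------------------------------------------------------
## bead-spring flex mechanophore toy
##
## A five-bead stand-in for a flex-activated mechanophore: a wide triangular
## base pad (atoms 1-2-3, the crosslinked anchor; atoms 1 and 2 are the
## polymer attachment points), an apex linker bead 4 bonded to all three pad
## atoms, and a payload bead 5 on the reactive (scissile) bond 4-5, tilted
## away from the pad normal.  The reactive bond sees a double well in its
## length d45 (bound well, barrier, cleaved well) whose barrier height is
## modulated by the bend angle 3-4-5 adjacent to the scissile bond: angular
## distortion away from the rest angle lowers the barrier
##
##   V_rxn = B(delta) * ((u^2 - 1)^2),  u = (d45 - r_ts) / w,
##   B(delta) = B0 * exp(-alpha * delta^2),  delta = theta_345 - theta0_345.
##
## This is the flex-activation motif in miniature, with the geometric
## frustration that makes compression productive: the wide pad pins the
## molecule's orientation against the compression plane (rigid rotation
## cannot hide the payload), the tilted payload bond couples linearly to a
## vertical squeeze, so pressing the structure toward the xy-plane must
## bend theta_345 — which switches the barrier off — while pulling the two
## attachment atoms apart is an x-symmetric deformation that leaves the
## bend angle nearly untouched.  Because B'(0) = 0 and the double well has
## stationary points exactly at u = -1 (reactant), u = 0 (transition state)
## and u = +1 (product), the unperturbed reactant and transition state sit
## exactly at the reference internal coordinates and the unperturbed
## barrier is exactly B0.
##
## All terms are functions of internal coordinates only, so the energy is
## rigorously invariant under rigid translations and rotations.
## --------------------------------------------------------------------------

## reference geometry in Angstrom (rows: atoms 1..5).  The payload azimuth
## is offset 20 degrees from the pad's mirror plane: a perfectly mirror-
## symmetric toy would put the compressed transition state on a pitchfork
## bifurcation (the sideways tilt mode buckles), whereas the offset unfolds
## every branch into a smooth, unique function of the compression strength
## — as for a real, unsymmetric mechanophore.
.bsf_reference_ang <- function() {
  tilt <- 90 * pi / 180   # payload bond tilt from the pad normal:
                          # horizontal, so stretching the scissile bond adds
                          # no height and compression couples maximally to
                          # the bend
  az <- 20 * pi / 180     # azimuth offset from the +y mirror plane
  p4 <- c(0, 0, 2.4)
  p5 <- p4 + 1.5 * c(sin(tilt) * sin(az), sin(tilt) * cos(az), cos(tilt))
  rbind(c(-3.04, -1.76, 0.0),
        c( 3.04, -1.76, 0.0),
        c( 0.00,  3.52, 0.0),
        p4,
        p5)
}

#' Bead-spring flex mechanophore toy surface
#'
#' A five-bead analytic molecular surface with a reactive bond whose
#' dissociation barrier is coupled to an adjacent bend angle, mimicking a
#' flex-activated mechanophore (see the package vignette for the closed
#' form).  A wide triangular base pad (atoms 1-2-3) anchors an apex linker
#' (atom 4) carrying the payload (atom 5) on a tilted scissile bond;
#' harmonic bonds and angle restraints hold the frame, and the reactive
#' bond 4-5 carries a double well of barrier `B0 * exp(-alpha * delta^2)`
#' where `delta` is the distortion of the bend angle 3-4-5 from its rest
#' value.  Atoms 1 and 2 are the polymer attachment points.  The
#' unperturbed barrier equals `B0` exactly; bending the 3-4-5 angle (which
#' is what uniaxial compression toward the xy-plane must do to flatten the
#' structure) lowers it, while pulling 1-2 apart is an x-symmetric
#' deformation that leaves it nearly unchanged.
#'
#' @param B0 unperturbed reaction barrier (hartree; default 0.05, about
#'   31.4 kcal/mol, a typical mechanophore scale).
#' @param alpha angle-coupling strength (1/rad^2); larger values switch the
#'   barrier off at smaller angular distortion, but `2 * alpha * B0` must
#'   stay below the bend-mode stiffness for the transition state to remain
#'   a first-order saddle.
#' @param k_bond pad/linker bond force constant (hartree/bohr^2).
#' @param k_angle restraint on the three payload bend angles i-4-5
#'   (hartree/rad^2).
#' @return a [potential_backend()] with analytic gradient (5 atoms,
#'   Angstrom coordinates).
#' @export
bead_spring_flex_backend <- function(B0 = 0.05, alpha = 2.4, k_bond = 0.3,
                                     k_angle = 0.3) {
  stopifnot(B0 > 0, alpha > 0, k_bond > 0, k_angle > 0)
  ref <- .ang_to_bohr(.bsf_reference_ang())
  dref <- function(i, j) sqrt(sum((ref[i, ] - ref[j, ])^2))
  aref <- function(i, j, k) .angle_value(ref[i, ], ref[j, ], ref[k, ])
  r_ts <- dref(4, 5) + 0.5 / .BOHR_ANG   # reactant well at u = -1
  w <- 0.5 / .BOHR_ANG
  bonds <- list(list(i = 1, j = 2, k = k_bond, d0 = dref(1, 2)),
                list(i = 2, j = 3, k = k_bond, d0 = dref(2, 3)),
                list(i = 3, j = 1, k = k_bond, d0 = dref(3, 1)),
                list(i = 1, j = 4, k = k_bond, d0 = dref(1, 4)),
                list(i = 2, j = 4, k = k_bond, d0 = dref(2, 4)),
                list(i = 3, j = 4, k = k_bond, d0 = dref(3, 4)))
  angles <- list(list(i = 1, j = 4, k = 5, kf = k_angle, t0 = aref(1, 4, 5)),
                 list(i = 2, j = 4, k = 5, kf = k_angle, t0 = aref(2, 4, 5)),
                 list(i = 3, j = 4, k = 5, kf = k_angle, t0 = aref(3, 4, 5)))
  t0_flex <- aref(3, 4, 5)
  eval_bsf <- function(x, want_grad) {
    e <- 0
    g <- matrix(0, 5, 3)
    for (b in bonds) {
      d <- sqrt(sum((x[b$i, ] - x[b$j, ])^2))
      e <- e + 0.5 * b$k * (d - b$d0)^2
      if (want_grad) {
        u <- (x[b$i, ] - x[b$j, ]) / d
        f <- b$k * (d - b$d0)
        g[b$i, ] <- g[b$i, ] + f * u
        g[b$j, ] <- g[b$j, ] - f * u
      }
    }
    for (an in angles) {
      av <- .angle_grad(x[an$i, ], x[an$j, ], x[an$k, ])
      e <- e + 0.5 * an$kf * (av$theta - an$t0)^2
      if (want_grad) {
        f <- an$kf * (av$theta - an$t0)
        g[an$i, ] <- g[an$i, ] + f * av$gi
        g[an$j, ] <- g[an$j, ] + f * av$gj
        g[an$k, ] <- g[an$k, ] + f * av$gk
      }
    }
    ## reactive bond with angle-coupled barrier
    av <- .angle_grad(x[3, ], x[4, ], x[5, ])
    delta <- av$theta - t0_flex
    B <- B0 * exp(-alpha * delta^2)
    d45 <- sqrt(sum((x[4, ] - x[5, ])^2))
    u <- (d45 - r_ts) / w
    q <- (u^2 - 1)^2
    e <- e + B * q
    if (want_grad) {
      dBdelta <- B * (-2 * alpha * delta)
      g[3, ] <- g[3, ] + dBdelta * q * av$gi
      g[4, ] <- g[4, ] + dBdelta * q * av$gj
      g[5, ] <- g[5, ] + dBdelta * q * av$gk
      dqdu <- 4 * u * (u^2 - 1)
      ub <- (x[4, ] - x[5, ]) / d45
      g[4, ] <- g[4, ] + B * dqdu / w * ub
      g[5, ] <- g[5, ] - B * dqdu / w * ub
    }
    list(e = e, g = g)
  }
  be <- potential_backend(
    name = "bead_spring_flex",
    energy = function(x) eval_bsf(x, FALSE)$e,
    gradient = function(x) eval_bsf(x, TRUE)$g,
    n_atoms = 5, coord_unit = "angstrom"
  )
  be$params <- list(B0 = B0, alpha = alpha, k_bond = k_bond,
                    k_angle = k_angle, r_ts_bohr = r_ts, w_bohr = w)
  be
}

#' Reference structures of the bead-spring flex toy
#'
#' Exact stationary points of the unperturbed [bead_spring_flex_backend()]:
#' the reactant minimum (reactive bond at its bound length) and the
#' transition state (reactive bond stretched to the barrier top), both at
#' the reference internal coordinates.  Atoms 1 and 2 are marked as the
#' attachment pair.
#'
#' @param which `"reactant"`, `"ts"` or `"product"`.
#' @return an [geometry()] object.
#' @export
bead_spring_flex_geometry <- function(which = c("reactant", "ts", "product")) {
  which <- match.arg(which)
  x <- .bsf_reference_ang()
  ## the double well in d45 has width w = 0.5 Angstrom: wells at -w/+w
  ## around the barrier top
  stretch <- switch(which, reactant = 0, ts = 0.5, product = 1.0)
  u45 <- (x[5, ] - x[4, ]) / sqrt(sum((x[5, ] - x[4, ])^2))
  x[5, ] <- x[5, ] + stretch * u45
  geometry(c("C", "C", "C", "C", "O"), x, attachment_pair = c(1, 2),
           comment = paste0("bead_spring_flex ", which))
}

## angle at j between arms j->i and j->k; value only
.angle_value <- function(pi_, pj, pk) {
  u <- pi_ - pj; v <- pk - pj
  cosang <- sum(u * v) / sqrt(sum(u^2) * sum(v^2))
  acos(max(-1, min(1, cosang)))
}

## angle and analytic gradients w.r.t. the three atom positions
.angle_grad <- function(pi_, pj, pk) {
  u <- pi_ - pj; v <- pk - pj
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  cosang <- sum(u * v) / (nu * nv)
  cosang <- max(-1 + 1e-12, min(1 - 1e-12, cosang))
  theta <- acos(cosang)
  sinang <- sqrt(1 - cosang^2)
  gi <- (cosang * u / nu - v / nv) / (nu * sinang)
  gk <- (cosang * v / nv - u / nu) / (nv * sinang)
  list(theta = theta, gi = gi, gj = -(gi + gk), gk = gk)
}
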