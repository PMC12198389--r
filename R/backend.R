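#' Potential backend contract
#'
#' A potential backend supplies the base (Born-Oppenheimer-like) surface:
#' given coordinates it returns an energy in hartree and, optionally, an
#' analytic gradient in hartree/bohr and an analytic Hessian.  All
#' optimizers, external perturbations and scan drivers in this package talk
#' to the surface exclusively through this contract, so any engine — the
#' built-in analytic toys, or a user-supplied wrapper around a quantum
#' chemistry code — can stand behind it.
#'
#' `coord_unit` controls the coordinate convention: `"angstrom"` backends
#' are molecular, and geometries (stored in Angstrom) are converted to bohr
#' before `energy`/`gradient`/`hessian` are called; `"internal"` backends
#' (the low-dimensional benchmarks) receive the stored coordinates as-is,
#' interpreted in the surface's own (bohr-equivalent) units.
#'
#' @param name identifier used in logs and scan metadata.
#' @param energy function(x) -> scalar hartree, `x` an N x 3 bohr matrix.
#' @param gradient optional function(x) -> N x 3 matrix (hartree/bohr).
#'   When absent, [evaluate_gradient()] falls back to central finite
#'   differences with step 1e-4 bohr.
#' @param hessian optional function(x) -> 3N x 3N matrix.  When absent,
#'   [evaluate_hessian()] uses central finite differences of the gradient
#'   with step 1e-3 bohr.
#' @param n_atoms fixed atom count the backend expects, or NULL for any.
#' @param coord_unit `"angstrom"` or `"internal"` (see above).
#' @return an object of class `potential_backend`.
#' @export
potential_backend <- function(name, energy, gradient = NULL, hessian = NULL,
                              n_atoms = NULL, coord_unit = "angstrom") {
  stopifnot(is.function(energy),
            is.null(gradient) || is.function(gradient),
            is.null(hessian) || is.function(hessian),
            coord_unit %in% c("angstrom", "internal"))
  structure(
    list(name = name, energy = energy, gradient = gradient,
         hessian = hessian,
         analytic_gradient_available = !is.null(gradient),
         n_atoms = if (!is.null(n_atoms)) as.integer(n_atoms),
         coord_unit = coord_unit),
    class = "potential_backend"
  )
}

#' @export
print.potential_backend <- function(x, ...) {
  cat(sprintf("<potential_backend '%s'%s, %s gradient>\n", x$name,
              if (!is.null(x$n_atoms)) sprintf(" (%d atoms)", x$n_atoms)
              else "",
              if (x$analytic_gradient_available) "analytic"
              else "finite-difference"))
  invisible(x)
}

## geometry -> coordinate matrix in the backend's working units, with the
## dimensionality check every evaluate_* shares
.working_coords <- function(geom, backend) {
  if (!inherits(geom, "fmpes_geometry")) {
    stop("expected an fmpes_geometry object", call. = FALSE)
  }
  if (!is.null(backend$n_atoms) && n_atoms(geom) != backend$n_atoms) {
    stop(sprintf(
      "backend '%s' expects %d atom(s) but geometry has %d (shape %d x 3)",
      backend$name, backend$n_atoms, n_atoms(geom), n_atoms(geom)),
      call. = FALSE)
  }
  if (backend$coord_unit == "angstrom") .ang_to_bohr(geom$coords)
  else geom$coords
}

.working_geom <- function(coords_working, geom, backend) {
  if (backend$coord_unit == "angstrom") {
    set_coords(geom, .bohr_to_ang(coords_working))
  } else {
    set_coords(geom, coords_working)
  }
}

#' Evaluate the energy of a geometry on a backend
#'
#' @param geom an [geometry()] object.
#' @param backend a [potential_backend()] (or [compose_modified_pes()]
#'   result, which satisfies the same contract).
#' @return scalar energy in hartree (internal units of the backend).
#' @examples
#' qw <- quartic_double_well_backend(a = 1, b = 2)
#' evaluate_energy(geometry("X", c(1, 0, 0)), qw)  # a - b = -1
#' @export
evaluate_energy <- function(geom, backend) {
  x <- .working_coords(geom, backend)
  e <- backend$energy(x)
  if (!is.finite(e)) {
    stop(sprintf("backend '%s' returned a non-finite energy", backend$name),
         call. = FALSE)
  }
  e
}

#' Evaluate the gradient of a geometry on a backend
#'
#' Uses the backend's analytic gradient when available, otherwise central
#' finite differences of the energy with the given step.
#'
#' @inheritParams evaluate_energy
#' @param fd_step finite-difference step in bohr (default 1e-4), used only
#'   when no analytic gradient is supplied.
#' @return N x 3 gradient matrix in hartree/bohr.
#' @export
evaluate_gradient <- function(geom, backend, fd_step = 1e-4) {
  x <- .working_coords(geom, backend)
  g <- if (!is.null(backend$gradient)) {
    backend$gradient(x)
  } else {
    .fd_gradient(backend$energy, x, fd_step)
  }
  if (!all(is.finite(g))) {
    stop(sprintf("backend '%s' returned a non-finite gradient", backend$name),
         call. = FALSE)
  }
  matrix(g, nrow(x), 3)
}

#' Evaluate the Hessian of a geometry on a backend
#'
#' Central finite differences of the gradient (step `fd_step` bohr) unless
#' the backend supplies an analytic Hessian.  The result is symmetrized as
#' (H + t(H)) / 2.
#'
#' @inheritParams evaluate_energy
#' @param fd_step finite-difference step in bohr (default 1e-3).
#' @return 3N x 3N symmetric matrix in hartree/bohr^2.
#' @export
evaluate_hessian <- function(geom, backend, fd_step = 1e-3) {
  x <- .working_coords(geom, backend)
  h <- if (!is.null(backend$hessian)) {
    backend$hessian(x)
  } else {
    grad_fun <- if (!is.null(backend$gradient)) backend$gradient
    else function(xx) .fd_gradient(backend$energy, xx, 1e-4)
    .fd_hessian(grad_fun, x, fd_step)
  }
  (h + t(h)) / 2
}

.fd_gradient <- function(energy, x, step) {
  g <- matrix(0, nrow(x), ncol(x))
  for (i in seq_len(nrow(x))) {
    for (j in seq_len(ncol(x))) {
      xp <- x; xp[i, j] <- xp[i, j] + step
      xm <- x; xm[i, j] <- xm[i, j] - step
      g[i, j] <- (energy(xp) - energy(xm)) / (2 * step)
    }
  }
  g
}

.fd_hessian <- function(grad_fun, x, step) {
  nd <- length(x)
  h <- matrix(0, nd, nd)
  for (d in seq_len(nd)) {
    xp <- x; xp[d] <- xp[d] + step
    xm <- x; xm[d] <- xm[d] - step
    ## column d: d(grad)/d(x_d); as.vector runs over atoms row-wise in
    ## column-major order of the coordinate matrix, consistent throughout
    h[, d] <- (as.vector(grad_fun(xp)) - as.vector(grad_fun(xm))) / (2 * step)
  }
  h
}
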