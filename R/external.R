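#' Uniaxial-compression external potential
#'
#' The generalized force-modified PES term for uniaxial pressure: a harmonic
#' penalty pushing every atom toward the xy-plane of the working frame,
#'
#'   V_ext = k/2 * sum_i z_i^2
#'
#' where z_i is the distance of atom i to the plane and k (N/m at the
#' interface) is the external parameter describing the strength of the
#' pressure.  The external force is the negative derivative, i.e.
#' (0, 0, -k z_i) on atom i — x and y components exactly zero.  V_ext is
#' non-negative, vanishes exactly for planar (z = 0) structures, and is
#' invariant under in-plane translations and rotations about the plane
#' normal.
#'
#' @param k force constant in N/m (>= 0); converted internally to
#'   hartree/bohr^2 via `fmpes_units`.
#' @return an external term usable in [compose_modified_pes()].
#' @examples
#' uniaxial_term(50)
#' @export
uniaxial_term <- function(k) {
  if (!is.numeric(k) || length(k) != 1 || !is.finite(k) || k < 0) {
    stop("compression strength k must be a non-negative number (N/m)",
         call. = FALSE)
  }
  k_au <- .k_Nm_to_au(k)
  .external_term(
    type = "uniaxial",
    label = sprintf("uniaxial(k=%g N/m)", k),
    params = list(k_Nm = k, k_au = k_au),
    energy = function(x) 0.5 * k_au * sum(x[, 3]^2),
    gradient = function(x) cbind(0 * x[, 1], 0 * x[, 2], k_au * x[, 3])
  )
}

#' Constant pulling-force external potential
#'
#' The standard constant-force FMPES convention (as in EFEI-type
#' approaches): a collinear force pair of magnitude F applied across the two
#' polymer attachment atoms, favouring their separation.  The energy term is
#' -F * d where d is the instantaneous attachment-pair distance; its
#' gradient is nonzero only on the two attachment atoms and antiparallel
#' along their connecting vector.
#'
#' @param force pulling force magnitude in nN (>= 0).
#' @param attachment_pair integer vector of two distinct 1-based atom
#'   indices; if NULL, taken from the geometry's own `attachment_pair` at
#'   evaluation time is not possible, so it must be given here.
#' @return an external term usable in [compose_modified_pes()].
#' @export
pulling_term <- function(force, attachment_pair) {
  if (!is.numeric(force) || length(force) != 1 || !is.finite(force) ||
      force < 0) {
    stop("pulling force must be a non-negative number (nN)", call. = FALSE)
  }
  pair <- as.integer(attachment_pair)
  if (length(pair) != 2 || anyNA(pair) || pair[1] == pair[2]) {
    stop("attachment_pair must hold two distinct atom indices", call. = FALSE)
  }
  f_au <- .force_nN_to_au(force)
  .external_term(
    type = "pulling",
    label = sprintf("pulling(F=%g nN, pair=%d-%d)", force, pair[1], pair[2]),
    params = list(force_nN = force, force_au = f_au, pair = pair),
    energy = function(x) {
      -f_au * .pair_distance(x, pair)
    },
    gradient = function(x) {
      d <- .pair_distance(x, pair)
      u <- (x[pair[1], ] - x[pair[2], ]) / d
      g <- matrix(0, nrow(x), 3)
      g[pair[1], ] <- -f_au * u
      g[pair[2], ] <- f_au * u
      g
    }
  )
}

.pair_distance <- function(x, pair) {
  d <- sqrt(sum((x[pair[1], ] - x[pair[2], ])^2))
  ## 1e-6 Angstrom expressed in bohr
  if (d < 1e-6 / .BOHR_ANG) {
    stop("attachment atoms are coincident; pulling direction undefined",
         call. = FALSE)
  }
  d
}

#' Linear tilt term (one-dimensional constant force)
#'
#' Convenience perturbation for the low-dimensional benchmarks: a constant
#' force F along one coordinate axis of one pseudo-atom, energy -F * x.
#' This is the one-dimensional analogue of [pulling_term()] and is what the
#' tilted-double-well closed-form oracle exercises.
#'
#' @param force force in nN (converted to hartree/bohr; may be negative
#'   here, the sign sets the tilt direction).
#' @param atom atom index the force acts on (default 1).
#' @param axis coordinate axis index 1..3 (default 1, the x axis).
#' @return an external term usable in [compose_modified_pes()].
#' @export
linear_tilt_term <- function(force, atom = 1L, axis = 1L) {
  f_au <- .force_nN_to_au(force)
  atom <- as.integer(atom); axis <- as.integer(axis)
  .external_term(
    type = "linear_tilt",
    label = sprintf("tilt(F=%g nN, atom %d axis %d)", force, atom, axis),
    params = list(force_nN = force, force_au = f_au, atom = atom,
                  axis = axis),
    energy = function(x) -f_au * x[atom, axis],
    gradient = function(x) {
      g <- matrix(0, nrow(x), 3)
      g[atom, axis] <- -f_au
      g
    }
  )
}

.external_term <- function(type, label, params, energy, gradient) {
  structure(list(type = type, label = label, params = params,
                 energy = energy, gradient = gradient),
            class = "fmpes_external_term")
}

#' @export
print.fmpes_external_term <- function(x, ...) {
  cat("<external term:", x$label, ">\n")
  invisible(x)
}

#' Compose a base potential with external perturbations
#'
#' Builds the force-modified potential energy surface: energy and gradient
#' are the base backend's plus the sum over external terms, evaluated in the
#' base backend's working coordinates.  The result satisfies the
#' [potential_backend()] contract and is accepted by every optimizer and
#' scan driver.
#'
#' @param base a [potential_backend()].
#' @param terms list of external terms ([uniaxial_term()],
#'   [pulling_term()], [linear_tilt_term()]); an empty list reproduces the
#'   base surface identically.
#' @return an object of classes `modified_pes` and `potential_backend`.
#' @examples
#' pes <- compose_modified_pes(bead_spring_flex_backend(),
#'                             list(uniaxial_term(10)))
#' @export
compose_modified_pes <- function(base, terms = list()) {
  stopifnot(inherits(base, "potential_backend"))
  if (inherits(terms, "fmpes_external_term")) terms <- list(terms)
  for (tm in terms) {
    if (!inherits(tm, "fmpes_external_term")) {
      stop("terms must be fmpes external-term objects", call. = FALSE)
    }
  }
  base_grad <- if (!is.null(base$gradient)) base$gradient
  else function(x) .fd_gradient(base$energy, x, 1e-4)
  labels <- vapply(terms, function(tm) tm$label, character(1))
  pes <- potential_backend(
    name = if (length(terms)) paste(base$name, "+",
                                    paste(labels, collapse = " + "))
    else base$name,
    energy = function(x) {
      e <- base$energy(x)
      for (tm in terms) e <- e + tm$energy(x)
      e
    },
    gradient = function(x) {
      g <- base_grad(x)
      for (tm in terms) g <- g + tm$gradient(x)
      g
    },
    n_atoms = base$n_atoms, coord_unit = base$coord_unit
  )
  pes$base <- base
  pes$terms <- terms
  class(pes) <- c("modified_pes", class(pes))
  pes
}

#' Uniaxial-compression energy of a geometry
#'
#' User-facing evaluation of V_ext = k/2 sum z_i^2 for a geometry in its
#' current frame (use [align_to_frame()] first if the molecule is not yet
#' oriented relative to the compression plane).
#'
#' @param geom an [geometry()] object (coordinates in Angstrom).
#' @param k force constant in N/m (>= 0).
#' @param unit `"kcal/mol"` (default) or `"hartree"`.
#' @return scalar V_ext.
#' @examples
#' g <- geometry(c("C", "C"), rbind(c(0, 0, 1), c(0, 0, -1)))
#' uniaxial_energy(g, 50)  # 71.96 kcal/mol
#' @export
uniaxial_energy <- function(geom, k, unit = c("kcal/mol", "hartree")) {
  unit <- match.arg(unit)
  e <- uniaxial_term(k)$energy(.ang_to_bohr(geom$coords))
  if (unit == "kcal/mol") e * .HARTREE_KCAL else e
}

#' Uniaxial-compression force on each atom
#'
#' The negative derivative of the compression potential with respect to the
#' spatial coordinates: (0, 0, -k z_i) on atom i.
#'
#' @inheritParams uniaxial_energy
#' @return N x 3 force matrix in hartree/bohr (x and y columns exactly 0).
#' @export
uniaxial_force <- function(geom, k) {
  -uniaxial_term(k)$gradient(.ang_to_bohr(geom$coords))
}

#' Constant pulling-force energy of a geometry
#'
#' @inheritParams uniaxial_energy
#' @param force pulling force in nN (>= 0).
#' @param attachment_pair two distinct atom indices; defaults to the
#'   geometry's own attachment pair.
#' @return scalar -F * d(attachment pair).
#' @examples
#' g <- geometry(c("C", "C"), rbind(c(0, 0, 0), c(2, 0, 0)),
#'               attachment_pair = c(1, 2))
#' pulling_energy(g, 1)  # -28.79 kcal/mol
#' @export
pulling_energy <- function(geom, force, attachment_pair = NULL,
                           unit = c("kcal/mol", "hartree")) {
  unit <- match.arg(unit)
  pair <- if (is.null(attachment_pair)) geom$attachment_pair
  else attachment_pair
  if (is.null(pair)) {
    stop("no attachment_pair given and none stored on the geometry",
         call. = FALSE)
  }
  e <- pulling_term(force, pair)$energy(.ang_to_bohr(geom$coords))
  if (unit == "kcal/mol") e * .HARTREE_KCAL else e
}
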