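#' Molecular geometry
#'
#' The object every potential-energy-surface operation acts on: element
#' symbols plus N x 3 Cartesian coordinates in Angstrom.  Optionally carries
#' the ordered pair of polymer attachment atoms (the atoms a pulling force
#' acts on), a per-atom frozen mask (atoms held fixed during optimization,
#' e.g. to mimic network anchoring) and a free-text comment.
#'
#' Low-dimensional benchmark surfaces (Mueller-Brown, quartic double well)
#' are represented as a single "pseudo-atom" whose unused coordinates are
#' ignored by the backend; see [muller_brown_backend()].
#'
#' @param elements character vector of element symbols (length N >= 1).
#' @param coords numeric N x 3 matrix of Cartesian coordinates (Angstrom);
#'   a length-3 vector is accepted for a single atom.
#' @param attachment_pair optional integer vector of length 2: ordered,
#'   distinct 1-based indices of the pulling attachment atoms.
#' @param frozen_mask optional logical vector of length N; `TRUE` atoms do
#'   not move during optimization.
#' @param comment free-text comment (stored on the XYZ comment line).
#' @return An object of class `fmpes_geometry`.
#' @examples
#' g <- geometry(c("O", "O"), rbind(c(0, 0, 1), c(0, 0, -1)),
#'               attachment_pair = c(1, 2))
#' g
#' @export
geometry <- function(elements, coords, attachment_pair = NULL,
                     frozen_mask = NULL, comment = "") {
  elements <- as.character(elements)
  n <- length(elements)
  if (n < 1) stop("geometry needs at least one atom", call. = FALSE)
  if (is.null(dim(coords))) {
    if (n == 1 && length(coords) == 3) coords <- matrix(coords, 1, 3)
    else stop("coords must be an N x 3 matrix", call. = FALSE)
  }
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  if (nrow(coords) != n || ncol(coords) != 3) {
    stop(sprintf("coords must be %d x 3, got %d x %d",
                 n, nrow(coords), ncol(coords)), call. = FALSE)
  }
  if (!all(is.finite(coords))) {
    stop("all coordinates must be finite", call. = FALSE)
  }
  if (!is.null(attachment_pair)) {
    attachment_pair <- as.integer(attachment_pair)
    if (length(attachment_pair) != 2 ||
        anyNA(attachment_pair) ||
        any(attachment_pair < 1L) || any(attachment_pair > n) ||
        attachment_pair[1] == attachment_pair[2]) {
      stop("attachment_pair must hold two distinct valid atom indices",
           call. = FALSE)
    }
  }
  if (!is.null(frozen_mask)) {
    frozen_mask <- as.logical(frozen_mask)
    if (length(frozen_mask) != n || anyNA(frozen_mask)) {
      stop("frozen_mask must be a logical vector with one entry per atom",
           call. = FALSE)
    }
  }
  structure(
    list(elements = elements, coords = coords,
         attachment_pair = attachment_pair, frozen_mask = frozen_mask,
         comment = as.character(comment)[1]),
    class = "fmpes_geometry"
  )
}

#' @export
print.fmpes_geometry <- function(x, ...) {
  cat(sprintf("<fmpes_geometry: %d atom%s>\n", n_atoms(x),
              if (n_atoms(x) == 1) "" else "s"))
  if (!is.null(x$attachment_pair)) {
    cat(sprintf("  attachment pair: %d-%d\n",
                x$attachment_pair[1], x$attachment_pair[2]))
  }
  if (!is.null(x$frozen_mask) && any(x$frozen_mask)) {
    cat("  frozen atoms:", paste(which(x$frozen_mask), collapse = ", "), "\n")
  }
  m <- cbind(format(x$elements, width = 2),
             formatC(x$coords, format = "f", digits = 6, width = 12))
  apply(m, 1, function(r) cat(" ", paste(r, collapse = " "), "\n"))
  invisible(x)
}

#' Number of atoms in a geometry
#' @param geom an [geometry()] object.
#' @return integer atom count.
#' @export
n_atoms <- function(geom) length(geom$elements)

#' Replace the coordinates of a geometry
#' @param geom an [geometry()] object.
#' @param coords new N x 3 coordinate matrix (Angstrom).
#' @return the geometry with coordinates replaced, other fields kept.
#' @export
set_coords <- function(geom, coords) {
  geometry(geom$elements, coords, geom$attachment_pair, geom$frozen_mask,
           geom$comment)
}

#' Sum of squared z displacements
#'
#' The quantity the uniaxial-compression potential penalizes: sum over atoms
#' of the squared distance to the xy-plane.  Useful for tracking how much a
#' structure flattens during a compression scan.
#'
#' @param geom an [geometry()] object.
#' @param unit `"angstrom2"` (default) or `"bohr2"`.
#' @return scalar sum of z_i^2.
#' @export
sum_z_squared <- function(geom, unit = c("angstrom2", "bohr2")) {
  unit <- match.arg(unit)
  s <- sum(geom$coords[, 3]^2)
  if (unit == "bohr2") s / .BOHR_ANG^2 else s
}

## rough atomic masses for inertia-tensor alignment; beads default to carbon
.atomic_masses <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999,
                    F = 18.998, S = 32.06, P = 30.974, X = 12.011)

.mass_of <- function(el) {
  m <- .atomic_masses[el]
  m[is.na(m)] <- 12.011
  unname(m)
}

#' Orient a geometry relative to the compression frame
#'
#' The uniaxial-compression potential is defined relative to the xy-plane of
#' the working frame, so molecular orientation matters.  Modes:
#'
#' * `"attachment_in_plane"`: centroid to the origin, then rotate the
#'   attachment vector onto the x-axis (so the pulled backbone lies in the
#'   compression plane), and finally rotate about x so the sum of squared z
#'   coordinates is minimal.  The last step pins the otherwise free
#'   rotation about the attachment axis to the orientation a vanishing
#'   compression would select, which keeps compression scans continuous as
#'   the force constant approaches zero.  Requires `attachment_pair`.
#' * `"principal_axes"`: centroid to the origin, axes of the mass-weighted
#'   inertia tensor ordered so the long molecular axis lies along x, the
#'   next along y and the thinnest direction along z.
#' * `"none"`: identity.
#'
#' All non-identity modes are rigid transformations: interatomic distances
#' are preserved exactly.  The applied transformation is attached as
#' attribute `"transform"` (list with rotation `R` and pre-translation `t`,
#' acting as `(x + t) %*% t(R)`) so the identical frame can be applied to a
#' companion structure with [apply_frame()].
#'
#' @param geom an [geometry()] object.
#' @param mode one of `"attachment_in_plane"`, `"principal_axes"`, `"none"`.
#' @return the re-oriented geometry with a `"transform"` attribute.
#' @export
align_to_frame <- function(geom,
                           mode = c("attachment_in_plane", "principal_axes",
                                    "none")) {
  mode <- match.arg(mode)
  if (mode == "none") {
    out <- geom
    attr(out, "transform") <- list(R = diag(3), t = c(0, 0, 0))
    return(out)
  }
  x <- geom$coords
  t_vec <- -colMeans(x)
  xc <- sweep(x, 2, -t_vec)
  if (mode == "attachment_in_plane") {
    if (is.null(geom$attachment_pair)) {
      stop("alignment mode 'attachment_in_plane' requires an attachment_pair",
           call. = FALSE)
    }
    a <- xc[geom$attachment_pair[2], ] - xc[geom$attachment_pair[1], ]
    R1 <- .rotation_onto(a / sqrt(sum(a^2)), c(1, 0, 0))
    x1 <- xc %*% t(R1)
    ## residual rotation about the attachment axis: minimize sum z^2
    syz <- sum(x1[, 2] * x1[, 3])
    sy2 <- sum(x1[, 2]^2); sz2 <- sum(x1[, 3]^2)
    phi0 <- 0.5 * atan2(-2 * syz, sy2 - sz2)
    zsq <- function(phi) {
      sum((sin(phi) * x1[, 2] + cos(phi) * x1[, 3])^2)
    }
    phi <- if (zsq(phi0) <= zsq(phi0 + pi / 2)) phi0 else phi0 + pi / 2
    rx <- matrix(c(1, 0, 0,
                   0, cos(phi), -sin(phi),
                   0, sin(phi), cos(phi)), 3, 3, byrow = TRUE)
    R <- rx %*% R1
  } else {
    m <- .mass_of(geom$elements)
    inert <- matrix(0, 3, 3)
    for (i in seq_len(nrow(xc))) {
      r <- xc[i, ]
      inert <- inert + m[i] * (sum(r^2) * diag(3) - tcrossprod(r))
    }
    e <- eigen(inert, symmetric = TRUE)
    ## smallest moment <-> long axis -> x; largest moment -> z
    R <- t(e$vectors[, order(e$values)])
    if (det(R) < 0) R[3, ] <- -R[3, ]
  }
  out <- set_coords(geom, sweep(x, 2, -t_vec) %*% t(R))
  attr(out, "transform") <- list(R = R, t = t_vec)
  out
}

#' Apply a previously computed frame transformation
#'
#' @param geom an [geometry()] object.
#' @param transform the `"transform"` attribute returned by
#'   [align_to_frame()].
#' @return the transformed geometry.
#' @export
apply_frame <- function(geom, transform) {
  set_coords(geom, sweep(geom$coords, 2, -transform$t) %*% t(transform$R))
}

## rotation matrix taking unit vector a onto unit vector b (Rodrigues)
.rotation_onto <- function(a, b) {
  v <- c(a[2] * b[3] - a[3] * b[2],
         a[3] * b[1] - a[1] * b[3],
         a[1] * b[2] - a[2] * b[1])
  c_ <- sum(a * b)
  s <- sqrt(sum(v^2))
  if (s < 1e-12) {
    if (c_ > 0) return(diag(3))
    ## antiparallel: rotate pi about any axis orthogonal to a
    p <- if (abs(a[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    axis <- p - sum(p * a) * a
    axis <- axis / sqrt(sum(axis^2))
    return(2 * tcrossprod(axis) - diag(3))
  }
  vx <- matrix(c(0, -v[3], v[2], v[3], 0, -v[1], -v[2], v[1], 0), 3, 3,
               byrow = TRUE)
  diag(3) + vx + vx %*% vx * ((1 - c_) / s^2)
}
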