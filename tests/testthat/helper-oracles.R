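# Independent oracles used to freeze expected values.  These deliberately
# avoid the package's minimize()/dimer_ts_search() code paths: stationary
# points are located by dense grid enumeration plus full-Hessian Newton
# polishing, and the tilted double well by closed-form root finding.

# Full-Newton refinement of a stationary point (any index) from a start.
# Walks x <- x - pinv(H) g on the working coordinates; modes with
# |eigenvalue| < 1e-8 are excluded from the inverse.
newton_refine <- function(pes, geom, tol = 1e-11, max_iter = 200) {
  x <- fmpes:::.working_coords(geom, pes)
  for (i in seq_len(max_iter)) {
    g <- as.vector(fmpes:::.grad_matrix(pes, x))
    if (max(abs(g)) < tol) break
    h <- pes$hessian
    hm <- if (!is.null(h)) h(x) else fmpes:::.fd_hessian(
      function(xx) fmpes:::.grad_matrix(pes, xx), x, 1e-3)
    hm <- (hm + t(hm)) / 2
    e <- eigen(hm, symmetric = TRUE)
    keep <- abs(e$values) > 1e-8
    step <- -e$vectors[, keep, drop = FALSE] %*%
      ((t(e$vectors[, keep, drop = FALSE]) %*% g) / e$values[keep])
    if (max(abs(step)) > 0.5) step <- step * 0.5 / max(abs(step))
    x <- x + matrix(as.vector(step), ncol = 3)
  }
  g <- as.vector(fmpes:::.grad_matrix(pes, x))
  list(coords = x, energy = pes$energy(x), max_grad = max(abs(g)),
       converged = max(abs(g)) < 1e-8)
}

# Enumerate the Mueller-Brown stationary points: Newton from a coarse grid
# of starts, keep converged points inside the benchmark window, classify by
# the analytic Hessian, deduplicate.  Returns minima and saddles sorted by
# energy.
mb_stationary_oracle <- function() {
  mb <- muller_brown_backend()
  starts <- expand.grid(x = seq(-1.4, 1.1, by = 0.25),
                        y = seq(-0.2, 2.0, by = 0.25))
  pts <- list()
  for (i in seq_len(nrow(starts))) {
    res <- newton_refine(mb, geometry("X", c(starts$x[i], starts$y[i], 0)))
    p <- res$coords[1, 1:2]
    if (!res$converged || any(abs(p) > 3)) next
    h <- mb$hessian(rbind(c(p, 0)))[1:2, 1:2]
    lam <- eigen((h + t(h)) / 2, symmetric = TRUE, only.values = TRUE)$values
    kind <- if (all(lam > 1e-8)) "minimum"
    else if (sum(lam < -1e-8) == 1) "saddle" else "other"
    if (kind == "other") next
    dup <- any(vapply(pts, function(q) sum((q$p - p)^2) < 1e-10, logical(1)))
    if (!dup) pts[[length(pts) + 1]] <- list(p = p, e = res$energy,
                                             kind = kind)
  }
  kinds <- vapply(pts, `[[`, character(1), "kind")
  es <- vapply(pts, `[[`, numeric(1), "e")
  list(minima = pts[kinds == "minimum"][order(es[kinds == "minimum"])],
       saddles = pts[kinds == "saddle"][order(es[kinds == "saddle"])])
}

# Closed-form barrier of the tilted quartic double well
# V(x) = a x^4 - b x^2 - f x: stationary points are the real roots of the
# cubic V'(x) = 4a x^3 - 2b x - f, classified by V''; the reactant is the
# force-destabilized (higher-energy) minimum.
tilted_quartic_barrier <- function(f_au, a = 1, b = 2) {
  roots <- polyroot(c(-f_au, -2 * b, 0, 4 * a))
  re <- Re(roots[abs(Im(roots)) < 1e-9])
  V <- function(x) a * x^4 - b * x^2 - f_au * x
  vpp <- 12 * a * re^2 - 2 * b
  mins <- re[vpp > 0]
  sad <- re[vpp < 0]
  stopifnot(length(sad) == 1, length(mins) == 2)
  V(sad) - max(V(mins))
}

# shared toy inputs
bsf_inputs <- function() {
  list(backend = bead_spring_flex_backend(),
       reactant = bead_spring_flex_geometry("reactant"),
       ts = bead_spring_flex_geometry("ts"))
}
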