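#' Generate toy geometry fixtures with reference values
#'
#' Deterministic fixture generator for tests and demos.  Every fixture is
#' built in code (no stored data): a named geometry, optionally jittered by
#' seeded Gaussian displacements, together with a sidecar of reference
#' values computed from the package's own closed forms.
#'
#' Available fixtures:
#' * `"bead_spring_flex_reactant"` / `"bead_spring_flex_ts"`: the exact
#'   stationary structures of [bead_spring_flex_backend()] (sidecar: the
#'   unperturbed barrier `B0` in hartree and kcal/mol).
#' * `"two_atom_dimer"`: two atoms at z = +/- 1 Angstrom (sidecar: the
#'   uniaxial compression energy at k = 50 N/m, 71.96 kcal/mol).
#' * `"planar_ring"`: a six-membered ring in the z = 0 plane (sidecar:
#'   uniaxial energy identically 0 at any k).
#'
#' @param name fixture name (see above).
#' @param seed integer seed controlling the jitter (same name + seed gives
#'   bit-identical output).
#' @param jitter Gaussian displacement scale in Angstrom (default 0: the
#'   exact reference structure).
#' @return list with `geometry` and `reference` (named list of expected
#'   values).
#' @examples
#' fx <- generate_fixture("two_atom_dimer")
#' fx$reference$uniaxial_kcal_at_k50
#' @export
generate_fixture <- function(name, seed = 1L, jitter = 0) {
  known <- c("bead_spring_flex_reactant", "bead_spring_flex_ts",
             "two_atom_dimer", "planar_ring")
  if (!name %in% known) {
    stop("unknown fixture '", name, "'; available: ",
         paste(known, collapse = ", "), call. = FALSE)
  }
  base <- switch(
    name,
    bead_spring_flex_reactant = bead_spring_flex_geometry("reactant"),
    bead_spring_flex_ts = bead_spring_flex_geometry("ts"),
    two_atom_dimer = geometry(c("C", "C"),
                              rbind(c(0, 0, 1), c(0, 0, -1)),
                              attachment_pair = c(1, 2),
                              comment = "two_atom_dimer"),
    planar_ring = {
      ang <- 2 * pi * (0:5) / 6
      geometry(rep("C", 6), cbind(1.4 * cos(ang), 1.4 * sin(ang), 0),
               comment = "planar_ring")
    }
  )
  if (jitter > 0) {
    old_seed <- if (exists(".Random.seed", .GlobalEnv)) {
      get(".Random.seed", .GlobalEnv)
    }
    on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                           .GlobalEnv))
    set.seed(as.integer(seed))
    base <- set_coords(base, base$coords +
                         matrix(stats::rnorm(3 * n_atoms(base), sd = jitter),
                                ncol = 3))
  }
  reference <- switch(
    name,
    bead_spring_flex_reactant = ,
    bead_spring_flex_ts = {
      b0 <- bead_spring_flex_backend()$params$B0
      list(barrier_hartree = b0, barrier_kcal = b0 * .HARTREE_KCAL)
    },
    two_atom_dimer = list(
      uniaxial_kcal_at_k50 = uniaxial_energy(base, 50)),
    planar_ring = list(uniaxial_kcal_at_k50 = 0)
  )
  list(geometry = base, reference = reference)
}
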