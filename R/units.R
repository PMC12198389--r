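#' Unit conversion constants
#'
#' All internal computation uses hartree / bohr atomic units.  User-facing
#' boundaries use the units in which mechanochemistry results are usually
#' reported: Angstrom for coordinates, kcal/mol for energies, nN for pulling
#' forces and N/m for compression force constants.  Every constant below is
#' derived from CODATA 2018 fundamental values so that conversions are
#' mutually consistent and auditable:
#'
#' * 1 hartree = 4.3597447222071e-18 J = 627.509474 kcal/mol
#' * 1 bohr    = 0.529177210903 Angstrom
#' * 1 hartree/bohr   = 82.387235 nN        (atomic unit of force)
#' * 1 hartree/bohr^2 = 1556.8931 N/m      (atomic unit of force constant)
#'
#' so a force constant k in N/m converts to atomic units as
#' k_au = k / 1556.8931 = k * 6.42310e-4, and a force F in nN as
#' F_au = F / 82.387235.
#'
#' @format A named list with elements `hartree_J`, `hartree_kcal_mol`,
#'   `bohr_angstrom`, `avogadro`, `au_force_nN`, `au_force_constant_N_m`.
#' @examples
#' fmpes_units$hartree_kcal_mol
#' # 50 N/m in atomic units:
#' 50 / fmpes_units$au_force_constant_N_m
#' @export
fmpes_units <- local({
  hartree_J <- 4.3597447222071e-18
  bohr_m <- 0.529177210903e-10
  avogadro <- 6.02214076e23
  cal_J <- 4.184
  list(
    hartree_J = hartree_J,
    hartree_kcal_mol = hartree_J * avogadro / (cal_J * 1000),
    bohr_angstrom = bohr_m * 1e10,
    avogadro = avogadro,
    au_force_nN = hartree_J / bohr_m * 1e9,
    au_force_constant_N_m = hartree_J / bohr_m^2
  )
})

## internal shorthands
.HARTREE_KCAL <- fmpes_units$hartree_kcal_mol
.BOHR_ANG <- fmpes_units$bohr_angstrom
.AU_FORCE_NN <- fmpes_units$au_force_nN
.AU_K_NM <- fmpes_units$au_force_constant_N_m

#' Convert energies between internal and reporting units
#'
#' @param x numeric vector of energies.
#' @param from,to one of `"hartree"`, `"kcal/mol"`.
#' @return numeric vector in the target unit.
#' @examples
#' convert_energy(1, "hartree", "kcal/mol")
#' @export
convert_energy <- function(x, from = "hartree", to = "kcal/mol") {
  units <- c("hartree" = 1, "kcal/mol" = 1 / .HARTREE_KCAL)
  if (!from %in% names(units) || !to %in% names(units)) {
    stop("unknown energy unit; use 'hartree' or 'kcal/mol'", call. = FALSE)
  }
  x / units[[from]] * units[[to]]
}

## nN -> hartree/bohr
.force_nN_to_au <- function(F_nN) F_nN / .AU_FORCE_NN

## N/m -> hartree/bohr^2
.k_Nm_to_au <- function(k_Nm) k_Nm / .AU_K_NM

## Angstrom matrix -> bohr matrix
.ang_to_bohr <- function(x) x / .BOHR_ANG

.bohr_to_ang <- function(x) x * .BOHR_ANG
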