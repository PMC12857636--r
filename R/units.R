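#' Physical constants and unit conversions
#'
#' Internal energies are in eV and lengths in Angstrom; profiles are reported
#' in kJ/mol and grid-based density analyses in hartree/bohr (atomic units).
#'
#' @name rotapath-units
#' @keywords internal
NULL

# eV -> kJ/mol
EV_TO_KJMOL <- 96.4853

# hartree -> eV (CODATA)
HARTREE_TO_EV <- 27.211386245988

# Angstrom -> bohr
ANGSTROM_TO_BOHR <- 1.8897261254578281

# Coulomb prefactor e^2/(4 pi eps0) in eV * Angstrom
COULOMB_EV_ANGSTROM <- 14.399645

# mean of 1/|x - y| for x, y uniform over the same unit cube; used for the
# same-cell correction in the grid Coulomb sum (computed once by tensor
# Gauss-Legendre quadrature of the folded 3D integral, converged to 8 digits)
CUBE_SELF_INV_R <- 1.88231264

# standard atomic masses (amu); "X" is a unit-mass fictitious bead
ATOMIC_MASSES <- c(
  H = 1.008, He = 4.0026, C = 12.011, N = 14.007, O = 15.999,
  F = 18.998, P = 30.974, S = 32.06, Cl = 35.45, X = 1.0
)

# nuclear charges for cube-file headers
ATOMIC_NUMBERS <- c(
  H = 1, He = 2, C = 6, N = 7, O = 8, F = 9, P = 15, S = 16, Cl = 17, X = 0
)

atomic_mass <- function(symbols) {
  m <- ATOMIC_MASSES[symbols]
  if (anyNA(m)) {
    stop("no tabulated mass for element(s): ",
         paste(unique(symbols[is.na(m)]), collapse = ", "))
  }
  unname(m)
}
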