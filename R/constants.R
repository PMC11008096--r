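#' Physical constants and unit conventions
#'
#' Units are fixed package-wide: lengths in Angstrom, energies in kcal/mol,
#' charges in elementary charge units, dipoles in e*Angstrom, quadrupoles in
#' e*Angstrom^2, polarizabilities in Angstrom^3, time in femtoseconds and
#' masses in atomic mass units. Parameter files may carry dipoles and
#' quadrupoles in e*Bohr (the Tinker convention); they are converted on load.
#'
#' @format A named list with elements:
#' \describe{
#'   \item{coulomb}{Coulomb constant, 332.063713 kcal*Angstrom/(mol*e^2)}
#'   \item{kB}{Boltzmann constant, 0.0019872041 kcal/(mol*K)}
#'   \item{bohr}{Bohr radius in Angstrom}
#'   \item{acc}{conversion from kcal/mol/(Angstrom*amu) to Angstrom/fs^2}
#' }
#' @export
cph_constants <- list(
  coulomb = 332.063713,
  kB      = 0.0019872041,
  bohr    = 0.52917721067,
  acc     = 4.184e-4
)

KCOUL  <- cph_constants$coulomb
KBOLTZ <- cph_constants$kB
BOHR   <- cph_constants$bohr
MDACC  <- cph_constants$acc

# atomic masses used when a parameter file does not provide them (amu)
.element_masses <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999,
                     S = 32.06, P = 30.974, NA. = 22.990, CL = 35.45,
                     ZN = 65.38, X = 20.0)

guess_mass <- function(name) {
  el <- toupper(substr(gsub("[0-9]", "", name), 1, 1))
  m <- .element_masses[el]
  ifelse(is.na(m), 20.0, m)
}
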