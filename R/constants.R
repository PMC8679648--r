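## Physical constants and unit conversions used throughout the package.
## All fixed in one place so every equation draws on the same values.

#' Physical constants used by orgsil
#'
#' Returns the set of physical constants the package uses: the molar gas
#' constant, Boltzmann's constant, the vacuum permittivity, Avogadro's number,
#' the Coulomb prefactor in molecular-simulation units, and the conversion
#' factor between a squared dipole per polarizability volume and a molar
#' energy.
#'
#' @return Named list of constants with units documented in the names:
#'   \describe{
#'     \item{R}{molar gas constant, J mol^-1 K^-1}
#'     \item{kB}{Boltzmann constant, J K^-1}
#'     \item{eps0}{vacuum permittivity, F m^-1}
#'     \item{avogadro}{Avogadro constant, mol^-1}
#'     \item{fCoulomb}{Coulomb prefactor 1/(4 pi eps0), kJ mol^-1 nm e^-2}
#'     \item{debye}{1 debye in C m}
#'     \item{kD2A3}{kJ/mol corresponding to 1 D^2 / Angstrom^3 of mu^2/alpha}
#'     \item{atm}{1 atm in bar}
#'     \item{mmHgPerBar}{mmHg in one bar}
#'   }
#' @export
#' @examples
#' orgsilConstants()$R
orgsilConstants <- function() {
  list(
    R         = 8.314462618,      # J / mol K
    kB        = 1.380649e-23,     # J / K
    eps0      = 8.8541878128e-12, # F / m
    avogadro  = 6.02214076e23,    # 1 / mol
    fCoulomb  = 138.935458,       # kJ mol^-1 nm e^-2, 1/(4 pi eps0)
    debye     = 3.33564095e-30,   # C m
    kD2A3     = 60.2214076,       # kJ/mol per D^2/A^3 (mu^2 / (4 pi eps0 alpha'))
    atm       = 1.01325,          # bar
    mmHgPerBar = 750.062          # mmHg per bar
  )
}

#' Convert pressures between mmHg, bar and Pa
#'
#' One central conversion table: 1 bar = 750.062 mmHg = 1e5 Pa.  Conversions
#' round-trip to machine precision.
#'
#' @param x numeric vector of pressures.
#' @param from,to one of \code{"mmHg"}, \code{"bar"}, \code{"Pa"}, \code{"atm"}.
#' @return numeric vector in the target unit.
#' @export
#' @examples
#' convertPressure(760, "mmHg", "bar")
convertPressure <- function(x, from, to) {
  units <- c(mmHg = 1 / 750.062, bar = 1, Pa = 1e-5, atm = 1.01325) # in bar
  from <- match.arg(from, names(units))
  to <- match.arg(to, names(units))
  x * units[[from]] / units[[to]]
}

`%||%` <- function(a, b) if (is.null(a)) b else a
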