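## Physical constants in the package's internal unit system:
## length Angstrom, charge elementary charge, energy kcal/mol (converted to
## kT at the run temperature wherever energies are reported).

#' @useDynLib contpka, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats setNames uniroot runif
#' @importFrom utils read.table write.table head
NULL

# Coulomb constant e^2/(4 pi eps0), kcal mol^-1 Angstrom e^-2
.COULOMB_K <- 332.0637

# Boltzmann constant, kcal mol^-1 K^-1
.KBOLTZ <- 0.0019872041

# Boltzmann constant, eV K^-1 (for pK <-> mV conversion)
.KBOLTZ_EV <- 8.617333262e-5

#' Thermal energy kT in kcal/mol
#' @param temperature Kelvin
#' @return kT in kcal/mol
#' @keywords internal
kT_kcal <- function(temperature) .KBOLTZ * temperature

#' Coulomb constant in kT Angstrom / e^2 at a given temperature
#' @param temperature Kelvin
#' @keywords internal
coulomb_kT <- function(temperature) .COULOMB_K / kT_kcal(temperature)

#' Millivolts per pK unit (ln10 kT / e)
#'
#' One pH unit of driving force corresponds to ln(10) kT of energy, i.e.
#' about 59.5 mV at 300 K.
#' @param temperature Kelvin
#' @return mV per pK unit
#' @export
mv_per_pk <- function(temperature = 300) {
  log(10) * .KBOLTZ_EV * temperature * 1000
}

#' Debye screening prefactor eps_w * kappa^2 in Angstrom^-2
#'
#' Defined so that the LPB screening term is eps_kappa2 * phi in the
#' ion-accessible region; kappa^2 itself is this value divided by eps_w.
#' @param ionic_strength mol/L
#' @param temperature Kelvin
#' @keywords internal
eps_kappa2 <- function(ionic_strength, temperature) {
  # 1 mol/L = 6.02214076e-4 charges per Angstrom^3
  8 * pi * .COULOMB_K * 6.02214076e-4 * ionic_strength / kT_kcal(temperature)
}

#' Debye screening constant kappa in 1/Angstrom
#' @param ionic_strength mol/L
#' @param temperature Kelvin
#' @param eps_water solvent dielectric constant
#' @export
debye_kappa <- function(ionic_strength, temperature = 300, eps_water = 80) {
  sqrt(eps_kappa2(ionic_strength, temperature) / eps_water)
}

#' Default continuum environment
#'
#' Dielectric and thermodynamic conditions for all electrostatic
#' calculations: protein interior dielectric 4, solvent 80, 100 mM ionic
#' strength, 300 K, pH 7, 2 Angstrom ion-exclusion (Stern) layer.
#'
#' @param eps_protein dielectric constant inside the molecular region
#' @param eps_water solvent dielectric constant
#' @param ionic_strength mol/L
#' @param temperature Kelvin
#' @param pH solution pH
#' @param ion_exclusion Stern-layer width in Angstrom
#' @return a list of class \code{"pka_env"}
#' @export
pka_env <- function(eps_protein = 4, eps_water = 80, ionic_strength = 0.1,
                    temperature = 300, pH = 7.0, ion_exclusion = 2.0) {
  stopifnot(eps_protein >= 1, eps_water >= 1, ionic_strength >= 0,
            temperature > 0, ion_exclusion >= 0)
  structure(list(eps_protein = eps_protein, eps_water = eps_water,
                 ionic_strength = ionic_strength, temperature = temperature,
                 pH = pH, ion_exclusion = ion_exclusion),
            class = "pka_env")
}
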