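# Unit conventions: internal energies are kJ/mol (GROMACS convention),
# lengths nm, angles radians internally (degrees at user-facing boundaries),
# reported free energies kcal/mol.

#' Physical constants used by rfepr
#'
#' Molar gas constant in kJ/(mol K) and kcal/(mol K), the thermochemical
#' calorie conversion, and the electric conversion factor
#' \eqn{f = 1/(4 \pi \epsilon_0)} in kJ mol\eqn{^{-1}} nm e\eqn{^{-2}}.
#'
#' `GAS_KCAL` is chosen as 1.98720425864e-3 kcal/(mol K) so that Boltzmann
#' population conversions reproduce conventional printed values (see
#' [population_ratio()]).
#'
#' @format A named list with elements `GAS_KJ`, `GAS_KCAL`, `KJ_PER_KCAL`,
#'   `COULOMB_KJ`.
#' @export
rfepr_constants <- list(
  GAS_KJ      = 8.31446261815324e-3, # kJ / (mol K)
  GAS_KCAL    = 1.98720425864e-3,    # kcal / (mol K)
  KJ_PER_KCAL = 4.184,
  COULOMB_KJ  = 138.935458           # kJ mol^-1 nm e^-2
)

#' Thermodynamic state
#'
#' Bundles the temperature with the gas constant in both unit systems so that
#' reduced potentials (u = U/RT) and kcal/mol reporting stay consistent.
#'
#' @param temperature Temperature in Kelvin; must be positive.
#' @return An object of class `thermo_state`: a list with `temperature`,
#'   `RT_kj` (kJ/mol), `RT_kcal` (kcal/mol).
#' @examples
#' th <- thermo_state(300)
#' th$RT_kj # about 2.494 kJ/mol
#' @export
thermo_state <- function(temperature = 300) {
  stopifnot(is.numeric(temperature), length(temperature) == 1L, is.finite(temperature))
  if (temperature <= 0) stop("temperature must be > 0 K")
  structure(
    list(
      temperature = temperature,
      RT_kj   = rfepr_constants$GAS_KJ * temperature,
      RT_kcal = rfepr_constants$GAS_KCAL * temperature
    ),
    class = "thermo_state"
  )
}

#' @export
print.thermo_state <- function(x, ...) {
  cat(sprintf("<thermo_state> T = %g K, RT = %.4f kJ/mol (%.4f kcal/mol)\n",
              x$temperature, x$RT_kj, x$RT_kcal))
  invisible(x)
}

#' Convert kJ/mol to kcal/mol
#' @param x Energy in kJ/mol.
#' @return Energy in kcal/mol.
#' @export
kj_to_kcal <- function(x) x / rfepr_constants$KJ_PER_KCAL

#' Convert kcal/mol to kJ/mol
#' @param x Energy in kcal/mol.
#' @return Energy in kJ/mol.
#' @export
kcal_to_kj <- function(x) x * rfepr_constants$KJ_PER_KCAL

as_thermo <- function(thermo) {
  if (inherits(thermo, "thermo_state")) return(thermo)
  if (is.numeric(thermo) && length(thermo) == 1L) return(thermo_state(thermo))
  stop("'thermo' must be a thermo_state or a temperature in K")
}
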