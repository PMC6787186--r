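# Internal unit system: length nm, time ns, energy kBT at the working
# temperature, charge e.  All user-facing energies in kcal/mol or eV are
# converted at the boundary.

# Boltzmann constant in eV/K and the molar gas constant in kcal/(mol K)
.kB_eV_per_K <- 8.617333262e-5
.R_kcal_per_mol_K <- 1.987204259e-3

#' Unit conventions at a working temperature
#'
#' The package works internally in nanometres, nanoseconds, elementary
#' charges and thermal energy units (kBT at the working temperature,
#' 300 K by default).  `units_convention()` collects the conversion
#' factors between kBT and laboratory energy units at a given temperature.
#'
#' @param temperature Absolute temperature in kelvin.
#' @return A list of class `units_convention` with elements
#'   `temperature` (K), `kBT_kcal_per_mol`, `kBT_eV`, and the unit labels
#'   for length (`"nm"`), time (`"ns"`) and energy (`"kBT"`).
#' @examples
#' u <- units_convention(300)
#' u$kBT_kcal_per_mol  # ~0.596
#' u$kBT_eV            # ~0.0259
#' @export
units_convention <- function(temperature = 300) {
  stopifnot(is.numeric(temperature), length(temperature) == 1L, temperature > 0)
  structure(
    list(
      temperature = temperature,
      kBT_kcal_per_mol = .R_kcal_per_mol_K * temperature,
      kBT_eV = .kB_eV_per_K * temperature,
      length_unit = "nm",
      time_unit = "ns",
      energy_unit = "kBT"
    ),
    class = "units_convention"
  )
}

#' Convert energies between kcal/mol and kBT
#'
#' @param x Numeric vector of energies.
#' @param temperature Temperature in kelvin.
#' @return Numeric vector in the target unit.
#' @examples
#' kcal_to_kbt(-6.1)   # the per-monomer well-depth contrast, ~-10.2 kBT
#' kbt_to_kcal(kcal_to_kbt(1)) # exactly 1
#' @export
kcal_to_kbt <- function(x, temperature = 300) {
  x / (.R_kcal_per_mol_K * temperature)
}

#' @rdname kcal_to_kbt
#' @export
kbt_to_kcal <- function(x, temperature = 300) {
  x * (.R_kcal_per_mol_K * temperature)
}

#' Thermal voltage kBT/e in volts
#'
#' Used to convert between the electrical and thermal energy scales when
#' forming field forces and the Einstein-relation effective charge.
#'
#' @param temperature Temperature in kelvin.
#' @return kBT/e in volts (numerically equal to kBT in eV).
#' @export
thermal_voltage <- function(temperature = 300) {
  .kB_eV_per_K * temperature
}

#' @export
print.units_convention <- function(x, ...) {
  cat("<units_convention> T =", x$temperature, "K;",
      "kBT =", format(x$kBT_kcal_per_mol, digits = 6), "kcal/mol =",
      format(x$kBT_eV, digits = 6), "eV;",
      "internal units nm / ns / kBT / e\n")
  invisible(x)
}
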