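#' Unit conversions
#'
#' Helpers converting between the package's canonical units (nm, nm^-3)
#' and the units common in structure files and experimental tables.
#'
#' @param x numeric vector to convert.
#' @return Converted numeric vector.
#' @name units
NULL

#' @rdname units
#' @export
nm_from_angstrom <- function(x) x / 10

#' @rdname units
#' @export
angstrom_from_nm <- function(x) x * 10

#' @rdname units
#' @export
molarity_from_density <- function(x) x / .NM3_PER_MOLAR

#' @rdname units
#' @export
density_from_molarity <- function(x) x * .NM3_PER_MOLAR

#' Thermodynamic parameters at a temperature
#'
#' Bundles the temperature with beta = 1/(N_A kB T) = 1/(R T) expressed in
#' mol/kcal, so that products like m * beta * rho3 (m in kcal mol^-1 M^-1,
#' rho3 in mol/L) are dimensionless.
#'
#' @param temperature temperature in K.
#' @return Object of class `thermo_params`: list with `temperature`, `beta`
#'   (mol/kcal) and `R` (kcal/(mol K)).
#' @examples
#' thermo_params(300)$beta  # 1.6774 mol/kcal
#' @export
thermo_params <- function(temperature) {
  stopifnot(is.numeric(temperature), length(temperature) == 1L,
            is.finite(temperature), temperature > 0)
  structure(list(temperature = temperature,
                 beta = 1 / (.R_KCAL * temperature),
                 R = .R_KCAL),
            class = "thermo_params")
}

#' @export
print.thermo_params <- function(x, ...) {
  cat(sprintf("Thermodynamic parameters: T = %g K, beta = %.6g mol/kcal\n",
              x$temperature, x$beta))
  invisible(x)
}
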