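#' Ionic conditions of the bath and pipette solutions
#'
#' Bundles the ion concentrations and temperature that set the Nernst
#' potentials of the model cell.  Defaults correspond to a standard
#' Tyrode's bath (2 mM K+, 140 mM Na+) against a KCl-based internal
#' solution (140 mM K+, 10 mM Na+) at room temperature.
#'
#' @param k_out,k_in Extracellular / intracellular K+ concentration (mM).
#' @param na_out,na_in Extracellular / intracellular Na+ concentration (mM).
#' @param temperature Bath temperature (degrees C); must lie in \[4, 45\].
#'
#' @return An object of class `ionic_conditions`.
#' @examples
#' cond <- ionic_conditions(k_out = 8)
#' nernst_potential(cond$k_out, cond$k_in, cond$temperature, 1)
#' @export
ionic_conditions <- function(k_out = 2, k_in = 140, na_out = 140, na_in = 10,
                             temperature = 23) {
  conc <- c(k_out = k_out, k_in = k_in, na_out = na_out, na_in = na_in)
  if (any(!is.finite(conc)) || any(conc <= 0))
    stop("all ion concentrations must be positive")
  if (temperature < 4 || temperature > 45)
    stop("temperature must lie between 4 and 45 degrees C")
  structure(list(k_out = k_out, k_in = k_in, na_out = na_out, na_in = na_in,
                 temperature = temperature),
            class = "ionic_conditions")
}

#' Nernst equilibrium potential
#'
#' Computes `(R*T / (z*F)) * ln(c_out / c_in)` in millivolts.
#'
#' @param c_out,c_in Outside / inside concentration (mM); must be positive.
#' @param temperature Temperature in degrees C.
#' @param valence Ion valence (nonzero integer; +1 for K+ and Na+).
#'
#' @return Equilibrium potential in mV.
#' @examples
#' nernst_potential(2, 140, 23, 1)   # K+ in 2 mM bath: about -108 mV
#' @export
nernst_potential <- function(c_out, c_in, temperature = 23, valence = 1) {
  if (any(c_out <= 0) || any(c_in <= 0))
    stop("concentrations must be positive")
  if (valence == 0) stop("valence must be nonzero")
  R <- 8.314462618     # J / (mol K)
  F <- 96485.33212     # C / mol
  T <- temperature + 273.15
  1000 * R * T / (valence * F) * log(c_out / c_in)
}

#' @export
print.ionic_conditions <- function(x, ...) {
  ek <- nernst_potential(x$k_out, x$k_in, x$temperature, 1)
  ena <- nernst_potential(x$na_out, x$na_in, x$temperature, 1)
  cat("Ionic conditions:",
      sprintf("K+ %g/%g mM (E_K %.1f mV),", x$k_out, x$k_in, ek),
      sprintf("Na+ %g/%g mM (E_Na %.1f mV),", x$na_out, x$na_in, ena),
      sprintf("%g degC\n", x$temperature))
  invisible(x)
}
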