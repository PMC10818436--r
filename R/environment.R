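#' Physical environment of a trapped bead
#'
#' Bundles the quantities entering the Stokes drag and the equipartition
#' relation: temperature, dynamic viscosity of the solvent and bead radius.
#' The Boltzmann constant is fixed at 1.38e-23 J/K, the value used in the
#' calibration formulas throughout the package.
#'
#' @param temperature absolute temperature (K).
#' @param viscosity dynamic viscosity of the solvent (Pa s).
#' @param bead_radius radius of the trapped sphere (m).
#'
#' @return An object of class `trap_environment`: a list with elements
#'   `temperature`, `viscosity`, `bead_radius`, `k_B` and the derived Stokes
#'   drag coefficient `gamma0` (= 6 pi eta r, kg/s).
#'
#' @examples
#' env <- trap_environment(297.25, 0.910e-3, 1.5e-6)
#' env$gamma0  # Stokes drag, kg/s
#' @export
trap_environment <- function(temperature, viscosity, bead_radius) {
  check_positive_scalar(temperature, "temperature")
  check_positive_scalar(viscosity, "viscosity")
  check_positive_scalar(bead_radius, "bead_radius")
  structure(
    list(temperature = temperature,
         viscosity = viscosity,
         bead_radius = bead_radius,
         k_B = .kB,
         gamma0 = 6 * pi * viscosity * bead_radius),
    class = "trap_environment")
}

#' @export
print.trap_environment <- function(x, ...) {
  cat("Trap environment\n")
  cat(sprintf("  temperature : %g K\n", x$temperature))
  cat(sprintf("  viscosity   : %g Pa s\n", x$viscosity))
  cat(sprintf("  bead radius : %g m\n", x$bead_radius))
  cat(sprintf("  Stokes drag : %g kg/s\n", x$gamma0))
  invisible(x)
}

as_trap_environment <- function(x) {
  if (inherits(x, "trap_environment")) return(x)
  stop_trapcal("expected a 'trap_environment' object", "parameter_error")
}
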