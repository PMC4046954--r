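#' Model configuration
#'
#' Numerical constants and switches that are not larval traits or
#' environmental drivers.
#'
#' @param prey_mass_coeff Coefficient `a` of the prey length--mass power law
#'   `m = a * l^b`, ug at 1 mm. Default 2.5, a typical dry mass for a 1-mm
#'   copepod.
#' @param prey_mass_exp Exponent `b` of the length--mass law. Default 2.03.
#' @param prey_speed_coeff Prey swimming speed in body lengths per second
#'   (speed `v = prey_speed_coeff * l`). Default 3.
#' @param kolmogorov_struct_const Constant of the second-order velocity
#'   structure function used for the root-mean-square turbulent velocity;
#'   default 1.62 = (55/18) x 0.53, with 0.53 the universal Kolmogorov
#'   constant of the energy spectrum.
#' @param o2_to_drymass Conversion factor from oxygen uptake to dry mass,
#'   ug ul^-1. A parameterization-time constant kept for documentation;
#'   runtime respiration is already expressed in dry-mass units.
#' @param bin_edges Prey length bin edges, mm. Default 0.04 to 2.00 mm in
#'   0.01-mm steps (196 bins).
#' @param respiration_scale Global multiplier on routine respiration.
#'   Default 1/24: the routine-loss percentages of the trait table are read
#'   as daily losses applied uniformly over the 24 hourly steps (see the
#'   methods vignette for the calibration rationale).
#' @param digestion_scale Global multiplier on digestive throughput.
#'   Default 1.
#' @param growth_def Definition of the daily specific growth rate:
#'   `"log"` for `ln(M24/M0)` (default) or `"arithmetic"` for
#'   `(M24 - M0)/M0`.
#' @param solver_rtol Relative tolerance of the bisection solvers on prey
#'   biomass. Default 1e-4.
#' @param satiation_atol Absolute tolerance on G (d^-1) used to declare the
#'   satiation point reached. Default 1e-6.
#' @return An object of class `model_config`.
#' @export
model_config <- function(prey_mass_coeff = 2.5,
                         prey_mass_exp = 2.03,
                         prey_speed_coeff = 3.0,
                         kolmogorov_struct_const = 1.62,
                         o2_to_drymass = 0.85,
                         bin_edges = seq(0.04, 2.00, by = 0.01),
                         respiration_scale = 1 / 24,
                         digestion_scale = 1,
                         growth_def = c("log", "arithmetic"),
                         solver_rtol = 1e-4,
                         satiation_atol = 1e-6) {
  growth_def <- match.arg(growth_def)
  chk <- function(ok, msg) {
    if (!isTRUE(ok)) rlang::abort(paste0("invalid model_config: ", msg),
                                  class = "larvforage_validation_error")
  }
  chk(prey_mass_coeff > 0, "prey_mass_coeff must be > 0")
  chk(prey_mass_exp > 0, "prey_mass_exp must be > 0")
  chk(prey_speed_coeff >= 0, "prey_speed_coeff must be >= 0")
  chk(kolmogorov_struct_const > 0, "kolmogorov_struct_const must be > 0")
  chk(length(bin_edges) >= 2 && all(diff(bin_edges) > 0),
      "bin_edges must be strictly increasing")
  chk(all(bin_edges > 0), "bin_edges must be positive")
  chk(respiration_scale > 0, "respiration_scale must be > 0")
  chk(digestion_scale > 0, "digestion_scale must be > 0")
  structure(list(prey_mass_coeff = prey_mass_coeff,
                 prey_mass_exp = prey_mass_exp,
                 prey_speed_coeff = prey_speed_coeff,
                 kolmogorov_struct_const = kolmogorov_struct_const,
                 o2_to_drymass = o2_to_drymass,
                 bin_edges = as.numeric(bin_edges),
                 respiration_scale = respiration_scale,
                 digestion_scale = digestion_scale,
                 growth_def = growth_def,
                 solver_rtol = solver_rtol,
                 satiation_atol = satiation_atol),
            class = "model_config")
}

#' @export
print.model_config <- function(x, ...) {
  cat("<model_config>\n")
  cat("  length-mass law: m =", x$prey_mass_coeff, "* l^", x$prey_mass_exp, "ug\n")
  cat("  prey speed:", x$prey_speed_coeff, "BL/s;  structure const:",
      x$kolmogorov_struct_const, "\n")
  cat("  bins:", length(x$bin_edges) - 1, "(",
      min(x$bin_edges), "-", max(x$bin_edges), "mm )\n")
  cat("  respiration_scale:", x$respiration_scale,
      " digestion_scale:", x$digestion_scale,
      " growth_def:", x$growth_def, "\n")
  invisible(x)
}
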