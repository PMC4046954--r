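#' Construct a foraging environment
#'
#' The exogenous drivers of a 24-hour simulation: water temperature,
#' photoperiod, small-scale turbulence, and the prey field. The prey field is
#' given either as a total plankton dry biomass `b_total` (mg m^-3) together
#' with a normalized biomass size-spectrum slope `s`, or as an explicit
#' [prey_field] object (see [explicit_field()]).
#'
#' @param temperature Water temperature, degC.
#' @param photoperiod Hours of daylight in \[0, 24\]. Alternatively supply
#'   `latitude` and `day_of_year` and leave `photoperiod` `NULL`.
#' @param epsilon Turbulent kinetic energy dissipation rate, W kg^-1
#'   (non-negative). Default `1e-7`, typical of wind-driven mixing.
#' @param b_total Total prey dry biomass in the 0.04--2 mm length range,
#'   mg m^-3.
#' @param s Normalized size-spectrum slope (dimensionless, typically
#'   negative). Default `-1.2`, the classical reference value for
#'   oligotrophic systems in equilibrium.
#' @param prey Optional explicit [prey_field]; overrides `b_total`/`s`.
#' @param latitude,day_of_year Optional; used to derive `photoperiod` via
#'   [photoperiod_from_date()].
#' @return An object of class `foraging_env`.
#' @export
#' @examples
#' foraging_env(temperature = 5.1, photoperiod = 11.8, b_total = 15)
foraging_env <- function(temperature, photoperiod = NULL, epsilon = 1e-7,
                         b_total = NULL, s = -1.2, prey = NULL,
                         latitude = NULL, day_of_year = NULL) {
  if (is.null(photoperiod)) {
    if (is.null(latitude) || is.null(day_of_year)) {
      rlang::abort("supply either photoperiod or latitude + day_of_year",
                   class = "larvforage_validation_error")
    }
    photoperiod <- photoperiod_from_date(latitude, day_of_year)
  }
  chk <- function(ok, msg) {
    if (!isTRUE(ok)) rlang::abort(paste0("invalid environment: ", msg),
                                  class = "larvforage_validation_error")
  }
  chk(is.numeric(temperature) && is.finite(temperature), "temperature must be finite")
  chk(is.numeric(photoperiod) && photoperiod >= 0 && photoperiod <= 24,
      "photoperiod must lie in [0, 24]")
  chk(is.numeric(epsilon) && epsilon >= 0, "epsilon must be >= 0")
  if (is.null(prey)) {
    chk(is.numeric(b_total) && b_total >= 0, "b_total must be >= 0")
    chk(is.numeric(s) && is.finite(s), "s must be finite")
  } else {
    chk(inherits(prey, "prey_field"), "prey must be a prey_field")
  }
  structure(list(temperature = as.numeric(temperature),
                 photoperiod = as.numeric(photoperiod),
                 epsilon = as.numeric(epsilon),
                 b_total = if (is.null(prey)) as.numeric(b_total) else NULL,
                 s = if (is.null(prey)) as.numeric(s) else NULL,
                 prey = prey),
            class = "foraging_env")
}

#' @export
print.foraging_env <- function(x, ...) {
  cat("<foraging_env> T =", x$temperature, "degC, photoperiod =",
      x$photoperiod, "h, epsilon =", x$epsilon, "W/kg\n")
  if (is.null(x$prey)) {
    cat("  prey: b_total =", x$b_total, "mg/m^3, slope s =", x$s, "\n")
  } else {
    cat("  prey: explicit field,", nrow(x$prey), "bins\n")
  }
  invisible(x)
}

#' Resolve the prey field of an environment
#' @keywords internal
env_prey_field <- function(env, cfg) {
  if (!is.null(env$prey)) env$prey else build_spectrum(env$b_total, env$s, cfg)
}

#' Hours of daylight from latitude and date
#'
#' Approximate photoperiod by the standard sunrise equation, with solar
#' declination computed from the day of year. Polar day and night are clamped
#' to 24 and 0 h. The approximation ignores atmospheric refraction and the
#' solar disc diameter and is accurate to roughly a tenth of an hour at
#' temperate latitudes.
#'
#' @param latitude_deg Latitude in degrees (positive north).
#' @param day_of_year Integer day of year (1--366).
#' @return Hours of daylight in \[0, 24\].
#' @export
#' @examples
#' photoperiod_from_date(54.5, 172) # around the June solstice
photoperiod_from_date <- function(latitude_deg, day_of_year) {
  decl <- 23.44 * sin(2 * pi * (284 + day_of_year) / 365) # degrees
  cos_h <- -tanpi(latitude_deg / 180) * tanpi(decl / 180)
  cos_h <- pmin(1, pmax(-1, cos_h))
  h <- acos(cos_h) * 180 / pi # half-day hour angle, degrees
  2 * h / 15
}
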