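#' Hourly daylight fractions
#'
#' Splits the 24-hour simulation window into one night followed by one day:
#' daylight occupies the final `photoperiod` hours, i.e. the interval
#' `[24 - photoperiod, 24]`. The light fraction of hourly step `t` is the
#' overlap of `[t - 1, t]` with that interval, so the fractions sum exactly
#' to the photoperiod and at most one step (dawn) is fractional.
#'
#' @param photoperiod Hours of daylight in \[0, 24\].
#' @return Numeric vector `lambda[1..24]` of daylight fractions.
#' @export
#' @examples
#' light_schedule(11.8)
light_schedule <- function(photoperiod) {
  if (photoperiod < 0 || photoperiod > 24) {
    rlang::abort("photoperiod must lie in [0, 24]",
                 class = "larvforage_domain_error")
  }
  t <- seq_len(24)
  dawn <- 24 - photoperiod
  pmax(0, pmin(t, 24) - pmax(t - 1, dawn))
}

#' Routine respiration
#'
#' Mass loss to routine metabolism: a fraction `x_res` of dry mass per hour
#' at 10 degC (times the global `respiration_scale`), corrected for ambient
#' temperature by the respiratory Q10:
#' `R = respiration_scale * x_res * M * x_rQ10^((T - 10)/10)`.
#' Temperatures above the larval upper thermal tolerance raise a
#' thermal-exclusion error.
#'
#' @param M Dry mass, ug.
#' @param temperature Water temperature, degC.
#' @param larva A [larval_type()].
#' @param cfg A [model_config()].
#' @return Respiration, ug h^-1.
#' @export
routine_respiration <- function(M, temperature, larva, cfg = model_config()) {
  if (any(M <= 0)) {
    rlang::abort("dry mass must be > 0", class = "larvforage_domain_error")
  }
  check_thermal(temperature, larva)
  cfg$respiration_scale * larva$x_res * M *
    larva$x_rQ10^((temperature - 10) / 10)
}

check_thermal <- function(temperature, larva) {
  if (temperature > larva$x_tol) {
    rlang::abort(
      paste0("temperature ", temperature,
             " degC exceeds upper thermal tolerance (x_tol = ", larva$x_tol,
             " degC) of ", larva$name, ": larva excluded"),
      class = "larvforage_thermal_exclusion")
  }
  invisible(TRUE)
}

#' Activity multiplier on respiration
#'
#' Respiration rises from routine at night to `y_act` times routine in full
#' daylight, linearly in the light fraction:
#' `A = 1 + (y_act - 1) * lambda`.
#'
#' @param lambda Light fraction of the hourly step, in \[0, 1\].
#' @param y_act Cost of foraging activity (multiple of routine respiration).
#' @return Dimensionless multiplier.
#' @export
activity_multiplier <- function(lambda, y_act) {
  1 + (y_act - 1) * lambda
}

#' Digestive capacity
#'
#' Maximum mass throughput of the gut: a fraction `y_dig` of dry mass per
#' hour at 10 degC (times the global `digestion_scale`), with digestive Q10
#' correction: `D = digestion_scale * y_dig * M * y_dQ10^((T - 10)/10)`.
#'
#' @inheritParams routine_respiration
#' @return Digestive capacity, ug h^-1.
#' @export
digestive_capacity <- function(M, temperature, larva, cfg = model_config()) {
  if (any(M <= 0)) {
    rlang::abort("dry mass must be > 0", class = "larvforage_domain_error")
  }
  cfg$digestion_scale * larva$y_dig * M *
    larva$y_dQ10^((temperature - 10) / 10)
}

#' Hourly ingestion
#'
#' Ingestion during one hourly step is the lesser of digestive capacity and
#' the foraging capacity realized over the daylight fraction of the step:
#' `I = min(D, 3600 * lambda * F)`.
#'
#' @param D Digestive capacity, ug h^-1.
#' @param F Foraging capacity, ug s^-1.
#' @param lambda Light fraction of the step.
#' @return Ingestion, ug h^-1.
#' @export
hourly_ingestion <- function(D, F, lambda) {
  pmin(D, 3600 * lambda * F)
}

#' Advance the larval state by one hour
#'
#' Explicit Euler update on the hourly grid using start-of-hour state for
#' all rates. Mass balance: `M' = M + y_eff * I - A * R`. Length growth is
#' isometric and irreversible: `L' = max(L, (M'/x_body)^(1/3))`, so a loss
#' of mass never shortens the larva.
#'
#' @param state List with `L` (mm), `M` (ug) and `hour`.
#' @param env A [foraging_env()].
#' @param larva A [larval_type()].
#' @param cfg A [model_config()].
#' @param field Optional pre-built `prey_field` (otherwise resolved from
#'   `env`).
#' @param ad_libitum If `TRUE`, ingestion is forced to the digestive
#'   capacity in every lit hour regardless of the prey field.
#' @return Updated state list, with the hour's diagnostics attached
#'   (`I`, `R`, `A`, `D`, `F`, `lambda`, `limitation`).
#' @export
step_hour <- function(state, env, larva, cfg = model_config(),
                      field = NULL, ad_libitum = FALSE) {
  lambda <- light_schedule(env$photoperiod)[state$hour]
  L <- state$L
  M <- state$M
  R <- routine_respiration(M, env$temperature, larva, cfg)
  A <- activity_multiplier(lambda, larva$y_act)
  D <- digestive_capacity(M, env$temperature, larva, cfg)
  if (lambda <= 0) {
    F_rate <- 0
    I <- 0
    limitation <- "dark"
  } else if (ad_libitum) {
    F_rate <- Inf
    I <- D
    limitation <- "digestion-limited"
  } else {
    if (is.null(field)) field <- env_prey_field(env, cfg)
    F_rate <- capacity_F(field, larva, env, cfg, L = L)
    I <- hourly_ingestion(D, F_rate, lambda)
    limitation <- if (D <= 3600 * lambda * F_rate) "digestion-limited"
                  else "foraging-limited"
  }
  M_new <- M + larva$y_eff * I - A * R
  dead <- M_new <= 0
  if (dead) M_new <- 1e-12 # floor so G remains reportable
  L_new <- max(L, (M_new / larva$x_body)^(1 / 3))
  list(L = L_new, M = M_new, hour = state$hour + 1,
       dead = isTRUE(state$dead) || dead,
       diag = list(lambda = lambda, M = M_new, L = L_new, I = I, R = R,
                   A = A, D = D, F = F_rate, limitation = limitation))
}

#' Simulate one 24-hour day
#'
#' Initializes the state at `L = x_len`, `M = x_body * x_len^3` and applies
#' 24 hourly [step_hour()] updates over the light schedule (night first,
#' then day). The daily specific growth rate is `G = ln(M24/M0)` per day
#' (or `(M24 - M0)/M0` when `cfg$growth_def = "arithmetic"`).
#'
#' @param larva A [larval_type()].
#' @param env A [foraging_env()].
#' @param cfg A [model_config()].
#' @param ad_libitum Force ingestion to digestive capacity in lit hours
#'   (used for growth-potential runs).
#' @return A `day_result` object: list with `G` (d^-1), `M0`, `M24`, `L24`,
#'   `dead`, and `trace`, a 24-row tibble of hourly diagnostics. Use
#'   [tidy()][generics::tidy] / [glance()][generics::glance] to extract
#'   tibbles.
#' @export
#' @examples
#' cod <- larval_type("cod")
#' env <- foraging_env(5.1, 11.8, epsilon = 1e-7, b_total = 15)
#' res <- simulate_day(cod, env)
#' glance(res)
simulate_day <- function(larva, env, cfg = model_config(),
                         ad_libitum = FALSE) {
  check_thermal(env$temperature, larva)
  field <- if (ad_libitum) NULL else env_prey_field(env, cfg)
  M0 <- larva$x_body * larva$x_len^3
  state <- list(L = larva$x_len, M = M0, hour = 1, dead = FALSE)
  rows <- vector("list", 24)
  for (t in seq_len(24)) {
    state <- step_hour(state, env, larva, cfg, field = field,
                       ad_libitum = ad_libitum)
    rows[[t]] <- state$diag
  }
  num <- function(nm) vapply(rows, function(r) r[[nm]], numeric(1))
  trace <- tibble::tibble(
    hour = seq_len(24), lambda = num("lambda"), M = num("M"), L = num("L"),
    I = num("I"), R = num("R"), A = num("A"), D = num("D"), F = num("F"),
    limitation = vapply(rows, function(r) r$limitation, character(1)))
  M24 <- state$M
  G <- switch(cfg$growth_def,
              log = log(M24 / M0),
              arithmetic = (M24 - M0) / M0)
  structure(list(G = G, M0 = M0, M24 = M24, L24 = state$L,
                 dead = state$dead, larva = larva$name,
                 trace = trace),
            class = "day_result")
}

#' @export
print.day_result <- function(x, ...) {
  cat("<day_result> ", x$larva, ": G = ", sprintf("%.4f", x$G),
      " /d  (M ", sprintf("%.1f", x$M0), " -> ", sprintf("%.1f", x$M24),
      " ug)", if (x$dead) "  [died]", "\n", sep = "")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Hourly trace of a day simulation
#' @param x A `day_result`.
#' @param ... Unused.
#' @return The 24-row hourly trace tibble.
#' @export
tidy.day_result <- function(x, ...) x$trace

#' One-row summary of a day simulation
#' @param x A `day_result`.
#' @param ... Unused.
#' @return A one-row tibble: `larva`, `G`, `M0`, `M24`, `L24`, `lit_hours`,
#'   `digestion_limited_hours`, `dead`.
#' @export
glance.day_result <- function(x, ...) {
  tibble::tibble(larva = x$larva, G = x$G, M0 = x$M0, M24 = x$M24,
                 L24 = x$L24,
                 lit_hours = sum(x$trace$lambda > 0),
                 digestion_limited_hours =
                   sum(x$trace$limitation == "digestion-limited"),
                 dead = x$dead)
}
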