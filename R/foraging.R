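#' Root-mean-square turbulent velocity between predator and prey
#'
#' Relative turbulent velocity at separation distance `d`, from the
#' second-order velocity structure function of inertial-subrange turbulence:
#' `w = sqrt(k * (eps * d)^(2/3))` with `k = 1.62` (= 55/18 of the universal
#' Kolmogorov constant 0.53) and `eps` the dissipation rate converted to
#' mm^2 s^-3 (1 W kg^-1 = 1e6 mm^2 s^-3). `w` scales as `eps^(1/3)`.
#'
#' @param epsilon Turbulent kinetic energy dissipation rate, W kg^-1
#'   (non-negative).
#' @param d Separation distance, mm (positive).
#' @param cfg A [model_config()].
#' @return Turbulent velocity, mm s^-1.
#' @export
#' @examples
#' turbulent_velocity(1e-7, 3.5) # about 0.9 mm/s
turbulent_velocity <- function(epsilon, d, cfg = model_config()) {
  if (any(epsilon < 0)) {
    rlang::abort("epsilon must be >= 0", class = "larvforage_domain_error")
  }
  if (any(d <= 0)) {
    rlang::abort("separation distance must be > 0",
                 class = "larvforage_domain_error")
  }
  eps_mm <- epsilon * 1e6
  sqrt(cfg$kolmogorov_struct_const * (eps_mm * d)^(2 / 3))
}

#' Observation success
#'
#' Probability that a prey item passing through the visual cylinder is
#' detected; a type-2 saturating response of prey length with half-detected
#' length `y_det`: `O = l / (l + y_det)`.
#'
#' @param l Prey length, mm.
#' @param y_det Half-detected prey length, mm.
#' @return Fraction in (0, 1).
#' @export
observation_success <- function(l, y_det) {
  if (any(l <= 0)) {
    rlang::abort("prey length must be > 0", class = "larvforage_domain_error")
  }
  l / (l + y_det)
}

#' Pursuit success
#'
#' Linearly reduced from 1 at zero turbulence to 0 where the turbulent
#' velocity reaches the maximum corrigible turbulent velocity `y_turb * L`:
#' `P = max(0, 1 - w / (y_turb * L))`.
#'
#' @param w Turbulent velocity, mm s^-1 (non-negative).
#' @param L Larval standard length, mm.
#' @param y_turb Corrigible turbulent velocity, body lengths s^-1.
#' @return Fraction in \[0, 1\].
#' @export
pursuit_success <- function(w, L, y_turb) {
  pmax(0, 1 - w / (y_turb * L))
}

#' Capture success
#'
#' Linearly reduced from 1 for infinitesimally small prey to 0 at the
#' maximum ingestible prey length `x_ing * L`:
#' `C = max(0, 1 - l / (x_ing * L))`.
#'
#' @param l Prey length, mm.
#' @param L Larval standard length, mm.
#' @param x_ing Maximum ingestible prey length as a fraction of `L`.
#' @return Fraction in \[0, 1\].
#' @export
capture_success <- function(l, L, x_ing) {
  if (any(l <= 0)) {
    rlang::abort("prey length must be > 0", class = "larvforage_domain_error")
  }
  pmax(0, 1 - l / (x_ing * L))
}

#' Prey swimming velocity
#'
#' Linear in prey length: `v = prey_speed_coeff * l`, with the default
#' coefficient of 3 body lengths per second typical of zooplankton under
#' 1 mm.
#'
#' @param l Prey length, mm.
#' @param cfg A [model_config()].
#' @return Velocity, mm s^-1.
#' @export
prey_velocity <- function(l, cfg = model_config()) {
  if (any(l <= 0)) {
    rlang::abort("prey length must be > 0", class = "larvforage_domain_error")
  }
  cfg$prey_speed_coeff * l
}

#' Combined predator-prey velocity
#'
#' Root-sum-of-squares of larval swimming, prey swimming and turbulent
#' velocities: `V = sqrt(u^2 + v^2 + w^2)`.
#'
#' @param u,v,w Component velocities, mm s^-1 (non-negative).
#' @return Combined velocity, mm s^-1.
#' @export
combined_velocity <- function(u, v, w) {
  sqrt(u^2 + v^2 + w^2)
}

#' Per-bin encounter rates
#'
#' Encounters per second with each prey bin: numeric prey concentration
#' times the volume swept per second by the effective visual cylinder
#' (radius `y_vis * L`, length the combined velocity), times observation
#' success: `E_i = c_i * pi * (y_vis L)^2 * V_i * O_i`. Larval swimming is
#' `u = y_swim * L`; the turbulent velocity is evaluated at separation
#' `d = y_dist * L`.
#'
#' @param field A `prey_field`.
#' @param larva A [larval_type()].
#' @param env A [foraging_env()] (only `epsilon` is used here).
#' @param cfg A [model_config()].
#' @param L Larval standard length, mm; defaults to the type's `x_len`.
#' @return A `foraging_breakdown` tibble with one row per bin (`l`, `m`,
#'   `c`, `v`, `V`, `O`, `C`, `E`, `e`, `clearance` in l h^-1) and scalar
#'   attributes `u`, `w`, `P`, `L`.
#' @export
encounter_rates <- function(field, larva, env, cfg = model_config(),
                            L = larva$x_len) {
  stopifnot(L > 0)
  u <- larva$y_swim * L
  w <- turbulent_velocity(env$epsilon, larva$y_dist * L, cfg)
  v <- cfg$prey_speed_coeff * field$l
  V <- combined_velocity(u, v, w)
  O <- observation_success(field$l, larva$y_det)
  C <- capture_success(field$l, L, larva$x_ing)
  P <- pursuit_success(w, L, larva$y_turb)
  area <- pi * (larva$y_vis * L)^2
  E <- field$c * area * V * O
  e <- P * C * field$m
  out <- tibble::tibble(l = field$l, m = field$m, c = field$c,
                        v = v, V = V, O = O, C = C, E = E, e = e,
                        clearance = area * V * O * 3600 / 1e6)
  tibble::new_tibble(out, class = "foraging_breakdown",
                     u = u, w = w, P = P, L = L)
}

#' Foraging capacity under optimal diet selection
#'
#' Holling-disk ingestion rate over the optimal diet subset S:
#' `F = sum_{i in S} E_i e_i / (1 + y_hand * sum_{i in S} E_i)` where
#' `e_i = P * C_i * m_i` is the expected ingested mass per encounter.
#' Handling time is charged once per encounter with any diet-included prey.
#' The diet is chosen by the classic profitability rule: bins are ranked by
#' `e_i / y_hand` (ties broken toward the smaller bin) and included greedily
#' while the rate strictly increases, which attains the global maximum over
#' all subsets.
#'
#' @inheritParams encounter_rates
#' @return A `foraging_breakdown` tibble as from [encounter_rates()], with
#'   an added logical column `in_diet` and attribute `F` (ug s^-1).
#' @export
foraging_capacity <- function(field, larva, env, cfg = model_config(),
                              L = larva$x_len) {
  br <- encounter_rates(field, larva, env, cfg, L = L)
  res <- optimal_diet_rate(br$E, br$e, larva$y_hand)
  br$in_diet <- res$in_diet
  attr(br, "F") <- res$F
  br
}

# fast scalar path used inside the hourly loop: F only, no tibble
capacity_F <- function(field, larva, env, cfg, L) {
  u <- larva$y_swim * L
  w <- turbulent_velocity(env$epsilon, larva$y_dist * L, cfg)
  V <- sqrt(u^2 + (cfg$prey_speed_coeff * field$l)^2 + w^2)
  O <- field$l / (field$l + larva$y_det)
  C <- pmax(0, 1 - field$l / (larva$x_ing * L))
  P <- max(0, 1 - w / (larva$y_turb * L))
  E <- field$c * (pi * (larva$y_vis * L)^2) * V * O
  optimal_diet_rate(E, P * C * field$m, larva$y_hand)$F
}

# Greedy optimal-diet Holling disk rate. Candidates need E > 0 and e > 0;
# inclusion in decreasing profitability (e) order while the rate strictly
# increases. With common handling time the greedy prefix is globally optimal.
optimal_diet_rate <- function(E, e, y_hand) {
  n <- length(E)
  in_diet <- rep(FALSE, n)
  cand <- which(E > 0 & e > 0)
  if (length(cand) == 0) return(list(F = 0, in_diet = in_diet))
  ord <- cand[order(-e[cand], cand)] # ties toward smaller bin index
  num <- cumsum(E[ord] * e[ord])
  den <- 1 + y_hand * cumsum(E[ord])
  rate <- num / den
  # last k for which the rate strictly increased at every inclusion
  k <- if (all(diff(rate) > 0)) length(rate) else which(diff(rate) <= 0)[1]
  in_diet[ord[seq_len(k)]] <- TRUE
  list(F = rate[k], in_diet = in_diet)
}

#' Diagnostic clearance rate
#'
#' Liters of water effectively searched per hour for prey of length `l`,
#' accounting for prey swimming and imperfect detection but not pursuit or
#' capture: `pi * (y_vis L)^2 * V(l) * O(l) * 3600 / 1e6`.
#'
#' @param l Prey length, mm.
#' @inheritParams encounter_rates
#' @return Clearance rate, l h^-1.
#' @export
#' @examples
#' herring <- larval_type("herring")
#' env <- foraging_env(14.7, 11.6, epsilon = 0, b_total = 1)
#' clearance_rate(0.2, herring, env) # about 5 l/h
clearance_rate <- function(l, larva, env, cfg = model_config(),
                           L = larva$x_len) {
  u <- larva$y_swim * L
  w <- turbulent_velocity(env$epsilon, larva$y_dist * L, cfg)
  v <- prey_velocity(l, cfg)
  V <- combined_velocity(u, v, w)
  O <- observation_success(l, larva$y_det)
  pi * (larva$y_vis * L)^2 * V * O * 3600 / 1e6
}

#' Chesson's alpha prey-sampling index
#'
#' Per-bin ingestion rate divided by ambient numeric concentration,
#' normalized to sum to one over the bins that hold prey:
#' `alpha_i` proportional to `pi * (y_vis L)^2 * V_i * O_i * P * C_i`.
#' Because the concentration cancels, alpha measures sampling bias for prey
#' sizes rather than preference, and is invariant to scaling `b_total`.
#'
#' @inheritParams encounter_rates
#' @return A tibble (`l`, `alpha`) over bins with non-zero prey, with
#'   attribute `peak_l`, the bin centre of maximal alpha.
#' @export
chesson_alpha <- function(field, larva, env, cfg = model_config(),
                          L = larva$x_len) {
  keep <- field$c > 0
  if (!any(keep)) {
    rlang::abort("prey field is empty: alpha undefined",
                 class = "larvforage_domain_error")
  }
  br <- encounter_rates(field, larva, env, cfg, L = L)
  raw <- (br$E / field$c) * attr(br, "P") * br$C
  raw[!keep] <- 0
  alpha <- raw[keep] / sum(raw[keep])
  out <- tibble::tibble(l = field$l[keep], alpha = alpha)
  attr(out, "peak_l") <- out$l[which.max(out$alpha)]
  out
}
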