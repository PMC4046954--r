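#' Growth potential under ad libitum feeding
#'
#' Daily specific growth rate when ingestion equals digestive capacity in
#' every lit hour, independent of the prey field.
#'
#' @param larva A [larval_type()].
#' @param temperature Water temperature, degC.
#' @param photoperiod Hours of daylight.
#' @param cfg A [model_config()].
#' @return Growth rate G, d^-1.
#' @export
growth_potential <- function(larva, temperature, photoperiod,
                             cfg = model_config()) {
  env <- foraging_env(temperature, photoperiod, epsilon = 0, b_total = 0)
  simulate_day(larva, env, cfg, ad_libitum = TRUE)$G
}

# G as a function of b_total with the rest of env fixed
g_of_b <- function(larva, env, cfg) {
  function(b_total) {
    e <- env
    e$b_total <- b_total
    e$prey <- NULL
    simulate_day(larva, e, cfg)$G
  }
}

# smallest b_total (mg m^-3) with g(b) >= target, by bisection on log10 b
# over [1e-3, 1e4]; Inf if unattainable, with a diagnostic message attr
solve_prey_level <- function(larva, env, cfg, target) {
  g <- g_of_b(larva, env, cfg)
  lo <- -3
  hi <- 4
  if (g(10^lo) >= target) return(10^lo)
  if (g(10^hi) < target) {
    out <- Inf
    attr(out, "diagnostic") <- paste0(
      "target G = ", target, " /d not attained at b_total = 1e4 mg m^-3")
    return(out)
  }
  rtol_log <- cfg$solver_rtol / log(10)
  while (hi - lo > rtol_log) {
    mid <- (lo + hi) / 2
    if (g(10^mid) >= target) hi <- mid else lo <- mid
  }
  10^hi
}

#' Starvation point
#'
#' Minimum total prey biomass (mg m^-3) needed for non-negative daily
#' growth, holding temperature, photoperiod, turbulence and the spectrum
#' slope at their environment values. Solved by bisection on log10 biomass
#' to the configured relative tolerance.
#'
#' @param larva A [larval_type()].
#' @param env A [foraging_env()] (its `b_total` is ignored).
#' @param cfg A [model_config()].
#' @return Prey biomass, mg m^-3; `Inf` (with a `"diagnostic"` attribute)
#'   when even ad libitum feeding cannot sustain growth.
#' @export
starvation_point <- function(larva, env, cfg = model_config()) {
  solve_prey_level(larva, env, cfg, target = 0)
}

#' Satiation point
#'
#' Minimum total prey biomass (mg m^-3) at which the larva reaches its
#' ad libitum growth potential (to within `cfg$satiation_atol` on G).
#'
#' @inheritParams starvation_point
#' @return Prey biomass, mg m^-3 (or `Inf` with diagnostic).
#' @export
satiation_point <- function(larva, env, cfg = model_config()) {
  g_max <- growth_potential(larva, env$temperature, env$photoperiod, cfg)
  solve_prey_level(larva, env, cfg, target = g_max - cfg$satiation_atol)
}

#' Prey requirement for a target growth rate
#'
#' Minimum total prey biomass (mg m^-3) sustaining a daily growth rate of at
#' least `G_target` (default 5 percent per day).
#'
#' @inheritParams starvation_point
#' @param G_target Target specific growth rate, d^-1.
#' @return Prey biomass, mg m^-3 (or `Inf` with diagnostic).
#' @export
prey_requirement <- function(larva, env, cfg = model_config(),
                             G_target = 0.05) {
  solve_prey_level(larva, env, cfg, target = G_target)
}

#' Perturbable parameters of the sensitivity machinery
#' @keywords internal
perturbable_parameters <- function() {
  c(trait_names(), "temperature", "photoperiod", "s", "epsilon")
}

# evaluate the sensitivity output at a multiplicative perturbation r of one
# parameter; non-finite outputs propagate as-is
perturbed_output <- function(parameter, r, output, larva, env, cfg,
                             G_target = 0.05) {
  if (parameter %in% trait_names()) {
    larva[[parameter]] <- larva[[parameter]] * r
    larva <- tryCatch(validate_larval_type(larva), error = function(e) NULL)
    if (is.null(larva)) return(NA_real_)
  } else {
    env[[parameter]] <- env[[parameter]] * r
    if (parameter == "photoperiod" && env$photoperiod > 24) return(NA_real_)
  }
  tryCatch(
    switch(output,
           growth_potential =
             growth_potential(larva, env$temperature, env$photoperiod, cfg),
           prey_requirement =
             prey_requirement(larva, env, cfg, G_target = G_target)),
    larvforage_thermal_exclusion = function(e) NA_real_)
}

#' Sensitivity range of one parameter
#'
#' Finds the interval of multiplicative perturbations of a single larval
#' trait or environmental factor within which a model output (ad libitum
#' growth potential or the prey requirement for 5 percent daily growth)
#' changes by less than 10 percent of its reference value:
#' `|Phi(r * theta) - Phi0| < 0.1 * |Phi0|` in both directions.
#' Bounds are located by bisection to 0.05 percent of the reference
#' parameter; a direction is reported open (0 or `Inf`) when even a tenfold
#' perturbation leaves the output within the band. Temperature is perturbed
#' on its numeric degC value.
#'
#' @param parameter One of the sixteen trait names, `"temperature"`,
#'   `"photoperiod"`, `"s"` or `"epsilon"`.
#' @param output `"growth_potential"` or `"prey_requirement"`.
#' @param larva A [larval_type()].
#' @param env A [foraging_env()] at the reference conditions.
#' @param cfg A [model_config()].
#' @param G_target Growth target for the prey-requirement output, d^-1.
#' @param band Relative output band (default 0.1).
#' @return A one-row tibble: `parameter`, `output`, `low_pct`, `high_pct`
#'   (percent of the reference parameter value; 0 / `Inf` mark open
#'   directions) and `reference`, the unperturbed output.
#' @export
sensitivity_range <- function(parameter,
                              output = c("prey_requirement",
                                         "growth_potential"),
                              larva, env, cfg = model_config(),
                              G_target = 0.05, band = 0.1) {
  output <- match.arg(output)
  if (!parameter %in% perturbable_parameters()) {
    rlang::abort(paste0("parameter '", parameter, "' is not perturbable"),
                 class = "larvforage_validation_error")
  }
  phi0 <- perturbed_output(parameter, 1, output, larva, env, cfg, G_target)
  if (!is.finite(phi0) || phi0 == 0) {
    rlang::abort("reference output must be finite and nonzero",
                 class = "larvforage_domain_error")
  }
  outside <- function(r) {
    phi <- perturbed_output(parameter, r, output, larva, env, cfg, G_target)
    if (!is.finite(phi)) TRUE else abs(phi - phi0) >= band * abs(phi0)
  }
  bound <- function(probe) {
    if (!outside(probe)) return(Inf) # open direction (sign fixed below)
    lo <- 1
    hi <- probe
    while (abs(hi - lo) > 5e-4) {
      mid <- (lo + hi) / 2
      if (outside(mid)) hi <- mid else lo <- mid
    }
    (lo + hi) / 2
  }
  up <- bound(10)
  dn <- bound(0.1)
  tibble::tibble(parameter = parameter, output = output,
                 low_pct = if (is.infinite(dn)) 0 else 100 * dn,
                 high_pct = if (is.infinite(up)) Inf else 100 * up,
                 reference = phi0)
}

#' Optimal prey length
#'
#' The prey bin maximizing the expected ingested dry mass per encounter
#' standardized by handling time, `e_i / y_hand = P * C_i * m_i / y_hand`.
#' Pursuit success and handling time are constant across bins, so the
#' argmax is that of `m_i * C_i`.
#'
#' @param larva A [larval_type()].
#' @param cfg A [model_config()].
#' @param L Standard length, mm (defaults to `x_len`).
#' @return One-row tibble: `species`, `L`, `max_l` (maximum ingestible
#'   length, mm), `optimal_l` (bin centre, mm) and `ratio` =
#'   `optimal_l / max_l`.
#' @export
#' @examples
#' optimal_prey_length(larval_type("cod"))
optimal_prey_length <- function(larva, cfg = model_config(), L = larva$x_len) {
  edges <- cfg$bin_edges
  l <- (utils::head(edges, -1) + utils::tail(edges, -1)) / 2
  m <- length_to_mass(l, cfg)
  C <- capture_success(l, L, larva$x_ing)
  i <- which.max(m * C)
  max_l <- larva$x_ing * L
  tibble::tibble(species = larva$name, L = L, max_l = max_l,
                 optimal_l = l[i], ratio = l[i] / max_l)
}

#' Optimal normalized size-spectrum slope
#'
#' Golden-section search for the slope `s` in \[-4, 0\] minimizing the
#' starvation point (or the satiation point), to an absolute tolerance of
#' 0.01 in `s`.
#'
#' @inheritParams starvation_point
#' @param objective `"starvation"` or `"satiation"`.
#' @param interval Search interval for `s`.
#' @param tol Absolute tolerance on `s`.
#' @return Optimal slope `s*` (numeric scalar) with attribute `"objective"`,
#'   the minimized prey biomass (mg m^-3).
#' @export
optimal_spectrum_slope <- function(larva, env, cfg = model_config(),
                                   objective = c("starvation", "satiation"),
                                   interval = c(-4, 0), tol = 0.01) {
  objective <- match.arg(objective)
  f <- function(s) {
    e <- env
    e$s <- s
    e$prey <- NULL
    switch(objective,
           starvation = starvation_point(larva, e, cfg),
           satiation = satiation_point(larva, e, cfg))
  }
  gr <- (sqrt(5) - 1) / 2
  a <- interval[1]
  b <- interval[2]
  x1 <- b - gr * (b - a)
  x2 <- a + gr * (b - a)
  f1 <- f(x1)
  f2 <- f(x2)
  if (!is.finite(f1) && !is.finite(f2)) {
    rlang::abort("starvation point not finite anywhere on the interval",
                 class = "larvforage_domain_error")
  }
  while (b - a > tol) {
    if (f1 <= f2) { # ties toward the left: deterministic on flat stretches
      b <- x2; x2 <- x1; f2 <- f1
      x1 <- b - gr * (b - a); f1 <- f(x1)
    } else {
      a <- x1; x1 <- x2; f1 <- f2
      x2 <- a + gr * (b - a); f2 <- f(x2)
    }
  }
  s_star <- if (f1 <= f2) x1 else x2
  structure(s_star, objective = min(f1, f2))
}

#' Starvation and satiation versus turbulence
#'
#' Computes the starvation and satiation points over a grid of turbulent
#' kinetic energy dissipation rates. Grid points at which feeding is
#' impossible (pursuit success zero for every bin) come out infinite.
#'
#' @inheritParams starvation_point
#' @param eps_grid Dissipation rates, W kg^-1.
#' @return Tibble: `epsilon`, `starvation`, `satiation` (mg m^-3).
#' @export
turbulence_response <- function(larva, env, cfg = model_config(),
                                eps_grid = c(0, 10^seq(-12, -4, by = 1))) {
  if (length(eps_grid) == 0) {
    rlang::abort("eps_grid must be nonempty",
                 class = "larvforage_validation_error")
  }
  rows <- purrr::map(eps_grid, function(eps) {
    e <- env
    e$epsilon <- eps
    tibble::tibble(epsilon = eps,
                   starvation = as.numeric(starvation_point(larva, e, cfg)),
                   satiation = as.numeric(satiation_point(larva, e, cfg)))
  })
  dplyr::bind_rows(rows)
}

#' Optimal foraging summary for a set of larval types
#'
#' Per type: maximum ingestible prey length, optimal prey length (bin
#' centre) and its ratio to the maximum, the optimal spectrum slope, and the
#' optimal dissipation rate (the grid argmin of the starvation point).
#'
#' @param species Character vector of built-in type names (default all
#'   four).
#' @param env A [foraging_env()] giving the reference temperature,
#'   photoperiod and slope for the slope/turbulence optimizations; defaults
#'   to 10 degC, 12 h, s = -1.2.
#' @param cfg A [model_config()].
#' @param eps_grid Dissipation grid for the turbulence optimum, W kg^-1.
#' @return Tibble with one row per type.
#' @export
optima_report <- function(species = builtin_types()$species,
                          env = foraging_env(10, 12, epsilon = 1e-7,
                                             b_total = 10),
                          cfg = model_config(),
                          eps_grid = c(0, 10^seq(-10, -4, by = 2))) {
  rows <- purrr::map(species, function(sp) {
    lt <- larval_type(sp)
    opt <- optimal_prey_length(lt, cfg)
    s_star <- optimal_spectrum_slope(lt, env, cfg)
    tr <- turbulence_response(lt, env, cfg, eps_grid = eps_grid)
    eps_star <- tr$epsilon[which.min(tr$starvation)]
    dplyr::mutate(opt, optimal_s = as.numeric(s_star),
                  optimal_epsilon = eps_star)
  })
  dplyr::bind_rows(rows)
}
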