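#' Generate synthetic test scenarios and trait sets
#'
#' Deterministic (seeded) generator of simulation scenarios for testing and
#' benchmarking. Each scenario pairs a larval type -- one of the built-ins
#' or a random trait set drawn uniformly within +/-50 percent of the
#' built-in trait ranges -- with an environment drawn from the envelope of
#' conditions young larvae plausibly experience: temperature 3--24 degC,
#' photoperiod 9--24 h, dissipation rate 1e-12--1e-5 W kg^-1 (log-uniform),
#' total prey biomass 0.1--100 mg m^-3 (log-uniform) and spectrum slope
#' -2.5 to -0.5. Scenarios never exceed the larva's thermal tolerance.
#'
#' @param seed Integer seed; the same seed reproduces the same scenarios.
#' @param n Number of scenarios (>= 1).
#' @param dir Optional directory: when given, a `scenarios.csv` table and
#'   one loadable YAML config per scenario are written there.
#' @return A tibble with one row per scenario (`label`, `type`, the sixteen
#'   traits, `temperature`, `photoperiod`, `epsilon`, `b_total`, `s`).
#' @export
#' @examples
#' generate_fixtures(seed = 1, n = 3)
generate_fixtures <- function(seed, n, dir = NULL) {
  if (!is.numeric(n) || n < 1) {
    rlang::abort("n must be >= 1", class = "larvforage_validation_error")
  }
  n <- as.integer(n)
  tab <- builtin_types()
  rng <- function(col) range(tab[[col]])
  out <- withr_seed(seed, {
    rows <- purrr::map(seq_len(n), function(i) {
      use_builtin <- stats::runif(1) < 0.5
      if (use_builtin) {
        sp <- sample(tab$species, 1)
        traits <- as.list(tab[tab$species == sp, trait_names()])
        type <- sp
      } else {
        traits <- lapply(trait_names(), function(nm) {
          r <- rng(nm)
          lo <- 0.5 * r[1]
          hi <- 1.5 * r[2]
          stats::runif(1, lo, hi)
        })
        names(traits) <- trait_names()
        # keep the draw inside the validity domain
        traits$y_eff <- min(traits$y_eff, 1)
        traits$y_act <- max(traits$y_act, 1)
        traits$x_rQ10 <- max(traits$x_rQ10, 1.01)
        traits$y_dQ10 <- max(traits$y_dQ10, 1.01)
        if (traits$x_ing * traits$x_len <= 0.045) traits$x_ing <- 0.1
        type <- "custom"
      }
      temperature <- stats::runif(1, 3, min(24, traits$x_tol))
      tibble::as_tibble(c(
        list(label = sprintf("scenario_%03d", i), type = type),
        traits,
        list(temperature = temperature,
             photoperiod = stats::runif(1, 9, 24),
             epsilon = 10^stats::runif(1, -12, -5),
             b_total = 10^stats::runif(1, -1, 2),
             s = stats::runif(1, -2.5, -0.5))))
    })
    dplyr::bind_rows(rows)
  })
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    utils::write.csv(out, file.path(dir, "scenarios.csv"), row.names = FALSE)
    for (i in seq_len(nrow(out))) {
      row <- out[i, ]
      bundle <- list(
        larva = rlang::exec(larval_type, species = NULL,
                            !!!as.list(row[trait_names()]),
                            name = row$label),
        env = foraging_env(row$temperature, row$photoperiod,
                           epsilon = row$epsilon, b_total = row$b_total,
                           s = row$s),
        cfg = model_config())
      write_config(bundle, file.path(dir, paste0(row$label, ".yaml")))
    }
  }
  out
}

# evaluate expr under a local RNG seed without disturbing the global stream
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
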