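#' Load a run configuration
#'
#' Reads a YAML configuration with up to three sections -- `larva`,
#' `environment` and `model` -- validates every field, and returns the
#' resolved bundle. Unknown keys are rejected. Values for percent-valued
#' traits may be given either as fractions (`0.157`) or as explicit percent
#' strings (`"15.7%"`).
#'
#' Recognized keys:
#' \itemize{
#'   \item `larva`: `type` (built-in name) and/or any of the sixteen
#'     traits, plus optional `name`.
#'   \item `environment`: `temperature`, `photoperiod` (or `latitude` +
#'     `day_of_year`), `epsilon`, `b_total`, `s`.
#'   \item `model`: any argument of [model_config()].
#' }
#'
#' @param path Path to a YAML file, or `NULL` to build purely from
#'   `overrides`.
#' @param overrides Named list merged over the file contents (same
#'   structure), e.g. from CLI flags.
#' @param quiet Suppress the effective-configuration log line (stderr).
#' @return A list with elements `larva` ([larval_type()]), `env`
#'   ([foraging_env()]) and `cfg` ([model_config()]).
#' @export
load_config <- function(path = NULL, overrides = list(), quiet = FALSE) {
  raw <- list()
  if (!is.null(path)) {
    raw <- tryCatch(
      yaml::read_yaml(path),
      error = function(e) {
        rlang::abort(paste0("cannot parse config '", path, "': ",
                            conditionMessage(e)),
                     class = "larvforage_parse_error")
      })
    if (!is.list(raw)) {
      rlang::abort(paste0("config '", path, "' is not a key-value mapping"),
                   class = "larvforage_parse_error")
    }
  }
  bad <- setdiff(names(raw), c("larva", "environment", "model"))
  if (length(bad) > 0) {
    rlang::abort(paste0("unknown config section(s): ",
                        paste(bad, collapse = ", ")),
                 class = "larvforage_validation_error")
  }
  merged <- utils::modifyList(raw, overrides)
  larva_spec <- lapply(merged$larva %||% list(), parse_percent)
  env_spec <- merged$environment %||% list()
  model_spec <- merged$model %||% list()

  known_larva <- c("type", "name", trait_names())
  bad <- setdiff(names(larva_spec), known_larva)
  if (length(bad) > 0) {
    rlang::abort(paste0("unknown larva key(s): ", paste(bad, collapse = ", ")),
                 class = "larvforage_validation_error")
  }
  traits <- larva_spec[intersect(names(larva_spec), trait_names())]
  larva <- rlang::exec(larval_type,
                       species = larva_spec$type %||% NULL,
                       !!!traits,
                       name = larva_spec$name %||% NULL)

  known_env <- c("temperature", "photoperiod", "epsilon", "b_total", "s",
                 "latitude", "day_of_year")
  bad <- setdiff(names(env_spec), known_env)
  if (length(bad) > 0) {
    rlang::abort(paste0("unknown environment key(s): ",
                        paste(bad, collapse = ", ")),
                 class = "larvforage_validation_error")
  }
  if (is.null(env_spec$temperature)) {
    rlang::abort("environment.temperature is required",
                 class = "larvforage_validation_error")
  }
  env <- foraging_env(
    temperature = env_spec$temperature,
    photoperiod = env_spec$photoperiod %||% NULL,
    epsilon = env_spec$epsilon %||% 1e-7,
    b_total = env_spec$b_total %||% 10,
    s = env_spec$s %||% -1.2,
    latitude = env_spec$latitude %||% NULL,
    day_of_year = env_spec$day_of_year %||% NULL)

  bad <- setdiff(names(model_spec), names(formals(model_config)))
  if (length(bad) > 0) {
    rlang::abort(paste0("unknown model key(s): ", paste(bad, collapse = ", ")),
                 class = "larvforage_validation_error")
  }
  cfg <- rlang::exec(model_config, !!!model_spec)

  if (!quiet) {
    message("config: larva=", larva$name,
            " T=", env$temperature, "C photoperiod=", round(env$photoperiod, 2),
            "h eps=", env$epsilon, " b_total=", env$b_total,
            " s=", env$s)
  }
  list(larva = larva, env = env, cfg = cfg)
}

# "15.7%" -> 0.157; numbers pass through
parse_percent <- function(x) {
  if (is.character(x) && length(x) == 1 && grepl("%\\s*$", x)) {
    as.numeric(sub("%\\s*$", "", x)) / 100
  } else x
}

#' Write a run configuration
#'
#' Serializes a `(larva, env, cfg)` bundle back to YAML such that
#' [load_config()] reproduces it exactly.
#'
#' @param bundle A list with `larva`, `env`, `cfg` as returned by
#'   [load_config()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(bundle, path) {
  larva <- bundle$larva
  env <- bundle$env
  cfg <- bundle$cfg
  out <- list(
    larva = c(list(name = larva$name), larva[trait_names()]),
    environment = list(temperature = env$temperature,
                       photoperiod = env$photoperiod,
                       epsilon = env$epsilon,
                       b_total = env$b_total,
                       s = env$s),
    model = cfg[setdiff(names(cfg), "bin_edges")])
  yaml::write_yaml(out, path, precision = 15)
  invisible(path)
}
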