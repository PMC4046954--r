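#' Built-in larval parameterizations
#'
#' Returns the trait table for the four built-in larval types: young
#' exogenously feeding European anchovy (5.5 mm), Atlantic cod (7 mm),
#' Atlantic herring (13 mm) and European sprat (7 mm). Traits printed as
#' percentages in the source literature are stored as fractions. The sprat
#' respiration traits (`x_res`, `x_rQ10`) are herring estimates, as no
#' species-specific measurements were available.
#'
#' Trait glossary (species-specific traits prefixed `x_`, generic `y_`):
#' \describe{
#'   \item{x_body}{body shape, upper limit of dry mass / length^3, ug mm^-3}
#'   \item{x_ing}{maximum ingestible prey length, fraction of standard length}
#'   \item{x_len}{initial standard length, mm}
#'   \item{x_res}{routine respiration at 10 degC, fraction of dry mass per hour}
#'   \item{x_rQ10}{respiratory Q10}
#'   \item{x_tol}{upper thermal tolerance, degC}
#'   \item{y_act}{cost of foraging activity, multiple of routine respiration}
#'   \item{y_det}{prey length detected to 50 percent, mm}
#'   \item{y_dig}{digestive throughput at 10 degC, fraction of dry mass per hour}
#'   \item{y_dQ10}{digestive Q10}
#'   \item{y_dist}{predator-prey encounter separation, fraction of length}
#'   \item{y_eff}{metabolic efficiency, fraction in (0, 1]}
#'   \item{y_hand}{prey handling time, s}
#'   \item{y_swim}{effective swimming speed, body lengths per s}
#'   \item{y_turb}{maximum corrigible turbulent velocity, body lengths per s}
#'   \item{y_vis}{effective visual cylinder radius, fraction of length}
#' }
#'
#' @return A tibble with one row per species and one column per trait.
#' @seealso [larval_type()] to construct a single (possibly modified) type.
#' @export
#' @examples
#' builtin_types()
builtin_types <- function() {
  tibble::tibble(
    species = c("anchovy", "cod", "herring", "sprat"),
    x_body  = c(0.226, 1.04, 0.168, 0.0684),
    x_ing   = c(0.0805, 0.157, 0.0784, 0.0384),
    x_len   = c(5.5, 7, 13, 7),
    x_res   = c(0.0411, 0.0203, 0.0240, 0.0240),
    x_rQ10  = c(1.39, 2.38, 1.71, 1.71),
    x_tol   = c(25, 15, 20, 16),
    y_act   = 2.0,
    y_det   = 0.07,
    y_dig   = 0.025,
    y_dQ10  = 2.5,
    y_dist  = 0.5,
    y_eff   = 0.675,
    y_hand  = 1.5,
    y_swim  = 0.75,
    y_turb  = 1.0,
    y_vis   = 0.6
  )
}

#' Names of the sixteen larval traits
#' @keywords internal
trait_names <- function() {
  c("x_body", "x_ing", "x_len", "x_res", "x_rQ10", "x_tol",
    "y_act", "y_det", "y_dig", "y_dQ10", "y_dist", "y_eff",
    "y_hand", "y_swim", "y_turb", "y_vis")
}

#' Construct a larval type
#'
#' Builds a validated larval type, either from scratch (all sixteen traits
#' supplied) or by overriding traits of a built-in species.
#'
#' @param species Name of a built-in type (`"anchovy"`, `"cod"`, `"herring"`,
#'   `"sprat"`) to start from, or `NULL` to supply every trait explicitly.
#' @param ... Named trait overrides (see [builtin_types()] for the glossary).
#' @param name Display name; defaults to `species` or `"custom"`.
#' @return An object of class `larval_type`: a named list of the sixteen
#'   traits plus `name`.
#' @export
#' @examples
#' cod <- larval_type("cod")
#' slow_cod <- larval_type("cod", y_swim = 0.5)
larval_type <- function(species = NULL, ..., name = NULL) {
  overrides <- list(...)
  bad <- setdiff(names(overrides), trait_names())
  if (length(bad) > 0 || (length(overrides) > 0 && is.null(names(overrides)))) {
    rlang::abort(paste0("unknown trait(s): ", paste(bad, collapse = ", ")),
                 class = "larvforage_validation_error")
  }
  if (!is.null(species)) {
    tab <- builtin_types()
    row <- tab[tab$species == species, ]
    if (nrow(row) != 1) {
      rlang::abort(paste0("unknown larval type '", species, "'"),
                   class = "larvforage_validation_error")
    }
    traits <- as.list(row[trait_names()])
  } else {
    missing <- setdiff(trait_names(), names(overrides))
    if (length(missing) > 0) {
      rlang::abort(paste0("missing trait(s): ", paste(missing, collapse = ", ")),
                   class = "larvforage_validation_error")
    }
    traits <- stats::setNames(vector("list", 16), trait_names())
  }
  traits[names(overrides)] <- overrides
  traits <- lapply(traits, as.numeric)
  out <- structure(c(list(name = name %||% species %||% "custom"), traits),
                   class = "larval_type")
  validate_larval_type(out)
  out
}

#' @keywords internal
validate_larval_type <- function(lt) {
  chk <- function(ok, field, msg) {
    if (!isTRUE(ok)) {
      rlang::abort(paste0("invalid larval type: field '", field, "' ", msg),
                   class = "larvforage_validation_error")
    }
  }
  num <- lt[trait_names()]
  for (nm in trait_names()) {
    chk(is.numeric(num[[nm]]) && length(num[[nm]]) == 1 && is.finite(num[[nm]]),
        nm, "must be a finite number")
  }
  positive <- setdiff(trait_names(), c("x_tol", "y_turb"))
  for (nm in positive) chk(num[[nm]] > 0, nm, "must be strictly positive")
  chk(num$y_eff <= 1, "y_eff", "must be <= 1")
  chk(num$y_act >= 1, "y_act", "must be >= 1")
  chk(num$x_rQ10 > 1, "x_rQ10", "must be > 1")
  chk(num$y_dQ10 > 1, "y_dQ10", "must be > 1")
  chk(num$y_turb >= 0, "y_turb", "must be non-negative")
  # at least one prey bin must be ingestible (smallest modeled prey is 0.04 mm)
  chk(num$x_ing * num$x_len > 0.04, "x_ing",
      "times x_len must exceed 0.04 mm (no ingestible prey bin)")
  invisible(lt)
}

#' @export
print.larval_type <- function(x, ...) {
  cat("<larval_type> ", x$name, "\n", sep = "")
  tr <- unlist(x[trait_names()])
  print(tr)
  invisible(x)
}

#' @export
format.larval_type <- function(x, ...) paste0("<larval_type: ", x$name, ">")

#' Coerce a larval type to a one-row tibble
#' @param x A `larval_type`.
#' @param ... Unused.
#' @export
as_tibble.larval_type <- function(x, ...) {
  tibble::as_tibble(c(list(species = x$name), x[trait_names()]))
}
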