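#' Prey length to dry mass
#'
#' Power-law length--mass relationship for the modeled plankton (protists and
#' copepods, 0.04--2 mm): `m = a * l^b` with `a = prey_mass_coeff` (ug at
#' 1 mm) and `b = prey_mass_exp`.
#'
#' @param l Prey length(s), mm (strictly positive).
#' @param cfg A [model_config()].
#' @return Dry mass, ug.
#' @export
#' @examples
#' length_to_mass(1.0) # 2.5 ug with defaults
length_to_mass <- function(l, cfg = model_config()) {
  if (any(!is.finite(l)) || any(l <= 0)) {
    rlang::abort("prey length must be positive", class = "larvforage_domain_error")
  }
  cfg$prey_mass_coeff * l^cfg$prey_mass_exp
}

# per-bin integral of m^s over [m_lo, m_hi]; analytic, s = -1 is the log case
spectrum_weights <- function(m_lo, m_hi, s) {
  if (abs(s + 1) < 1e-12) log(m_hi / m_lo)
  else (m_hi^(s + 1) - m_lo^(s + 1)) / (s + 1)
}

new_prey_field <- function(tbl, b_total_ug, s = NA_real_) {
  out <- tibble::new_tibble(tbl, class = "prey_field",
                            b_total = b_total_ug, s = s)
  out
}

#' Build a binned prey field from a normalized biomass size spectrum
#'
#' Distributes a total plankton dry biomass over the prey length bins
#' according to a normalized biomass size spectrum of slope `s`: the biomass
#' density per unit body mass is proportional to `m^s`, so bin `i` receives
#' biomass proportional to the analytic integral of `m^s` between the bin
#' edge masses. The result is normalized so the bin biomasses sum exactly to
#' `b_total` (converted to ug mm^-3; 1 mg m^-3 = 1e-6 ug mm^-3).
#'
#' @param b_total Total prey dry biomass, mg m^-3 (non-negative).
#' @param s Spectrum slope (s = -1 is the log-uniform case, handled
#'   analytically).
#' @param cfg A [model_config()].
#' @return A `prey_field` tibble with one row per bin: `l_lo`, `l_hi`, `l`
#'   (bin centre, mm), `m_lo`, `m_hi`, `m` (ug), `b` (ug mm^-3) and `c`
#'   (mm^-3), plus attributes `b_total` (ug mm^-3) and `s`.
#' @export
#' @examples
#' pf <- build_spectrum(15, -1.2)
#' sum(pf$b) * 1e6 # back to mg m^-3
build_spectrum <- function(b_total, s, cfg = model_config()) {
  if (!is.numeric(b_total) || b_total < 0) {
    rlang::abort("b_total must be >= 0", class = "larvforage_domain_error")
  }
  edges <- cfg$bin_edges
  l_lo <- utils::head(edges, -1)
  l_hi <- utils::tail(edges, -1)
  l <- (l_lo + l_hi) / 2
  m_lo <- length_to_mass(l_lo, cfg)
  m_hi <- length_to_mass(l_hi, cfg)
  m <- length_to_mass(l, cfg)
  b_tot_ug <- b_total * 1e-6 # mg m^-3 -> ug mm^-3
  w <- spectrum_weights(m_lo, m_hi, s)
  b <- if (b_tot_ug > 0) b_tot_ug * w / sum(w) else rep(0, length(w))
  new_prey_field(
    tibble::tibble(l_lo = l_lo, l_hi = l_hi, l = l,
                   m_lo = m_lo, m_hi = m_hi, m = m,
                   b = b, c = b / m),
    b_total_ug = b_tot_ug, s = s)
}

#' Build a prey field from explicit per-bin biomasses
#'
#' Bypasses the size-spectrum idealization: supply the biomass in each prey
#' length bin directly.
#'
#' @param l_bins Bin centre lengths, mm. Must match the bin centres implied
#'   by `cfg$bin_edges`, or be a subset of them (other bins get zero
#'   biomass).
#' @param biomasses Per-bin dry biomass, mg m^-3 (non-negative, same length
#'   as `l_bins`).
#' @param cfg A [model_config()].
#' @return A `prey_field` tibble (see [build_spectrum()]); the slope
#'   attribute is `NA`.
#' @export
explicit_field <- function(l_bins, biomasses, cfg = model_config()) {
  if (length(l_bins) != length(biomasses)) {
    rlang::abort("l_bins and biomasses must have the same length",
                 class = "larvforage_validation_error")
  }
  if (any(biomasses < 0)) {
    rlang::abort("biomasses must be non-negative",
                 class = "larvforage_validation_error")
  }
  base <- build_spectrum(0, s = -1.2, cfg = cfg)
  idx <- match(round(l_bins, 10), round(base$l, 10))
  if (anyNA(idx)) {
    rlang::abort(paste0("l_bins not aligned with configured bin centres: ",
                        paste(l_bins[is.na(idx)], collapse = ", ")),
                 class = "larvforage_validation_error")
  }
  b <- rep(0, nrow(base))
  b[idx] <- biomasses * 1e-6 # mg m^-3 -> ug mm^-3
  base$b <- b
  base$c <- b / base$m
  new_prey_field(base, b_total_ug = sum(b), s = NA_real_)
}

#' Write / read a prey field as CSV
#'
#' Round-trip safe plain-text export. The header row carries the field-level
#' scalars (`b_total` in ug mm^-3 and the slope `s`) as commented key-value
#' lines.
#'
#' @param field A `prey_field`.
#' @param path File path.
#' @return `write_prey_field()` returns `path` invisibly;
#'   `read_prey_field()` returns a `prey_field`.
#' @export
write_prey_field <- function(field, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# b_total=%.17g", attr(field, "b_total")), con)
  writeLines(sprintf("# s=%.17g", attr(field, "s")), con)
  utils::write.csv(as.data.frame(field), con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_prey_field
#' @export
read_prey_field <- function(path) {
  hdr <- readLines(path, n = 2)
  b_total <- as.numeric(sub("# b_total=", "", hdr[1], fixed = TRUE))
  s <- as.numeric(sub("# s=", "", hdr[2], fixed = TRUE))
  tbl <- utils::read.csv(path, comment.char = "#")
  new_prey_field(tibble::as_tibble(tbl), b_total_ug = b_total, s = s)
}

#' @export
print.prey_field <- function(x, ...) {
  cat("<prey_field> ", nrow(x), " bins, b_total = ",
      format(attr(x, "b_total") * 1e6), " mg/m^3, s = ",
      format(attr(x, "s")), "\n", sep = "")
  NextMethod()
}
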