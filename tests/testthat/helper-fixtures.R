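# Shared fixtures: reference conditions for the four built-in types
# (temperature degC, photoperiod h; turbulence 1e-7 W/kg, slope -1.2).
reference_conditions <- function() {
  tibble::tibble(
    species = c("anchovy", "cod", "herring", "sprat"),
    temperature = c(15.0, 5.1, 14.7, 8.9),
    photoperiod = c(15.9, 11.8, 11.6, 16.0))
}

reference_env <- function(species, b_total = 15) {
  rc <- reference_conditions()
  row <- rc[rc$species == species, ]
  foraging_env(row$temperature, row$photoperiod, epsilon = 1e-7,
               b_total = b_total, s = -1.2)
}

# zero-turbulence, low-prey environment used for pure foraging geometry
geometry_env <- function() foraging_env(10, 12, epsilon = 0, b_total = 1)

# Brute-force oracle for the optimal-diet Holling disk rate: exhaustive
# maximum over all subsets of candidate bins. Independent of the greedy
# implementation.
brute_force_diet_rate <- function(E, e, y_hand) {
  cand <- which(E > 0)
  best <- 0
  n <- length(cand)
  if (n == 0) return(0)
  for (mask in seq_len(2^n) - 1) {
    idx <- cand[bitwAnd(mask, 2^(seq_len(n) - 1)) > 0]
    if (length(idx) == 0) next
    rate <- sum(E[idx] * e[idx]) / (1 + y_hand * sum(E[idx]))
    if (rate > best) best <- rate
  }
  best
}

# Independent sunrise-equation oracle for photoperiod (same approximation,
# written from the textbook formula rather than the package code path).
sunrise_daylength <- function(lat_deg, doy) {
  decl <- 23.44 * pi / 180 * sin(2 * pi * (284 + doy) / 365)
  x <- -tan(lat_deg * pi / 180) * tan(decl)
  x <- min(1, max(-1, x))
  24 / pi * acos(x)
}
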