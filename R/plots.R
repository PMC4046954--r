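#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a prey field
#'
#' Biomass and numeric concentration across prey length on log-log axes.
#'
#' @param object A `prey_field`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.prey_field <- function(object, ...) {
  df <- dplyr::bind_rows(
    tibble::tibble(l = object$l, value = object$b * 1e6,
                   what = "biomass (mg m⁻³ per bin)"),
    tibble::tibble(l = object$l, value = object$c * 1e9,
                   what = "numbers (m⁻³ per bin)"))
  df <- dplyr::filter(df, .data$value > 0)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$l, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(ggplot2::vars(.data$what), scales = "free_y") +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "prey length (mm)", y = NULL,
                  title = sprintf("prey field: b_total = %.3g mg m⁻³, s = %.2f",
                                  attr(object, "b_total") * 1e6,
                                  attr(object, "s")))
}

#' Plot a foraging breakdown
#'
#' Expected ingested mass per encounter across prey length, with the
#' diet-included bins highlighted when present.
#'
#' @param object A `foraging_breakdown` from [encounter_rates()] or
#'   [foraging_capacity()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.foraging_breakdown <- function(object, ...) {
  df <- tibble::as_tibble(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$l, y = .data$e)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "prey length (mm)",
                  y = "expected ingested mass per encounter (µg)")
  if ("in_diet" %in% names(df)) {
    p <- p + ggplot2::geom_point(
      data = dplyr::filter(df, .data$in_diet),
      ggplot2::aes(x = .data$l, y = .data$e), size = 0.6)
  }
  p
}

#' Plot a day simulation
#'
#' Hourly dry-mass trajectory with lit hours shaded.
#'
#' @param object A `day_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.day_result <- function(object, ...) {
  tr <- object$trace
  lit <- dplyr::filter(tr, .data$lambda > 0)
  ggplot2::ggplot(tr, ggplot2::aes(x = .data$hour, y = .data$M)) +
    ggplot2::geom_rect(data = lit,
                       ggplot2::aes(xmin = .data$hour - 1, xmax = .data$hour,
                                    ymin = -Inf, ymax = Inf),
                       inherit.aes = FALSE, alpha = 0.15, fill = "gold") +
    ggplot2::geom_step() +
    ggplot2::labs(x = "hour", y = "dry mass (µg)",
                  title = sprintf("%s: G = %.3f d⁻¹",
                                  object$larva, object$G))
}

#' Plot starvation/satiation versus turbulence
#'
#' @param tab A tibble from [turbulence_response()].
#' @return A ggplot (log-log).
#' @export
plot_turbulence_response <- function(tab) {
  df <- tidyr_longer(tab)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$epsilon, y = .data$value,
                                   linetype = .data$point)) +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "dissipation rate ε (W kg⁻¹)",
                  y = "prey biomass (mg m⁻³)", linetype = NULL)
}

# minimal long-format helper (avoids a tidyr dependency for one call)
tidyr_longer <- function(tab) {
  dplyr::bind_rows(
    tibble::tibble(epsilon = tab$epsilon, value = tab$starvation,
                   point = "starvation"),
    tibble::tibble(epsilon = tab$epsilon, value = tab$satiation,
                   point = "satiation"))
}
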