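#' Plot a fragment-size histogram
#'
#' Trace-style line plot of the size histogram, with the fetal zone shaded
#' when given.
#'
#' @param object A [size_histogram()].
#' @param zone Optional length-2 window (bp) to shade.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.size_histogram <- function(object, zone = NULL, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$bin_mid, y = .data$count)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "fragment length (bp)", y = "fragments") +
    ggplot2::theme_minimal()
  if (!is.null(zone)) {
    p <- p + ggplot2::annotate("rect", xmin = zone[1], xmax = zone[2],
                               ymin = -Inf, ymax = Inf, alpha = 0.15,
                               fill = "steelblue")
  }
  p
}

#' Plot a limit-of-detection table
#'
#' Detection rate per fetal-fraction bin, the classic LoD bar chart.
#'
#' @param object An `lod_table` from [run_lod_experiment()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.lod_table <- function(object, ...) {
  dat <- dplyr::mutate(tibble::as_tibble(object),
                       bin = factor(.data$bin, levels = .data$bin))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$bin, y = .data$detection_rate_pct)) +
    ggplot2::geom_col(fill = "grey30") +
    ggplot2::geom_hline(yintercept = 100, linetype = "dashed") +
    ggplot2::labs(x = "fetal fraction bin", y = "detection rate (%)") +
    ggplot2::theme_minimal()
}

#' Plot a weight-FF regression fit
#'
#' Scatter of FF (%) against maternal weight with the fitted line and the
#' 5% FF reference level.
#'
#' @param object An `ff_weight_fit` from [weight_ff_regression()].
#' @param target_ff Reference FF level to draw (fraction, default 0.05).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ff_weight_fit <- function(object, target_ff = 0.05, ...) {
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$weight, y = .data$ff_pct)) +
    ggplot2::geom_point(alpha = 0.3, size = 0.8) +
    ggplot2::geom_abline(intercept = object$intercept_pct,
                         slope = object$slope_pct_per_kg, colour = "firebrick") +
    ggplot2::geom_hline(yintercept = 100 * target_ff, linetype = "dashed") +
    ggplot2::labs(x = "maternal weight (kg)", y = "fetal fraction (%)",
                  title = paste("stratum", object$stratum)) +
    ggplot2::theme_minimal()
}

#' Plot the gestational-age trend of fetal fraction
#'
#' @param trend A [ga_trend()] table.
#' @return A ggplot (mean FF % per bin with SD bars).
#' @export
plot_ga_trend <- function(trend) {
  dat <- dplyr::filter(trend, .data$n > 0) |>
    dplyr::mutate(mid = ifelse(is.finite(.data$ga_hi),
                               (.data$ga_lo + .data$ga_hi) / 2, .data$ga_lo + 1))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$mid, y = 100 * .data$mean_ff)) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = 100 * (.data$mean_ff - .data$sd_ff),
                                        ymax = 100 * (.data$mean_ff + .data$sd_ff)),
                           width = 0.2, colour = "grey60") +
    ggplot2::geom_point() +
    ggplot2::geom_line() +
    ggplot2::labs(x = "gestational age (weeks)", y = "fetal fraction (%)") +
    ggplot2::theme_minimal()
}
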