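# broom-style accessors and ggplot2 autoplot methods for the result types

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a phase-amplitude profile
#'
#' @param x A `pac_profile` from [phase_amp_distribution()] or
#'   [pac_for_trial()].
#' @param ... Unused.
#' @return `tidy()`: the per-bin tibble (`bin`, `bin_center`, `mean_amp`,
#'   `p`); `glance()`: a one-row tibble with `mi`, `preferred_phase`,
#'   `n_bins`.
#' @export
tidy.pac_profile <- function(x, ...) {
  tibble::tibble(bin = x$bin, bin_center = x$bin_center,
                 mean_amp = x$mean_amp, p = x$p)
}

#' @rdname tidy.pac_profile
#' @export
glance.pac_profile <- function(x, ...) {
  tibble::tibble(
    mi = attr(x, "mi"),
    preferred_phase = attr(x, "preferred_phase"),
    n_bins = attr(x, "n_bins")
  )
}

#' Tidy detected SWR events
#'
#' @param x An `swr_events` tibble.
#' @param ... Unused.
#' @return `tidy()`: the event tibble stripped of attributes; `glance()`: a
#'   one-row tibble with the event count and feature means.
#' @export
tidy.swr_events <- function(x, ...) {
  tibble::as_tibble(unclass(x)[c("start_s", "end_s", "duration_ms",
                                 "peak_z", "integral_z", "peak_time_s")])
}

#' @rdname tidy.swr_events
#' @export
glance.swr_events <- function(x, ...) {
  tibble::tibble(
    n_events = nrow(x),
    mean_peak_z = if (nrow(x)) mean(x$peak_z) else NA_real_,
    mean_duration_ms = if (nrow(x)) mean(x$duration_ms) else NA_real_,
    mean_integral = if (nrow(x)) mean(x$integral_z) else NA_real_
  )
}

#' Plot a phase-amplitude profile
#'
#' Mean gamma amplitude per theta-phase bin, with the Modulation Index in the
#' subtitle.
#'
#' @param object A `pac_profile`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.pac_profile <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = .data$bin_center, y = .data$mean_amp)) +
    ggplot2::geom_col(width = 2 * pi / attr(object, "n_bins") * 0.9,
                      fill = "steelblue") +
    ggplot2::scale_x_continuous(
      breaks = c(-pi, -pi / 2, 0, pi / 2, pi),
      labels = c(expression(-pi), expression(-pi / 2), "0",
                 expression(pi / 2), expression(pi))) +
    ggplot2::labs(
      x = "theta phase (rad)", y = "mean gamma amplitude",
      subtitle = sprintf("Modulation Index = %.4g", attr(object, "mi"))) +
    ggplot2::theme_minimal()
}

#' Plot an LFP trace with detected events highlighted
#'
#' @param object An `lfp_tbl` (or z-scored envelope tibble with a `z` column).
#' @param events Optional `swr_events` to shade.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.lfp_tbl <- function(object, events = NULL, ...) {
  ycol <- if ("voltage" %in% names(object)) "voltage" else "z"
  p <- ggplot2::ggplot(tibble::as_tibble(object),
                       ggplot2::aes(x = .data$time_s, y = .data[[ycol]])) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "time (s)", y = ycol) +
    ggplot2::theme_minimal()
  if (!is.null(events) && nrow(events) > 0) {
    p <- p + ggplot2::geom_rect(
      data = tidy(events), inherit.aes = FALSE,
      ggplot2::aes(xmin = .data$start_s, xmax = .data$end_s,
                   ymin = -Inf, ymax = Inf),
      fill = "firebrick", alpha = 0.2)
  }
  p
}

#' @importFrom rlang .data
NULL
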