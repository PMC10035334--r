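#' Plot a recording with detected events
#'
#' Trace of the EEG with shaded event intervals, optionally faceted by event
#' source. Long recordings should be windowed with `xlim` first.
#'
#' @param rec An [eeg_recording()].
#' @param events A `spindle_events` tibble (optional).
#' @param xlim Time window in seconds (length-2), or `NULL` for everything.
#' @return A ggplot object.
#' @export
plot_recording <- function(rec, events = NULL, xlim = NULL) {
  stopifnot(inherits(rec, "eeg_recording"))
  df <- tibble::tibble(time_s = rec_times(rec), uv = rec$samples)
  if (!is.null(xlim)) {
    df <- dplyr::filter(df, .data$time_s >= xlim[1], .data$time_s <= xlim[2])
  }
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$time_s, y = .data$uv)) +
    ggplot2::geom_line(linewidth = 0.25) +
    ggplot2::labs(x = "time (s)", y = "amplitude (µV)",
                  title = sprintf("%s / %s", rec$subject_id, rec$channel)) +
    ggplot2::theme_minimal()
  if (!is.null(events) && nrow(events) > 0L) {
    ev <- events
    if (!is.null(xlim)) {
      ev <- dplyr::filter(ev, .data$offset_s >= xlim[1],
                          .data$onset_s <= xlim[2])
    }
    if (nrow(ev) > 0L) {
      p <- p + ggplot2::geom_rect(
        data = ev,
        ggplot2::aes(xmin = .data$onset_s, xmax = .data$offset_s,
                     ymin = -Inf, ymax = Inf, fill = .data$source),
        alpha = 0.2, inherit.aes = FALSE
      )
    }
  }
  p
}

#' Plot method for detection results
#'
#' Per-source event raster: one row per detector output, one segment per
#' event, making coincidences and fusion decisions visible at a glance.
#'
#' @param object A `spindle_detection`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot spindle_detection
#' @export
autoplot.spindle_detection <- function(object, ...) {
  ev <- object$events
  ggplot2::ggplot(ev) +
    ggplot2::geom_segment(
      ggplot2::aes(x = .data$onset_s, xend = .data$offset_s,
                   y = .data$source, yend = .data$source,
                   colour = .data$source),
      linewidth = 4
    ) +
    ggplot2::labs(x = "time (s)", y = NULL) +
    ggplot2::guides(colour = "none") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot method for cohort reports
#'
#' Per-algorithm DS-average counts as grouped bars (A-, R- and E-spindle).
#'
#' @param object A `spindle_cohort_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot spindle_cohort_report
#' @export
autoplot.spindle_cohort_report <- function(object, ...) {
  long <- object$summary |>
    dplyr::select("algorithm", "a_spindle", "r_spindle", "e_spindle") |>
    tidyr::pivot_longer(-"algorithm", names_to = "count",
                        values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$algorithm, y = .data$value,
                                     fill = .data$count)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "DS-average spindle count") +
    ggplot2::theme_minimal()
}
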