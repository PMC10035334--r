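#' Windowed RMS of a recording
#'
#' Tiles the recording into consecutive non-overlapping windows aligned to
#' t = 0 and computes the root mean square `sqrt(mean(x^2))` in each, the
#' amplitude measure the RMS detector thresholds. The input is expected to
#' already be band-passed to the sigma band (11-16 Hz). A trailing partial
#' window is dropped.
#'
#' @param rec An [eeg_recording()].
#' @param window_s Window length in seconds (default 0.25).
#' @return A tibble of class `rms_series` with columns `window_start_s`,
#'   `rms_uv`, and attributes `window_s` and `fs`.
#' @export
#' @examples
#' rec <- eeg_recording(rep(2, 512), fs = 512)
#' window_rms(rec, 0.25)  # every window has RMS 2
window_rms <- function(rec, window_s = 0.25) {
  stopifnot(inherits(rec, "eeg_recording"))
  w <- round(window_s * rec$fs)
  if (w < 1L) stop("window_s * fs must be >= 1", call. = FALSE)
  n_win <- length(rec$samples) %/% w
  if (n_win < 1L) {
    stop("recording shorter than one RMS window", call. = FALSE)
  }
  x <- rec$samples[seq_len(n_win * w)]
  m <- matrix(x^2, nrow = w)
  vals <- sqrt(colMeans(m))
  out <- tibble::tibble(
    window_start_s = (seq_len(n_win) - 1L) * w / rec$fs,
    rms_uv = vals
  )
  attr(out, "window_s") <- w / rec$fs
  attr(out, "fs") <- rec$fs
  class(out) <- unique(c("rms_series", class(out)))
  out
}

#' Per-window RMS detection threshold
#'
#' In the default global mode the threshold is `factor` times the mean of all
#' window RMS values, identical for every window. In epoch mode the windows
#' are grouped into `epoch_s` blocks and the threshold is recomputed per
#' block.
#'
#' @param series An `rms_series` from [window_rms()].
#' @param factor Threshold multiplier (default 0.95).
#' @param epoch_s Epoch length in seconds (used in epoch mode; default 5).
#' @param epoch_mode Recompute per epoch instead of globally.
#' @return Numeric vector of thresholds, one per window.
#' @export
rms_threshold <- function(series, factor = 0.95, epoch_s = 5,
                          epoch_mode = FALSE) {
  stopifnot(inherits(series, "rms_series"))
  if (factor <= 0) stop("factor must be positive", call. = FALSE)
  if (!epoch_mode) {
    return(rep(factor * mean(series$rms_uv), nrow(series)))
  }
  block <- floor(series$window_start_s / epoch_s)
  means <- tapply(series$rms_uv, block, mean)
  as.numeric(factor * means[as.character(block)])
}

#' Detect spindle events from a thresholded RMS series
#'
#' Maximal runs of at least `consecutive` windows whose RMS strictly exceeds
#' the per-window threshold become events spanning the first window's start
#' to the last window's end; events must last between `min_dur_s` and
#' `max_dur_s` inclusive. Event boundaries are therefore multiples of the
#' RMS window length.
#'
#' @param series An `rms_series`.
#' @param thresholds Per-window threshold vector from [rms_threshold()].
#' @param consecutive Minimum run length in windows (default 2).
#' @param min_dur_s,max_dur_s Duration gate in seconds.
#' @param subject_id,channel Labels for the resulting events.
#' @return A `spindle_events` tibble with `source = "rms"`.
#' @export
detect_rms_events <- function(series, thresholds, consecutive = 2,
                              min_dur_s = 0.5, max_dur_s = 3.0,
                              subject_id = "S1", channel = "C3") {
  stopifnot(inherits(series, "rms_series"),
            length(thresholds) == nrow(series))
  if (consecutive < 1) stop("consecutive must be >= 1", call. = FALSE)
  win_s <- attr(series, "window_s")
  runs <- supra_runs(series$rms_uv > thresholds)
  if (nrow(runs) > 0L) runs <- runs[(runs$end - runs$start + 1L) >= consecutive, ]
  if (nrow(runs) == 0L) {
    return(spindle_events(source = "rms", subject_id = subject_id,
                          channel = channel))
  }
  onset <- series$window_start_s[runs$start]
  offset <- series$window_start_s[runs$end] + win_s
  dur <- offset - onset
  keep <- dur >= min_dur_s - 1e-9 & dur <= max_dur_s + 1e-9
  spindle_events(onset[keep], offset[keep], source = "rms",
                 subject_id = subject_id, channel = channel)
}

#' Run the full windowed-RMS detector
#'
#' Band-passes the recording to the sigma band with the doubled-order
#' linear-phase FIR, computes 0.25 s window RMS values, thresholds them at
#' `rms_threshold_factor` times the mean (globally, or per epoch when
#' `rms_epoch_mode` is set) and extracts runs of at least `rms_consecutive`
#' supra-threshold windows lasting 0.5-3 s.
#'
#' @param rec An [eeg_recording()] at the analysis rate.
#' @param config A [detection_config()].
#' @return A `spindle_events` tibble with `source = "rms"`.
#' @export
detect_rms <- function(rec, config = detection_config()) {
  filt <- bandpass(rec, config$spindle_band)
  series <- window_rms(filt, config$rms_win_s)
  thr <- rms_threshold(series, config$rms_threshold_factor,
                       config$rms_epoch_s, config$rms_epoch_mode)
  detect_rms_events(series, thr, config$rms_consecutive,
                    config$min_dur_s, config$max_dur_s,
                    subject_id = rec$subject_id, channel = rec$channel)
}
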