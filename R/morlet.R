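#' Complex Morlet wavelet kernel
#'
#' Samples the complex Morlet wavelet
#' `f(x) = (pi * FB)^(-1/2) * exp(2i * pi * FC * x) * exp(-x^2 / FB)`
#' on a symmetric time grid, where `FC` is the centre frequency, `n` the
#' number of cycles, `s = n / (2 * pi * FC)` the Gaussian width in seconds
#' and `FB = 2 * s^2` the bandwidth parameter. Support is truncated at
#' `+/- 4 s`, where the Gaussian tail is below 1e-6 of the peak.
#'
#' @param fc Centre frequency in Hz (`0 < fc < fs/2`).
#' @param n_cycles Cycle count n (default 7, the usual time-frequency
#'   compromise).
#' @param fs Sampling rate in Hz.
#' @return A list of class `morlet_kernel` with elements `fc`, `n_cycles`,
#'   `s`, `fb`, `x` (time grid, seconds) and `taps` (complex samples).
#' @export
#' @examples
#' k <- morlet_kernel(13.5, 7, 512)
#' k$fb  # 2 * (7 / (2 * pi * 13.5))^2
morlet_kernel <- function(fc, n_cycles = 7, fs = 512) {
  if (fc <= 0 || n_cycles < 1) {
    stop("fc must be positive and n_cycles >= 1", call. = FALSE)
  }
  if (fc >= fs / 2) {
    stop("centre frequency ", fc, " Hz is at or above Nyquist (", fs / 2,
         " Hz)", call. = FALSE)
  }
  s <- n_cycles / (2 * pi * fc)
  fb <- 2 * s^2
  half <- ceiling(4 * s * fs)
  x <- (-half:half) / fs
  taps <- (pi * fb)^(-0.5) * exp(2i * pi * fc * x) * exp(-x^2 / fb)
  structure(list(fc = fc, n_cycles = n_cycles, s = s, fb = fb, x = x,
                 taps = taps),
            class = "morlet_kernel")
}

#' Wavelet amplitude envelope
#'
#' Convolves the recording with a complex Morlet kernel at each centre
#' frequency of `fc_grid` (delay-compensated, same length as the input,
#' reflect-padded edges) and takes the magnitude; the returned envelope is
#' the pointwise maximum across the grid, scaled by `1/fs` so its units track
#' the input amplitude. The input is expected to already carry the wide
#' (5-35 Hz) pre-filter of the wavelet path.
#'
#' @param rec An [eeg_recording()].
#' @param fc_grid Centre frequencies in Hz (non-empty).
#' @param n_cycles Morlet cycle count.
#' @return A list of class `envelope` with `values` (non-negative, same
#'   length as the recording) and `fs`.
#' @export
wavelet_envelope <- function(rec, fc_grid, n_cycles = 7) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (length(fc_grid) == 0L) {
    stop("fc_grid must contain at least one centre frequency", call. = FALSE)
  }
  env <- numeric(length(rec$samples))
  for (fc in fc_grid) {
    k <- morlet_kernel(fc, n_cycles, rec$fs)
    mag <- Mod(fir_zero_phase_complex(rec$samples, k$taps)) / rec$fs
    env <- pmax(env, mag)
  }
  structure(list(values = env, fs = rec$fs), class = "envelope")
}

# Same-length delay-compensated convolution with a complex symmetric-support
# kernel; reflect-padded edges, as fir_zero_phase but keeping the complex
# result.
fir_zero_phase_complex <- function(x, h) {
  half <- (length(h) - 1L) %/% 2L
  xp <- reflect_pad(x, half)
  y <- conv_full(xp, h)
  y[(2L * half + 1L):(2L * half + length(x))]
}

#' Smooth an envelope with a centred moving average
#'
#' The window is `round(win_s * fs)` samples forced odd; edge samples are
#' averaged over the part of the window that exists.
#'
#' @param env An `envelope` (from [wavelet_envelope()]).
#' @param win_s Window length in seconds.
#' @return The smoothed `envelope`.
#' @export
smooth_envelope <- function(env, win_s) {
  stopifnot(inherits(env, "envelope"))
  if (win_s <= 0) stop("win_s must be positive", call. = FALSE)
  w <- round(win_s * env$fs)
  if (w %% 2 == 0) w <- w + 1L
  n <- length(env$values)
  if (w > n) stop("smoothing window (", w, " samples) exceeds signal length (",
                  n, ")", call. = FALSE)
  if (w == 1L) return(env)
  half <- (w - 1L) %/% 2L
  cs <- c(0, cumsum(env$values))
  i <- seq_len(n)
  lo <- pmax(i - half, 1L)
  hi <- pmin(i + half, n)
  env$values <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  env
}

#' Threshold an envelope into candidate spindle events
#'
#' The threshold is `factor` times the mean of the envelope over the whole
#' analysed segment; maximal runs of samples strictly above it become
#' candidate intervals, and candidates whose duration lies in
#' `[min_dur_s, max_dur_s]` are kept.
#'
#' @param env An `envelope`.
#' @param factor Threshold multiplier (default 4.5).
#' @param min_dur_s,max_dur_s Duration gate in seconds.
#' @param subject_id,channel Labels for the resulting events.
#' @return A `spindle_events` tibble with `source = "morlet"`.
#' @export
threshold_events <- function(env, factor = 4.5, min_dur_s = 0.5,
                             max_dur_s = 3.0, subject_id = "S1",
                             channel = "C3") {
  stopifnot(inherits(env, "envelope"))
  if (length(env$values) == 0L) stop("empty envelope", call. = FALSE)
  thr <- factor * mean(env$values)
  runs <- supra_runs(env$values > thr)
  if (nrow(runs) == 0L) {
    return(spindle_events(source = "morlet", subject_id = subject_id,
                          channel = channel))
  }
  onset <- (runs$start - 1L) / env$fs
  offset <- runs$end / env$fs
  dur <- offset - onset
  keep <- dur >= min_dur_s & dur <= max_dur_s
  spindle_events(onset[keep], offset[keep], source = "morlet",
                 subject_id = subject_id, channel = channel)
}

# Maximal runs of TRUE in a logical vector -> tibble(start, end) inclusive.
supra_runs <- function(flag) {
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  tibble::tibble(start = starts[keep], end = ends[keep])
}

#' Merge nearby events
#'
#' Scans left to right and merges consecutive events whose gap is below
#' `gap_s`, provided the merged duration stays strictly below `max_dur_s`;
#' repeats until stable. This is the detector's rule that two spindles less
#' than a second apart whose combined span is still under three seconds are
#' one spindle.
#'
#' @param ev A sorted, non-overlapping `spindle_events` tibble.
#' @param gap_s Maximum gap (exclusive) for merging, in seconds.
#' @param max_dur_s Maximum merged duration (exclusive), in seconds.
#' @return The merged `spindle_events` tibble.
#' @export
merge_events <- function(ev, gap_s = 1.0, max_dur_s = 3.0) {
  ev <- validate_events(ev)
  if (nrow(ev) < 2L) return(ev)
  repeat {
    merged_any <- FALSE
    onset <- ev$onset_s; offset <- ev$offset_s
    amp <- ev$peak_amp_uv
    out_on <- onset[1]; out_off <- offset[1]; out_amp <- amp[1]
    res <- list()
    for (i in seq_along(onset)[-1]) {
      gap <- onset[i] - out_off
      if (gap < gap_s && (offset[i] - out_on) < max_dur_s) {
        out_off <- max(out_off, offset[i])
        out_amp <- max(out_amp, amp[i], na.rm = FALSE)
        merged_any <- TRUE
      } else {
        res[[length(res) + 1L]] <- c(out_on, out_off, out_amp)
        out_on <- onset[i]; out_off <- offset[i]; out_amp <- amp[i]
      }
    }
    res[[length(res) + 1L]] <- c(out_on, out_off, out_amp)
    m <- do.call(rbind, res)
    ev <- spindle_events(m[, 1], m[, 2], source = ev$source[1],
                         peak_amp_uv = m[, 3],
                         subject_id = ev$subject_id[1],
                         channel = ev$channel[1])
    if (!merged_any) break
  }
  ev
}

#' Run the full Morlet wavelet detector
#'
#' Band-passes the recording with the wide pre-filter, computes the smoothed
#' multi-frequency wavelet envelope, applies the mean-relative threshold and
#' duration gate, and merges nearby events.
#'
#' @param rec An [eeg_recording()] at the analysis rate.
#' @param config A [detection_config()].
#' @return A `spindle_events` tibble with `source = "morlet"`.
#' @export
detect_morlet <- function(rec, config = detection_config()) {
  pre <- bandpass(rec, config$preproc_band)
  env <- wavelet_envelope(pre, config$morlet_fc_grid, config$morlet_n_cycles)
  env <- smooth_envelope(env, config$morlet_smooth_win_s)
  ev <- threshold_events(env, config$morlet_threshold_factor,
                         config$min_dur_s, config$max_dur_s,
                         subject_id = rec$subject_id, channel = rec$channel)
  merge_events(ev, config$merge_gap_s, config$max_dur_s)
}
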