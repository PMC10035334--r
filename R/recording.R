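#' Construct an EEG recording
#'
#' A recording is a single channel of EEG voltages sampled at a fixed rate,
#' with subject and 10/20-system channel metadata. All amplitudes are in
#' microvolts; times are seconds from the start of the recording.
#'
#' @param samples Numeric vector of voltages in microvolts. Must be finite and
#'   non-empty.
#' @param fs Sampling rate in Hz (positive scalar).
#' @param subject_id Subject identifier.
#' @param channel 10/20-system channel label, e.g. `"C3"`.
#' @param t0 Time of the first sample in seconds (default 0).
#'
#' @return An object of class `eeg_recording`: a list with elements `samples`,
#'   `fs`, `subject_id`, `channel` and `t0`.
#' @export
#' @examples
#' rec <- eeg_recording(sin(2 * pi * 13 * seq(0, 1, by = 1 / 512)), fs = 512)
#' rec_duration(rec)
eeg_recording <- function(samples, fs, subject_id = "S1", channel = "C3", t0 = 0) {
  samples <- as.numeric(samples)
  if (length(samples) < 1L) {
    stop("recording must contain at least one sample", call. = FALSE)
  }
  if (!all(is.finite(samples))) {
    stop("all recording samples must be finite", call. = FALSE)
  }
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0) {
    stop("`fs` must be a positive finite scalar", call. = FALSE)
  }
  structure(
    list(
      samples = samples,
      fs = as.numeric(fs),
      subject_id = as.character(subject_id),
      channel = as.character(channel),
      t0 = as.numeric(t0)
    ),
    class = "eeg_recording"
  )
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf(
    "<eeg_recording> subject %s, channel %s: %d samples @ %g Hz (%.2f s)\n",
    x$subject_id, x$channel, length(x$samples), x$fs, rec_duration(x)
  ))
  invisible(x)
}

#' Duration of a recording in seconds
#'
#' @param rec An [eeg_recording()].
#' @return Length of the recording in seconds (`n / fs`).
#' @export
rec_duration <- function(rec) {
  stopifnot(inherits(rec, "eeg_recording"))
  length(rec$samples) / rec$fs
}

#' Sample times of a recording
#'
#' @param rec An [eeg_recording()].
#' @return Numeric vector of sample times in seconds (starting at `t0`).
#' @export
rec_times <- function(rec) {
  rec$t0 + (seq_along(rec$samples) - 1) / rec$fs
}

#' Read a single-channel recording from disk
#'
#' Reads either an EDF/EDF+ file (extension `.edf`, case-insensitive) or a
#' two-column delimited text file of `time_s, value_uv` rows. EDF physical
#' units are converted to microvolts on read (mV and V channels are rescaled;
#' channels already in uV pass through). For text input the sampling rate is
#' inferred from the median spacing of the time column, which must be uniform.
#'
#' @param path Path to an `.edf` file or delimited text file.
#' @param channel Channel label to extract (default `"C3"`). Ignored for text
#'   files, where it only labels the result.
#' @param subject_id Subject label stored on the result; for EDF files the
#'   default is taken from the header's patient field.
#'
#' @return An [eeg_recording()].
#' @export
read_recording <- function(path, channel = "C3", subject_id = NULL) {
  if (!file.exists(path)) {
    stop("recording file not found: ", path, call. = FALSE)
  }
  if (grepl("\\.edf$", path, ignore.case = TRUE)) {
    return(read_edf_channel(path, channel, subject_id))
  }
  tab <- utils::read.table(path, header = FALSE, sep = "", comment.char = "#",
                           col.names = c("time_s", "value_uv"))
  if (nrow(tab) < 2L) {
    stop("text recording needs at least two rows", call. = FALSE)
  }
  dt <- diff(tab$time_s)
  if (any(dt <= 0) || (max(dt) - min(dt)) > 1e-6 * stats::median(dt) + 1e-12) {
    stop("text recording time column must be uniformly increasing", call. = FALSE)
  }
  fs <- 1 / stats::median(dt)
  # snap to an integer rate when within float noise of one
  if (abs(fs - round(fs)) < 1e-6) fs <- round(fs)
  eeg_recording(tab$value_uv, fs = fs,
                subject_id = subject_id %||% "S1",
                channel = channel, t0 = tab$time_s[1])
}

#' Write a recording as two-column text
#'
#' Inverse of the text branch of [read_recording()]: writes `time_s value_uv`
#' rows, whitespace-separated, no header.
#'
#' @param rec An [eeg_recording()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"))
  utils::write.table(
    data.frame(time_s = rec_times(rec), value_uv = rec$samples),
    path, row.names = FALSE, col.names = FALSE, quote = FALSE
  )
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
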