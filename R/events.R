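#' Spindle event tables
#'
#' Detected and annotated spindles are plain tibbles with one row per event
#' and columns `subject_id`, `channel`, `source`, `onset_s`, `offset_s`,
#' `peak_amp_uv`. Intervals are half-open `[onset, offset)` in seconds from
#' the start of the recording; `peak_amp_uv` is the event's peak amplitude in
#' microvolts and may be `NA` before feature extraction. `source` records
#' where the events came from: one of `"morlet"`, `"rms"`, `"coincident"`,
#' `"fusion"`, `"expert1"`, `"expert2"`, `"expert3"`, `"consensus"`, `"truth"`.
#'
#' @param onset_s,offset_s Event boundaries in seconds (`offset_s > onset_s`,
#'   `onset_s >= 0`).
#' @param source Event source tag (recycled).
#' @param peak_amp_uv Peak amplitude in microvolts, or `NA`.
#' @param subject_id,channel Metadata labels (recycled).
#'
#' @return A tibble of class `spindle_events`, sorted by onset.
#' @export
#' @examples
#' spindle_events(c(10, 40), c(11.2, 41), source = "expert1")
spindle_events <- function(onset_s = numeric(), offset_s = numeric(),
                           source = "truth", peak_amp_uv = NA_real_,
                           subject_id = "S1", channel = "C3") {
  ev <- tibble::tibble(
    subject_id = as.character(subject_id),
    channel = as.character(channel),
    source = as.character(source),
    onset_s = as.numeric(onset_s),
    offset_s = as.numeric(offset_s),
    peak_amp_uv = as.numeric(peak_amp_uv)
  )
  validate_events(ev)
}

#' @rdname spindle_events
#' @export
event_sources <- function() {
  c("morlet", "rms", "coincident", "fusion",
    "expert1", "expert2", "expert3", "consensus", "truth")
}

#' Validate and sort a spindle event table
#'
#' Checks the `spindle_events` contract (columns, `offset > onset`,
#' non-negative onsets, known source tags) and returns the table sorted by
#' onset. Errors name the first offending row.
#'
#' @param ev A data frame with the six event columns.
#' @return The validated tibble with class `spindle_events`.
#' @export
validate_events <- function(ev) {
  needed <- c("subject_id", "channel", "source", "onset_s", "offset_s",
              "peak_amp_uv")
  missing_cols <- setdiff(needed, names(ev))
  if (length(missing_cols) > 0L) {
    stop("event table is missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  ev <- tibble::as_tibble(ev)[needed]
  bad_src <- setdiff(unique(ev$source), event_sources())
  if (length(bad_src) > 0L) {
    stop("unknown event source(s): ", paste(bad_src, collapse = ", "),
         call. = FALSE)
  }
  bad <- which(!(ev$offset_s > ev$onset_s))
  if (length(bad) > 0L) {
    stop("event row ", bad[1], ": offset_s (", ev$offset_s[bad[1]],
         ") must exceed onset_s (", ev$onset_s[bad[1]], ")", call. = FALSE)
  }
  bad <- which(ev$onset_s < 0)
  if (length(bad) > 0L) {
    stop("event row ", bad[1], ": onset_s must be >= 0", call. = FALSE)
  }
  ev <- dplyr::arrange(ev, .data$onset_s, .data$offset_s)
  class(ev) <- unique(c("spindle_events", class(ev)))
  ev
}

#' Event durations
#'
#' @param ev A `spindle_events` tibble.
#' @return Numeric vector `offset_s - onset_s`.
#' @export
event_durations <- function(ev) ev$offset_s - ev$onset_s

#' Read spindle events from CSV
#'
#' The on-disk format is UTF-8 CSV with header columns `subject_id, channel,
#' source, onset_s, offset_s, peak_amp_uv`; an empty `peak_amp_uv` field reads
#' back as `NA`. Rows are sorted by onset on read.
#'
#' @param path CSV file path.
#' @return A `spindle_events` tibble.
#' @export
read_events <- function(path) {
  ev <- readr::read_csv(
    path,
    col_types = readr::cols(
      subject_id = readr::col_character(),
      channel = readr::col_character(),
      source = readr::col_character(),
      onset_s = readr::col_double(),
      offset_s = readr::col_double(),
      peak_amp_uv = readr::col_double()
    ),
    progress = FALSE
  )
  validate_events(ev)
}

#' Write spindle events to CSV
#'
#' Round-trips exactly through [read_events()]: times are written with full
#' double precision and absent amplitudes as empty fields.
#'
#' @param ev A `spindle_events` tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_events <- function(ev, path) {
  ev <- validate_events(ev)
  readr::write_csv(ev, path, na = "", progress = FALSE)
  invisible(path)
}

# Internal: merge overlapping (or touching, when gap <= tol) intervals into
# their unions. Returns tibble with onset_s/offset_s plus count merged.
union_intervals <- function(onset, offset, tol = 0) {
  if (length(onset) == 0L) {
    return(tibble::tibble(onset_s = numeric(), offset_s = numeric(),
                          n_merged = integer()))
  }
  o <- order(onset, offset)
  onset <- onset[o]; offset <- offset[o]
  out_on <- onset[1]; out_off <- offset[1]; out_n <- 1L
  res_on <- numeric(); res_off <- numeric(); res_n <- integer()
  for (i in seq_along(onset)[-1]) {
    if (onset[i] <= out_off + tol) {
      out_off <- max(out_off, offset[i])
      out_n <- out_n + 1L
    } else {
      res_on <- c(res_on, out_on); res_off <- c(res_off, out_off)
      res_n <- c(res_n, out_n)
      out_on <- onset[i]; out_off <- offset[i]; out_n <- 1L
    }
  }
  tibble::tibble(onset_s = c(res_on, out_on), offset_s = c(res_off, out_off),
                 n_merged = c(res_n, out_n))
}

# Internal: total length of the intersection between one interval [a, b) and
# a set of intervals.
overlap_length <- function(a, b, onset, offset) {
  if (length(onset) == 0L) return(0)
  sum(pmax(0, pmin(b, offset) - pmax(a, onset)))
}
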