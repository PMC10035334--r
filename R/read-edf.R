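# Minimal EDF/EDF+ reader: fixed-layout ASCII header, 16-bit little-endian
# sample records, physical scaling per channel. Covers the subset needed to
# pull one EEG channel out of a polysomnography export; annotation channels
# ("EDF Annotations") are ignored.

read_edf_header <- function(con) {
  ascii <- function(n) {
    raw <- readBin(con, "raw", n = n)
    trimws(rawToChar(raw))
  }
  version <- ascii(8L)
  patient <- ascii(80L)
  recording <- ascii(80L)
  ascii(8L)  # start date
  ascii(8L)  # start time
  header_bytes <- suppressWarnings(as.integer(ascii(8L)))
  ascii(44L) # reserved ("EDF+C"/"EDF+D" for EDF+)
  n_records <- suppressWarnings(as.integer(ascii(8L)))
  record_dur <- suppressWarnings(as.numeric(ascii(8L)))
  ns <- suppressWarnings(as.integer(ascii(4L)))
  if (is.na(ns) || ns < 1L || is.na(n_records) || is.na(record_dur) ||
      is.na(header_bytes)) {
    stop("unreadable EDF header", call. = FALSE)
  }
  field <- function(width) vapply(seq_len(ns), function(i) ascii(width), "")
  labels <- field(16L)
  field(80L)  # transducer
  phys_dim <- field(8L)
  phys_min <- as.numeric(field(8L))
  phys_max <- as.numeric(field(8L))
  dig_min <- as.numeric(field(8L))
  dig_max <- as.numeric(field(8L))
  field(80L)  # prefiltering
  samples_per_record <- as.integer(field(8L))
  field(32L)  # reserved
  list(
    version = version, patient = patient, recording = recording,
    header_bytes = header_bytes, n_records = n_records,
    record_dur = record_dur, ns = ns, labels = labels, phys_dim = phys_dim,
    phys_min = phys_min, phys_max = phys_max, dig_min = dig_min,
    dig_max = dig_max, samples_per_record = samples_per_record
  )
}

# Physical-unit multiplier to microvolts.
edf_unit_to_uv <- function(dim) {
  d <- tolower(trimws(dim))
  if (d %in% c("uv", "µv", "microvolt", "microvolts", "")) return(1)
  if (d == "mv") return(1e3)
  if (d == "v") return(1e6)
  warning("unknown EDF physical dimension '", dim, "'; assuming microvolts")
  1
}

read_edf_channel <- function(path, channel, subject_id = NULL) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- tryCatch(read_edf_header(con), error = function(e) {
    stop("unreadable EDF header in ", path, call. = FALSE)
  })
  # EDF labels look like "EEG C3-M2" or plain "C3": match on the bare token
  tokens <- lapply(strsplit(hdr$labels, "[ -]+"), toupper)
  idx <- which(vapply(seq_len(hdr$ns), function(i) {
    toupper(hdr$labels[i]) == toupper(channel) || toupper(channel) %in% tokens[[i]]
  }, logical(1)))
  if (length(idx) == 0L) {
    stop("channel '", channel, "' not found; file has: ",
         paste(hdr$labels, collapse = ", "), call. = FALSE)
  }
  idx <- idx[1]
  spr <- hdr$samples_per_record
  gain <- (hdr$phys_max[idx] - hdr$phys_min[idx]) /
    (hdr$dig_max[idx] - hdr$dig_min[idx])
  offset <- hdr$phys_max[idx] - gain * hdr$dig_max[idx]
  to_uv <- edf_unit_to_uv(hdr$phys_dim[idx])

  seek(con, hdr$header_bytes)
  per_record <- sum(spr)
  out <- vector("list", hdr$n_records)
  before <- if (idx > 1L) sum(spr[seq_len(idx - 1L)]) else 0L
  for (r in seq_len(hdr$n_records)) {
    rec <- readBin(con, "integer", n = per_record, size = 2L,
                   signed = TRUE, endian = "little")
    if (length(rec) < per_record) {
      stop("EDF data truncated at record ", r, call. = FALSE)
    }
    out[[r]] <- rec[(before + 1L):(before + spr[idx])]
  }
  digital <- unlist(out, use.names = FALSE)
  physical <- (digital * gain + offset) * to_uv
  fs <- spr[idx] / hdr$record_dur
  eeg_recording(physical, fs = fs,
                subject_id = subject_id %||%
                  (if (nzchar(hdr$patient)) strsplit(hdr$patient, " ")[[1]][1] else "S1"),
                channel = channel)
}
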