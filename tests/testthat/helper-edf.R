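# Test-only EDF writer: builds a minimal valid EDF file in code so the
# reader can be exercised without shipping binary fixtures.
write_test_edf <- function(path, channels, fs, record_dur = 1,
                           phys_range = c(-200, 200), unit = "uV",
                           patient = "S1") {
  ns <- length(channels)
  n <- length(channels[[1]])
  stopifnot(all(vapply(channels, length, 1L) == n))
  spr <- fs * record_dur
  n_records <- n %/% spr
  stopifnot(n_records >= 1)
  dig_range <- c(-32768, 32767)
  pad <- function(x, w) formatC(as.character(x), width = w, flag = "-")
  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(s, w) writeBin(charToRaw(pad(s, w)), con)
  wr("0", 8); wr(patient, 80); wr("test recording", 80)
  wr("01.01.24", 8); wr("00.00.00", 8)
  wr(256 + ns * 256, 8); wr("", 44); wr(n_records, 8)
  wr(format(record_dur), 8); wr(ns, 4)
  for (nm in names(channels)) wr(nm, 16)
  for (i in 1:ns) wr("test", 80)
  for (i in 1:ns) wr(unit, 8)
  for (i in 1:ns) wr(format(phys_range[1]), 8)
  for (i in 1:ns) wr(format(phys_range[2]), 8)
  for (i in 1:ns) wr(dig_range[1], 8)
  for (i in 1:ns) wr(dig_range[2], 8)
  for (i in 1:ns) wr("none", 80)
  for (i in 1:ns) wr(spr, 8)
  for (i in 1:ns) wr("", 32)
  gain <- (phys_range[2] - phys_range[1]) / (dig_range[2] - dig_range[1])
  offset <- phys_range[2] - gain * dig_range[2]
  for (r in seq_len(n_records)) {
    idx <- ((r - 1) * spr + 1):(r * spr)
    for (nm in names(channels)) {
      dig <- round((channels[[nm]][idx] - offset) / gain)
      dig <- pmin(pmax(dig, dig_range[1]), dig_range[2])
      writeBin(as.integer(dig), con, size = 2, endian = "little")
    }
  }
  invisible(path)
}
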