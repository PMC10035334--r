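#' Simulation specification
#'
#' Parameters of the synthetic single-channel EEG generator: a 1/f-shaped
#' Gaussian background plus Hann-windowed sigma-band sinusoidal bursts with
#' known onsets, offsets and amplitudes, and three simulated "experts" who
#' annotate the truth with misses, boundary jitter and false alarms.
#'
#' Defaults define the package's standard study conditions: 512 Hz, ten
#' minutes per subject, 20 spindles per subject (about two per minute, a
#' typical stage-2 density), 11-16 Hz bursts of 0.5-3 s and 10-60 uV peak
#' amplitude over a 2 uV-RMS background — so the weakest burst is five times
#' the background RMS — with a 1/f power spectrum.
#'
#' @param fs Sampling rate in Hz.
#' @param duration_s Recording length in seconds.
#' @param n_spindles Number of injected bursts.
#' @param freq_range_hz Burst frequency range (uniform draw), Hz.
#' @param dur_range_s Burst duration range (uniform draw), seconds.
#' @param amp_range_uv Burst peak-amplitude range (uniform draw), uV.
#' @param background_rms_uv Broadband RMS of the background, uV.
#' @param one_over_f_exponent Power-spectral-density exponent beta in
#'   `S(f) ~ 1/f^beta` (0 = white).
#' @param min_gap_s Minimum gap between consecutive bursts, seconds.
#' @param expert_jitter_sd_s SD of the Gaussian boundary jitter per expert.
#' @param expert_miss_rate Per-event probability an expert misses it.
#' @param expert_false_rate Expert false annotations per minute (Poisson).
#' @param seed Integer RNG seed.
#' @return A list of class `sim_spec`.
#' @export
sim_spec <- function(fs = 512, duration_s = 600, n_spindles = 20,
                     freq_range_hz = c(11, 16), dur_range_s = c(0.5, 3),
                     amp_range_uv = c(10, 60), background_rms_uv = 2,
                     one_over_f_exponent = 1, min_gap_s = 2,
                     expert_jitter_sd_s = 0.1, expert_miss_rate = 0.05,
                     expert_false_rate = 0.5, seed = 1) {
  spec <- list(
    fs = fs, duration_s = duration_s, n_spindles = n_spindles,
    freq_range_hz = freq_range_hz, dur_range_s = dur_range_s,
    amp_range_uv = amp_range_uv, background_rms_uv = background_rms_uv,
    one_over_f_exponent = one_over_f_exponent, min_gap_s = min_gap_s,
    expert_jitter_sd_s = expert_jitter_sd_s,
    expert_miss_rate = expert_miss_rate,
    expert_false_rate = expert_false_rate, seed = as.integer(seed)
  )
  rng_ok <- function(r) all(r >= 0 & r <= 1)
  if (spec$n_spindles * (max(dur_range_s) + min_gap_s) > duration_s) {
    stop("infeasible spec: n_spindles * (max duration + min gap) exceeds ",
         "duration_s", call. = FALSE)
  }
  if (!rng_ok(expert_miss_rate)) {
    stop("expert_miss_rate must be in [0, 1]", call. = FALSE)
  }
  stopifnot(freq_range_hz[1] < freq_range_hz[2],
            dur_range_s[1] < dur_range_s[2],
            amp_range_uv[1] < amp_range_uv[2])
  class(spec) <- "sim_spec"
  spec
}

with_seed <- function(seed, code) {
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(seed)
  force(code)
}

#' Generate 1/f background EEG
#'
#' White Gaussian noise is spectrally shaped in the frequency domain so its
#' power spectral density falls as `1/f^beta` (frequencies below 0.5 Hz are
#' flattened to keep the variance finite) and rescaled so the sample RMS
#' equals `background_rms_uv`. Deterministic for a given `spec$seed`.
#'
#' @param spec A [sim_spec()].
#' @param subject_id,channel Labels for the recording.
#' @return An [eeg_recording()].
#' @export
make_background <- function(spec, subject_id = "S1", channel = "C3") {
  stopifnot(inherits(spec, "sim_spec"))
  n <- round(spec$duration_s * spec$fs)
  with_seed(spec$seed, {
    w <- stats::rnorm(n)
    beta <- spec$one_over_f_exponent
    if (beta != 0) {
      W <- stats::fft(w)
      freqs <- spec$fs * (0:(n - 1)) / n
      freqs <- pmin(freqs, spec$fs - freqs)  # two-sided
      f_eff <- pmax(freqs, 0.5)
      shape <- f_eff^(-beta / 2)
      shape[1] <- 0  # remove DC
      w <- Re(stats::fft(W * shape, inverse = TRUE)) / n
    }
    w <- w - mean(w)
    w <- w * spec$background_rms_uv / sqrt(mean(w^2))
    eeg_recording(w, fs = spec$fs, subject_id = subject_id, channel = channel)
  })
}

#' Inject spindle bursts with known ground truth
#'
#' Adds `n_spindles` Hann-windowed sinusoidal bursts to a recording, with
#' frequency, duration and peak amplitude drawn uniformly from the spec's
#' ranges, placed without overlap and with at least `min_gap_s` between
#' bursts. Ground-truth onsets and offsets are the full support of the Hann
#' envelope.
#'
#' @param rec An [eeg_recording()] (typically from [make_background()]).
#' @param spec A [sim_spec()].
#' @param seed Seed for the burst draws (default `spec$seed + 1`).
#' @return A list with `recording` (bursts added) and `truth` (a
#'   `spindle_events` tibble, `source = "truth"`, `peak_amp_uv` = injected
#'   amplitude).
#' @export
inject_spindles <- function(rec, spec, seed = spec$seed + 1L) {
  stopifnot(inherits(rec, "eeg_recording"), inherits(spec, "sim_spec"))
  n_sp <- spec$n_spindles
  total <- rec_duration(rec)
  with_seed(seed, {
    durs <- stats::runif(n_sp, spec$dur_range_s[1], spec$dur_range_s[2])
    slack <- total - sum(durs) - (n_sp + 1) * spec$min_gap_s
    if (slack < 0) {
      stop("cannot place ", n_sp, " bursts of total ", round(sum(durs), 1),
           " s with gaps in ", total, " s", call. = FALSE)
    }
    # distribute the slack over the n_sp + 1 gaps via sorted uniforms
    cuts <- sort(stats::runif(n_sp))
    gap_extra <- diff(c(0, cuts, 1)) * slack
    onsets <- numeric(n_sp)
    t <- 0
    for (i in seq_len(n_sp)) {
      t <- t + spec$min_gap_s + gap_extra[i]
      onsets[i] <- t
      t <- t + durs[i]
    }
    freqs <- stats::runif(n_sp, spec$freq_range_hz[1], spec$freq_range_hz[2])
    amps <- stats::runif(n_sp, spec$amp_range_uv[1], spec$amp_range_uv[2])
    phases <- stats::runif(n_sp, 0, 2 * pi)
    x <- rec$samples
    for (i in seq_len(n_sp)) {
      i0 <- floor(onsets[i] * rec$fs) + 1L
      i1 <- min(length(x), ceiling((onsets[i] + durs[i]) * rec$fs))
      tt <- ((i0:i1) - 1) / rec$fs - onsets[i]
      hann <- 0.5 * (1 - cos(2 * pi * tt / durs[i]))
      x[i0:i1] <- x[i0:i1] +
        amps[i] * hann * sin(2 * pi * freqs[i] * tt + phases[i])
    }
    truth <- spindle_events(onsets, onsets + durs, source = "truth",
                            peak_amp_uv = amps, subject_id = rec$subject_id,
                            channel = rec$channel)
    attr(truth, "freq_hz") <- freqs[order(onsets)]
    list(
      recording = eeg_recording(x, fs = rec$fs, subject_id = rec$subject_id,
                                channel = rec$channel, t0 = rec$t0),
      truth = truth
    )
  })
}

#' Simulate noisy expert annotation sets
#'
#' Each of the three experts independently drops truth events with
#' probability `expert_miss_rate`, jitters both boundaries by
#' `Normal(0, expert_jitter_sd_s)` (keeping a minimum 0.2 s duration), and
#' adds Poisson false annotations at `expert_false_rate` per minute with
#' 0.5-1.5 s durations. Deterministic for a given seed.
#'
#' @param truth The ground-truth `spindle_events` tibble.
#' @param spec A [sim_spec()].
#' @param duration_s Recording duration (for placing false annotations).
#' @param seed Base seed (default `spec$seed + 2`); expert e uses `seed + e`.
#' @return A list of three `spindle_events` tibbles with sources
#'   `expert1`..`expert3`.
#' @export
make_expert_sets <- function(truth, spec, duration_s = spec$duration_s,
                             seed = spec$seed + 2L) {
  truth <- validate_events(truth)
  sid <- c(truth$subject_id, "S1")[1]
  ch <- c(truth$channel, "C3")[1]
  lapply(1:3, function(e) {
    with_seed(seed + e, {
      keep <- stats::runif(nrow(truth)) >= spec$expert_miss_rate
      ev <- truth[keep, , drop = FALSE]
      n <- nrow(ev)
      if (n > 0L && spec$expert_jitter_sd_s > 0) {
        on <- pmax(0, ev$onset_s + stats::rnorm(n, 0, spec$expert_jitter_sd_s))
        off <- ev$offset_s + stats::rnorm(n, 0, spec$expert_jitter_sd_s)
        off <- pmax(off, on + 0.2)
        ev$onset_s <- on
        ev$offset_s <- pmin(off, duration_s)
      }
      n_false <- stats::rpois(1, spec$expert_false_rate * duration_s / 60)
      if (n_false > 0L) {
        f_on <- stats::runif(n_false, 0, duration_s - 1.5)
        f_dur <- stats::runif(n_false, 0.5, 1.5)
        ev <- dplyr::bind_rows(
          ev,
          tibble::tibble(
            subject_id = sid, channel = ch,
            source = "truth", onset_s = f_on, offset_s = f_on + f_dur,
            peak_amp_uv = NA_real_
          )
        )
      }
      ev$source <- paste0("expert", e)
      validate_events(ev)
    })
  })
}

#' Simulate one subject end to end
#'
#' Background plus injected bursts plus three expert annotation sets, all
#' derived deterministically from `spec$seed`.
#'
#' @param spec A [sim_spec()].
#' @param subject_id,channel Labels.
#' @return A list with `recording`, `truth` and `experts` (list of three).
#' @export
simulate_subject <- function(spec, subject_id = "S1", channel = "C3") {
  bg <- make_background(spec, subject_id, channel)
  inj <- inject_spindles(bg, spec)
  experts <- make_expert_sets(inj$truth, spec)
  list(recording = inj$recording, truth = inj$truth, experts = experts)
}

#' Write a multi-subject synthetic cohort to disk
#'
#' One subdirectory per subject containing `recording.txt` (two-column
#' `time_s value_uv`), `truth.csv`, `expert1.csv`..`expert3.csv`, plus a
#' top-level `manifest.json` echoing the spec. Subject s uses seed
#' `spec$seed + 1000 * s`, so cohorts are reproducible from
#' `(seed, n_subjects)` and subjects are independent.
#'
#' @param n_subjects Number of subjects.
#' @param spec A [sim_spec()].
#' @param dir Output directory.
#' @param overwrite Allow writing into an existing non-empty directory.
#' @param write_recordings If `FALSE`, skip the (large) recording files and
#'   write only events and the manifest.
#' @return The manifest as a list, invisibly.
#' @export
make_cohort <- function(n_subjects, spec, dir, overwrite = FALSE,
                        write_recordings = TRUE) {
  stopifnot(inherits(spec, "sim_spec"), n_subjects >= 1)
  if (dir.exists(dir) && length(list.files(dir)) > 0L && !overwrite) {
    stop("directory ", dir, " exists and is not empty; set overwrite = TRUE",
         call. = FALSE)
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  subjects <- sprintf("S%02d", seq_len(n_subjects))
  for (s in seq_len(n_subjects)) {
    sub_spec <- spec
    sub_spec$seed <- spec$seed + 1000L * s
    sim <- simulate_subject(sub_spec, subject_id = subjects[s])
    sdir <- file.path(dir, subjects[s])
    dir.create(sdir, showWarnings = FALSE)
    if (write_recordings) {
      write_recording(sim$recording, file.path(sdir, "recording.txt"))
    }
    write_events(sim$truth, file.path(sdir, "truth.csv"))
    for (e in 1:3) {
      write_events(sim$experts[[e]], file.path(sdir,
                                               paste0("expert", e, ".csv")))
    }
  }
  manifest <- list(
    n_subjects = n_subjects,
    subjects = subjects,
    spec = unclass(spec),
    files = c(if (write_recordings) "recording.txt", "truth.csv",
              "expert1.csv", "expert2.csv", "expert3.csv")
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' The package's standard synthetic study conditions
#'
#' Twenty subjects of ten minutes each under the default [sim_spec()]
#' parameters; used by the end-to-end evaluation of the fusion detector.
#'
#' @param seed Cohort base seed.
#' @return A [sim_spec()].
#' @export
standard_cohort_spec <- function(seed = 1) {
  sim_spec(seed = seed)
}
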