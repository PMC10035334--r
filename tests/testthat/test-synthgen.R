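test_that("background noise hits its target RMS and is reproducible", {
  spec <- sim_spec(duration_s = 30, n_spindles = 3, background_rms_uv = 10,
                   seed = 12)
  bg <- make_background(spec)
  rms <- sqrt(mean(bg$samples^2))
  expect_gt(rms, 9); expect_lt(rms, 11)
  bg2 <- make_background(spec)
  expect_identical(bg$samples, bg2$samples)
})

test_that("spectral exponent zero gives a flat spectrum", {
  spec <- sim_spec(duration_s = 60, n_spindles = 3, one_over_f_exponent = 0,
                   seed = 13)
  bg <- make_background(spec)
  p <- stats::spec.pgram(bg$samples, plot = FALSE, taper = 0)
  f_hz <- p$freq * spec$fs
  keep <- f_hz > 1 & f_hz < 200
  beta <- -stats::coef(stats::lm(log(p$spec[keep]) ~ log(f_hz[keep])))[2]
  expect_lt(abs(beta), 0.2)
})

test_that("the default background has a falling 1/f spectrum", {
  spec <- sim_spec(duration_s = 60, n_spindles = 3, seed = 14)
  bg <- make_background(spec)
  p <- stats::spec.pgram(bg$samples, plot = FALSE, taper = 0)
  f_hz <- p$freq * spec$fs
  keep <- f_hz > 1 & f_hz < 200
  beta <- -stats::coef(stats::lm(log(p$spec[keep]) ~ log(f_hz[keep])))[2]
  expect_gt(beta, 0.7); expect_lt(beta, 1.3)
})

test_that("injected spindles honour the spec ranges and spacing", {
  spec <- sim_spec(duration_s = 300, n_spindles = 20, seed = 15)
  sim <- simulate_subject(spec)
  truth <- sim$truth
  expect_equal(nrow(truth), 20)
  durs <- event_durations(truth)
  expect_true(all(durs >= 0.5 & durs <= 3))
  expect_true(all(truth$peak_amp_uv >= 10 & truth$peak_amp_uv <= 60))
  gaps <- truth$onset_s[-1] - truth$offset_s[-nrow(truth)]
  expect_true(all(gaps >= spec$min_gap_s - 1e-9))

  # dominant frequency of each injected segment lies in the sigma band
  for (i in seq_len(nrow(truth))) {
    i0 <- floor(truth$onset_s[i] * spec$fs) + 1
    i1 <- ceiling(truth$offset_s[i] * spec$fs)
    seg <- sim$recording$samples[i0:i1]
    p <- stats::spec.pgram(seg, plot = FALSE, taper = 0)
    fmax <- p$freq[which.max(p$spec)] * spec$fs
    expect_gte(fmax, spec$freq_range_hz[1] - 0.5)
    expect_lte(fmax, spec$freq_range_hz[2] + 0.5)
  }
})

test_that("injected amplitudes are recovered by feature extraction", {
  spec <- sim_spec(duration_s = 300, n_spindles = 15, seed = 16)
  sim <- simulate_subject(spec)
  sigma <- bandpass(sim$recording, c(11, 16))
  ft <- extract_features(sim$truth, sigma)
  rel_err <- abs(ft$peak_amp_uv - sim$truth$peak_amp_uv) /
    sim$truth$peak_amp_uv
  expect_true(all(rel_err < 0.10))
})

test_that("noiseless experts reproduce the truth exactly", {
  spec <- sim_spec(duration_s = 120, n_spindles = 8,
                   expert_jitter_sd_s = 0, expert_miss_rate = 0,
                   expert_false_rate = 0, seed = 17)
  sim <- simulate_subject(spec)
  for (e in 1:3) {
    expect_equal(sim$experts[[e]]$onset_s, sim$truth$onset_s)
    expect_equal(sim$experts[[e]]$offset_s, sim$truth$offset_s)
  }
  # total-miss limit
  spec_miss <- sim_spec(duration_s = 120, n_spindles = 8,
                        expert_miss_rate = 1, expert_false_rate = 0,
                        seed = 18)
  sim_miss <- simulate_subject(spec_miss)
  expect_true(all(vapply(sim_miss$experts, nrow, 1L) == 0))
})

test_that("expert miss rates behave binomially across seeds", {
  kept <- integer()
  for (seed in 1:10) {
    spec <- sim_spec(duration_s = 3000, n_spindles = 100,
                     expert_miss_rate = 0.2, expert_false_rate = 0,
                     expert_jitter_sd_s = 0, seed = seed)
    sim <- simulate_subject(spec)
    kept <- c(kept, vapply(sim$experts, nrow, 1L))
  }
  # mean kept per expert should be near 80 (3 sigma of the binomial is 12)
  expect_gt(mean(kept), 80 - 12)
  expect_lt(mean(kept), 80 + 12)
})

test_that("cohorts are written reproducibly with manifests", {
  spec <- sim_spec(duration_s = 30, n_spindles = 3, seed = 19)
  dir1 <- withr::local_tempdir()
  dir2 <- withr::local_tempdir()
  make_cohort(2, spec, dir1, overwrite = TRUE, write_recordings = FALSE)
  make_cohort(2, spec, dir2, overwrite = TRUE, write_recordings = FALSE)
  expect_setequal(list.files(dir1, recursive = TRUE),
                  list.files(dir2, recursive = TRUE))
  t1 <- readLines(file.path(dir1, "S01", "truth.csv"))
  t2 <- readLines(file.path(dir2, "S01", "truth.csv"))
  expect_identical(t1, t2)
  m <- jsonlite::read_json(file.path(dir1, "manifest.json"))
  expect_equal(m$n_subjects, 2)
  expect_equal(m$spec$seed, 19)
  # refuse to clobber without overwrite
  expect_error(make_cohort(1, spec, dir1), "not empty")
})

test_that("a one-minute subject runs end to end with computable metrics", {
  spec <- sim_spec(duration_s = 60, n_spindles = 4, seed = 20)
  sim <- simulate_subject(spec)
  det <- detect_spindles(sim$recording)
  res <- evaluate_detection(
    dplyr::filter(det$events, source == "fusion"), sim$truth,
    duration_s = 60
  )
  expect_true(is.finite(res$f1))
  expect_gt(res$recall, 0.5)
})
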