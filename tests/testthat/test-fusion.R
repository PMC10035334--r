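test_that("partitioning matches brute-force interval intersection", {
  # worked example: morlet [10, 11.2) and rms [11, 12) overlap -> union
  m <- spindle_events(10, 11.2, source = "morlet")
  r <- spindle_events(11, 12, source = "rms")
  parts <- partition_events(m, r)
  expect_equal(nrow(parts$coincident), 1)
  expect_equal(parts$coincident$onset_s, 10)
  expect_equal(parts$coincident$offset_s, 12)
  expect_equal(nrow(parts$non_coincident), 0)

  # identical lists -> all coincident
  m2 <- random_event_set(10, 100, "morlet", seed = 2)
  r2 <- m2; r2$source <- "rms"
  parts2 <- partition_events(m2, r2)
  expect_equal(nrow(parts2$coincident), nrow(m2))
  expect_equal(nrow(parts2$non_coincident), 0)

  # disjoint lists -> nothing coincident
  m3 <- spindle_events(c(0, 10), c(1, 11), source = "morlet")
  r3 <- spindle_events(c(5, 20), c(6, 21), source = "rms")
  parts3 <- partition_events(m3, r3)
  expect_equal(nrow(parts3$coincident), 0)
  expect_equal(nrow(parts3$non_coincident), 4)

  expect_error(
    partition_events(spindle_events(1, 2, source = "morlet", subject_id = "A"),
                     spindle_events(1, 2, source = "rms", subject_id = "B")),
    "different subjects"
  )
})

test_that("partition conserves events over random sets (property)", {
  for (seed in 1:200) {
    set.seed(seed)
    m <- random_event_set(sample(1:8, 1), 60, "morlet", seed = seed)
    r <- random_event_set(sample(1:8, 1), 60, "rms", seed = seed + 1000)
    parts <- partition_events(m, r)
    # conservation: every input event is in exactly one of the two outputs
    expect_equal(2 * nrow(parts$coincident) + nrow(parts$non_coincident),
                 nrow(m) + nrow(r))
    # no pair left on the table: if brute force finds any overlap between a
    # leftover morlet and leftover rms event, greedy matching failed
    left_m <- parts$non_coincident[parts$non_coincident$source == "morlet", ]
    left_r <- parts$non_coincident[parts$non_coincident$source == "rms", ]
    if (nrow(left_m) > 0 && nrow(left_r) > 0) {
      pairs <- oracle_overlap_pairs(left_m$onset_s, left_m$offset_s,
                                    left_r$onset_s, left_r$offset_s)
      expect_null(pairs)
    }
  }
})

test_that("amplitude features recover injected sinusoid amplitudes", {
  fs <- 512
  t <- seq(0, 10 - 1 / fs, by = 1 / fs)
  x <- numeric(length(t))
  seg1 <- t >= 2 & t < 3.2
  seg2 <- t >= 6 & t < 7.5
  x[seg1] <- 30 * sin(2 * pi * 13 * t[seg1])
  x[seg2] <- 15 * sin(2 * pi * 14 * t[seg2])
  rec <- eeg_recording(x, fs = fs)
  ev <- spindle_events(c(2, 6), c(3.2, 7.5), source = "rms")
  ft <- extract_features(ev, rec)
  expect_equal(ft$peak_amp_uv[1], 30, tolerance = 0.05 * 30)
  expect_equal(ft$peak_amp_uv[2], 15, tolerance = 0.05 * 15)
  expect_lt(ft$peak_amp_uv[2], ft$peak_amp_uv[1])

  zero <- eeg_recording(rep(0, 1000), fs = 512)
  ftz <- extract_features(spindle_events(0.2, 1.2, source = "rms"), zero)
  expect_equal(ftz$peak_amp_uv, 0)

  expect_error(extract_features(spindle_events(999, 1000, source = "rms"), rec),
               "outside")
})

test_that("LOF scores match the direct-definition oracle", {
  x <- c(20, 21, 22, 23, 200)
  got <- lof_scores(x, n_neighbors = 2)
  ref <- oracle_lof(x, 2)
  expect_equal(got, ref, tolerance = 1e-12)
  expect_gt(got[5], 1.5)
  expect_equal(which.max(got), 5)

  # identical points: all scores 1 by convention
  expect_equal(lof_scores(rep(7, 6), 2), rep(1, 6))

  # interior point of an even grid scores near 1
  grid <- seq(0, 10, by = 1)
  g <- lof_scores(grid, 3)
  expect_gt(g[6], 0.8)
  expect_lt(g[6], 1.2)

  # random sets, several k (property)
  for (seed in 1:20) {
    set.seed(seed)
    y <- runif(sample(5:10, 1), 0, 50)
    k <- sample(2:(length(y) - 1), 1)
    expect_equal(lof_scores(y, k), oracle_lof(y, k), tolerance = 1e-10)
  }
})

test_that("outlier removal drops exactly the high-LOF rows", {
  ev <- spindle_events(1:5, (1:5) + 0.8, source = "rms",
                       peak_amp_uv = c(20, 21, 22, 23, 200))
  out <- remove_outliers(ev, n_neighbors = 2, threshold = 1.5)
  expect_equal(sort(out$peak_amp_uv), c(20, 21, 22, 23))

  # nothing above threshold -> unchanged
  ev2 <- spindle_events(1:4, (1:4) + 0.8, source = "rms",
                        peak_amp_uv = c(20, 21, 22, 23))
  expect_equal(nrow(remove_outliers(ev2, 2, 1.5)), 4)

  # tiny sets pass through with a warning
  ev3 <- spindle_events(1:2, (1:2) + 0.5, source = "rms",
                        peak_amp_uv = c(1, 2))
  expect_warning(out3 <- remove_outliers(ev3), "too few")
  expect_equal(nrow(out3), 2)
})

test_that("k-means finds the enumeration optimum on small 1-D instances", {
  x <- c(10, 11, 12, 30, 31, 32, 50, 51, 52, 70, 71, 72, 90, 91, 92)
  fit <- spindle_kmeans(x, k = 5, seed = 1)
  expect_equal(sort(fit$centers[, 1]), c(11, 31, 51, 71, 91))
  expect_equal(fit$sse, 10)  # five groups of (x-1,x,x+1): SSE 2 each

  # SSE trace is non-increasing within the winning run
  expect_true(all(diff(fit$sse_trace) <= 1e-9))

  # k = number of distinct points -> SSE 0
  fit0 <- spindle_kmeans(c(1, 5, 9), 3, seed = 1)
  expect_equal(fit0$sse, 0)

  # agreement with exhaustive optimum on random <= 12-point instances
  for (seed in 1:15) {
    set.seed(seed)
    y <- round(runif(sample(6:12, 1), 0, 100), 1)
    k <- sample(2:4, 1)
    fit_y <- spindle_kmeans(y, k, seed = seed)
    expect_equal(fit_y$sse, oracle_kmeans_1d_sse(y, k), tolerance = 1e-9)
  }

  expect_error(spindle_kmeans(1:3, 4), "exceeds")
})

test_that("scaling the data scales SSE quadratically with identical labels", {
  set.seed(4)
  x <- c(rnorm(10, 10), rnorm(10, 40))
  f1 <- spindle_kmeans(x, 2, seed = 2)
  f2 <- spindle_kmeans(2 * x, 2, seed = 2)
  expect_equal(f2$sse, 4 * f1$sse, tolerance = 1e-9)
  # labels identical up to permutation
  expect_equal(length(unique(paste(f1$labels, f2$labels))), 2)
})

test_that("independent engine agrees with our k-means on the optimum", {
  # stats::kmeans as cross-check, never the implementation
  set.seed(8)
  x <- c(rnorm(20, 10, 1), rnorm(20, 50, 1), rnorm(20, 100, 1))
  ours <- spindle_kmeans(x, 3, seed = 3)
  ref <- stats::kmeans(x, 3, nstart = 10)
  expect_equal(ours$sse, ref$tot.withinss, tolerance = 1e-6)
})

test_that("gap statistic recovers obvious cluster counts", {
  set.seed(1)
  x3 <- c(rnorm(20, 0, 0.5), rnorm(20, 8, 0.5), rnorm(20, 40, 0.5))
  expect_equal(select_k(x3, k_max = 6, seed = 42), 3)
  # independent implementation agrees on this instance
  cg <- cluster::clusGap(
    matrix(x3),
    FUNcluster = function(x, k) {
      list(cluster = stats::kmeans(x, k, nstart = 10)$cluster)
    },
    K.max = 6, B = 20, verbose = FALSE
  )
  expect_equal(
    cluster::maxSE(cg$Tab[, "gap"], cg$Tab[, "SE.sim"],
                   method = "firstSEmax"),
    3
  )
  set.seed(2)
  x1 <- rnorm(30, 10, 0.3)
  expect_equal(select_k(x1, k_max = 5, seed = 42), 1)
})

test_that("extreme-amplitude clusters are pruned, middle ones kept", {
  # five well-separated groups; drop lowest and highest centres
  amps <- c(5, 5.1, 15, 15.1, 25, 25.1, 40, 40.1, 80, 80.1)
  on <- seq(0, by = 2, length.out = 10)
  ev <- spindle_events(on, on + 1, source = "rms", peak_amp_uv = amps)
  fit <- spindle_kmeans(amps, 5, seed = 1)
  kept <- prune_clusters(fit, ev, keep = 3)
  expect_equal(sort(kept$peak_amp_uv), c(15, 15.1, 25, 25.1, 40, 40.1))

  expect_error(prune_clusters(spindle_kmeans(amps, 3, seed = 1), ev, keep = 3),
               "smaller than k")
})

test_that("fusion unions overlapping events and respects trivial identities", {
  coin <- spindle_events(10, 11.5, source = "coincident")
  ret <- spindle_events(11, 12, source = "rms")
  fused <- fuse_events(coin, ret)
  expect_equal(nrow(fused), 1)
  expect_equal(fused$onset_s, 10)
  expect_equal(fused$offset_s, 12)
  expect_equal(fused$source, "fusion")

  # union with empty = coincident set
  empty <- spindle_events(source = "rms")
  f2 <- fuse_events(coin, empty)
  expect_equal(f2$onset_s, coin$onset_s)

  # disjoint 7 + 3 -> 10
  a <- spindle_events(seq(0, 60, by = 10)[1:7], seq(0, 60, by = 10)[1:7] + 1,
                      source = "coincident")
  b <- spindle_events(c(100, 110, 120), c(101, 111, 121), source = "rms")
  expect_equal(nrow(fuse_events(a, b)), 10)
})
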