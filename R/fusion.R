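#' Partition two detectors' events into coincident and non-coincident sets
#'
#' A Morlet event and an RMS event with any non-zero temporal overlap form a
#' coincident pair, represented once by the union of the two intervals
#' (`source = "coincident"`). Pairing is one-to-one: Morlet events are taken
#' in onset order and matched greedily to the unmatched RMS event with the
#' largest overlap. Everything unpaired from either detector keeps its
#' original source tag and goes to the non-coincident set.
#'
#' @param morlet,rms `spindle_events` tibbles from the two detectors, for the
#'   same subject and channel.
#' @return A list with `coincident` and `non_coincident` `spindle_events`.
#' @export
partition_events <- function(morlet, rms) {
  morlet <- validate_events(morlet); rms <- validate_events(rms)
  if (nrow(morlet) > 0L && nrow(rms) > 0L) {
    if (morlet$subject_id[1] != rms$subject_id[1] ||
        morlet$channel[1] != rms$channel[1]) {
      stop("morlet and rms event sets are for different subjects/channels",
           call. = FALSE)
    }
  }
  sid <- c(morlet$subject_id, rms$subject_id, "S1")[1]
  ch <- c(morlet$channel, rms$channel, "C3")[1]
  nm <- nrow(morlet); nr <- nrow(rms)
  rms_taken <- logical(nr)
  pair_of <- rep(NA_integer_, nm)
  for (i in seq_len(nm)) {
    if (nr == 0L) break
    ov <- pmin(morlet$offset_s[i], rms$offset_s) -
      pmax(morlet$onset_s[i], rms$onset_s)
    ov[rms_taken] <- -Inf
    j <- which.max(ov)
    if (length(j) == 1L && ov[j] > 0) {
      pair_of[i] <- j
      rms_taken[j] <- TRUE
    }
  }
  paired <- which(!is.na(pair_of))
  coincident <- spindle_events(
    pmin(morlet$onset_s[paired], rms$onset_s[pair_of[paired]]),
    pmax(morlet$offset_s[paired], rms$offset_s[pair_of[paired]]),
    source = "coincident", subject_id = sid, channel = ch
  )
  non <- dplyr::bind_rows(
    morlet[is.na(pair_of), , drop = FALSE],
    rms[!rms_taken, , drop = FALSE]
  )
  non <- if (nrow(non) > 0L) validate_events(non) else
    spindle_events(subject_id = sid, channel = ch)
  list(coincident = coincident, non_coincident = non)
}

#' Extract the amplitude feature for each event
#'
#' The clustering input of the fusion layer: for each event, half the
#' peak-to-peak excursion of the sigma-band (11-16 Hz) filtered signal within
#' the event interval, i.e. the event's peak amplitude in microvolts. The
#' value is stored back in `peak_amp_uv`.
#'
#' @param ev A `spindle_events` tibble.
#' @param rec The sigma-band-filtered [eeg_recording()] the events refer to.
#' @return `ev` with `peak_amp_uv` filled in.
#' @export
extract_features <- function(ev, rec) {
  ev <- validate_events(ev)
  stopifnot(inherits(rec, "eeg_recording"))
  n <- length(rec$samples)
  if (nrow(ev) == 0L) return(ev)
  if (any(ev$onset_s < rec$t0 - 1e-9) ||
      any(ev$offset_s > rec$t0 + n / rec$fs + 1e-9)) {
    stop("event extends outside the recording", call. = FALSE)
  }
  amp <- vapply(seq_len(nrow(ev)), function(i) {
    i0 <- max(1L, floor((ev$onset_s[i] - rec$t0) * rec$fs) + 1L)
    i1 <- min(n, ceiling((ev$offset_s[i] - rec$t0) * rec$fs))
    seg <- rec$samples[i0:i1]
    (max(seg) - min(seg)) / 2
  }, numeric(1))
  ev$peak_amp_uv <- amp
  ev
}

#' Local outlier factor scores
#'
#' Standard LOF: for each point, the ratio of its neighbours' mean local
#' reachability density to its own. Points inside uniform regions score
#' about 1; isolated points score well above 1. When every pairwise distance
#' in a neighbourhood is zero (duplicated values) the score is defined as 1.
#'
#' @param x Numeric vector or matrix of features (rows = events).
#' @param n_neighbors Neighbourhood size k (`1 <= k < n`).
#' @return Numeric vector of LOF scores.
#' @export
#' @examples
#' lof_scores(c(20, 21, 22, 23, 200), n_neighbors = 2)
lof_scores <- function(x, n_neighbors) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < 2L) stop("LOF needs at least two points", call. = FALSE)
  k <- as.integer(n_neighbors)
  if (k < 1L || k >= n) {
    stop("n_neighbors must be in [1, n - 1]", call. = FALSE)
  }
  d <- as.matrix(stats::dist(x))
  diag(d) <- Inf
  # k-distance and k-neighbourhood (all points within the k-distance,
  # so ties are included, per the standard definition)
  kdist <- numeric(n)
  nbrs <- vector("list", n)
  for (i in seq_len(n)) {
    srt <- sort(d[i, ])
    kdist[i] <- srt[k]
    nbrs[[i]] <- which(d[i, ] <= kdist[i])
  }
  lrd <- numeric(n)
  for (i in seq_len(n)) {
    reach <- pmax(kdist[nbrs[[i]]], d[i, nbrs[[i]]])
    m <- mean(reach)
    lrd[i] <- if (m == 0) Inf else 1 / m
  }
  score <- numeric(n)
  for (i in seq_len(n)) {
    ratio <- lrd[nbrs[[i]]] / lrd[i]
    ratio[is.nan(ratio)] <- 1  # Inf / Inf: co-located duplicates
    score[i] <- mean(ratio)
  }
  score
}

#' Remove LOF outliers from an event table
#'
#' Drops events whose LOF score exceeds `threshold`, preserving order. With
#' fewer than three events (or `n_neighbors >= n`) pruning is skipped with a
#' warning and the table passes through unchanged.
#'
#' @param ev A `spindle_events` tibble with `peak_amp_uv` filled in.
#' @param n_neighbors LOF neighbourhood size; `NULL` means `min(20, n - 1)`.
#' @param threshold LOF score above which an event is dropped (default 1.5).
#' @return The pruned `spindle_events` tibble.
#' @export
remove_outliers <- function(ev, n_neighbors = NULL, threshold = 1.5) {
  ev <- validate_events(ev)
  n <- nrow(ev)
  if (n < 3L) {
    if (n > 0L) warning("too few events for LOF pruning; skipped")
    return(ev)
  }
  k <- n_neighbors %||% min(20L, n - 1L)
  if (k >= n) k <- n - 1L
  scores <- lof_scores(ev$peak_amp_uv, k)
  kept <- ev[scores <= threshold, , drop = FALSE]
  if (nrow(kept) == 0L) {
    stop("LOF pruning removed every event", call. = FALSE)
  }
  validate_events(kept)
}

#' K-means clustering with seeded restarts and an SSE trace
#'
#' Lloyd's algorithm from greedy k-means++ seeded centres, iterated until the
#' assignments are stable; the best of `nstart` restarts by the sum of
#' squared Euclidean distances to own centre (SSE) is returned. For
#' one-dimensional features (the default amplitude clustering) one
#' additional restart is seeded from the exact dynamic-programming optimum
#' over contiguous partitions of the sorted data, so 1-D fits attain the
#' global minimum SSE. The SSE after each Lloyd iteration of the winning
#' restart is recorded so its monotonicity can be audited.
#'
#' @param x Numeric vector or matrix of features (rows = points).
#' @param k Number of clusters (`k <=` number of rows).
#' @param seed Integer seed for the restarts.
#' @param nstart Number of restarts (default 10).
#' @param max_iter Iteration cap per restart.
#' @return An object of class `spindle_kmeans`: list with `labels` (1..k),
#'   `centers`, `sse`, `k` and `sse_trace`.
#' @export
spindle_kmeans <- function(x, k, seed = 1, nstart = 10, max_iter = 100) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (k > n) stop("k (", k, ") exceeds the number of points (", n, ")",
                  call. = FALSE)
  if (k < 1L) stop("k must be >= 1", call. = FALSE)
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(seed)
  best <- NULL
  for (r in seq_len(nstart)) {
    fit <- kmeans_once(x, k, max_iter)
    if (is.null(best) || fit$sse < best$sse) best <- fit
  }
  if (ncol(x) == 1L) {
    fit <- kmeans_once(x, k, max_iter, init_centers = dp_centers_1d(x[, 1], k))
    if (fit$sse < best$sse) best <- fit
  }
  best$k <- k
  class(best) <- "spindle_kmeans"
  best
}

# Exact 1-D k-means centres: O(k n^2) dynamic programme over contiguous
# partitions of the sorted values (optimal 1-D clusters are contiguous).
dp_centers_1d <- function(x, k) {
  xs <- sort(x)
  n <- length(xs)
  cs <- c(0, cumsum(xs))
  cs2 <- c(0, cumsum(xs^2))
  seg_cost <- function(i, j) {
    # SSE of xs[i..j]
    s <- cs[j + 1] - cs[i]
    q <- cs2[j + 1] - cs2[i]
    q - s^2 / (j - i + 1)
  }
  cost <- matrix(Inf, k, n)
  cut <- matrix(0L, k, n)
  for (j in 1:n) cost[1, j] <- seg_cost(1, j)
  if (k > 1) {
    for (g in 2:k) {
      for (j in g:n) {
        for (i in g:j) {
          c_ij <- cost[g - 1, i - 1] + seg_cost(i, j)
          if (c_ij < cost[g, j]) {
            cost[g, j] <- c_ij
            cut[g, j] <- i
          }
        }
      }
    }
  }
  bounds <- integer(k + 1)
  bounds[k + 1] <- n
  if (k > 1) {
    for (g in k:2) bounds[g] <- cut[g, bounds[g + 1]] - 1L
  }
  bounds[1] <- 0L
  centers <- vapply(seq_len(k), function(g) {
    mean(xs[(bounds[g] + 1):bounds[g + 1]])
  }, numeric(1))
  matrix(centers, k, 1)
}

# One Lloyd run from k-means++ seeded centres (or explicit ones).
kmeans_once <- function(x, k, max_iter, init_centers = NULL) {
  n <- nrow(x)
  centers <- init_centers %||% x[kmeanspp_init(x, k), , drop = FALSE]
  labels <- integer(n)
  trace <- numeric()
  for (it in seq_len(max_iter)) {
    d2 <- point_center_dist2(x, centers)
    new_labels <- max.col(-d2, ties.method = "first")
    # recompute centres; re-seed any emptied cluster at the farthest point
    for (j in seq_len(k)) {
      pts <- x[new_labels == j, , drop = FALSE]
      if (nrow(pts) == 0L) {
        far <- which.max(apply(d2, 1, min))
        centers[j, ] <- x[far, ]
        new_labels[far] <- j
      } else {
        centers[j, ] <- colMeans(pts)
      }
    }
    d2 <- point_center_dist2(x, centers)
    sse <- sum(d2[cbind(seq_len(n), new_labels)])
    trace <- c(trace, sse)
    if (identical(new_labels, labels)) break
    labels <- new_labels
  }
  list(labels = labels, centers = centers, sse = sse, sse_trace = trace)
}

# Greedy k-means++: each new centre is chosen among several D^2-sampled
# candidates as the one that most reduces the seeding potential.
kmeanspp_init <- function(x, k) {
  n <- nrow(x)
  idx <- integer(k)
  idx[1] <- sample.int(n, 1L)
  if (k == 1L) return(idx)
  n_cand <- 2L + as.integer(floor(log(k)))
  d2 <- rowSums((x - matrix(x[idx[1], ], n, ncol(x), byrow = TRUE))^2)
  for (j in 2:k) {
    cands <- if (all(d2 == 0)) {
      sample.int(n, n_cand, replace = TRUE)
    } else {
      sample.int(n, n_cand, replace = TRUE, prob = d2)
    }
    best_pot <- Inf
    best_d2 <- d2
    for (c in cands) {
      cand_d2 <- pmin(d2, rowSums((x - matrix(x[c, ], n, ncol(x),
                                              byrow = TRUE))^2))
      pot <- sum(cand_d2)
      if (pot < best_pot) {
        best_pot <- pot
        best_d2 <- cand_d2
        idx[j] <- c
      }
    }
    d2 <- best_d2
  }
  idx
}

point_center_dist2 <- function(x, centers) {
  k <- nrow(centers)
  sapply(seq_len(k), function(j) {
    rowSums((x - matrix(centers[j, ], nrow(x), ncol(x), byrow = TRUE))^2)
  })
}

#' @export
print.spindle_kmeans <- function(x, ...) {
  cat(sprintf("<spindle_kmeans> k = %d, SSE = %.4g, centres: %s\n", x$k,
              x$sse, paste(signif(sort(x$centers[, 1]), 4), collapse = ", ")))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a k-means fit
#'
#' @param x A `spindle_kmeans` object.
#' @param ... Unused.
#' @return One row per cluster: `cluster`, `center` (first feature
#'   dimension), `size`.
#' @method tidy spindle_kmeans
#' @export
tidy.spindle_kmeans <- function(x, ...) {
  tibble::tibble(
    cluster = seq_len(x$k),
    center = x$centers[, 1],
    size = tabulate(x$labels, nbins = x$k)
  )
}

#' Glance at a k-means fit
#'
#' @param x A `spindle_kmeans` object.
#' @param ... Unused.
#' @return A one-row tibble with `k`, `sse` and `iterations`.
#' @method glance spindle_kmeans
#' @export
glance.spindle_kmeans <- function(x, ...) {
  tibble::tibble(k = x$k, sse = x$sse, iterations = length(x$sse_trace))
}

#' Select the number of clusters by the gap (difference) statistic
#'
#' For k = 1..`k_max`, compares `log(SSE_k)` on the data against its
#' expectation under `B` uniform reference draws over the feature bounding
#' box, and returns the smallest k whose gap is at least `gap(k+1) -
#' s(k+1)`; if no k qualifies, `k_max`.
#'
#' @param x Numeric vector or matrix of features.
#' @param k_max Largest k considered.
#' @param seed Integer seed for the reference draws and restarts.
#' @param B Number of reference datasets (default 20).
#' @return The selected k (integer).
#' @export
select_k <- function(x, k_max = 8, seed = 1, B = 20) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (k_max < 1L) stop("k_max must be >= 1", call. = FALSE)
  if (n < k_max) {
    warning("fewer points than k_max; lowering k_max to ", n)
    k_max <- n
  }
  lo <- apply(x, 2, min); hi <- apply(x, 2, max)
  log_sse <- function(dat, k) {
    sse <- spindle_kmeans(dat, k, seed = seed, nstart = 5)$sse
    log(max(sse, 1e-12))
  }
  gap <- numeric(k_max); sk <- numeric(k_max)
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(seed)
  refs <- lapply(seq_len(B), function(b) {
    matrix(stats::runif(n * ncol(x), rep(lo, each = n), rep(hi, each = n)),
           n, ncol(x))
  })
  for (k in seq_len(k_max)) {
    obs <- log_sse(x, k)
    ref_log <- vapply(refs, log_sse, numeric(1), k = k)
    gap[k] <- mean(ref_log) - obs
    sk[k] <- stats::sd(ref_log) * sqrt(1 + 1 / B)
  }
  for (k in seq_len(k_max - 1L)) {
    if (gap[k] >= gap[k + 1L] - sk[k + 1L]) return(k)
  }
  k_max
}

#' Discard the extreme-amplitude clusters
#'
#' Ranks clusters by centre amplitude and drops the highest- and
#' lowest-centre clusters until `keep` remain (for the default five clusters
#' with three kept, the maximum- and minimum-amplitude clusters are removed
#' and the middle three survive). When the number dropped is odd, the extra
#' cluster is dropped from the low-amplitude end, where non-spindle
#' background events concentrate.
#'
#' @param fit A `spindle_kmeans` fit on the events' amplitudes.
#' @param ev The `spindle_events` tibble that was clustered (row i of `ev`
#'   has label `fit$labels[i]`).
#' @param keep Number of clusters to retain (`< fit$k`).
#' @return The retained `spindle_events` tibble (possibly empty).
#' @export
prune_clusters <- function(fit, ev, keep = 3) {
  stopifnot(inherits(fit, "spindle_kmeans"))
  ev <- validate_events(ev)
  if (nrow(ev) != length(fit$labels)) {
    stop("event table and clustering labels differ in length", call. = FALSE)
  }
  if (fit$k <= keep) {
    stop("keep (", keep, ") must be smaller than k (", fit$k, ")",
         call. = FALSE)
  }
  ord <- order(fit$centers[, 1])  # low -> high amplitude
  n_drop <- fit$k - keep
  drop_low <- ceiling(n_drop / 2)
  drop_high <- n_drop - drop_low
  dropped <- c(utils::head(ord, drop_low),
               if (drop_high > 0) utils::tail(ord, drop_high))
  kept <- ev[!fit$labels %in% dropped, , drop = FALSE]
  if (nrow(kept) == 0L) {
    return(spindle_events(subject_id = ev$subject_id[1],
                          channel = ev$channel[1]))
  }
  validate_events(kept)
}

#' Fuse coincident and cluster-retained events
#'
#' The final output of the hierarchical detector: the union of the coincident
#' set and the retained non-coincident events, sorted, with overlapping
#' members unioned into single events. Events created by such unioning are
#' re-checked against the duration gate; untouched events pass through.
#'
#' @param coincident,retained `spindle_events` tibbles.
#' @param min_dur_s,max_dur_s Duration gate applied to merged events only.
#' @return A `spindle_events` tibble with `source = "fusion"`.
#' @export
fuse_events <- function(coincident, retained, min_dur_s = 0.5,
                        max_dur_s = 3.0) {
  coincident <- validate_events(coincident)
  retained <- validate_events(retained)
  sid <- c(coincident$subject_id, retained$subject_id, "S1")[1]
  ch <- c(coincident$channel, retained$channel, "C3")[1]
  all_ev <- dplyr::bind_rows(coincident, retained)
  if (nrow(all_ev) == 0L) {
    return(spindle_events(source = "fusion", subject_id = sid, channel = ch))
  }
  u <- union_intervals(all_ev$onset_s, all_ev$offset_s)
  dur <- u$offset_s - u$onset_s
  keep <- u$n_merged == 1L | (dur >= min_dur_s & dur <= max_dur_s)
  spindle_events(u$onset_s[keep], u$offset_s[keep], source = "fusion",
                 subject_id = sid, channel = ch)
}
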