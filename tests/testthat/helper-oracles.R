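# Independent brute-force oracles used to validate the package's
# implementations. These deliberately share no code with R/.

# LOF straight from its definition, naive loops.
oracle_lof <- function(x, k) {
  x <- as.matrix(x)
  n <- nrow(x)
  dmat <- matrix(0, n, n)
  for (i in 1:n) for (j in 1:n) {
    dmat[i, j] <- sqrt(sum((x[i, ] - x[j, ])^2))
  }
  kdist <- numeric(n)
  neigh <- vector("list", n)
  for (i in 1:n) {
    d <- dmat[i, -i]
    ids <- (1:n)[-i]
    o <- order(d)
    kdist[i] <- d[o][k]
    neigh[[i]] <- ids[d <= kdist[i]]
  }
  lrd <- numeric(n)
  for (i in 1:n) {
    rd <- sapply(neigh[[i]], function(o) max(kdist[o], dmat[i, o]))
    lrd[i] <- if (mean(rd) == 0) Inf else 1 / mean(rd)
  }
  lof <- numeric(n)
  for (i in 1:n) {
    r <- lrd[neigh[[i]]] / lrd[i]
    r[is.nan(r)] <- 1
    lof[i] <- mean(r)
  }
  lof
}

# Optimal 1-D k-means SSE by enumerating contiguous partitions of the sorted
# data (optimal 1-D clusters are contiguous).
oracle_kmeans_1d_sse <- function(x, k) {
  x <- sort(x)
  n <- length(x)
  splits <- utils::combn(n - 1, k - 1)
  best <- Inf
  sse_of <- function(seg) sum((seg - mean(seg))^2)
  for (c in seq_len(ncol(splits))) {
    bounds <- c(0, splits[, c], n)
    sse <- 0
    for (g in seq_len(k)) {
      sse <- sse + sse_of(x[(bounds[g] + 1):bounds[g + 1]])
    }
    best <- min(best, sse)
  }
  best
}

# Brute-force threshold scan: intervals where env > thr, sample-resolution.
oracle_threshold_scan <- function(env_values, fs, thr) {
  above <- env_values > thr
  out <- NULL
  i <- 1
  n <- length(above)
  while (i <= n) {
    if (above[i]) {
      j <- i
      while (j < n && above[j + 1]) j <- j + 1
      out <- rbind(out, c((i - 1) / fs, j / fs))
      i <- j + 1
    } else {
      i <- i + 1
    }
  }
  out
}

# All (morlet, rms) index pairs with strictly positive overlap.
oracle_overlap_pairs <- function(m_on, m_off, r_on, r_off) {
  pairs <- NULL
  for (i in seq_along(m_on)) {
    for (j in seq_along(r_on)) {
      ov <- min(m_off[i], r_off[j]) - max(m_on[i], r_on[j])
      if (ov > 0) pairs <- rbind(pairs, c(i, j, ov))
    }
  }
  pairs
}

# Consensus by vote counting on a 1 ms grid over [0, horizon).
oracle_consensus_grid <- function(sets, min_votes, horizon, min_dur = 0.5) {
  grid <- seq(0, horizon, by = 0.001)
  votes <- rep(0L, length(grid))
  for (s in sets) {
    cover <- rep(FALSE, length(grid))
    for (r in seq_len(nrow(s))) {
      cover <- cover | (grid >= s$onset_s[r] & grid < s$offset_s[r])
    }
    votes <- votes + cover
  }
  above <- votes >= min_votes
  out <- NULL
  i <- 1
  while (i <= length(above)) {
    if (above[i]) {
      j <- i
      while (j < length(above) && above[j + 1]) j <- j + 1
      on <- grid[i]; off <- grid[j] + 0.001
      if (off - on >= min_dur) out <- rbind(out, c(on, off))
      i <- j + 1
    } else {
      i <- i + 1
    }
  }
  out
}

# Random non-overlapping event set on [0, horizon].
random_event_set <- function(n, horizon, source = "morlet", seed = 1) {
  set.seed(seed)
  starts <- sort(runif(n, 0, horizon - 1))
  # enforce non-overlap by clipping each offset at the next onset
  durs <- runif(n, 0.3, 1.5)
  offs <- pmin(starts + durs, c(starts[-1], horizon))
  keep <- offs - starts > 0.05
  spindle_events(starts[keep], offs[keep], source = source)
}
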