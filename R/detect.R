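#' Run the hierarchical fusion spindle detector
#'
#' The full two-layer pipeline on a single channel. Layer one runs the Morlet
#' wavelet detector (5-35 Hz pre-filter, multi-frequency envelope, 4.5x mean
#' threshold) and the windowed-RMS detector (11-16 Hz filter, 0.25 s windows,
#' 0.95x mean threshold, two consecutive windows) independently. Layer two
#' partitions their events into coincident pairs (kept outright) and
#' non-coincident events, which are pruned by local-outlier-factor scoring on
#' amplitude and clustered with k-means; the extreme-amplitude clusters are
#' discarded and the survivors are fused with the coincident set.
#'
#' Non-coincident events enter the fusion output only after the cluster
#' filter has vouched for them. When the set is too small to cluster (fewer
#' events than `kmeans_k` after LOF pruning), no noise cluster can be
#' identified and the detector falls back to the coincident set alone — the
#' same degenerate-case convention used when LOF pruning removes every
#' event.
#'
#' @param rec An [eeg_recording()]. Resampled to `config$target_fs` first if
#'   its rate is higher.
#' @param config A [detection_config()].
#' @return An object of class `spindle_detection`: list with `events` (a
#'   `spindle_events` tibble holding the `morlet`, `rms`, `coincident` and
#'   `fusion` event sets stacked, distinguished by `source`), `config`,
#'   `diagnostics` (per-event amplitude/LOF/cluster table for the
#'   non-coincident set) and `kmeans_fit`.
#' @export
#' @examples
#' \donttest{
#' spec <- sim_spec(duration_s = 60, n_spindles = 4, seed = 7)
#' sim <- simulate_subject(spec)
#' det <- detect_spindles(sim$recording)
#' dplyr::count(det$events, source)
#' }
detect_spindles <- function(rec, config = detection_config()) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (rec$fs > config$target_fs) {
    rec <- resample_recording(rec, config$target_fs)
  }
  morlet <- detect_morlet(rec, config)
  rms <- detect_rms(rec, config)
  parts <- partition_events(morlet, rms)
  sigma <- bandpass(rec, config$spindle_band)

  non <- extract_features(parts$non_coincident, sigma)
  diagnostics <- NULL
  fit <- NULL
  if (isTRUE(config$amp_hard_gate) && nrow(non) > 0L) {
    non <- non[non$peak_amp_uv >= config$amp_range_uv[1] &
                 non$peak_amp_uv <= config$amp_range_uv[2], , drop = FALSE]
  }
  empty_set <- spindle_events(subject_id = rec$subject_id,
                              channel = rec$channel)
  retained <- empty_set
  if (nrow(non) >= 3L) {
    pruned <- tryCatch(
      remove_outliers(non, config$lof_neighbors, config$lof_threshold),
      error = function(e) NULL
    )
    if (is.null(pruned)) {
      # every event scored as an outlier: fall back to coincident-only
      retained <- empty_set
    } else if (nrow(pruned) >= config$kmeans_k) {
      k <- if (isTRUE(config$select_k)) {
        max(2L, select_k(pruned$peak_amp_uv,
                         k_max = min(config$kmeans_k + 3L, nrow(pruned)),
                         seed = config$rng_seed))
      } else {
        config$kmeans_k
      }
      keep <- min(config$clusters_kept, k - 1L)
      fit <- spindle_kmeans(pruned$peak_amp_uv, k, seed = config$rng_seed)
      retained <- prune_clusters(fit, pruned, keep)
      diagnostics <- tibble::tibble(
        onset_s = pruned$onset_s,
        offset_s = pruned$offset_s,
        peak_amp_uv = pruned$peak_amp_uv,
        cluster = fit$labels,
        kept = pruned$onset_s %in% retained$onset_s
      )
    } else {
      # too few survivors to form the k clusters: coincident-only fallback
      retained <- empty_set
    }
  }
  fusion <- fuse_events(parts$coincident, retained,
                        config$min_dur_s, config$max_dur_s)
  events <- dplyr::bind_rows(morlet, rms, parts$coincident, fusion)
  events <- if (nrow(events) > 0L) validate_events(events) else
    spindle_events(subject_id = rec$subject_id, channel = rec$channel)
  structure(
    list(events = events, config = config, diagnostics = diagnostics,
         kmeans_fit = fit),
    class = "spindle_detection"
  )
}

#' @export
print.spindle_detection <- function(x, ...) {
  counts <- dplyr::count(x$events, .data$source)
  cat("<spindle_detection>\n")
  for (i in seq_len(nrow(counts))) {
    cat(sprintf("  %-10s %d events\n", counts$source[i], counts$n[i]))
  }
  invisible(x)
}

#' Tidy a detection result
#'
#' @param x A `spindle_detection` object.
#' @param ... Unused.
#' @return The stacked `spindle_events` tibble (all sources).
#' @method tidy spindle_detection
#' @export
tidy.spindle_detection <- function(x, ...) x$events

#' Glance at a detection result
#'
#' @param x A `spindle_detection` object.
#' @param ... Unused.
#' @return A one-row tibble of per-source event counts.
#' @method glance spindle_detection
#' @export
glance.spindle_detection <- function(x, ...) {
  counts <- table(factor(x$events$source,
                         levels = c("morlet", "rms", "coincident", "fusion")))
  tibble::as_tibble(as.list(counts))
}
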