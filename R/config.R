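#' Detector configuration
#'
#' Bundles every tunable constant of the two base detectors and the fusion
#' layer. Defaults are the published operating point of the method: analysis
#' at 512 Hz; a 5-35 Hz pre-filter on the wavelet path and an 11-16 Hz
#' filter on the RMS path; a 7-cycle complex Morlet kernel thresholded at
#' 4.5x the mean smoothed envelope (0.1 s smoothing window); 0.5-3 s
#' duration gate with a sub-1 s merge rule; 0.25 s RMS windows thresholded
#' at 0.95x the mean with two consecutive supra-threshold windows required;
#' five amplitude clusters of which the middle three are kept.
#'
#' @param target_fs Analysis sampling rate in Hz.
#' @param preproc_band Passband (Hz) of the wavelet-path pre-filter.
#' @param spindle_band Sigma band (Hz); the RMS-path filter and the Morlet
#'   centre-frequency grid live here.
#' @param morlet_n_cycles Cycle count n of the Morlet kernel.
#' @param morlet_fc_grid Centre frequencies (Hz) for the wavelet envelope;
#'   `NULL` means every 0.5 Hz across `spindle_band`.
#' @param morlet_threshold_factor Envelope threshold as a multiple of the
#'   mean smoothed envelope.
#' @param morlet_smooth_win_s Envelope smoothing window in seconds.
#' @param min_dur_s,max_dur_s Admissible spindle duration range in seconds.
#' @param merge_gap_s Merge events closer than this many seconds (when the
#'   merged duration stays below `max_dur_s`).
#' @param rms_win_s RMS window length in seconds.
#' @param rms_epoch_s Epoch length for per-epoch RMS thresholding.
#' @param rms_threshold_factor RMS threshold as a multiple of the mean RMS.
#' @param rms_consecutive Minimum number of consecutive supra-threshold RMS
#'   windows.
#' @param rms_epoch_mode If `TRUE`, recompute the RMS threshold per
#'   `rms_epoch_s` epoch instead of once globally.
#' @param kmeans_k Number of amplitude clusters.
#' @param clusters_kept Number of clusters retained after discarding the
#'   extremes (must be `< kmeans_k`).
#' @param select_k If `TRUE`, choose k by the gap (difference) statistic
#'   instead of using `kmeans_k`.
#' @param lof_neighbors Neighbourhood size for local-outlier-factor pruning;
#'   `NULL` means `min(20, n - 1)`.
#' @param lof_threshold LOF score above which an event is pruned as an
#'   outlier.
#' @param amp_range_uv Plausible spindle peak-amplitude range in microvolts.
#' @param amp_hard_gate If `TRUE`, hard-reject non-coincident events whose
#'   amplitude falls outside `amp_range_uv` before clustering.
#' @param rng_seed Seed for k-means restarts and gap-statistic references.
#'
#' @return A list of class `detection_config`.
#' @export
#' @examples
#' cfg <- detection_config()
#' cfg$morlet_threshold_factor
detection_config <- function(target_fs = 512,
                             preproc_band = c(5, 35),
                             spindle_band = c(11, 16),
                             morlet_n_cycles = 7,
                             morlet_fc_grid = NULL,
                             morlet_threshold_factor = 4.5,
                             morlet_smooth_win_s = 0.1,
                             min_dur_s = 0.5,
                             max_dur_s = 3.0,
                             merge_gap_s = 1.0,
                             rms_win_s = 0.25,
                             rms_epoch_s = 5.0,
                             rms_threshold_factor = 0.95,
                             rms_consecutive = 2,
                             rms_epoch_mode = FALSE,
                             kmeans_k = 5,
                             clusters_kept = 3,
                             select_k = FALSE,
                             lof_neighbors = NULL,
                             lof_threshold = 1.5,
                             amp_range_uv = c(10, 60),
                             amp_hard_gate = FALSE,
                             rng_seed = 20230309) {
  cfg <- list(
    target_fs = target_fs, preproc_band = preproc_band,
    spindle_band = spindle_band, morlet_n_cycles = morlet_n_cycles,
    morlet_fc_grid = morlet_fc_grid %||%
      seq(spindle_band[1], spindle_band[2], by = 0.5),
    morlet_threshold_factor = morlet_threshold_factor,
    morlet_smooth_win_s = morlet_smooth_win_s,
    min_dur_s = min_dur_s, max_dur_s = max_dur_s, merge_gap_s = merge_gap_s,
    rms_win_s = rms_win_s, rms_epoch_s = rms_epoch_s,
    rms_threshold_factor = rms_threshold_factor,
    rms_consecutive = rms_consecutive, rms_epoch_mode = rms_epoch_mode,
    kmeans_k = kmeans_k, clusters_kept = clusters_kept, select_k = select_k,
    lof_neighbors = lof_neighbors, lof_threshold = lof_threshold,
    amp_range_uv = amp_range_uv, amp_hard_gate = amp_hard_gate,
    rng_seed = rng_seed
  )
  validate_config(cfg)
}

validate_config <- function(cfg) {
  chk <- function(cond, msg) if (!cond) stop("invalid config: ", msg, call. = FALSE)
  band_ok <- function(b) length(b) == 2L && is.finite(b[1]) && b[1] > 0 && b[1] < b[2]
  chk(cfg$target_fs > 0, "target_fs must be positive")
  chk(band_ok(cfg$preproc_band), "preproc_band must be an increasing pair")
  chk(band_ok(cfg$spindle_band), "spindle_band must be an increasing pair")
  chk(cfg$morlet_n_cycles >= 1, "morlet_n_cycles must be >= 1")
  chk(length(cfg$morlet_fc_grid) >= 1 && all(cfg$morlet_fc_grid > 0),
      "morlet_fc_grid must be non-empty and positive")
  chk(cfg$morlet_threshold_factor > 0, "morlet_threshold_factor must be > 0")
  for (f in c("morlet_smooth_win_s", "min_dur_s", "max_dur_s", "merge_gap_s",
              "rms_win_s", "rms_epoch_s")) {
    chk(cfg[[f]] > 0, paste(f, "must be > 0"))
  }
  chk(cfg$min_dur_s < cfg$max_dur_s, "min_dur_s must be < max_dur_s")
  chk(cfg$rms_threshold_factor > 0, "rms_threshold_factor must be > 0")
  chk(cfg$rms_consecutive >= 1, "rms_consecutive must be >= 1")
  chk(cfg$kmeans_k >= 2, "kmeans_k must be >= 2")
  chk(cfg$clusters_kept >= 1 && cfg$clusters_kept < cfg$kmeans_k,
      "clusters_kept must satisfy 1 <= clusters_kept < kmeans_k")
  chk(is.null(cfg$lof_neighbors) || cfg$lof_neighbors >= 1,
      "lof_neighbors must be >= 1 or NULL")
  chk(cfg$lof_threshold > 0, "lof_threshold must be > 0")
  chk(band_ok(cfg$amp_range_uv), "amp_range_uv must be an increasing pair")
  class(cfg) <- "detection_config"
  cfg
}

#' Load a detector configuration from a key-value file
#'
#' The config file is flat TOML-style text: one `key = value` pair per line,
#' `#` comments, numeric scalars, `true`/`false` booleans, and pairs or lists
#' written as `[a, b]`. Keys not present in the file keep their
#' [detection_config()] defaults; unknown keys are an error that lists the
#' valid keys.
#'
#' @param path Path to the config file, or `NULL` for all defaults.
#' @return A `detection_config` list.
#' @export
load_config <- function(path = NULL) {
  if (is.null(path)) return(detection_config())
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  defaults <- formals(detection_config)
  overrides <- list()
  for (ln in lines) {
    if (!grepl("=", ln, fixed = TRUE)) {
      stop("config line is not 'key = value': ", ln, call. = FALSE)
    }
    key <- trimws(sub("=.*$", "", ln))
    val <- trimws(sub("^[^=]*=", "", ln))
    if (!key %in% names(defaults)) {
      stop("unknown config key '", key, "'; valid keys: ",
           paste(names(defaults), collapse = ", "), call. = FALSE)
    }
    overrides[[key]] <- parse_config_value(val, key)
  }
  do.call(detection_config, overrides)
}

parse_config_value <- function(val, key) {
  if (grepl("^\\[.*\\]$", val)) {
    parts <- trimws(strsplit(gsub("^\\[|\\]$", "", val), ",")[[1]])
    return(as.numeric(parts))
  }
  if (tolower(val) %in% c("true", "false")) return(tolower(val) == "true")
  num <- suppressWarnings(as.numeric(val))
  if (is.na(num)) {
    stop("config key '", key, "' has unparseable value: ", val, call. = FALSE)
  }
  num
}
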