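#' Expert consensus event set
#'
#' Builds the gold standard from three expert annotation sets: time regions
#' covered by at least `min_votes` experts become consensus events (each
#' maximal supra-quorum region is one event); regions shorter than
#' `min_dur_s` are dropped. The vote count is computed exactly by a sweep
#' over the interval endpoints, not on a sampling grid.
#'
#' @param expert_sets List of exactly three `spindle_events` tibbles.
#' @param min_votes Quorum (default 2: marked by two or three experts).
#' @param min_dur_s Minimum consensus-event duration in seconds.
#' @return A `spindle_events` tibble with `source = "consensus"`.
#' @export
consensus_events <- function(expert_sets, min_votes = 2, min_dur_s = 0.5) {
  if (length(expert_sets) != 3L) {
    stop("consensus requires exactly three expert event sets", call. = FALSE)
  }
  expert_sets <- lapply(expert_sets, validate_events)
  sid <- c(unlist(lapply(expert_sets, function(e) e$subject_id)), "S1")[1]
  ch <- c(unlist(lapply(expert_sets, function(e) e$channel)), "C3")[1]
  # Per-expert coverage must count each expert once even if their own events
  # overlap, so union within each expert first.
  per_expert <- lapply(expert_sets, function(e) {
    union_intervals(e$onset_s, e$offset_s)
  })
  edges <- sort(unique(unlist(lapply(per_expert, function(u) {
    c(u$onset_s, u$offset_s)
  }))))
  if (length(edges) < 2L) {
    return(spindle_events(source = "consensus", subject_id = sid,
                          channel = ch))
  }
  seg_on <- edges[-length(edges)]
  seg_off <- edges[-1]
  mid <- (seg_on + seg_off) / 2
  votes <- rowSums(sapply(per_expert, function(u) {
    vapply(mid, function(t) any(u$onset_s <= t & t < u$offset_s), logical(1))
  }))
  keep <- votes >= min_votes
  if (!any(keep)) {
    return(spindle_events(source = "consensus", subject_id = sid,
                          channel = ch))
  }
  merged <- union_intervals(seg_on[keep], seg_off[keep], tol = 1e-12)
  dur <- merged$offset_s - merged$onset_s
  merged <- merged[dur >= min_dur_s, , drop = FALSE]
  spindle_events(merged$onset_s, merged$offset_s, source = "consensus",
                 subject_id = sid, channel = ch)
}

#' Event-level confusion counts
#'
#' Matches detected events to gold events greedily in detected-onset order
#' with an any-overlap criterion, one-to-one (ties broken by the larger
#' overlap): each detected event paired with an unmatched overlapping gold
#' event is a true positive; unpaired detected events are false positives;
#' unmatched gold events are false negatives. True negatives, which the
#' event-level view does not define by itself, are counted as the number of
#' `bin_s`-second bins of the recording that are less than half covered by
#' any gold or detected event.
#'
#' @param detected,gold `spindle_events` tibbles.
#' @param duration_s Recording duration in seconds; required for `tn` (pass
#'   `NA` to skip the negative universe, leaving `tn = NA`).
#' @param bin_s Background bin width in seconds (default 0.5, the minimum
#'   spindle duration).
#' @return A one-row tibble with integer columns `tp`, `fp`, `fn`, `tn`.
#' @export
match_events <- function(detected, gold, duration_s = NA, bin_s = 0.5) {
  detected <- validate_events(detected)
  gold <- validate_events(gold)
  nd <- nrow(detected); ng <- nrow(gold)
  gold_taken <- logical(ng)
  tp <- 0L
  for (i in seq_len(nd)) {
    if (ng == 0L) break
    ov <- pmin(detected$offset_s[i], gold$offset_s) -
      pmax(detected$onset_s[i], gold$onset_s)
    ov[gold_taken] <- -Inf
    j <- which.max(ov)
    if (length(j) == 1L && ov[j] > 0) {
      gold_taken[j] <- TRUE
      tp <- tp + 1L
    }
  }
  fp <- nd - tp
  fn <- ng - tp
  tn <- NA_integer_
  if (!is.na(duration_s)) {
    n_bins <- floor(duration_s / bin_s)
    if (n_bins < 1L) stop("duration_s shorter than one bin", call. = FALSE)
    starts <- (seq_len(n_bins) - 1L) * bin_s
    all_on <- c(detected$onset_s, gold$onset_s)
    all_off <- c(detected$offset_s, gold$offset_s)
    u <- union_intervals(all_on, all_off)
    cov <- vapply(starts, function(a) {
      overlap_length(a, a + bin_s, u$onset_s, u$offset_s)
    }, numeric(1))
    tn <- sum(cov < 0.5 * bin_s)
  }
  tibble::tibble(tp = tp, fp = fp, fn = fn, tn = tn)
}

#' Detection metrics from confusion counts
#'
#' `recall = TP/(TP+FN)`, `precision = TP/(TP+FP)`,
#' `specificity = TN/(TN+FP)`, `accuracy = (TP+TN)/(TP+FP+TN+FN)`,
#' `f1 = 2*precision*recall/(precision+recall)`. A metric whose denominator
#' is zero (or that needs an undefined `tn`) is `NA`; the others are still
#' computed.
#'
#' @param cc A one-row tibble (or list) with `tp`, `fp`, `fn`, `tn`.
#' @return A one-row tibble with `precision`, `recall`, `specificity`,
#'   `accuracy`, `f1`.
#' @export
compute_metrics <- function(cc) {
  tp <- cc$tp; fp <- cc$fp; fn <- cc$fn; tn <- cc$tn
  safe_div <- function(num, den) {
    if (any(is.na(den)) || den == 0) NA_real_ else num / den
  }
  precision <- safe_div(tp, tp + fp)
  recall <- safe_div(tp, tp + fn)
  specificity <- safe_div(tn, tn + fp)
  accuracy <- safe_div(tp + tn, tp + fp + tn + fn)
  f1 <- if (is.na(precision) || is.na(recall) || precision + recall == 0) {
    NA_real_
  } else {
    2 * precision * recall / (precision + recall)
  }
  tibble::tibble(precision = precision, recall = recall,
                 specificity = specificity, accuracy = accuracy, f1 = f1)
}

#' Evaluate a detector against a gold standard
#'
#' Convenience wrapper: confusion counts plus derived metrics in one row.
#'
#' @param detected,gold `spindle_events` tibbles.
#' @param duration_s Recording duration in seconds (for `tn`); `NA` skips it.
#' @param bin_s Background bin width for the `tn` universe.
#' @return A one-row tibble with counts and metrics.
#' @export
evaluate_detection <- function(detected, gold, duration_s = NA, bin_s = 0.5) {
  cc <- match_events(detected, gold, duration_s, bin_s)
  dplyr::bind_cols(cc, compute_metrics(cc))
}

# Half-up rounding (R's round() is banker's rounding).
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

#' Cohort report of per-subject spindle counts
#'
#' Takes per-subject A/R/E spindle counts (all auto-detected events,
#' auto-detected events matching gold, gold events) for one or more
#' algorithms and produces the cohort summary: a DS-average row per
#' algorithm (arithmetic mean of each count column, rounded half-up to an
#' integer), ratio-of-means precision `R/A` and recall `R/E` in percent
#' computed from the DS-average counts, per-subject minimum and maximum of
#' both ratios, and per-column maxima.
#'
#' @param counts A data frame with columns `subject_id`, `algorithm`,
#'   `a_spindle`, `r_spindle`, `e_spindle` (one row per subject x algorithm).
#' @param digits Decimal places for the ratio percentages (half-up; default 1
#'   as printed in cohort tables, 2 for finer comparison).
#' @return An object of class `spindle_cohort_report`: list with `counts`
#'   (input plus the DS-average rows), `summary` (per-algorithm tibble with
#'   DS-average counts, `precision_pct`, `recall_pct`, per-subject
#'   `precision_min/max_pct`, `recall_min/max_pct`, `max_a_spindle`) and
#'   `digits`.
#' @export
#' @examples
#' counts <- reference_cohort_counts()
#' rep <- cohort_report(counts)
#' dplyr::filter(rep$summary, algorithm == "fusion")
cohort_report <- function(counts, digits = 1) {
  needed <- c("subject_id", "algorithm", "a_spindle", "r_spindle", "e_spindle")
  if (!all(needed %in% names(counts))) {
    stop("counts must have columns ", paste(needed, collapse = ", "),
         call. = FALSE)
  }
  counts <- tibble::as_tibble(counts)
  if (nrow(counts) == 0L) stop("empty cohort", call. = FALSE)
  bad <- counts$r_spindle > counts$a_spindle |
    counts$r_spindle > counts$e_spindle
  if (any(bad)) {
    stop("row ", which(bad)[1],
         ": r_spindle must not exceed a_spindle or e_spindle", call. = FALSE)
  }
  avg <- counts |>
    dplyr::group_by(.data$algorithm) |>
    dplyr::summarise(
      a_spindle = round_half_up(mean(.data$a_spindle)),
      r_spindle = round_half_up(mean(.data$r_spindle)),
      e_spindle = round_half_up(mean(.data$e_spindle)),
      .groups = "drop"
    ) |>
    dplyr::mutate(subject_id = "DS-average")
  per_subject <- counts |>
    dplyr::mutate(
      precision_pct = 100 * .data$r_spindle / .data$a_spindle,
      recall_pct = 100 * .data$r_spindle / .data$e_spindle
    )
  summary <- avg |>
    dplyr::mutate(
      precision_pct = round_half_up(100 * .data$r_spindle / .data$a_spindle,
                                    digits),
      recall_pct = round_half_up(100 * .data$r_spindle / .data$e_spindle,
                                 digits)
    ) |>
    dplyr::select(-"subject_id") |>
    dplyr::left_join(
      per_subject |>
        dplyr::group_by(.data$algorithm) |>
        dplyr::summarise(
          precision_min_pct = round_half_up(min(.data$precision_pct), digits),
          precision_max_pct = round_half_up(max(.data$precision_pct), digits),
          recall_min_pct = round_half_up(min(.data$recall_pct), digits),
          recall_max_pct = round_half_up(max(.data$recall_pct), digits),
          max_a_spindle = max(.data$a_spindle),
          max_r_spindle = max(.data$r_spindle),
          .groups = "drop"
        ),
      by = "algorithm"
    )
  structure(
    list(
      counts = dplyr::bind_rows(counts, avg[c(needed[c(1, 2)],
                                              needed[c(3, 4, 5)])]),
      summary = summary,
      per_subject = per_subject,
      digits = digits
    ),
    class = "spindle_cohort_report"
  )
}

#' @export
print.spindle_cohort_report <- function(x, ...) {
  cat("<spindle_cohort_report>\n")
  print(x$summary)
  invisible(x)
}

#' Tidy a cohort report
#'
#' @param x A `spindle_cohort_report`.
#' @param ... Unused.
#' @return The per-algorithm summary tibble.
#' @method tidy spindle_cohort_report
#' @export
tidy.spindle_cohort_report <- function(x, ...) x$summary

#' Write a cohort report as TSV
#'
#' Emits the per-subject counts (with DS-average rows) as a tab-separated
#' table mirroring the usual per-algorithm A/R/E layout.
#'
#' @param x A `spindle_cohort_report`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_cohort_report <- function(x, path) {
  stopifnot(inherits(x, "spindle_cohort_report"))
  readr::write_tsv(x$counts, path, progress = FALSE)
  invisible(path)
}

#' Published reference cohort counts
#'
#' Per-subject A/R/E spindle counts for four detectors (Morlet wavelet,
#' windowed RMS, an HMM+SVM baseline, and the hierarchical fusion algorithm)
#' on a 20-subject clinical sleep-disorder cohort, shipped with the package
#' as reference data for [cohort_report()].
#'
#' @return A tibble with columns `subject_id`, `algorithm`, `a_spindle`,
#'   `r_spindle`, `e_spindle`.
#' @export
reference_cohort_counts <- function() {
  path <- system.file("extdata", "clinical_cohort_counts.csv",
                      package = "spindlefusion", mustWork = TRUE)
  readr::read_csv(path, col_types = "ccinn", progress = FALSE) |>
    dplyr::mutate(a_spindle = as.integer(.data$a_spindle),
                  r_spindle = as.integer(.data$r_spindle),
                  e_spindle = as.integer(.data$e_spindle))
}
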