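#' Score detected onsets against ground-truth stimuli
#'
#' Matches detections to stimuli by greedy earliest-first one-to-one
#' assignment: a detection `d` matches a stimulus `s` iff `d` lies in
#' `[s, s + tolerance]` — right-sided only, because the haemodynamic
#' response always lags the stimulus (default tolerance 2 samples = 2 TR).
#' Matched stimuli are true positives, unmatched stimuli false negatives,
#' unmatched detections false positives, and every remaining sample a true
#' negative, so `tp + fn` equals the stimulus count and the four tallies
#' sum to `n_samples`.
#'
#' @param stimuli,detected onset trains (tibbles with `sample_index` or
#'   numeric vectors of 0-based indices).
#' @param n_samples total number of evaluable samples (after any initial
#'   discard).
#' @param tolerance matching window in samples, >= 0.
#' @return A one-row tibble with columns `tp`, `fp`, `fn`, `tn`,
#'   `n_samples`.
#' @examples
#' classify_detections(c(5, 50), c(6, 80), n_samples = 100)
#' @export
classify_detections <- function(stimuli, detected, n_samples, tolerance = 2) {
  s <- onset_indices(stimuli, "stimuli")
  d <- onset_indices(detected, "detected")
  n_samples <- check_count(n_samples, "n_samples")
  if (!is.numeric(tolerance) || length(tolerance) != 1L || is.na(tolerance) ||
      tolerance < 0) {
    abort("`tolerance` must be >= 0.")
  }
  tp <- match_onsets(s, d, max_delay = tolerance, allow_advance = FALSE)
  fn <- length(s) - tp
  fp <- length(d) - tp
  tn <- n_samples - tp - fn - fp
  if (tn < 0) abort("`n_samples` is too small for the supplied trains.")
  tibble::tibble(tp = tp, fp = fp, fn = fn, tn = as.integer(tn),
                 n_samples = n_samples)
}

#' Sensitivity and specificity of detection counts
#'
#' `sensitivity = TP / (TP + FN)` (fraction of stimuli recovered) and
#' `specificity = TN / (TN + FP)` (fraction of non-stimulus samples left
#' alone).  A zero denominator leaves the value undefined (`NA_real_`),
#' never coerced to 0 or 1.
#'
#' @param counts one-row tibble (or named list) with `tp`, `fp`, `fn`,
#'   `tn`, e.g. from [classify_detections()].
#' @return numeric value in [0, 1] or `NA_real_`.
#' @export
sensitivity <- function(counts) {
  den <- counts$tp + counts$fn
  if (den == 0) {
    warn("no stimuli: sensitivity undefined (NA).")
    return(NA_real_)
  }
  counts$tp / den
}

#' @rdname sensitivity
#' @export
specificity <- function(counts) {
  den <- counts$tn + counts$fp
  if (den == 0) {
    warn("no negative samples: specificity undefined (NA).")
    return(NA_real_)
  }
  counts$tn / den
}

#' Jaccard similarity between two binary masks
#'
#' `|A intersect B| / |A union B|` on identical grids; the conventional
#' overlap score for activation-map reliability.  Two empty masks are
#' defined as identical (similarity 1) with a warning.
#'
#' @param mask_a,mask_b logical arrays of identical dimensions.
#' @return numeric value in [0, 1].
#' @export
jaccard <- function(mask_a, mask_b) {
  if (!identical(dim(mask_a), dim(mask_b)) ||
      length(mask_a) != length(mask_b)) {
    abort("masks must share the same grid.")
  }
  a <- as.logical(mask_a); b <- as.logical(mask_b)
  uni <- sum(a | b)
  if (uni == 0L) {
    warn("both masks empty: Jaccard defined as 1.")
    return(1)
  }
  sum(a & b) / uni
}

#' Split map scores into co-activation and non-co-activation groups
#'
#' Partitions the defined values of a connectivity volume by a binary
#' active-region mask: scores of voxels inside the region are co-activation
#' scores, those outside are non-co-activation scores.  A well-behaved
#' metric separates the two distributions, so the mean difference
#' `mean(co) - mean(non_co)` summarises how sharply the map singles out the
#' active region.
#'
#' @param map an [fc_volume()].
#' @param active_mask logical array on the map's grid.
#' @return An object of class `score_split` with elements `co_scores`,
#'   `non_co_scores` and summary statistics; see [glance.score_split()].
#' @export
split_scores <- function(map, active_mask) {
  stopifnot(inherits(map, "fc_volume"))
  if (!identical(dim(active_mask), dim(map$values))) {
    abort("`active_mask` must be on the map's grid.")
  }
  defined <- !is.na(map$values)
  co <- map$values[defined & active_mask]
  non <- map$values[defined & !active_mask]
  if (length(co) == 0L || length(non) == 0L) {
    abort("both partitions must be non-empty.")
  }
  structure(list(
    co_scores = co, non_co_scores = non,
    co_mean = mean(co), co_sd = sd(co),
    non_co_mean = mean(non), non_co_sd = sd(non),
    mean_difference = mean(co) - mean(non)
  ), class = "score_split")
}

#' @export
print.score_split <- function(x, ...) {
  cat(sprintf("<score_split> co: %.3f +/- %.3f (n=%d); non-co: %.3f +/- %.3f (n=%d)\n",
              x$co_mean, x$co_sd, length(x$co_scores),
              x$non_co_mean, x$non_co_sd, length(x$non_co_scores)))
  cat(sprintf("  mean difference: %.3f\n", x$mean_difference))
  invisible(x)
}

#' Summarise a score split
#'
#' @param x a `score_split` from [split_scores()].
#' @param ... unused.
#' @return one-row tibble with the group means, SDs, sizes and the mean
#'   difference.
#' @export
glance.score_split <- function(x, ...) {
  tibble::tibble(
    co_mean = x$co_mean, co_sd = x$co_sd, n_co = length(x$co_scores),
    non_co_mean = x$non_co_mean, non_co_sd = x$non_co_sd,
    n_non_co = length(x$non_co_scores),
    mean_difference = x$mean_difference
  )
}

#' Monte-Carlo benchmark of onset detectors
#'
#' Repeatedly simulates a BOLD time course with a known impulse train,
#' runs each detector, scores the detections against the truth with the
#' right-sided 2 TR matching rule, and averages sensitivity and specificity
#' across runs.  Default conditions follow the package's reference
#' simulation: 400 samples at TR 2 s, 20 impulses at random positions,
#' additive white Gaussian noise with sigma equal to `noise_frac` times the
#' clean peak amplitude.
#'
#' @param n_runs number of Monte-Carlo repetitions.
#' @param seed integer seed; run `r` uses `seed + r` so individual runs are
#'   reproducible in isolation.
#' @param detectors character vector among `"zfr"`, `"threshold"`.
#' @param n_time,tr,n_events simulation size, repetition time, impulse
#'   count per course.
#' @param noise_frac Gaussian noise sigma as a fraction of the clean peak.
#' @param n1,threshold detector parameters.
#' @param tolerance matching window in samples for scoring.
#' @return An object of class `detector_benchmark`; [tidy()] returns the
#'   run-level table (detector, run, seed, sensitivity, specificity) and
#'   [glance()] the per-detector means.
#' @export
detector_benchmark <- function(n_runs = 100, seed = 1,
                               detectors = c("zfr", "threshold"),
                               n_time = 400, tr = 2, n_events = 20,
                               noise_frac = 0.2, n1 = 15, threshold = 1,
                               tolerance = 2) {
  n_runs <- check_count(n_runs, "n_runs")
  detectors <- match.arg(detectors, several.ok = TRUE)
  n_time <- check_count(n_time, "n_time", min = 10L)
  n_events <- check_count(n_events, "n_events")
  hrf <- canonical_hrf(tr = tr)
  runs <- purrr::map_dfr(seq_len(n_runs), function(r) {
    run_seed <- seed + r
    sim <- with_seed(run_seed, {
      train <- sort(sample.int(n_time, n_events) - 1L)
      clean <- synthesize_bold(train, hrf, n_time = n_time)$clean
      sigma <- noise_frac * max(abs(clean))
      list(train = train, values = clean + rnorm(n_time, sd = sigma))
    })
    purrr::map_dfr(detectors, function(det) {
      idx <- detect_indices(sim$values, det, n1 = n1, threshold = threshold)
      counts <- classify_detections(sim$train, idx, n_samples = n_time,
                                    tolerance = tolerance)
      tibble::tibble(detector = det, run = r, seed = run_seed,
                     sensitivity = sensitivity(counts),
                     specificity = specificity(counts),
                     tp = counts$tp, fp = counts$fp, fn = counts$fn,
                     tn = counts$tn)
    })
  })
  structure(list(runs = runs,
                 config = list(n_runs = n_runs, seed = seed, n_time = n_time,
                               tr = tr, n_events = n_events,
                               noise_frac = noise_frac, n1 = n1,
                               threshold = threshold, tolerance = tolerance)),
            class = "detector_benchmark")
}

#' @export
print.detector_benchmark <- function(x, ...) {
  cat(sprintf("<detector_benchmark> %d runs, %d samples, %d events/course\n",
              x$config$n_runs, x$config$n_time, x$config$n_events))
  print(glance(x), ...)
  invisible(x)
}

#' @describeIn detector_benchmark run-level results.
#' @param x a `detector_benchmark`.
#' @param ... unused.
#' @export
tidy.detector_benchmark <- function(x, ...) x$runs

#' @describeIn detector_benchmark per-detector mean sensitivity/specificity.
#' @export
glance.detector_benchmark <- function(x, ...) {
  dplyr::summarise(
    dplyr::group_by(x$runs, .data$detector),
    mean_sensitivity = mean(.data$sensitivity, na.rm = TRUE),
    mean_specificity = mean(.data$specificity, na.rm = TRUE),
    sd_sensitivity = sd(.data$sensitivity, na.rm = TRUE),
    sd_specificity = sd(.data$specificity, na.rm = TRUE),
    .groups = "drop"
  )
}
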