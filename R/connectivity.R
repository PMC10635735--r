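#' Match detected onsets between two trains
#'
#' Greedy earliest-first one-to-one matching: seed onsets are visited in
#' increasing order and each claims the earliest unused target onset inside
#' its tolerance window.  A target onset `t` is compatible with a seed onset
#' `s` when `t` lies in `[s, s + max_delay]`, or in
#' `[s - max_delay, s + max_delay]` when `allow_advance = TRUE` (used when
#' matching against an external stimulus reference, where the haemodynamic
#' delay can run either way after convolution).  With `one_to_one = FALSE`
#' every seed onset with at least one compatible target counts, which can
#' push the conditional rate above 1; the default keeps the matching a
#' partial bijection.
#'
#' @param seed,target onset trains: tibbles with a `sample_index` column
#'   (e.g. from [detect_onsets()]) or numeric vectors of 0-based indices.
#' @param max_delay tolerance in samples (default 2, i.e. 2 TR).
#' @param allow_advance also accept targets up to `max_delay` samples early.
#' @param one_to_one each onset used at most once (default).
#' @return integer count of matched seed onsets.
#' @examples
#' match_onsets(c(10, 20, 30), c(11, 22, 50)) # 2
#' @export
match_onsets <- function(seed, target, max_delay = 2, allow_advance = FALSE,
                         one_to_one = TRUE) {
  s <- onset_indices(seed, "seed")
  t <- onset_indices(target, "target")
  if (max_delay < 0) abort("`max_delay` must be >= 0.")
  if (length(s) == 0L || length(t) == 0L) return(0L)
  lo_off <- if (allow_advance) -max_delay else 0
  if (!one_to_one) {
    return(sum(vapply(s, function(si) any(t >= si + lo_off & t <= si + max_delay),
                      logical(1))))
  }
  used <- rep(FALSE, length(t))
  matched <- 0L
  for (si in s) {
    ok <- which(!used & t >= si + lo_off & t <= si + max_delay)
    if (length(ok)) {
      used[ok[1L]] <- TRUE
      matched <- matched + 1L
    }
  }
  matched
}

#' Conditional rate between two onset trains
#'
#' The conditional rate (CR) is the fraction of seed onsets for which a
#' matching onset exists in the target train within the delay tolerance:
#' matched pairs divided by the seed onset count.  Co-activated voxel pairs
#' fire together, so their CR approaches 1; unrelated pairs score low.  With
#' the default one-to-one matching the rate is guaranteed to lie in [0, 1].
#'
#' For voxel-to-voxel CR the convention is delays only
#' (`allow_advance = FALSE`); when the seed is an external stimulus
#' reference, advances are usually allowed as well (see [match_onsets()]).
#'
#' An empty seed train leaves the rate undefined: the function returns
#' `NA_real_` (never 0) so that undefined cells drop out of averages.
#'
#' @inheritParams match_onsets
#' @return numeric rate in [0, 1], or `NA_real_` when the seed train is empty.
#' @examples
#' conditional_rate(c(10, 20, 30), c(11, 22, 50)) # 2/3
#' @export
conditional_rate <- function(seed, target, max_delay = 2,
                             allow_advance = FALSE, one_to_one = TRUE) {
  s <- onset_indices(seed, "seed")
  if (length(s) == 0L) {
    warn("empty seed train: conditional rate is undefined (NA).")
    return(NA_real_)
  }
  match_onsets(s, target, max_delay = max_delay, allow_advance = allow_advance,
               one_to_one = one_to_one) / length(s)
}

#' High-SNR regions around detected onsets
#'
#' Around each detected onset `n_c` the BOLD signal carries most of its
#' evoked energy; the high-SNR (HSNR) window is the inclusive index interval
#' `[n_c - 2, n_c + w - 3]` of length `w` (default 6 samples), clipped to
#' the signal.  Overlapping windows are kept separate, so a cluster of
#' onsets up-weights its epoch in the aggregated correlation.
#'
#' @param onsets onset train (tibble with `sample_index` or 0-based vector).
#' @param n_time signal length in samples.
#' @param w window length in samples, at least 3.
#' @return A tibble with columns `onset`, `start`, `end` (all 0-based,
#'   inclusive) and `n_samples`.
#' @examples
#' hsnr_regions(c(10, 40), n_time = 100) # [8,13] and [38,43]
#' @export
hsnr_regions <- function(onsets, n_time, w = 6) {
  idx <- onset_indices(onsets)
  n_time <- check_count(n_time, "n_time")
  w <- check_count(w, "w")
  if (w < 3L) abort("`w` must be at least 3 so the window contains the onset context.")
  if (length(idx) && max(idx) >= n_time) abort("onsets must lie within [0, n_time).")
  start <- pmax(idx - 2, 0)
  end <- pmin(idx + w - 3, n_time - 1)
  tibble::tibble(
    onset = as.integer(idx),
    start = as.integer(start),
    end = as.integer(end),
    n_samples = as.integer(end - start + 1L)
  )
}

#' Aggregated Pearson correlation over HSNR regions
#'
#' For each HSNR window derived from the seed's detected onsets, computes
#' the Pearson correlation between the seed segment and the same temporal
#' segment of the target time course, then returns the unweighted mean over
#' contributing windows.  Windows with fewer than 3 samples or zero variance
#' in either segment are skipped.  The score uses less than half of the time
#' points yet tracks full-length correlation for co-activated pairs.
#'
#' @param seed_tc,target_tc time courses of equal length (tibbles with a
#'   `value` column or numeric vectors).
#' @param regions HSNR window set from [hsnr_regions()].
#' @param weight_by_length weight each window's correlation by its sample
#'   count instead of equally (default `FALSE`).
#' @return numeric score in [-1, 1], or `NA_real_` when no window
#'   contributes.
#' @export
hsnr_correlation <- function(seed_tc, target_tc, regions,
                             weight_by_length = FALSE) {
  a <- tc_values(seed_tc, "seed_tc")
  b <- tc_values(target_tc, "target_tc")
  if (length(a) != length(b)) abort("seed and target time courses must have equal length.")
  if (!is.data.frame(regions) || !all(c("start", "end") %in% names(regions))) {
    abort("`regions` must be a tibble from hsnr_regions().")
  }
  cors <- lens <- numeric(0)
  for (i in seq_len(nrow(regions))) {
    sl <- (regions$start[i] + 1L):(regions$end[i] + 1L)
    if (length(sl) < 3L) next
    sa <- a[sl]; sb <- b[sl]
    if (sd(sa) == 0 || sd(sb) == 0) next
    cors <- c(cors, cor(sa, sb))
    lens <- c(lens, length(sl))
  }
  if (length(cors) == 0L) {
    warn("no HSNR region with enough samples and variance: score undefined (NA).")
    return(NA_real_)
  }
  if (weight_by_length) sum(cors * lens) / sum(lens) else mean(cors)
}

#' Full-length Pearson correlation between two time courses
#'
#' The conventional seed-based functional-connectivity metric, used as the
#' reference against which the point-process metrics are compared.
#'
#' @inheritParams hsnr_correlation
#' @return Pearson correlation coefficient.
#' @export
pearson_fc <- function(seed_tc, target_tc) {
  a <- tc_values(seed_tc, "seed_tc")
  b <- tc_values(target_tc, "target_tc")
  if (length(a) != length(b)) abort("time courses must have equal length.")
  if (length(a) < 3L) abort("time courses must have at least 3 samples.")
  if (sd(a) == 0 || sd(b) == 0) abort("zero-variance time course.")
  cor(a, b)
}

#' Pairwise connectivity matrix over a set of ROI time courses
#'
#' Computes every pairwise connectivity score between region-of-interest
#' (ROI) average time courses under one of four metrics: full-length Pearson
#' `"correlation"`, conditional rate on onsets from the threshold detector
#' (`"cr_threshold"`) or the ZFR detector (`"cr_zfr"`), or the HSNR-region
#' aggregated correlation (`"hsnr"`).  Correlation is symmetric; CR entries
#' may be asymmetric because rows are normalised by the seed's onset count,
#' and HSNR scores may be asymmetric because the windows come from the row
#' (seed) ROI's onsets.  Undefined cells (e.g. an onset-free seed) are
#' `NA`, never coerced to 0.
#'
#' @param roi ROI time courses: a data frame whose columns are ROIs, or a
#'   named list of numeric vectors of equal length.
#' @param metric one of `"correlation"`, `"cr_threshold"`, `"cr_zfr"`,
#'   `"hsnr"`.
#' @param tr sampling interval in seconds (needed by the detectors).
#' @param n1,threshold detector parameters (see [detect_onsets()]).
#' @param max_delay,allow_advance CR matching policy (see [match_onsets()]).
#' @param w HSNR window length (see [hsnr_regions()]).
#' @return A square numeric matrix of class `fc_matrix` with ROI dimnames
#'   and attributes `metric`; use [tidy()] for a long tibble.
#' @export
roi_connectivity <- function(roi,
                             metric = c("correlation", "cr_threshold", "cr_zfr", "hsnr"),
                             tr = 2, n1 = 15, threshold = 1,
                             max_delay = 2, allow_advance = FALSE, w = 6) {
  metric <- match.arg(metric)
  if (is.data.frame(roi)) {
    keep <- vapply(roi, is.numeric, logical(1))
    roi <- as.list(roi[keep])
  }
  if (!is.list(roi) || length(roi) < 2L) abort("`roi` must supply at least 2 ROI time courses.")
  lens <- lengths(roi)
  if (length(unique(lens)) != 1L) abort("all ROI time courses must have equal length.")
  labels <- names(roi) %||% paste0("roi", seq_along(roi))
  labels[labels == ""] <- paste0("roi", which(labels == ""))
  k <- length(roi)
  n_time <- lens[[1L]]

  detector <- switch(metric, cr_threshold = "threshold", cr_zfr = "zfr", NULL)
  onsets <- NULL
  if (metric %in% c("cr_threshold", "cr_zfr", "hsnr")) {
    det <- if (metric == "hsnr") "zfr" else detector
    onsets <- lapply(roi, function(v) {
      detect_onsets(v, det, tr = tr, n1 = n1, threshold = threshold)$sample_index
    })
  }

  m <- matrix(NA_real_, k, k, dimnames = list(labels, labels))
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      m[i, j] <- tryCatch(
        switch(metric,
          correlation = pearson_fc(roi[[i]], roi[[j]]),
          cr_threshold = ,
          cr_zfr = suppressWarnings(
            conditional_rate(onsets[[i]], onsets[[j]], max_delay = max_delay,
                             allow_advance = allow_advance)
          ),
          hsnr = suppressWarnings(
            hsnr_correlation(roi[[i]], roi[[j]],
                             hsnr_regions(onsets[[i]], n_time = n_time, w = w))
          )
        ),
        error = function(e) NA_real_
      )
    }
  }
  structure(m, class = c("fc_matrix", "matrix", "array"), metric = metric)
}

#' @export
print.fc_matrix <- function(x, digits = 3, ...) {
  cat(sprintf("<fc_matrix> %d x %d, metric = %s\n", nrow(x), ncol(x),
              attr(x, "metric")))
  print(round(unclass(x), digits), ...)
  invisible(x)
}

#' @describeIn roi_connectivity long-format tibble with columns `seed`,
#'   `target`, `score`.
#' @param x an `fc_matrix`.
#' @param ... unused.
#' @export
tidy.fc_matrix <- function(x, ...) {
  tibble::tibble(
    seed = rep(rownames(x), times = ncol(x)),
    target = rep(colnames(x), each = nrow(x)),
    score = as.vector(unclass(x)),
    metric = attr(x, "metric")
  )
}
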