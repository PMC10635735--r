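#' Zero-frequency resonator filter
#'
#' Passes a BOLD time course through an ideal zero-frequency resonator, the
#' second-order system with a double pole at zero frequency defined by the
#' recurrence
#' \deqn{y[n] = m[n] + 2\,y[n-1] - y[n-2], \qquad y[-1] = y[-2] = 0,}
#' whose output is exactly the cumulative sum of the input applied twice.
#' An impulse in the input has equal energy at every frequency, including
#' zero, so its timing survives this drastic low-pass operation while the
#' haemodynamic response shape and wide-band noise are suppressed.  The
#' output grows polynomially with time; the event information lives in its
#' local fluctuations, which [remove_local_mean()] extracts.
#'
#' @param x numeric time course (or data frame with a `value` column).
#' @return numeric vector, the resonator output.
#' @examples
#' zfr_filter(c(1, 0, 0, 0, 0)) # ramp 1..5
#' @export
zfr_filter <- function(x) {
  v <- tc_values(x, "x")
  if (length(v) == 0L) abort("`x` must have at least one sample.")
  y <- cumsum(cumsum(v))
  if (any(abs(y) > 1e300)) {
    abort("zero-frequency resonator output exceeded 1e300; input too long or too large.")
  }
  y
}

#' Remove the local mean from a resonator output
#'
#' Subtracts a sliding-window mean from the resonator output to yield the
#' zero-frequency filtered signal
#' \deqn{z[n] = y[n] - \frac{1}{2N_1+1} \sum_{k=-N_1}^{N_1} y[n-k].}
#' The window holds `2 * n1 + 1` samples; at the series ends it is clipped
#' to the available samples and the mean taken over those, so no samples are
#' discarded (onsets that fall inside the first or last `n1` samples are
#' flagged as boundary-unreliable by [detect_onsets()]).
#'
#' @param y numeric resonator output (or data frame with a `value` column).
#' @param n1 half-window length in samples; the full window `2 * n1 + 1`
#'   must be shorter than the signal.  The package default is 15 for
#'   event-related designs and synthetic data, 11 for block designs.
#' @return numeric vector, the zero-frequency filtered signal.
#' @export
remove_local_mean <- function(y, n1 = 15) {
  v <- tc_values(y, "y")
  n1 <- check_count(n1, "n1")
  n <- length(v)
  if (2L * n1 + 1L >= n) {
    abort("window `2 * n1 + 1` must be smaller than the signal length.")
  }
  cs <- c(0, cumsum(v))
  lo <- pmax(seq_len(n) - n1, 1L)
  hi <- pmin(seq_len(n) + n1, n)
  v - (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Positive zero-crossings of a filtered signal
#'
#' An index `n` (0-based) is an onset iff `z[n - 1] < 0` and `z[n] >= 0`:
#' the signal changes sign from negative to non-negative, so a touch of zero
#' from below registers at the first non-negative sample.
#'
#' @param z numeric zero-frequency filtered signal (length >= 2).
#' @return integer vector of 0-based crossing indices, in increasing order.
#' @examples
#' positive_zero_crossings(c(-1, -0.5, 0.2, 1)) # 2
#' @export
positive_zero_crossings <- function(z) {
  v <- tc_values(z, "z")
  if (length(v) < 2L) abort("`z` must have at least 2 samples.")
  idx <- which(v[-length(v)] < 0 & v[-1L] >= 0)
  as.integer(idx) # R position idx+1 is the crossing => 0-based index = idx
}

#' Detect BOLD event onsets in a time course
#'
#' The `"zfr"` detector estimates event onsets without any knowledge of the
#' stimulus paradigm.  The course is differenced `diff_order` times (the
#' detrending step of zero-frequency filtering practice), passed through
#' the zero-frequency resonator ([zfr_filter()]), the local mean is removed
#' ([remove_local_mean()]), and the positive zero-crossings of the
#' resulting zero-frequency filtered signal mark the onsets
#' ([positive_zero_crossings()]).  A salience guard drops crossings whose
#' following positive excursion is negligible (area below `min_excursion`
#' standard deviations of the filtered signal): such shallow crossings come
#' from noise or from the small rebound at the offset of each response, not
#' from a neuronal event.  With the defaults the detected onset falls on
#' the rising edge of the response, about one TR after the true impulse.
#'
#' The `"threshold"` baseline standardizes the time course to zero mean and
#' unit variance and marks every upward crossing of the z-score threshold
#' (default 1); a contiguous supra-threshold plateau yields a single onset,
#' and sample 0 is an onset when it already sits at or above the threshold.
#'
#' ZFR onsets within the first or last `n1` samples are computed from a
#' clipped local-mean window and are flagged `boundary = TRUE`; they are
#' retained, not dropped.
#'
#' @param tc time course: tibble from [synthesize_bold()] or numeric vector.
#' @param detector `"zfr"` or `"threshold"`.
#' @param tr sampling interval in seconds (taken from `tc` when present).
#' @param n1 ZFR local-mean half-window in samples (default 15 for
#'   event-related and synthetic data; 11 is the usual block-design
#'   choice).
#' @param threshold z-score threshold for the baseline detector (default 1).
#' @param diff_order number of differencing passes before the resonator
#'   (default 2; 0 reproduces the raw resonator cascade).
#' @param min_excursion salience guard for zero-crossings, in standard
#'   deviations of the filtered signal (default 1.5; 0 disables).
#' @param discard_initial number of initial samples to drop before detection
#'   (magnetisation steady-state trimming; default 0).  Reported
#'   `sample_index` values stay on the trimmed series.
#' @return A tibble with columns `sample_index` (0-based), `time_s`,
#'   `detector`, `boundary`.
#' @examples
#' hrf <- canonical_hrf(tr = 2)
#' bold <- synthesize_bold(c(50), hrf, n_time = 150)
#' detect_onsets(bold, "zfr", n1 = 15)
#' @export
detect_onsets <- function(tc, detector = c("zfr", "threshold"), tr = NULL,
                          n1 = 15, threshold = 1, diff_order = 2,
                          min_excursion = 1.5, discard_initial = 0) {
  detector <- match.arg(detector)
  v <- tc_values(tc)
  tr <- tc_tr(tc, tr)
  discard_initial <- check_count(discard_initial, "discard_initial", min = 0L)
  if (discard_initial > 0L) {
    if (discard_initial >= length(v)) abort("`discard_initial` leaves no samples.")
    v <- v[-seq_len(discard_initial)]
  }
  if (length(v) < 3L) abort("time course must have at least 3 samples.")

  idx <- detect_indices(v, detector, n1 = n1, threshold = threshold,
                        diff_order = diff_order, min_excursion = min_excursion)
  boundary <- if (detector == "zfr") {
    idx < n1 | idx >= length(v) - n1
  } else {
    rep(FALSE, length(idx))
  }
  tibble::tibble(
    sample_index = as.integer(idx),
    time_s = idx * tr,
    detector = detector,
    boundary = boundary
  )
}

# Bare-vector detection path shared with the voxel-wise mappers, where
# building a tibble per voxel would dominate the run time.
detect_indices <- function(v, detector, n1 = 15, threshold = 1,
                           diff_order = 2, min_excursion = 1.5) {
  if (detector == "zfr") {
    n1 <- check_count(n1, "n1")
    detect_zfr_indices(v, n1 = n1, diff_order = diff_order,
                       min_excursion = min_excursion)
  } else {
    s <- sd(v)
    if (s == 0) abort("threshold detector needs a time course with nonzero variance.")
    zs <- (v - mean(v)) / s
    idx <- as.integer(which(zs[-1L] >= threshold & zs[-length(zs)] < threshold))
    if (zs[1L] >= threshold) idx <- c(0L, idx)
    idx
  }
}

# The ZFR onset estimator.
#
# 1. The course is differenced `diff_order` times (length-preserving; the
#    first sample is repeated so the pre-signal baseline stays exactly
#    zero).  Differencing removes the DC/drift content before the
#    zero-frequency resonator, as in zero-frequency filtering practice;
#    without it the double integrator turns every response into a monotone
#    ramp whose filtered signal crosses zero at the response OFFSET (one
#    local-mean window after the event), not at its onset.  With the
#    default two rounds the resonator-plus-local-mean cascade reduces
#    algebraically to subtracting the local mean from the course itself,
#    and the positive crossing lands on the rising edge of the
#    haemodynamic response, about one sample (one TR) after the impulse.
# 2. Double cumulative sum (the resonator) and local-mean removal.
# 3. Values below 1e-9 of the filtered signal's peak magnitude are snapped
#    to zero so exactly-flat stretches of a noiseless course cannot
#    produce floating-point zero-crossings.
# 4. Salience guard: a candidate crossing is kept only when the positive
#    excursion it initiates (the area of the following non-negative run of
#    z) reaches `min_excursion` standard deviations of z.  This suppresses
#    both the shallow offset echo of each response and noise-born
#    crossings; set min_excursion = 0 for the raw crossing rule.
detect_zfr_indices <- function(v, n1, diff_order = 2, min_excursion = 1.5) {
  if (diff_order < 0) abort("`diff_order` must be >= 0.")
  x <- v
  if (diff_order > 0) for (i in seq_len(diff_order)) x <- diff(c(x[1L], x))
  y <- zfr_filter(x)
  z <- remove_local_mean(y, n1 = n1)
  z[abs(z) < 1e-9 * max(abs(z))] <- 0
  idx <- positive_zero_crossings(z)
  if (length(idx) && min_excursion > 0) {
    lim <- min_excursion * sd(z)
    if (lim > 0) {
      runs <- rle(z >= 0)
      ends <- cumsum(runs$lengths)
      starts <- ends - runs$lengths + 1L
      run_of <- findInterval(idx + 1L, starts)
      areas <- vapply(seq_along(idx), function(m) {
        sum(z[(idx[m] + 1L):ends[run_of[m]]])
      }, numeric(1))
      idx <- idx[areas >= lim]
    }
  }
  idx
}
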