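#' Canonical double-gamma haemodynamic response function
#'
#' Samples the canonical HRF used throughout the package: the difference of
#' two gamma probability densities, one generating the positive response peak
#' and one the post-stimulus undershoot,
#' \deqn{h(t) = g(t;\, \alpha_1, \beta_1) - \frac{1}{r}\, g(t;\, \alpha_2, \beta_2),}
#' with shapes \eqn{\alpha_i = \mathrm{delay}_i / \mathrm{dispersion}_i} and
#' scales \eqn{\beta_i = \mathrm{dispersion}_i}.  The defaults (peak delay
#' 6 s, undershoot delay 16 s, unit dispersions, undershoot ratio 6, 32 s of
#' support) are the SPM convention.  The sampled kernel is scaled to unit
#' peak so that a unit impulse produces a response of amplitude 1.
#'
#' @param tr sampling interval in seconds (the fMRI repetition time).
#' @param duration kernel support in seconds; the kernel has
#'   `floor(duration / tr) + 1` samples at `t = 0, tr, 2 tr, ...`.
#' @param peak_delay,undershoot_delay delays of the response peak and the
#'   undershoot, in seconds.
#' @param dispersion_1,dispersion_2 dispersions (gamma scales) of the two
#'   components.
#' @param undershoot_ratio peak-to-undershoot amplitude ratio.
#' @return A tibble with columns `time_s` and `value` (unit peak).  Functions
#'   that consume an HRF accept this tibble or its bare `value` vector.
#' @examples
#' hrf <- canonical_hrf(tr = 0.5)
#' hrf$time_s[which.max(hrf$value)] # close to 5 s
#' @export
canonical_hrf <- function(tr, duration = 32,
                          peak_delay = 6, undershoot_delay = 16,
                          dispersion_1 = 1, dispersion_2 = 1,
                          undershoot_ratio = 6) {
  check_positive(tr, "tr")
  check_positive(duration, "duration")
  check_positive(peak_delay, "peak_delay")
  check_positive(undershoot_delay, "undershoot_delay")
  check_positive(dispersion_1, "dispersion_1")
  check_positive(dispersion_2, "dispersion_2")
  check_positive(undershoot_ratio, "undershoot_ratio")
  if (duration < tr) abort("`duration` must be at least one `tr`.")

  t <- seq(0, by = tr, length.out = floor(duration / tr) + 1L)
  h <- dgamma(t, shape = peak_delay / dispersion_1, scale = dispersion_1) -
    dgamma(t, shape = undershoot_delay / dispersion_2, scale = dispersion_2) /
      undershoot_ratio
  h <- h / max(h)
  out <- tibble::tibble(time_s = t, value = h)
  attr(out, "tr") <- tr
  out
}

# Coerce an HRF argument (tibble from canonical_hrf() or numeric vector)
# to the bare sampled kernel.
hrf_values <- function(hrf) {
  v <- tc_values(hrf, arg = "hrf")
  if (length(v) == 0L) abort("`hrf` kernel must be non-empty.")
  v
}
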