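#' Simulate a sparse impulse train of neuronal events
#'
#' Each of `n_time` samples is independently an event with probability
#' `prob`, the standard sparse-event model for task-free BOLD simulation
#' (default event probability 0.07 per sample).
#'
#' @param n_time number of samples in the time course.
#' @param prob per-sample event probability, strictly inside (0, 1).
#' @param amplitude per-event amplitude(s), positive; recycled to the number
#'   of events drawn.
#' @param seed optional integer seed for reproducible draws; when supplied
#'   the draw is made in a local RNG scope that does not disturb the global
#'   random stream.
#' @return A tibble with columns `sample_index` (0-based), `amplitude`, and
#'   an `n_time` attribute recording the train length.
#' @examples
#' simulate_impulse_train(150, prob = 0.07, seed = 1)
#' @export
simulate_impulse_train <- function(n_time, prob, amplitude = 1, seed = NULL) {
  n_time <- check_count(n_time, "n_time")
  check_probability(prob)
  if (any(amplitude <= 0)) abort("`amplitude` must be positive.")
  draw <- function() which(rbinom(n_time, 1L, prob) == 1L) - 1L
  onsets <- if (is.null(seed)) draw() else with_seed(seed, draw())
  out <- tibble::tibble(
    sample_index = as.integer(onsets),
    amplitude = rep_len(as.numeric(amplitude), length(onsets))
  )
  attr(out, "n_time") <- n_time
  out
}

# Evaluate `expr` under `seed` without touching the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Describe the additive noise of a simulated BOLD signal
#'
#' Two models are supported.  `"white_gaussian"` adds independent
#' `N(0, sigma^2)` noise.  `"rician"` replaces each sample by the magnitude
#' of a complex Gaussian perturbation,
#' `sqrt((x + sigma * e1)^2 + (sigma * e2)^2)`, the standard model for MRI
#' magnitude images; its level is set through the contrast-to-noise ratio
#' `cnr`, defined here as (peak clean amplitude above baseline) / sigma.
#'
#' @param kind `"white_gaussian"` or `"rician"`.
#' @param sigma noise standard deviation in signal units (Gaussian model).
#' @param cnr contrast-to-noise ratio (Rician model); `sigma` is derived from
#'   the clean signal at application time as `peak_amplitude / cnr`.
#' @param seed optional integer seed.
#' @return A list of class `noise_spec`.
#' @export
noise_spec <- function(kind = c("white_gaussian", "rician"),
                       sigma = NULL, cnr = NULL, seed = NULL) {
  kind <- match.arg(kind)
  if (kind == "white_gaussian") {
    if (is.null(sigma)) abort("white_gaussian noise needs `sigma`.")
    check_positive(sigma, "sigma")
  } else {
    if (is.null(cnr)) abort("rician noise needs `cnr`.")
    check_positive(cnr, "cnr")
  }
  structure(list(kind = kind, sigma = sigma, cnr = cnr, seed = seed),
            class = "noise_spec")
}

# Apply a noise_spec to a clean signal. `baseline` is subtracted before the
# peak amplitude that defines the Rician CNR is measured.
apply_noise <- function(clean, noise, baseline = 0) {
  if (is.null(noise)) return(clean)
  if (!inherits(noise, "noise_spec")) abort("`noise` must come from noise_spec().")
  n <- length(clean)
  run <- function() {
    if (noise$kind == "white_gaussian") {
      clean + rnorm(n, sd = noise$sigma)
    } else {
      peak <- max(abs(clean - baseline))
      if (peak == 0) peak <- 1 # flat signal: interpret CNR against unit contrast
      sigma <- peak / noise$cnr
      sqrt((clean + sigma * rnorm(n))^2 + (sigma * rnorm(n))^2)
    }
  }
  if (is.null(noise$seed)) run() else with_seed(noise$seed, run())
}

#' Synthesize a BOLD time course from an impulse train
#'
#' Implements the forward model `m[n] = s[n] * h[n] + e[n]`: the impulse
#' train is convolved with the sampled HRF kernel (zero-padded linear
#' convolution truncated to the train length) and noise is added according
#' to `noise`.
#'
#' @param impulses impulse train: a tibble from [simulate_impulse_train()] or
#'   a numeric vector of 0-based onset indices.
#' @param hrf sampled HRF kernel ([canonical_hrf()] tibble or numeric vector).
#' @param tr sampling interval in seconds; taken from `hrf` when it is a
#'   [canonical_hrf()] tibble.
#' @param n_time output length in samples; defaults to the train's recorded
#'   length.
#' @param noise optional [noise_spec()]; `NULL` for a noiseless course.
#' @param baseline constant added to the clean signal.
#' @return A tibble with columns `sample_index`, `time_s`, `value` and
#'   `clean` (the noiseless signal, so `value - clean` is the realised
#'   noise for additive models).
#' @examples
#' hrf <- canonical_hrf(tr = 2)
#' bold <- synthesize_bold(c(10, 40), hrf, n_time = 100)
#' @export
synthesize_bold <- function(impulses, hrf, tr = NULL, n_time = NULL,
                            noise = NULL, baseline = 0) {
  idx <- onset_indices(impulses, "impulses")
  amp <- if (is.data.frame(impulses) && "amplitude" %in% names(impulses)) {
    impulses$amplitude
  } else {
    rep(1, length(idx))
  }
  n_time <- n_time %||% attr(impulses, "n_time", exact = TRUE)
  if (is.null(n_time)) abort("`n_time` must be given when `impulses` does not record one.")
  n_time <- check_count(n_time, "n_time")
  if (length(idx) && max(idx) >= n_time) {
    abort("impulse indices must lie in [0, n_time).")
  }
  tr <- tc_tr(hrf, tr)
  kernel <- hrf_values(hrf)

  clean <- rep(baseline, n_time)
  for (i in seq_along(idx)) {
    # exact sparse convolution: add the shifted, scaled kernel
    pos <- (idx[i] + 1L):min(n_time, idx[i] + length(kernel))
    clean[pos] <- clean[pos] + amp[i] * kernel[seq_along(pos)]
  }
  values <- apply_noise(clean, noise, baseline = baseline)
  timecourse_tibble(values, tr, clean = clean)
}

# Zero-padded linear convolution truncated to length(x).  Computed directly
# over the nonzero input samples: impulse trains are sparse, and the direct
# sum keeps zero stretches exactly zero (an FFT route leaves ~1e-16 residue
# that the double integrator in zfr_filter() would amplify).
convolve_truncate <- function(x, kernel) {
  out <- numeric(length(x))
  for (i in which(x != 0)) {
    pos <- i:min(length(x), i + length(kernel) - 1L)
    out[pos] <- out[pos] + x[i] * kernel[seq_along(pos)]
  }
  out
}

#' Build a stimulus function from known stimulus timings
#'
#' Convolves the experimental stimulus train with the canonical HRF to give
#' the noiseless reference time course used as the seed for paradigm-driven
#' connectivity maps.
#'
#' @inheritParams synthesize_bold
#' @param stimuli stimulus train (tibble with `sample_index` or numeric
#'   vector of 0-based indices).
#' @return A tibble time course (`sample_index`, `time_s`, `value`, `clean`).
#' @export
stimulus_function <- function(stimuli, hrf, tr = NULL, n_time = NULL) {
  synthesize_bold(stimuli, hrf, tr = tr, n_time = n_time, noise = NULL)
}
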