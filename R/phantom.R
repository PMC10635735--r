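#' Simulate a two-dimensional multi-component BOLD phantom
#'
#' Builds a small 4-D-style dataset (2-D voxel grid x time) in which each
#' spatial component carries its own sparse event train: every voxel time
#' course is
#' \deqn{v(x, t) = \mathrm{baseline} + \sum_c w_c(x)\, (s_c * h)(t) + \varepsilon,}
#' a linear combination of component time courses (impulse train convolved
#' with the canonical HRF) weighted by the component's spatial profile, plus
#' noise.  Ground-truth masks and impulse trains are returned exactly as
#' used, so every downstream stage can be scored against them.
#'
#' Components are circular blobs.  With `shape = "disk"` (default) the
#' weight is 1 inside `radius` and 0 outside, so the ground-truth mask is
#' unambiguous; `shape = "gaussian"` tapers the weight as
#' `exp(-d^2 / (2 (radius/2)^2))` truncated at the mask edge.  Inter-subject
#' variability is emulated by jittering each component's centre
#' (`jitter_center_sd`, voxels) and radius (`jitter_radius_frac`,
#' fractional), mirroring spatial variability in translation and spread.
#'
#' Defaults follow the package's reference simulation conditions: a
#' 100 x 100 grid, 150 time points at TR 2 s, two components with
#' per-sample event probability 0.07, and Rician noise at a
#' contrast-to-noise ratio between 0.65 and 1.
#'
#' @param grid 2-element integer vector, the in-plane voxel dimensions.
#' @param n_time number of time points.
#' @param tr repetition time in seconds.
#' @param components list of component descriptions, each a list with
#'   `center` (x, y voxel coordinates, 1-based), `radius` (voxels), `prob`
#'   (per-sample event probability) and optional `amplitude` (default 1).
#' @param baseline constant tissue baseline added to every voxel.
#' @param noise optional [noise_spec()].  For Rician noise the sigma is set
#'   globally from the strongest component amplitude above baseline:
#'   `sigma = peak / cnr`.
#' @param shape `"disk"` or `"gaussian"` spatial weight profile.
#' @param jitter_center_sd,jitter_radius_frac per-subject spatial jitter
#'   (0 = reproduce the nominal geometry).
#' @param seed integer seed driving events, jitter and noise.
#' @return An object of class `bold_phantom`: a list with `data` (array
#'   `grid[1] x grid[2] x n_time`), `masks` (list of logical matrices, one
#'   per component), `onsets` (tibble with `component`, `sample_index`,
#'   `time_s`), `component_tc` (tibble of noiseless component time courses),
#'   `tr`, `baseline`, and the realised component geometry.
#' @examples
#' ph <- simulate_phantom(grid = c(20, 20), n_time = 60,
#'                        components = list(
#'                          list(center = c(6, 10), radius = 4, prob = 0.07),
#'                          list(center = c(15, 10), radius = 4, prob = 0.07)),
#'                        noise = NULL, seed = 1)
#' dim(ph$data)
#' @export
simulate_phantom <- function(grid = c(100, 100), n_time = 150, tr = 2,
                             components = list(
                               list(center = c(27, 50), radius = 20, prob = 0.07),
                               list(center = c(73, 50), radius = 20, prob = 0.07)
                             ),
                             baseline = 10, noise = noise_spec("rician", cnr = 1),
                             shape = c("disk", "gaussian"),
                             jitter_center_sd = 0, jitter_radius_frac = 0,
                             seed = NULL) {
  shape <- match.arg(shape)
  if (length(grid) != 2L) abort("`grid` must give two in-plane dimensions.")
  nx <- check_count(grid[1L], "grid[1]"); ny <- check_count(grid[2L], "grid[2]")
  n_time <- check_count(n_time, "n_time", min = 2L)
  check_positive(tr, "tr")
  if (length(components) < 1L) abort("at least one component is required.")

  run <- function() {
    hrf <- canonical_hrf(tr = tr)
    if (n_time < 2L * nrow(hrf)) {
      warn("n_time is shorter than twice the HRF support; responses will overlap heavily.")
    }
    xs <- matrix(rep(seq_len(nx), ny), nx, ny)
    ys <- matrix(rep(seq_len(ny), each = nx), nx, ny)

    masks <- list(); weights <- list(); trains <- list(); geom <- list()
    clean_tc <- matrix(0, n_time, length(components))
    for (ci in seq_along(components)) {
      cmp <- components[[ci]]
      check_probability(cmp$prob, "component prob")
      center <- cmp$center + stats::rnorm(2L, sd = jitter_center_sd)
      radius <- cmp$radius * (1 + stats::rnorm(1L, sd = jitter_radius_frac))
      if (radius <= 0) abort("component radius must remain positive after jitter.")
      d2 <- (xs - center[1L])^2 + (ys - center[2L])^2
      mask <- d2 <= radius^2
      if (!any(mask)) abort("component mask is empty: blob falls outside the grid.")
      w <- if (shape == "disk") {
        mask * 1
      } else {
        ifelse(mask, exp(-d2 / (2 * (radius / 2)^2)), 0)
      }
      amp <- cmp$amplitude %||% 1
      train <- which(rbinom(n_time, 1L, cmp$prob) == 1L) - 1L
      clean_tc[, ci] <- amp * convolve_truncate(
        { s <- numeric(n_time); s[train + 1L] <- 1; s }, hrf$value
      )
      masks[[ci]] <- mask
      weights[[ci]] <- w
      trains[[ci]] <- train
      geom[[ci]] <- list(center = center, radius = radius, prob = cmp$prob,
                         amplitude = amp)
    }

    data <- array(baseline, dim = c(nx, ny, n_time))
    for (ci in seq_along(components)) {
      wv <- as.vector(weights[[ci]])
      idx <- which(wv > 0)
      if (length(idx)) {
        # outer product: voxels x time contribution of this component
        contrib <- outer(wv[idx], clean_tc[, ci])
        flat <- matrix(data, nx * ny, n_time)
        flat[idx, ] <- flat[idx, ] + contrib
        data <- array(flat, dim = c(nx, ny, n_time))
      }
    }

    if (!is.null(noise)) {
      if (!inherits(noise, "noise_spec")) abort("`noise` must come from noise_spec().")
      if (noise$kind == "white_gaussian") {
        data <- data + array(rnorm(length(data), sd = noise$sigma), dim = dim(data))
      } else {
        peak <- max(vapply(seq_along(components),
                           function(ci) geom[[ci]]$amplitude * max(abs(clean_tc[, ci])),
                           numeric(1)))
        if (peak == 0) peak <- 1
        sigma <- peak / noise$cnr
        data <- sqrt((data + array(rnorm(length(data), sd = sigma), dim = dim(data)))^2 +
                       array(rnorm(length(data), sd = sigma), dim = dim(data))^2)
      }
    }

    onsets <- purrr::map_dfr(seq_along(trains), function(ci) {
      tibble::tibble(component = ci, sample_index = as.integer(trains[[ci]]),
                     time_s = trains[[ci]] * tr)
    })
    structure(list(
      data = data, masks = masks,
      onsets = onsets,
      component_tc = purrr::map_dfr(seq_len(ncol(clean_tc)), function(ci) {
        dplyr::mutate(timecourse_tibble(clean_tc[, ci], tr), component = ci)
      }),
      tr = tr, baseline = baseline, noise = noise, geometry = geom, seed = seed
    ), class = "bold_phantom")
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

#' @export
print.bold_phantom <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<bold_phantom> %d x %d voxels, %d time points (TR %g s), %d components\n",
              d[1], d[2], d[3], x$tr, length(x$masks)))
  cat(sprintf("  baseline %g, noise: %s\n", x$baseline,
              if (is.null(x$noise)) "none" else x$noise$kind))
  counts <- table(factor(x$onsets$component, levels = seq_along(x$masks)))
  cat("  events per component:", paste(counts, collapse = ", "), "\n")
  invisible(x)
}

#' Ground-truth component time course of a phantom
#'
#' @param phantom a `bold_phantom`.
#' @param component component number.
#' @return tibble time course of the noiseless component response
#'   (`sample_index`, `time_s`, `value`).
#' @export
phantom_component_tc <- function(phantom, component = 1) {
  stopifnot(inherits(phantom, "bold_phantom"))
  out <- dplyr::filter(phantom$component_tc, .data$component == !!component)
  out <- dplyr::select(out, -"component")
  attr(out, "tr") <- phantom$tr
  out
}
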