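#' Construct a functional-connectivity volume
#'
#' A thin container pairing voxel-wise scores with an in-brain mask.
#' Scores are defined only inside the mask; voxels where the metric is
#' undefined (e.g. zero variance, onset-free seed) hold `NA`.
#'
#' @param values numeric array of voxel scores (2-D or 3-D grid).
#' @param mask logical array of the same dimensions; `NULL` means every
#'   voxel is in-brain.
#' @param metric character tag recording how the scores were computed.
#' @return An object of class `fc_volume`.
#' @export
fc_volume <- function(values, mask = NULL, metric = "unknown") {
  if (is.null(dim(values))) abort("`values` must be an array with dimensions.")
  if (is.null(mask)) mask <- array(TRUE, dim = dim(values))
  if (!identical(dim(mask), dim(values))) abort("`mask` and `values` dimensions differ.")
  values[!mask] <- NA_real_
  structure(list(values = values, mask = mask, metric = metric),
            class = "fc_volume")
}

#' @export
print.fc_volume <- function(x, ...) {
  v <- x$values[x$mask]
  cat(sprintf("<fc_volume> %s grid, metric = %s\n",
              paste(dim(x$values), collapse = " x "), x$metric))
  cat(sprintf("  %d in-mask voxels (%d undefined); range [%g, %g]\n",
              sum(x$mask), sum(is.na(v)),
              suppressWarnings(min(v, na.rm = TRUE)),
              suppressWarnings(max(v, na.rm = TRUE))))
  invisible(x)
}

#' @describeIn fc_volume long tibble with voxel coordinates (`x`, `y` and,
#'   for 3-D grids, `z`), `value` and `in_mask`.
#' @param x an `fc_volume`.
#' @param ... unused.
#' @export
tidy.fc_volume <- function(x, ...) {
  d <- dim(x$values)
  coords <- arrayInd(seq_along(x$values), d)
  out <- tibble::tibble(x = coords[, 1L], y = coords[, 2L])
  if (length(d) >= 3L) out$z <- coords[, 3L]
  out$value <- as.vector(x$values)
  out$in_mask <- as.vector(x$mask)
  out
}

# Resolve 4-D-style inputs (bold_phantom, 3-D array [x, y, t], 4-D array
# [x, y, z, t]) into a voxels-by-time matrix plus grid metadata.
flatten_dataset <- function(data, mask = NULL) {
  if (inherits(data, "bold_phantom")) data <- data$data
  d <- dim(data)
  if (is.null(d) || length(d) < 3L) abort("`data` must be a 3-D (x, y, t) or 4-D (x, y, z, t) array.")
  grid <- d[-length(d)]
  nt <- d[length(d)]
  if (is.null(mask)) mask <- array(TRUE, dim = grid)
  if (!identical(as.integer(dim(mask)), as.integer(grid))) abort("`mask` does not match the data grid.")
  list(mat = matrix(data, prod(grid), nt), grid = grid, mask = mask, n_time = nt)
}

#' Seed-based voxel-wise connectivity map
#'
#' Scores every in-mask voxel time course against a seed time course under
#' the chosen metric: full-length Pearson `"correlation"`, conditional rate
#' of onsets detected with the threshold (`"cr_threshold"`) or ZFR
#' (`"cr_zfr"`) detector, or the HSNR-region aggregated correlation
#' (`"hsnr"`).  The seed may be a measured voxel/ROI time course or a
#' stimulus function built with [stimulus_function()].  For the CR metrics
#' the seed's onsets are detected once with the same detector as the
#' targets; for `"hsnr"` the windows are derived once from the seed's ZFR
#' onsets and the same temporal regions are used in every target.
#'
#' @param data a `bold_phantom`, a 3-D array (x, y, time), or a 4-D array
#'   (x, y, z, time).
#' @param seed_tc seed time course (tibble with `value` or numeric vector)
#'   of length equal to the data's time dimension.
#' @param metric one of `"correlation"`, `"cr_threshold"`, `"cr_zfr"`,
#'   `"hsnr"`.
#' @param mask optional logical array selecting in-brain voxels.
#' @param n1,threshold detector parameters (see [detect_onsets()]).
#' @param max_delay,allow_advance CR matching policy; advances are allowed
#'   by default only when the caller says the seed is an external reference.
#' @param w HSNR window length.
#' @return An [fc_volume()] whose `values` hold the per-voxel scores.
#' @export
seed_map <- function(data, seed_tc,
                     metric = c("correlation", "cr_threshold", "cr_zfr", "hsnr"),
                     mask = NULL, n1 = 15, threshold = 1,
                     max_delay = 2, allow_advance = FALSE, w = 6) {
  metric <- match.arg(metric)
  fl <- flatten_dataset(data, mask)
  seed <- tc_values(seed_tc, "seed_tc")
  if (length(seed) != fl$n_time) abort("`seed_tc` length must equal the data time dimension.")
  voxels <- which(as.vector(fl$mask))
  if (length(voxels) == 0L) abort("mask selects no voxels.")

  detector <- switch(metric, cr_threshold = "threshold", cr_zfr = "zfr", NULL)
  seed_onsets <- regions <- NULL
  if (metric %in% c("cr_zfr", "cr_threshold")) {
    seed_onsets <- detect_indices(seed, detector, n1 = n1, threshold = threshold)
  } else if (metric == "hsnr") {
    seed_onsets <- detect_indices(seed, "zfr", n1 = n1)
    regions <- hsnr_regions(seed_onsets, n_time = fl$n_time, w = w)
  }

  score_one <- function(v) {
    switch(metric,
      correlation = if (sd(v) == 0) NA_real_ else cor(seed, v),
      cr_threshold = ,
      cr_zfr = {
        if (length(seed_onsets) == 0L || sd(v) == 0) return(NA_real_)
        tgt <- detect_indices(v, detector, n1 = n1, threshold = threshold)
        match_onsets(seed_onsets, tgt, max_delay = max_delay,
                     allow_advance = allow_advance) / length(seed_onsets)
      },
      hsnr = suppressWarnings(
        tryCatch(hsnr_correlation(seed, v, regions), error = function(e) NA_real_)
      )
    )
  }
  vals <- rep(NA_real_, nrow(fl$mat))
  vals[voxels] <- vapply(voxels, function(i) {
    tryCatch(score_one(fl$mat[i, ]), error = function(e) NA_real_)
  }, numeric(1))
  fc_volume(array(vals, dim = fl$grid), mask = fl$mask, metric = metric)
}

#' Min-max normalize a connectivity volume
#'
#' Rescales the defined voxel scores to `(v - min) / (max - min)`, so the
#' output spans exactly `[0, 1]` (at least one 0 and one 1) and voxel rank
#' order is preserved.  A constant volume maps to all zeros with a warning.
#'
#' @param vol an [fc_volume()].
#' @return an `fc_volume` on the [0, 1] scale.
#' @export
minmax_normalize <- function(vol) {
  stopifnot(inherits(vol, "fc_volume"))
  v <- vol$values
  defined <- !is.na(v)
  if (!any(defined)) abort("volume has no defined values.")
  rng <- range(v[defined])
  if (rng[1L] == rng[2L]) {
    warn("constant volume: min-max normalization maps it to all zeros.")
    v[defined] <- 0
  } else {
    v[defined] <- (v[defined] - rng[1L]) / (rng[2L] - rng[1L])
  }
  fc_volume(v, mask = vol$mask, metric = paste0(vol$metric, "_minmax"))
}

#' Keep the top fraction of voxels of a connectivity volume
#'
#' Selects the `ceiling(fraction * n_defined)` highest-scoring defined
#' voxels (default top 20%).  Ties at the cutoff are all included, so the
#' selection is deterministic regardless of sort order and may slightly
#' exceed the nominal count.  Undefined voxels never enter the ranking.
#'
#' @param vol an [fc_volume()].
#' @param fraction fraction of defined voxels to keep, in (0, 1].
#' @return logical array of the volume's dimensions (the binary mask).
#' @export
top_fraction_threshold <- function(vol, fraction = 0.2) {
  stopifnot(inherits(vol, "fc_volume"))
  if (!is.numeric(fraction) || length(fraction) != 1L || is.na(fraction) ||
      fraction <= 0 || fraction > 1) {
    abort("`fraction` must lie in (0, 1].")
  }
  v <- vol$values
  defined <- which(!is.na(v))
  if (length(defined) == 0L) abort("volume has no defined values.")
  k <- ceiling(fraction * length(defined))
  cutoff <- sort(v[defined], decreasing = TRUE)[k]
  out <- array(FALSE, dim = dim(v))
  out[defined] <- v[defined] >= cutoff
  out
}

#' Remove small clusters from a binary activation mask
#'
#' Computes connected components of the active voxels and removes
#' components smaller than `min_cluster_size` — the standard cluster-extent
#' rule (default 16 voxels for acquired 3-D data, 8 for 2-D synthetic
#' slices).  Connectivity is `"full"` (8-neighbourhood in 2-D,
#' 26-neighbourhood in 3-D) or `"orthogonal"` (4- / 6-neighbourhood).
#' `rule = "neighbor_count"` gives the alternative per-voxel reading, in
#' which an active voxel survives only if it has at least
#' `min_cluster_size` active neighbours.
#'
#' @param mask logical array (2-D or 3-D).
#' @param min_cluster_size minimum component size (or neighbour count), >= 1.
#' @param connectivity `"full"` or `"orthogonal"`.
#' @param rule `"component_size"` (default) or `"neighbor_count"`.
#' @return logical array; always a subset of the input mask.
#' @export
cluster_filter <- function(mask, min_cluster_size = 16,
                           connectivity = c("full", "orthogonal"),
                           rule = c("component_size", "neighbor_count")) {
  connectivity <- match.arg(connectivity)
  rule <- match.arg(rule)
  min_cluster_size <- check_count(min_cluster_size, "min_cluster_size")
  if (is.null(dim(mask))) abort("`mask` must be an array on a regular grid.")
  d <- dim(mask)
  if (!length(d) %in% c(2L, 3L)) abort("`mask` must be 2-D or 3-D.")
  active <- which(as.vector(mask))
  if (length(active) == 0L) return(array(FALSE, dim = d))

  offsets <- neighbor_offsets(length(d), connectivity)
  coords <- arrayInd(active, d)
  pos <- integer(prod(d)); pos[active] <- seq_along(active)

  if (rule == "neighbor_count") {
    counts <- integer(length(active))
    for (r in seq_len(nrow(offsets))) {
      nb <- sweep(coords, 2L, offsets[r, ], `+`)
      ok <- rowSums(nb >= 1L & nb <= matrix(d, nrow(nb), length(d), byrow = TRUE)) == length(d)
      lin <- integer(length(active))
      lin[ok] <- linear_index(nb[ok, , drop = FALSE], d)
      counts <- counts + (ok & lin > 0 & pos[pmax(lin, 1L)] > 0)
    }
    keep <- active[counts >= min_cluster_size]
    out <- array(FALSE, dim = d); out[keep] <- TRUE
    return(out)
  }

  # component rule: adjacency graph of active voxels -> igraph components
  edges <- list()
  for (r in seq_len(nrow(offsets))) {
    off <- offsets[r, ]
    if (positive_offset(off)) { # each undirected pair once
      nb <- sweep(coords, 2L, off, `+`)
      ok <- rowSums(nb >= 1L & nb <= matrix(d, nrow(nb), length(d), byrow = TRUE)) == length(d)
      if (!any(ok)) next
      lin <- linear_index(nb[ok, , drop = FALSE], d)
      hit <- pos[lin] > 0
      if (any(hit)) {
        edges[[length(edges) + 1L]] <- cbind(which(ok)[hit], pos[lin][hit])
      }
    }
  }
  g <- igraph::make_empty_graph(n = length(active), directed = FALSE)
  if (length(edges)) g <- igraph::add_edges(g, t(do.call(rbind, edges)))
  comp <- igraph::components(g)
  keep_comp <- which(comp$csize >= min_cluster_size)
  keep <- active[comp$membership %in% keep_comp]
  out <- array(FALSE, dim = d); out[keep] <- TRUE
  out
}

neighbor_offsets <- function(ndim, connectivity) {
  g <- as.matrix(expand.grid(rep(list(-1:1), ndim)))
  g <- g[rowSums(g != 0) > 0, , drop = FALSE]
  if (connectivity == "orthogonal") g <- g[rowSums(g != 0) == 1, , drop = FALSE]
  g
}

# lexicographically positive offsets enumerate each undirected pair once
positive_offset <- function(off) {
  nz <- off[off != 0]
  length(nz) > 0 && nz[1L] > 0
}

linear_index <- function(coords, d) {
  idx <- coords[, 1L]
  mult <- 1L
  for (k in seq_along(d)[-1L]) {
    mult <- mult * d[k - 1L]
    idx <- idx + (coords[, k] - 1L) * mult
  }
  idx
}

#' Average connectivity volumes across subjects
#'
#' Voxel-wise mean over a list of volumes on identical grids.  Voxels
#' undefined in some subjects are averaged over the available ones provided
#' at least `min_count` subjects contribute (default: all of them,
#' otherwise the voxel is `NA`).
#'
#' @param volumes list of [fc_volume()] objects with identical grids.
#' @param min_count minimum number of contributing subjects per voxel;
#'   `NULL` means all subjects.
#' @return an `fc_volume` of the group mean.
#' @export
group_average <- function(volumes, min_count = NULL) {
  if (!is.list(volumes) || length(volumes) < 1L ||
      !all(vapply(volumes, inherits, logical(1), "fc_volume"))) {
    abort("`volumes` must be a non-empty list of fc_volume objects.")
  }
  dims <- lapply(volumes, function(v) dim(v$values))
  if (length(unique(dims)) != 1L) abort("volumes are on different grids.")
  min_count <- min_count %||% length(volumes)
  stack <- vapply(volumes, function(v) as.vector(v$values),
                  numeric(length(volumes[[1L]]$values)))
  stack <- matrix(stack, ncol = length(volumes))
  n_avail <- rowSums(!is.na(stack))
  mean_v <- rowMeans(stack, na.rm = TRUE)
  mean_v[n_avail < min_count | n_avail == 0L] <- NA_real_
  mask <- Reduce(`|`, lapply(volumes, function(v) v$mask))
  fc_volume(array(mean_v, dim = dims[[1L]]), mask = mask,
            metric = paste0("group_mean_", volumes[[1L]]$metric))
}
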