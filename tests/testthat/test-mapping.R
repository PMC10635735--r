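small_phantom <- function(seed = 2, noise = NULL) {
  simulate_phantom(
    grid = c(20, 20), n_time = 100,
    components = list(list(center = c(6, 10), radius = 4, prob = 0.07),
                      list(center = c(15, 10), radius = 4, prob = 0.07)),
    baseline = 5, noise = noise, seed = seed
  )
}

test_that("correlation seed map scores component voxels at 1 when noiseless", {
  ph <- small_phantom()
  vol <- seed_map(ph, phantom_component_tc(ph, 1), metric = "correlation")
  expect_equal(unname(vol$values[ph$masks[[1]]]),
               rep(1, sum(ph$masks[[1]])), tolerance = 1e-12)
  # baseline-only voxels have zero variance: undefined, not 0
  expect_true(all(is.na(vol$values[!(ph$masks[[1]] | ph$masks[[2]])])))
})

test_that("CR seed map ranks the seeded component above the other", {
  ph <- small_phantom(seed = 3, noise = noise_spec("rician", cnr = 1))
  stc <- stimulus_function(ph$onsets$sample_index[ph$onsets$component == 1],
                           canonical_hrf(tr = 2), n_time = 100)
  vol <- seed_map(ph, stc, metric = "cr_zfr", allow_advance = TRUE)
  expect_gt(mean(vol$values[ph$masks[[1]]], na.rm = TRUE),
            mean(vol$values[ph$masks[[2]]], na.rm = TRUE))
  expect_true(all(vol$values[!is.na(vol$values)] >= 0 &
                    vol$values[!is.na(vol$values)] <= 1))
})

test_that("a constant dataset yields an all-missing map", {
  const <- array(7, dim = c(5, 5, 40))
  vol <- seed_map(const, rnorm(40), metric = "correlation")
  expect_true(all(is.na(vol$values)))
})

test_that("min-max normalization spans [0,1] and preserves ranks", {
  vol <- fc_volume(array(c(2, 4, 6, NA), dim = c(2, 2)),
                   mask = array(c(TRUE, TRUE, TRUE, FALSE), dim = c(2, 2)))
  norm <- minmax_normalize(vol)
  expect_equal(as.vector(norm$values)[1:3], c(0, 0.5, 1))
  expect_true(is.na(norm$values[2, 2]))
  # idempotent on already-normalized input
  expect_equal(minmax_normalize(norm)$values, norm$values)
  withr::with_seed(4, {
    v <- fc_volume(array(rnorm(100), dim = c(10, 10)))
    n <- minmax_normalize(v)
    expect_equal(rank(as.vector(v$values)), rank(as.vector(n$values)))
    expect_equal(range(n$values), c(0, 1))
  })
  expect_warning(z <- minmax_normalize(fc_volume(array(3, dim = c(2, 2)))), "constant")
  expect_equal(as.vector(z$values), rep(0, 4))
})

test_that("top-fraction threshold keeps the highest voxels with inclusive ties", {
  vol <- fc_volume(array(as.numeric(1:10), dim = c(10, 1)))
  mask <- top_fraction_threshold(vol, 0.3)
  expect_equal(which(mask), 8:10)
  expect_equal(sum(top_fraction_threshold(vol, 1)), 10)
  # ties at the cutoff are all included
  tied <- fc_volume(array(c(1, 2, 3, 3, 3, 0), dim = c(6, 1)))
  expect_equal(sum(top_fraction_threshold(tied, 1 / 3)), 3)
  expect_error(top_fraction_threshold(vol, 0), "fraction")
  expect_error(top_fraction_threshold(vol, 1.2), "fraction")
  withr::with_seed(6, {
    v <- fc_volume(array(rnorm(400), dim = c(20, 20)))
    expect_gte(sum(top_fraction_threshold(v, 0.2)), 80)
  })
})

test_that("cluster filtering removes small components", {
  m <- array(FALSE, c(12, 12))
  m[2, 2] <- TRUE                 # isolated voxel
  m[5:7, 5:10] <- TRUE            # 18-voxel block
  out <- cluster_filter(m, min_cluster_size = 16)
  expect_false(out[2, 2])
  expect_equal(sum(out), 18)
  # both removed at a larger threshold
  expect_equal(sum(cluster_filter(m, min_cluster_size = 19)), 0)
  # empty mask passes through
  expect_equal(sum(cluster_filter(array(FALSE, c(4, 4)), 2)), 0)
})

test_that("cluster filtering agrees with a flood-fill oracle", {
  withr::with_seed(7, {
    for (i in 1:5) {
      m <- array(runif(20 * 20) < 0.25, dim = c(20, 20))
      lab <- oracle_components(m)
      sizes <- tabulate(lab)
      expected <- array(FALSE, dim = dim(m))
      expected[lab > 0 & sizes[pmax(lab, 1)] >= 8] <- TRUE
      expect_equal(cluster_filter(m, min_cluster_size = 8), expected)
    }
    # 3-D case
    a <- array(runif(10 * 10 * 4) < 0.2, dim = c(10, 10, 4))
    lab <- oracle_components(a)
    sizes <- tabulate(lab)
    expected <- array(FALSE, dim = dim(a))
    expected[lab > 0 & sizes[pmax(lab, 1)] >= 16] <- TRUE
    expect_equal(cluster_filter(a, min_cluster_size = 16), expected)
  })
})

test_that("the per-voxel neighbour-count reading is available", {
  m <- array(TRUE, c(4, 4))
  # interior voxels of a 4x4 full mask have 8 active neighbours, corners 3
  out <- cluster_filter(m, min_cluster_size = 8, rule = "neighbor_count")
  expect_equal(which(out), which(array(c(FALSE, FALSE, FALSE, FALSE,
                                         FALSE, TRUE, TRUE, FALSE,
                                         FALSE, TRUE, TRUE, FALSE,
                                         FALSE, FALSE, FALSE, FALSE), c(4, 4))))
})

test_that("threshold-then-cluster is a contraction of the mask", {
  withr::with_seed(8, {
    v <- fc_volume(array(rnorm(900), dim = c(30, 30)))
    top <- top_fraction_threshold(minmax_normalize(v), 0.2)
    act <- cluster_filter(top, min_cluster_size = 8)
    expect_true(all(top[act]))
    expect_lte(sum(act), sum(top))
  })
})

test_that("group averaging is voxel-wise with a minimum-count rule", {
  a <- fc_volume(array(c(1, 2, 3, 4), dim = c(2, 2)))
  b <- fc_volume(array(c(3, 2, 1, NA), dim = c(2, 2)))
  expect_equal(group_average(list(a, a))$values, a$values)
  neg <- fc_volume(-a$values)
  expect_equal(as.vector(group_average(list(a, neg))$values), rep(0, 4))
  avg <- group_average(list(a, b))
  expect_true(is.na(avg$values[2, 2])) # missing in one subject, default all
  relaxed <- group_average(list(a, b), min_count = 1)
  expect_equal(relaxed$values[2, 2], 4)
  expect_error(group_average(list(a, fc_volume(array(1, dim = c(3, 3))))), "grids")
})

test_that("the full pipeline recovers phantom components from averaged CRMs", {
  # scaled-down version of the reference simulation: 40x40 grid, 3 subjects
  comps <- list(list(center = c(12, 20), radius = 8, prob = 0.07),
                list(center = c(29, 20), radius = 8, prob = 0.07))
  hrf <- canonical_hrf(tr = 2)
  subjects <- lapply(1:3, function(k) {
    simulate_phantom(grid = c(40, 40), n_time = 150, components = comps,
                     noise = noise_spec("rician", cnr = 1), seed = 100 + k)
  })
  jac <- vapply(1:2, function(ci) {
    vols <- lapply(subjects, function(ph) {
      stc <- stimulus_function(ph$onsets$sample_index[ph$onsets$component == ci],
                               hrf, n_time = 150)
      seed_map(ph, stc, metric = "cr_zfr", allow_advance = TRUE)
    })
    act <- cluster_filter(top_fraction_threshold(minmax_normalize(group_average(vols)), 0.2),
                          min_cluster_size = 8)
    jaccard(act, subjects[[1]]$masks[[ci]])
  }, numeric(1))
  expect_true(all(jac >= 0.4))
})
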