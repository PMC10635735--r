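test_that("detections are scored by right-sided one-to-one matching", {
  counts <- classify_detections(c(5, 50), c(6, 80), n_samples = 100)
  expect_equal(counts[, c("tp", "fp", "fn", "tn")],
               tibble::tibble(tp = 1L, fp = 1L, fn = 1L, tn = 97L))
  perfect <- classify_detections(c(5, 50), c(5, 50), n_samples = 100)
  expect_equal(c(perfect$tp, perfect$fp, perfect$fn), c(2L, 0L, 0L))
  # a detection one sample before the stimulus does not match
  left <- classify_detections(10, 9, n_samples = 50, tolerance = 2)
  expect_equal(c(left$tp, left$fp, left$fn), c(0L, 1L, 1L))
  expect_error(classify_detections(1, 1, n_samples = 10, tolerance = -1), "tolerance")
})

test_that("detection counts satisfy their accounting identities", {
  withr::with_seed(12, {
    for (i in 1:50) {
      stim <- sort(sample(0:99, sample(1:15, 1)))
      det <- sort(sample(0:99, sample(0:15, 1)))
      counts <- classify_detections(stim, det, n_samples = 100)
      expect_equal(counts$tp + counts$fn, length(stim))
      expect_equal(counts$tp + counts$fp + counts$fn + counts$tn, 100L)
      expect_true(all(counts[, c("tp", "fp", "fn", "tn")] >= 0))
    }
  })
})

test_that("sensitivity and specificity follow their definitions", {
  counts <- classify_detections(c(5, 50), c(6, 80), n_samples = 100)
  expect_equal(sensitivity(counts), 0.5)
  expect_equal(specificity(counts), 97 / 98)
  perfect <- tibble::tibble(tp = 3L, fp = 0L, fn = 0L, tn = 97L)
  expect_equal(specificity(perfect), 1)
  none <- tibble::tibble(tp = 0L, fp = 0L, fn = 0L, tn = 0L)
  expect_warning(s1 <- sensitivity(none), "undefined")
  expect_true(is.na(s1))
  # a detector returning no onsets: zero sensitivity, perfect specificity
  empty <- classify_detections(c(10, 40), integer(0), n_samples = 100)
  expect_equal(sensitivity(empty), 0)
  expect_equal(specificity(empty), 1)
})

test_that("scores are monotone in the matching tolerance", {
  withr::with_seed(13, {
    for (i in 1:20) {
      stim <- sort(sample(0:199, 12))
      det <- sort(sample(0:199, 15))
      sens <- vapply(0:5, function(tol) {
        sensitivity(classify_detections(stim, det, n_samples = 200, tolerance = tol))
      }, numeric(1))
      spec <- vapply(0:5, function(tol) {
        specificity(classify_detections(stim, det, n_samples = 200, tolerance = tol))
      }, numeric(1))
      expect_true(all(diff(sens) >= 0))
      expect_true(all(diff(spec) >= 0))
    }
  })
})

test_that("jaccard measures mask overlap", {
  grid <- c(10, 1)
  as_mask <- function(idx) {
    m <- array(FALSE, grid); m[idx] <- TRUE; m
  }
  expect_equal(jaccard(as_mask(1:3), as_mask(2:4)), 0.5)
  expect_equal(jaccard(as_mask(1:3), as_mask(1:3)), 1)
  expect_equal(jaccard(as_mask(1:3), as_mask(5:7)), 0)
  expect_warning(j <- jaccard(as_mask(integer(0)), as_mask(integer(0))), "empty")
  expect_equal(j, 1)
  expect_error(jaccard(as_mask(1), array(FALSE, c(5, 2))), "grid")
  # symmetry
  withr::with_seed(14, {
    a <- array(runif(50) < 0.4, c(10, 5))
    b <- array(runif(50) < 0.4, c(10, 5))
    expect_equal(jaccard(a, b), jaccard(b, a))
  })
})

test_that("score splits partition map values by the active mask", {
  const <- fc_volume(array(0.5, c(4, 4)))
  mask <- array(c(rep(TRUE, 8), rep(FALSE, 8)), c(4, 4))
  expect_equal(split_scores(const, mask)$mean_difference, 0)
  vol <- fc_volume(array(c(rep(1, 2), rep(0, 2)), c(4, 1)))
  m2 <- array(c(TRUE, TRUE, FALSE, FALSE), c(4, 1))
  sp <- split_scores(vol, m2)
  expect_equal(sp$mean_difference, 1)
  g <- glance(sp)
  expect_equal(g$n_co, 2L)
  expect_equal(g$mean_difference, 1)
  expect_error(split_scores(const, array(TRUE, c(4, 4))), "non-empty")
})

test_that("phantom score split matches a brute-force partition", {
  ph <- simulate_phantom(
    grid = c(20, 20), n_time = 100,
    components = list(list(center = c(6, 10), radius = 4, prob = 0.07),
                      list(center = c(15, 10), radius = 4, prob = 0.07)),
    baseline = 5, noise = noise_spec("white_gaussian", sigma = 0.05), seed = 15
  )
  vol <- seed_map(ph, phantom_component_tc(ph, 1), metric = "correlation")
  sp <- split_scores(vol, ph$masks[[1]])
  co <- non <- c()
  for (i in 1:20) for (j in 1:20) {
    v <- vol$values[i, j]
    if (is.na(v)) next
    if (ph$masks[[1]][i, j]) co <- c(co, v) else non <- c(non, v)
  }
  expect_equal(sp$mean_difference, mean(co) - mean(non), tolerance = 1e-12)
})

test_that("noiseless detection of well-separated impulses is perfect", {
  hrf <- canonical_hrf(tr = 2)
  train <- c(20, 60, 100, 140)
  bold <- synthesize_bold(train, hrf, n_time = 200)
  det <- detect_onsets(bold, "zfr", n1 = 15)
  counts <- classify_detections(train, det$sample_index, n_samples = 200)
  expect_equal(sensitivity(counts), 1)
  expect_equal(specificity(counts), 1)
})

test_that("benchmark output is tidy and reproducible", {
  a <- detector_benchmark(n_runs = 5, seed = 3)
  b <- detector_benchmark(n_runs = 5, seed = 3)
  expect_identical(tidy(a), tidy(b))
  expect_equal(nrow(tidy(a)), 10)
  expect_named(glance(a), c("detector", "mean_sensitivity", "mean_specificity",
                            "sd_sensitivity", "sd_specificity"))
})

test_that("specificity exceeds sensitivity in sparse-event regimes", {
  bm <- detector_benchmark(n_runs = 20, seed = 5, n_time = 300, n_events = 15)
  g <- glance(bm)
  expect_true(all(g$mean_specificity > g$mean_sensitivity))
})
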