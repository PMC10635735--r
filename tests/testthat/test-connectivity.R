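test_that("onset matching follows the tolerance window policy", {
  expect_equal(match_onsets(c(10, 20, 30), c(11, 22, 50), max_delay = 2), 2L)
  expect_equal(match_onsets(c(10, 20, 30), c(10, 20, 30)), 3L)
  # advances only count when allowed
  expect_equal(match_onsets(10, 8, max_delay = 2, allow_advance = TRUE), 1L)
  expect_equal(match_onsets(10, 8, max_delay = 2, allow_advance = FALSE), 0L)
  expect_equal(match_onsets(integer(0), c(1, 2)), 0L)
  # one-to-one: a single target cannot serve two seeds
  expect_equal(match_onsets(c(10, 11), 11, max_delay = 2), 1L)
  expect_equal(match_onsets(c(10, 11), 11, max_delay = 2, one_to_one = FALSE), 2L)
})

test_that("conditional rate is a fraction of seed onsets", {
  expect_equal(conditional_rate(c(10, 20, 30), c(11, 22, 50), max_delay = 2), 2 / 3)
  expect_equal(conditional_rate(c(5, 9, 40), c(5, 9, 40)), 1)
  expect_equal(conditional_rate(c(10, 20, 30), integer(0)), 0)
  expect_warning(cr <- conditional_rate(integer(0), c(1, 2)), "undefined")
  expect_true(is.na(cr))
})

test_that("conditional rate is bounded and monotone in tolerance", {
  withr::with_seed(5, {
    for (i in 1:500) {
      seed <- sort(sample(0:99, sample(1:12, 1)))
      target <- sort(sample(0:99, sample(0:12, 1)))
      rates <- vapply(0:5, function(d) {
        suppressWarnings(conditional_rate(seed, target, max_delay = d))
      }, numeric(1))
      expect_true(all(rates >= 0 & rates <= 1))
      expect_true(all(diff(rates) >= -1e-15))
    }
  })
})

test_that("HSNR windows implement [n_c - 2, n_c + w - 3]", {
  r <- hsnr_regions(10, n_time = 100, w = 6)
  expect_equal(r$start, 8L)
  expect_equal(r$end, 13L)
  expect_equal(r$n_samples, 6L)
  # boundary clip
  r2 <- hsnr_regions(1, n_time = 100, w = 6)
  expect_equal(c(r2$start, r2$end, r2$n_samples), c(0L, 4L, 5L))
  # two onsets, two separate unmerged windows
  r3 <- hsnr_regions(c(10, 40), n_time = 100, w = 6)
  expect_equal(nrow(r3), 2)
  expect_equal(r3$n_samples, c(6L, 6L))
  expect_error(hsnr_regions(10, n_time = 100, w = 2), "at least 3")
})

test_that("HSNR correlation aggregates per-region Pearson values", {
  withr::with_seed(8, {
    a <- rnorm(100)
    regions <- hsnr_regions(c(10, 50), n_time = 100)
    expect_equal(hsnr_correlation(a, a, regions), 1)
    expect_equal(hsnr_correlation(a, -a, regions), -1)
    # construct one perfectly correlated and one uncorrelated region
    b <- a
    seg <- 49:54 # 0-based [48, 53] window of onset 50
    b[seg + 1] <- c(0, 1, 0, -1, 0, 1)
    a[seg + 1] <- c(1, 1, -1, -1, 1, -1)
    r1 <- cor(a[9:14], b[9:14])
    r2 <- cor(a[seg + 1], b[seg + 1])
    regions2 <- hsnr_regions(c(10, 51), n_time = 100)
    expect_equal(hsnr_correlation(a, b, regions2), mean(c(r1, r2)), tolerance = 1e-12)
  })
})

test_that("HSNR correlation is affine invariant and flags empty region sets", {
  withr::with_seed(9, {
    a <- rnorm(80)
    b <- rnorm(80)
    regions <- hsnr_regions(c(20, 40, 60), n_time = 80)
    base <- hsnr_correlation(a, b, regions)
    expect_equal(hsnr_correlation(3 * a + 7, b, regions), base, tolerance = 1e-12)
    expect_equal(hsnr_correlation(a, 0.2 * b - 4, regions), base, tolerance = 1e-12)
  })
  expect_warning(
    out <- hsnr_correlation(rep(1, 50), rnorm(50), hsnr_regions(25, n_time = 50)),
    "undefined"
  )
  expect_true(is.na(out))
})

test_that("a full-length window degenerates to plain Pearson correlation", {
  withr::with_seed(10, {
    a <- rnorm(60)
    b <- rnorm(60)
    regions <- hsnr_regions(2, n_time = 60, w = 60)
    expect_equal(regions$start, 0L)
    expect_equal(regions$end, 59L)
    expect_equal(hsnr_correlation(a, b, regions), pearson_fc(a, b), tolerance = 1e-12)
  })
})

test_that("pearson_fc matches the covariance formula oracle", {
  withr::with_seed(11, {
    a <- rnorm(100)
    b <- rnorm(100)
    oracle <- sum((a - mean(a)) * (b - mean(b))) /
      sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
    expect_equal(pearson_fc(a, b), oracle, tolerance = 1e-12)
    expect_equal(pearson_fc(a, a), 1)
    expect_equal(pearson_fc(a, -a), -1)
  })
  expect_error(pearson_fc(rep(1, 10), rnorm(10)), "variance")
  expect_error(pearson_fc(rnorm(5), rnorm(6)), "equal length")
})

test_that("ROI connectivity matrices have the documented structure", {
  v <- as.numeric(scale(cumsum(rnorm(150)))) # any non-degenerate course
  m <- roi_connectivity(tibble::tibble(a = v, b = v, c = v), metric = "correlation")
  expect_equal(unclass(m), matrix(1, 3, 3, dimnames = list(c("a", "b", "c"), c("a", "b", "c"))),
               ignore_attr = TRUE)
  hrf <- canonical_hrf(tr = 2)
  t1 <- synthesize_bold(c(20, 60, 100), hrf, n_time = 150)$value
  m2 <- roi_connectivity(list(x = t1, y = t1), metric = "cr_zfr", tr = 2)
  expect_equal(as.vector(unclass(m2)), rep(1, 4))
  # disjoint event trains: duplicates score high, cross pairs low
  t2 <- synthesize_bold(c(40, 80, 120), hrf, n_time = 150)$value
  m3 <- roi_connectivity(list(a = t1, b = t1, c = t2), metric = "correlation")
  expect_equal(m3["a", "b"], 1)
  expect_lt(m3["a", "c"], 0.5)
  td <- tidy(m3)
  expect_equal(nrow(td), 9)
  expect_equal(td$score[td$seed == "a" & td$target == "b"], 1)
})
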