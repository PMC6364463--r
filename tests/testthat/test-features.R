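test_that("hand-computed histogram example is reproduced", {
  f <- extract_features(vol_of(c(1, 2, 3, 4)), mask_all(4),
                        histogram_spec(4))
  # four values in four equal-width bins over [1, 4]: p_i = 1/4 each
  expect_equal(f$entropy, 2.0)
  expect_equal(f$mean_gray, 2.5)
  expect_equal(f$n_voxels, 4)
})

test_that("constant region yields degenerate features", {
  f <- extract_features(vol_of(rep(7, 50)), mask_all(50))
  expect_equal(f$sd, 0)
  expect_equal(f$entropy, 0)
  expect_true(is.na(f$skewness))
  expect_true(is.na(f$kurtosis))
  expect_error(extract_features(vol_of(5), mask_all(1)), "single-voxel")
})

test_that("moments match known values for large normal samples", {
  set.seed(2024)
  x <- rnorm(1e5)
  f <- extract_features(vol_of(x), mask_all(1e5))
  expect_lt(abs(f$mean_gray), 0.05)
  expect_lt(abs(f$sd - 1), 0.05)
  expect_lt(abs(f$skewness), 0.05)
  expect_lt(abs(f$kurtosis - 3), 0.05)
})

test_that("features agree with the direct-formula oracle", {
  set.seed(99)
  for (i in 1:25) {
    vol <- random_volume()
    msk <- random_mask()
    f <- extract_features(vol, msk)
    x <- vol$data[msk$data]
    o <- moment_oracle(x)
    expect_equal(f$mean_gray, o$mean, tolerance = 1e-12)
    expect_equal(f$sd, o$sd, tolerance = 1e-12)
    expect_equal(f$skewness, o$skewness, tolerance = 1e-12)
    expect_equal(f$kurtosis, o$kurtosis, tolerance = 1e-12)
    expect_equal(f$entropy, entropy_oracle(x, 256), tolerance = 1e-12)
  }
})

test_that("entropy attains its bounds at the extreme histograms", {
  nb <- 16
  # uniform occupancy: maximal entropy log2(n_bins)
  x <- rep(seq(0.5, nb - 0.5), each = 10)
  f <- extract_features(vol_of(x), mask_all(length(x)),
                        histogram_spec(nb, "fixed", range = c(0, nb)))
  expect_equal(f$entropy, log2(nb))
  # all mass in one bin: zero entropy
  g <- extract_features(vol_of(runif(40, 0.1, 0.2)),
                        mask_all(40),
                        histogram_spec(nb, "fixed", range = c(0, nb)))
  expect_equal(g$entropy, 0)
})

test_that("entropy is invariant under affine rescaling with per-ROI range", {
  set.seed(5)
  for (i in 1:10) {
    x <- runif(500, -30, 170)
    h1 <- extract_features(vol_of(x), mask_all(500))$entropy
    h2 <- extract_features(vol_of(2.5 * x + 1000), mask_all(500))$entropy
    expect_equal(h1, h2)
  }
})

test_that("a uniform necrotic core lowers entropy of a textured lesion", {
  set.seed(31)
  n <- 4000
  rim <- rnorm(n, 90, 30)
  with_core <- c(rim[seq_len(0.6 * n)], rnorm(0.4 * n, 25, 1))
  h_without <- extract_features(vol_of(rim), mask_all(n))$entropy
  h_with <- extract_features(vol_of(with_core), mask_all(n))$entropy
  expect_lt(h_with, h_without)
})

test_that("cohort extraction produces 6 deterministic records per subject", {
  tmp <- withr::local_tempdir()
  spec <- tiny_spec(seed = 5)
  man <- generate_cohort(spec, tmp)
  expect_equal(nrow(man), 12)  # (3 + 3) subjects x 2 phases
  feats <- extract_cohort(man)
  expect_equal(nrow(feats), 36)  # 6 subjects x 2 phases x 3 channels
  expect_setequal(unique(feats$filter), c("none", "fine", "coarse"))
  feats2 <- extract_cohort(man)
  expect_identical(feats, feats2)
})
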