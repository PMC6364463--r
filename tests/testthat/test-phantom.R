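test_that("cohort generation writes the expected files and manifest", {
  tmp <- withr::local_tempdir()
  man <- generate_cohort(tiny_spec(seed = 2), tmp)
  expect_equal(nrow(man), 12)  # (3+3) subjects x 2 phases
  expect_true(all(file.exists(man$volume)))
  expect_true(all(file.exists(man$mask)))
  expect_true(file.exists(file.path(tmp, "manifest.csv")))
  expect_equal(sort(unique(man$phase)),
               sort(c("corticomedullary", "nephrographic")))
  # phantom geometry: header carries the 3 mm slice thickness
  v <- read_volume(man$volume[1])
  expect_equal(v$spacing, c(1, 1, 3))
  # every lesion spans at least 7 axial slices
  for (mp in unique(man$mask))
    expect_gte(mask_slice_count(read_mask(mp)), 7)
})

test_that("with all randomness off, lesion voxels equal the phase mean", {
  spec <- tiny_spec(noise_sd = 0, texture_field_sd = 0,
                    necrosis_fraction = 0, subject_mean_sd = 0,
                    texture_sd_cv = 0, corr_length_cv = 0,
                    necrosis_jitter = 0, seed = 8)
  sim <- cttar:::simulate_subject(spec, "low-001", "low")
  les <- sim$volumes$corticomedullary$data[sim$mask$data]
  expect_true(all(les == spec$lesion_mean_hu["low", "corticomedullary"]))
  les2 <- sim$volumes$nephrographic$data[sim$mask$data]
  expect_true(all(les2 == spec$lesion_mean_hu["low", "nephrographic"]))
})

test_that("generation is reproducible from the seed and varies across seeds", {
  spec <- tiny_spec(seed = 4)
  f1 <- simulate_features(spec)
  f2 <- simulate_features(spec)
  expect_identical(f1, f2)
  f3 <- simulate_features(spec, seed = 5)
  expect_false(identical(f1$mean_gray, f3$mean_gray))
  expect_identical(f1[, c("subject_id", "group", "phase", "filter")],
                   f3[, c("subject_id", "group", "phase", "filter")])
})

test_that("subject substreams are stable under cohort growth", {
  small <- tiny_spec(seed = 9)
  big <- phantom_spec(n_low = 4, n_high = 3, volume_shape = c(48, 48, 20),
                      lesion_radius_range = c(12, 15), seed = 9)
  fs <- simulate_features(small)
  fb <- simulate_features(big)
  merged <- merge(fs, fb, by = c("subject_id", "phase", "filter"))
  expect_equal(merged$entropy.x, merged$entropy.y)
})

test_that("degenerate specs are rejected loudly", {
  expect_error(phantom_spec(n_low = 1), "at least 2")
  expect_error(phantom_spec(lesion_radius_range = c(0, 0)), "degenerate")
  # lesions too thin to span 7 x 3 mm slices
  expect_error(phantom_spec(lesion_radius_range = c(5, 8)), "7 axial slices")
  expect_error(phantom_spec(necrosis_fraction = 1.2), "\\[0, 1\\]")
  expect_error(generate_cohort(tiny_spec(), "/proc/nowrite/xyz"),
               "directory")
})

test_that("null specs force identical group parameters", {
  ns <- null_spec(phantom_spec())
  expect_equal(ns$lesion_mean_hu["high", ], ns$lesion_mean_hu["low", ])
  expect_equal(unname(ns$necrosis_fraction["high"]),
               unname(ns$necrosis_fraction["low"]))
  expect_equal(unname(ns$texture_intermittency["high"]),
               unname(ns$texture_intermittency["low"]))
})

test_that("texture amplitude maps monotonically onto the SD feature", {
  sds <- c(10, 30, 50)
  mean_sd <- vapply(sds, function(s) {
    spec <- tiny_spec(texture_field_sd = s, seed = 21)
    f <- simulate_features(spec)
    mean(f$sd[f$filter == "none"])
  }, 0)
  expect_true(all(diff(mean_sd) > 0))
})

test_that("stronger intermittency lowers entropy and raises kurtosis", {
  spec <- phantom_spec(n_low = 6, n_high = 6, volume_shape = c(48, 48, 20),
                       lesion_radius_range = c(12, 15),
                       lesion_mean_hu = list(
                         low = c(corticomedullary = 88, nephrographic = 80),
                         high = c(corticomedullary = 88, nephrographic = 80)),
                       necrosis_fraction = 0.1,
                       texture_intermittency = c(low = 0.2, high = 1.0),
                       seed = 13)
  f <- simulate_features(spec)
  f0 <- f[f$filter == "none", ]
  expect_lt(mean(f0$entropy[f0$group == "high"]),
            mean(f0$entropy[f0$group == "low"]))
  expect_gt(mean(f0$kurtosis[f0$group == "high"]),
            mean(f0$kurtosis[f0$group == "low"]))
})
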