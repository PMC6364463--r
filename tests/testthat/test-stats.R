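# Build a feature table directly from per-subject values for one cell,
# filling the remaining grid cells with uninformative noise.
feature_table <- function(low, high, feature = "entropy",
                          filter = "fine", phase = "corticomedullary") {
  n <- length(low) + length(high)
  ids <- sprintf("s%02d", seq_len(n))
  grp <- rep(c("low", "high"), c(length(low), length(high)))
  grid <- expand.grid(phase = c("corticomedullary", "nephrographic"),
                      filter = c("none", "fine", "coarse"),
                      stringsAsFactors = FALSE)
  rows <- do.call(rbind, lapply(seq_len(nrow(grid)), function(i) {
    df <- data.frame(subject_id = ids, group = grp,
                     phase = grid$phase[i], filter = grid$filter[i],
                     mean_gray = rnorm(n), sd = runif(n, 1, 2),
                     entropy = runif(n, 5, 6), skewness = rnorm(n),
                     kurtosis = rnorm(n, 3), n_voxels = 100L)
    if (grid$phase[i] == phase && grid$filter[i] == filter)
      df[[feature]] <- c(low, high)
    df
  }))
  rows
}

test_that("the Welch test matches its textbook closed form", {
  set.seed(1)
  a <- 1:5; b <- 2:6
  f <- feature_table(a, b)
  cmp <- compare_groups(f)
  row <- cmp[cmp$phase == "corticomedullary" & cmp$feature == "entropy" &
             cmp$filter == "fine", ]
  # equal variances s^2 = 2.5 and n = 5 give t = -1 with Welch df = 8
  se <- sqrt(var(a) / 5 + var(b) / 5)
  df_welch <- se^4 / ((var(a) / 5)^2 / 4 + (var(b) / 5)^2 / 4)
  expect_equal(row$t, -1)
  expect_equal(df_welch, 8)
  expect_equal(row$p, 2 * pt(-1, 8))
  expect_equal(row$mean_low, 3)
  expect_equal(row$sd_high, sqrt(2.5))
})

test_that("identical groups give t = 0 and p = 1", {
  set.seed(2)
  f <- feature_table(c(4, 5, 6, 7), c(4, 5, 6, 7))
  cmp <- compare_groups(f)
  row <- cmp[cmp$phase == "corticomedullary" & cmp$feature == "entropy" &
             cmp$filter == "fine", ]
  expect_equal(row$t, 0)
  expect_equal(row$p, 1)
})

test_that("Welch reduces to Student's t for equal variance and n", {
  set.seed(3)
  f <- feature_table(rnorm(10), rnorm(10, 1))
  w <- compare_groups(f, var_equal = FALSE)
  s <- compare_groups(f, var_equal = TRUE)
  cell <- function(cmp) cmp[cmp$phase == "corticomedullary" &
                            cmp$feature == "entropy" &
                            cmp$filter == "fine", ]
  expect_equal(cell(w)$t, cell(s)$t, tolerance = 1e-12)
})

test_that("BH adjustment matches an independent step-up oracle", {
  set.seed(4)
  for (i in 1:50) {
    p <- runif(30)^sample(1:3, 1)
    expect_equal(p.adjust(p, "BH"), bh_oracle(p), tolerance = 1e-14)
  }
  # adjustment never decreases a p-value and stays within [0, 1]
  f <- feature_table(rnorm(8), rnorm(8, 2))
  cmp <- compare_groups(f)
  expect_true(all(cmp$p_adj >= cmp$p))
  expect_true(all(cmp$p_adj <= 1 & cmp$p >= 0))
  expect_equal(cmp$p_adj, bh_oracle(cmp$p), tolerance = 1e-14)
  expect_equal(nrow(cmp), 30)
})

test_that("AUC matches the pair-count oracle on the worked example", {
  set.seed(5)
  f <- feature_table(c(0.1, 0.4), c(0.35, 0.8))
  roc <- roc_analysis(f, data.frame(phase = "corticomedullary",
                                    feature = "entropy", filter = "fine"))
  # 3 concordant of 4 pairs
  expect_equal(roc$auc, 0.75)
  expect_equal(roc$auc, auc_pair_oracle(c(0.1, 0.4), c(0.35, 0.8)))
  expect_equal(roc$positive_direction, "high-grade-high-values")
})

test_that("perfect separation yields a perfect operating point", {
  set.seed(6)
  f <- feature_table(1:10, 21:30)
  roc <- roc_analysis(f, data.frame(phase = "corticomedullary",
                                    feature = "entropy", filter = "fine"))
  expect_equal(roc$auc, 1)
  expect_equal(roc$sensitivity, 1)
  expect_equal(roc$specificity, 1)
  expect_gt(roc$cutoff, 10)
  expect_lt(roc$cutoff, 21)
})

test_that("a feature lower in high grade is flipped and recorded", {
  set.seed(7)
  low <- rnorm(30, 6, 0.3); high <- rnorm(30, 5, 0.3)
  f <- feature_table(low, high)
  roc <- roc_analysis(f, data.frame(phase = "corticomedullary",
                                    feature = "entropy", filter = "fine"))
  expect_gte(roc$auc, 0.5)
  expect_equal(roc$positive_direction, "high-grade-low-values")
  expect_equal(roc$auc, auc_pair_oracle(-low, -high))
  # the reported cutoff lives on the original feature scale
  expect_gt(roc$cutoff, 4)
  expect_lt(roc$cutoff, 7)
})

test_that("permuted labels give chance-level AUC", {
  set.seed(8)
  n <- 400
  scores <- rnorm(2 * n)
  auc <- auc_pair_oracle(scores[1:n], scores[(n + 1):(2 * n)])
  f <- feature_table(scores[1:n], scores[(n + 1):(2 * n)])
  roc <- roc_analysis(f, data.frame(phase = "corticomedullary",
                                    feature = "entropy", filter = "fine"))
  expect_lt(abs(roc$auc - 0.5), 3 / sqrt(2 * n))
  expect_equal(roc$auc, max(auc, 1 - auc))
})

test_that("AUC and Youden cutoff agree with pROC on tied, messy data", {
  skip_if_not_installed("pROC")
  set.seed(9)
  low <- sample(1:8, 25, replace = TRUE)
  high <- sample(3:12, 20, replace = TRUE)
  f <- feature_table(low, high)
  roc <- roc_analysis(f, data.frame(phase = "corticomedullary",
                                    feature = "entropy", filter = "fine"))
  ref <- pROC::roc(response = rep(c(0, 1), c(25, 20)),
                   predictor = c(low, high), quiet = TRUE,
                   direction = "<")
  expect_equal(roc$auc, as.numeric(ref$auc), tolerance = 1e-12)
  best <- pROC::coords(ref, "best", best.method = "youden",
                       transpose = FALSE)
  # same Youden optimum (pROC may return several tied optima)
  expect_true(any(abs(best$sensitivity - roc$sensitivity) < 1e-12 &
                  abs(best$specificity - roc$specificity) < 1e-12))
})

test_that("one-class input and missing cells are handled explicitly", {
  set.seed(10)
  f <- feature_table(rnorm(5), rnorm(5))
  f_one <- f[f$group == "low", ]
  expect_error(roc_analysis(f_one, data.frame(phase = "corticomedullary",
                                              feature = "entropy",
                                              filter = "fine")),
               "both classes")
  f_na <- f
  f_na$kurtosis <- NA_real_
  expect_warning(cmp <- compare_groups(f_na), "excluded")
  expect_equal(nrow(cmp), 24)  # kurtosis cells dropped from the family
})
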