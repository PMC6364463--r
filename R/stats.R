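#' @title Group comparison and ROC analysis of the feature grid
#' @description Two-sample comparison of every cell of the
#'   phase x feature x filter grid (2 x 5 x 3 = 30 tests) with
#'   Benjamini-Hochberg false-discovery-rate adjustment across the whole
#'   grid, followed by ROC characterization of the significant features
#'   with Youden-optimal cutoffs.
#' @name grid-stats
NULL

#' Compare the two groups over the feature grid
#'
#' For each (phase, feature, filter) cell, the low- and high-grade values
#' are compared with a two-sample t-test (Welch by default, the safer
#' choice under unequal group variances; the pooled-variance Student test
#' is available via `var_equal = TRUE`).  P-values are adjusted jointly
#' across all tested cells with the Benjamini-Hochberg step-up procedure,
#' and cells with adjusted p below `alpha` are flagged significant.
#' Cells with fewer than 2 usable values in either group are excluded
#' with a warning, shrinking the adjustment family accordingly.
#'
#' @param features feature `data.frame` from [extract_cohort()] or
#'   [simulate_features()].
#' @param alpha significance level on the adjusted p-value.
#' @param var_equal use the pooled-variance test instead of Welch.
#' @return a `data.frame` of class `ctta_comparison`: one row per tested
#'   cell with group means and SDs, `t`, `p`, `p_adj`, `significant`.
#' @export
compare_groups <- function(features, alpha = 0.05, var_equal = FALSE) {
  features <- as.data.frame(features)
  stopifnot(all(c("group", "phase", "filter") %in% names(features)))
  grid <- expand.grid(phase = PHASES, feature = FEATURE_NAMES,
                      filter = FILTER_LEVELS, stringsAsFactors = FALSE,
                      KEEP.OUT.ATTRS = FALSE)
  rows <- vector("list", nrow(grid))
  skipped <- character(0)
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    sel <- features$phase == g$phase & features$filter == g$filter
    x <- features[sel & features$group == "low", g$feature]
    y <- features[sel & features$group == "high", g$feature]
    x <- x[is.finite(x)]
    y <- y[is.finite(y)]
    if (length(x) < 2 || length(y) < 2 || (sd(x) == 0 && sd(y) == 0)) {
      skipped <- c(skipped, paste(g$phase, g$feature, g$filter))
      next
    }
    tt <- stats::t.test(x, y, var.equal = var_equal)
    rows[[i]] <- data.frame(
      phase = g$phase, feature = g$feature, filter = g$filter,
      mean_low = mean(x), sd_low = sd(x),
      mean_high = mean(y), sd_high = sd(y),
      t = unname(tt$statistic), p = tt$p.value,
      stringsAsFactors = FALSE)
  }
  if (length(skipped))
    warning("excluded from comparison (too few usable values): ",
            paste(skipped, collapse = "; "))
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no testable cells in the feature grid")
  out$p_adj <- stats::p.adjust(out$p, method = "BH")
  out$significant <- out$p_adj < alpha
  rownames(out) <- NULL
  attr(out, "alpha") <- alpha
  attr(out, "test") <- if (var_equal) "student" else "welch"
  class(out) <- c("ctta_comparison", "data.frame")
  out
}

# Empirical ROC of scores (positives should tend to score high after
# orientation).  Returns threshold-free curve points: TPR/FPR swept over
# the distinct observed scores, descending.
empirical_roc <- function(neg, pos) {
  u <- sort(unique(c(neg, pos)), decreasing = TRUE)
  tpr <- c(0, cumsum(sapply(u, function(t) sum(pos == t))) / length(pos))
  fpr <- c(0, cumsum(sapply(u, function(t) sum(neg == t))) / length(neg))
  list(tpr = tpr, fpr = fpr)
}

# Trapezoidal AUC of an empirical ROC curve; with tied scores grouped on
# one vertex this equals the Mann-Whitney concordance with ties counted
# one half.
trapezoid_auc <- function(roc) {
  sum(diff(roc$fpr) * (utils::head(roc$tpr, -1) + utils::tail(roc$tpr, -1)) / 2)
}

roc_one <- function(low, high) {
  if (length(low) == 0 || length(high) == 0)
    stop("ROC needs both classes present")
  # orient so that the high-grade class scores high: flip whenever the
  # unflipped concordance is below one half, so auc >= 0.5 always
  flip <- trapezoid_auc(empirical_roc(low, high)) < 0.5
  neg <- if (flip) -low else low
  pos <- if (flip) -high else high
  roc <- empirical_roc(neg, pos)
  auc <- trapezoid_auc(roc)

  # candidate cutpoints: midpoints between adjacent distinct scores,
  # plus open ends; classifier calls "high grade" when score > cut
  u <- sort(unique(c(neg, pos)))
  cand <- c(u[1] - 1, (utils::head(u, -1) + utils::tail(u, -1)) / 2,
            u[length(u)] + 1)
  sens <- vapply(cand, function(cut) mean(pos > cut), 0)
  spec <- vapply(cand, function(cut) mean(neg <= cut), 0)
  j <- sens + spec - 1
  best <- which(j == max(j))
  if (length(best) > 1) {
    mid <- (stats::median(pos) + stats::median(neg)) / 2
    best <- best[which.min(abs(cand[best] - mid))]
  }
  cut <- cand[best]
  list(auc = auc,
       cutoff = if (flip) -cut else cut,
       sensitivity = sens[best], specificity = spec[best],
       positive_direction = if (flip) "high-grade-low-values"
                            else "high-grade-high-values",
       curve = if (flip)
         list(tpr = roc$tpr, fpr = roc$fpr) else roc)
}

#' ROC analysis of selected feature cells
#'
#' Computes, for each selected (phase, feature, filter) cell, the
#' empirical ROC for discriminating high grade (positive class) from low
#' grade, the trapezoidal AUC, and the cutoff maximizing Youden's
#' J = sensitivity + specificity - 1 (ties resolved toward the midpoint
#' of the two group medians; the reported cutoff is the midpoint between
#' adjacent observed values).  Features lower in the high-grade group
#' (as entropy is) are flipped so AUC >= 0.5, and the flip is recorded in
#' `positive_direction`.
#'
#' @param features feature `data.frame`.
#' @param selected either a `data.frame` with columns
#'   `phase`, `feature`, `filter`, or a `ctta_comparison` from which the
#'   FDR-significant rows are taken.
#' @return a `data.frame` of class `ctta_roc` with `auc`, `cutoff`,
#'   `sensitivity`, `specificity`, `positive_direction`; ROC curve points
#'   are kept in the `"curves"` attribute for plotting.
#' @export
roc_analysis <- function(features, selected) {
  features <- as.data.frame(features)
  if (inherits(selected, "ctta_comparison"))
    selected <- selected[selected$significant,
                         c("phase", "feature", "filter")]
  selected <- as.data.frame(selected)
  rows <- vector("list", nrow(selected))
  curves <- vector("list", nrow(selected))
  for (i in seq_len(nrow(selected))) {
    g <- selected[i, ]
    sel <- features$phase == g$phase & features$filter == g$filter
    x <- features[sel & features$group == "low", g$feature]
    y <- features[sel & features$group == "high", g$feature]
    r <- roc_one(x[is.finite(x)], y[is.finite(y)])
    rows[[i]] <- data.frame(
      phase = g$phase, feature = g$feature, filter = g$filter,
      auc = r$auc, cutoff = r$cutoff, sensitivity = r$sensitivity,
      specificity = r$specificity,
      positive_direction = r$positive_direction,
      stringsAsFactors = FALSE)
    curves[[i]] <- r$curve
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(phase = character(), feature = character(),
               filter = character(), auc = numeric(), cutoff = numeric(),
               sensitivity = numeric(), specificity = numeric(),
               positive_direction = character())
  rownames(out) <- NULL
  attr(out, "curves") <- curves
  class(out) <- c("ctta_roc", "data.frame")
  out
}
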