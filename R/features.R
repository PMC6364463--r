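#' @title First-order histogram features
#' @description The five first-order statistics of the masked voxel
#'   intensity distribution: mean gray intensity, standard deviation,
#'   entropy, skewness, and kurtosis.  These summarize the intensity
#'   histogram and ignore spatial arrangement; entropy quantifies
#'   gray-level disorder and is the pipeline's primary heterogeneity
#'   marker.
#' @name features
NULL

#' Histogram specification for entropy
#'
#' Entropy is computed from a binned histogram of the masked intensities.
#' The default uses 256 equal-width bins spanning the per-ROI min-max
#' range, which keeps entropy invariant under affine intensity rescaling
#' and is well defined for signed, unbounded filtered channels.
#'
#' @param n_bins number of histogram bins (>= 2).
#' @param range_rule `"roi"` (per-ROI min-max, default) or `"fixed"` with
#'   an explicit `range`.
#' @param range length-2 numeric, used only when `range_rule = "fixed"`.
#' @return a list of class `histogram_spec`.
#' @export
histogram_spec <- function(n_bins = 256, range_rule = c("roi", "fixed"),
                           range = NULL) {
  range_rule <- match.arg(range_rule)
  if (!is.numeric(n_bins) || n_bins < 2) stop("n_bins must be >= 2")
  if (range_rule == "fixed" &&
      (is.null(range) || length(range) != 2 || diff(range) <= 0))
    stop("range_rule = 'fixed' needs an increasing length-2 range")
  structure(list(n_bins = as.integer(n_bins), range_rule = range_rule,
                 range = range),
            class = "histogram_spec")
}

# Shannon entropy (bits) of values binned into n_bins equal-width bins
# over rng.  Empty bins contribute nothing; a degenerate range (all
# values identical) puts all mass in one bin, entropy 0.
bin_entropy <- function(x, n_bins, rng) {
  if (rng[1] >= rng[2]) return(0)
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  idx <- findInterval(x, breaks, rightmost.closed = TRUE, all.inside = TRUE)
  p <- tabulate(idx, nbins = n_bins) / length(x)
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' First-order features of masked voxels
#'
#' Computes the five features over the foreground voxels of `mask` in
#' `channel`.  Conventions: sample (n-1) standard deviation; skewness and
#' kurtosis as the third and fourth standardized population moments with
#' no small-sample bias correction; kurtosis in the non-excess convention
#' (a Gaussian scores 3); entropy in bits from the histogram given by
#' `hist`.  For a constant region the standard deviation and entropy are
#' exactly 0 and skewness/kurtosis are undefined (0/0) and reported as
#' `NA`.
#'
#' @param channel a [ct_volume()] (raw or filtered).
#' @param mask a congruent [roi_mask()].
#' @param hist a [histogram_spec()].
#' @return one-row `data.frame` with columns `mean_gray`, `sd`, `entropy`,
#'   `skewness`, `kurtosis`, `n_voxels`.
#' @export
extract_features <- function(channel, mask, hist = histogram_spec()) {
  stopifnot(inherits(channel, "ct_volume"), inherits(mask, "roi_mask"),
            inherits(hist, "histogram_spec"))
  check_congruent(channel, mask, "channel and mask")
  x <- channel$data[mask$data]
  n <- length(x)
  if (n == 0L) stop("empty mask: no voxels to analyze")
  if (n == 1L) stop("single-voxel mask: dispersion features undefined")
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 == 0) {
    skew <- kurt <- NA_real_
    s <- 0
  } else {
    skew <- mean((x - m)^3) / m2^1.5
    kurt <- mean((x - m)^4) / m2^2
    s <- sqrt(m2 * n / (n - 1))
  }
  rng <- if (hist$range_rule == "fixed") hist$range else range(x)
  data.frame(mean_gray = m, sd = s,
             entropy = bin_entropy(x, hist$n_bins, rng),
             skewness = skew, kurtosis = kurt, n_voxels = n)
}

FILTER_LEVELS <- c("none", "fine", "coarse")
FEATURE_NAMES <- c("mean_gray", "sd", "entropy", "skewness", "kurtosis")
PHASES <- c("corticomedullary", "nephrographic")

# Features of all three channels of one volume/mask pair -> 3 rows.
extract_channels <- function(volume, mask, hist = histogram_spec(), ...) {
  ch <- channelize(volume, ...)
  out <- do.call(rbind, lapply(FILTER_LEVELS, function(lv)
    extract_features(ch[[lv]], mask, hist)))
  cbind(data.frame(filter = FILTER_LEVELS), out)
}

#' Extract the feature table of a whole cohort
#'
#' Runs [channelize()] and [extract_features()] for every subject x phase
#' in the manifest: 6 feature records per subject (2 phases x 3 filter
#' levels).  Subjects whose extraction fails are recorded with a reason
#' and skipped; the rest proceed.
#'
#' @param manifest a cohort manifest `data.frame` (see [read_manifest()]).
#' @param hist a [histogram_spec()].
#' @param ... filtering options passed to [channelize()].
#' @return a `data.frame` with columns `subject_id`, `group`, `phase`,
#'   `filter`, the five features and `n_voxels`; failed subjects are
#'   listed in the `"failures"` attribute.
#' @export
extract_cohort <- function(manifest, hist = histogram_spec(), ...) {
  manifest <- as.data.frame(manifest)
  rows <- list()
  failures <- character(0)
  for (i in seq_len(nrow(manifest))) {
    r <- manifest[i, ]
    rec <- tryCatch({
      vol <- read_volume(r$volume)
      msk <- read_mask(r$mask)
      extract_channels(vol, msk, hist, ...)
    }, error = function(e) conditionMessage(e))
    if (is.character(rec)) {
      failures[paste(r$subject_id, r$phase)] <- rec
      next
    }
    rows[[length(rows) + 1L]] <-
      cbind(data.frame(subject_id = r$subject_id, group = r$group,
                       phase = r$phase), rec)
  }
  if (!length(rows)) stop("feature extraction failed for every subject")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out <- out[, c("subject_id", "group", "phase", "filter",
                 FEATURE_NAMES, "n_voxels")]
  attr(out, "failures") <- failures
  out
}
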