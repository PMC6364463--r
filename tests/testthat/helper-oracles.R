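# Independent oracle implementations used to pin the package's numerics.
# These deliberately use different code paths from the package internals.

# Direct-formula first-order moments on a flat vector.
moment_oracle <- function(x) {
  n <- length(x)
  m <- sum(x) / n
  d <- x - m
  m2 <- sum(d^2) / n
  list(mean = m,
       sd = sqrt(sum(d^2) / (n - 1)),
       skewness = (sum(d^3) / n) / m2^1.5,
       kurtosis = (sum(d^4) / n) / m2^2)
}

# Histogram entropy oracle via cut()/table() rather than findInterval().
entropy_oracle <- function(x, n_bins, rng = range(x)) {
  if (rng[1] >= rng[2]) return(0)
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1)
  cnt <- as.vector(table(cut(x, breaks, include.lowest = TRUE)))
  p <- cnt[cnt > 0] / length(x)
  -sum(p * log2(p))
}

# Benjamini-Hochberg step-up, written out directly.
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  stepped <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(stepped)))
  adj <- pmin(adj, 1)
  out <- numeric(n)
  out[o] <- adj
  out
}

# AUC as Mann-Whitney concordance by exhaustive pair enumeration,
# ties counted one half; positives expected high after orientation.
auc_pair_oracle <- function(neg, pos) {
  conc <- outer(pos, neg, ">") + 0.5 * outer(pos, neg, "==")
  mean(conc)
}

# Brute-force 2D convolution of one slice with an explicit kernel matrix,
# reflect (half-sample symmetric) padding, via explicit pad-and-shift.
conv2_bruteforce <- function(slice, kern) {
  r <- (nrow(kern) - 1) %/% 2
  n1 <- nrow(slice); n2 <- ncol(slice)
  reflect_idx <- function(p, n) {
    q <- (p - 1) %% (2 * n)
    ifelse(q < n, q + 1, 2 * n - q)
  }
  pad <- slice[reflect_idx(seq(1 - r, n1 + r), n1),
               reflect_idx(seq(1 - r, n2 + r), n2)]
  out <- matrix(0, n1, n2)
  for (i in seq_len(nrow(kern)))
    for (j in seq_len(ncol(kern)))
      out <- out + kern[i, j] * pad[(seq_len(n1) + i - 1),
                                    (seq_len(n2) + j - 1)]
  out
}

# The package's documented 2D LoG kernel built independently from the
# analytic formula: sampled Gaussian-derivative separable terms with the
# shared normalizer and the DC (zero-sum) correction.
log2d_kernel_oracle <- function(sigma, truncate = 4) {
  r <- ceiling(truncate * sigma)
  x <- seq(-r, r)
  e <- exp(-x^2 / (2 * sigma^2))
  g <- e / sum(e)
  d2 <- (x^2 / sigma^2 - 1) / sigma^2 * e / sum(e)
  d2 <- d2 - mean(d2)
  outer(d2, g) + outer(g, d2)
}

# Small random volume/mask pair on a shared grid.
random_volume <- function(shape = c(12, 12, 8), spacing = c(1, 1, 3),
                          integer_valued = FALSE) {
  v <- array(stats::rnorm(prod(shape), 50, 20), shape)
  if (integer_valued) v <- round(v)
  ct_volume(v, spacing)
}

random_mask <- function(shape = c(12, 12, 8), spacing = c(1, 1, 3),
                        p = 0.4) {
  m <- array(stats::runif(prod(shape)) < p, shape)
  m[1, 1, 1] <- TRUE  # never empty
  roi_mask(m, spacing)
}

# 1D value vectors as degenerate volumes/masks, for feature tests.
vol_of <- function(x) ct_volume(array(x, c(length(x), 1, 1)))
mask_all <- function(n) roi_mask(array(TRUE, c(n, 1, 1)))

# Minimal fast phantom spec for tests.
tiny_spec <- function(...) {
  phantom_spec(n_low = 3, n_high = 3, volume_shape = c(48, 48, 20),
               lesion_radius_range = c(12, 15), ...)
}
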