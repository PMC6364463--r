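#' @title Laplacian-of-Gaussian multiscale filtering
#' @description The three analysis channels used throughout the pipeline:
#'   the unfiltered volume, a fine-scale LoG response (sigma = 1.0) and a
#'   coarse-scale LoG response (sigma = 2.5).  Small sigma emphasizes fine
#'   texture; large sigma emphasizes coarse texture.  Filtering is always
#'   applied to the full volume before any masking, so voxels near the ROI
#'   boundary see their true image context.
#' @name filtering
NULL

# Sampled Gaussian kernel, truncated at `truncate` sigmas, normalized to
# unit sum so that smoothing preserves the mean of a constant field.
gauss_kernel <- function(sigma, truncate = 4) {
  if (!is.finite(sigma) || sigma <= 0) stop("sigma must be positive")
  r <- ceiling(truncate * sigma)
  x <- seq.int(-r, r)
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

# Sampled second derivative of the Gaussian, same support and the same
# normalization constant as gauss_kernel.  The kernel is mean-subtracted
# so that its discrete sum is exactly zero: the LoG response to a constant
# volume (any uniform HU offset) is then exactly zero, which the truncated
# analytic samples only achieve approximately.
gauss_deriv2_kernel <- function(sigma, truncate = 4) {
  if (!is.finite(sigma) || sigma <= 0) stop("sigma must be positive")
  r <- ceiling(truncate * sigma)
  x <- seq.int(-r, r)
  e <- exp(-x^2 / (2 * sigma^2))
  k <- (x^2 / sigma^2 - 1) / sigma^2 * e / sum(e)
  k - mean(k)
}

.conv_cache <- new.env(parent = emptyenv())

# Dense banded matrix realizing 1D convolution with reflect
# (half-sample symmetric) boundary handling: ... c b a | a b c d ...
# Cached: the same (length, kernel) pairs recur for every volume of a
# cohort.
conv_matrix <- function(n, kernel) {
  key <- paste(n, paste(signif(kernel, 15), collapse = ","))
  hit <- .conv_cache[[key]]
  if (!is.null(hit)) return(hit)
  M <- conv_matrix_build(n, kernel)
  .conv_cache[[key]] <- M
  M
}

conv_matrix_build <- function(n, kernel) {
  r <- (length(kernel) - 1L) %/% 2L
  M <- matrix(0, n, n)
  for (t in seq_along(kernel)) {
    p <- seq_len(n) + (t - r - 1L)
    q <- (p - 1L) %% (2L * n)
    j <- ifelse(q < n, q + 1L, 2L * n - q)
    ij <- cbind(seq_len(n), j)
    M[ij] <- M[ij] + kernel[t]
  }
  M
}

# Convolve a 3D array along one axis (1, 2 or 3) with a 1D kernel.
conv_axis <- function(a, kernel, axis) {
  d <- dim(a)
  M <- conv_matrix(d[axis], kernel)
  if (axis == 1L) {
    array(M %*% matrix(a, d[1L]), d)
  } else if (axis == 2L) {
    out <- array(0, d)
    Mt <- t(M)
    for (k in seq_len(d[3L])) out[, , k] <- a[, , k] %*% Mt
    out
  } else {
    array(matrix(a, d[1L] * d[2L]) %*% t(M), d)
  }
}

# Separable 3D Gaussian smoothing with per-axis sigmas (voxel units);
# sigma of 0 skips the axis.
gauss_smooth3 <- function(a, sigma_vox, truncate = 4) {
  for (ax in 1:3)
    if (sigma_vox[ax] > 0)
      a <- conv_axis(a, gauss_kernel(sigma_vox[ax], truncate), ax)
  a
}

#' Filter specification for one analysis channel
#'
#' @param level one of `"none"`, `"fine"`, `"coarse"`.
#' @param sigma Gaussian scale.  Defaults: 1.0 for `"fine"`, 2.5 for
#'   `"coarse"`, unused for `"none"`.  Interpreted in in-plane voxel units
#'   by default (`sigma_units = "voxel"`); with `sigma_units = "mm"` the
#'   scale is converted per axis using the voxel spacing.
#' @param mode `"2d"` (default) applies the LoG within each axial slice,
#'   appropriate when slices are thick relative to sigma; `"3d"` uses the
#'   full 3D operator.
#' @param truncate kernel truncation radius in multiples of sigma.
#' @param sigma_units `"voxel"` or `"mm"`.
#' @return a list of class `filter_spec`.
#' @export
filter_spec <- function(level = c("none", "fine", "coarse"), sigma = NULL,
                        mode = c("2d", "3d"), truncate = 4,
                        sigma_units = c("voxel", "mm")) {
  level <- match.arg(level)
  mode <- match.arg(mode)
  sigma_units <- match.arg(sigma_units)
  if (is.null(sigma))
    sigma <- switch(level, none = NA_real_, fine = 1.0, coarse = 2.5)
  if (level != "none" && (!is.finite(sigma) || sigma <= 0))
    stop("sigma must be positive for level '", level, "'")
  structure(list(level = level, sigma = sigma, mode = mode,
                 truncate = truncate, sigma_units = sigma_units),
            class = "filter_spec")
}

#' Laplacian-of-Gaussian filter of a volume
#'
#' Returns the LoG response of the volume at the scale given by `spec`:
#' the sum over axes of the second Gaussian derivative along that axis and
#' Gaussian smoothing along the others.  In `"2d"` mode only the two
#' in-plane axes participate, so each axial slice is filtered
#' independently.  Boundary handling is reflect padding; kernels are
#' truncated at `spec$truncate` sigmas; the response carries no
#' sigma^2 scale normalization.  `level = "none"` returns the input
#' unchanged.
#'
#' The response of a band-pass kernel is signed: masked means of filtered
#' channels are legitimately negative.
#'
#' @param volume a [ct_volume()].
#' @param spec a [filter_spec()].
#' @return a [ct_volume()] on the same grid.
#' @export
log_filter <- function(volume, spec = filter_spec("fine")) {
  stopifnot(inherits(volume, "ct_volume"), inherits(spec, "filter_spec"))
  if (spec$level == "none") return(volume)
  if (!is.finite(spec$sigma) || spec$sigma <= 0)
    stop("sigma must be positive")
  # per-axis sigma in voxel units
  if (spec$sigma_units == "mm") {
    sig <- spec$sigma / volume$spacing
  } else {
    # voxel units on the in-plane grid; out-of-plane corrected for
    # anisotropy so the operator is isotropic in mm
    sig <- spec$sigma * volume$spacing[1] / volume$spacing
  }
  if (spec$mode == "2d") {
    # slicewise separable form: L = D S G' + G S D'
    d <- dim(volume$data)
    D1 <- conv_matrix(d[1], gauss_deriv2_kernel(sig[1], spec$truncate))
    G1 <- conv_matrix(d[1], gauss_kernel(sig[1], spec$truncate))
    D2t <- t(conv_matrix(d[2], gauss_deriv2_kernel(sig[2], spec$truncate)))
    G2t <- t(conv_matrix(d[2], gauss_kernel(sig[2], spec$truncate)))
    out <- array(0, d)
    for (k in seq_len(d[3])) {
      s <- volume$data[, , k]
      out[, , k] <- D1 %*% s %*% G2t + G1 %*% s %*% D2t
    }
  } else {
    out <- 0
    for (ax in 1:3) {
      term <- conv_axis(volume$data,
                        gauss_deriv2_kernel(sig[ax], spec$truncate), ax)
      for (other in setdiff(1:3, ax))
        term <- conv_axis(term, gauss_kernel(sig[other], spec$truncate),
                          other)
      out <- out + term
    }
  }
  structure(list(data = out, spacing = volume$spacing),
            class = "ct_volume")
}

#' Produce the three analysis channels of a volume
#'
#' @param volume a [ct_volume()].
#' @param sigma_fine,sigma_coarse LoG scales for the two filtered
#'   channels.
#' @param mode,truncate,sigma_units passed to [filter_spec()].
#' @return a named list with elements `none`, `fine`, `coarse`, each a
#'   [ct_volume()].
#' @export
channelize <- function(volume, sigma_fine = 1.0, sigma_coarse = 2.5,
                       mode = "2d", truncate = 4, sigma_units = "voxel") {
  list(
    none = volume,
    fine = log_filter(volume, filter_spec("fine", sigma_fine, mode,
                                          truncate, sigma_units)),
    coarse = log_filter(volume, filter_spec("coarse", sigma_coarse, mode,
                                            truncate, sigma_units))
  )
}
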