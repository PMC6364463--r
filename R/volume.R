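#' @title Image volumes and ROI masks
#' @description Lightweight containers for 3D CT-like volumes and binary
#'   lesion masks, plus NIfTI-1 I/O and the two-reader ROI superposition
#'   rule.  Geometry (voxel spacing, in mm) is always taken from the NIfTI
#'   header; voxel indices are 1-based in R code.
#' @name volume
NULL

#' Construct an image volume
#'
#' @param data 3D numeric array of voxel intensities (HU scale for raw CT).
#' @param spacing numeric length-3 vector of voxel spacings in mm
#'   (in-plane x, in-plane y, slice thickness).
#' @return An object of class `ct_volume`: a list with elements `data`
#'   (the array) and `spacing`.
#' @export
ct_volume <- function(data, spacing = c(1, 1, 1)) {
  data <- unclass(data)
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("volume data must be a 3D array, got ", length(dim(data)), " dimensions")
  if (!is.numeric(spacing) || length(spacing) != 3L || any(!is.finite(spacing)) ||
      any(spacing <= 0))
    stop("spacing must be 3 positive finite values (mm)")
  if (any(!is.finite(data)))
    stop("volume contains non-finite voxel values")
  structure(list(data = data, spacing = as.numeric(spacing)),
            class = "ct_volume")
}

#' Construct a binary ROI mask
#'
#' @param data 3D array; nonzero voxels are foreground.
#' @param spacing voxel spacing in mm, as in [ct_volume()].
#' @return An object of class `roi_mask` with logical `data` and `spacing`.
#' @export
roi_mask <- function(data, spacing = c(1, 1, 1)) {
  data <- unclass(data)
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("mask data must be a 3D array")
  v <- structure(list(data = array(data != 0, dim(data)),
                      spacing = as.numeric(spacing)),
                 class = "roi_mask")
  if (!is.numeric(spacing) || length(spacing) != 3L || any(spacing <= 0))
    stop("spacing must be 3 positive values (mm)")
  v
}

#' @export
print.ct_volume <- function(x, ...) {
  cat("<ct_volume> ", paste(dim(x$data), collapse = " x "),
      " voxels, spacing ", paste(format(x$spacing), collapse = " x "),
      " mm\n", sep = "")
  cat("  intensity range [", format(min(x$data)), ", ",
      format(max(x$data)), "]\n", sep = "")
  invisible(x)
}

#' @export
print.roi_mask <- function(x, ...) {
  cat("<roi_mask> ", paste(dim(x$data), collapse = " x "),
      " voxels, ", sum(x$data), " foreground, spans ",
      mask_slice_count(x), " axial slices\n", sep = "")
  invisible(x)
}

#' Number of axial slices touched by a mask
#'
#' Counts slices (third array index) containing at least one foreground
#' voxel.  Study-conformant lesions must span at least 7 slices.
#' @param mask an [roi_mask()].
#' @return integer slice count.
#' @export
mask_slice_count <- function(mask) {
  stopifnot(inherits(mask, "roi_mask"))
  sum(apply(mask$data, 3, any))
}

nifti_spacing <- function(img) {
  pd <- RNifti::pixdim(img)
  as.numeric(pd[seq_len(3)])
}

#' Read a 3D volume from a NIfTI file
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @return a [ct_volume()] with spacing taken from the header (no
#'   resampling, no reorientation).
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3L)
    stop("expected a 3D volume, but '", path, "' has ", length(d),
         " dimensions")
  ct_volume(array(as.numeric(img), d), nifti_spacing(img))
}

#' Read a binary ROI mask from a NIfTI file
#'
#' @inheritParams read_volume
#' @return an [roi_mask()]; any nonzero voxel is foreground.
#' @export
read_mask <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3L)
    stop("expected a 3D mask, but '", path, "' has ", length(d),
         " dimensions")
  roi_mask(array(as.numeric(img), d) != 0, nifti_spacing(img))
}

#' Write a volume or mask to a NIfTI-1 file
#'
#' Volumes are stored as 32-bit float (ample for HU-scale data), masks as
#' unsigned 8-bit integers with values 0/1.
#'
#' @param x a `ct_volume` or `roi_mask`.
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(x, path) {
  stopifnot(inherits(x, "ct_volume") || inherits(x, "roi_mask"))
  dat <- if (inherits(x, "roi_mask")) array(as.integer(x$data), dim(x$data))
         else x$data
  img <- RNifti::asNifti(dat)
  RNifti::pixdim(img) <- x$spacing
  dt <- if (inherits(x, "roi_mask")) "uint8" else "float"
  RNifti::writeNifti(img, path, datatype = dt)
  invisible(path)
}

check_congruent <- function(a, b, what = "inputs") {
  if (!identical(dim(a$data), dim(b$data)))
    stop("geometry error: ", what, " have different shapes (",
         paste(dim(a$data), collapse = "x"), " vs ",
         paste(dim(b$data), collapse = "x"), ")")
  if (max(abs(a$spacing - b$spacing)) > 1e-6)
    stop("geometry error: ", what, " have different voxel spacings")
  invisible(TRUE)
}

#' Superimpose two readers' ROI masks
#'
#' Combines two independent delineations of the same lesion into the final
#' analysis ROI.  The default rule is the voxelwise union, which keeps the
#' full extent captured by either reader (including the heterogeneous
#' tumor periphery); the intersection rule keeps only voxels both readers
#' agreed on.
#'
#' @param mask_a,mask_b congruent [roi_mask()] objects.
#' @param rule `"union"` (default) or `"intersection"`.
#' @return an [roi_mask()]; the rule used is recorded in the
#'   `"superposition_rule"` attribute.
#' @export
superimpose_rois <- function(mask_a, mask_b,
                             rule = c("union", "intersection")) {
  rule <- match.arg(rule)
  stopifnot(inherits(mask_a, "roi_mask"), inherits(mask_b, "roi_mask"))
  check_congruent(mask_a, mask_b, "masks")
  dat <- if (rule == "union") mask_a$data | mask_b$data
         else mask_a$data & mask_b$data
  out <- roi_mask(dat, mask_a$spacing)
  attr(out, "superposition_rule") <- rule
  out
}
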