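#' @title Cohort manifests
#' @description The manifest maps each subject to a group label and to the
#'   volume/mask file of each contrast phase.  Validation encodes the
#'   study inclusion rules as checks: both phases present, volume and mask
#'   geometry congruent, and the lesion spanning at least 7 axial slices.
#' @name manifest
NULL

MANIFEST_COLS <- c("subject_id", "group", "phase", "volume", "mask")

#' Read a cohort manifest CSV
#'
#' @param path CSV with header `subject_id,group,phase,volume,mask`;
#'   relative file paths are resolved against the manifest's directory.
#' @return a `data.frame` with the five manifest columns.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop("no such manifest: ", path)
  m <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(MANIFEST_COLS %in% names(m)))
    stop("manifest must have columns ", paste(MANIFEST_COLS, collapse = ","))
  base <- dirname(normalizePath(path))
  for (col in c("volume", "mask")) {
    rel <- !grepl("^(/|[A-Za-z]:)", m[[col]])
    m[[col]][rel] <- file.path(base, m[[col]][rel])
  }
  m[, MANIFEST_COLS]
}

#' Validate a cohort manifest
#'
#' Checks every subject against the inclusion rules and returns a
#' per-subject report.  A subject fails if a phase row is missing or
#' duplicated, a file is absent, volume and mask shapes or spacings
#' disagree, the mask is empty, or (when `require_slices` is kept at its
#' study-conformant default of 7) the lesion spans too few axial slices.
#'
#' @param manifest manifest `data.frame` or path to a manifest CSV.
#' @param require_slices minimum axial slice span of the lesion; set to
#'   `0` to disable the check.
#' @return `data.frame` with columns `subject_id`, `group`, `pass`,
#'   `reasons` (semicolon-separated), of class `cohort_validation`.
#' @export
validate_cohort <- function(manifest, require_slices = 7) {
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  manifest <- as.data.frame(manifest)
  if (nrow(manifest) == 0L) stop("empty manifest")
  if (!all(manifest$group %in% c("low", "high")))
    stop("group labels must be 'low' or 'high'")
  subjects <- unique(manifest$subject_id)
  res <- lapply(subjects, function(id) {
    rows <- manifest[manifest$subject_id == id, ]
    reasons <- character(0)
    for (ph in PHASES) {
      k <- sum(rows$phase == ph)
      if (k == 0L) reasons <- c(reasons, paste("missing phase:", ph))
      if (k > 1L) reasons <- c(reasons, paste("duplicated phase:", ph))
    }
    for (i in seq_len(nrow(rows))) {
      r <- rows[i, ]
      if (!file.exists(r$volume)) {
        reasons <- c(reasons, paste("missing volume file:", r$phase))
        next
      }
      if (!file.exists(r$mask)) {
        reasons <- c(reasons, paste("missing mask file:", r$phase))
        next
      }
      ok <- tryCatch({
        vol <- read_volume(r$volume)
        msk <- read_mask(r$mask)
        check_congruent(vol, msk, "volume and mask")
        if (sum(msk$data) == 0L)
          reasons <- c(reasons, paste("empty mask:", r$phase))
        else if (require_slices > 0 &&
                 mask_slice_count(msk) < require_slices)
          reasons <- c(reasons, sprintf(
            "slice count: lesion spans %d < %d slices (%s)",
            mask_slice_count(msk), require_slices, r$phase))
        TRUE
      }, error = function(e) conditionMessage(e))
      if (is.character(ok)) reasons <- c(reasons, ok)
    }
    data.frame(subject_id = id, group = rows$group[1],
               pass = length(reasons) == 0L,
               reasons = paste(reasons, collapse = "; "),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  class(out) <- c("cohort_validation", "data.frame")
  out
}

#' @export
print.cohort_validation <- function(x, ...) {
  cat("Cohort validation: ", sum(x$pass), "/", nrow(x),
      " subjects pass\n", sep = "")
  bad <- x[!x$pass, ]
  for (i in seq_len(nrow(bad)))
    cat("  FAIL ", bad$subject_id[i], ": ", bad$reasons[i], "\n", sep = "")
  invisible(x)
}
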