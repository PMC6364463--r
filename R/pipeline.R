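#' @title End-to-end CTTA study
#' @description One call that runs the whole pipeline — cohort input (disk
#'   manifest or phantom specification), validation, channelization,
#'   feature extraction, FDR-corrected group comparison, and ROC analysis
#'   of the significant features — and returns a single classed result
#'   object.  Every paper-silent convention the run resolved (sigma units,
#'   filter mode, binning, kurtosis convention, test variant, ROI
#'   superposition rule) is recorded in the run log so results are
#'   auditable.
#' @name pipeline
NULL

cttar_settings <- function(n_bins, sigma_fine, sigma_coarse, mode,
                           truncate, sigma_units, alpha, var_equal,
                           require_slices, seed) {
  list(
    n_bins = n_bins, histogram_range = "per-ROI min-max",
    entropy_base = "log2 (bits)",
    kurtosis_convention = "non-excess (Gaussian = 3)",
    sd_convention = "sample (n-1)",
    sigma_fine = sigma_fine, sigma_coarse = sigma_coarse,
    sigma_units = sigma_units, filter_mode = mode,
    filter_boundary = "reflect", filter_truncate = truncate,
    log_normalization = "none (no sigma^2 scaling)",
    test = if (var_equal) "pooled-variance t" else "Welch t",
    alpha = alpha, p_adjust = "Benjamini-Hochberg, joint over the grid",
    cutoff_rule = "Youden's J, midpoint-between-observations",
    roi_superposition_default = "union",
    require_slices = require_slices, seed = seed)
}

#' Run the full texture-analysis study
#'
#' Either `manifest` (a cohort on disk) or `spec` (a [phantom_spec()]
#' generated in memory) must be supplied.  Disk cohorts are validated
#' first; subjects failing validation are excluded with a warning unless
#' `force = TRUE`.  When `out_dir` is given, the run writes
#' `features.csv`, `table1.csv` (the full comparison grid), `table2.csv`
#' (ROC of significant features), `roc.svg`, `run_log.txt` and
#' `provenance.json`.
#'
#' @param manifest manifest `data.frame` or path to `manifest.csv`.
#' @param spec a [phantom_spec()] for an in-memory phantom cohort.
#' @param seed run seed (defaults to `spec$seed` for phantom runs).
#' @param null for phantom runs, generate under the global null.
#' @param out_dir optional output directory for report files.
#' @param n_bins histogram bins for entropy.
#' @param sigma_fine,sigma_coarse,mode,truncate,sigma_units filtering
#'   options, see [filter_spec()].
#' @param alpha,var_equal comparison options, see [compare_groups()].
#' @param require_slices minimum lesion slice span for validation.
#' @param force keep subjects that fail validation.
#' @return an object of class `ctta_study` with elements `features`,
#'   `comparison`, `roc`, `validation`, `settings`.
#' @examples
#' spec <- phantom_spec(n_low = 4, n_high = 4, seed = 7)
#' fit <- ctta_study(spec = spec)
#' summary(fit)
#' @export
ctta_study <- function(manifest = NULL, spec = NULL, seed = NULL,
                       null = FALSE, out_dir = NULL, n_bins = 256,
                       sigma_fine = 1.0, sigma_coarse = 2.5, mode = "2d",
                       truncate = 4, sigma_units = "voxel", alpha = 0.05,
                       var_equal = FALSE, require_slices = 7,
                       force = FALSE) {
  if (is.null(manifest) == is.null(spec))
    stop("supply exactly one of 'manifest' or 'spec'")
  hist <- histogram_spec(n_bins)
  validation <- NULL
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  if (!is.null(manifest)) {
    if (is.character(manifest)) manifest <- read_manifest(manifest)
    validation <- stage("validate", validate_cohort(manifest, require_slices))
    if (!all(validation$pass) && !force) {
      bad <- validation$subject_id[!validation$pass]
      warning("excluding subjects failing validation: ",
              paste(bad, collapse = ", "))
      manifest <- manifest[!(manifest$subject_id %in% bad), ]
      if (nrow(manifest) == 0L) stop("no subjects pass validation")
    }
    features <- stage("extract",
      extract_cohort(manifest, hist, sigma_fine = sigma_fine,
                     sigma_coarse = sigma_coarse, mode = mode,
                     truncate = truncate, sigma_units = sigma_units))
  } else {
    stopifnot(inherits(spec, "phantom_spec"))
    if (is.null(seed)) seed <- spec$seed
    features <- stage("simulate",
      simulate_features(spec, seed = seed, null = null, hist = hist,
                        sigma_fine = sigma_fine,
                        sigma_coarse = sigma_coarse, mode = mode,
                        truncate = truncate, sigma_units = sigma_units))
  }
  comparison <- stage("compare",
                      compare_groups(features, alpha, var_equal))
  roc <- stage("roc", roc_analysis(features, comparison))
  obj <- structure(list(
    features = features, comparison = comparison, roc = roc,
    validation = validation,
    settings = cttar_settings(n_bins, sigma_fine, sigma_coarse, mode,
                              truncate, sigma_units, alpha, var_equal,
                              require_slices, seed)),
    class = "ctta_study")
  if (!is.null(out_dir)) write_study(obj, out_dir)
  obj
}

num_csv <- function(df) {
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], function(x) signif(x, 12))
  df
}

#' Write the report files of a study
#'
#' @param x a `ctta_study`.
#' @param out_dir output directory, created if needed.
#' @return `out_dir`, invisibly.
#' @export
write_study <- function(x, out_dir) {
  stopifnot(inherits(x, "ctta_study"))
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", out_dir)
  utils::write.csv(num_csv(x$features),
                   file.path(out_dir, "features.csv"), row.names = FALSE)
  utils::write.csv(num_csv(as.data.frame(x$comparison)),
                   file.path(out_dir, "table1.csv"), row.names = FALSE)
  roc_df <- as.data.frame(x$roc)
  attr(roc_df, "curves") <- NULL
  utils::write.csv(num_csv(roc_df),
                   file.path(out_dir, "table2.csv"), row.names = FALSE)
  log_lines <- c("resolved run settings:",
                 paste0("  ", names(x$settings), " = ",
                        vapply(x$settings, function(v)
                          paste(format(v), collapse = " "), "")))
  writeLines(log_lines, file.path(out_dir, "run_log.txt"))
  jsonlite::write_json(
    list(settings = x$settings,
         package_version = as.character(utils::packageVersion("cttar")),
         r_version = R.version.string),
    file.path(out_dir, "provenance.json"), auto_unbox = TRUE, digits = NA)
  if (nrow(x$roc) > 0 && capabilities("cairo")) {
    grDevices::svg(file.path(out_dir, "roc.svg"), width = 6, height = 6)
    plot(x)
    grDevices::dev.off()
  }
  invisible(out_dir)
}

#' Run a study from a YAML configuration
#'
#' The configuration maps directly onto [ctta_study()] and
#' [phantom_spec()] arguments: top-level keys `manifest`, `out_dir`,
#' `seed`, `null`; a `phantom:` block with `phantom_spec` fields; a
#' `histogram:` block (`n_bins`); a `filter:` block (`sigma_fine`,
#' `sigma_coarse`, `mode`, `truncate`, `sigma_units`); and a `stats:`
#' block (`alpha`, `var_equal`).
#'
#' @param config path to a YAML file, or an equivalent nested list.
#' @return a `ctta_study` object.
#' @export
ctta_run <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  args <- list(
    manifest = config$manifest,
    seed = config$seed, null = isTRUE(config$null),
    out_dir = config$out_dir)
  if (!is.null(config$phantom)) {
    ph <- config$phantom
    if (!is.null(ph$lesion_mean_hu))
      ph$lesion_mean_hu <- lapply(ph$lesion_mean_hu, unlist)
    for (nm in c("texture_field_sd", "texture_correlation_length",
                 "necrosis_fraction"))
      if (!is.null(ph[[nm]])) ph[[nm]] <- unlist(ph[[nm]])
    args$spec <- do.call(phantom_spec, ph)
  }
  for (nm in names(config$histogram)) args[[nm]] <- config$histogram[[nm]]
  for (nm in names(config$filter)) args[[nm]] <- config$filter[[nm]]
  for (nm in names(config$stats)) args[[nm]] <- config$stats[[nm]]
  args <- args[!vapply(args, is.null, TRUE)]
  do.call(ctta_study, args)
}

#' @export
print.ctta_study <- function(x, ...) {
  f <- x$features
  ns <- tapply(f$subject_id, f$group, function(s) length(unique(s)))
  cat("CT texture-analysis study\n")
  cat("  subjects: ", ns[["low"]], " low grade, ", ns[["high"]],
      " high grade\n", sep = "")
  cat("  feature records: ", nrow(f), " (2 phases x 3 filter levels)\n",
      sep = "")
  cat("  tests: ", nrow(x$comparison), " cells, ",
      sum(x$comparison$significant), " FDR-significant at alpha = ",
      x$settings$alpha, "\n", sep = "")
  if (nrow(x$roc) > 0) {
    cat("  ROC of significant features:\n")
    r <- x$roc
    for (i in seq_len(nrow(r)))
      cat(sprintf("    %-16s %-9s %-7s AUC %.2f sens %.2f spec %.2f cutoff %.3g\n",
                  r$phase[i], r$feature[i], r$filter[i], r$auc[i],
                  r$sensitivity[i], r$specificity[i], r$cutoff[i]))
  } else cat("  no feature significant after FDR; no ROC computed\n")
  invisible(x)
}

#' @export
summary.ctta_study <- function(object, ...) {
  structure(list(comparison = object$comparison, roc = object$roc,
                 settings = object$settings),
            class = "summary.ctta_study")
}

#' @export
print.summary.ctta_study <- function(x, ...) {
  cat("Group comparison grid (", nrow(x$comparison), " tests, ",
      x$settings$test, ", BH-adjusted):\n\n", sep = "")
  tab <- as.data.frame(x$comparison)
  tab$low <- sprintf("%.2f ± %.2f", tab$mean_low, tab$sd_low)
  tab$high <- sprintf("%.2f ± %.2f", tab$mean_high, tab$sd_high)
  tab$p <- signif(tab$p, 2)
  tab$p_adj <- signif(tab$p_adj, 2)
  tab$sig <- ifelse(tab$significant, "*", "")
  print(tab[, c("phase", "feature", "filter", "low", "high", "p",
                "p_adj", "sig")], row.names = FALSE)
  if (nrow(x$roc) > 0) {
    cat("\nROC of FDR-significant features:\n\n")
    r <- as.data.frame(x$roc)
    r$auc <- round(r$auc, 2)
    r$sensitivity <- round(r$sensitivity, 2)
    r$specificity <- round(r$specificity, 2)
    r$cutoff <- signif(r$cutoff, 3)
    print(r, row.names = FALSE)
  }
  invisible(x)
}

#' Plot ROC curves of the significant features
#'
#' @param x a `ctta_study`.
#' @param ... passed to `plot.default`.
#' @export
plot.ctta_study <- function(x, ...) {
  r <- x$roc
  if (nrow(r) == 0L) {
    graphics::plot.new()
    graphics::title("no FDR-significant features")
    return(invisible(x))
  }
  curves <- attr(r, "curves")
  cols <- grDevices::hcl.colors(max(3, nrow(r)), "Dark 3")
  graphics::plot(c(0, 1), c(0, 1), type = "l", lty = 3, col = "grey50",
                 xlab = "1 - specificity", ylab = "sensitivity",
                 main = "ROC of FDR-significant texture features", ...)
  for (i in seq_len(nrow(r)))
    graphics::lines(curves[[i]]$fpr, curves[[i]]$tpr, col = cols[i],
                    lwd = 2)
  graphics::legend("bottomright", bty = "n", lwd = 2,
                   col = cols[seq_len(nrow(r))],
                   legend = sprintf("%s %s (%s), AUC %.2f", r$phase,
                                    r$feature, r$filter, r$auc))
  invisible(x)
}
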