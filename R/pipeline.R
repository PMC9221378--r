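read_manifest <- function(manifest, data_dir = NULL) {
  if (is.character(manifest) && length(manifest) == 1) {
    data_dir <- data_dir %||% dirname(manifest)
    manifest <- utils::read.csv(manifest, stringsAsFactors = FALSE)
  }
  manifest <- as.data.frame(manifest)
  need <- c("sample_id", "class", "modality", "path")
  if (!all(need %in% names(manifest)))
    stop("manifest must have columns: ", paste(need, collapse = ", "))
  if (!is.null(data_dir))
    manifest$path <- file.path(data_dir, manifest$path)
  manifest
}

#' Per-sample OCT scanning-window features from a manifest
#'
#' Reads each listed B-scan, builds its tissue mask ([build_mask()]),
#' extracts the 12 window features ([oct_image_features()]), and averages
#' them per sample. Files that fail to process are skipped with a warning.
#'
#' @param manifest Manifest data frame or CSV path (columns `sample_id`,
#'   `class`, `modality`, `path`); only `modality == "OCT"` rows are used.
#' @param data_dir Directory against which manifest paths are resolved
#'   (defaults to the manifest's own directory when a path is given).
#' @param window Scanning-window side (default 15).
#' @param n_top_rows Saturation-rule row count (default 15).
#' @param method,level Threshold settings, see [threshold_mask()].
#' @return List with `features` (data frame: `sample_id`, `class`,
#'   `n_images`, 12 feature columns), `qc` (per-image mask QC log), and
#'   `failed` (paths that could not be processed).
#' @export
extract_oct_features <- function(manifest, data_dir = NULL, window = 15,
                                 n_top_rows = 15, method = "otsu",
                                 level = NULL) {
  m <- read_manifest(manifest, data_dir)
  m <- m[m$modality == "OCT", , drop = FALSE]
  failed <- character(0)
  qc <- list(); rows <- list()
  for (sid in unique(m$sample_id)) {
    ms <- m[m$sample_id == sid, , drop = FALSE]
    vecs <- list()
    for (k in seq_len(nrow(ms))) {
      res <- tryCatch({
        img <- read_oct_tiff(ms$path[k], sample_id = sid)
        msk <- build_mask(img, method = method, level = level,
                          n_top_rows = n_top_rows)
        list(feat = oct_image_features(img, msk, window = window),
             qc = mask_qc(msk, basename(ms$path[k])))
      }, error = function(e) {
        warning("OCT file skipped (", basename(ms$path[k]), "): ",
                conditionMessage(e), call. = FALSE)
        NULL
      })
      if (!is.null(res)) {
        vecs[[length(vecs) + 1L]] <- res$feat
        qc[[length(qc) + 1L]] <- res$qc
      } else failed <- c(failed, ms$path[k])
    }
    if (length(vecs)) {
      f <- aggregate_sample(vecs)
      rows[[length(rows) + 1L]] <- cbind(
        data.frame(sample_id = sid, class = ms$class[1],
                   n_images = length(vecs), stringsAsFactors = FALSE),
        as.data.frame(as.list(f)))
    } else {
      warning("sample ", sid, " dropped from OCT features (no usable image)",
              call. = FALSE)
    }
  }
  list(features = if (length(rows)) do.call(rbind, rows) else NULL,
       qc = if (length(qc)) do.call(rbind, qc) else NULL,
       failed = failed)
}

#' Per-sample Raman band features from a manifest
#'
#' Reads each listed spectrum CSV, extracts p1-p8 ([raman_features()]), and
#' averages them per sample. Files that fail to process are skipped with a
#' warning.
#'
#' @inheritParams extract_oct_features
#' @param order Baseline polynomial order (default 7).
#' @param bands Band definitions (default [default_bands()]).
#' @param anchor_lo,anchor_hi Normalization anchor window (cm^-1).
#' @param grid Canonical wavenumber grid.
#' @return List with `features` (data frame: `sample_id`, `class`,
#'   `n_spectra`, `p1`..`p8`) and `failed`.
#' @export
extract_raman_features <- function(manifest, data_dir = NULL, order = 7,
                                   bands = default_bands(),
                                   anchor_lo = 1425, anchor_hi = 1460,
                                   grid = seq(920, 2070, by = 1)) {
  m <- read_manifest(manifest, data_dir)
  m <- m[m$modality == "Raman", , drop = FALSE]
  failed <- character(0)
  rows <- list()
  for (sid in unique(m$sample_id)) {
    ms <- m[m$sample_id == sid, , drop = FALSE]
    vecs <- list()
    for (k in seq_len(nrow(ms))) {
      res <- tryCatch(
        raman_features(read_spectrum_csv(ms$path[k], sample_id = sid),
                       order = order, bands = bands, anchor_lo = anchor_lo,
                       anchor_hi = anchor_hi, grid = grid),
        error = function(e) {
          warning("Raman file skipped (", basename(ms$path[k]), "): ",
                  conditionMessage(e), call. = FALSE)
          NULL
        })
      if (!is.null(res)) vecs[[length(vecs) + 1L]] <- res
      else failed <- c(failed, ms$path[k])
    }
    if (length(vecs)) {
      f <- aggregate_sample_spectra(vecs)
      rows[[length(rows) + 1L]] <- cbind(
        data.frame(sample_id = sid, class = ms$class[1],
                   n_spectra = length(vecs), stringsAsFactors = FALSE),
        as.data.frame(as.list(f)))
    } else {
      warning("sample ", sid, " dropped from Raman features (no usable spectrum)",
              call. = FALSE)
    }
  }
  list(features = if (length(rows)) do.call(rbind, rows) else NULL,
       failed = failed)
}

dataset_report <- function(features, feature_cols) {
  x <- as.matrix(features[, feature_cols, drop = FALSE])
  rownames(x) <- features$sample_id
  pred <- loocv_lda(x, features$class, sample_ids = features$sample_id)
  metrics <- sens_spec_table(pred)
  sig <- NULL
  if (all(table(features$class) >= 3))
    sig <- mann_whitney_matrix(features[, feature_cols, drop = FALSE],
                               features$class)
  acc <- mean(pred$true_label == pred$predicted_label)
  merged <- merge_malignant(pred)
  list(features = features, predictions = pred, metrics = metrics,
       significance = sig, accuracy = acc,
       merged_accuracy = mean(merged$true_label == merged$predicted_label))
}

#' Run the full multimodal classification pipeline
#'
#' Extracts per-sample OCT and Raman features from a manifest, assembles the
#' OCT-only, Raman-only and combined feature matrices, and for each runs
#' leave-one-out LDA classification, per-class and merged-malignant
#' sensitivity/specificity, and Mann-Whitney significance matrices.
#' Optionally writes feature tables, prediction tables, a metrics JSON,
#' significance tables and LD-scatter coordinates to `out_dir`.
#'
#' Per-file failures drop the file (and, if nothing of a sample remains, the
#' sample) with a warning; the run aborts if more than `max_drop_frac` of
#' the manifest's samples drop out of any dataset.
#'
#' @inheritParams extract_oct_features
#' @param modalities Subset of `c("OCT", "Raman")`; the combined dataset is
#'   produced when both are present.
#' @param out_dir Optional output directory for report files.
#' @param max_drop_frac Maximum tolerated fraction of dropped samples.
#' @param oct_args,raman_args Named lists of extra arguments for
#'   [extract_oct_features()] / [extract_raman_features()].
#' @return An object of class `tumor_report`: list with one entry per
#'   dataset (`OCT`, `Raman`, `combined`), each holding `features`,
#'   `predictions`, `metrics`, `significance`, `accuracy`,
#'   `merged_accuracy`.
#' @export
run_pipeline <- function(manifest, data_dir = NULL,
                         modalities = c("OCT", "Raman"),
                         out_dir = NULL, max_drop_frac = 0.2,
                         oct_args = list(), raman_args = list()) {
  modalities <- match.arg(modalities, c("OCT", "Raman"), several.ok = TRUE)
  m <- read_manifest(manifest, data_dir)
  n_expected <- length(unique(m$sample_id[m$modality %in% modalities]))

  feats <- list()
  if ("OCT" %in% modalities) {
    ex <- do.call(extract_oct_features, c(list(manifest = m), oct_args))
    feats$OCT <- list(df = ex$features, cols = oct_feature_names(), qc = ex$qc)
  }
  if ("Raman" %in% modalities) {
    ex <- do.call(extract_raman_features, c(list(manifest = m), raman_args))
    feats$Raman <- list(df = ex$features, cols = c(paste0("p", 1:7), "p8"))
  }
  for (tag in names(feats)) {
    kept <- if (is.null(feats[[tag]]$df)) 0 else nrow(feats[[tag]]$df)
    if ((n_expected - kept) / n_expected > max_drop_frac)
      stop("run_pipeline: more than ", round(100 * max_drop_frac),
           "% of samples dropped from the ", tag, " dataset")
  }

  datasets <- list()
  for (tag in names(feats)) {
    datasets[[tag]] <- dataset_report(feats[[tag]]$df, feats[[tag]]$cols)
    datasets[[tag]]$qc <- feats[[tag]]$qc
  }
  if (all(c("OCT", "Raman") %in% names(feats))) {
    a <- feats$OCT$df; b <- feats$Raman$df
    common <- intersect(a$sample_id, b$sample_id)
    if ((n_expected - length(common)) / n_expected > max_drop_frac)
      stop("run_pipeline: more than ", round(100 * max_drop_frac),
           "% of samples dropped from the combined dataset")
    a <- a[match(common, a$sample_id), , drop = FALSE]
    b <- b[match(common, b$sample_id), , drop = FALSE]
    comb <- cbind(a[, c("sample_id", "class", feats$OCT$cols)],
                  b[, feats$Raman$cols, drop = FALSE])
    datasets$combined <- dataset_report(comb, c(feats$OCT$cols, feats$Raman$cols))
  }

  report <- structure(list(datasets = datasets,
                           n_samples = n_expected,
                           modalities = modalities),
                      class = "tumor_report")
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  metrics <- list()
  for (tag in names(report$datasets)) {
    d <- report$datasets[[tag]]
    utils::write.csv(d$features,
                     file.path(out_dir, sprintf("features_%s.csv", tag)),
                     row.names = FALSE)
    utils::write.csv(as.data.frame(d$predictions),
                     file.path(out_dir, sprintf("predictions_%s.csv", tag)),
                     row.names = FALSE)
    if (!is.null(d$significance))
      utils::write.csv(as.data.frame(d$significance),
                       file.path(out_dir, sprintf("significance_%s.csv", tag)),
                       row.names = FALSE)
    ld_cols <- grep("^LD", names(d$predictions), value = TRUE)
    utils::write.csv(d$predictions[, c("sample_id", "true_label", ld_cols)],
                     file.path(out_dir, sprintf("ld_scatter_%s.csv", tag)),
                     row.names = FALSE)
    metrics[[tag]] <- list(
      n_samples = nrow(d$features),
      accuracy = d$accuracy,
      merged_accuracy = d$merged_accuracy,
      sens_spec = d$metrics)
  }
  jsonlite::write_json(metrics, file.path(out_dir, "metrics.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' @export
print.tumor_report <- function(x, ...) {
  cat("Multimodal tumor classification report\n")
  cat("  datasets:", paste(names(x$datasets), collapse = ", "), "\n")
  for (tag in names(x$datasets)) {
    d <- x$datasets[[tag]]
    mal <- d$metrics[d$metrics$class == "malignant", ]
    cat(sprintf("  %-8s n=%d  LOOCV accuracy %.3f (merged %.3f)",
                tag, nrow(d$features), d$accuracy, d$merged_accuracy))
    if (nrow(mal))
      cat(sprintf("  malignant sens %.3f spec %.3f",
                  mal$sensitivity, mal$specificity))
    cat("\n")
  }
  invisible(x)
}
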