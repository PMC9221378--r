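#' Leave-one-out cross-validated predictions
#'
#' For each sample, a [tissue_lda()] model is fitted on all remaining
#' samples (standardization re-estimated within each training fold) and the
#' held-out sample is predicted. Discriminant coordinates in the returned
#' table come from the full-data fit and serve plotting only; they are not
#' cross-validated.
#'
#' @param x Feature matrix/data frame, rows = samples.
#' @param grouping Class label per row; every class needs >= 2 samples.
#' @param sample_ids Optional sample identifiers (default row names or
#'   `1:n`).
#' @param ... Passed to [tissue_lda()].
#' @return A `prediction_table` data frame: `sample_id`, `true_label`,
#'   `predicted_label`, and `LD1`..`LD(k-1)` columns.
#' @export
loocv_lda <- function(x, grouping, sample_ids = NULL, ...) {
  x <- as.matrix(x)
  grouping <- as_class_factor(grouping)
  n <- nrow(x)
  nk <- table(grouping)
  if (any(nk < 2))
    stop("loocv_lda: class(es) with a single sample cannot be cross-validated: ",
         paste(names(nk)[nk < 2], collapse = ", "))
  sample_ids <- sample_ids %||% (rownames(x) %||% as.character(seq_len(n)))

  full <- tissue_lda(x, grouping, ...)
  ld <- predict(full, x)$x

  pred <- character(n)
  for (i in seq_len(n)) {
    fit <- tissue_lda(x[-i, , drop = FALSE], grouping[-i], ...)
    pred[i] <- as.character(predict(fit, x[i, , drop = FALSE])$class)
  }
  out <- data.frame(sample_id = sample_ids,
                    true_label = as.character(grouping),
                    predicted_label = pred,
                    stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(ld))
  class(out) <- c("prediction_table", "data.frame")
  out
}

#' Merge the malignant classes of a prediction table
#'
#' Relabels MCT and STS as `"malignant"` in both the true and the predicted
#' columns, so an MCT sample predicted STS (or vice versa) counts as a
#' correct malignant call; skin and lipoma are untouched.
#'
#' @param p A `prediction_table` from [loocv_lda()].
#' @return A `prediction_table` with merged labels.
#' @export
merge_malignant <- function(p) {
  stopifnot(inherits(p, "prediction_table"))
  relabel <- function(v) ifelse(v %in% c("MCT", "STS"), "malignant", v)
  p$true_label <- relabel(p$true_label)
  p$predicted_label <- relabel(p$predicted_label)
  p
}

#' One-vs-rest sensitivity and specificity for one class
#'
#' @param p A `prediction_table`.
#' @param class_label The positive class; must occur among the true labels.
#' @return One-row data frame: `class`, `sensitivity`, `specificity`, and
#'   the `tp`, `fn`, `tn`, `fp` counts (summing to the number of samples).
#' @export
confusion_metrics <- function(p, class_label) {
  stopifnot(inherits(p, "prediction_table"))
  if (!class_label %in% p$true_label)
    stop("confusion_metrics: class '", class_label,
         "' absent from the true labels")
  pos_t <- p$true_label == class_label
  pos_p <- p$predicted_label == class_label
  tp <- sum(pos_t & pos_p); fn <- sum(pos_t & !pos_p)
  tn <- sum(!pos_t & !pos_p); fp <- sum(!pos_t & pos_p)
  data.frame(class = class_label,
             sensitivity = tp / (tp + fn),
             specificity = tn / (tn + fp),
             tp = tp, fn = fn, tn = tn, fp = fp)
}

#' Sensitivity/specificity table over all classes plus merged malignant
#'
#' @param p A 4-class `prediction_table`.
#' @return Data frame with one row per class present, plus a `malignant`
#'   row computed after [merge_malignant()] when MCT or STS are present.
#' @export
sens_spec_table <- function(p) {
  stopifnot(inherits(p, "prediction_table"))
  classes <- intersect(CANONICAL_CLASSES, unique(p$true_label))
  if (!length(classes)) classes <- unique(p$true_label)
  rows <- lapply(classes, function(cl) confusion_metrics(p, cl))
  if (any(p$true_label %in% c("MCT", "STS"))) {
    rows <- c(rows, list(confusion_metrics(merge_malignant(p), "malignant")))
  }
  do.call(rbind, rows)
}

#' @export
print.prediction_table <- function(x, ...) {
  acc <- mean(x$true_label == x$predicted_label)
  cat(sprintf("<prediction_table> %d samples, accuracy %.3f\n", nrow(x), acc))
  print.data.frame(x, ...)
  invisible(x)
}
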