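#' Confusion counts over labeled voxels
#'
#' Counts are accumulated only over annotated voxels (code != 0), so
#' predictions on unlabeled slices never influence evaluation.  Axon voxels
#' (code 2) are the positive class; background, artifact, and edge voxels
#' (codes 1, 3, 4) are negatives.  `EA` additionally counts edge voxels
#' predicted positive; the edge-corrected metrics subtract it from the false
#' positives so that boundary-width disagreement with the annotator is not
#' penalised.
#'
#' @param pred Logical prediction mask `(z, y, x)`.
#' @param labels Label array of the same shape.
#' @return A `confusion_counts` list with `TP`, `TN`, `FP`, `FN`, `EA`.
#' @export
confusion_counts <- function(pred, labels) {
  check_that(all(dim(pred) == dim(labels)),
             "prediction (%s) and labels (%s) shapes differ",
             paste(dim(pred), collapse = "x"),
             paste(dim(labels), collapse = "x"))
  pred <- as.logical(pred)
  lab <- as.integer(labels)
  pos <- lab == LABEL_CODES[["axon"]]
  neg <- lab == LABEL_CODES[["background"]] |
    lab == LABEL_CODES[["artifact"]] | lab == LABEL_CODES[["edge"]]
  structure(list(TP = sum(pred & pos),
                 TN = sum(!pred & neg),
                 FP = sum(pred & neg),
                 FN = sum(!pred & pos),
                 EA = sum(pred & lab == LABEL_CODES[["edge"]])),
            class = "confusion_counts")
}

#' Segmentation metrics with edge-corrected variants
#'
#' Computes accuracy, precision, recall, F1, and the edge-corrected
#' precision and F1 in which edge voxels predicted positive (`EA`) are
#' removed from the false positives:
#' \deqn{EdgePrecision = TP / (TP + FP - EA)}
#' \deqn{EdgeF1 = 2 \cdot Recall \cdot EdgePrecision /
#'   (Recall + EdgePrecision)}
#' Any metric whose denominator is zero is reported as `NA` (undefined),
#' never silently as 0.
#'
#' @param counts A [confusion_counts()].
#' @return A `metrics_report` list of fractions in `[0, 1]` (or `NA`).
#' @export
compute_metrics <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  sdiv <- function(num, den) if (den <= 0) NA_real_ else num / den
  with(counts, {
    accuracy <- sdiv(TP + TN, TP + TN + FP + FN)
    precision <- sdiv(TP, TP + FP)
    edge_precision <- sdiv(TP, TP + FP - EA)
    recall <- sdiv(TP, TP + FN)
    f1 <- if (is.na(precision) || is.na(recall)) NA_real_ else
      sdiv(2 * recall * precision, recall + precision)
    edge_f1 <- if (is.na(edge_precision) || is.na(recall)) NA_real_ else
      sdiv(2 * recall * edge_precision, recall + edge_precision)
    structure(list(accuracy = accuracy, precision = precision,
                   edge_precision = edge_precision, recall = recall,
                   f1 = f1, edge_f1 = edge_f1),
              class = "metrics_report")
  })
}

#' @export
print.metrics_report <- function(x, ...) {
  for (nm in names(x))
    cat(sprintf("%-15s %s\n", nm,
                if (is.na(x[[nm]])) "undefined" else
                  sprintf("%.1f%%", 100 * x[[nm]])))
  invisible(x)
}

#' Evaluate a prediction mask against sparse labels
#'
#' @param pred Logical mask or probability volume (thresholded at
#'   `threshold` when numeric).
#' @param labels Label array of the same shape.
#' @param threshold Binarization threshold for probability input.
#' @return List with `counts` and `metrics`.
#' @export
evaluate_prediction <- function(pred, labels, threshold = 0.5) {
  if (is.numeric(pred)) pred <- binarize(pred, threshold)
  counts <- confusion_counts(pred, labels)
  list(counts = counts, metrics = compute_metrics(counts))
}
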