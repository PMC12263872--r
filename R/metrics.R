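#' One-vs-rest confusion counts for binary labels
#'
#' Tallies true/false positives and negatives of `y_pred` against `y_true`
#' treating `positive_class` as the positive label.
#'
#' @param y_true Vector of true labels in \{0, 1\}.
#' @param y_pred Vector of predicted labels in \{0, 1\}; same length.
#' @param positive_class The label counted as positive (default `1`).
#' @return An object of class `confusion_counts`: a list with integer
#'   fields `TP`, `FP`, `FN`, `TN`.
#' @examples
#' confusion_counts(c(1, 1, 1, 0), c(1, 0, 1, 1))
#' @export
confusion_counts <- function(y_true, y_pred, positive_class = 1) {
  if (length(y_true) != length(y_pred)) {
    stop("y_true and y_pred must have equal length", call. = FALSE)
  }
  if (length(y_true) == 0L) stop("empty label vectors", call. = FALSE)
  if (!all(c(y_true, y_pred) %in% c(0, 1))) {
    stop("labels must be 0 or 1", call. = FALSE)
  }
  tp <- sum(y_true == positive_class & y_pred == positive_class)
  fp <- sum(y_true != positive_class & y_pred == positive_class)
  fn <- sum(y_true == positive_class & y_pred != positive_class)
  tn <- sum(y_true != positive_class & y_pred != positive_class)
  structure(list(TP = as.integer(tp), FP = as.integer(fp),
                 FN = as.integer(fn), TN = as.integer(tn)),
            class = "confusion_counts")
}

#' Precision, recall and F1 from confusion counts
#'
#' Precision = TP/(TP+FP), recall = TP/(TP+FN), F1 = harmonic mean of the
#' two. Any 0/0 ratio is defined as 0 and reported with a warning, so that
#' macro averaging over classes stays total.
#'
#' @param counts A `confusion_counts` object.
#' @return Named numeric vector `c(precision, recall, f1)`.
#' @export
prf <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  safe_ratio <- function(num, den, what) {
    if (den == 0) {
      if (num != 0) stop("inconsistent confusion counts", call. = FALSE)
      warning(sprintf("%s undefined (0/0); reporting 0", what), call. = FALSE)
      return(0)
    }
    num / den
  }
  p <- safe_ratio(counts$TP, counts$TP + counts$FP, "precision")
  r <- safe_ratio(counts$TP, counts$TP + counts$FN, "recall")
  f1 <- if (p + r == 0) 0 else 2 * p * r / (p + r)
  c(precision = p, recall = r, f1 = f1)
}

#' Per-class and macro-averaged precision/recall/F1
#'
#' Computes one-vs-rest precision, recall and F1 for class 0 and class 1
#' and their unweighted (macro) means — the reporting convention for
#' imbalanced screening data.
#'
#' @param y_true True labels in \{0, 1\}; both classes must appear.
#' @param y_pred Predicted labels in \{0, 1\}.
#' @return An object of class `screen_metrics`: list with `per_class`
#'   (2 x 3 matrix, rows `class0`/`class1`), `macro_precision`,
#'   `macro_recall`, `macro_f1`, and the positive-class `confusion`.
#' @examples
#' m <- macro_metrics(c(1, 1, 1, 0, 0, 0), c(1, 1, 0, 0, 0, 1))
#' m$macro_f1  # 2/3
#' @export
macro_metrics <- function(y_true, y_pred) {
  if (length(unique(y_true)) < 2L) {
    stop("y_true must contain both classes", call. = FALSE)
  }
  per <- rbind(
    class0 = prf(confusion_counts(y_true, y_pred, positive_class = 0)),
    class1 = prf(confusion_counts(y_true, y_pred, positive_class = 1))
  )
  structure(list(
    per_class = per,
    macro_precision = mean(per[, "precision"]),
    macro_recall = mean(per[, "recall"]),
    macro_f1 = mean(per[, "f1"]),
    confusion = confusion_counts(y_true, y_pred, positive_class = 1)
  ), class = "screen_metrics")
}

#' @export
print.screen_metrics <- function(x, ...) {
  cat("Binary screening metrics (macro-averaged)\n")
  cat(sprintf("  macro precision: %.4f\n", x$macro_precision))
  cat(sprintf("  macro recall:    %.4f\n", x$macro_recall))
  cat(sprintf("  macro F1:        %.4f\n", x$macro_f1))
  cat("  per-class:\n")
  print(round(x$per_class, 4))
  cc <- x$confusion
  cat(sprintf("  confusion (positive = 1): TP=%d FP=%d FN=%d TN=%d\n",
              cc$TP, cc$FP, cc$FN, cc$TN))
  invisible(x)
}

#' Write an evaluation report as structured text
#'
#' @param metrics A `screen_metrics` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_metrics_report <- function(metrics, path) {
  stopifnot(inherits(metrics, "screen_metrics"))
  cc <- metrics$confusion
  lines <- c(
    "metric,class,value",
    sprintf("precision,class0,%.10g", metrics$per_class["class0", "precision"]),
    sprintf("recall,class0,%.10g",    metrics$per_class["class0", "recall"]),
    sprintf("f1,class0,%.10g",        metrics$per_class["class0", "f1"]),
    sprintf("precision,class1,%.10g", metrics$per_class["class1", "precision"]),
    sprintf("recall,class1,%.10g",    metrics$per_class["class1", "recall"]),
    sprintf("f1,class1,%.10g",        metrics$per_class["class1", "f1"]),
    sprintf("precision,macro,%.10g",  metrics$macro_precision),
    sprintf("recall,macro,%.10g",     metrics$macro_recall),
    sprintf("f1,macro,%.10g",         metrics$macro_f1),
    sprintf("confusion,TP,%d", cc$TP), sprintf("confusion,FP,%d", cc$FP),
    sprintf("confusion,FN,%d", cc$FN), sprintf("confusion,TN,%d", cc$TN)
  )
  writeLines(lines, path)
  invisible(path)
}
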