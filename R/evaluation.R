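#' Confusion matrix
#'
#' Cross-tabulates true against predicted class indices: `counts[t, p]` is
#' the number of samples with true class `t` predicted as `p`. Rows are
#' true classes, columns predictions.
#'
#' @param y_true,y_pred Integer class indices (1-based) of equal length.
#' @param n_classes Number of classes; defaults to the largest index seen.
#' @return An `n_classes x n_classes` integer matrix of class
#'   `confusion_matrix`.
#' @export
confusion_matrix <- function(y_true, y_pred, n_classes = NULL) {
  y_true <- as.integer(y_true); y_pred <- as.integer(y_pred)
  if (length(y_true) != length(y_pred)) {
    stop_negdrop("y_true and y_pred must have equal length")
  }
  if (is.null(n_classes)) n_classes <- max(y_true, y_pred, 1L)
  if (any(c(y_true, y_pred) < 1L | c(y_true, y_pred) > n_classes)) {
    stop_negdrop("class index out of range 1..", n_classes)
  }
  cm <- matrix(0L, n_classes, n_classes,
               dimnames = list(true = seq_len(n_classes),
                               pred = seq_len(n_classes)))
  for (i in seq_along(y_true)) {
    cm[y_true[i], y_pred[i]] <- cm[y_true[i], y_pred[i]] + 1L
  }
  structure(cm, class = c("confusion_matrix", "matrix"))
}

#' Classification accuracy
#'
#' Fraction of correctly classified samples, `trace(counts) / n`. In the
#' binary case this is `(TP + TN) / (TP + TN + FP + FN)`.
#'
#' @param cm A [confusion_matrix()].
#' @return Scalar in [0, 1].
#' @export
accuracy <- function(cm) {
  n <- sum(cm)
  if (n < 1) stop_negdrop("confusion matrix is empty")
  sum(diag(cm)) / n
}

per_class_f1 <- function(cm) {
  k <- nrow(cm)
  vapply(seq_len(k), function(c) {
    tp <- cm[c, c]
    fp <- sum(cm[-c, c])
    fn <- sum(cm[c, -c])
    if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
  }, numeric(1))
}

#' F1 score from a confusion matrix
#'
#' Binary averaging computes `2 TP / (2 TP + FP + FN)` for the designated
#' positive class. Macro averaging (default, used for multi-class
#' problems) is the unweighted mean of the per-class one-vs-rest F1
#' scores; a class with neither support nor predictions contributes 0.
#' Weighted averaging weights per-class F1 by class support.
#'
#' @param cm A [confusion_matrix()].
#' @param average `"macro"`, `"binary"` or `"weighted"`.
#' @param positive Positive class index for binary averaging (default 2,
#'   the second class level).
#' @return Scalar in [0, 1].
#' @export
f1_score <- function(cm, average = c("macro", "binary", "weighted"),
                     positive = 2L) {
  average <- match.arg(average)
  f1s <- per_class_f1(cm)
  switch(average,
    binary = {
      if (nrow(cm) != 2L) {
        stop_negdrop("binary averaging requires exactly 2 classes")
      }
      f1s[positive]
    },
    macro = mean(f1s),
    weighted = {
      w <- rowSums(cm)
      if (sum(w) == 0) 0 else sum(f1s * w) / sum(w)
    })
}

#' Evaluate a model on a clinical table
#'
#' Dropout-free prediction followed by confusion-matrix metrics.
#'
#' @param model A trained [build_backbone()] model.
#' @param table A complete [clinical_table()].
#' @return List with `accuracy`, `f1_macro`, `confusion` (the matrix), and
#'   `per_class_f1`.
#' @export
evaluate_model <- function(model, table) {
  y <- class_index(table)
  yhat <- predict_classes(model, table$values)
  cm <- confusion_matrix(y, yhat, n_classes_of(table$schema))
  list(accuracy = accuracy(cm), f1_macro = f1_score(cm, "macro"),
       confusion = cm, per_class_f1 = per_class_f1(cm))
}
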