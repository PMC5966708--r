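#' Build a 2x2 confusion matrix
#'
#' @param observed,predicted vectors of class labels.
#' @param labels length-2 label order (negative class first).
#' @return 2x2 integer matrix, rows = observed, cols = predicted.
#' @export
confusion_matrix2 <- function(observed, predicted, labels = c("high", "low")) {
  obs <- factor(as.character(observed), levels = labels)
  pre <- factor(as.character(predicted), levels = labels)
  if (anyNA(obs) || anyNA(pre)) stop_bad("labels outside {%s}", paste(labels, collapse = ", "))
  m <- table(observed = obs, predicted = pre)
  matrix(as.integer(m), 2, 2, dimnames = dimnames(m))
}

#' Percent summaries of a 2x2 classification table
#'
#' Reproduces the percent cells of a classification table in the layout the
#' study prints: per-observed-class percent correct (recall), the overall
#' percent correct, and the predicted-class marginal percentages.
#'
#' @param cm 2x2 count matrix, rows observed (negative class first), columns
#'   predicted in the same order.
#' @return list with `counts`, `recall` (length 2, percent, `NA` for an empty
#'   observed class), `overall` (percent), `predicted_marginal_pct` (length 2),
#'   `n`.
#' @export
confusion_metrics <- function(cm) {
  cm <- as.matrix(cm)
  if (!all(dim(cm) == c(2, 2))) stop_bad("expected a 2x2 matrix")
  if (any(cm < 0) || sum(cm) == 0) stop_bad("counts must be nonnegative with a positive total")
  n <- sum(cm)
  row_tot <- rowSums(cm)
  recall <- ifelse(row_tot > 0, 100 * diag(cm) / row_tot, NA_real_)
  list(counts = cm,
       recall = stats::setNames(recall, rownames(cm)),
       overall = 100 * sum(diag(cm)) / n,
       predicted_marginal_pct = stats::setNames(100 * colSums(cm) / n, colnames(cm)),
       n = n)
}
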