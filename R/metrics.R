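#' Binary classification metrics
#'
#' Accuracy (proportion of true positives and true negatives among all
#' classifications), F1 (harmonic mean of precision and recall), true
#' positive rate (sensitivity), true negative rate (specificity) and AUC by
#' trapezoidal integration of the ROC curve over score thresholds. When
#' \code{y_true} contains a single class, TPR/TNR/AUC are undefined and
#' returned as \code{NA} with a warning.
#'
#' @param y_true,y_pred Factors (or vectors) over the same two levels.
#' @param scores Optional numeric scores for the positive class (higher =
#'   more positive); required for AUC.
#' @param positive The positive-class label. Defaults to the last factor
#'   level (the pipeline's convention: Hard, pain).
#' @return Named vector \code{(accuracy, f1, tpr, tnr, auc)}.
#' @export
binary_metrics <- function(y_true, y_pred, scores = NULL,
                           positive = NULL) {
  y_true <- factor(y_true)
  if (is.null(positive)) positive <- levels(y_true)[nlevels(y_true)]
  if (!length(y_true)) stop("empty y_true")
  y_pred <- factor(y_pred, levels = levels(y_true))
  pos_t <- y_true == positive
  pos_p <- y_pred == positive
  tp <- sum(pos_t & pos_p); fn <- sum(pos_t & !pos_p)
  fp <- sum(!pos_t & pos_p); tn <- sum(!pos_t & !pos_p)
  acc <- (tp + tn) / length(y_true)
  prec <- if (tp + fp > 0) tp / (tp + fp) else 0
  rec <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
  if (length(unique(y_true)) < 2) {
    warning("single-class y_true: tpr/tnr/auc undefined")
    return(c(accuracy = acc, f1 = f1, tpr = NA_real_, tnr = NA_real_,
             auc = NA_real_))
  }
  tpr <- tp / (tp + fn)
  tnr <- tn / (tn + fp)
  auc <- if (is.null(scores)) NA_real_ else roc_auc(pos_t, scores)
  c(accuracy = acc, f1 = f1, tpr = tpr, tnr = tnr, auc = auc)
}

# trapezoidal area under the ROC curve; ties in score collapse to one
# threshold step
roc_auc <- function(is_pos, scores) {
  stopifnot(length(is_pos) == length(scores))
  ord <- order(scores, decreasing = TRUE)
  is_pos <- is_pos[ord]; scores <- scores[ord]
  dup <- rev(duplicated(rev(scores)))  # keep last index of each tie group
  tp <- cumsum(is_pos)[!dup]
  fp <- cumsum(!is_pos)[!dup]
  tpr <- c(0, tp / sum(is_pos))
  fpr <- c(0, fp / sum(!is_pos))
  sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
}

#' Corrected chance level for a finite test set
#'
#' The accuracy that random guessing exceeds with probability \code{alpha}:
#' the smallest k with binomial CDF(k; n, 1/n_classes) at least
#' \code{1 - alpha}, divided by n. Decreases toward 1/n_classes as the test
#' set grows.
#'
#' @param n_test Test-set size (>= 1).
#' @param alpha Significance level in (0, 1). Default 0.05.
#' @param n_classes Number of classes. Default 2.
#' @return Corrected chance proportion.
#' @examples
#' chance_threshold(400)  # 0.54
#' chance_threshold(160)  # 0.5625
#' @export
chance_threshold <- function(n_test, alpha = 0.05, n_classes = 2) {
  if (any(n_test < 1)) stop("n_test must be at least 1")
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  if (n_classes < 2) stop("n_classes must be at least 2")
  stats::qbinom(1 - alpha, n_test, 1 / n_classes) / n_test
}
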