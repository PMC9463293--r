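#' Classification metrics for one evaluation fold
#'
#' Computes the five reported metrics from true labels and predicted class
#' probabilities: macro-averaged F1, precision (PPV) and recall (TPR) over
#' the two classes, plain accuracy under argmax, and AUROC from the
#' probability assigned to the positive class (`very_soft`, the tumor-like
#' class). Macro averaging treats both stiffness classes symmetrically; with
#' balanced classes it makes F1 track accuracy closely.
#'
#' AUROC uses the Mann-Whitney rank statistic (ties averaged). If `y_true`
#' contains a single class, AUROC is undefined and returned as `NA` with a
#' warning.
#'
#' @param y_true Factor (or character) of true labels.
#' @param y_prob Numeric matrix of class probabilities, one column per
#'   class, columns named by class.
#' @param positive Name of the positive class for AUROC.
#' @return Named numeric vector `c(F1, ACC, PPV, TPR, AUROC)`.
#' @export
compute_metrics <- function(y_true, y_prob,
                            positive = "very_soft") {
  lev <- colnames(y_prob)
  if (is.null(lev)) stop_config("y_prob must have class-named columns")
  y_true <- factor(as.character(y_true), levels = lev)
  if (nrow(y_prob) != length(y_true))
    stop_config("y_true and y_prob lengths differ")
  if (any(y_prob < -1e-9 | y_prob > 1 + 1e-9))
    stop_config("probabilities outside [0, 1]")

  pred <- factor(lev[max.col(y_prob, ties.method = "first")], levels = lev)
  cm <- table(truth = y_true, pred = pred)

  per_class <- vapply(lev, function(cl) {
    tp <- cm[cl, cl]
    fp <- sum(cm[, cl]) - tp
    fn <- sum(cm[cl, ]) - tp
    ppv <- if (tp + fp == 0) 0 else tp / (tp + fp)
    tpr <- if (tp + fn == 0) 0 else tp / (tp + fn)
    f1 <- if (ppv + tpr == 0) 0 else 2 * ppv * tpr / (ppv + tpr)
    c(F1 = f1, PPV = ppv, TPR = tpr)
  }, c(F1 = 0, PPV = 0, TPR = 0))

  acc <- mean(pred == y_true)
  auroc <- auroc_rank(y_true == positive, y_prob[, positive])

  c(F1 = mean(per_class["F1", ]), ACC = acc,
    PPV = mean(per_class["PPV", ]), TPR = mean(per_class["TPR", ]),
    AUROC = auroc)
}

# Mann-Whitney AUROC: P(score_pos > score_neg) + 0.5 P(equal).
auroc_rank <- function(is_pos, score) {
  n_pos <- sum(is_pos); n_neg <- sum(!is_pos)
  if (n_pos == 0 || n_neg == 0) {
    warning("single-class fold: AUROC undefined, returning NA")
    return(NA_real_)
  }
  r <- rank(score)
  (sum(r[is_pos]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Aggregate per-fold metrics into mean and standard deviation
#'
#' @param fold_metrics Matrix or data.frame, one row per fold, columns =
#'   metrics.
#' @return Data.frame with columns `metric`, `mean`, `sd` (sd over folds).
#' @export
aggregate_metrics <- function(fold_metrics) {
  m <- as.matrix(fold_metrics)
  data.frame(metric = colnames(m),
             mean = colMeans(m, na.rm = TRUE),
             sd = apply(m, 2, stats::sd, na.rm = TRUE),
             row.names = NULL)
}
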