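#' Classification metrics with PD as the positive class
#'
#' @param true_labels,predicted_labels equal-length label vectors ("PD"/"CT").
#' @return list with `accuracy`, `precision`, `recall`, `f1` and the
#'   confusion counts.
#' @examples
#' evaluate(c("PD", "PD", "CT"), c("PD", "CT", "CT"))$recall  # 0.5
#' @export
evaluate <- function(true_labels, predicted_labels) {
  true_labels <- as.character(true_labels)
  predicted_labels <- as.character(predicted_labels)
  if (length(true_labels) == 0) stop("empty label vectors")
  stopifnot(length(true_labels) == length(predicted_labels))
  tp <- sum(true_labels == "PD" & predicted_labels == "PD")
  fp <- sum(true_labels == "CT" & predicted_labels == "PD")
  fn <- sum(true_labels == "PD" & predicted_labels == "CT")
  tn <- sum(true_labels == "CT" & predicted_labels == "CT")
  precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  recall <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  f1 <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0)
    2 * precision * recall / (precision + recall) else NA_real_
  list(accuracy = (tp + tn) / length(true_labels),
       precision = precision, recall = recall, f1 = f1,
       tp = tp, fp = fp, fn = fn, tn = tn)
}

#' Per-fold and pooled cross-validation performance
#'
#' Computes accuracy, precision, recall and F1 per fold, then summarizes
#' across folds as mean plus/minus a 95 percent normal-approximation
#' half-width, 1.96 * sd / sqrt(k).
#'
#' @param subjects data.frame with `true_class`, `predicted_class`, `fold`.
#' @return list with `per_fold` (data.frame) and `pooled` (data.frame of
#'   mean and half-width per metric).
#' @export
evaluate_cv <- function(subjects) {
  stopifnot(all(c("true_class", "predicted_class", "fold") %in%
                  names(subjects)),
            !anyNA(subjects$predicted_class))
  folds <- sort(unique(subjects$fold))
  per <- do.call(rbind, lapply(folds, function(f) {
    s <- subjects[subjects$fold == f, ]
    e <- evaluate(s$true_class, s$predicted_class)
    data.frame(fold = f, n = nrow(s), accuracy = e$accuracy,
               precision = e$precision, recall = e$recall, f1 = e$f1)
  }))
  k <- length(folds)
  pooled <- do.call(rbind, lapply(c("accuracy", "precision", "recall", "f1"),
    function(m) {
      v <- per[[m]]
      data.frame(metric = m, mean = mean(v),
                 half_width = 1.96 * sd(v) / sqrt(k))
    }))
  list(per_fold = per, pooled = pooled)
}
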