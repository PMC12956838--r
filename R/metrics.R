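#' P4 composite classification score
#'
#' The harmonic mean of precision, recall, specificity and negative
#' predictive value: `4 / (1/prec + 1/rec + 1/spec + 1/npv)`. A single
#' conservative scalar that penalizes weakness in any of the four
#' conditional rates; symmetric under swapping the positive and negative
#' class. If any component's denominator is zero the score is reported as
#' 0 with a flag rather than an error, since degenerate folds do occur in
#' small stratified cells.
#'
#' @param tp,fp,tn,fn non-negative confusion-matrix counts.
#' @return Scalar in [0, 1]; attribute `flagged` is TRUE when a component
#'   was undefined.
#' @export
p4_score <- function(tp, fp, tn, fn) {
  stopifnot(tp >= 0, fp >= 0, tn >= 0, fn >= 0)
  denoms <- c(tp + fp, tp + fn, tn + fp, tn + fn)
  if (any(denoms == 0)) {
    return(structure(0, flagged = TRUE))
  }
  precision <- tp / (tp + fp)
  recall <- tp / (tp + fn)
  specificity <- tn / (tn + fp)
  npv <- tn / (tn + fn)
  if (any(c(precision, recall, specificity, npv) == 0)) {
    return(structure(0, flagged = TRUE))
  }
  structure(4 / (1 / precision + 1 / recall + 1 / specificity + 1 / npv),
            flagged = FALSE)
}

#' Rank-statistic AUC with half credit for ties
#'
#' The probability that a random positive outscores a random negative,
#' counting ties as 1/2 (the Mann-Whitney convention). Invariant to any
#' strictly monotone transform of the scores.
#'
#' @param labels logical or character vector; `positive` marks the
#'   positive class.
#' @param scores numeric scores, higher = more positive.
#' @param positive value of `labels` denoting the positive class.
#' @return AUC in [0, 1]; `NA` if either class is absent.
#' @export
rank_auc <- function(labels, scores, positive = "positive") {
  pos <- labels == positive
  n1 <- sum(pos)
  n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores) # ties -> average ranks, i.e. half credit
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Compute the full metric set for one evaluation
#'
#' Accuracy, precision, recall, specificity, F1, AUC and P4 from
#' predicted labels and continuous scores. Ratios with a zero denominator
#' are reported as 0 and the set is flagged (never an error), keeping
#' fold averages total.
#'
#' @param truth true labels.
#' @param predicted predicted labels.
#' @param scores continuous scores for the positive class (used for AUC).
#' @param positive positive-class label (default `"positive"`).
#' @return One-row tibble: counts, the 7 metrics and a `flagged` column.
#' @export
compute_metrics <- function(truth, predicted, scores,
                            positive = "positive") {
  stopifnot(length(truth) >= 1, length(truth) == length(predicted))
  is_pos <- truth == positive
  pred_pos <- predicted == positive
  tp <- sum(is_pos & pred_pos)
  fp <- sum(!is_pos & pred_pos)
  tn <- sum(!is_pos & !pred_pos)
  fn <- sum(is_pos & !pred_pos)
  safe_div <- function(num, den) if (den == 0) 0 else num / den
  precision <- safe_div(tp, tp + fp)
  recall <- safe_div(tp, tp + fn)
  specificity <- safe_div(tn, tn + fp)
  f1 <- if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  auc <- rank_auc(truth, scores, positive)
  p4 <- p4_score(tp, fp, tn, fn)
  flagged <- isTRUE(attr(p4, "flagged")) ||
    (tp + fp) == 0 || (tp + fn) == 0 || (tn + fp) == 0 || is.na(auc)
  tibble::tibble(
    tp = tp, fp = fp, tn = tn, fn = fn,
    accuracy = (tp + tn) / length(truth),
    precision = precision, recall = recall, specificity = specificity,
    f1 = f1,
    auc = if (is.na(auc)) 0 else auc,
    p4 = as.numeric(p4),
    flagged = flagged
  )
}

#' Vertically averaged ROC curve across folds
#'
#' Computes each fold's ROC curve from score thresholds, interpolates its
#' true-positive rate at 101 evenly spaced false-positive-rate points
#' (endpoints pinned at (0,0) and (1,1)), and averages across folds.
#'
#' @param folds list of lists, each with elements `labels` and `scores`.
#' @param positive positive-class label.
#' @return List with `curve` (tibble: fpr, mean_tpr, sd_tpr), `fold_auc`,
#'   `mean_auc`, `sd_auc`.
#' @export
mean_roc <- function(folds, positive = "positive") {
  grid <- seq(0, 1, length.out = 101)
  usable <- Filter(function(f) {
    length(unique(f$labels == positive)) == 2
  }, folds)
  if (length(usable) == 0) stop("no fold has both classes present")
  tprs <- matrix(NA_real_, nrow = length(usable), ncol = length(grid))
  aucs <- numeric(length(usable))
  for (i in seq_along(usable)) {
    roc <- roc_points(usable[[i]]$labels, usable[[i]]$scores, positive)
    tprs[i, ] <- stats::approx(roc$fpr, roc$tpr, xout = grid,
                               ties = "ordered", rule = 2)$y
    aucs[i] <- rank_auc(usable[[i]]$labels, usable[[i]]$scores, positive)
  }
  tprs[, 1] <- 0
  tprs[, length(grid)] <- 1
  list(
    curve = tibble::tibble(
      fpr = grid,
      mean_tpr = colMeans(tprs),
      sd_tpr = apply(tprs, 2, sd)
    ),
    fold_auc = aucs,
    mean_auc = mean(aucs),
    sd_auc = if (length(aucs) > 1) sd(aucs) else 0
  )
}

# raw ROC step-curve points (fpr, tpr), ascending fpr
roc_points <- function(labels, scores, positive = "positive") {
  ord <- order(scores, decreasing = TRUE)
  lab <- (labels == positive)[ord]
  sc <- scores[ord]
  n1 <- sum(lab)
  n0 <- sum(!lab)
  # cut only between distinct score values so ties move diagonally
  keep <- c(diff(sc) != 0, TRUE)
  tp <- cumsum(lab)[keep]
  fp <- cumsum(!lab)[keep]
  tibble::tibble(
    fpr = c(0, fp / n0),
    tpr = c(0, tp / n1)
  )
}
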