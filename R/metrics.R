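## Evaluation metrics: confusion-matrix statistics, Dice similarity,
## ROC curve with trapezoidal AUC, and the Youden-index operating point.

#' Confusion counts
#'
#' @param tp,fp,tn,fn non-negative integer counts; their total must be
#'   positive.
#' @return a `confusion_counts` object.
#' @export
confusion_counts <- function(tp, fp, tn, fn) {
  v <- c(tp = tp, fp = fp, tn = tn, fn = fn)
  if (any(v < 0)) stop("confusion counts must be non-negative")
  if (sum(v) == 0) stop("confusion counts must have a positive total")
  structure(as.list(v), class = "confusion_counts")
}

#' Accuracy, recall, precision, specificity and F1 from confusion counts
#'
#' Standard definitions: accuracy = (TP+TN)/total, recall (sensitivity) =
#' TP/(TP+FN), precision = TP/(TP+FP), specificity = TN/(TN+FP), and F1 the
#' harmonic mean of precision and recall. A metric whose denominator is
#' zero is reported as `NA` (undefined), never as 0.
#'
#' @param counts a [confusion_counts()] object.
#' @return one-row tibble with columns accuracy, recall, precision,
#'   specificity, f1.
#' @export
classification_metrics <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  tp <- counts$tp; fp <- counts$fp; tn <- counts$tn; fn <- counts$fn
  safe_div <- function(num, den) if (den == 0) NA_real_ else num / den
  recall <- safe_div(tp, tp + fn)
  precision <- safe_div(tp, tp + fp)
  f1 <- if (is.na(recall) || is.na(precision) || recall + precision == 0) {
    NA_real_
  } else {
    2 * precision * recall / (precision + recall)
  }
  tibble::tibble(
    accuracy = safe_div(tp + tn, tp + fp + tn + fn),
    recall = recall,
    precision = precision,
    specificity = safe_div(tn, tn + fp),
    f1 = f1)
}

#' Dice similarity coefficient of two binary masks
#'
#' `DSC = 2|A n B| / (|A| + |B|)`; symmetric, 1 for identical non-empty
#' masks, 0 for disjoint non-empty masks, `NA` (undefined) when both masks
#' are empty.
#'
#' @param a,b logical (or 0/1) matrices on the same grid.
#' @return numeric scalar in `[0, 1]`, or `NA` when undefined.
#' @export
dsc <- function(a, b) {
  a <- a > 0; b <- b > 0
  if (!identical(dim(a), dim(b))) stop("masks must share the same grid")
  denom <- sum(a) + sum(b)
  if (denom == 0) return(NA_real_)
  2 * sum(a & b) / denom
}

#' ROC curve with trapezoidal AUC
#'
#' Sweeps thresholds over the unique scores (a score `>= threshold` is
#' called positive, consistent with the `>= 0.95` operating rule), plots
#' sensitivity against 1 - specificity, and integrates by the trapezoidal
#' rule. The curve always contains the endpoints (0, 0) (threshold above
#' every score) and (1, 1) (threshold at the minimum score).
#'
#' @param scores numeric per-image confidences.
#' @param labels logical (or 0/1) ground-truth positives.
#' @return a `roc_curve`: list with `$points` (tibble: threshold,
#'   sensitivity, fpr, specificity) and `$auc`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- labels > 0
  if (length(scores) != length(labels)) stop("scores/labels length mismatch")
  n_pos <- sum(labels); n_neg <- sum(!labels)
  if (n_pos == 0 || n_neg == 0) {
    stop("ROC requires both positive and negative examples")
  }
  thresholds <- c(Inf, sort(unique(scores), decreasing = TRUE))
  sens <- vapply(thresholds, function(t) sum(scores >= t & labels) / n_pos,
                 numeric(1))
  fpr <- vapply(thresholds, function(t) sum(scores >= t & !labels) / n_neg,
                numeric(1))
  auc <- sum(diff(fpr) * (utils::head(sens, -1) + sens[-1]) / 2)
  structure(list(points = tibble::tibble(threshold = thresholds,
                                         sensitivity = sens, fpr = fpr,
                                         specificity = 1 - fpr),
                 auc = auc, n_pos = n_pos, n_neg = n_neg),
            class = "roc_curve")
}

#' Youden-index optimal cut-point of an ROC curve
#'
#' Maximises `J = sensitivity + specificity - 1` over the finite thresholds
#' of the curve; ties are broken toward the higher threshold.
#'
#' @param curve a `roc_curve` from [roc_auc()].
#' @return the optimal threshold, with the achieved index as attribute
#'   `"youden"`.
#' @export
youden_cutpoint <- function(curve) {
  stopifnot(inherits(curve, "roc_curve"))
  pts <- curve$points[is.finite(curve$points$threshold), ]
  if (nrow(pts) == 0) stop("degenerate ROC curve")
  j <- pts$sensitivity + pts$specificity - 1
  best <- which(j >= max(j) - 1e-12) # tolerate float noise in ties
  pick <- best[which.max(pts$threshold[best])]
  structure(pts$threshold[pick], youden = j[pick])
}

#' Wilson score confidence interval for a proportion
#'
#' @param x successes, `n` trials, `conf` confidence level.
#' @param n,conf see above.
#' @return numeric c(lower, upper).
#' @export
wilson_ci <- function(x, n, conf = 0.95) {
  if (n == 0) return(c(NA_real_, NA_real_))
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- x / n
  den <- 1 + z^2 / n
  ctr <- (p + z^2 / (2 * n)) / den
  hw <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
  c(max(0, ctr - hw), min(1, ctr + hw))
}

#' Paired comparison of image calls before vs after refinement
#'
#' Offers both McNemar's test on the paired binary calls (appropriate for
#' paired proportions) and a paired t-test on the 0/1 correctness
#' indicators.
#'
#' @param correct_before,correct_after logical vectors: was each image
#'   called correctly before / after refinement?
#' @return tibble with the two p-values and the discordant counts.
#' @export
compare_paired_calls <- function(correct_before, correct_after) {
  b01 <- sum(!correct_before & correct_after)
  b10 <- sum(correct_before & !correct_after)
  mcn <- if (b01 + b10 == 0) NA_real_ else
    stats::mcnemar.test(table(factor(correct_before, c(FALSE, TRUE)),
                              factor(correct_after, c(FALSE, TRUE))))$p.value
  tt <- if (stats::sd(correct_after - correct_before) == 0) NA_real_ else
    stats::t.test(as.numeric(correct_after), as.numeric(correct_before),
                  paired = TRUE)$p.value
  tibble::tibble(mcnemar_p = mcn, paired_t_p = tt,
                 gained = b01, lost = b10)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.roc_curve <- function(x, ...) x$points

#' @export
glance.roc_curve <- function(x, ...) {
  cp <- youden_cutpoint(x)
  tibble::tibble(auc = x$auc, n_pos = x$n_pos, n_neg = x$n_neg,
                 youden_cutpoint = as.numeric(cp),
                 youden_index = attr(cp, "youden"))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot an ROC curve
#' @param object a `roc_curve`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.roc_curve <- function(object, ...) {
  ggplot2::ggplot(object$points,
                  ggplot2::aes(x = .data$fpr, y = .data$sensitivity)) +
    ggplot2::geom_step() +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::labs(x = "1 - Specificity", y = "Sensitivity",
                  title = sprintf("AUC = %.4f", object$auc)) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 .data
NULL
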