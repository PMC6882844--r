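#' Balanced error probability
#'
#' Class-balanced misclassification rate of a two-hypothesis discriminator:
#' the unweighted mean of the two conditional error rates
#' `P(pred = j | truth = i), j != i`. Chance level is 0.5 regardless of
#' class imbalance.
#'
#' @param true_labels vector of true hypothesis labels (exactly two classes
#'   must be present).
#' @param pred_labels vector of predicted labels, same length.
#' @return an object of class `"error_report"`: list with `p_error`,
#'   `conditional` (named per-class error rates) and `n_per_class`.
#' @export
#' @examples
#' error_probability(rep(1:2, each = 10),
#'                   c(rep(1, 8), rep(2, 2), rep(1, 4), rep(2, 6)))
error_probability <- function(true_labels, pred_labels) {
  if (length(true_labels) != length(pred_labels))
    stop("label vectors must have the same length")
  labs <- sort(unique(true_labels))
  if (length(labs) != 2L)
    stop("exactly two classes must be present in 'true_labels'")
  cond <- vapply(labs, function(l)
    mean(pred_labels[true_labels == l] != l), numeric(1))
  names(cond) <- as.character(labs)
  structure(list(p_error = mean(cond), conditional = cond,
                 n_per_class = as.integer(table(factor(true_labels, labs)))),
            class = "error_report")
}

#' @export
print.error_report <- function(x, ...) {
  cat(sprintf("<error_report> balanced error = %.4f (per class: %s; n = %s)\n",
              x$p_error,
              paste(sprintf("%s: %.4f", names(x$conditional), x$conditional),
                    collapse = ", "),
              paste(x$n_per_class, collapse = "/")))
  invisible(x)
}

#' ROC curve and AUC
#'
#' Threshold-sweep receiver operating characteristic: scores are thresholded
#' at every distinct value (descending), a trace counting as positive when
#' its score strictly exceeds the threshold. The curve runs from (0,0) to
#' (1,1); the AUC is the trapezoidal area, which equals the all-pairs
#' concordance (Mann-Whitney) statistic with ties counted one half.
#'
#' @param scores real-valued classifier scores, larger meaning "more like
#'   the positive class".
#' @param true_labels vector with exactly two classes.
#' @param positive the label that large scores indicate; default the
#'   second label in sort order.
#' @return an object of class `"roc_result"`: list with `points` (a
#'   data.frame of `fpr`, `tpr`, ordered) and `auc`.
#' @export
#' @examples
#' roc_auc(c(0.9, 0.8, 0.3, 0.1), c(1, 1, 0, 0), positive = 1)
roc_auc <- function(scores, true_labels,
                    positive = sort(unique(true_labels))[2]) {
  if (length(scores) != length(true_labels))
    stop("'scores' and 'true_labels' must have the same length")
  labs <- sort(unique(true_labels))
  if (length(labs) != 2L)
    stop("exactly two classes must be present in 'true_labels'")
  pos <- true_labels == positive
  n_pos <- sum(pos); n_neg <- sum(!pos)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; p <- pos[ord]
  # collapse tied thresholds: one ROC vertex per distinct score
  grp <- cumsum(!duplicated(s))
  tp <- cumsum(p); fp <- cumsum(!p)
  last <- which(!duplicated(grp, fromLast = TRUE))
  pts <- data.frame(fpr = c(0, fp[last] / n_neg),
                    tpr = c(0, tp[last] / n_pos))
  auc <- sum(diff(pts$fpr) * (utils::head(pts$tpr, -1) +
                                utils::tail(pts$tpr, -1)) / 2)
  structure(list(points = pts, auc = auc, positive = positive),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> AUC = %.4f (%d thresholds, positive = %s)\n",
              x$auc, nrow(x$points) - 1L, format(x$positive)))
  invisible(x)
}
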