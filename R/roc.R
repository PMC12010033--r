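#' Empirical ROC curve and AUC
#'
#' Builds the empirical receiver operating characteristic curve of a score
#' against a binary label over all distinct score thresholds and computes
#' the area under it by the trapezoidal rule. Ties across classes produce
#' diagonal segments, so the trapezoidal area equals the pair-counting
#' probability (concordant pairs + half the tied pairs) / (n+ * n-), i.e.
#' the probability that a random positive outranks a random negative.
#'
#' Because the direction of a clinical score's association with an outcome
#' can be ambiguous, the orientation is an explicit argument and the
#' complementary AUC (`1 - auc`) is always carried in the result.
#'
#' @param scores numeric vector.
#' @param labels logical vector (or 0/1) of the same length; `TRUE` marks
#'   the positive class. Both classes must be present.
#' @param positive_label name of the positive outcome, used in printing.
#' @param direction `"higher_score_positive"` if larger scores should
#'   indicate the positive class, `"lower_score_positive"` otherwise.
#' @return an object of class `bka_roc`: list with `points` (data.frame of
#'   `fpr`, `tpr` from (0,0) to (1,1)), `auc`, `auc_complement`,
#'   `positive_label`, `direction`, `n_pos`, `n_neg`.
#' @examples
#' roc_auc(c(1, 2, 3, 4), c(FALSE, FALSE, TRUE, TRUE))  # AUC = 1
#' @export
roc_auc <- function(scores, labels, positive_label = "positive",
                    direction = c("higher_score_positive",
                                  "lower_score_positive")) {
  direction <- match.arg(direction)
  labels <- check_flag(labels, "labels")
  if (length(scores) != length(labels)) {
    stop("`scores` and `labels` must have equal length", call. = FALSE)
  }
  if (anyNA(scores)) stop("NA scores are not allowed", call. = FALSE)
  n_pos <- sum(labels)
  n_neg <- sum(!labels)
  if (n_pos == 0L || n_neg == 0L) {
    stop("both classes must be present in `labels`", call. = FALSE)
  }
  s <- if (direction == "higher_score_positive") scores else -scores

  # sweep thresholds from +Inf down through each distinct score value
  thr <- sort(unique(s), decreasing = TRUE)
  tpr <- c(0, vapply(thr, function(t) sum(s[labels] >= t) / n_pos, numeric(1)))
  fpr <- c(0, vapply(thr, function(t) sum(s[!labels] >= t) / n_neg, numeric(1)))
  auc <- sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)

  structure(
    list(points = data.frame(fpr = fpr, tpr = tpr),
         auc = auc, auc_complement = 1 - auc,
         positive_label = positive_label, direction = direction,
         n_pos = n_pos, n_neg = n_neg),
    class = "bka_roc"
  )
}

#' @export
print.bka_roc <- function(x, ...) {
  cat("Empirical ROC:", x$positive_label,
      sprintf("(%d positive, %d negative), %s\n", x$n_pos, x$n_neg, x$direction))
  cat(sprintf("  AUC = %.3f (opposite orientation: %.3f)\n",
              x$auc, x$auc_complement))
  invisible(x)
}

#' @param y ignored.
#' @rdname roc_auc
#' @export
plot.bka_roc <- function(x, y, ...) {
  plot(x$points$fpr, x$points$tpr, type = "l",
       xlab = "False positive rate", ylab = "True positive rate",
       main = sprintf("ROC: %s (AUC = %.3f)", x$positive_label, x$auc), ...)
  graphics::abline(0, 1, lty = 3)
  invisible(x)
}
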