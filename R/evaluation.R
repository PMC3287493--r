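# Performance measures (AUC/ACC/SEN/SPE), repeated-CV summary, and
# condition-comparison statistics (Welch t-test, one-way ANOVA).

#' Area under the ROC curve
#'
#' Counted directly over all positive-negative pairs:
#' `(concordant + 0.5 * tied) / (n1 * n0)`.
#'
#' @param scores numeric vector of predicted scores/probabilities.
#' @param labels 0/1 vector, both classes present.
#' @return AUC in \[0, 1\].
#' @examples
#' rocAuc(c(0.9, 0.4, 0.8, 0.3), c(1, 1, 0, 0))  # 0.75
#' @export
rocAuc <- function(scores, labels) {
  labels <- as.integer(labels)
  if (length(scores) != length(labels)) stop("length mismatch")
  s1 <- scores[labels == 1L]; s0 <- scores[labels == 0L]
  if (!length(s1) || !length(s0))
    stop("AUC undefined: both classes must be present")
  cmp <- outer(s1, s0, "-")
  (sum(cmp > 0) + 0.5 * sum(cmp == 0)) / (length(s1) * length(s0))
}

#' Accuracy, sensitivity and specificity at a probability threshold
#'
#' Predicts class 1 iff `score >= tau` and reads the confusion table:
#' accuracy (TP+TN)/n, sensitivity TP/(TP+FN), specificity TN/(TN+FP).
#'
#' @inheritParams rocAuc
#' @param tau decision threshold (default 0.5, matching calibrated
#'   probability output).
#' @return Named numeric vector `c(acc, sen, spe)`.
#' @export
thresholdMetrics <- function(scores, labels, tau = 0.5) {
  labels <- as.integer(labels)
  if (!any(labels == 1L) || !any(labels == 0L))
    stop("metrics undefined: both classes must be present")
  pred <- as.integer(scores >= tau)
  tp <- sum(pred == 1L & labels == 1L); tn <- sum(pred == 0L & labels == 0L)
  fp <- sum(pred == 1L & labels == 0L); fn <- sum(pred == 0L & labels == 1L)
  c(acc = (tp + tn) / length(labels),
    sen = tp / (tp + fn),
    spe = tn / (tn + fp))
}

#' Median performance over cross-validation repeats
#'
#' Element-wise median of the per-repeat pooled metrics (for an even repeat
#' count, the mean of the two middle values, R's default median).
#'
#' @param result a [CVResult-class].
#' @return Named numeric vector `c(auc, acc, sen, spe)`.
#' @export
summarizeCV <- function(result) {
  stopifnot(is(result, "CVResult"))
  m <- cvMetrics(result)
  if (!nrow(m)) stop("empty CV result")
  vapply(c(auc = "auc", acc = "acc", sen = "sen", spe = "spe"),
         function(col) stats::median(m[[col]]), numeric(1))
}

#' Compare performance between experimental conditions
#'
#' Two-sided Welch (unequal-variance) two-sample t-test between `a` and `b`,
#' or one-way ANOVA across `groups`. The degenerate case — zero variance in
#' every group with equal means — returns p = 1 with a message; zero
#' variance with unequal means returns p = 0 (perfect separation).
#'
#' @param a,b numeric samples (>= 2 values each) for `method = "welch_t"`.
#' @param method `"welch_t"` or `"anova"`.
#' @param groups list of >= 2 numeric samples for `method = "anova"`.
#' @return p-value in \[0, 1\].
#' @examples
#' compareConditions(c(1, 2, 3), c(4, 5, 6))  # ~0.021
#' @export
compareConditions <- function(a = NULL, b = NULL,
                              method = c("welch_t", "anova"),
                              groups = NULL) {
  method <- match.arg(method)
  if (method == "welch_t") {
    if (length(a) < 2 || length(b) < 2)
      stop("welch_t needs >= 2 values per sample")
    if (stats::var(a) == 0 && stats::var(b) == 0) {
      if (mean(a) == mean(b)) {
        message("compareConditions: degenerate samples (zero variance), p = 1")
        return(1)
      }
      return(0)
    }
    return(stats::t.test(a, b, var.equal = FALSE)$p.value)
  }
  if (is.null(groups) && !is.null(a) && !is.null(b)) groups <- list(a, b)
  if (length(groups) < 2) stop("anova needs >= 2 groups")
  vals <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), lengths(groups)))
  withinVar <- vapply(groups, stats::var, numeric(1))
  if (all(withinVar == 0, na.rm = TRUE)) {
    mns <- vapply(groups, mean, numeric(1))
    if (max(mns) == min(mns)) {
      message("compareConditions: degenerate groups (zero variance), p = 1")
      return(1)
    }
    return(0)
  }
  stats::anova(stats::aov(vals ~ g))[["Pr(>F)"]][1]
}
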