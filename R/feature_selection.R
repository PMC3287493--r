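# Per-feature association screening against the binary ADR-class label:
# Fisher's exact test for binary columns, Wilcoxon rank-sum for integer
# weights, keep p < alpha.

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' The two-sided p-value sums, over all tables with the observed margins, the
#' hypergeometric point probabilities not exceeding that of the observed
#' table (with relative tolerance 1e-7 on the comparison, the usual 2x2
#' convention). A table with a zero margin is degenerate and returns p = 1
#' with a message rather than an error, so constant feature columns simply
#' fail selection.
#'
#' @param table 2x2 non-negative integer matrix.
#' @return p-value in (0, 1].
#' @examples
#' fisherExactTwoSided(matrix(c(5, 0, 0, 5), 2))  # ~0.0079
#' @export
fisherExactTwoSided <- function(table) {
  stopifnot(is.matrix(table), all(dim(table) == 2L))
  if (any(table < 0) || any(table != round(table)))
    stop("table must contain non-negative integers")
  r1 <- sum(table[1, ]); c1 <- sum(table[, 1]); N <- sum(table)
  if (r1 == 0 || c1 == 0 || r1 == N || c1 == N) {
    message("fisherExactTwoSided: degenerate table (zero margin), p = 1")
    return(1)
  }
  k <- max(0, r1 + c1 - N):min(r1, c1)
  d <- stats::dhyper(k, c1, N - c1, r1)
  obs <- stats::dhyper(table[1, 1], c1, N - c1, r1)
  min(1, sum(d[d <= obs * (1 + 1e-7)]))
}

#' Two-sided Wilcoxon rank-sum test
#'
#' For small samples (total n <= 12) the exact permutation p-value is
#' computed with midranks for ties: the fraction of all equally-likely group
#' assignments whose rank sum deviates from its mean at least as much as the
#' observed one. Larger samples use the tie-corrected normal approximation
#' with continuity correction.
#'
#' @param xs,ys non-empty numeric samples.
#' @return p-value in (0, 1].
#' @examples
#' ranksumTwoSided(c(1, 2, 3), c(4, 5, 6))  # 0.1
#' @export
ranksumTwoSided <- function(xs, ys) {
  if (!length(xs) || !length(ys)) stop("both samples must be non-empty")
  n1 <- length(xs); n2 <- length(ys); n <- n1 + n2
  r <- rank(c(xs, ys))                      # midranks
  w <- sum(r[seq_len(n1)])
  mu <- n1 * (n + 1) / 2
  if (n <= 12L) {
    r2 <- as.integer(round(2 * r))          # half-ranks -> exact integers
    w2 <- sum(r2[seq_len(n1)]); mu2 <- n1 * (n + 1)
    sums <- utils::combn(r2, n1, sum)
    return(mean(abs(sums - mu2) >= abs(w2 - mu2)))
  }
  ties <- table(r)
  sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  if (sigma2 <= 0) return(1)                # all observations tied
  z <- (w - mu - sign(w - mu) * 0.5) / sqrt(sigma2)
  min(1, 2 * stats::pnorm(-abs(z)))
}

#' Screen features against the class label
#'
#' Every column of `X` is tested for association with `y`: a binary column
#' (all values in {0, 1}) via Fisher's exact test on its 2x2
#' presence-by-label table, an integer-weight column via the Wilcoxon
#' rank-sum test between the label groups. Columns with p < `alpha` are
#' returned sorted by ascending p (ties broken lexically by feature id).
#' No multiple-testing correction is applied; the screen is a raw p < 0.05
#' filter by design.
#'
#' @param X a [FactsMatrix-class] (or plain matrix with dimnames).
#' @param y an [ADRClassLabels-class] (or 0/1 vector) aligned to the rows
#'   of `X`.
#' @param alpha selection threshold on the p-value (default 0.05).
#' @return data.frame with columns `feature_id`, `test_used`
#'   (`"fisher"`/`"ranksum"`), `p_value`.
#' @export
selectFeatures <- function(X, y, alpha = 0.05) {
  v <- if (is(X, "FactsMatrix")) factValues(X) else X
  yy <- if (is(y, "ADRClassLabels")) classLabels(y) else y
  if (nrow(v) != length(yy))
    stop("X rows and y length are misaligned")
  yy <- as.integer(yy)
  pos <- yy == 1L
  ids <- colnames(v)
  res <- data.frame(feature_id = character(0), test_used = character(0),
                    p_value = numeric(0), stringsAsFactors = FALSE)
  if (!ncol(v)) return(res)
  if (all(pos) || !any(pos)) {
    message("selectFeatures: single-class labels, nothing selectable")
    return(res)
  }
  p <- numeric(ncol(v)); test <- character(ncol(v))
  for (j in seq_len(ncol(v))) {
    col <- v[, j]
    if (length(unique(col)) == 1L) {          # constant: no association
      p[j] <- 1; test[j] <- if (all(col %in% c(0, 1))) "fisher" else "ranksum"
    } else if (all(col %in% c(0, 1))) {
      tab <- matrix(c(sum(col == 1 & pos), sum(col == 1 & !pos),
                      sum(col == 0 & pos), sum(col == 0 & !pos)),
                    2, 2, byrow = TRUE)
      p[j] <- suppressMessages(fisherExactTwoSided(tab))
      test[j] <- "fisher"
    } else {
      p[j] <- ranksumTwoSided(col[pos], col[!pos])
      test[j] <- "ranksum"
    }
  }
  res <- data.frame(feature_id = ids, test_used = test, p_value = p,
                    stringsAsFactors = FALSE)
  res <- res[res$p_value < alpha, , drop = FALSE]
  res <- res[order(res$p_value, res$feature_id), , drop = FALSE]
  rownames(res) <- NULL
  res
}
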