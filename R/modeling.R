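# Majority-class partition balancing, probability-output classifiers and
# repeated stratified k-fold cross-validation.

#' Partition the majority class into minority-sized parts
#'
#' The ids are shuffled with the current RNG stream and dealt into
#' `max(1, round(length(majorIds) / minorSize))` parts whose sizes differ by
#' at most one, so each part is close to the minority-class size. Together
#' with [fitPredictBalanced()] this implements undersampling-free class
#' balancing: every majority sample is used exactly once per ensemble.
#'
#' @param majorIds character or integer vector of majority-class ids.
#' @param minorSize size of the minority class (>= 1).
#' @return List of disjoint id vectors covering `majorIds`.
#' @examples
#' set.seed(1)
#' lengths(partitionMajorClass(1:23, 5))  # 5 parts, sizes 5/5/5/4/4
#' @export
partitionMajorClass <- function(majorIds, minorSize) {
  if (!length(majorIds)) stop("majorIds must be non-empty")
  if (minorSize < 1) stop("minorSize must be >= 1")
  nParts <- max(1L, as.integer(round(length(majorIds) / minorSize)))
  shuffled <- sample(majorIds)
  unname(split(shuffled, rep_len(seq_len(nParts), length(shuffled))))
}

# Fit one classifier on (x, y01) and return P(class = 1) for newx.
fitOne <- function(x, y01, newx, spec) {
  fam <- spec@family
  h <- spec@hyperparameters
  if (fam == "svm_rbf") {
    gamma <- if (!is.null(h$gamma)) h$gamma else 1 / max(1L, ncol(x))
    fit <- suppressWarnings(
      e1071::svm(x, factor(y01, levels = c(0, 1)), kernel = "radial",
                 cost = if (!is.null(h$cost)) h$cost else 1,
                 gamma = gamma, probability = TRUE))
    pr <- attr(predict(fit, newx, probability = TRUE), "probabilities")
    unname(pr[, "1"])
  } else {
    df <- data.frame(x, check.names = FALSE)
    colnames(df) <- paste0("f", seq_len(ncol(x)))
    df$.y <- y01
    fit <- suppressWarnings(
      stats::glm(.y ~ ., data = df, family = stats::binomial()))
    nd <- data.frame(newx, check.names = FALSE)
    colnames(nd) <- paste0("f", seq_len(ncol(newx)))
    p <- suppressWarnings(
      unname(stats::predict(fit, newdata = nd, type = "response")))
    pmin(1, pmax(0, p))
  }
}

#' Balanced-ensemble fit and prediction
#'
#' The majority class of the training set is partitioned into
#' minority-sized parts ([partitionMajorClass()]); one classifier is fitted
#' per balanced training set (part plus the whole minority class) and the
#' returned probability for each test row is the arithmetic mean of the
#' sub-models' fitted class-1 probabilities.
#'
#' Uses the current RNG stream (for the partition); seed at the caller.
#'
#' @param trainX,trainY training feature matrix and 0/1 label vector
#'   (both classes required).
#' @param testX feature matrix to predict (same columns as `trainX`).
#' @param spec a [ModelSpec-class].
#' @return Numeric vector of probabilities in \[0, 1\], one per `testX` row.
#' @export
fitPredictBalanced <- function(trainX, trainY, testX, spec) {
  stopifnot(is(spec, "ModelSpec"))
  trainY <- as.integer(trainY)
  if (length(unique(trainY)) < 2L)
    stop("training data contain a single class")
  major <- if (sum(trainY == 1L) >= sum(trainY == 0L)) 1L else 0L
  majIdx <- which(trainY == major)
  minIdx <- which(trainY != major)
  parts <- partitionMajorClass(majIdx, length(minIdx))
  probs <- vapply(parts, function(part) {
    idx <- c(part, minIdx)
    fitOne(trainX[idx, , drop = FALSE], trainY[idx], testX, spec)
  }, numeric(nrow(testX)))
  rowMeans(matrix(probs, nrow = nrow(testX)))
}

# Stratified fold assignment: within each class, shuffle and deal fold ids
# cyclically; preserves class proportions per fold up to rounding.
stratifiedFolds <- function(y, folds) {
  assign <- integer(length(y))
  for (cls in unique(y)) {
    idx <- sample(which(y == cls))
    assign[idx] <- rep_len(seq_len(folds), length(idx))
  }
  assign
}

#' Repeated stratified k-fold cross-validation of the ADR classifier
#'
#' Per repeat, drugs are dealt into `folds` stratified folds. For each fold,
#' feature screening ([selectFeatures()]) runs on the training rows only (no
#' leakage into the validation fold), the balanced ensemble
#' ([fitPredictBalanced()]) is fitted on the selected columns, and
#' probabilities are produced for the untouched — still imbalanced —
#' validation fold. Per-repeat AUC/ACC/SEN/SPE pool all out-of-fold
#' predictions of the repeat. If no feature passes `alpha` in a fold, the
#' single smallest-p feature is used so a model can always be fitted.
#'
#' @param X a [FactsMatrix-class].
#' @param y an [ADRClassLabels-class] aligned to `drugIds(X)` (or 0/1
#'   vector).
#' @param spec a [ModelSpec-class].
#' @param folds number of folds (default 10).
#' @param repeats number of repeats (default 3).
#' @param alpha feature-screen threshold (default 0.05).
#' @param seed integer seed; the whole procedure is a deterministic function
#'   of its inputs and this seed.
#' @param selectGlobally if `TRUE`, screen features once on all rows before
#'   cross-validation (optimistic; kept for compatibility with pipelines
#'   that select up front). Default `FALSE`.
#' @return A [CVResult-class].
#' @seealso [summarizeCV()]
#' @export
crossValidate <- function(X, y, spec, folds = 10, repeats = 3,
                          alpha = 0.05, seed = 1, selectGlobally = FALSE) {
  v <- if (is(X, "FactsMatrix")) factValues(X) else X
  yy <- if (is(y, "ADRClassLabels")) classLabels(y) else y
  yy <- as.integer(yy)
  if (nrow(v) != length(yy)) stop("X rows and y length are misaligned")
  if (folds < 2) stop("folds must be >= 2")
  tab <- table(factor(yy, levels = c(0, 1)))
  if (any(tab < folds))
    stop(sprintf(
      "class with %d members cannot fill %d folds; use fewer folds",
      min(tab), folds))
  ids <- rownames(v)
  withr::with_seed(as.integer(seed), {
    if (selectGlobally) {
      selAll <- selectFeatures(v, yy, alpha)
      keepAll <- if (nrow(selAll)) selAll$feature_id
                 else globalFallback(v, yy)
    }
    pred <- vector("list", repeats * folds)
    met <- vector("list", repeats)
    for (r in seq_len(repeats)) {
      foldOf <- stratifiedFolds(yy, folds)
      for (f in seq_len(folds)) {
        tr <- foldOf != f
        keep <- if (selectGlobally) keepAll else {
          sel <- suppressMessages(
            selectFeatures(v[tr, , drop = FALSE], yy[tr], alpha))
          if (nrow(sel)) sel$feature_id else globalFallback(v[tr, , drop = FALSE], yy[tr])
        }
        p <- fitPredictBalanced(v[tr, keep, drop = FALSE], yy[tr],
                                v[!tr, keep, drop = FALSE], spec)
        pred[[(r - 1L) * folds + f]] <- data.frame(
          repeat_id = r, fold = f, drug_id = ids[!tr],
          label = yy[!tr], prob = p, stringsAsFactors = FALSE)
      }
      rp <- do.call(rbind, pred[((r - 1L) * folds + 1L):(r * folds)])
      m <- thresholdMetrics(rp$prob, rp$label, tau = 0.5)
      met[[r]] <- data.frame(repeat_id = r,
                             auc = rocAuc(rp$prob, rp$label),
                             acc = m[["acc"]], sen = m[["sen"]],
                             spe = m[["spe"]])
    }
    new("CVResult", predictions = do.call(rbind, pred),
        metrics = do.call(rbind, met))
  })
}

# Fallback when no feature clears alpha: the single least-null feature
# (smallest p, ties lexical), so the classifier always has an input.
globalFallback <- function(v, yy) {
  sel <- suppressMessages(selectFeatures(v, yy, alpha = 1.0001))
  if (nrow(sel)) sel$feature_id[1] else colnames(v)[1]
}
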