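# Two well-separated Gaussian blobs with a 3:1 class imbalance.
blobs <- function(n1, n0, shift = 6, p = 3) {
  X <- rbind(matrix(rnorm(n1 * p, mean = shift), n1, p),
             matrix(rnorm(n0 * p, mean = 0), n0, p))
  rownames(X) <- sprintf("d%d", seq_len(n1 + n0))
  colnames(X) <- sprintf("f%d", seq_len(p))
  list(X = X, y = c(rep(1L, n1), rep(0L, n0)))
}

test_that("majority-class partitioning follows the rounding rule", {
  withr::with_seed(410, {
    expect_equal(sort(lengths(partitionMajorClass(1:23, 5)),
                      decreasing = TRUE), c(5L, 5L, 5L, 4L, 4L))
    expect_equal(lengths(partitionMajorClass(1:10, 10)), 10L)
    expect_equal(sort(lengths(partitionMajorClass(1:7, 3)),
                      decreasing = TRUE), c(4L, 3L))
    expect_error(partitionMajorClass(integer(0), 3), "non-empty")
    expect_error(partitionMajorClass(1:5, 0), ">= 1")
  })
})

test_that("partitions are disjoint, covering and minority-sized", {
  withr::with_seed(411, {
    for (i in 1:100) {
      nMajor <- sample(1:200, 1)
      minorSize <- sample(1:50, 1)
      parts <- partitionMajorClass(seq_len(nMajor), minorSize)
      all <- unlist(parts)
      expect_equal(sort(all), seq_len(nMajor))        # coverage, disjoint
      expect_equal(length(all), nMajor)
      expect_lte(max(lengths(parts)) - min(lengths(parts)), 1L)
      expect_equal(length(parts),
                   max(1L, as.integer(round(nMajor / minorSize))))
    }
  })
})

test_that("balanced ensemble reduces to a single fit for equal classes", {
  withr::with_seed(412, {
    b <- blobs(12, 12, shift = 2)
    test <- blobs(4, 4, shift = 2)
    spec <- modelSpec("logistic")   # deterministic given data
    pEns <- fitPredictBalanced(b$X, b$y, test$X, spec)
    # one part == whole majority, so the ensemble is one model
    fitRef <- suppressWarnings(stats::glm.fit(cbind(1, b$X), b$y,
                                              family = binomial()))
    pRef <- 1 / (1 + exp(-(cbind(1, test$X) %*% fitRef$coefficients)))
    expect_equal(pEns, as.numeric(pRef), tolerance = 1e-6)
  })
})

test_that("both families separate well-separated blobs perfectly", {
  withr::with_seed(413, {
    b <- blobs(30, 10)
    test <- blobs(10, 10)
    for (fam in c("svm_rbf", "logistic")) {
      p <- fitPredictBalanced(b$X, b$y, test$X, modelSpec(fam))
      expect_true(all(p >= 0 & p <= 1))
      expect_equal(rocAuc(p, test$y), 1.0)
    }
  })
})

test_that("degenerate modeling inputs raise argument errors", {
  b <- blobs(10, 10)
  expect_error(fitPredictBalanced(b$X, rep(1L, 20), b$X,
                                  modelSpec("logistic")), "single class")
  expect_error(modelSpec("decision_tree"))
  expect_error(new("ModelSpec", family = "mystery",
                   hyperparameters = list()), "unknown model family")
  expect_error(modelSpec("svm_rbf", cost = -1), "cost")
})

test_that("cross-validation predicts each drug exactly once per repeat", {
  withr::with_seed(414, {
    b <- blobs(12, 8, shift = 1.5)
    cv <- crossValidate(b$X, b$y, modelSpec("logistic"), folds = 2,
                        repeats = 2, seed = 5)
    pr <- cvPredictions(cv)
    for (r in 1:2)
      expect_setequal(pr$drug_id[pr$repeat_id == r], rownames(b$X))
    expect_true(all(pr$prob >= 0 & pr$prob <= 1))
    expect_equal(nrow(cvMetrics(cv)), 2L)
  })
})

test_that("cross-validation is a deterministic function of the seed", {
  b <- withr::with_seed(415, blobs(15, 10, shift = 1))
  a1 <- crossValidate(b$X, b$y, modelSpec("svm_rbf"), folds = 5,
                      repeats = 2, seed = 9)
  a2 <- crossValidate(b$X, b$y, modelSpec("svm_rbf"), folds = 5,
                      repeats = 2, seed = 9)
  expect_identical(cvPredictions(a1), cvPredictions(a2))
  expect_identical(cvMetrics(a1), cvMetrics(a2))
})

test_that("a class smaller than the fold count is rejected with advice", {
  b <- withr::with_seed(416, blobs(4, 16))
  expect_error(crossValidate(b$X, b$y, modelSpec("logistic"), folds = 10,
                             repeats = 1, seed = 1), "fewer folds")
})

test_that("per-fold feature screening never sees validation rows", {
  b <- withr::with_seed(417, blobs(14, 10, shift = 1))
  seen <- list()
  real <- selectFeatures
  testthat::local_mocked_bindings(
    selectFeatures = function(X, y, alpha = 0.05) {
      seen[[length(seen) + 1L]] <<- rownames(X)
      real(X, y, alpha)
    },
    .package = "adrnet")
  cv <- crossValidate(b$X, b$y, modelSpec("logistic"), folds = 4,
                      repeats = 1, seed = 3)
  pr <- cvPredictions(cv)
  expect_gte(length(seen), 4L)   # >= once per fold (fallback may re-screen)
  # every screening call saw exactly the training rows of one fold:
  # never the full data, never a validation drug
  folds <- split(pr$drug_id, pr$fold)
  all <- rownames(b$X)
  for (u in seen) {
    hits <- vapply(folds, function(f)
      length(intersect(u, f)) == 0 && setequal(u, setdiff(all, f)),
      logical(1))
    expect_equal(sum(hits), 1L)
  }
  # and each fold's training set was screened at least once
  for (f in folds)
    expect_true(any(vapply(seen, function(u)
      setequal(u, setdiff(all, f)), logical(1))))
})
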