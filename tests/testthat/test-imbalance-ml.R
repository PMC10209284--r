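test_that("safe-level SMOTE balances classes with on-segment synthetics", {
  set.seed(31)
  Xmin <- matrix(rnorm(16, 0, 0.5), 8, 2)
  Xmaj <- matrix(rnorm(60, 4, 0.5), 30, 2)
  X <- rbind(Xmin, Xmaj)
  y <- rep(c("+", "-"), c(8, 30))
  sm <- safeLevelSmote(X, y, k = 5, seed = 2)
  expect_equal(unname(table(sm$y)["+"]), unname(table(sm$y)["-"]))
  expect_equal(sm$n_synthetic, 22L)

  # every synthetic point lies on a closed segment between two minority points
  synth <- sm$X[(nrow(X) + 1):nrow(sm$X), , drop = FALSE]
  onSegment <- function(s) {
    for (i in 1:nrow(Xmin)) for (j in 1:nrow(Xmin)) {
      if (i == j) next
      d <- Xmin[j, ] - Xmin[i, ]
      tt <- sum((s - Xmin[i, ]) * d) / sum(d^2)
      if (tt >= -1e-9 && tt <= 1 + 1e-9 &&
          sqrt(sum((Xmin[i, ] + tt * d - s)^2)) < 1e-8) return(TRUE)
    }
    FALSE
  }
  expect_true(all(apply(synth, 1, onSegment)))

  # deterministic given the seed
  sm2 <- safeLevelSmote(X, y, k = 5, seed = 2)
  expect_identical(sm$X, sm2$X)

  expect_error(safeLevelSmote(X, rep("+", 38)), "two classes")
})

test_that("a fully unsafe minority generates nothing, with a warning", {
  # two isolated minority points, each engulfed by majority neighbours
  Xmin <- rbind(c(0, 0), c(20, 20))
  ring <- function(cen) t(vapply(seq(0, 2 * pi, length.out = 7)[-7],
                                 function(a) cen + 0.2 * c(cos(a), sin(a)),
                                 c(0, 0)))
  Xmaj <- rbind(ring(c(0, 0)), ring(c(20, 20)), matrix(rnorm(20, 10, 1), 10, 2))
  X <- rbind(Xmin, Xmaj)
  y <- rep(c("+", "-"), c(2, nrow(Xmaj)))
  expect_warning(sm <- safeLevelSmote(X, y, k = 5, seed = 1), "unsafe")
  expect_equal(sm$n_synthetic, 0L)
})

test_that("cross-validation metrics follow their confusion-count definitions", {
  cm <- bmradiomics:::confusionMetrics(
    factor(rep(c("pos", "neg"), c(8, 31)), levels = c("neg", "pos")),
    factor(c(rep("pos", 3), rep("neg", 5), rep("neg", 30), "pos"),
           levels = c("neg", "pos")))
  expect_equal(unname(cm["recall"]), 3 / 8)            # 0.375
  expect_equal(unname(cm["specificity"]), 30 / 31)     # 0.968
  expect_equal(unname(cm["accuracy"]), 33 / 39)
  prec <- 3 / 4
  expect_equal(unname(cm["f1"]), 2 * prec * (3 / 8) / (prec + 3 / 8))
})

test_that("cross-validation separates separable data and stays null on noise", {
  set.seed(32)
  X <- rbind(matrix(rnorm(60, 0, 0.3), 30, 2), matrix(rnorm(60, 5, 0.3), 30, 2))
  y <- rep(c("-", "+"), c(30, 30))
  rep1 <- crossValidate(X, y, "logistic_regression", folds = 5, seed = 3)
  expect_equal(rep1$auc, 1)

  # labels independent of features: AUC near 0.5
  Xn <- matrix(rnorm(120), 60, 2)
  repn <- crossValidate(Xn, y, "logistic_regression", folds = 5, seed = 3)
  expect_gt(repn$auc, 0.35)
  expect_lt(repn$auc, 0.65)

  # pooled-score AUC agrees with the rank (Mann-Whitney) statistic
  sc <- c(rnorm(20), rnorm(20, 1))
  cls <- factor(rep(c("neg", "pos"), each = 20), levels = c("neg", "pos"))
  aucRank <- (sum(rank(sc)[cls == "pos"]) - 20 * 21 / 2) / (20 * 20)
  aucRoc <- as.numeric(pROC::auc(pROC::roc(cls, sc,
                                           levels = c("neg", "pos"),
                                           direction = "<", quiet = TRUE)))
  expect_equal(aucRoc, aucRank)

  expect_error(crossValidate(X[1:12, ], y[1:12], "knn", folds = 5),
               "fewer folds")
})

test_that("the model suite returns eight deterministic reports in fixed order", {
  set.seed(33)
  X <- rbind(matrix(rnorm(80, 0, 1), 40, 2), matrix(rnorm(80, 3, 1), 40, 2))
  y <- rep(c("-", "+"), c(40, 40))
  repA <- runModelSuite(X, y, folds = 5, seed = 4)
  repB <- runModelSuite(X, y, folds = 5, seed = 4)
  expect_equal(nrow(repA), 8L)
  expect_identical(repA$model, modelNames())
  expect_identical(repA, repB)
  expect_true(all(repA$auc >= 0 & repA$auc <= 1))
  expect_true(all(repA$specificity >= 0 & repA$specificity <= 1))
})

test_that("within-fold oversampling keeps synthetic points out of the test folds", {
  set.seed(34)
  X <- rbind(matrix(rnorm(30, 0, 1), 15, 2), matrix(rnorm(90, 2.5, 1), 45, 2))
  y <- rep(c("+", "-"), c(15, 45))
  rep1 <- crossValidate(X, y, "logistic_regression", folds = 5, seed = 5,
                        smote = TRUE)
  expect_true(all(c(rep1$auc, rep1$accuracy) > 0))
  expect_equal(nrow(rep1), 1L)
})
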