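## Safe-Level-SMOTE oversampling and the eight-classifier, five-fold
## cross-validated suite with six performance metrics.

#' Safe-Level-SMOTE oversampling
#'
#' Synthetic minority samples are interpolated between a minority seed p and
#' one of its k nearest minority neighbours n, with the interpolation gap
#' modulated by the "safe levels" sl(p) and sl(n) - the number of minority
#' points among each point's k nearest neighbours in the full data set
#' (Euclidean distance on min-max scaled features):
#' both zero: skip; sl(n) = 0 only: duplicate p (gap 0); ratio
#' sl(p)/sl(n) = 1: gap ~ U(0,1); ratio > 1: gap ~ U(0, 1/ratio);
#' ratio < 1: gap ~ U(1 - ratio, 1). Generation repeats until the classes
#' are balanced. If every seed-neighbour combination is unsafe, no points
#' are generated and a warning is emitted.
#'
#' @param X numeric feature matrix (rows = samples).
#' @param y factor or vector with exactly two classes.
#' @param k number of nearest neighbours (default 5; capped at minority
#'   count - 1).
#' @param seed integer RNG seed; output is deterministic given the seed.
#' @return list with the augmented `X`, `y`, and `n_synthetic`.
#' @export
safeLevelSmote <- function(X, y, k = 5L, seed = 1L) {
  X <- as.matrix(X)
  y <- as.factor(y)
  if (nlevels(droplevels(y)) != 2L)
    stop("need exactly two classes", call. = FALSE)
  y <- droplevels(y)
  counts <- table(y)
  minLab <- names(counts)[which.min(counts)]
  majLab <- names(counts)[which.max(counts)]
  need <- as.integer(counts[majLab] - counts[minLab])
  if (need == 0L) return(list(X = X, y = y, n_synthetic = 0L))
  k <- max(1L, min(as.integer(k), as.integer(counts[minLab]) - 1L))

  # min-max scale for the neighbourhood geometry only
  rng <- apply(X, 2, range)
  span <- pmax(rng[2, ] - rng[1, ], .Machine$double.eps)
  Xs <- sweep(sweep(X, 2, rng[1, ]), 2, span, "/")
  D <- as.matrix(stats::dist(Xs))
  diag(D) <- Inf

  minIdx <- which(y == minLab)
  # safe level of every sample: minority count among its k nearest neighbours
  slAll <- apply(D, 1, function(drow) {
    nb <- order(drow)[seq_len(k)]
    sum(y[nb] == minLab)
  })
  # k nearest minority neighbours of each minority point
  minNb <- lapply(minIdx, function(i) {
    dm <- D[i, minIdx]
    minIdx[order(dm)[seq_len(min(k, length(minIdx) - 1L))]]
  })

  withSeed(seed, {
    synth <- matrix(numeric(0), 0, ncol(X))
    guard <- 0L
    while (nrow(synth) < need) {
      produced <- FALSE
      for (s in sample(seq_along(minIdx))) {
        if (nrow(synth) >= need) break
        p <- minIdx[s]
        nb <- minNb[[s]]
        if (length(nb) == 0L) next
        nSel <- nb[sample.int(length(nb), 1L)]
        slp <- slAll[p]; sln <- slAll[nSel]
        if (slp == 0 && sln == 0) next
        gap <- if (sln == 0) 0
        else {
          ratio <- slp / sln
          if (ratio == 1) stats::runif(1)
          else if (ratio > 1) stats::runif(1, 0, 1 / ratio)
          else stats::runif(1, 1 - ratio, 1)
        }
        synth <- rbind(synth, X[p, ] + gap * (X[nSel, ] - X[p, ]))
        produced <- TRUE
      }
      if (!produced) {
        warning("all minority samples are unsafe; no synthetic points generated")
        break
      }
      guard <- guard + 1L
      if (guard > need + 10L) break
    }
    if (nrow(synth) > 0) {
      colnames(synth) <- colnames(X)
      X <- rbind(X, synth)
      y <- factor(c(as.character(y), rep(minLab, nrow(synth))),
                  levels = levels(y))
    }
    list(X = X, y = y, n_synthetic = nrow(synth))
  })
}

#' Names of the eight classifiers, in report order
#'
#' @return character(8).
#' @export
modelNames <- function() {
  c("decision_tree", "svm_rbf", "svm_polynomial", "svm_linear",
    "random_forest", "neural_network", "logistic_regression", "knn")
}

# fit one model on training data and return scores (P(positive)-like) and
# predicted classes for the test set; y has levels c("neg", "pos")
fitPredict <- function(model, Xtr, ytr, Xte, hyper) {
  dtr <- data.frame(Xtr, y = ytr, check.names = FALSE)
  dte <- data.frame(Xte, check.names = FALSE)
  if (model == "decision_tree") {
    fit <- rpart::rpart(y ~ ., dtr, method = "class",
                        control = rpart::rpart.control(cp = hyper$tree_cp))
    pr <- stats::predict(fit, dte, type = "prob")[, "pos"]
  } else if (model %in% c("svm_rbf", "svm_polynomial", "svm_linear")) {
    kern <- switch(model, svm_rbf = "radial", svm_polynomial = "polynomial",
                   svm_linear = "linear")
    fit <- e1071::svm(y ~ ., dtr, kernel = kern, cost = hyper$svm_cost,
                      degree = hyper$svm_degree, scale = FALSE)
    pcls <- stats::predict(fit, dte, decision.values = TRUE)
    dv <- attr(pcls, "decision.values")
    # orient the decision value so larger means more positive
    pr <- if (grepl("^pos/", colnames(dv))) dv[, 1] else -dv[, 1]
    return(list(score = as.numeric(pr),
                class = factor(as.character(pcls), levels = c("neg", "pos"))))
  } else if (model == "random_forest") {
    fit <- randomForest::randomForest(Xtr, ytr, ntree = hyper$rf_ntree)
    pr <- stats::predict(fit, Xte, type = "prob")[, "pos"]
  } else if (model == "neural_network") {
    fit <- nnet::nnet(y ~ ., dtr, size = hyper$nn_size, decay = hyper$nn_decay,
                      maxit = hyper$nn_maxit, trace = FALSE,
                      MaxNWts = 10000)
    pr <- as.numeric(stats::predict(fit, dte, type = "raw"))
  } else if (model == "logistic_regression") {
    fit <- suppressWarnings(stats::glm(y ~ ., dtr,
                                       family = stats::binomial()))
    pr <- suppressWarnings(stats::predict(fit, dte, type = "response"))
  } else if (model == "knn") {
    pred <- class::knn(Xtr, Xte, ytr, k = hyper$knn_k, prob = TRUE)
    win <- attr(pred, "prob")
    pr <- ifelse(pred == "pos", win, 1 - win)
  } else stop("unknown model: ", model, call. = FALSE)
  cls <- factor(ifelse(pr >= 0.5, "pos", "neg"), levels = c("neg", "pos"))
  list(score = as.numeric(pr), class = cls)
}

defaultHyper <- function() {
  list(tree_cp = 0.01, svm_cost = 1, svm_degree = 3, rf_ntree = 500L,
       nn_size = 8L, nn_decay = 0.01, nn_maxit = 300L, knn_k = 5L)
}

stratifiedFolds <- function(y, folds, seed) {
  withSeed(seed, {
    fold <- integer(length(y))
    for (lv in levels(y)) {
      idx <- sample(which(y == lv))
      fold[idx] <- rep_len(seq_len(folds), length(idx))
    }
    fold
  })
}

confusionMetrics <- function(truth, pred) {
  TP <- sum(truth == "pos" & pred == "pos")
  TN <- sum(truth == "neg" & pred == "neg")
  FP <- sum(truth == "neg" & pred == "pos")
  FN <- sum(truth == "pos" & pred == "neg")
  precision <- if (TP + FP > 0) TP / (TP + FP) else 0
  recall <- if (TP + FN > 0) TP / (TP + FN) else 0
  f1 <- if (precision + recall > 0)
    2 * precision * recall / (precision + recall) else 0
  c(accuracy = (TP + TN) / length(truth), f1 = f1, precision = precision,
    recall = recall,
    specificity = if (TN + FP > 0) TN / (TN + FP) else 0)
}

#' Cross-validate one classifier
#'
#' Stratified k-fold cross-validation with predictions pooled across folds.
#' Features are standardized with training-fold statistics. The positive
#' class is the "+" label; AUC comes from the pooled scores, the remaining
#' metrics from the pooled class predictions.
#'
#' @param X numeric feature matrix.
#' @param y two-class labels; "+" (or level "pos") is the positive class.
#' @param model one of [modelNames()].
#' @param folds number of folds (default 5).
#' @param seed integer RNG seed.
#' @param hyper hyperparameter list; see `bmradiomics:::defaultHyper()`.
#' @param smote apply [safeLevelSmote()] to the training fold only
#'   (leakage-safe oversampling inside cross-validation; default FALSE).
#' @param smote_k neighbours for the within-fold oversampling.
#' @return one-row data.frame: model, auc, accuracy, f1, precision, recall,
#'   specificity, acceptable (all metrics > 0.7), outstanding (> 0.9).
#' @export
crossValidate <- function(X, y, model, folds = 5L, seed = 1L, hyper = NULL,
                          smote = FALSE, smote_k = 5L) {
  X <- as.matrix(X)
  y <- normalizeClass(y)
  hyper <- utils::modifyList(defaultHyper(), hyper %||% list())
  if (min(table(y)) < folds)
    stop("a fold would lack a class; use fewer folds", call. = FALSE)
  fold <- stratifiedFolds(y, folds, seed)
  score <- numeric(length(y))
  pred <- factor(rep("neg", length(y)), levels = c("neg", "pos"))
  for (f in seq_len(folds)) {
    tr <- fold != f
    Xf <- X[tr, , drop = FALSE]
    yf <- y[tr]
    if (isTRUE(smote)) {
      sm <- safeLevelSmote(Xf, yf, k = smote_k, seed = seed + 100L + f)
      Xf <- sm$X
      yf <- normalizeClass(sm$y)
    }
    mu <- colMeans(Xf)
    sg <- apply(Xf, 2, stats::sd)
    sg[sg == 0] <- 1
    Xtr <- sweep(sweep(Xf, 2, mu), 2, sg, "/")
    Xte <- sweep(sweep(X[!tr, , drop = FALSE], 2, mu), 2, sg, "/")
    res <- withSeed(seed + f, fitPredict(model, Xtr, yf, Xte, hyper))
    score[!tr] <- res$score
    pred[!tr] <- res$class
  }
  auc <- as.numeric(pROC::auc(pROC::roc(response = y, predictor = score,
                                        levels = c("neg", "pos"),
                                        direction = "<", quiet = TRUE)))
  m <- confusionMetrics(y, pred)
  data.frame(model = model, auc = auc, accuracy = m["accuracy"],
             f1 = m["f1"], precision = m["precision"], recall = m["recall"],
             specificity = m["specificity"],
             acceptable = all(c(auc, m) > 0.7),
             outstanding = all(c(auc, m) > 0.9),
             row.names = NULL, stringsAsFactors = FALSE)
}

normalizeClass <- function(y) {
  if (is.factor(y)) y <- as.character(y)
  if (all(y %in% c("+", "-")))
    y <- ifelse(y == "+", "pos", "neg")
  factor(y, levels = c("neg", "pos"))
}

#' Run the eight-classifier suite
#'
#' Decision tree, SVM with RBF / polynomial / linear kernels, random forest,
#' neural network, logistic regression and k-nearest neighbours, each
#' cross-validated with [crossValidate()].
#'
#' @inheritParams crossValidate
#' @return data.frame with 8 rows (one per model, fixed order) and the six
#'   metrics plus threshold flags.
#' @export
runModelSuite <- function(X, y, folds = 5L, seed = 1L, hyper = NULL,
                          smote = FALSE, smote_k = 5L) {
  do.call(rbind, lapply(modelNames(), function(m)
    crossValidate(X, y, m, folds = folds, seed = seed, hyper = hyper,
                  smote = smote, smote_k = smote_k)))
}
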