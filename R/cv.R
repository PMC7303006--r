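#' Stratified cross-validation folds
#'
#' Fold assignment is a pure function of the label vector, fold count,
#' repeat count and seed: both classifiers in a comparison see identical
#' partitions.
#'
#' @param labels two-level factor (or coercible).
#' @param nFolds folds per repeat.
#' @param nRepeats independent repeats.
#' @param seed RNG seed.
#' @return list of integer fold-id vectors, one per repeat.
#' @export
makeStratifiedFolds <- function(labels, nFolds = 10L, nRepeats = 10L,
                                seed = 1L) {
  labels <- factor(labels)
  n <- length(labels)
  withSeed(seed, lapply(seq_len(nRepeats), function(r) {
    fold <- integer(n)
    for (lv in levels(labels)) {
      idx <- sample(which(labels == lv))
      fold[idx] <- rep_len(seq_len(nFolds), length(idx))
    }
    fold
  }))
}

## logistic-regression CV accuracy for a fixed design matrix and fold list;
## returns accuracy/sensitivity/specificity averaged over repeats.
## positive = the factor's FIRST level (sensitivity = recall on it).
.cvMetrics <- function(X, y, folds, classifier = "logistic",
                       ridgeLambda = 0.05) {
  y01 <- as.integer(y == levels(y)[1])
  X <- cbind(1, as.matrix(X))
  perRepeat <- vapply(folds, function(fold) {
    pred <- integer(length(y01))
    for (f in unique(fold)) {
      tr <- fold != f
      if (classifier == "ridge") {
        if (!requireNamespace("glmnet", quietly = TRUE))
          stop("classifier = 'ridge' needs the glmnet package")
        fit <- glmnet::glmnet(X[tr, -1, drop = FALSE], y01[tr],
                              family = "binomial", alpha = 0,
                              lambda = ridgeLambda)
        ph <- as.numeric(stats::predict(fit, X[!tr, -1, drop = FALSE],
                                        type = "response"))
      } else {
        fit <- suppressWarnings(
          stats::glm.fit(X[tr, , drop = FALSE], y01[tr],
                         family = stats::binomial()))
        eta <- X[!tr, , drop = FALSE] %*% fit$coefficients
        ph <- 1 / (1 + exp(-eta))
      }
      pred[!tr] <- as.integer(ph > 0.5)
    }
    c(acc = mean(pred == y01),
      sens = mean(pred[y01 == 1] == 1),
      spec = mean(pred[y01 == 0] == 0))
  }, c(acc = 0, sens = 0, spec = 0))
  rowMeans(perRepeat)
}

#' Cross-validated added value of a signature feature
#'
#' Compares two classifiers of treatment outcome under identical stratified
#' cross-validation partitions: a base model on demographic/clinical features
#' and the same model augmented with one added feature (the per-subject
#' signature mean). The improvement p-value comes from permuting the added
#' feature across subjects and recomputing the augmented model's
#' cross-validated accuracy each time (the base model is untouched by the
#' permutation): `p = (1 + #\{perm >= observed\}) / (1 + nPerm)`.
#'
#' @param baseFeatures subjects x k matrix/data.frame of base predictors.
#' @param addedFeature numeric per-subject signature measure.
#' @param labels two-level outcome factor; the first level is the positive
#'   class for sensitivity.
#' @param nFolds,nRepeats cross-validation scheme (default 10 x 10).
#' @param nPerm permutations for the improvement test (default 1000).
#' @param classifier `"logistic"` (maximum-likelihood, default) or
#'   `"ridge"` (L2-regularized via glmnet).
#' @param ridgeLambda penalty for the ridge classifier.
#' @param seed RNG seed controlling folds and permutations.
#' @return list of class `CVComparisonResult`: `base` and `augmented`
#'   (accuracy/sensitivity/specificity), `improvement_p`, `nFolds`,
#'   `nRepeats`, `nPerm`, `seed`.
#' @export
cvModelComparison <- function(baseFeatures, addedFeature, labels,
                              nFolds = 10L, nRepeats = 10L, nPerm = 1000L,
                              classifier = c("logistic", "ridge"),
                              ridgeLambda = 0.05, seed = 1L) {
  classifier <- match.arg(classifier)
  labels <- droplevels(factor(labels))
  if (nlevels(labels) != 2)
    stop("labels must have exactly two classes, got ", nlevels(labels))
  Xb <- as.matrix(as.data.frame(baseFeatures))
  n <- nrow(Xb)
  if (n < 20) stop("need at least 20 subjects")
  stopifnot(length(addedFeature) == n, length(labels) == n)
  folds <- makeStratifiedFolds(labels, nFolds, nRepeats, seed)
  base <- .cvMetrics(Xb, labels, folds, classifier, ridgeLambda)
  aug <- .cvMetrics(cbind(Xb, signature = addedFeature), labels, folds,
                    classifier, ridgeLambda)
  permAcc <- if (nPerm > 0)
    withSeed(seed + 1L, vapply(seq_len(nPerm), function(b) {
      xp <- addedFeature[sample.int(n)]
      .cvMetrics(cbind(Xb, signature = xp), labels, folds, classifier,
                 ridgeLambda)[["acc"]]
    }, numeric(1)))
  else numeric(0)
  structure(list(base = base, augmented = aug,
                 improvement_p = if (nPerm > 0)
                   (1 + sum(permAcc >= aug[["acc"]])) / (1 + nPerm)
                 else NA_real_,
                 null_accuracy = permAcc, nFolds = nFolds,
                 nRepeats = nRepeats, nPerm = nPerm, seed = seed,
                 classifier = classifier),
            class = "CVComparisonResult")
}

#' @export
print.CVComparisonResult <- function(x, ...) {
  cat(sprintf("Cross-validated model comparison (%d-fold x %d, %s)\n",
              x$nFolds, x$nRepeats, x$classifier))
  cat(sprintf("  base:      accuracy %.1f%%, sensitivity %.1f%%, specificity %.1f%%\n",
              100 * x$base[["acc"]], 100 * x$base[["sens"]],
              100 * x$base[["spec"]]))
  cat(sprintf("  augmented: accuracy %.1f%%, sensitivity %.1f%%, specificity %.1f%%\n",
              100 * x$augmented[["acc"]], 100 * x$augmented[["sens"]],
              100 * x$augmented[["spec"]]))
  cat(sprintf("  improvement p = %.4g (%d permutations of the added feature)\n",
              x$improvement_p, x$nPerm))
  invisible(x)
}
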