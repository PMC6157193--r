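# Nested k-fold cross-validation.  The outer loop measures out-of-sample
# prediction (each sample predicted exactly once by a model that never saw
# it); within each outer training set an inner loop selects the penalty by
# mean validation MSE over a lambda grid computed from that training set
# and shared across its inner splits.

#' Random k-fold assignment
#'
#' Uniformly random partition into k folds with sizes differing by at most
#' one; deterministic under the seed.
#'
#' @param n number of samples
#' @param k number of folds, 2 <= k <= n
#' @param seed integer seed
#' @return integer vector of fold labels in 1..k
#' @export
makeFolds <- function(n, k, seed = NULL) {
  if (k < 2) stop("k must be at least 2")
  if (k > n) stop("k cannot exceed n")
  .withSeed(seed, sample(rep(seq_len(k), length.out = n)))
}

#' Inner cross-validation selection of the penalty
#'
#' For each inner split, fits the path on the inner-training samples over
#' the supplied grid and computes validation MSE per lambda; selects the
#' lambda minimizing the mean MSE across inner folds, resolving ties
#' toward the larger lambda (parsimony).
#'
#' @param X,y training data
#' @param kInner number of inner folds (>= 2)
#' @param lambda descending penalty grid (shared across inner splits so
#'   the mean-MSE curve is well-defined)
#' @param tol,maxIter,standardize,screen passed to
#'   \code{\link{fitLassoPath}}
#' @param seed integer seed for the inner fold assignment
#' @return list with \code{lambda} (selected value), \code{index} (grid
#'   position), \code{meanMSE} (curve over the grid) and \code{converged}
#'   (all inner fits converged?)
#' @export
innerSelectLambda <- function(X, y, kInner, lambda, tol = 1e-7,
                              maxIter = 1e5, standardize = TRUE,
                              screen = FALSE, seed = NULL) {
  stopifnot(kInner >= 2, nrow(X) == length(y))
  folds <- makeFolds(nrow(X), kInner, seed)
  mseMat <- matrix(NA_real_, kInner, length(lambda))
  allConv <- TRUE
  for (f in seq_len(kInner)) {
    if (nrow(X) * ncol(X) > 1e8) gc(FALSE)  # release the previous split
    tr <- folds != f
    fit <- fitLassoPath(X[tr, , drop = FALSE], y[tr], lambda = lambda,
                        tol = tol, maxIter = maxIter,
                        standardize = standardize, screen = screen)
    allConv <- allConv && all(fit@converged)
    yhat <- .predictGrid(fit, X[!tr, , drop = FALSE])
    mseMat[f, ] <- colMeans((y[!tr] - yhat)^2)
  }
  meanMSE <- colMeans(mseMat)
  idx <- which.min(meanMSE)   # first minimum = largest lambda on ties
  list(lambda = lambda[idx], index = idx, meanMSE = meanMSE,
       converged = allConv)
}

# predictions at every grid point at once (samples x lambda), restricted
# to the union of active predictors for speed
.predictGrid <- function(path, X) {
  if (anyNA(X)) {
    for (j in seq_len(ncol(X))) {
      miss <- is.na(X[, j])
      if (any(miss)) X[miss, j] <- path@center[j]
    }
  }
  act <- which(rowSums(path@beta != 0) > 0)
  yhat <- matrix(rep(path@intercept, each = nrow(X)), nrow(X))
  if (length(act))
    yhat <- yhat + X[, act, drop = FALSE] %*% path@beta[act, , drop = FALSE]
  yhat
}

#' Nested cross-validation of LASSO prediction
#'
#' For each outer fold: compute the lambda grid from the outer-training
#' set, select lambda by inner cross-validation on that set, refit on the
#' full outer-training set at the selected lambda, and predict the held-
#' out fold.  Pools all test predictions and evaluates them with
#' \code{\link{evaluatePredictions}}; records per-fold coefficients of any
#' tracked SNPs with their mean and SD (n-1) across folds.
#'
#' @param X n x p predictor matrix (or \linkS4class{GenotypeMatrix})
#' @param y response vector
#' @param kOuter,kInner fold counts (default 10 and 10)
#' @param nLambda,lambdaMinRatio,tol,maxIter,standardize,screen solver
#'   settings (see \code{\link{fitLassoPath}})
#' @param trackedSnps column indices (or names) whose coefficients are
#'   recorded per fold
#' @param seed integer seed driving the outer and inner fold draws
#' @return a \linkS4class{CVReport}
#' @examples
#' set.seed(1)
#' X <- matrix(rbinom(200 * 30, 2, 0.3), 200, 30)
#' y <- -0.8 * X[, 7] + rnorm(200)
#' rep <- nestedCV(X, y, kOuter = 5, kInner = 3, nLambda = 30,
#'                 trackedSnps = 7, seed = 42)
#' rep
#' @export
nestedCV <- function(X, y, kOuter = 10, kInner = 10, nLambda = 100,
                     lambdaMinRatio = NULL, tol = 1e-7, maxIter = 1e5,
                     standardize = TRUE, screen = FALSE,
                     trackedSnps = integer(), seed = NULL) {
  if (is(X, "GenotypeMatrix")) X <- dosages(X)
  stopifnot(nrow(X) == length(y))
  n <- nrow(X); p <- ncol(X)
  if (is.character(trackedSnps))
    trackedSnps <- match(trackedSnps, colnames(X))
  trackedSnps <- as.integer(trackedSnps)
  if (anyNA(X)) {
    for (j in seq_len(p)) {
      miss <- is.na(X[, j])
      if (any(miss)) X[miss, j] <- mean(X[, j], na.rm = TRUE)
    }
  }
  if (is.null(lambdaMinRatio))
    lambdaMinRatio <- if (n > p) 1e-4 else 0.01
  folds <- makeFolds(n, kOuter, seed)
  baseSeed <- if (is.null(seed)) 0L else as.integer(seed)
  preds <- rep(NA_real_, n)
  selLambda <- numeric(kOuter)
  innerCurves <- vector("list", kOuter)
  foldCoefs <- matrix(0, p, kOuter)
  for (f in seq_len(kOuter)) {
    if (n * as.double(p) > 1e8) gc(FALSE)  # release the previous fold
    tr <- folds != f
    Xtr <- X[tr, , drop = FALSE]; ytr <- y[tr]
    lmax <- lambdaMax(Xtr, ytr, standardize = standardize)
    grid <- .lambdaGrid(lmax, nLambda, lambdaMinRatio)
    sel <- innerSelectLambda(Xtr, ytr, kInner, grid, tol = tol,
                             maxIter = maxIter, standardize = standardize,
                             screen = screen,
                             seed = baseSeed * 100L + f)
    # refit on the full outer-training set, warm-started down the grid
    # truncated at the selected lambda
    fit <- fitLassoPath(Xtr, ytr, lambda = grid[seq_len(sel$index)],
                        tol = tol, maxIter = maxIter,
                        standardize = standardize, screen = screen)
    preds[!tr] <- predict(fit, X[!tr, , drop = FALSE], sel$index)
    selLambda[f] <- sel$lambda
    innerCurves[[f]] <- data.frame(lambda = grid, meanMSE = sel$meanMSE)
    foldCoefs[, f] <- coef(fit)[, sel$index]
  }
  stopifnot(!anyNA(preds))   # every sample predicted exactly once
  metrics <- evaluatePredictions(y, preds)
  trackedCoefs <- foldCoefs[trackedSnps, , drop = FALSE]
  rownames(foldCoefs) <- colnames(X)
  rownames(trackedCoefs) <- colnames(X)[trackedSnps]
  new("CVReport",
      folds = as.integer(folds), selectedLambda = selLambda,
      lambdaRange = range(selLambda), innerMSE = innerCurves,
      foldCoefs = foldCoefs, trackedCoefs = trackedCoefs,
      trackedMean = apply(trackedCoefs, 1, mean),
      trackedSD = apply(trackedCoefs, 1, sd),
      predictions = preds, observed = as.numeric(y),
      metrics = metrics$metrics, degenerate = metrics$degenerate)
}

#' Prediction-accuracy metrics
#'
#' Pearson correlation between observed and predicted (bounded by the
#' square root of heritability for a genetic predictor), mean squared
#' error, and the slope of the best-fit line of predicted on observed
#' (1 = perfect prediction; heavy shrinkage gives a slope far below 1).
#' Constant predictions are degenerate: r and slope are reported as 0
#' with \code{degenerate = TRUE}.
#'
#' @param yObserved,yPredicted numeric vectors of equal length >= 3
#' @return list with \code{metrics} (named numeric: pearsonR, mse, slope)
#'   and \code{degenerate}
#' @examples
#' evaluatePredictions(c(0, 1, 2, 3), c(0.1, 0.8, 2.2, 2.9))
#' @export
evaluatePredictions <- function(yObserved, yPredicted) {
  if (length(yObserved) != length(yPredicted))
    stop("observed and predicted lengths differ")
  if (length(yObserved) < 3) stop("need at least 3 observations")
  mse <- mean((yObserved - yPredicted)^2)
  degenerate <- sd(yPredicted) == 0
  if (degenerate) {
    r <- 0; slope <- 0
  } else {
    r <- cor(yObserved, yPredicted)
    # slope of predicted regressed on observed
    slope <- cov(yObserved, yPredicted) / var(yObserved)
  }
  list(metrics = c(pearsonR = r, mse = mse, slope = slope),
       degenerate = degenerate)
}

#' Export a CVReport
#'
#' JSON for machine use (selected lambdas, metrics, tracked
#' coefficients) plus two TSVs: a per-fold table and the pooled
#' out-of-sample predictions.
#'
#' @param report a \linkS4class{CVReport}
#' @param prefix output path prefix
#' @param sampleIds optional sample identifiers for the prediction table
#' @return \code{prefix}, invisibly
#' @export
writeCVReport <- function(report, prefix, sampleIds = NULL) {
  stopifnot(is(report, "CVReport"))
  k <- length(report@selectedLambda)
  foldTab <- data.frame(fold = seq_len(k),
                        selectedLambda = report@selectedLambda)
  if (nrow(report@trackedCoefs))
    foldTab <- cbind(foldTab, t(report@trackedCoefs))
  write.table(foldTab, paste0(prefix, "_folds.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  n <- length(report@observed)
  predTab <- data.frame(
    sample_id = if (is.null(sampleIds)) seq_len(n) else sampleIds,
    fold = report@folds, observed = report@observed,
    predicted = report@predictions)
  write.table(predTab, paste0(prefix, "_predictions.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(metrics = as.list(report@metrics),
         selectedLambda = report@selectedLambda,
         lambdaRange = report@lambdaRange,
         trackedMean = report@trackedMean,
         trackedSD = report@trackedSD,
         degenerate = report@degenerate),
    paste0(prefix, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(prefix)
}
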