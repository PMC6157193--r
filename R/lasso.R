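# LASSO by cyclic coordinate descent along a descending lambda grid with
# warm starts.  Objective: (1/(2n)) RSS + lambda * ||beta||_1 on
# (optionally) standardized predictors; the 1/(2n) scaling makes lambda
# values commensurable across fold sizes and with standard solver output.
# The unscaled-RSS form of the objective is available through
# objectiveScaling = "rss" (internally lambda is divided by 2n, which
# yields the identical minimizer).  The intercept is never penalized.

#' Soft-thresholding operator
#'
#' \code{S(z, gamma) = sign(z) * max(|z| - gamma, 0)}, the coordinate-wise
#' solution of the one-dimensional LASSO problem.
#'
#' @param z numeric input
#' @param gamma threshold, >= 0
#' @return thresholded value(s)
#' @examples
#' softThreshold(3, 1)     # 2
#' softThreshold(-0.5, 1)  # 0
#' @export
softThreshold <- function(z, gamma) {
  if (any(gamma < 0)) stop("gamma must be non-negative")
  sign(z) * pmax(abs(z) - gamma, 0)
}

# per-column population (1/n) standardization stats
.colStats <- function(X) {
  n <- nrow(X)
  m <- colMeans(X)
  v <- colMeans(X * X) - m^2
  v[v < 0] <- 0
  list(center = m, scale = sqrt(v))
}

#' Smallest penalty with an all-zero solution
#'
#' \code{lambda_max = max_j |x_j' y_c| / n} on column-standardized
#' predictors and centered response; fitting at any lambda at or above
#' this value returns the zero coefficient vector.
#'
#' @param X predictor matrix
#' @param y response
#' @param standardize standardize columns first (population variance)?
#' @return lambda_max (0 when y is orthogonal to every column)
#' @export
lambdaMax <- function(X, y, standardize = TRUE) {
  stopifnot(nrow(X) == length(y))
  n <- nrow(X)
  yc <- y - mean(y)
  st <- .colStats(X)
  g <- abs(as.vector(crossprod(X, yc)) - st$center * sum(yc)) / n
  if (standardize) {
    if (any(st$scale == 0 & g > 1e-12))
      stop("zero-variance column cannot be standardized")
    ok <- st$scale > 0
    g <- ifelse(ok, g / st$scale, 0)
  }
  if (!length(g)) return(0)
  # one-part-in-1e12 guard so the all-zero solution holds at the reported
  # value despite summation-order differences between BLAS kernels
  max(g) * (1 + 1e-12)
}

# descending log-spaced grid from lambda_max
.lambdaGrid <- function(lmax, nLambda, lambdaMinRatio) {
  exp(seq(log(lmax), log(lmax * lambdaMinRatio), length.out = nLambda))
}

#' Fit a LASSO regularization path
#'
#' Cyclic coordinate descent on standardized predictors over a descending
#' log-spaced lambda grid from \code{lambda_max} down to
#' \code{lambdaMinRatio * lambda_max}, warm-starting each lambda from the
#' previous solution.  Per lambda: a full sweep, then iteration on the
#' active set until stable, then a confirming full sweep; convergence is
#' a maximum standardized-coefficient change below \code{tol}, which
#' certifies the KKT conditions coordinate-wise.  Coefficients are
#' returned on the original dosage scale with the intercept
#' \code{ybar - sum(beta_j * xbar_j)}.  Missing predictor entries are
#' mean-imputed per column before fitting.
#'
#' @param X n x p predictor matrix (or \linkS4class{GenotypeMatrix})
#' @param y numeric response, length n >= 2
#' @param nLambda grid size (default 100)
#' @param lambdaMinRatio smallest lambda as a fraction of lambda_max;
#'   default 1e-4 when n > p, 0.01 otherwise
#' @param lambda explicit descending grid (overrides the two above)
#' @param tol convergence tolerance on the maximum standardized
#'   coefficient change per sweep (default 1e-7)
#' @param maxIter cap on coordinate-descent sweeps per lambda
#' @param standardize standardize predictors (population 1/n variance)
#'   before fitting? (default TRUE; coefficients are always reported on
#'   the original scale)
#' @param screen use sequential strong-rule screening with an exact
#'   full-KKT backstop?  Default FALSE (every coordinate visited each full
#'   sweep); the screened path satisfies the same optimality conditions
#'   and is much faster when p is large.
#' @param objectiveScaling \code{"half_n"} for (1/(2n)) RSS +
#'   lambda ||beta||_1 (default) or \code{"rss"} for the unscaled form
#'   RSS + lambda ||beta||_1
#' @param trackObjective record the per-sweep objective trace per lambda
#'   (for convergence diagnostics)?
#' @return a \linkS4class{LassoPath}; non-converged lambda values are
#'   flagged and reported with a warning, never silently
#' @examples
#' set.seed(1)
#' X <- matrix(rnorm(200), 40, 5)
#' y <- X[, 2] * 1.5 + rnorm(40)
#' fit <- fitLassoPath(X, y, nLambda = 20)
#' fit
#' coef(fit)[, 20]
#' @export
fitLassoPath <- function(X, y, nLambda = 100, lambdaMinRatio = NULL,
                         lambda = NULL, tol = 1e-7, maxIter = 1e5,
                         standardize = TRUE, screen = FALSE,
                         objectiveScaling = c("half_n", "rss"),
                         trackObjective = FALSE) {
  if (is(X, "GenotypeMatrix")) X <- dosages(X)
  stopifnot(is.matrix(X), nrow(X) == length(y), nrow(X) >= 1)
  if (tol <= 0) stop("tol must be positive")
  objectiveScaling <- match.arg(objectiveScaling)
  if (anyNA(X)) {
    for (j in seq_len(ncol(X))) {
      miss <- is.na(X[, j])
      if (any(miss)) X[miss, j] <- mean(X[, j], na.rm = TRUE)
    }
  }
  n <- nrow(X); p <- ncol(X)
  if (is.null(lambda)) {
    if (is.null(lambdaMinRatio))
      lambdaMinRatio <- if (n > p) 1e-4 else 0.01
    if (lambdaMinRatio <= 0 || lambdaMinRatio >= 1)
      stop("lambdaMinRatio must lie in (0, 1)")
    lmax <- lambdaMax(X, y, standardize = standardize)
    if (objectiveScaling == "rss") lmax <- lmax * 2 * n
    if (lmax <= 0)
      stop("lambda_max is 0 (response uncorrelated with all predictors); ",
           "supply an explicit lambda grid")
    lambda <- .lambdaGrid(lmax, nLambda, lambdaMinRatio)
  } else {
    lambda <- as.numeric(lambda)
    if (is.unsorted(rev(lambda))) stop("lambda grid must be descending")
  }
  workLambda <- if (objectiveScaling == "rss") lambda / (2 * n) else lambda
  fit <- cd_lasso_path_cpp(X, as.numeric(y), workLambda, tol,
                           as.integer(maxIter), standardize, screen,
                           trackObjective)
  scl <- as.numeric(fit$scale); ctr <- as.numeric(fit$center)
  betaStd <- fit$beta_std
  betaOrig <- if (standardize) betaStd / scl else betaStd
  intercept <- fit$ybar - as.vector(crossprod(betaOrig, ctr))
  if (!all(fit$converged))
    warning(sum(!fit$converged),
            " lambda value(s) did not converge within maxIter sweeps")
  rownames(betaOrig) <- colnames(X)
  new("LassoPath", lambda = lambda, beta = betaOrig,
      intercept = intercept, nNonzero = as.integer(fit$n_nonzero),
      converged = as.logical(fit$converged),
      iterations = as.integer(fit$iterations),
      center = ctr, scale = scl,
      ybar = fit$ybar, standardize = standardize,
      objectiveScaling = objectiveScaling,
      objectives = as.list(fit$objectives))
}

#' Predict from a LassoPath at one grid point
#'
#' \code{yhat = intercept + X beta} at the chosen lambda, original
#' predictor scale.  Missing entries are imputed with the training column
#' means stored in the path.
#'
#' @param object a \linkS4class{LassoPath}
#' @param X new predictor matrix (columns aligned with the training
#'   matrix)
#' @param lambdaIndex index into the lambda grid
#' @param ... ignored
#' @return numeric predictions
#' @export
setMethod("predict", "LassoPath", function(object, X, lambdaIndex, ...) {
  if (is(X, "GenotypeMatrix")) X <- dosages(X)
  if (ncol(X) != nrow(object@beta))
    stop("predictor columns do not match the fitted path")
  if (lambdaIndex < 1 || lambdaIndex > length(object@lambda))
    stop("lambdaIndex out of range")
  if (anyNA(X)) {
    for (j in seq_len(ncol(X))) {
      miss <- is.na(X[, j])
      if (any(miss)) X[miss, j] <- object@center[j]
    }
  }
  b <- object@beta[, lambdaIndex]
  active <- which(b != 0)
  yhat <- rep(object@intercept[lambdaIndex], nrow(X))
  if (length(active))
    yhat <- yhat + as.vector(X[, active, drop = FALSE] %*% b[active])
  yhat
})

#' Count KKT violations of a fitted path
#'
#' Certifies optimality at one grid point: with standardized predictors
#' and gradient \code{g_j = (1/n) x_j'(y - yhat)}, counts coordinates
#' where \code{beta_j = 0} but \code{|g_j| > lambda + tol}, or
#' \code{beta_j != 0} but \code{|g_j - lambda * sign(beta_j)| > tol}.
#' A converged fit has zero violations.
#'
#' @param path a \linkS4class{LassoPath}
#' @param X,y the training data the path was fitted on
#' @param lambdaIndex grid point to check
#' @param kktTol violation tolerance (default 1e-6)
#' @return integer violation count
#' @export
kktViolations <- function(path, X, y, lambdaIndex, kktTol = 1e-6) {
  if (is(X, "GenotypeMatrix")) X <- dosages(X)
  stopifnot(is(path, "LassoPath"))
  if (anyNA(X)) {
    for (j in seq_len(ncol(X))) {
      miss <- is.na(X[, j])
      if (any(miss)) X[miss, j] <- path@center[j]
    }
  }
  n <- nrow(X)
  lam <- path@lambda[lambdaIndex]
  if (path@objectiveScaling == "rss") lam <- lam / (2 * n)
  bOrig <- path@beta[, lambdaIndex]
  scl <- if (path@standardize) path@scale else rep(1, ncol(X))
  ok <- scl > 0
  bStd <- ifelse(ok, bOrig * scl, 0)
  yc <- y - mean(y)
  r <- yc - as.vector(scale(X, center = path@center,
                            scale = FALSE) %*% bOrig)
  g <- (as.vector(crossprod(X, r)) - path@center * sum(r)) / n
  g <- ifelse(ok, g / scl, 0)
  atZero <- bStd == 0
  sum((atZero & abs(g) > lam + kktTol) |
        (!atZero & abs(g - lam * sign(bStd)) > kktTol))
}
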