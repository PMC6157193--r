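test_that("soft-thresholding operator is correct", {
  expect_equal(softThreshold(3, 1), 2)
  expect_equal(softThreshold(-0.5, 1), 0)
  expect_equal(softThreshold(-3, 1), -2)
  z <- c(-2, -0.1, 0, 0.1, 2)
  expect_equal(softThreshold(z, 0), z)       # gamma = 0 is the identity
  expect_error(softThreshold(1, -1), "non-negative")
})

test_that("lambdaMax bounds the all-zero solution exactly", {
  set.seed(83)
  # single standardized column with (1/n) x'y = 0.3
  n <- 40
  x <- rnorm(n); x <- (x - mean(x)) / sqrt(mean((x - mean(x))^2))
  y <- 0.3 * x
  expect_equal(lambdaMax(matrix(x), y), 0.3, tolerance = 1e-9)
  expect_equal(lambdaMax(matrix(x), rep(0, n)), 0)
  X <- matrix(rnorm(n * 6), n, 6)
  yy <- rnorm(n)
  lmax <- lambdaMax(X, yy)
  fit <- fitLassoPath(X, yy, lambda = c(1.01 * lmax, lmax))
  expect_true(all(coef(fit) == 0))
  expect_equal(fit@intercept, rep(mean(yy), 2))
  # just below lambda_max at least one coefficient activates
  fit2 <- fitLassoPath(X, yy, lambda = c(lmax, 0.99 * lmax))
  expect_gt(fit2@nNonzero[2], 0)
})

test_that("orthonormal design recovers the soft-thresholded OLS solution", {
  set.seed(89)
  n <- 64; p <- 8
  Q <- qr.Q(qr(scale(matrix(rnorm(n * p), n, p), scale = FALSE)))
  y <- rnorm(n, sd = 2)
  lmax <- lambdaMax(Q, y)
  lambda <- lmax * c(0.8, 0.5, 0.2, 0.05)
  fit <- fitLassoPath(Q, y, lambda = lambda, tol = 1e-12)
  sdQ <- sqrt(1 / n)                   # population sd of orthonormal cols
  Qs <- scale(Q, scale = FALSE) * sqrt(n)
  betaOLS <- as.vector(crossprod(Qs, y - mean(y))) / n
  for (l in seq_along(lambda)) {
    betaStd <- coef(fit)[, l] * sdQ
    expect_equal(betaStd, softThreshold(betaOLS, lambda[l]),
                 tolerance = 1e-10, ignore_attr = TRUE)
  }
})

test_that("objective matches the exhaustive sign-pattern oracle", {
  set.seed(97)
  for (i in 1:20) {
    p <- sample(2:8, 1)
    n <- 30
    X <- matrix(rnorm(n * p), n, p)
    beta0 <- rnorm(p) * rbinom(p, 1, 0.5)
    y <- X %*% beta0 + rnorm(n)
    lam <- runif(1, 0.05, 0.8) * lambdaMax(X, y, standardize = FALSE)
    fit <- fitLassoPath(X, y, lambda = lam, standardize = FALSE,
                        tol = 1e-12)
    Xc <- scale(X, scale = FALSE); yc <- y - mean(y)
    r <- yc - Xc %*% coef(fit)[, 1]
    obj <- sum(r^2) / (2 * n) + lam * sum(abs(coef(fit)[, 1]))
    expect_equal(obj, lassoSignOracle(X, y, lam), tolerance = 1e-8)
  }
})

test_that("objective is non-increasing across coordinate-descent sweeps", {
  set.seed(101)
  X <- matrix(rnorm(60 * 20), 60, 20)
  y <- X[, 1] - 2 * X[, 2] + rnorm(60)
  fit <- fitLassoPath(X, y, nLambda = 25, trackObjective = TRUE)
  for (tr in fit@objectives) {
    if (length(tr) > 1)
      expect_true(all(diff(tr) <= 1e-12 * max(1, abs(tr[1]))))
  }
})

test_that("L1 norm is non-increasing in lambda along the path", {
  set.seed(103)
  X <- matrix(rnorm(80 * 30), 80, 30)
  y <- rnorm(80)
  fit <- fitLassoPath(X, y, nLambda = 40)
  l1 <- colSums(abs(coef(fit)))
  expect_true(all(diff(l1) >= -1e-8))  # lambda descends along the grid
})

test_that("smallest-lambda solution approaches OLS when p < n", {
  set.seed(107)
  X <- matrix(rnorm(100 * 10), 100, 10)
  y <- X %*% rnorm(10) + rnorm(100)
  fit <- fitLassoPath(X, y, nLambda = 60, lambdaMinRatio = 1e-6,
                      tol = 1e-10)
  bOLS <- unname(coef(lm(y ~ X))[-1])
  bHat <- coef(fit)[, 60]
  expect_lt(max(abs(bHat - bOLS)), 1e-3 * max(abs(bOLS)))
})

test_that("solution is invariant to positive predictor rescaling", {
  set.seed(109)
  X <- matrix(rnorm(50 * 8), 50, 8)
  y <- X[, 3] + rnorm(50)
  f1 <- fitLassoPath(X, y, nLambda = 20, tol = 1e-10)
  X2 <- X; X2[, 3] <- X[, 3] * 10
  f2 <- fitLassoPath(X2, y, nLambda = 20, tol = 1e-10)
  expect_equal(lambdaGrid(f1), lambdaGrid(f2), tolerance = 1e-12)
  expect_equal(coef(f2)[3, ] * 10, coef(f1)[3, ], tolerance = 1e-6)
  expect_equal(coef(f2)[-3, ], coef(f1)[-3, ], tolerance = 1e-6)
})

test_that("KKT certification: converged fits pass, truncated fits fail", {
  set.seed(113)
  n <- 50; p <- 30
  Z <- matrix(rnorm(n * p), n, p)
  X <- Z + 2 * matrix(rnorm(n), n, p)        # strongly correlated design
  y <- X %*% c(rep(1.5, 4), rep(0, p - 4)) + rnorm(n)
  fit <- fitLassoPath(X, y, nLambda = 20, tol = 1e-10)
  for (l in c(1, 10, 20))
    expect_equal(kktViolations(fit, X, y, l, kktTol = 1e-6), 0)
  # a single sweep cannot solve the correlated design at small lambda
  expect_warning(
    fitTrunc <- fitLassoPath(X, y, lambda = lambdaGrid(fit)[20],
                             maxIter = 1),
    "did not converge")
  expect_false(all(fitTrunc@converged))
  expect_gt(kktViolations(fitTrunc, X, y, 1, kktTol = 1e-6), 0)
})

test_that("strong-rule screening reproduces the unscreened path exactly", {
  set.seed(127)
  X <- matrix(rnorm(80 * 200), 80, 200)
  y <- X[, 5] - 0.8 * X[, 50] + rnorm(80)
  f1 <- fitLassoPath(X, y, nLambda = 30, tol = 1e-9)
  f2 <- fitLassoPath(X, y, nLambda = 30, tol = 1e-9, screen = TRUE)
  expect_equal(coef(f1), coef(f2), tolerance = 1e-10)
  expect_equal(f1@intercept, f2@intercept, tolerance = 1e-10)
})

test_that("missing predictors are mean-imputed before fitting", {
  set.seed(131)
  X <- matrix(rbinom(60 * 10, 2, 0.4), 60, 10)
  y <- X[, 2] + rnorm(60)
  Xna <- X; Xna[cbind(sample(60, 8), sample(10, 8, TRUE))] <- NA
  Ximp <- Xna
  for (j in 1:10) Ximp[is.na(Ximp[, j]), j] <- mean(Ximp[, j], na.rm = TRUE)
  f1 <- fitLassoPath(Xna, y, nLambda = 15)
  f2 <- fitLassoPath(Ximp, y, nLambda = 15)
  expect_equal(coef(f1), coef(f2), tolerance = 1e-12)
})

test_that("predictions are exact linear scores at the chosen lambda", {
  set.seed(137)
  X <- matrix(rnorm(40 * 6), 40, 6)
  y <- X[, 1] + rnorm(40)
  fit <- fitLassoPath(X, y, nLambda = 10)
  # lambda_max model predicts the constant ybar
  expect_equal(predict(fit, X, 1), rep(mean(y), 40))
  # permuting sample order permutes predictions identically
  perm <- sample(40)
  expect_equal(predict(fit, X[perm, ], 10), predict(fit, X, 10)[perm])
  # near-zero lambda prediction approaches the OLS fit
  fit2 <- fitLassoPath(X, y, nLambda = 40, lambdaMinRatio = 1e-6,
                       tol = 1e-10)
  expect_equal(predict(fit2, X, 40), unname(fitted(lm(y ~ X))),
               tolerance = 1e-4)
  expect_error(predict(fit, X[, 1:3], 1), "columns")
  expect_error(predict(fit, X, 11), "out of range")
})

test_that("unscaled-RSS objective scaling yields the same minimizer family", {
  set.seed(139)
  X <- matrix(rnorm(50 * 5), 50, 5)
  y <- X[, 1] + rnorm(50)
  n <- 50
  lamHalf <- 0.3 * lambdaMax(X, y)
  f1 <- fitLassoPath(X, y, lambda = lamHalf, tol = 1e-11)
  f2 <- fitLassoPath(X, y, lambda = lamHalf * 2 * n, tol = 1e-11,
                     objectiveScaling = "rss")
  expect_equal(coef(f1), coef(f2), tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(kktViolations(f2, X, y, 1), 0)
})

test_that("coefficient paths agree with an independent reference solver", {
  set.seed(149)
  X <- matrix(rnorm(100 * 50), 100, 50)
  y <- X[, 10] - 1.2 * X[, 20] + rnorm(100)
  fit <- fitLassoPath(X, y, nLambda = 30, tol = 1e-10)
  gl <- glmnet::glmnet(X, y, lambda = lambdaGrid(fit), standardize = TRUE,
                       thresh = 1e-14)
  expect_equal(coef(fit), as.matrix(gl$beta), tolerance = 1e-5,
               ignore_attr = TRUE)
  expect_equal(fit@intercept, unname(gl$a0), tolerance = 1e-5)
})
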