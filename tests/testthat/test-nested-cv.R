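test_that("fold assignment partitions with near-equal sizes", {
  f <- makeFolds(10, 10, seed = 1)
  expect_setequal(f, 1:10)                       # ten singletons
  f2 <- makeFolds(23, 10, seed = 2)
  sizes <- tabulate(f2, 10)
  expect_equal(sum(sizes), 23)
  expect_lte(diff(range(sizes)), 1)              # sizes 2 or 3
  expect_identical(makeFolds(100, 5, seed = 7), makeFolds(100, 5, seed = 7))
  expect_false(identical(makeFolds(100, 5, seed = 7),
                         makeFolds(100, 5, seed = 8)))
  expect_error(makeFolds(5, 6), "exceed")
  expect_error(makeFolds(5, 1), "at least 2")
})

test_that("inner selection returns the grid point minimizing mean MSE", {
  set.seed(151)
  X <- matrix(rnorm(120 * 10), 120, 10)
  y <- 2 * X[, 1] + rnorm(120)
  lmax <- lambdaMax(X, y)
  # a grid of length 1 is returned as-is
  one <- innerSelectLambda(X, y, kInner = 3, lambda = 0.5 * lmax, seed = 3)
  expect_equal(one$lambda, 0.5 * lmax)
  expect_equal(one$index, 1L)
  grid <- exp(seq(log(lmax), log(lmax * 1e-4), length.out = 30))
  sel <- innerSelectLambda(X, y, kInner = 5, lambda = grid, seed = 3)
  expect_equal(sel$lambda, grid[which.min(sel$meanMSE)])
})

test_that("pure noise selects heavy penalties, strong signal light ones", {
  noiseIdx <- signalIdx <- integer()
  for (seed in 1:10) {
    set.seed(seed)
    Xn <- matrix(rnorm(60 * 30), 60, 30)
    yn <- rnorm(60)
    gridN <- exp(seq(log(lambdaMax(Xn, yn)),
                     log(lambdaMax(Xn, yn) * 0.01), length.out = 30))
    noiseIdx <- c(noiseIdx,
                  innerSelectLambda(Xn, yn, 3, gridN, seed = seed)$index)
    Xs <- matrix(rnorm(400 * 5), 400, 5)
    ys <- Xs %*% c(2, -1.5, 1, 0.8, -2) + rnorm(400)
    gridS <- exp(seq(log(lambdaMax(Xs, ys)),
                     log(lambdaMax(Xs, ys) * 1e-4), length.out = 30))
    signalIdx <- c(signalIdx,
                   innerSelectLambda(Xs, ys, 3, gridS, seed = seed)$index)
  }
  # null model wins: selected at or near lambda_max
  expect_lte(median(noiseIdx), 5)
  # strong signal with n >> p: selected near the grid minimum
  expect_gte(median(signalIdx), 25)
})

test_that("evaluation metrics match hand arithmetic and flag degeneracy", {
  ev <- evaluatePredictions(c(0, 1, 2, 3), c(0.1, 0.8, 2.2, 2.9))
  # cov = 4.9/3, var(obs) = 5/3, var(pred) = 4.9/3
  expect_equal(unname(ev$metrics["slope"]), 4.9 / 5, tolerance = 1e-12)
  expect_equal(unname(ev$metrics["pearsonR"]), sqrt(4.9 / 5),
               tolerance = 1e-12)
  expect_equal(unname(ev$metrics["mse"]), 0.025, tolerance = 1e-12)
  y <- rnorm(10)
  perfect <- evaluatePredictions(y, y)
  expect_equal(unname(perfect$metrics), c(1, 0, 1))
  const <- evaluatePredictions(y, rep(0.7, 10))
  expect_true(const$degenerate)
  expect_equal(unname(const$metrics["slope"]), 0)
  expect_equal(unname(const$metrics["pearsonR"]), 0)
  # MSE of a constant predictor: Var(y)*(n-1)/n + bias^2
  expect_equal(unname(const$metrics["mse"]),
               var(y) * 9 / 10 + (mean(y) - 0.7)^2, tolerance = 1e-12)
  expect_error(evaluatePredictions(1:4, 1:3), "lengths differ")
  expect_error(evaluatePredictions(1:2, 1:2), "at least 3")
})

test_that("nested CV pools each sample exactly once without leakage", {
  set.seed(157)
  X <- matrix(rbinom(150 * 40, 2, 0.3), 150, 40)
  y <- -0.8 * X[, 11] + rnorm(150)
  rep <- nestedCV(X, y, kOuter = 5, kInner = 3, nLambda = 25,
                  trackedSnps = 11, seed = 11)
  expect_equal(sort(unique(rep@folds)), 1:5)
  expect_false(anyNA(rep@predictions))           # complete cover
  expect_equal(length(rep@predictions), 150)
  expect_equal(rep@lambdaRange, range(rep@selectedLambda))
  expect_equal(rep@observed, y)
  # rerun determinism
  rep2 <- nestedCV(X, y, kOuter = 5, kInner = 3, nLambda = 25,
                   trackedSnps = 11, seed = 11)
  expect_identical(rep@predictions, rep2@predictions)
  # a strong causal SNP is picked up in every fold
  expect_true(all(rep@trackedCoefs < 0))
  expect_equal(rep@trackedMean,
               mean(rep@trackedCoefs), ignore_attr = TRUE)
  expect_equal(rep@trackedSD, sd(rep@trackedCoefs), ignore_attr = TRUE)
})

test_that("null heritability gives pooled r centered on zero", {
  rs <- vapply(1:8, function(seed) {
    set.seed(seed * 7)
    X <- matrix(rbinom(120 * 60, 2, 0.3), 120, 60)
    y <- rnorm(120)                              # h2 = 0
    rep <- nestedCV(X, y, kOuter = 5, kInner = 3, nLambda = 20,
                    seed = seed)
    unname(cvMetrics(rep)["pearsonR"])
  }, 0)
  expect_lt(abs(mean(rs)), 0.12)                 # no optimism
  expect_true(all(abs(rs) < 0.3))
})

test_that("degenerate smoke case runs end-to-end", {
  set.seed(163)
  X <- matrix(rbinom(4 * 3, 2, 0.5), 4, 3)
  y <- rnorm(4)
  rep <- tryCatch(
    nestedCV(X, y, kOuter = 2, kInner = 2, nLambda = 5, seed = 1),
    error = function(e) e)
  expect_s4_class(rep, "CVReport")
})

test_that("CVReport export writes consistent JSON and TSVs", {
  set.seed(167)
  X <- matrix(rbinom(60 * 10, 2, 0.3), 60, 10)
  y <- X[, 3] + rnorm(60)
  rep <- nestedCV(X, y, kOuter = 3, kInner = 2, nLambda = 10,
                  trackedSnps = 3, seed = 5)
  prefix <- tempfile("cv")
  writeCVReport(rep, prefix)
  js <- jsonlite::read_json(paste0(prefix, ".json"))
  expect_equal(js$metrics$pearsonR, unname(cvMetrics(rep)["pearsonR"]),
               tolerance = 1e-12)
  preds <- read.delim(paste0(prefix, "_predictions.tsv"))
  expect_equal(nrow(preds), 60)
  expect_equal(preds$predicted, unname(rep@predictions),
               tolerance = 1e-10)
})
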