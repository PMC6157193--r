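test_that("baseline/follow-up means use natural logs with fallback", {
  v <- data.frame(sampleId = c("a", "b", "c", "d"),
                  tg1 = c(exp(2), NA, exp(1), NA),
                  tg2 = c(exp(2), exp(3), exp(2), NA),
                  tg3 = c(exp(1), exp(1), NA, exp(1)),
                  tg4 = c(exp(3), exp(1), NA, exp(1)))
  out <- buildBaselineFollowup(v)
  m <- out$measures
  expect_equal(m$baseline[m$sampleId == "a"], 2)     # mean of logs
  expect_equal(m$baseline[m$sampleId == "b"], 3)     # single-visit fallback
  expect_equal(m$followup[m$sampleId == "a"], 2)     # (1 + 3)/2
  # c misses both follow-up visits, d both baseline visits
  expect_setequal(out$dropped$sampleId, c("c", "d"))
  expect_equal(out$dropped$reason[out$dropped$sampleId == "c"],
               "no follow-up visits")
  bad <- v; bad$tg1[1] <- -1
  expect_error(buildBaselineFollowup(bad), "positive")
})

test_that("PC scores are unit-variance, orthogonal, and duplicate-safe", {
  g <- randomGeno(60, 120, seed = 5)
  d <- dosages(g)
  d[2, ] <- d[1, ]                      # duplicated individual
  g2 <- GenotypeMatrix(d)
  pcs <- computePCs(g2, k = 5)
  expect_equal(pcs[1, ], pcs[2, ], tolerance = 1e-8)
  expect_equal(apply(pcs, 2, sd), rep(1, 5), ignore_attr = TRUE)
  cp <- crossprod(pcs)
  expect_lt(max(abs(cp[upper.tri(cp)])), 1e-6)       # diagonal cross-product
  expect_error(computePCs(g2, k = 100), "k exceeds")
})

test_that("PC1 separates two simulated subpopulations", {
  set.seed(17)
  n <- 100; p <- 200
  popA <- matrix(rbinom(n * p, 2, rep(runif(p, 0.05, 0.2), each = n)), n, p)
  popB <- matrix(rbinom(n * p, 2, rep(runif(p, 0.3, 0.5), each = n)), n, p)
  g <- GenotypeMatrix(rbind(popA, popB))
  pcs <- computePCs(g, k = 2)
  grp <- rep(c(0, 1), each = n)
  expect_gt(abs(cor(pcs[, 1], grp)), 0.9)
})

test_that("adjustment returns standardized residuals orthogonal to design", {
  set.seed(23)
  n <- 200
  g <- randomGeno(n, 50, seed = 3)
  cov <- data.frame(sampleId = sampleIds(g), age = runif(n, 30, 70),
                    center = sample(1:2, n, TRUE),
                    smoking = rbinom(n, 1, 0.3))
  meas <- data.frame(sampleId = sampleIds(g),
                     baseline = rnorm(n, 4.5, 0.5), followup = 0)
  meas$followup <- 0.8 * meas$baseline + 0.01 * cov$age +
    0.2 * (cov$center == 2) + rnorm(n, 0, 0.3)
  pcs <- computePCs(g, k = 4)
  out <- adjustPhenotype(meas, cov, pcs)
  ph <- out$phenotype
  expect_equal(mean(ph), 0, tolerance = 1e-10)
  expect_equal(sd(ph), 1, tolerance = 1e-10)
  mm <- model.matrix(~ baseline + age + factor(center) + smoking,
                     cbind(meas, cov))
  orth <- crossprod(scale(mm[, -1]), ph) / n
  expect_lt(max(abs(orth)), 1e-8)
  expect_lt(max(abs(crossprod(scale(pcs), ph) / n)), 1e-8)
})

test_that("adjustment recovers injected noise and flags rank deficiency", {
  set.seed(29)
  n <- 5000
  cov <- data.frame(sampleId = sprintf("s%04d", 1:n),
                    age = runif(n, 30, 70),
                    center = sample(1:2, n, TRUE),
                    smoking = rbinom(n, 1, 0.3))
  noise <- rnorm(n)
  meas <- data.frame(sampleId = cov$sampleId, baseline = rnorm(n, 4.5, 0.5))
  meas$followup <- 1.5 + 0.9 * meas$baseline + 0.02 * cov$age +
    0.3 * (cov$center == 2) - 0.1 * cov$smoking + noise
  out <- adjustPhenotype(meas, cov, pcs = NULL)
  expect_gt(cor(out$phenotype, noise), 0.999)
  covBad <- cov; covBad$center <- 1
  expect_error(adjustPhenotype(meas, covBad, NULL),
               "rank-deficient|contrasts")
  # incomplete covariates are dropped and recorded
  covNA <- cov; covNA$age[c(3, 9)] <- NA
  outNA <- adjustPhenotype(meas, covNA, NULL)
  expect_setequal(outNA$dropped$sampleId, cov$sampleId[c(3, 9)])
  expect_equal(length(outNA$phenotype) + nrow(outNA$dropped), n)
})

test_that("Q-Q diagnostic and inflation factor behave correctly", {
  m <- 2000
  pu <- (seq_len(m) - 0.5) / m          # exactly uniform grid
  qq <- qqDiagnostic(pu)
  expect_equal(qq$table$observed, qq$table$expected, tolerance = 1e-12)
  expect_equal(qq$lambdaGC, 1, tolerance = 1e-2)
  qq2 <- qqDiagnostic(pu / 2)           # halving p inflates
  expect_gt(qq2$lambdaGC, 1)
  expect_error(qqDiagnostic(numeric()), "empty")
  expect_error(qqDiagnostic(c(0.5, 0)), "p-values")
  # null simulation: lambda_GC within [0.95, 1.05] at m = 1e4
  set.seed(31)
  pn <- runif(1e4)
  expect_gt(qqDiagnostic(pn)$lambdaGC, 0.95)
  expect_lt(qqDiagnostic(pn)$lambdaGC, 1.05)
})

test_that("null visit pipeline yields uniform association p-values", {
  g <- simulateGenotypes(300, 5000, seed = 37)
  v <- simulateVisits(g, 1, beta = 0, seed = 38)   # zero causal effect
  bf <- buildBaselineFollowup(v)
  pcs <- computePCs(g, k = 20)
  adj <- adjustPhenotype(bf$measures,
                         v[, c("sampleId", "age", "center", "smoking")],
                         pcs)
  keep <- match(names(adj$phenotype), sampleIds(g))
  assoc <- singleSnpRegression(g[keep, ], adj$phenotype)
  ks <- suppressWarnings(ks.test(assoc$p, "punif"))
  expect_gt(ks$p.value, 0.01)
  # dropped-sample accounting
  expect_equal(length(adj$phenotype) + nrow(adj$dropped) +
                 nrow(bf$dropped), 300)
})
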