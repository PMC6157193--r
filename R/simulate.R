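# Synthetic genotype / phenotype generators.
#
# Genotypes: block-structured allele-copying model.  SNPs are grouped into
# blocks of ldBlockSize consecutive columns; the first SNP of each block
# (the anchor) is drawn as Binomial(2, maf) per individual with the block's
# maf ~ Uniform(mafLow, mafHigh); each allele of a non-anchor SNP copies
# the corresponding anchor allele with probability ldCopyProb and is a
# fresh Bernoulli(maf) draw otherwise, so the expected allelic correlation
# with the anchor is ldCopyProb and the expected dosage r^2 is
# ldCopyProb^2.  ldBlockSize = 1 gives independent SNPs in Hardy-Weinberg
# proportions.
#
# Phenotypes: y_i = beta * g_i + e_i with e_i ~ N(0, sigma^2) and sigma^2
# chosen by noiseVarianceForH2() so that the modeled genetic variance is
# the fraction h2 of the total.

# evaluate expr with a locally-seeded RNG, restoring the caller's stream
.withSeed <- function(seed, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
  if (!exists(".Random.seed", globalenv(), inherits = FALSE)) set.seed(NULL)
  old <- get(".Random.seed", globalenv())
  on.exit(assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  eval.parent(substitute(expr))
}

#' Simulate SNP genotypes with optional LD blocks
#'
#' Draws an n x p dosage matrix under the allele-copying block model (see
#' Details).  With \code{ldBlockSize = 1} all SNPs are independent draws
#' from Binomial(2, maf) with per-SNP maf uniform on
#' \code{[mafLow, mafHigh]}; with larger blocks, within-block allelic
#' correlation equals \code{ldCopyProb}, giving direct control of the
#' dosage r-squared (\code{ldCopyProb^2} in expectation) used by the
#' clumping stage.  SNP metadata places consecutive SNPs 10 kb apart.
#'
#' @param nIndividuals,nSnps matrix dimensions (positive)
#' @param mafLow,mafHigh allele-frequency bounds, in (0, 0.5]
#' @param ldBlockSize SNPs per LD block (1 = independent SNPs); the final
#'   block is truncated at \code{nSnps}
#' @param ldCopyProb within-block allele-copy probability, in [0, 1]
#' @param missingRate per-entry missingness probability, in [0, 1)
#' @param nChromosomes number of chromosomes the SNPs are split across
#' @param seed integer seed; fully determines the output
#' @return a \linkS4class{GenotypeMatrix}
#' @examples
#' g <- simulateGenotypes(100, 20, ldBlockSize = 5, ldCopyProb = 0.9,
#'                        seed = 7)
#' cor(dosages(g)[, 1], dosages(g)[, 2])^2  # high within-block r^2
#' @export
simulateGenotypes <- function(nIndividuals, nSnps, mafLow = 0.05,
                              mafHigh = 0.5, ldBlockSize = 1,
                              ldCopyProb = 0, missingRate = 0,
                              nChromosomes = 1, seed = NULL) {
  stopifnot(nIndividuals >= 1, nSnps >= 1, ldBlockSize >= 1,
            nChromosomes >= 1)
  if (mafLow <= 0 || mafHigh > 0.5 || mafLow > mafHigh)
    stop("maf bounds must satisfy 0 < mafLow <= mafHigh <= 0.5")
  if (ldCopyProb < 0 || ldCopyProb > 1)
    stop("ldCopyProb must be in [0, 1]")
  if (missingRate < 0 || missingRate >= 1)
    stop("missingRate must be in [0, 1)")
  n <- as.integer(nIndividuals); p <- as.integer(nSnps)
  bs <- as.integer(ldBlockSize)
  .withSeed(seed, {
    nb <- ceiling(p / bs)
    mafB <- runif(nb, mafLow, mafHigh)
    d <- matrix(0, n, p)
    # generate in batches of whole blocks so temporaries stay small even
    # for cohort-scale matrices
    batchBlocks <- max(1L, ceiling(4e6 / (n * bs)))
    for (bStart in seq(1L, nb, by = batchBlocks)) {
      kb <- bStart:min(bStart + batchBlocks - 1L, nb)
      mafK <- rep(mafB[kb], each = n)
      # anchor alleles (two per individual per block)
      # Bernoulli alleles by inversion (exact, and much faster than
      # rbinom at cohort scale)
      a1 <- matrix(as.integer(runif(n * length(kb)) < mafK), n)
      a2 <- matrix(as.integer(runif(n * length(kb)) < mafK), n)
      anchorCol <- (kb - 1L) * bs + 1L
      d[, anchorCol] <- a1 + a2
      if (bs > 1L) {
        for (off in seq_len(bs - 1L)) {
          cols <- anchorCol + off
          keep <- cols <= p
          if (!any(keep)) break
          cols <- cols[keep]; kk <- which(keep)
          mafO <- rep(mafB[kb[kk]], each = n)
          cp <- matrix(runif(n * length(kk)) < ldCopyProb, n)
          b1 <- ifelse(cp, a1[, kk, drop = FALSE],
                       matrix(as.integer(runif(n * length(kk)) < mafO), n))
          cp <- matrix(runif(n * length(kk)) < ldCopyProb, n)
          b2 <- ifelse(cp, a2[, kk, drop = FALSE],
                       matrix(as.integer(runif(n * length(kk)) < mafO), n))
          d[, cols] <- b1 + b2
        }
      }
      if (missingRate > 0) {
        first <- (kb[1] - 1L) * bs + 1L
        last <- min(kb[length(kb)] * bs, p)
        span <- (last - first + 1L) * n
        idx <- which(runif(span) < missingRate)
        if (length(idx)) d[(first - 1L) * n + idx] <- NA
      }
    }
    chrom <- rep(seq_len(nChromosomes), each = ceiling(p / nChromosomes),
                 length.out = p)
    withinChrom <- stats::ave(seq_len(p), chrom, FUN = seq_along)
    snpInfo <- data.frame(id = sprintf("snp_%05d", seq_len(p)),
                          chrom = as.character(chrom),
                          pos = 10000L * withinChrom,
                          a1 = "A", a2 = "B", stringsAsFactors = FALSE)
    GenotypeMatrix(d, snpInfo, sprintf("S%05d", seq_len(n)))
  })
}

#' Noise variance inducing a target heritability
#'
#' For a causal model y = beta * g + e with g ~ Binomial(2, maf) in
#' Hardy-Weinberg proportions, the genetic variance is
#' \code{beta^2 * 2 * maf * (1 - maf)}; this returns the environmental
#' variance \code{sigma^2 = betaVar * (1 - h2) / h2} so that the simulated
#' phenotype has heritability \code{h2} in expectation.  For several
#' (independent) causal SNPs pass vectors; the genetic variances add.
#'
#' @param beta effect size(s) on the raw 0/1/2 dosage scale; must be
#'   nonzero when \code{h2 > 0}
#' @param maf causal allele frequency(ies), each in (0, 1)
#' @param h2 target heritability, in (0, 1)
#' @return the noise variance sigma^2 (scalar)
#' @examples
#' noiseVarianceForH2(-0.44, 0.3, 0.05)  # ~1.545
#' @export
noiseVarianceForH2 <- function(beta, maf, h2) {
  stopifnot(length(beta) == length(maf))
  if (!is.finite(h2) || h2 <= 0 || h2 >= 1)
    stop("h2 must lie strictly between 0 and 1")
  if (any(maf <= 0 | maf >= 1))
    stop("maf must lie strictly between 0 and 1")
  if (any(beta == 0))
    stop("beta = 0 cannot induce a positive heritability")
  varGen <- sum(beta^2 * 2 * maf * (1 - maf))
  varGen * (1 - h2) / h2
}

#' Simulate a quantitative phenotype from causal SNPs
#'
#' Generates y = sum_j beta_j * g_j + e with Gaussian noise whose variance
#' is set by \code{\link{noiseVarianceForH2}} at each causal column's
#' EMPIRICAL allele frequency, so the realized heritability matches
#' \code{h2} up to sampling error.  Missing causal dosages are mean-imputed
#' for the genetic value.
#'
#' @param G a \linkS4class{GenotypeMatrix}
#' @param snpIndex causal column index (or vector of indices)
#' @param beta effect size(s), raw dosage scale
#' @param h2 target heritability in (0, 1)
#' @param seed integer seed for the noise draw
#' @param noiseVar optional override of the noise variance (e.g. 0 for the
#'   noiseless h2 -> 1 limit); bypasses the h2 computation
#' @return list with \code{phenotype} (numeric, named by sample id),
#'   \code{genetic} (the noiseless genetic values), and \code{noiseVar}
#' @examples
#' g <- simulateGenotypes(500, 10, seed = 1)
#' ph <- simulatePhenotype(g, snpIndex = 3, beta = -0.44, h2 = 0.05,
#'                         seed = 2)
#' cor(ph$phenotype, ph$genetic)  # near sqrt(0.05)
#' @export
simulatePhenotype <- function(G, snpIndex, beta, h2, seed = NULL,
                              noiseVar = NULL) {
  stopifnot(is(G, "GenotypeMatrix"), length(snpIndex) == length(beta))
  if (any(snpIndex < 1 | snpIndex > nSnps(G)))
    stop("causal snpIndex out of range")
  X <- dosages(G)[, snpIndex, drop = FALSE]
  f <- colMeans(X, na.rm = TRUE) / 2
  if (any(!is.finite(f)) || any(f <= 0 | f >= 1) ||
      any(apply(X, 2, function(z) var(z[!is.na(z)])) == 0))
    stop("causal column is monomorphic")
  for (j in seq_len(ncol(X))) {
    miss <- is.na(X[, j])
    if (any(miss)) X[miss, j] <- mean(X[, j], na.rm = TRUE)
  }
  if (is.null(noiseVar))
    noiseVar <- noiseVarianceForH2(beta, f, h2)
  genetic <- as.vector(X %*% beta)
  y <- .withSeed(seed,
                 genetic + rnorm(nSamples(G), 0, sqrt(noiseVar)))
  names(y) <- names(genetic) <- sampleIds(G)
  list(phenotype = y, genetic = genetic, noiseVar = noiseVar)
}

#' Simulate a 4-visit triglyceride-style raw phenotype table
#'
#' Emulates the repeated-measures design behind the phenotype-construction
#' stage: two pre-treatment visits and two post-treatment visits of a
#' positive, log-normally distributed trait (triglycerides), with age,
#' center and smoking covariates acting on the log scale, a treatment
#' shift between baseline and follow-up, and a causal-SNP effect injected
#' into the follow-up log values.  Per-visit missingness is applied
#' independently, exercising the single-visit fallback downstream.
#'
#' @param G a \linkS4class{GenotypeMatrix}
#' @param snpIndex,beta causal SNP column and its effect on follow-up
#'   log-TG (use \code{beta = 0} for a null run)
#' @param ageEffect,centerEffect,smokingEffect covariate effects on log-TG
#'   (per year centered at 50; per center level; smokers vs not)
#' @param baselineMean,baselineSD mean and between-subject SD of baseline
#'   log-TG
#' @param treatmentShift additive change in log-TG after treatment
#'   (negative for a lipid-lowering drug)
#' @param visitNoiseSD within-subject per-visit SD (log scale), >= 0
#' @param missingRate per-visit missingness probability, in [0, 1)
#' @param nCenters number of study centers (categorical covariate levels)
#' @param seed integer seed
#' @return data.frame with columns \code{sampleId}, \code{tg1}-\code{tg4}
#'   (raw scale, NA = missed visit), \code{age}, \code{center},
#'   \code{smoking}
#' @export
simulateVisits <- function(G, snpIndex, beta, ageEffect = 0.005,
                           centerEffect = 0.1, smokingEffect = 0.15,
                           baselineMean = log(100), baselineSD = 0.5,
                           treatmentShift = -0.25, visitNoiseSD = 0.1,
                           missingRate = 0.05, nCenters = 2, seed = NULL) {
  stopifnot(is(G, "GenotypeMatrix"), baselineSD >= 0, visitNoiseSD >= 0,
            nCenters >= 1)
  if (missingRate < 0 || missingRate >= 1)
    stop("missingRate must be in [0, 1)")
  n <- nSamples(G)
  g <- dosages(G)[, snpIndex]
  if (anyNA(g)) g[is.na(g)] <- mean(g, na.rm = TRUE)
  .withSeed(seed, {
    age <- round(runif(n, 25, 75))
    center <- sample(seq_len(nCenters), n, replace = TRUE)
    smoking <- rbinom(n, 1, 0.25)
    logBase <- baselineMean + ageEffect * (age - 50) +
      centerEffect * (center - 1) + smokingEffect * smoking +
      rnorm(n, 0, baselineSD)
    logFollow <- logBase + treatmentShift + beta * g
    visits <- cbind(
      logBase + rnorm(n, 0, visitNoiseSD),
      logBase + rnorm(n, 0, visitNoiseSD),
      logFollow + rnorm(n, 0, visitNoiseSD),
      logFollow + rnorm(n, 0, visitNoiseSD))
    tg <- exp(visits)
    if (missingRate > 0)
      tg[matrix(runif(4 * n) < missingRate, n, 4)] <- NA
    data.frame(sampleId = sampleIds(G),
               tg1 = tg[, 1], tg2 = tg[, 2], tg3 = tg[, 3], tg4 = tg[, 4],
               age = age, center = factor(center), smoking = smoking,
               stringsAsFactors = FALSE)
  })
}
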