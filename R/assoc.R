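# Per-SNP simple linear regression of the analysis phenotype on dosage.
# The phenotype is already covariate-adjusted (two-stage residual
# approach), so the model is y ~ dosage with no further covariates.

#' Single-SNP association scan
#'
#' For each SNP, OLS of the phenotype on dosage over that SNP's complete
#' cases: slope \code{sum((x - xbar)(y - ybar)) / sum((x - xbar)^2)},
#' standard error from the residual variance on n - 2 df, two-sided p from
#' the t distribution.  Monomorphic SNPs are flagged with beta = 0,
#' p = 1.  Computed in chunks with vectorized cross-products, so a scan of
#' tens of thousands of SNPs takes seconds.
#'
#' @param G a \linkS4class{GenotypeMatrix}
#' @param y numeric phenotype, length \code{nSamples(G)}
#' @param chunkSize SNPs per vectorized block (memory/speed trade-off)
#' @return data.frame aligned with the SNP columns: id, chrom, pos, beta,
#'   se, tstat, p, nUsed, monomorphic
#' @examples
#' g <- simulateGenotypes(300, 20, seed = 1)
#' ph <- simulatePhenotype(g, 5, beta = -0.44, h2 = 0.3, seed = 2)
#' head(singleSnpRegression(g, ph$phenotype))
#' @export
singleSnpRegression <- function(G, y, chunkSize = 2000L) {
  stopifnot(is(G, "GenotypeMatrix"), length(y) == nSamples(G))
  d <- dosages(G)
  n <- nrow(d); p <- ncol(d)
  if (n < 3) stop("need at least 3 samples")
  beta <- se <- tstat <- pval <- numeric(p)
  nUsed <- integer(p)
  mono <- logical(p)
  for (start in seq(1L, p, by = chunkSize)) {
    jj <- start:min(start + chunkSize - 1L, p)
    X <- d[, jj, drop = FALSE]
    if (anyNA(X)) {
      M <- !is.na(X)
      Xz <- X; Xz[!M] <- 0
      nj <- colSums(M)
      sx <- colSums(Xz)
      sxx <- colSums(Xz * Xz)
      sy <- as.vector(crossprod(M, y))
      syy <- as.vector(crossprod(M, y * y))
      sxy <- as.vector(crossprod(Xz, y))
    } else {
      nj <- rep(n, length(jj))
      sx <- colSums(X)
      sxx <- colSums(X * X)
      sy <- rep(sum(y), length(jj))
      syy <- rep(sum(y * y), length(jj))
      sxy <- as.vector(crossprod(X, y))
    }
    sxxC <- sxx - sx^2 / nj
    sxyC <- sxy - sx * sy / nj
    syyC <- syy - sy^2 / nj
    isMono <- sxxC <= 1e-12 | nj < 3
    b <- ifelse(isMono, 0, sxyC / sxxC)
    rss <- pmax(syyC - b * sxyC, 0)
    s2 <- rss / (nj - 2)
    serr <- ifelse(isMono, NA_real_, sqrt(s2 / sxxC))
    tj <- ifelse(isMono, 0, b / serr)
    tj[!isMono & serr == 0] <- sign(b[!isMono & serr == 0]) * Inf
    pj <- ifelse(isMono, 1, 2 * pt(abs(tj), df = nj - 2,
                                   lower.tail = FALSE))
    pj <- pmax(pj, .Machine$double.xmin)
    beta[jj] <- b; se[jj] <- serr; tstat[jj] <- tj; pval[jj] <- pj
    nUsed[jj] <- nj; mono[jj] <- isMono
  }
  si <- snpInfo(G)
  data.frame(id = si$id, chrom = si$chrom, pos = si$pos, beta = beta,
             se = se, tstat = tstat, p = pval, nUsed = nUsed,
             monomorphic = mono, stringsAsFactors = FALSE)
}

#' Per-fold OLS estimate of a single SNP's effect
#'
#' Fits the single-SNP regression on each outer-training set (all samples
#' outside the fold) and summarizes the k slopes; the unpenalized
#' comparator for the LASSO shrinkage analysis.
#'
#' @param G a \linkS4class{GenotypeMatrix}
#' @param y phenotype vector
#' @param snpId SNP identifier (a \code{snpInfo(G)$id} value)
#' @param folds integer fold labels per sample (see
#'   \code{\link{makeFolds}})
#' @return list with \code{estimates} (per-fold slopes), \code{mean} and
#'   \code{sd} (n-1 denominator; 0 when k = 1)
#' @export
perFoldOlsEstimate <- function(G, y, snpId, folds) {
  stopifnot(is(G, "GenotypeMatrix"), length(y) == nSamples(G),
            length(folds) == nSamples(G))
  j <- match(snpId, snpInfo(G)$id)
  if (is.na(j)) stop("SNP not found: ", snpId)
  x <- dosages(G)[, j]
  k <- max(folds)
  est <- vapply(seq_len(k), function(f) {
    tr <- folds != f & !is.na(x)
    xt <- x[tr]; yt <- y[tr]
    sxx <- sum((xt - mean(xt))^2)
    if (sxx == 0) return(0)
    sum((xt - mean(xt)) * (yt - mean(yt))) / sxx
  }, 0)
  list(estimates = est, mean = mean(est),
       sd = if (k > 1) sd(est) else 0)
}

#' Manhattan-ready association table
#'
#' Adds a cumulative genome coordinate (chromosomes laid end to end) and
#' the genome-wide significance level for plotting.
#'
#' @param assoc association table from \code{\link{singleSnpRegression}}
#' @param significance genome-wide line (default 5e-8, the GWAS
#'   convention)
#' @return the table with columns \code{cumPos} and \code{genomewide}
#'   added
#' @export
manhattanTable <- function(assoc, significance = 5e-8) {
  chroms <- unique(assoc$chrom)
  offset <- 0
  cum <- numeric(nrow(assoc))
  for (ch in chroms) {
    idx <- assoc$chrom == ch
    cum[idx] <- assoc$pos[idx] + offset
    offset <- offset + max(assoc$pos[idx])
  }
  assoc$cumPos <- cum
  assoc$genomewide <- significance
  assoc
}
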