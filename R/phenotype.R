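# Analysis-phenotype construction: natural-log visit means with
# single-visit fallback, genotype principal components, OLS covariate
# adjustment, standardized residuals, and Q-Q / genomic-inflation
# diagnostics.

#' Baseline and follow-up measures from a 4-visit table
#'
#' Works on the natural-log scale: baseline is the mean of log visit 1 and
#' log visit 2, follow-up the mean of log visits 3 and 4.  When one visit
#' of a pair is missing the single available visit is used; samples
#' missing both visits of either pair are dropped and recorded.
#'
#' @param visits data.frame with columns \code{sampleId} and
#'   \code{tg1}-\code{tg4} (positive raw-scale values, NA = missing), as
#'   from \code{\link{simulateVisits}}
#' @return list with \code{measures} (data.frame sampleId, baseline,
#'   followup) and \code{dropped} (data.frame sampleId, reason)
#' @examples
#' v <- data.frame(sampleId = "a", tg1 = NA, tg2 = exp(3),
#'                 tg3 = exp(1), tg4 = exp(3))
#' buildBaselineFollowup(v)$measures  # baseline 3 (fallback), followup 2
#' @export
buildBaselineFollowup <- function(visits) {
  need <- c("sampleId", paste0("tg", 1:4))
  stopifnot(all(need %in% names(visits)))
  tg <- as.matrix(visits[, paste0("tg", 1:4)])
  if (any(tg[!is.na(tg)] <= 0))
    stop("TG values must be positive")
  lt <- log(tg)
  baseline <- rowMeans(lt[, 1:2, drop = FALSE], na.rm = TRUE)
  followup <- rowMeans(lt[, 3:4, drop = FALSE], na.rm = TRUE)
  noBase <- !is.finite(baseline)
  noFollow <- !is.finite(followup)
  drop <- noBase | noFollow
  reason <- ifelse(noBase & noFollow, "no baseline or follow-up visits",
                   ifelse(noBase, "no baseline visits",
                          "no follow-up visits"))
  list(measures = data.frame(sampleId = visits$sampleId[!drop],
                             baseline = baseline[!drop],
                             followup = followup[!drop],
                             stringsAsFactors = FALSE),
       dropped = data.frame(sampleId = visits$sampleId[drop],
                            reason = reason[drop],
                            stringsAsFactors = FALSE))
}

#' Top genotype principal components
#'
#' Mean-imputes missing dosages per SNP, column-standardizes (dropping
#' monomorphic SNPs), and returns the top-k left singular directions as
#' scores scaled to unit variance.  Sign convention: the
#' largest-magnitude SNP loading of each component is positive.  Used to
#' adjust the phenotype for relatedness / population stratification.
#'
#' @param G a \linkS4class{GenotypeMatrix}
#' @param k number of components (default 20); must not exceed the rank of
#'   the standardized matrix
#' @return n x k matrix of PC scores (rownames = sample ids)
#' @export
computePCs <- function(G, k = 20) {
  stopifnot(is(G, "GenotypeMatrix"))
  X <- dosages(G)
  for (j in seq_len(ncol(X))) {
    miss <- is.na(X[, j])
    if (any(miss)) X[miss, j] <- mean(X[, j], na.rm = TRUE)
  }
  sds <- apply(X, 2, sd)
  X <- X[, sds > 0, drop = FALSE]
  X <- scale(X)
  n <- nrow(X)
  if (k > min(dim(X))) stop("k exceeds matrix dimensions")
  # eigen of the n x n Gram matrix: cheap for n << p
  K <- tcrossprod(X)
  eig <- eigen(K, symmetric = TRUE)
  posRank <- sum(eig$values > max(eig$values) * 1e-9)
  if (k > posRank)
    stop("k = ", k, " exceeds the rank (", posRank,
         ") of the standardized genotype matrix")
  U <- eig$vectors[, seq_len(k), drop = FALSE]
  scores <- apply(U, 2, function(u) u / sd(u))
  loadings <- crossprod(X, scores)          # p x k
  for (j in seq_len(k)) {
    top <- which.max(abs(loadings[, j]))
    if (loadings[top, j] < 0) scores[, j] <- -scores[, j]
  }
  dimnames(scores) <- list(sampleIds(G), paste0("PC", seq_len(k)))
  scores
}

#' Covariate- and PC-adjusted standardized phenotype
#'
#' Ordinary least squares of the follow-up measure on intercept, baseline
#' measure, age, center (dummy-coded), smoking and the genotype PCs; the
#' standardized residuals (mean 0, SD 1, n-1 denominator) are the final
#' analysis phenotype.  Complete cases only; incomplete samples are
#' dropped and recorded.  A rank-deficient design (e.g. a single-level
#' center) raises an error naming the offending column.
#'
#' @param measures data.frame (sampleId, baseline, followup), as from
#'   \code{\link{buildBaselineFollowup}}
#' @param covariates data.frame (sampleId, age, center, smoking)
#' @param pcs PC score matrix with rownames = sample ids (or NULL to skip)
#' @return list with \code{phenotype} (named numeric, standardized
#'   residuals) and \code{dropped} (data.frame sampleId, reason)
#' @export
adjustPhenotype <- function(measures, covariates, pcs = NULL) {
  stopifnot(all(c("sampleId", "baseline", "followup") %in% names(measures)),
            all(c("sampleId", "age", "center", "smoking") %in%
                  names(covariates)))
  df <- merge(measures, covariates, by = "sampleId", sort = FALSE)
  if (!is.null(pcs)) {
    idx <- match(df$sampleId, rownames(pcs))
    df <- cbind(df, as.data.frame(pcs[idx, , drop = FALSE]))
  }
  cc <- stats::complete.cases(df)
  dropped <- data.frame(sampleId = df$sampleId[!cc],
                        reason = rep("incomplete covariates", sum(!cc)),
                        stringsAsFactors = FALSE)
  df <- df[cc, , drop = FALSE]
  df$center <- factor(df$center)
  pcNames <- if (is.null(pcs)) character() else colnames(pcs)
  form <- stats::reformulate(
    c("baseline", "age", "center", "smoking", pcNames),
    response = "followup")
  mm <- model.matrix(form, df)
  qrm <- qr(mm)
  if (qrm$rank < ncol(mm)) {
    aliased <- colnames(mm)[qrm$pivot[(qrm$rank + 1):ncol(mm)]]
    stop("rank-deficient adjustment design; offending column(s): ",
         paste(aliased, collapse = ", "))
  }
  fit <- lm(form, data = df)
  res <- stats::residuals(fit)
  pheno <- (res - mean(res)) / sd(res)
  names(pheno) <- df$sampleId
  list(phenotype = pheno, dropped = dropped)
}

#' Q-Q table and genomic-inflation factor for association p-values
#'
#' Expected quantile for rank i of m is \code{-log10((i - 0.5) / m)};
#' the genomic-inflation factor is the median association chi-square
#' divided by its null median, \code{qchisq(0.5, 1) = 0.4549}.  Values
#' near 1 indicate controlled confounding.
#'
#' @param pvalues vector of p-values in (0, 1]
#' @return list with \code{table} (data.frame expected, observed, both
#'   -log10 scale, ascending-p order) and \code{lambdaGC}
#' @export
qqDiagnostic <- function(pvalues) {
  if (!length(pvalues)) stop("empty p-value vector")
  if (any(pvalues <= 0 | pvalues > 1)) stop("p-values must lie in (0, 1]")
  m <- length(pvalues)
  srt <- sort(pvalues)
  tab <- data.frame(expected = -log10((seq_len(m) - 0.5) / m),
                    observed = -log10(srt))
  chisq <- qchisq(pvalues, df = 1, lower.tail = FALSE)
  list(table = tab, lambdaGC = median(chisq) / qchisq(0.5, df = 1,
                                                      lower.tail = FALSE))
}
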