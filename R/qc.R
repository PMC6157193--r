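# SNP-level quality control: minor allele frequency, Hardy-Weinberg exact
# test, call rate.  Filter order is MAF -> HWE -> call rate, each SNP
# attributed to its first failing rule, so the per-rule removal counts are
# well-defined and partition the input.  Boundary conventions follow the
# usual reporting: MAF failures are strict (maf < threshold), HWE failures
# inclusive (p <= threshold).

#' Minor allele frequency of a dosage vector
#'
#' \code{maf = min(f, 1 - f)} with \code{f = sum(dosage) / (2 * n)} over
#' non-missing entries.
#'
#' @param column dosage vector (0/1/2/NA); at least one non-missing entry
#' @return the minor allele frequency, in [0, 0.5]
#' @examples
#' minorAlleleFreq(c(0, 0, 1, 2))  # f = 3/8 -> 0.375
#' @export
minorAlleleFreq <- function(column) {
  ok <- !is.na(column)
  if (!any(ok)) stop("all dosages missing")
  f <- sum(column[ok]) / (2 * sum(ok))
  min(f, 1 - f)
}

# log P(nHet | allele counts) for the conditional (exact-test) distribution
.hweLogProb <- function(nHet, nA, n) {
  nAA <- (nA - nHet) / 2
  nBB <- n - nAA - nHet
  lgamma(n + 1) - lgamma(nAA + 1) - lgamma(nHet + 1) - lgamma(nBB + 1) +
    nHet * log(2) + lgamma(nA + 1) + lgamma(2 * n - nA + 1) -
    lgamma(2 * n + 1)
}

#' Hardy-Weinberg equilibrium exact test
#'
#' Two-sided exact test conditioning on the observed allele counts: sums,
#' over all heterozygote counts compatible with the allele counts, the
#' conditional probabilities no larger than that of the observed
#' heterozygote count (computed in log space).  Monomorphic sites return
#' p = 1; the test is symmetric under swapping the homozygote counts.
#'
#' @param nHomA1,nHet,nHomA2 genotype counts (non-negative, total >= 1)
#' @return exact p-value in (0, 1]
#' @examples
#' hweExactP(20, 10, 20)   # marked heterozygote deficit, tiny p
#' hweExactP(12, 26, 12)   # near HWE proportions, p ~ 1
#' @export
hweExactP <- function(nHomA1, nHet, nHomA2) {
  if (any(c(nHomA1, nHet, nHomA2) < 0)) stop("negative genotype counts")
  n <- nHomA1 + nHet + nHomA2
  if (n < 1) stop("empty genotype counts")
  nA <- 2 * nHomA1 + nHet                 # copies of allele 1
  nMinor <- min(nA, 2 * n - nA)
  if (nMinor == 0) return(1)
  hets <- seq(nMinor %% 2, nMinor, by = 2) # feasible het counts, same parity
  lp <- .hweLogProb(hets, nA, n)
  lp <- lp - max(lp)
  pr <- exp(lp); pr <- pr / sum(pr)
  pObs <- pr[match(nHet, hets)]
  min(1, sum(pr[pr <= pObs * (1 + 1e-12)]))
}

#' Hardy-Weinberg chi-square test (asymptotic alternative)
#'
#' One-degree-of-freedom goodness-of-fit test against expected HWE
#' proportions; offered for comparison with \code{\link{hweExactP}} (the
#' default used by \code{\link{applyQC}}).
#'
#' @inheritParams hweExactP
#' @return asymptotic p-value
#' @export
hweChisqP <- function(nHomA1, nHet, nHomA2) {
  n <- nHomA1 + nHet + nHomA2
  if (n < 1) stop("empty genotype counts")
  f <- (2 * nHomA1 + nHet) / (2 * n)
  if (f == 0 || f == 1) return(1)
  expd <- n * c(f^2, 2 * f * (1 - f), (1 - f)^2)
  stat <- sum((c(nHomA1, nHet, nHomA2) - expd)^2 / expd)
  pchisq(stat, df = 1, lower.tail = FALSE)
}

#' Apply SNP-level quality control
#'
#' Removes SNPs with \code{maf < mafThreshold} (strict), then among the
#' survivors those with exact HWE \code{p <= hweThreshold} (inclusive),
#' then those with call rate below \code{callrateThreshold} (off by
#' default).  Column order of survivors is preserved and every SNP is
#' attributed to exactly one verdict.
#'
#' @param G a \linkS4class{GenotypeMatrix}
#' @param mafThreshold minimum minor allele frequency (default 0.01)
#' @param hweThreshold HWE exact-test removal boundary (default 1e-5)
#' @param callrateThreshold minimum call rate (default 0 = disabled)
#' @param hweTest \code{"exact"} (default) or \code{"chisq"}
#' @return list with \code{genotypes} (filtered
#'   \linkS4class{GenotypeMatrix}) and \code{report}
#'   (\linkS4class{QCReport})
#' @examples
#' g <- simulateGenotypes(200, 50, mafLow = 0.005, mafHigh = 0.5, seed = 1)
#' qc <- applyQC(g)
#' qc$report
#' @export
applyQC <- function(G, mafThreshold = 0.01, hweThreshold = 1e-5,
                    callrateThreshold = 0, hweTest = c("exact", "chisq")) {
  stopifnot(is(G, "GenotypeMatrix"))
  thr <- c(maf = mafThreshold, hwe = hweThreshold,
           callrate = callrateThreshold)
  if (any(thr < 0 | thr > 1)) stop("thresholds must lie in [0, 1]")
  hweTest <- match.arg(hweTest)
  hweFun <- if (hweTest == "exact") hweExactP else hweChisqP
  d <- dosages(G)
  n <- nrow(d); p <- ncol(d)
  notNA <- !is.na(d)
  callRate <- colSums(notNA) / n
  maf <- vapply(seq_len(p), function(j) minorAlleleFreq(d[, j]), 0)
  hweP <- vapply(seq_len(p), function(j) {
    x <- d[notNA[, j], j]
    hweFun(sum(x == 2), sum(x == 1), sum(x == 0))
  }, 0)
  verdict <- rep("pass", p)
  verdict[maf < mafThreshold] <- "maf"
  verdict[verdict == "pass" & hweP <= hweThreshold] <- "hwe"
  verdict[verdict == "pass" & callRate < callrateThreshold] <- "callrate"
  keep <- verdict == "pass"
  report <- new("QCReport",
    nInput = p, nRemovedMaf = sum(verdict == "maf"),
    nRemovedHwe = sum(verdict == "hwe"),
    nRemovedCallrate = sum(verdict == "callrate"),
    nRetained = sum(keep),
    table = data.frame(id = snpInfo(G)$id, maf = maf, hweP = hweP,
                       callRate = callRate, verdict = verdict,
                       stringsAsFactors = FALSE),
    thresholds = thr)
  list(genotypes = G[, which(keep)], report = report)
}

#' Write a QC report to disk
#'
#' Per-SNP table as TSV plus a JSON summary of counts and thresholds.
#'
#' @param report a \linkS4class{QCReport}
#' @param prefix output path prefix (writes \code{<prefix>.tsv} and
#'   \code{<prefix>.json})
#' @return \code{prefix}, invisibly
#' @export
writeQCReport <- function(report, prefix) {
  stopifnot(is(report, "QCReport"))
  write.table(report@table, paste0(prefix, ".tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(nInput = report@nInput, nRemovedMaf = report@nRemovedMaf,
         nRemovedHwe = report@nRemovedHwe,
         nRemovedCallrate = report@nRemovedCallrate,
         nRetained = report@nRetained,
         thresholds = as.list(report@thresholds)),
    paste0(prefix, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(prefix)
}
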