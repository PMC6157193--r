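# Greedy LD-based clumping: rank SNPs by association p-value, repeatedly
# take the best unassigned SNP as a clump index, and assign to it every
# unassigned same-chromosome SNP within the physical window whose dosage
# r^2 with the index reaches the threshold.  One representative (the
# index) is retained per clump, reducing dimensionality before the LASSO
# stage.

#' Pairwise dosage r-squared between two SNPs
#'
#' Squared Pearson correlation of dosages over pairwise-complete samples
#' (genotypic LD; no phasing required).  If either column is monomorphic
#' on the complete set, r^2 is defined as 0 and flagged via the
#' \code{"degenerate"} attribute.
#'
#' @param colA,colB dosage vectors of equal length
#' @return r^2 in [0, 1], with attribute \code{degenerate}
#' @export
pairwiseR2 <- function(colA, colB) {
  stopifnot(length(colA) == length(colB))
  ok <- !is.na(colA) & !is.na(colB)
  if (sum(ok) < 2) stop("fewer than 2 pairwise-complete observations")
  a <- colA[ok]; b <- colB[ok]
  if (sd(a) == 0 || sd(b) == 0)
    return(structure(0, degenerate = TRUE))
  structure(cor(a, b)^2, degenerate = FALSE)
}

#' Greedy LD clumping
#'
#' SNPs are sorted by ascending p (ties broken by ascending position,
#' then id).  The best-ranked unassigned SNP with \code{p <= indexPMax}
#' seeds a clump and absorbs every unassigned same-chromosome SNP within
#' \code{windowKb} whose r^2 with it is \code{>= r2Threshold} and whose
#' p is \code{<= memberPMax}; assigned SNPs never seed clumps.  Retained =
#' the clump indexes plus any SNP never assigned.  Index/member p
#' thresholds default to 1 because the procedure is used here for
#' dimensionality reduction of the whole SNP set, not hit refinement;
#' r^2 = 0.5 and a 250 kb window follow the wrapped tool's conventions.
#' Cross-chromosome SNPs never clump regardless of r^2.
#'
#' @param assoc association table aligned with the columns of \code{G}
#'   (see \code{\link{singleSnpRegression}})
#' @param G the \linkS4class{GenotypeMatrix} the table was computed from
#' @param r2Threshold minimum r^2 for clump membership (default 0.5)
#' @param windowKb physical window around the index SNP, kb (default 250)
#' @param indexPMax,memberPMax p-value eligibility bounds (default 1)
#' @return list with \code{clumps} (list of \code{list(index, members)}),
#'   \code{retained} (SNP ids in original column order) and \code{table}
#'   (data.frame index, members, size)
#' @export
clumpSnps <- function(assoc, G, r2Threshold = 0.5, windowKb = 250,
                      indexPMax = 1, memberPMax = 1) {
  stopifnot(is(G, "GenotypeMatrix"))
  if (nrow(assoc) != nSnps(G) || !all(assoc$id == snpInfo(G)$id))
    stop("association table does not align with the genotype matrix")
  if (r2Threshold < 0 || r2Threshold > 1) stop("r2Threshold outside [0,1]")
  d <- dosages(G)
  p <- nrow(assoc)
  ord <- order(assoc$p, assoc$pos, assoc$id)
  assigned <- logical(p)
  isIndex <- logical(p)
  clumps <- list()
  window <- windowKb * 1000
  for (i in ord) {
    if (assigned[i] || assoc$p[i] > indexPMax) next
    assigned[i] <- TRUE
    isIndex[i] <- TRUE
    cand <- which(!assigned &
                    assoc$chrom == assoc$chrom[i] &
                    abs(assoc$pos - assoc$pos[i]) <= window &
                    assoc$p <= memberPMax)
    members <- integer()
    if (length(cand)) {
      r2 <- vapply(cand, function(j)
        as.numeric(pairwiseR2(d[, i], d[, j])), 0)
      members <- cand[r2 >= r2Threshold]
      assigned[members] <- TRUE
    }
    clumps[[length(clumps) + 1L]] <-
      list(index = assoc$id[i], members = assoc$id[members])
  }
  retainedIdx <- which(isIndex | !assigned)
  list(clumps = clumps,
       retained = assoc$id[retainedIdx],
       table = data.frame(
         index = vapply(clumps, `[[`, "", "index"),
         members = vapply(clumps, function(cl)
           paste(cl$members, collapse = ","), ""),
         size = vapply(clumps, function(cl)
           length(cl$members) + 1L, 0L),
         stringsAsFactors = FALSE))
}
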