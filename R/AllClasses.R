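#' @useDynLib snpLasso, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
#' @importFrom stats coef cor cov lm median model.matrix pchisq pt qchisq
#'   rbinom rnorm runif sd var predict
#' @importFrom utils read.table write.table head
NULL

#' GenotypeMatrix: SNP dosages with per-SNP metadata
#'
#' Container for an n-sample x p-SNP dosage matrix (entries 0, 1, 2 or
#' \code{NA} for missing), per-SNP metadata (id, chromosome, base-pair
#' position, alleles) and sample identifiers.  Dosage counts copies of the
#' A1 allele (the PLINK \code{.bim} A1 column, conventionally the minor
#' allele), so \code{colMeans(dosages(x))/2} estimates the A1 allele
#' frequency.  Positions are 1-based base pairs; chromosome is stored as
#' character so "X"/"MT" need no special-casing.
#'
#' @slot dosages numeric matrix, n x p, entries in {0, 1, 2, NA}
#' @slot snpInfo data.frame with columns \code{id}, \code{chrom},
#'   \code{pos}, \code{a1}, \code{a2}; one row per SNP, aligned with the
#'   columns of \code{dosages}
#' @slot sampleIds character vector of length n, unique
#'
#' @examples
#' g <- simulateGenotypes(nIndividuals = 10, nSnps = 4, seed = 1)
#' g
#' dosages(g)[1:3, ]
#' @aliases GenotypeMatrix
#' @exportClass GenotypeMatrix
setClass("GenotypeMatrix",
  representation(dosages = "matrix", snpInfo = "data.frame",
                 sampleIds = "character"))

setValidity("GenotypeMatrix", function(object) {
  d <- object@dosages
  si <- object@snpInfo
  msg <- character()
  if (!is.numeric(d))
    msg <- c(msg, "dosages must be numeric")
  if (nrow(si) != ncol(d))
    msg <- c(msg, "snpInfo rows must match dosage columns")
  if (length(object@sampleIds) != nrow(d))
    msg <- c(msg, "sampleIds length must match dosage rows")
  need <- c("id", "chrom", "pos", "a1", "a2")
  if (!all(need %in% names(si)))
    msg <- c(msg, paste("snpInfo must have columns:",
                        paste(need, collapse = ", ")))
  else {
    if (anyDuplicated(si$id))
      msg <- c(msg, "SNP ids must be unique")
    if (any(si$pos < 0))
      msg <- c(msg, "positions must be non-negative")
  }
  if (anyDuplicated(object@sampleIds))
    msg <- c(msg, "sample ids must be unique")
  if (!.dosagesValid(d))
    msg <- c(msg, "dosages must be 0, 1, 2 or NA")
  if (length(msg)) msg else TRUE
})

# chunked scan keeping temporaries small for cohort-scale matrices
.dosagesValid <- function(d) {
  p <- ncol(d)
  if (p == 0) return(TRUE)
  step <- max(1L, as.integer(4e6 / max(1L, nrow(d))))
  for (start in seq(1L, p, by = step)) {
    blk <- d[, start:min(start + step - 1L, p), drop = FALSE]
    blk <- blk[!is.na(blk)]
    if (length(blk) && !all(blk == 0 | blk == 1 | blk == 2))
      return(FALSE)
  }
  TRUE
}

#' Construct a GenotypeMatrix
#'
#' @param dosages n x p numeric matrix of allele dosages (0/1/2/NA)
#' @param snpInfo per-SNP data.frame (id, chrom, pos, a1, a2); generated
#'   with 10 kb spacing on chromosome "1" when omitted
#' @param sampleIds sample identifiers; defaults to \code{S0001, ...}
#' @return a \linkS4class{GenotypeMatrix}
#' @export
GenotypeMatrix <- function(dosages, snpInfo = NULL, sampleIds = NULL) {
  dosages <- as.matrix(dosages)
  if (storage.mode(dosages) != "double")
    storage.mode(dosages) <- "double"
  p <- ncol(dosages); n <- nrow(dosages)
  if (is.null(snpInfo)) {
    snpInfo <- data.frame(
      id = if (is.null(colnames(dosages)))
        sprintf("snp_%05d", seq_len(p)) else colnames(dosages),
      chrom = "1", pos = 10000L * seq_len(p),
      a1 = "A", a2 = "B", stringsAsFactors = FALSE)
  }
  if (is.null(sampleIds)) {
    sampleIds <- if (is.null(rownames(dosages)))
      sprintf("S%05d", seq_len(n)) else rownames(dosages)
  }
  dimnames(dosages) <- list(sampleIds, snpInfo$id)
  rownames(snpInfo) <- NULL
  new("GenotypeMatrix", dosages = dosages, snpInfo = snpInfo,
      sampleIds = as.character(sampleIds))
}

#' @describeIn GenotypeMatrix-class dosage matrix accessor
#' @param x,object a \code{GenotypeMatrix}
#' @export
setGeneric("dosages", function(x) standardGeneric("dosages"))

#' @export
setMethod("dosages", "GenotypeMatrix", function(x) x@dosages)

#' @describeIn GenotypeMatrix-class per-SNP metadata accessor
#' @export
setGeneric("snpInfo", function(x) standardGeneric("snpInfo"))

#' @export
setMethod("snpInfo", "GenotypeMatrix", function(x) x@snpInfo)

#' @describeIn GenotypeMatrix-class sample identifier accessor
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' @export
setMethod("sampleIds", "GenotypeMatrix", function(x) x@sampleIds)

#' @describeIn GenotypeMatrix-class number of samples
#' @export
setGeneric("nSamples", function(x) standardGeneric("nSamples"))

#' @export
setMethod("nSamples", "GenotypeMatrix", function(x) nrow(x@dosages))

#' @describeIn GenotypeMatrix-class number of SNPs
#' @export
setGeneric("nSnps", function(x) standardGeneric("nSnps"))

#' @export
setMethod("nSnps", "GenotypeMatrix", function(x) ncol(x@dosages))

#' @export
setMethod("show", "GenotypeMatrix", function(object) {
  d <- object@dosages
  cat("GenotypeMatrix:", nrow(d), "samples x", ncol(d), "SNPs\n")
  cat("  chromosomes:", paste(unique(object@snpInfo$chrom), collapse = ", "),
      "\n")
  miss <- mean(is.na(d))
  cat(sprintf("  missing dosages: %.2f%%\n", 100 * miss))
})

#' @describeIn GenotypeMatrix-class subset samples (i) and/or SNPs (j)
#' @param i,j sample / SNP indices
#' @param drop ignored
#' @param ... ignored
#' @export
setMethod("[", "GenotypeMatrix", function(x, i, j, ..., drop = FALSE) {
  if (missing(i)) i <- seq_len(nrow(x@dosages))
  if (missing(j)) j <- seq_len(ncol(x@dosages))
  new("GenotypeMatrix",
      dosages = x@dosages[i, j, drop = FALSE],
      snpInfo = x@snpInfo[j, , drop = FALSE],
      sampleIds = x@sampleIds[i])
})

#' QCReport: per-SNP quality-control audit
#'
#' Produced by \code{\link{applyQC}}.  Each SNP is attributed to the first
#' failing rule in the order MAF -> HWE -> call rate, so the removal counts
#' partition the input: \code{nInput = nRemovedMaf + nRemovedHwe +
#' nRemovedCallrate + nRetained}.
#'
#' @slot nInput,nRemovedMaf,nRemovedHwe,nRemovedCallrate,nRetained counts
#' @slot table per-SNP data.frame (id, maf, hweP, callRate, verdict)
#' @slot thresholds named numeric (maf, hwe, callrate)
#' @exportClass QCReport
setClass("QCReport",
  representation(nInput = "integer", nRemovedMaf = "integer",
                 nRemovedHwe = "integer", nRemovedCallrate = "integer",
                 nRetained = "integer", table = "data.frame",
                 thresholds = "numeric"))

setValidity("QCReport", function(object) {
  tot <- object@nRemovedMaf + object@nRemovedHwe +
    object@nRemovedCallrate + object@nRetained
  if (tot != object@nInput)
    return("removal counts and retained count must partition the input")
  if (nrow(object@table) != object@nInput)
    return("per-SNP table must have one row per input SNP")
  TRUE
})

#' @export
setMethod("show", "QCReport", function(object) {
  cat("QCReport:", object@nInput, "SNPs in\n")
  cat(sprintf("  removed: %d MAF < %g, %d HWE p <= %g, %d call rate < %g\n",
              object@nRemovedMaf, object@thresholds[["maf"]],
              object@nRemovedHwe, object@thresholds[["hwe"]],
              object@nRemovedCallrate, object@thresholds[["callrate"]]))
  cat("  retained:", object@nRetained, "\n")
})

#' @describeIn QCReport-class per-SNP QC table accessor
#' @param x a \code{QCReport}
#' @export
setGeneric("qcTable", function(x) standardGeneric("qcTable"))

#' @export
setMethod("qcTable", "QCReport", function(x) x@table)

#' LassoPath: LASSO solutions along a regularization path
#'
#' Fitted by \code{\link{fitLassoPath}}.  Coefficients are stored on the
#' ORIGINAL dosage scale; \code{center}/\code{scale} record the per-column
#' standardization used internally so KKT conditions can be re-checked.
#' At \code{lambda[1] = lambda_max} all coefficients are exactly zero.
#'
#' @slot lambda descending penalty grid
#' @slot beta p x nLambda coefficient matrix, original predictor scale
#' @slot intercept per-lambda intercepts
#' @slot nNonzero integer nonzero counts per lambda
#' @slot converged logical per lambda
#' @slot iterations sweep counts per lambda
#' @slot center,scale per-column standardization constants
#' @slot ybar training response mean
#' @slot standardize whether predictors were standardized
#' @slot objectiveScaling \code{"half_n"} or \code{"rss"} (see
#'   \code{\link{fitLassoPath}})
#' @slot objectives per-lambda per-sweep objective traces (list; empty
#'   unless requested)
#' @exportClass LassoPath
setClass("LassoPath",
  representation(lambda = "numeric", beta = "matrix", intercept = "numeric",
                 nNonzero = "integer", converged = "logical",
                 iterations = "integer", center = "numeric",
                 scale = "numeric", ybar = "numeric",
                 standardize = "logical", objectiveScaling = "character",
                 objectives = "list"))

setValidity("LassoPath", function(object) {
  nl <- length(object@lambda)
  if (ncol(object@beta) != nl || length(object@intercept) != nl)
    return("beta columns and intercepts must match the lambda grid")
  if (is.unsorted(rev(object@lambda)))
    return("lambda grid must be descending")
  if (any(!is.finite(object@beta)))
    return("coefficients must be finite")
  TRUE
})

#' @export
setMethod("show", "LassoPath", function(object) {
  nl <- length(object@lambda)
  cat("LassoPath:", nrow(object@beta), "predictors,", nl, "lambda values\n")
  cat(sprintf("  lambda: %.4g ... %.4g\n", object@lambda[1],
              object@lambda[nl]))
  cat("  nonzero range:", min(object@nNonzero), "-", max(object@nNonzero),
      "\n")
  if (!all(object@converged))
    cat("  WARNING:", sum(!object@converged), "lambda values not converged\n")
})

#' @describeIn LassoPath-class coefficient matrix (original scale); rows =
#'   predictors, columns = lambda grid
#' @param object a \code{LassoPath}
#' @param ... ignored
#' @export
setMethod("coef", "LassoPath", function(object, ...) object@beta)

#' @describeIn LassoPath-class the lambda grid
#' @param x a \code{LassoPath}
#' @export
setGeneric("lambdaGrid", function(x) standardGeneric("lambdaGrid"))

#' @export
setMethod("lambdaGrid", "LassoPath", function(x) x@lambda)

#' CVReport: nested cross-validation results
#'
#' Produced by \code{\link{nestedCV}}.  Holds the per-outer-fold selected
#' penalty, inner mean-MSE curves, full coefficient vectors and tracked-SNP
#' coefficients, the pooled out-of-sample predictions (each sample
#' predicted exactly once, by a model that never saw it), and the pooled
#' metrics: Pearson r, mean squared error, and the slope of the best-fit
#' line of predicted on observed.
#'
#' @slot folds outer fold assignment (integer per sample)
#' @slot selectedLambda per-fold selected penalty
#' @slot lambdaRange c(min, max) of selected penalties across folds
#' @slot innerMSE list of per-fold data.frames (lambda, meanMSE)
#' @slot foldCoefs p x kOuter matrix of refit coefficients
#' @slot trackedCoefs tracked-SNP x kOuter coefficient matrix
#' @slot trackedMean,trackedSD per-tracked-SNP mean and SD (n-1) across folds
#' @slot predictions pooled out-of-sample predictions, sample order
#' @slot observed the observed response, sample order
#' @slot metrics named numeric (pearsonR, mse, slope)
#' @slot degenerate TRUE when pooled predictions were constant
#' @exportClass CVReport
setClass("CVReport",
  representation(folds = "integer", selectedLambda = "numeric",
                 lambdaRange = "numeric", innerMSE = "list",
                 foldCoefs = "matrix", trackedCoefs = "matrix",
                 trackedMean = "numeric", trackedSD = "numeric",
                 predictions = "numeric", observed = "numeric",
                 metrics = "numeric", degenerate = "logical"))

setValidity("CVReport", function(object) {
  if (length(object@predictions) != length(object@observed))
    return("predictions and observed must align")
  if (length(object@selectedLambda) != max(object@folds))
    return("one selected lambda per outer fold")
  rng <- range(object@selectedLambda)
  if (!isTRUE(all.equal(rng, object@lambdaRange)))
    return("lambdaRange inconsistent with per-fold selections")
  TRUE
})

#' @export
setMethod("show", "CVReport", function(object) {
  k <- max(object@folds)
  cat("CVReport:", k, "outer folds,", length(object@observed), "samples\n")
  cat(sprintf("  selected lambda range: %.4g - %.4g\n",
              object@lambdaRange[1], object@lambdaRange[2]))
  m <- object@metrics
  cat(sprintf("  pooled: r = %.4f, MSE = %.4f, slope = %.4f\n",
              m[["pearsonR"]], m[["mse"]], m[["slope"]]))
  if (length(object@trackedMean))
    cat(sprintf("  tracked SNP coefficient: mean %s, SD %s\n",
                paste(signif(object@trackedMean, 4), collapse = ", "),
                paste(signif(object@trackedSD, 4), collapse = ", ")))
})

#' @describeIn CVReport-class pooled evaluation metrics
#' @param x a \code{CVReport}
#' @export
setGeneric("cvMetrics", function(x) standardGeneric("cvMetrics"))

#' @export
setMethod("cvMetrics", "CVReport", function(x) x@metrics)

#' @describeIn CVReport-class per-outer-fold selected penalties
#' @export
setGeneric("selectedLambda", function(x) standardGeneric("selectedLambda"))

#' @export
setMethod("selectedLambda", "CVReport", function(x) x@selectedLambda)
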