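# End-to-end orchestration: simulate -> QC -> phenotype -> association ->
# clumping -> nested CV, with every intermediate artifact written to a run
# directory and a stage ledger reconciling record counts.  Reruns with the
# same config are bit-identical.

#' Pipeline configuration
#'
#' Assembles and validates the full set of stage parameters.  The
#' \code{phenotypeMode} decides how the response is built:
#' \code{"direct"} simulates y = beta * g + noise at the stated
#' heritability (the illustrative single-causal-SNP design);
#' \code{"visits"} simulates a 4-visit raw table and runs the full
#' phenotype-construction stage (log visit means, covariate + PC
#' adjustment, standardized residuals).
#'
#' @param nIndividuals,nSnps simulated cohort size
#' @param mafLow,mafHigh,ldBlockSize,ldCopyProb,missingRate genotype
#'   simulator settings (see \code{\link{simulateGenotypes}})
#' @param phenotypeMode \code{"direct"} or \code{"visits"}
#' @param causalIndex,beta,h2 causal model (direct mode); \code{beta} is
#'   also the follow-up log-TG effect in visits mode
#' @param nPCs principal components for the adjustment (visits mode)
#' @param runQC,runClump stage toggles
#' @param mafThreshold,hweThreshold,callrateThreshold QC settings
#' @param clumpR2,clumpKb,clumpP1,clumpP2 clumping settings
#' @param kOuter,kInner,nLambda,lambdaMinRatio,tol,screen nested-CV and
#'   solver settings
#' @param seed global seed; propagates deterministically to every stage
#' @return a validated config list (class \code{snpLassoConfig})
#' @export
pipelineConfig <- function(nIndividuals = 700, nSnps = 56000,
                           mafLow = 0.05, mafHigh = 0.5, ldBlockSize = 1,
                           ldCopyProb = 0, missingRate = 0,
                           phenotypeMode = c("direct", "visits"),
                           causalIndex = NULL, beta = -0.44, h2 = 0.05,
                           nPCs = 20, runQC = TRUE, runClump = TRUE,
                           mafThreshold = 0.01, hweThreshold = 1e-5,
                           callrateThreshold = 0, clumpR2 = 0.5,
                           clumpKb = 250, clumpP1 = 1, clumpP2 = 1,
                           kOuter = 10, kInner = 10, nLambda = 100,
                           lambdaMinRatio = NULL, tol = 1e-7,
                           screen = FALSE, seed = 1) {
  phenotypeMode <- match.arg(phenotypeMode)
  if (is.null(causalIndex)) causalIndex <- max(1L, nSnps %/% 2L)
  cfg <- list(nIndividuals = nIndividuals, nSnps = nSnps, mafLow = mafLow,
              mafHigh = mafHigh, ldBlockSize = ldBlockSize,
              ldCopyProb = ldCopyProb, missingRate = missingRate,
              phenotypeMode = phenotypeMode, causalIndex = causalIndex,
              beta = beta, h2 = h2, nPCs = nPCs, runQC = runQC,
              runClump = runClump, mafThreshold = mafThreshold,
              hweThreshold = hweThreshold,
              callrateThreshold = callrateThreshold, clumpR2 = clumpR2,
              clumpKb = clumpKb, clumpP1 = clumpP1, clumpP2 = clumpP2,
              kOuter = kOuter, kInner = kInner, nLambda = nLambda,
              lambdaMinRatio = lambdaMinRatio, tol = tol, screen = screen,
              seed = seed)
  stopifnot(cfg$nIndividuals >= 4, cfg$nSnps >= 1,
            cfg$causalIndex >= 1, cfg$causalIndex <= cfg$nSnps)
  class(cfg) <- "snpLassoConfig"
  cfg
}

#' Named pipeline presets
#'
#' Three fully synthetic presets mirroring the study designs the package
#' reproduces: \code{"gaw20-like"} (a 680-sample cohort with the 4-visit
#' phenotype-construction stage), \code{"illustrative-n700"} and
#' \code{"illustrative-n7753"} (single causal SNP, effect -0.44,
#' heritability 0.05, 56,000 post-clump-scale independent SNPs).
#'
#' @param name preset name
#' @param ... overrides passed to \code{\link{pipelineConfig}}
#' @return a config list
#' @export
pipelinePreset <- function(name = c("gaw20-like", "illustrative-n700",
                                    "illustrative-n7753"), ...) {
  name <- match.arg(name)
  base <- switch(name,
    "gaw20-like" = list(nIndividuals = 680, nSnps = 56000,
                        phenotypeMode = "visits", beta = -0.44, h2 = 0.05,
                        runQC = TRUE, runClump = TRUE),
    "illustrative-n700" = list(nIndividuals = 700, nSnps = 56000,
                               phenotypeMode = "direct", beta = -0.44,
                               h2 = 0.05, runQC = FALSE, runClump = FALSE),
    "illustrative-n7753" = list(nIndividuals = 7753, nSnps = 56000,
                                phenotypeMode = "direct", beta = -0.44,
                                h2 = 0.05, runQC = FALSE,
                                runClump = FALSE))
  do.call(pipelineConfig, utils::modifyList(base, list(...)))
}

#' Read a pipeline config from a YAML file
#'
#' Keys are the \code{\link{pipelineConfig}} argument names.
#'
#' @param path YAML file
#' @return a config list
#' @export
readPipelineConfig <- function(path) {
  do.call(pipelineConfig, yaml::read_yaml(path))
}

#' Run the full analysis pipeline
#'
#' Executes simulate -> (QC) -> phenotype -> association -> (clump) ->
#' nested CV, writing every intermediate artifact under \code{outDir}:
#' PLINK genotypes with a JSON parameter sidecar, phenotype TSV, QC
#' report, association TSV, clump table, CV report (JSON + TSVs) and a
#' stage ledger (\code{stages.tsv}) whose record counts reconcile at
#' every stage.  Rerunning with the same config reproduces all outputs
#' bit-identically.  Any stage error aborts with the stage name.
#'
#' @param config from \code{\link{pipelineConfig}} /
#'   \code{\link{pipelinePreset}}
#' @param outDir run directory (created if needed)
#' @return invisibly, a list with the final \linkS4class{CVReport}, the
#'   stage ledger and the artifact paths
#' @examples
#' cfg <- pipelinePreset("illustrative-n700", nIndividuals = 80,
#'                       nSnps = 60, causalIndex = 30, kOuter = 3,
#'                       kInner = 2, nLambda = 20, seed = 11)
#' res <- runPipeline(cfg, tempfile("run"))
#' res$cvReport
#' @export
runPipeline <- function(config, outDir) {
  stopifnot(inherits(config, "snpLassoConfig"))
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  art <- function(...) file.path(outDir, paste0(...))
  ledger <- data.frame(stage = character(), samples = integer(),
                       snps = integer(), stringsAsFactors = FALSE)
  note <- function(stage, ns, np)
    ledger <<- rbind(ledger, data.frame(stage = stage, samples = ns,
                                        snps = np))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  G <- stage("simulate", simulateGenotypes(
    config$nIndividuals, config$nSnps, config$mafLow, config$mafHigh,
    config$ldBlockSize, config$ldCopyProb, config$missingRate,
    seed = config$seed))
  note("simulate", nSamples(G), nSnps(G))
  writePlinkBed(G, art("genotypes"))
  jsonlite::write_json(unclass(config), art("config.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  causalId <- snpInfo(G)$id[config$causalIndex]

  if (config$runQC) {
    qc <- stage("qc", applyQC(G, config$mafThreshold, config$hweThreshold,
                              config$callrateThreshold))
    writeQCReport(qc$report, art("qc_report"))
    G <- qc$genotypes
    note("qc", nSamples(G), nSnps(G))
    if (!causalId %in% snpInfo(G)$id)
      stop("pipeline stage 'qc' failed: causal SNP removed by QC")
  }

  if (config$phenotypeMode == "direct") {
    ph <- stage("phenotype", simulatePhenotype(
      G, match(causalId, snpInfo(G)$id), config$beta, config$h2,
      seed = config$seed + 1L))
    y <- ph$phenotype
  } else {
    visits <- stage("phenotype", simulateVisits(
      G, match(causalId, snpInfo(G)$id), config$beta,
      seed = config$seed + 1L))
    bf <- buildBaselineFollowup(visits)
    pcs <- computePCs(G, k = min(config$nPCs, nSamples(G) - 1L))
    adj <- adjustPhenotype(bf$measures,
                           visits[, c("sampleId", "age", "center",
                                      "smoking")], pcs)
    y <- adj$phenotype
    keep <- match(names(y), sampleIds(G))
    G <- G[keep, ]
    write.table(data.frame(sample_id = rownames(pcs), pcs),
                art("pc_scores.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  note("phenotype", length(y), nSnps(G))
  write.table(data.frame(sample_id = names(y), phenotype = y),
              art("phenotype.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)

  assoc <- stage("assoc", singleSnpRegression(G, y))
  write.table(manhattanTable(assoc), art("assoc.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  qq <- qqDiagnostic(assoc$p)
  write.table(qq$table, art("qq.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  note("assoc", length(y), nrow(assoc))

  if (config$runClump) {
    cl <- stage("clump", clumpSnps(assoc, G, config$clumpR2,
                                   config$clumpKb, config$clumpP1,
                                   config$clumpP2))
    write.table(cl$table, art("clumps.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    G <- G[, match(cl$retained, snpInfo(G)$id)]
    note("clump", nSamples(G), nSnps(G))
  }

  tracked <- match(causalId, snpInfo(G)$id)
  if (is.na(tracked)) tracked <- integer()
  cv <- stage("nested_cv", nestedCV(
    G, y, kOuter = config$kOuter, kInner = config$kInner,
    nLambda = config$nLambda, lambdaMinRatio = config$lambdaMinRatio,
    tol = config$tol, screen = config$screen, trackedSnps = tracked,
    seed = config$seed + 2L))
  writeCVReport(cv, art("cv_report"), sampleIds = names(y))
  note("nested_cv", length(y), nSnps(G))

  write.table(ledger, art("stages.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(list(cvReport = cv, ledger = ledger, outDir = outDir,
                 causalId = causalId))
}
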