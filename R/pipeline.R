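#' Default pipeline configuration
#'
#' Returns the configuration list consumed by [runPipeline()], with the
#' published study conditions as defaults: two-stage synthetic study
#' (discovery n = 783, replication n = 538), QC thresholds MAF 0.01 /
#' call rate 0.90 / HWE P 1e-5 / INFO 0.9, covariates sex + bmi + study +
#' six PCs, and filtering thresholds 1e-5 / 0.05 / 5e-8 with concordance
#' required.
#'
#' @param outdir output directory.
#' @param seed root seed.
#' @return nested configuration list.
#' @export
defaultPipelineConfig <- function(outdir = tempfile("ageGWIS_run_"),
                                  seed = 1L) {
  list(
    seed = as.integer(seed),
    outdir = outdir,
    simulate = list(nDisc = 783L, nRep = 538L, nVariants = 50L,
                    nCausal = 1L, maf = 0.49, beta0 = -0.32,
                    betaG = 0.17, betaE = 0.97, betaI = -0.875,
                    missRate = 0.0, writeCohorts = FALSE),
    genotypes = list(discovery = NULL, replication = NULL),
    phenotypes = list(discovery = NULL, replication = NULL),
    qc = list(mafMin = 0.01, callRateMin = 0.90, hwePMin = 1e-5,
              infoMin = 0.9),
    covariates = c("sex", "bmi", "study"),
    nPcs = 6L,
    criteria = list(pDiscoveryMax = 1e-5, pReplicationMax = 0.05,
                    pJointMax = 5e-8, requireConcordance = TRUE),
    genes = NULL,
    flank = 10000)
}

.loadStage <- function(config, stage) {
  gpath <- config$genotypes[[stage]]
  ppath <- config$phenotypes[[stage]]
  if (is.null(gpath) || is.null(ppath))
    .configError(paste("no input files configured for stage", stage))
  x <- readGenotypes(gpath)
  attachPhenotypes(x, readPhenotypes(ppath))
}

#' Run the full two-stage GWIS pipeline
#'
#' Orchestrates simulate (optional) -> QC -> PCA covariates -> exposure
#' transform -> per-stage GWIS -> two-stage joint analysis -> optional
#' candidate-gene annotation, writing `qc_report.tsv`, `disc.tsv`,
#' `rep.tsv`, `joint.tsv`, `lambda.txt` (and `gene_proxies.tsv` when a
#' gene file is configured) into `config$outdir`. Every artifact is
#' stamped with the seed and a checksum of the configuration; reruns with
#' the same configuration produce byte-identical tables.
#'
#' When `config$simulate` is non-NULL a synthetic two-stage study is
#' generated; otherwise `config$genotypes`/`config$phenotypes` must name
#' per-stage input files (VCF or dosage TSV, phenotype TSV).
#'
#' @param config configuration list as from [defaultPipelineConfig()], or
#'   the path of a YAML file with the same structure.
#' @return invisibly, a list with the per-stage results, joint table,
#'   lambda values and artifact paths.
#' @export
runPipeline <- function(config = defaultPipelineConfig()) {
  if (is.character(config)) {
    if (!file.exists(config))
      .configError(paste("config file not found:", config))
    config <- utils::modifyList(defaultPipelineConfig(),
                                read_yaml(config))
  }
  if (is.null(config$outdir)) .configError("config$outdir is required")
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  stamp <- .stamp(seed, .configHash(config))

  if (!is.null(config$simulate)) {
    sc <- config$simulate
    pd <- SimulationParams(beta0 = sc$beta0, betaG = sc$betaG,
                           betaE = sc$betaE, betaI = sc$betaI,
                           maf = sc$maf, nSamples = sc$nDisc,
                           nVariants = sc$nVariants,
                           nCausal = sc$nCausal, seed = seed)
    pr <- pd
    pr@nSamples <- as.integer(sc$nRep)
    pr@seed <- .streamSeed(seed, "replication")
    stages <- simulateTwoStageStudy(pd, pr)
    if (!is.null(sc$missRate) && sc$missRate > 0)
      stages <- lapply(stages, injectMissingness, rate = sc$missRate,
                       seed = seed)
    if (isTRUE(sc$writeCohorts))
      for (st in names(stages))
        writeCohort(stages[[st]], file.path(config$outdir, st))
  } else {
    stages <- list(discovery = .loadStage(config, "discovery"),
                   replication = .loadStage(config, "replication"))
  }

  thr <- QCThresholds(mafMin = config$qc$mafMin,
                      callRateMin = config$qc$callRateMin,
                      hwePMin = config$qc$hwePMin,
                      infoMin = config$qc$infoMin)
  qcReports <- list()
  results <- list()
  for (st in names(stages)) {
    qc <- applyQC(stages[[st]], thr)
    qcReports[[st]] <- cbind(stage = st, qc$report)
    x <- qc$experiment
    nPcs <- min(config$nPcs, dim(x) - 1L)
    covs <- config$covariates
    if (nPcs > 0) {
      x <- addPcaCovariates(x, k = nPcs)
      covs <- c(covs, paste0("PC", seq_len(nPcs)))
    }
    covs <- intersect(covs, colnames(colData(x)))
    results[[st]] <- runGwis(x, covariates = covs)
  }

  crit <- FilterCriteria(
    pDiscoveryMax = config$criteria$pDiscoveryMax,
    pReplicationMax = config$criteria$pReplicationMax,
    pJointMax = config$criteria$pJointMax,
    requireConcordance = isTRUE(config$criteria$requireConcordance))
  joint <- runTwoStage(results$discovery, results$replication, crit)

  lambda <- vapply(results, function(r)
    genomicLambda(r$p[r$converged & !is.na(r$p)]), numeric(1))

  out <- file.path(config$outdir,
                   c(qc_report = "qc_report.tsv", disc = "disc.tsv",
                     rep = "rep.tsv", joint = "joint.tsv",
                     lambda = "lambda.txt"))
  names(out) <- c("qc_report", "disc", "rep", "joint", "lambda")
  .writeTsv(do.call(rbind, qcReports), out["qc_report"], stamp)
  .writeTsv(results$discovery, out["disc"], stamp)
  .writeTsv(results$replication, out["rep"], stamp)
  .writeTsv(joint, out["joint"], stamp)
  writeLines(c(stamp, sprintf("%s\t%.6f", names(lambda), lambda)),
             out["lambda"])

  proxies <- NULL
  if (!is.null(config$genes)) {
    genes <- if (is.character(config$genes)) readGeneWindows(config$genes)
             else config$genes
    proxies <- assignGeneProxy(results$discovery, genes,
                               flank = config$flank)
    out <- c(out, proxies = file.path(config$outdir, "gene_proxies.tsv"))
    .writeTsv(proxies, out["proxies"], stamp)
  }

  invisible(list(stages = results, joint = joint, lambda = lambda,
                 qc = qcReports, proxies = proxies, artifacts = out,
                 seed = seed))
}
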