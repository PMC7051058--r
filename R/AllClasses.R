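#' GwisExperiment: genotype dosages with sample phenotypes
#'
#' A thin extension of [SummarizedExperiment::SummarizedExperiment] holding a
#' `"dosage"` assay (variants x samples, additive counted-allele dosage in
#' `[0, 2]`, `NA` = missing call), per-variant metadata in `rowData()`
#' (`id`, `chrom`, `pos`, `major`, `minor`, optional `info` imputation
#' quality and `causal` flag), and per-sample phenotypes in `colData()`
#' (`outcome` 0/1, `age` in years, optional `exposure` on the transformed
#' scale, `sex`, `bmi`, `study`, `PC1..PCk`). The analysis stage
#' (`"discovery"` or `"replication"`) lives in `metadata(x)$stage`.
#'
#' @slot .. inherited from SummarizedExperiment.
#' @aliases GwisExperiment-class
#' @exportClass GwisExperiment
setClass("GwisExperiment", contains = "SummarizedExperiment")

setValidity("GwisExperiment", function(object) {
  msg <- character(0)
  if (!"dosage" %in% assayNames(object))
    msg <- c(msg, "assay 'dosage' is required")
  else {
    d <- assay(object, "dosage")
    if (!is.numeric(d))
      msg <- c(msg, "'dosage' must be numeric")
    else {
      r <- suppressWarnings(range(d, na.rm = TRUE))
      if (is.finite(r[1]) && (r[1] < 0 || r[2] > 2))
        msg <- c(msg, "'dosage' values must lie in [0, 2]")
    }
  }
  cd <- colData(object)
  if ("outcome" %in% colnames(cd)) {
    y <- cd$outcome
    if (!all(y[!is.na(y)] %in% c(0, 1)))
      msg <- c(msg, "'outcome' must be coded 0/1")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a GwisExperiment
#'
#' @param dosage variants x samples numeric matrix of counted-allele dosages
#'   in `[0, 2]`; `NA` marks missing calls.
#' @param variants `data.frame`/`DataFrame` of per-variant metadata (one row
#'   per dosage row). A missing `id` column is filled from row names.
#' @param samples `data.frame`/`DataFrame` of per-sample phenotypes (one row
#'   per dosage column).
#' @param stage analysis stage label stored in `metadata()$stage`.
#' @return a [GwisExperiment-class] object.
#' @examples
#' g <- simulateGenotypes(20, maf = c(0.3, 0.4), seed = 1)
#' ge <- GwisExperiment(g)
#' dim(ge)
#' @export
GwisExperiment <- function(dosage, variants = NULL, samples = NULL,
                           stage = NA_character_) {
  dosage <- as.matrix(dosage)
  if (is.null(rownames(dosage)))
    rownames(dosage) <- sprintf("snp%05d", seq_len(nrow(dosage)))
  if (is.null(colnames(dosage)))
    colnames(dosage) <- sprintf("sample%05d", seq_len(ncol(dosage)))
  if (is.null(variants))
    variants <- DataFrame(id = rownames(dosage))
  variants <- DataFrame(variants)
  if (!"id" %in% colnames(variants)) variants$id <- rownames(dosage)
  if (is.null(samples))
    samples <- DataFrame(sample_id = colnames(dosage))
  samples <- DataFrame(samples)
  se <- SummarizedExperiment(
    assays = list(dosage = dosage),
    rowData = variants, colData = samples,
    metadata = list(stage = stage))
  new("GwisExperiment", se)
}

#' Per-variant simulation and generative-model parameters
#'
#' Parameters of the logistic gene-by-environment generative model
#' `logit P(Y = 1) = beta0 + betaG * G + betaE * E + betaI * G * E`,
#' plus cohort dimensions. Defaults are the model estimated in the
#' discovery cohort: intercept -0.32, genotype main effect 0.17 per
#' counted allele, exposure main effect 0.97 per SD of transformed age,
#' MAF 0.49, and n = 783. The interaction coefficient defaults to
#' -0.875, the midpoint of the -1.00..-0.75 grid used for power
#' analysis; its sign is a free choice (see the methods vignette).
#'
#' @slot beta0 log-odds intercept.
#' @slot betaG log-OR per counted (minor) allele.
#' @slot betaE log-OR per unit of the standard-normal exposure.
#' @slot betaI interaction log-OR per (allele x exposure unit).
#' @slot maf minor-allele frequency in (0, 0.5].
#' @slot nSamples,nVariants,nCausal cohort dimensions; the first `nCausal`
#'   variants carry `betaG` and `betaI`, all others are null.
#' @slot seed root RNG seed, split into named streams internally.
#' @exportClass SimulationParams
setClass("SimulationParams",
  representation(beta0 = "numeric", betaG = "numeric", betaE = "numeric",
                 betaI = "numeric", maf = "numeric", nSamples = "integer",
                 nVariants = "integer", nCausal = "integer",
                 seed = "integer"))

setValidity("SimulationParams", function(object) {
  msg <- character(0)
  co <- c(object@beta0, object@betaG, object@betaE, object@betaI)
  if (length(co) != 4L || !all(is.finite(co)))
    msg <- c(msg, "all coefficients must be finite scalars")
  if (length(object@maf) != 1L || is.na(object@maf) ||
      object@maf <= 0 || object@maf > 0.5)
    msg <- c(msg, "maf must lie in (0, 0.5]")
  if (object@nSamples < 1L) msg <- c(msg, "nSamples must be >= 1")
  if (object@nVariants < 1L) msg <- c(msg, "nVariants must be >= 1")
  if (object@nCausal < 0L || object@nCausal > object@nVariants)
    msg <- c(msg, "nCausal must lie in [0, nVariants]")
  if (length(msg)) msg else TRUE
})

#' @rdname SimulationParams-class
#' @param beta0,betaG,betaE,betaI generative-model coefficients (log-odds).
#' @param maf minor-allele frequency in (0, 0.5].
#' @param nSamples,nVariants,nCausal cohort dimensions.
#' @param seed integer root seed.
#' @return a `SimulationParams` object.
#' @export
SimulationParams <- function(beta0 = -0.32, betaG = 0.17, betaE = 0.97,
                             betaI = -0.875, maf = 0.49, nSamples = 783L,
                             nVariants = 1L, nCausal = 1L, seed = 1L) {
  new("SimulationParams", beta0 = beta0, betaG = betaG, betaE = betaE,
      betaI = betaI, maf = maf, nSamples = as.integer(nSamples),
      nVariants = as.integer(nVariants), nCausal = as.integer(nCausal),
      seed = as.integer(seed))
}

#' Variant quality-control thresholds
#'
#' Exclusion is strictly below each threshold: variants with MAF < `mafMin`,
#' call rate < `callRateMin`, HWE exact P < `hwePMin`, or imputation INFO <
#' `infoMin` are removed; values exactly at a threshold pass.
#'
#' @slot mafMin minimum minor-allele frequency (default 0.01).
#' @slot callRateMin minimum genotype call rate (default 0.90).
#' @slot hwePMin minimum Hardy-Weinberg exact-test P (default 1e-5).
#' @slot infoMin minimum imputation quality score (default 0.9).
#' @exportClass QCThresholds
setClass("QCThresholds",
  representation(mafMin = "numeric", callRateMin = "numeric",
                 hwePMin = "numeric", infoMin = "numeric"))

setValidity("QCThresholds", function(object) {
  v <- c(object@mafMin, object@callRateMin, object@hwePMin, object@infoMin)
  if (length(v) != 4L || any(is.na(v)) || any(v < 0) || any(v > 1))
    "all thresholds must lie in [0, 1]" else TRUE
})

#' @rdname QCThresholds-class
#' @param mafMin,callRateMin,hwePMin,infoMin thresholds in `[0, 1]`.
#' @return a `QCThresholds` object.
#' @export
QCThresholds <- function(mafMin = 0.01, callRateMin = 0.90,
                         hwePMin = 1e-5, infoMin = 0.9) {
  new("QCThresholds", mafMin = mafMin, callRateMin = callRateMin,
      hwePMin = hwePMin, infoMin = infoMin)
}

#' Two-stage filtering criteria
#'
#' Discovery suggestive threshold, replication nominal threshold,
#' genome-wide joint threshold, and the direction-concordance gate
#' applied before weighted Z-score joint analysis.
#'
#' @slot pDiscoveryMax discovery suggestive threshold (default 1e-5).
#' @slot pReplicationMax replication nominal threshold (default 0.05).
#' @slot pJointMax genome-wide significance threshold (default 5e-8).
#' @slot requireConcordance require equal interaction-effect signs in both
#'   stages (default TRUE).
#' @exportClass FilterCriteria
setClass("FilterCriteria",
  representation(pDiscoveryMax = "numeric", pReplicationMax = "numeric",
                 pJointMax = "numeric", requireConcordance = "logical"))

setValidity("FilterCriteria", function(object) {
  v <- c(object@pDiscoveryMax, object@pReplicationMax, object@pJointMax)
  if (length(v) != 3L || any(is.na(v)) || any(v <= 0) || any(v >= 1))
    return("all P thresholds must lie in (0, 1)")
  if (length(object@requireConcordance) != 1L ||
      is.na(object@requireConcordance))
    return("requireConcordance must be TRUE or FALSE")
  TRUE
})

#' @rdname FilterCriteria-class
#' @param pDiscoveryMax,pReplicationMax,pJointMax P-value thresholds in
#'   (0, 1).
#' @param requireConcordance logical flag.
#' @return a `FilterCriteria` object.
#' @export
FilterCriteria <- function(pDiscoveryMax = 1e-5, pReplicationMax = 0.05,
                           pJointMax = 5e-8, requireConcordance = TRUE) {
  new("FilterCriteria", pDiscoveryMax = pDiscoveryMax,
      pReplicationMax = pReplicationMax, pJointMax = pJointMax,
      requireConcordance = requireConcordance)
}

#' Empirical power-simulation parameters
#'
#' Configuration of the empirical G-by-E power calculation for a binary
#' outcome: cohorts of `nSamples` are simulated repeatedly under
#' [SimulationParams()] coefficients for each interaction effect in
#' `betaIGrid`, the interaction model (G, E, G:E, no covariates) is
#' fitted, and power is the fraction of converged fits with interaction
#' P below `alpha`. Defaults reproduce the published configuration:
#' n = 783, MAF 0.49, grid -1.00 to -0.75 by 0.05, alpha 5e-8, 10,000
#' replicates.
#'
#' @slot sim a [SimulationParams-class] carrying beta0/betaG/betaE/maf and
#'   nSamples (betaI is overridden by the grid).
#' @slot betaIGrid interaction log-ORs to evaluate.
#' @slot alpha significance level in (0, 1).
#' @slot nReps simulation replicates per grid point.
#' @slot seed root RNG seed.
#' @exportClass PowerParams
setClass("PowerParams",
  representation(sim = "SimulationParams", betaIGrid = "numeric",
                 alpha = "numeric", nReps = "integer", seed = "integer"))

setValidity("PowerParams", function(object) {
  msg <- character(0)
  if (length(object@betaIGrid) < 1L || !all(is.finite(object@betaIGrid)))
    msg <- c(msg, "betaIGrid must be a non-empty finite vector")
  if (length(object@alpha) != 1L || is.na(object@alpha) ||
      object@alpha <= 0 || object@alpha >= 1)
    msg <- c(msg, "alpha must lie in (0, 1)")
  if (object@nReps < 1L) msg <- c(msg, "nReps must be >= 1")
  if (length(msg)) msg else TRUE
})

#' @rdname PowerParams-class
#' @param sim a [SimulationParams-class] object.
#' @param betaIGrid grid of interaction log-ORs.
#' @param alpha significance level.
#' @param nReps replicates per grid point.
#' @param seed integer root seed.
#' @return a `PowerParams` object.
#' @export
PowerParams <- function(sim = SimulationParams(),
                        betaIGrid = seq(-1, -0.75, by = 0.05),
                        alpha = 5e-8, nReps = 10000L, seed = 1L) {
  new("PowerParams", sim = sim, betaIGrid = betaIGrid, alpha = alpha,
      nReps = as.integer(nReps), seed = as.integer(seed))
}
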