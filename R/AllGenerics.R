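#' @rdname GwisExperiment-class
#' @param x a `GwisExperiment`.
#' @export
setGeneric("dosages", function(x) standardGeneric("dosages"))

#' @rdname GwisExperiment-class
#' @export
setGeneric("stageLabel", function(x) standardGeneric("stageLabel"))

#' @rdname GwisExperiment-class
#' @param value replacement stage label.
#' @export
setGeneric("stageLabel<-", function(x, value) standardGeneric("stageLabel<-"))

#' @rdname GwisExperiment-class
#' @export
setMethod("dosages", "GwisExperiment", function(x) assay(x, "dosage"))

#' @rdname GwisExperiment-class
#' @export
setMethod("stageLabel", "GwisExperiment", function(x) metadata(x)$stage)

#' @rdname GwisExperiment-class
#' @export
setReplaceMethod("stageLabel", "GwisExperiment", function(x, value) {
  metadata(x)$stage <- value
  x
})

setMethod("show", "GwisExperiment", function(object) {
  d <- dosages(object)
  cat("GwisExperiment:", nrow(object), "variants x", ncol(object),
      "samples\n")
  st <- stageLabel(object)
  if (!is.na(st)) cat("  stage:", st, "\n")
  miss <- mean(is.na(d))
  cat(sprintf("  missing calls: %.2f%%\n", 100 * miss))
  cd <- colData(object)
  if ("outcome" %in% colnames(cd))
    cat("  outcome: ", sum(cd$outcome == 1, na.rm = TRUE), " cases / ",
        sum(cd$outcome == 0, na.rm = TRUE), " controls\n", sep = "")
  cat("  colData:", paste(colnames(cd), collapse = ", "), "\n")
})

setMethod("show", "SimulationParams", function(object) {
  cat("SimulationParams\n")
  cat(sprintf(
    "  logit P(Y=1) = %.3g %+.3g*G %+.3g*E %+.3g*G*E\n",
    object@beta0, object@betaG, object@betaE, object@betaI))
  cat(sprintf("  maf = %.3g, n = %d, variants = %d (causal %d), seed = %d\n",
              object@maf, object@nSamples, object@nVariants,
              object@nCausal, object@seed))
})

setMethod("show", "QCThresholds", function(object) {
  cat("QCThresholds (exclusion strictly below threshold)\n")
  cat(sprintf("  MAF >= %g, call rate >= %g, HWE P >= %g, INFO >= %g\n",
              object@mafMin, object@callRateMin, object@hwePMin,
              object@infoMin))
})

setMethod("show", "FilterCriteria", function(object) {
  cat("FilterCriteria\n")
  cat(sprintf("  discovery P < %g, replication P < %g, joint P < %g\n",
              object@pDiscoveryMax, object@pReplicationMax,
              object@pJointMax))
  cat("  direction concordance:",
      if (object@requireConcordance) "required" else "not required", "\n")
})

setMethod("show", "PowerParams", function(object) {
  cat("PowerParams\n")
  show(object@sim)
  cat(sprintf("  betaI grid: %s\n",
              paste(format(object@betaIGrid), collapse = ", ")))
  cat(sprintf("  alpha = %g, reps = %d, seed = %d\n", object@alpha,
              object@nReps, object@seed))
})
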