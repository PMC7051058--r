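#' Simulate Hardy-Weinberg genotype dosages
#'
#' Each variant's genotypes are the sum of two independent Bernoulli(maf)
#' allele draws, i.e. Binomial(2, maf), which is exactly Hardy-Weinberg
#' equilibrium with genotype class probabilities (p^2, 2pq, q^2).
#'
#' @param nSamples number of samples (columns).
#' @param maf per-variant counted-allele frequency, each in (0, 1); values
#'   above 0.5 are permitted here (the frequency is folded downstream).
#' @param seed integer seed; draws come from the dedicated "genotypes"
#'   stream so other simulation components are unaffected.
#' @return integer matrix, `length(maf)` variants x `nSamples` samples,
#'   entries in `{0, 1, 2}`.
#' @examples
#' g <- simulateGenotypes(1000, maf = 0.49, seed = 7)
#' mean(g) / 2   # close to 0.49
#' @export
simulateGenotypes <- function(nSamples, maf, seed = 1L) {
  if (length(nSamples) != 1L || is.na(nSamples) || nSamples < 1)
    stop("nSamples must be a positive integer")
  if (length(maf) < 1L || any(is.na(maf)) || any(maf <= 0) || any(maf >= 1))
    stop("each maf must lie strictly within (0, 1)")
  .withStream(seed, "genotypes", {
    g <- matrix(rbinom(length(maf) * nSamples, size = 2L,
                       prob = rep(maf, each = nSamples)),
                nrow = length(maf), ncol = nSamples, byrow = TRUE)
  })
  rownames(g) <- sprintf("snp%05d", seq_along(maf))
  colnames(g) <- sprintf("sample%05d", seq_len(nSamples))
  g
}

#' Simulate the standard-normal exposure
#'
#' The exposure plays the role of quantile-normalised age: i.i.d. draws
#' from Normal(0, 1).
#'
#' @inheritParams simulateGenotypes
#' @return numeric vector of length `nSamples`.
#' @export
simulateExposure <- function(nSamples, seed = 1L) {
  if (length(nSamples) != 1L || is.na(nSamples) || nSamples < 1)
    stop("nSamples must be a positive integer")
  .withStream(seed, "exposure", rnorm(nSamples))
}

#' Simulate the binary outcome under the logistic G-by-E model
#'
#' Draws `Y ~ Bernoulli(expit(beta0 + betaG*G + betaE*E + betaI*G*E))`
#' per sample.
#'
#' @param genotypes dosage vector (one variant).
#' @param exposure exposure vector, same length.
#' @param params a [SimulationParams-class] supplying the coefficients.
#' @param seed integer seed ("outcome" stream).
#' @return integer 0/1 vector.
#' @export
simulateOutcome <- function(genotypes, exposure, params = SimulationParams(),
                            seed = 1L) {
  if (length(genotypes) != length(exposure))
    stop("genotypes and exposure must have the same length")
  eta <- params@beta0 + params@betaG * genotypes + params@betaE * exposure +
    params@betaI * genotypes * exposure
  .withStream(seed, "outcome", rbinom(length(eta), 1L, plogis(eta)))
}

#' Simulate a full cohort
#'
#' Generates a [GwisExperiment-class]: HWE genotypes at `params@maf` for
#' `params@nVariants` variants, a standard-normal exposure, independent
#' covariates (sex ~ Bernoulli(0.5); BMI ~ Normal(26, 4^2); study label
#' uniform over `nStudies` levels), and a binary outcome in which only the
#' first `params@nCausal` variants contribute: for each causal variant j,
#' `betaG*G_j + betaI*G_j*E` enters the linear predictor (with one causal
#' variant this is exactly the single-SNP generative model); non-causal
#' variants are null. A raw `age` column is derived as a fixed monotone
#' (right-skewed, log-normal) map of the exposure so that rank-based
#' transformation of age recovers the exposure's ranks.
#'
#' @param params a [SimulationParams-class].
#' @param stage `"discovery"` or `"replication"` label.
#' @param nStudies number of study levels for the `study` covariate.
#' @return a [GwisExperiment-class] with `causal` flagged in `rowData()`.
#' @examples
#' co <- simulateCohort(SimulationParams(nSamples = 200, nVariants = 5))
#' co
#' @export
simulateCohort <- function(params = SimulationParams(),
                           stage = "discovery", nStudies = 2L) {
  validObject(params)
  n <- params@nSamples
  m <- params@nVariants
  g <- simulateGenotypes(n, rep(params@maf, m), seed = params@seed)
  e <- simulateExposure(n, seed = params@seed)
  causal <- seq_len(m) <= params@nCausal
  eta <- params@beta0 + params@betaE * e
  for (j in which(causal))
    eta <- eta + params@betaG * g[j, ] + params@betaI * g[j, ] * e
  y <- .withStream(params@seed, "outcome", rbinom(n, 1L, plogis(eta)))
  cov <- .withStream(params@seed, "covariates", {
    data.frame(
      sex = rbinom(n, 1L, 0.5),
      bmi = rnorm(n, 26, 4),
      study = paste0("S", sample.int(nStudies, n, replace = TRUE)))
  })
  # age: fixed monotone right-skewed map of the exposure (years)
  age <- round(exp(3.0 + 0.5 * e), 1)
  prefix <- substr(stage, 1, 4)
  samples <- DataFrame(
    sample_id = sprintf("%s%05d", prefix, seq_len(n)),
    outcome = y, age = age, exposure = e,
    sex = cov$sex, bmi = cov$bmi, study = cov$study)
  variants <- DataFrame(
    id = rownames(g), chrom = "1",
    pos = 10000L + 5000L * (seq_len(m) - 1L),
    major = "A", minor = "G", info = 1.0, causal = causal)
  colnames(g) <- samples$sample_id
  GwisExperiment(g, variants = variants, samples = samples, stage = stage)
}

#' Simulate a two-stage discovery/replication study
#'
#' Two independent cohorts with the published default sample sizes
#' (discovery n = 783, replication n = 538). With `concordant = FALSE`
#' the causal interaction sign is flipped in the replication stage to
#' exercise the direction-concordance gate.
#'
#' @param paramsDisc discovery [SimulationParams-class].
#' @param paramsRep replication parameters; by default the discovery
#'   parameters with `nSamples = 538` and an independent derived seed.
#' @param concordant if `FALSE`, `betaI` is negated in the replication
#'   cohort.
#' @return named list with elements `discovery` and `replication`.
#' @export
simulateTwoStageStudy <- function(paramsDisc = SimulationParams(),
                                  paramsRep = NULL, concordant = TRUE) {
  validObject(paramsDisc)
  if (is.null(paramsRep)) {
    paramsRep <- paramsDisc
    paramsRep@nSamples <- 538L
    paramsRep@seed <- .streamSeed(paramsDisc@seed, "replication")
  }
  validObject(paramsRep)
  if (!isTRUE(concordant)) paramsRep@betaI <- -paramsRep@betaI
  list(discovery = simulateCohort(paramsDisc, stage = "discovery"),
       replication = simulateCohort(paramsRep, stage = "replication"))
}

#' Mask genotype calls at random
#'
#' Sets a uniformly random fraction `rate` of dosage entries to `NA`,
#' emulating ungenotyped calls so the call-rate filter has a target.
#'
#' @param x a [GwisExperiment-class] or a dosage matrix.
#' @param rate expected masked fraction, in `[0, 1)`.
#' @param seed integer seed ("missingness" stream).
#' @return object of the same type with masked entries.
#' @export
injectMissingness <- function(x, rate, seed = 1L) {
  if (length(rate) != 1L || is.na(rate) || rate < 0 || rate >= 1)
    stop("rate must lie in [0, 1)")
  d <- if (is(x, "GwisExperiment")) dosages(x) else as.matrix(x)
  if (rate > 0) {
    mask <- .withStream(seed, "missingness",
                        runif(length(d)) < rate)
    d[mask] <- NA
  }
  if (is(x, "GwisExperiment")) {
    assay(x, "dosage") <- d
    metadata(x)$missingness_rate <- rate
    x
  } else d
}
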