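#' Rank-based inverse-normal (quantile-normalised) transform
#'
#' Maps values to standard-normal quantiles via Blom offsets:
#' `qnorm((rank - 3/8) / (n + 1/4))`, with average ranks for ties. Used to
#' tame skew and outliers in the raw age distribution before it enters the
#' interaction model.
#'
#' @param values finite numeric vector.
#' @return transformed vector, rank-preserving, approximately N(0, 1).
#' @examples
#' inverseNormalTransform(c(5, 10, 15))
#' @export
inverseNormalTransform <- function(values) {
  if (length(values) < 1L || any(!is.finite(values)))
    stop("values must be finite and non-empty")
  n <- length(values)
  qnorm((rank(values, ties.method = "average") - 0.375) / (n + 0.25))
}

# Expand a covariate data.frame/matrix into a full-rank numeric matrix:
# numeric columns pass through, character/factor columns are one-hot
# encoded with the first level as reference.
.covariateMatrix <- function(covariates, n) {
  if (is.null(covariates)) return(matrix(numeric(0), nrow = n, ncol = 0))
  covariates <- as.data.frame(covariates)
  cols <- list()
  for (nm in names(covariates)) {
    v <- covariates[[nm]]
    if (is.numeric(v) || is.logical(v)) {
      cols[[nm]] <- as.numeric(v)
    } else {
      f <- factor(v)
      for (lv in levels(f)[-1])
        cols[[paste0(nm, lv)]] <- as.numeric(f == lv)
    }
  }
  out <- do.call(cbind, cols)
  if (is.null(out)) matrix(numeric(0), nrow = n, ncol = 0) else out
}

.fitResultRow <- function(fit, nUsed, id = NA_character_) {
  z975 <- .z975()
  conv <- isTRUE(fit$converged)
  b <- fit$beta
  se <- fit$se
  data.frame(
    id = id,
    beta_int = b[4], se = se[4], or_int = exp(b[4]),
    ci_low = exp(b[4] - z975 * se[4]), ci_high = exp(b[4] + z975 * se[4]),
    p = 2 * pnorm(-abs(b[4] / se[4])),
    beta_g = b[2], beta_e = b[3],
    n_used = nUsed, converged = conv,
    stringsAsFactors = FALSE)
}

#' Fit one logistic interaction model
#'
#' Maximum-likelihood logistic regression of a binary outcome on genotype
#' dosage, exposure, their product, and optional covariates, fitted by
#' iteratively reweighted least squares. Inference on the interaction term
#' is Wald: `z = beta_int / se`, `p = 2 (1 - Phi(|z|))`, 95% CI
#' `exp(beta_int +/- 1.96 se)`. Samples with any missing value are dropped
#' (complete-case). Quasi-complete separation (any |beta| > 15) or
#' non-convergence yields `converged = FALSE` with estimates flagged, and
#' a rank-deficient design (e.g. constant dosage) yields `NA` estimates.
#'
#' @param outcome 0/1 vector.
#' @param dosage genotype dosage vector in `[0, 2]`.
#' @param exposure exposure vector (transformed scale).
#' @param covariates optional data.frame/matrix of adjustment covariates;
#'   character/factor columns are one-hot encoded, first level reference.
#' @param maxit,tol IRLS iteration cap and relative deviance tolerance.
#' @return one-row `data.frame`: `beta_int`, `se`, `or_int`, `ci_low`,
#'   `ci_high`, `p`, `beta_g`, `beta_e`, `n_used`, `converged`.
#' @export
fitInteractionModel <- function(outcome, dosage, exposure,
                                covariates = NULL, maxit = 25L,
                                tol = 1e-8) {
  n <- length(outcome)
  if (length(dosage) != n || length(exposure) != n)
    stop("outcome, dosage and exposure must have equal length")
  C <- .covariateMatrix(covariates, n)
  if (nrow(C) != n) stop("covariates must have one row per sample")
  keep <- complete.cases(outcome, dosage, exposure, C)
  y <- outcome[keep]
  g <- dosage[keep]
  e <- exposure[keep]
  C <- C[keep, , drop = FALSE]
  if (length(unique(y)) < 2L)
    stop("degenerate outcome: both classes required among complete cases")
  X <- cbind(1, g, e, g * e, C)
  fit <- .Call_logisticIrls(X, y, maxit = maxit, tol = tol)
  .fitResultRow(fit, sum(keep))
}

#' Genome-wide interaction scan
#'
#' Fits the interaction model of [fitInteractionModel()] at every variant
#' of a [GwisExperiment-class]. The exposure is `colData(x)$exposure` when
#' present, otherwise the rank-based inverse-normal transform of
#' `colData(x)$age` computed within this cohort (stages are transformed
#' separately). Samples with missing phenotype/covariates are dropped once;
#' missing dosages are dropped per variant. Non-converged variants are
#' retained with `converged = FALSE`.
#'
#' @param x a [GwisExperiment-class] with `outcome` (and `exposure` or
#'   `age`) in `colData()`.
#' @param covariates character vector of `colData()` column names to adjust
#'   for; `NULL` selects the conventional set present in the data: sex,
#'   bmi, study and PC1..PC6.
#' @param maxit,tol IRLS controls.
#' @return `data.frame` with one row per variant: `chrom`, `pos`, `id`,
#'   `major`, `minor`, `maf`, `n`, `beta_int`, `se`, `or`, `ci_low`,
#'   `ci_high`, `p`, `converged`.
#' @export
runGwis <- function(x, covariates = NULL, maxit = 25L, tol = 1e-8) {
  stopifnot(is(x, "GwisExperiment"))
  cd <- colData(x)
  if (!"outcome" %in% colnames(cd)) .dataError("colData lacks 'outcome'")
  if (is.null(covariates))
    covariates <- intersect(c("sex", "bmi", "study", paste0("PC", 1:6)),
                            colnames(cd))
  missing <- setdiff(covariates, colnames(cd))
  if (length(missing))
    .dataError(paste("covariates not in colData:",
                     paste(missing, collapse = ", ")))
  expo <- if ("exposure" %in% colnames(cd)) cd$exposure
          else if ("age" %in% colnames(cd))
            inverseNormalTransform(cd$age)
          else .dataError("colData lacks 'exposure' and 'age'")

  C <- .covariateMatrix(as.data.frame(cd[, covariates, drop = FALSE]),
                        ncol(x))
  keep <- complete.cases(cd$outcome, expo, C)
  d <- dosages(x)[, keep, drop = FALSE]
  y <- as.numeric(cd$outcome[keep])
  e <- expo[keep]
  C <- C[keep, , drop = FALSE]

  scan <- .Call_gwisScan(d, y, e, C, maxit = maxit, tol = tol)
  z975 <- .z975()
  rd <- rowData(x)
  gdf <- function(col, default) if (col %in% colnames(rd)) rd[[col]]
                                else default
  maf <- apply(d, 1, function(v) {
    if (all(is.na(v))) NA_real_ else {
      f <- mean(v, na.rm = TRUE) / 2
      min(f, 1 - f)
    }
  })
  data.frame(
    chrom = gdf("chrom", NA_character_),
    pos = gdf("pos", NA_integer_),
    id = gdf("id", rownames(d)),
    major = gdf("major", NA_character_),
    minor = gdf("minor", NA_character_),
    maf = maf,
    n = scan[, "n_used"],
    beta_int = scan[, "beta_int"],
    se = scan[, "se_int"],
    or = exp(scan[, "beta_int"]),
    ci_low = exp(scan[, "beta_int"] - z975 * scan[, "se_int"]),
    ci_high = exp(scan[, "beta_int"] + z975 * scan[, "se_int"]),
    p = 2 * pnorm(-abs(scan[, "beta_int"] / scan[, "se_int"])),
    converged = scan[, "converged"] == 1,
    stringsAsFactors = FALSE, row.names = NULL)
}

#' Reconstruct a Wald P value from an odds ratio and its 95% CI
#'
#' `se = (ln ciHigh - ln ciLow) / (2 * 1.96)`;
#' `p = 2 (1 - Phi(|ln OR| / se))`. Useful for checking published
#' interaction tables where only OR and CI are printed.
#'
#' @param orValue odds ratio (> 0).
#' @param ciLow,ciHigh 95% confidence bounds with
#'   `0 < ciLow <= orValue <= ciHigh`.
#' @return two-sided P value (vectorised).
#' @examples
#' waldPFromOrCi(2.33, 1.61, 3.38)  # approx 7.8e-6
#' @export
waldPFromOrCi <- function(orValue, ciLow, ciHigh) {
  if (any(ciLow <= 0) || any(ciLow > orValue) || any(orValue > ciHigh))
    stop("require 0 < ciLow <= orValue <= ciHigh")
  se <- (log(ciHigh) - log(ciLow)) / (2 * .z975())
  z <- ifelse(se == 0, ifelse(orValue == 1, 0, Inf), abs(log(orValue)) / se)
  2 * pnorm(-z)
}

#' Genomic inflation factor lambda
#'
#' Median of the observed 1-df chi-square statistics implied by the P
#' values, divided by the null median `qchisq(0.5, 1) = 0.4549`. Values
#' near 1 indicate no inflation from stratification or model
#' misspecification.
#'
#' @param pValues vector of two-sided P values in (0, 1].
#' @return scalar lambda.
#' @export
genomicLambda <- function(pValues) {
  pValues <- pValues[!is.na(pValues)]
  if (length(pValues) < 2L) stop("need at least two P values")
  if (any(pValues <= 0) || any(pValues > 1))
    stop("P values must lie in (0, 1]")
  chisq <- qchisq(pValues, df = 1, lower.tail = FALSE)
  median(chisq) / qchisq(0.5, df = 1)
}

#' Quantile-quantile plot coordinates
#'
#' Expected vs observed -log10 P under the uniform null, ready for
#' plotting.
#'
#' @inheritParams genomicLambda
#' @return `data.frame` with columns `expected` and `observed`, sorted.
#' @export
qqCoordinates <- function(pValues) {
  pValues <- sort(pValues[!is.na(pValues)])
  data.frame(expected = -log10(ppoints(length(pValues))),
             observed = -log10(pValues))
}
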