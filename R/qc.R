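#' Minor-allele frequency of a dosage vector
#'
#' `min(f, 1 - f)` with `f = mean(dosage) / 2` over non-missing entries
#' (folded frequency of the counted allele).
#'
#' @param dosages numeric dosage vector in `[0, 2]`, `NA` = missing.
#' @return frequency in `[0, 0.5]`.
#' @examples
#' computeMaf(c(0, 0, 1, 1, 2))   # 0.4
#' computeMaf(c(2, 2, 2, 1))      # 0.125 (folded)
#' @export
computeMaf <- function(dosages) {
  ok <- !is.na(dosages)
  if (!any(ok)) stop("undefined frequency: all dosages are missing")
  f <- mean(dosages[ok]) / 2
  min(f, 1 - f)
}

#' Genotype call rate
#'
#' @inheritParams computeMaf
#' @return fraction of non-missing entries, in `[0, 1]`.
#' @export
callRate <- function(dosages) {
  if (length(dosages) < 1L) stop("empty dosage vector")
  mean(!is.na(dosages))
}

# Exact distribution of the heterozygote count given fixed allele counts,
# via the standard up/down recurrence from the modal configuration.
# Returns list(het = attainable het counts, prob = their probabilities).
.hweHetDistribution <- function(nRef, nAlt) {
  rare <- min(nRef, nAlt)
  if (rare == 0L) return(list(het = 0L, prob = 1))
  n2 <- nRef + nAlt
  hets <- seq.int(rare %% 2L, rare, by = 2L)
  # start at (approximately) the modal het count with the right parity
  mode <- round(nRef * (nAlt / n2))
  if (mode %% 2L != rare %% 2L) mode <- mode + 1L
  mode <- min(max(mode, rare %% 2L), rare)
  prob <- numeric(length(hets))
  i0 <- match(mode, hets)
  prob[i0] <- 1
  # downward: P(h-2)/P(h) = h(h-1) / (4 (homR+1)(homA+1))
  h <- mode
  if (i0 > 1L) for (i in (i0 - 1L):1L) {
    homR <- (nRef - h) / 2
    homA <- (nAlt - h) / 2
    prob[i] <- prob[i + 1L] * h * (h - 1) / (4 * (homR + 1) * (homA + 1))
    h <- h - 2L
  }
  # upward: P(h+2)/P(h) = 4 homR homA / ((h+1)(h+2))
  h <- mode
  if (i0 < length(hets)) for (i in (i0 + 1L):length(hets)) {
    homR <- (nRef - h) / 2
    homA <- (nAlt - h) / 2
    prob[i] <- prob[i - 1L] * 4 * homR * homA / ((h + 1) * (h + 2))
    h <- h + 2L
  }
  list(het = hets, prob = prob / sum(prob))
}

#' Hardy-Weinberg exact test
#'
#' Exact two-sided test of Hardy-Weinberg genotype proportions: all
#' heterozygote counts consistent with the observed allele counts are
#' enumerated (by a numerically stable recurrence from the modal
#' configuration), and the P value is the sum of probabilities of
#' configurations no more probable than the observed one. No mid-P
#' correction is applied.
#'
#' @param nHomRef,nHet,nHomAlt genotype class counts (non-negative,
#'   total >= 1).
#' @return exact two-sided P value in (0, 1].
#' @examples
#' hweExactTest(25, 50, 25)  # balanced: P = 1 region
#' hweExactTest(2, 2, 1)
#' @export
hweExactTest <- function(nHomRef, nHet, nHomAlt) {
  counts <- c(nHomRef, nHet, nHomAlt)
  if (length(counts) != 3L || any(is.na(counts)) || any(counts < 0))
    stop("genotype counts must be non-negative")
  if (sum(counts) < 1) stop("at least one genotype is required")
  nRef <- 2L * as.integer(nHomRef) + as.integer(nHet)
  nAlt <- 2L * as.integer(nHomAlt) + as.integer(nHet)
  d <- .hweHetDistribution(nRef, nAlt)
  pObs <- d$prob[match(as.integer(nHet), d$het)]
  min(1, sum(d$prob[d$prob <= pObs * (1 + 1e-10)]))
}

#' Apply variant quality-control filters
#'
#' Retains exactly the variants with MAF >= `mafMin`, call rate >=
#' `callRateMin`, HWE exact P >= `hwePMin` and INFO >= `infoMin`
#' (exclusion is strictly below each threshold). HWE is computed on all
#' samples from hard calls (dosage rounded to the nearest integer). The
#' INFO rule uses `rowData(x)$info` (or `infoScores`); if no scores are
#' available at all, the rule is skipped (directly typed genotypes), while
#' an individually missing score excludes that variant with rule
#' `"info_missing"`.
#'
#' @param x a [GwisExperiment-class].
#' @param thresholds a [QCThresholds-class].
#' @param infoScores optional per-variant imputation quality scores,
#'   overriding `rowData(x)$info`.
#' @return list with `experiment` (filtered [GwisExperiment-class]),
#'   `report` (per-variant `data.frame`: id, maf, call_rate, hwe_p, info,
#'   pass, rules_failed), and `summary` (named counts: `n_input`, `n_pass`,
#'   and per-rule exclusions attributed sequentially in the order maf,
#'   call_rate, hwe, info, info_missing).
#' @export
applyQC <- function(x, thresholds = QCThresholds(), infoScores = NULL) {
  stopifnot(is(x, "GwisExperiment"))
  validObject(thresholds)
  d <- dosages(x)
  m <- nrow(d)
  if (is.null(infoScores) && "info" %in% colnames(rowData(x)))
    infoScores <- rowData(x)$info
  haveInfo <- !is.null(infoScores)

  cr <- rowMeans(!is.na(d))
  f <- rowMeans(d, na.rm = TRUE) / 2
  maf <- pmin(f, 1 - f)
  maf[cr == 0] <- NA

  hard <- round(d)
  hweP <- vapply(seq_len(m), function(j) {
    h <- hard[j, ]
    h <- h[!is.na(h)]
    if (!length(h)) return(NA_real_)
    hweExactTest(sum(h == 0), sum(h == 1), sum(h == 2))
  }, numeric(1))

  rules <- vector("list", m)
  for (j in seq_len(m)) {
    r <- character(0)
    if (is.na(maf[j]) || maf[j] < thresholds@mafMin) r <- c(r, "maf")
    if (cr[j] < thresholds@callRateMin) r <- c(r, "call_rate")
    if (is.na(hweP[j]) || hweP[j] < thresholds@hwePMin) r <- c(r, "hwe")
    if (haveInfo) {
      if (is.na(infoScores[j])) r <- c(r, "info_missing")
      else if (infoScores[j] < thresholds@infoMin) r <- c(r, "info")
    }
    rules[[j]] <- r
  }
  pass <- lengths(rules) == 0L
  first <- vapply(rules, function(r) if (length(r)) r[1] else NA_character_,
                  character(1))
  ruleOrder <- c("maf", "call_rate", "hwe", "info", "info_missing")
  excl <- vapply(ruleOrder, function(r) sum(first == r, na.rm = TRUE),
                 numeric(1))

  report <- data.frame(
    id = rowData(x)$id, maf = maf, call_rate = cr, hwe_p = hweP,
    info = if (haveInfo) infoScores else NA_real_, pass = pass,
    rules_failed = vapply(rules, paste, character(1), collapse = ","),
    stringsAsFactors = FALSE)
  summary <- c(n_input = m, n_pass = sum(pass), excl)
  list(experiment = x[pass, ], report = report, summary = summary)
}

#' Principal-component covariates from genotypes
#'
#' Standardises each variant on its non-missing entries (centred at `2f`,
#' scaled by `sqrt(2 f (1 - f))`, missing values mean-imputed to zero
#' after centring; monomorphic variants dropped) and returns the leading
#' `k` per-sample principal-component scores, ordered by decreasing
#' explained variance. Samples farther than 6 SD from the mean on any
#' returned component are flagged in the `"outlier"` attribute.
#'
#' @param x a [GwisExperiment-class] or a variants x samples dosage matrix.
#' @param k number of components (reduced with a warning if it exceeds the
#'   attainable rank).
#' @return samples x k score matrix with columns `PC1..PCk` and attributes
#'   `"varExplained"` (fraction per returned component) and `"outlier"`
#'   (logical per sample).
#' @export
pcaCovariates <- function(x, k = 6L) {
  d <- if (is(x, "GwisExperiment")) dosages(x) else as.matrix(x)
  f <- rowMeans(d, na.rm = TRUE) / 2
  keep <- !is.na(f) & f > 0 & f < 1
  d <- d[keep, , drop = FALSE]
  f <- f[keep]
  s <- (d - 2 * f) / sqrt(2 * f * (1 - f))
  s[is.na(s)] <- 0
  maxk <- min(dim(s))
  if (k > maxk) {
    warning("k reduced to attainable rank ", maxk)
    k <- maxk
  }
  sv <- svd(t(s), nu = k, nv = 0)
  scores <- sv$u %*% diag(sv$d[seq_len(k)], nrow = k)
  colnames(scores) <- paste0("PC", seq_len(k))
  rownames(scores) <- colnames(d)
  ve <- sv$d^2 / sum(sv$d^2)
  attr(scores, "varExplained") <- ve[seq_len(k)]
  zs <- scale(scores)
  attr(scores, "outlier") <- apply(abs(zs) > 6, 1, any)
  scores
}

#' Add PCA covariates to a GwisExperiment
#'
#' Convenience wrapper around [pcaCovariates()] writing `PC1..PCk` into
#' `colData(x)`.
#'
#' @inheritParams pcaCovariates
#' @return the input with PC columns added.
#' @export
addPcaCovariates <- function(x, k = 6L) {
  stopifnot(is(x, "GwisExperiment"))
  pcs <- pcaCovariates(x, k = k)
  for (j in seq_len(ncol(pcs))) colData(x)[[colnames(pcs)[j]]] <- pcs[, j]
  x
}
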