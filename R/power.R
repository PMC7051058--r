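#' Empirical power for a G-by-E interaction at one effect size
#'
#' Simulates `nReps` independent cohorts under the logistic generative
#' model (genotypes Binomial(2, maf), standard-normal exposure, outcome
#' from `beta0 + betaG*G + betaE*E + betaI*G*E`), fits the unadjusted
#' interaction model (intercept, G, E, G:E) to each, and reports the
#' fraction of converged fits whose interaction Wald P falls below
#' `alpha`. Non-converged replicates are excluded from the denominator
#' and counted in `n_failed_fits`.
#'
#' @param params a [PowerParams-class]; its `sim` slot supplies beta0,
#'   betaG, betaE, maf and nSamples.
#' @param betaI interaction log-OR for this run.
#' @param nReps,alpha,seed optional overrides of the corresponding
#'   `params` slots.
#' @return one-row `data.frame`: `betaI`, `power`, `mc_se`
#'   (`sqrt(p(1-p)/n)`), `n_failed_fits`, `n_reps`.
#' @examples
#' pp <- PowerParams(nReps = 200, alpha = 0.05)
#' estimatePower(pp, betaI = 0)
#' @export
estimatePower <- function(params, betaI, nReps = NULL, alpha = NULL,
                          seed = NULL) {
  validObject(params)
  sim <- params@sim
  n <- sim@nSamples
  if (is.null(nReps)) nReps <- params@nReps
  if (is.null(alpha)) alpha <- params@alpha
  if (is.null(seed)) seed <- params@seed
  set.seed(.streamSeed(seed, "power"))
  reject <- 0L
  failed <- 0L
  for (r in seq_len(nReps)) {
    g <- rbinom(n, 2L, sim@maf)
    e <- rnorm(n)
    eta <- sim@beta0 + sim@betaG * g + sim@betaE * e + betaI * g * e
    y <- rbinom(n, 1L, plogis(eta))
    if (length(unique(y)) < 2L) {
      failed <- failed + 1L
      next
    }
    X <- cbind(1, g, e, g * e)
    fit <- .Call_logisticIrls(X, y)
    if (!isTRUE(fit$converged)) {
      failed <- failed + 1L
      next
    }
    pInt <- 2 * pnorm(-abs(fit$beta[4] / fit$se[4]))
    if (pInt < alpha) reject <- reject + 1L
  }
  nConv <- nReps - failed
  if (nConv == 0L) stop("all replicate fits failed")
  pw <- reject / nConv
  data.frame(betaI = betaI, power = pw,
             mc_se = sqrt(pw * (1 - pw) / nConv),
             n_failed_fits = failed, n_reps = nReps)
}

#' Empirical power over a grid of interaction effects
#'
#' Runs [estimatePower()] at every value of `params@betaIGrid`, each grid
#' point on its own derived RNG stream so the table is reproducible and
#' insensitive to grid order. The default grid covers betaI from -1.00 to
#' -0.75 in steps of 0.05 (6 points).
#'
#' @param params a [PowerParams-class].
#' @return `data.frame` with one row per grid point (columns as in
#'   [estimatePower()]).
#' @export
powerGrid <- function(params) {
  validObject(params)
  rows <- lapply(seq_along(params@betaIGrid), function(i) {
    estimatePower(params, betaI = params@betaIGrid[i],
                  seed = .streamSeed(params@seed,
                                     sprintf("grid%.6f",
                                             params@betaIGrid[i])))
  })
  do.call(rbind, rows)
}
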