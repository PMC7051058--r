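#' Signed Z from a two-sided P value
#'
#' `z = direction * qnorm(1 - p/2)`, evaluated on the log scale for very
#' small P to avoid underflow. The direction carries the sign of the
#' interaction effect estimate.
#'
#' @param pTwoSided two-sided P values in (0, 1].
#' @param direction +1 or -1 per value.
#' @return signed normal deviates (vectorised).
#' @examples
#' signedZFromP(0.05, 1)   # 1.959964
#' @export
signedZFromP <- function(pTwoSided, direction) {
  if (any(is.na(pTwoSided)) || any(pTwoSided <= 0) || any(pTwoSided > 1))
    stop("P values must lie in (0, 1]")
  if (!all(direction %in% c(-1, 1)))
    stop("direction must be -1 or +1")
  z <- ifelse(pTwoSided < 1e-300,
              qnorm(log(pTwoSided) - log(2), lower.tail = FALSE,
                    log.p = TRUE),
              qnorm(pTwoSided / 2, lower.tail = FALSE))
  direction * z
}

#' Sample-size-weighted Z-score (Stouffer) combination
#'
#' Combines per-stage two-sided P values with effect directions into a
#' joint statistic `z = sum(w_i z_i) / sqrt(sum(w_i^2))` with weights
#' `w_i = sqrt(n_i)` (the standard sample-size-weighted convention), and
#' a two-sided joint P `2 (1 - Phi(|z|))`.
#'
#' @param p vector of per-stage two-sided P values in (0, 1].
#' @param direction per-stage effect signs (+1/-1).
#' @param n per-stage sample sizes (> 0).
#' @return list with elements `z` and `p`.
#' @examples
#' weightedZCombine(c(0.05, 0.05), c(1, 1), c(100, 100))
#' @export
weightedZCombine <- function(p, direction, n) {
  if (length(p) < 1L) stop("at least one stage is required")
  if (length(direction) != length(p) || length(n) != length(p))
    stop("p, direction and n must have equal length")
  if (any(is.na(n)) || any(n <= 0)) stop("stage sizes must be positive")
  z <- signedZFromP(p, direction)
  w <- sqrt(n)
  zj <- sum(w * z) / sqrt(sum(w^2))
  list(z = zj, p = 2 * pnorm(-abs(zj)))
}

#' Two-stage discovery/replication filtering and joint analysis
#'
#' Implements the filtering pipeline: keep variants with discovery P below
#' the suggestive threshold, replication P below the nominal threshold,
#' and (by default) concordant interaction-effect directions; then combine
#' the retained stage P values with the sample-size-weighted Z-score
#' method and flag joint genome-wide significance. Variants flagged
#' non-converged in either stage, or absent from either stage, are not
#' eligible. When both tables carry `major`/`minor` columns, variants with
#' mismatched allele orientation are dropped with a warning.
#'
#' @param disc,rep summary-statistic tables as returned by [runGwis()]
#'   (minimally: `id`, `beta_int`, `p`; optionally `n`, `converged`,
#'   `major`, `minor`).
#' @param criteria a [FilterCriteria-class].
#' @param nDisc,nRep fallback stage sample sizes when the tables carry no
#'   `n` column (defaults 783 and 538).
#' @return `data.frame`, one row per variant passing the stage filters,
#'   ordered by joint P: `id`, `p_disc`, `p_rep`, `sign_disc`, `sign_rep`,
#'   `concordant`, `z_joint`, `p_joint`, `pass_joint`, `n_disc`, `n_rep`.
#' @export
runTwoStage <- function(disc, rep, criteria = FilterCriteria(),
                        nDisc = 783, nRep = 538) {
  validObject(criteria)
  need <- c("id", "beta_int", "p")
  for (tab in list(disc, rep))
    if (!all(need %in% names(tab)))
      .dataError("stage tables need columns id, beta_int, p")
  dn <- if ("n" %in% names(disc)) disc$n else base::rep(nDisc, nrow(disc))
  rn <- if ("n" %in% names(rep)) rep$n else base::rep(nRep, nrow(rep))
  dok <- if ("converged" %in% names(disc)) disc$converged
         else base::rep(TRUE, nrow(disc))
  rok <- if ("converged" %in% names(rep)) rep$converged
         else base::rep(TRUE, nrow(rep))

  i <- match(rep$id, disc$id)
  shared <- which(!is.na(i))
  di <- i[shared]

  if (all(c("major", "minor") %in% names(disc)) &&
      all(c("major", "minor") %in% names(rep))) {
    okOrient <- disc$major[di] == rep$major[shared] &
      disc$minor[di] == rep$minor[shared]
    okOrient[is.na(okOrient)] <- TRUE
    if (any(!okOrient))
      warning(sum(!okOrient), " variant(s) dropped: allele orientation ",
              "mismatch between stages")
    shared <- shared[okOrient]
    di <- di[okOrient]
  }

  pd <- disc$p[di]
  pr <- rep$p[shared]
  sd_ <- ifelse(disc$beta_int[di] >= 0, 1, -1)
  sr <- ifelse(rep$beta_int[shared] >= 0, 1, -1)
  conc <- sd_ == sr
  eligible <- (dok[di] & rok[shared] & !is.na(pd) & !is.na(pr) &
                 pd < criteria@pDiscoveryMax & pr < criteria@pReplicationMax)
  if (criteria@requireConcordance) eligible <- eligible & conc
  shared <- shared[eligible]
  di <- di[eligible]
  pd <- pd[eligible]
  pr <- pr[eligible]
  sd_ <- sd_[eligible]
  sr <- sr[eligible]
  conc <- conc[eligible]

  zj <- pj <- numeric(length(shared))
  for (k in seq_along(shared)) {
    cmb <- weightedZCombine(c(pd[k], pr[k]), c(sd_[k], sr[k]),
                            c(dn[di[k]], rn[shared[k]]))
    zj[k] <- cmb$z
    pj[k] <- cmb$p
  }
  out <- data.frame(
    id = rep$id[shared], p_disc = pd, p_rep = pr,
    sign_disc = sd_, sign_rep = sr, concordant = conc,
    z_joint = zj, p_joint = pj,
    pass_joint = pj < criteria@pJointMax,
    n_disc = dn[di], n_rep = rn[shared],
    stringsAsFactors = FALSE)
  out[order(out$p_joint), , drop = FALSE]
}
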