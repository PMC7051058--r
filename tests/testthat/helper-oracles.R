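# Independent oracles used across the suite. These deliberately take
# different numerical routes than the package implementation.

# HWE exact test by direct log-factorial enumeration of every heterozygote
# count compatible with the observed allele counts.
oracleHweP <- function(nHomRef, nHet, nHomAlt) {
  n <- nHomRef + nHet + nHomAlt
  nRef <- 2 * nHomRef + nHet
  nAlt <- 2 * nHomAlt + nHet
  rare <- min(nRef, nAlt)
  hets <- seq(rare %% 2, rare, by = 2)
  lp <- vapply(hets, function(h) {
    homR <- (nRef - h) / 2
    homA <- (nAlt - h) / 2
    lfactorial(n) - lfactorial(homR) - lfactorial(h) - lfactorial(homA) +
      h * log(2) + lfactorial(nRef) + lfactorial(nAlt) -
      lfactorial(nRef + nAlt)
  }, numeric(1))
  pr <- exp(lp - max(lp))
  pr <- pr / sum(pr)
  pObs <- pr[match(nHet, hets)]
  min(1, sum(pr[pr <= pObs * (1 + 1e-10)]))
}

# Direct maximum-likelihood logistic regression via quasi-Newton
# optimisation of the log-likelihood (no IRLS).
oracleLogisticML <- function(X, y) {
  nll <- function(b) {
    eta <- drop(X %*% b)
    sum(log1p(exp(-(2 * y - 1) * eta)))
  }
  gr <- function(b) {
    mu <- plogis(drop(X %*% b))
    -drop(crossprod(X, y - mu))
  }
  fit <- optim(rep(0, ncol(X)), nll, gr, method = "BFGS",
               control = list(maxit = 2000, reltol = 1e-16))
  fit$par
}

# Signed-Z via root finding on the two-sided tail identity, avoiding
# qnorm on the half-P directly.
oracleSignedZ <- function(p, direction) {
  z <- uniroot(function(z) 2 * pnorm(-z) - p, c(0, 50), tol = 1e-14)$root
  direction * z
}

# Analytic Wald-approximation power for the unadjusted G x E interaction
# model: expected per-observation information from numerical integration
# over G ~ Binom(2, maf) (HWE) and E ~ N(0, 1), then a normal
# approximation to the Wald test with non-centrality
# betaI / sqrt((I^-1)_{44} / n).
oracleAnalyticPower <- function(beta0, betaG, betaE, betaI, maf, n, alpha) {
  pg <- c((1 - maf)^2, 2 * maf * (1 - maf), maf^2)
  egrid <- seq(-8, 8, by = 0.005)
  we <- dnorm(egrid) * 0.005
  info <- matrix(0, 4, 4)
  for (g in 0:2) {
    x <- rbind(1, g, egrid, g * egrid)
    mu <- plogis(beta0 + betaG * g + betaE * egrid + betaI * g * egrid)
    w <- mu * (1 - mu) * we * pg[g + 1]
    info <- info + x %*% (t(x) * w)
  }
  seInf <- sqrt(solve(info)[4, 4] / n)
  ncp <- betaI / seInf
  zc <- qnorm(1 - alpha / 2)
  pnorm(-zc - ncp) + pnorm(-zc + ncp)
}

# A fixed 12-sample hand dataset for coefficient-level comparisons.
handDataset <- function() {
  list(
    y = c(0, 1, 0, 1, 1, 0, 1, 0, 1, 1, 0, 0),
    g = c(0, 1, 2, 1, 0, 2, 1, 0, 2, 1, 0, 1),
    e = c(-1.2, 0.3, 0.8, -0.5, 1.5, -0.9, 0.1, 0.7, -1.8, 0.4,
          1.1, -0.2))
}
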