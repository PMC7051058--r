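test_that("MAF and call rate follow the hand-count definitions", {
  expect_equal(computeMaf(c(0, 0, 1, 1, 2)), 0.4)
  expect_equal(computeMaf(rep(0, 8)), 0)
  expect_equal(computeMaf(c(2, 2, 2, 1)), 0.125)   # folded to the minor
  expect_equal(computeMaf(c(NA, 0, 2)), 0.5)
  expect_error(computeMaf(c(NA, NA)), "missing")

  expect_equal(callRate(c(0, 1, 2)), 1)
  expect_equal(callRate(c(NA, rep(1, 9))), 0.9)
  expect_equal(callRate(c(NA, NA)), 0)
  expect_error(callRate(numeric(0)), "empty")
})

test_that("HWE exact test agrees with full enumeration", {
  # monomorphic: a single attainable configuration
  expect_equal(hweExactTest(10, 0, 0), 1)
  expect_equal(hweExactTest(0, 0, 7), 1)

  # (2, 2, 1): 6 ref / 4 alt alleles, het in {0, 2, 4}
  expect_equal(hweExactTest(2, 2, 1), oracleHweP(2, 2, 1), tolerance = 1e-12)

  # all triples with total <= 20, absolute agreement to 1e-12
  for (n in 1:20)
    for (nHet in 0:n)
      for (nHomAlt in 0:(n - nHet)) {
        nHomRef <- n - nHet - nHomAlt
        expect_equal(hweExactTest(nHomRef, nHet, nHomAlt),
                     oracleHweP(nHomRef, nHet, nHomAlt),
                     tolerance = 1e-12)
      }

  expect_error(hweExactTest(-1, 2, 3), "non-negative")
  expect_error(hweExactTest(0, 0, 0), "at least one")
})

test_that("HWE heterozygote distribution is normalised", {
  set.seed(99)
  for (i in 1:25) {
    counts <- sample(0:50, 3, replace = TRUE)
    if (sum(counts) == 0) counts[1] <- 1
    nRef <- 2 * counts[1] + counts[2]
    nAlt <- 2 * counts[3] + counts[2]
    d <- ageGWIS:::.hweHetDistribution(nRef, nAlt)
    expect_equal(sum(d$prob), 1, tolerance = 1e-12)
    expect_true(all(d$prob >= 0))
  }
})

test_that("HWE null rejection at P < 1e-5 is conservative", {
  n <- 1000
  tested <- 0L
  reject <- 0L
  for (maf in c(0.05, 0.25, 0.49)) {
    set.seed(round(1000 * maf))
    for (r in 1:400) {
      g <- rbinom(n, 2, maf)
      p <- hweExactTest(sum(g == 0), sum(g == 1), sum(g == 2))
      tested <- tested + 1L
      if (p < 1e-5) reject <- reject + 1L
    }
  }
  expect_lte(reject / tested, 0.001)
})

buildQcFixture <- function() {
  # five variants engineered to violate one rule each, plus one clean
  n <- 400
  set.seed(7)
  clean <- rbinom(n, 2, 0.3)
  lowMaf <- rbinom(n, 2, 0.002)          # MAF below 1%
  lowCall <- rbinom(n, 2, 0.3)
  lowCall[seq_len(0.2 * n)] <- NA        # call rate 0.8
  hweBad <- rep(1, n)                    # all-heterozygote: HWE P tiny
  lowInfo <- rbinom(n, 2, 0.3)           # INFO below 0.9
  d <- rbind(clean = clean, lowMaf = lowMaf, lowCall = lowCall,
             hweBad = hweBad, lowInfo = lowInfo)
  GwisExperiment(d, variants = S4Vectors::DataFrame(
    id = rownames(d), chrom = "1", pos = 1:5 * 100L,
    major = "A", minor = "G",
    info = c(1, 1, 1, 1, 0.5)))
}

test_that("applyQC attributes each exclusion to the right rule", {
  x <- buildQcFixture()
  qc <- applyQC(x)
  expect_identical(unname(qc$summary["n_input"]), 5)
  expect_identical(unname(qc$summary["n_pass"]), 1)
  expect_identical(rownames(dosages(qc$experiment)), "clean")
  rep <- qc$report
  expect_identical(rep$rules_failed[rep$id == "lowMaf"], "maf")
  expect_identical(rep$rules_failed[rep$id == "lowCall"], "call_rate")
  expect_identical(rep$rules_failed[rep$id == "hweBad"], "hwe")
  expect_identical(rep$rules_failed[rep$id == "lowInfo"], "info")
  # sequential accounting: passes plus first-rule exclusions cover input
  expect_equal(unname(qc$summary["n_pass"] +
                        sum(qc$summary[c("maf", "call_rate", "hwe",
                                         "info", "info_missing")])),
               unname(qc$summary["n_input"]))
})

test_that("applyQC threshold semantics are strictly-below and idempotent", {
  x <- buildQcFixture()
  # all-zero thresholds keep every variant with at least one call
  qc0 <- applyQC(x, QCThresholds(mafMin = 0, callRateMin = 0,
                                 hwePMin = 0, infoMin = 0))
  expect_identical(nrow(qc0$experiment), nrow(x))

  # value exactly at the threshold passes: call rate exactly 0.9
  n <- 400
  set.seed(8)
  d <- rbind(v1 = c(rep(NA, 40), rbinom(n - 40, 2, 0.3)))
  ge <- GwisExperiment(d)
  qc <- applyQC(ge, QCThresholds(callRateMin = 0.9, mafMin = 0,
                                 hwePMin = 0, infoMin = 0))
  expect_identical(unname(qc$summary["n_pass"]), 1)

  # idempotence: a second pass removes nothing
  qc1 <- applyQC(x)
  qc2 <- applyQC(qc1$experiment)
  expect_identical(nrow(qc2$experiment), nrow(qc1$experiment))
})

test_that("applyQC exclusions are invariant to variant order", {
  x <- buildQcFixture()
  perm <- c(4, 2, 5, 1, 3)
  qc1 <- applyQC(x)
  qc2 <- applyQC(x[perm, ])
  expect_identical(sort(qc1$report$id[qc1$report$pass]),
                   sort(qc2$report$id[qc2$report$pass]))
  expect_identical(qc1$summary[order(names(qc1$summary))],
                   qc2$summary[order(names(qc2$summary))])
})

test_that("missing INFO scores exclude the variant with a named rule", {
  x <- buildQcFixture()
  rowData(x)$info[1] <- NA
  qc <- applyQC(x)
  expect_identical(qc$report$rules_failed[1], "info_missing")
  expect_identical(unname(qc$summary["n_pass"]), 0)
})

test_that("PCA separates planted subpopulations and is orthogonal", {
  set.seed(17)
  n <- 500
  m <- 2000
  lab <- rep(c(0, 1), each = n / 2)
  f1 <- runif(m, 0.1, 0.4)
  f2 <- pmin(f1 + 0.15, 0.95)
  d <- matrix(0, m, n)
  d[, lab == 0] <- rbinom(m * sum(lab == 0), 2, f1)
  d[, lab == 1] <- rbinom(m * sum(lab == 1), 2, f2)
  sc <- pcaCovariates(d, k = 4)

  side <- sc[, 1] > median(sc[, 1])
  acc <- max(mean(side == (lab == 1)), mean(side == (lab == 0)))
  expect_gte(acc, 0.95)

  gram <- crossprod(sc)
  off <- max(abs(gram[upper.tri(gram)]))
  expect_lt(off, 1e-8 * max(diag(gram)))

  ve <- attr(sc, "varExplained")
  expect_true(all(diff(ve) <= 1e-12))
})

test_that("PCA handles rank deficiency with a reduced-k warning", {
  base <- rbinom(50, 2, 0.5)
  d <- rbind(base, base, base)   # rank-1 after standardisation
  expect_warning(sc <- pcaCovariates(d, k = 5), "reduced")
  expect_lte(ncol(sc), 3)
  sc1 <- suppressWarnings(pcaCovariates(d, k = 1))
  expect_gte(attr(sc1, "varExplained")[1], 0.999)
})
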