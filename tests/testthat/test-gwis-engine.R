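test_that("inverse-normal transform matches Blom closed forms", {
  expect_equal(inverseNormalTransform(5), 0)
  z <- qnorm((3 - 0.375) / 3.25)
  expect_equal(inverseNormalTransform(c(5, 10, 15)), c(-z, 0, z))
  expect_equal(inverseNormalTransform(rep(4.2, 9)), rep(0, 9))
  expect_error(inverseNormalTransform(c(1, NA)), "finite")
  expect_error(inverseNormalTransform(c(1, Inf)), "finite")
})

test_that("inverse-normal transform is rank-preserving and idempotent", {
  set.seed(5)
  x <- rlnorm(200)
  t1 <- inverseNormalTransform(x)
  expect_identical(rank(t1), rank(x))
  expect_equal(inverseNormalTransform(t1), t1)
  expect_lt(abs(mean(t1)), 1e-10)
})

test_that("interaction fit matches a direct likelihood maximiser", {
  h <- handDataset()
  fit <- fitInteractionModel(h$y, h$g, h$e)
  X <- cbind(1, h$g, h$e, h$g * h$e)
  ml <- oracleLogisticML(X, h$y)
  expect_equal(fit$beta_g, ml[2], tolerance = 1e-6)
  expect_equal(fit$beta_e, ml[3], tolerance = 1e-6)
  expect_equal(fit$beta_int, ml[4], tolerance = 1e-6)
  expect_true(fit$converged)
  expect_identical(fit$n_used, 12L)

  # a batch of random small fixtures, against both the optimiser and glm
  set.seed(6)
  for (r in 1:10) {
    n <- 20
    g <- rbinom(n, 2, 0.4)
    e <- rnorm(n)
    y <- rbinom(n, 1, plogis(0.2 * g - 0.3 * e))
    f <- fitInteractionModel(y, g, e)
    if (!f$converged) next
    X <- cbind(1, g, e, g * e)
    expect_equal(unlist(f[c("beta_g", "beta_e", "beta_int")]),
                 setNames(oracleLogisticML(X, y)[2:4],
                          c("beta_g", "beta_e", "beta_int")),
                 tolerance = 1e-6)
    gl <- suppressWarnings(glm.fit(X, y, family = binomial()))
    expect_equal(f$beta_int, unname(gl$coefficients[4]), tolerance = 1e-6)
  }
})

test_that("interaction fit handles degenerate designs and outcomes", {
  set.seed(7)
  n <- 100
  e <- rnorm(n)
  y <- rbinom(n, 1, 0.5)
  # constant dosage: interaction inestimable, flagged not thrown
  f <- fitInteractionModel(y, rep(0, n), e)
  expect_false(f$converged)
  expect_true(is.na(f$beta_int))
  # one-class outcome is a hard error
  expect_error(fitInteractionModel(rep(1, n), rbinom(n, 2, 0.3), e),
               "degenerate")
  expect_error(fitInteractionModel(y, rbinom(5, 2, 0.3), e), "length")
})

test_that("interaction OR and CI are internally consistent", {
  set.seed(8)
  n <- 400
  g <- rbinom(n, 2, 0.4)
  e <- rnorm(n)
  y <- rbinom(n, 1, plogis(-0.2 + 0.4 * g * e))
  f <- fitInteractionModel(y, g, e,
                           covariates = data.frame(sex = rbinom(n, 1, 0.5)))
  expect_equal(f$or_int, exp(f$beta_int))
  expect_lte(f$ci_low, f$or_int)
  expect_gte(f$ci_high, f$or_int)
  expect_gt(f$p, 0)
  expect_lte(f$p, 1)
  # reconstruction round-trip through the OR/CI representation
  expect_equal(waldPFromOrCi(f$or_int, f$ci_low, f$ci_high), f$p,
               tolerance = 1e-10)
})

test_that("scan results are invariant to ordering and covariate encoding", {
  co <- simulateCohort(SimulationParams(nSamples = 250L, nVariants = 6L,
                                        nCausal = 1L, seed = 9L))
  r1 <- runGwis(co, covariates = c("sex", "bmi"))
  # sample order
  perm <- sample(ncol(co))
  r2 <- runGwis(co[, perm], covariates = c("sex", "bmi"))
  expect_equal(r1$beta_int, r2$beta_int, tolerance = 1e-10)
  # variant order
  vp <- c(4, 1, 6, 2, 5, 3)
  r3 <- runGwis(co[vp, ], covariates = c("sex", "bmi"))
  expect_equal(r3$beta_int, r1$beta_int[vp], tolerance = 1e-12)
  # affine re-encoding of a covariate leaves the interaction unchanged
  co2 <- co
  colData(co2)$bmi <- 10 * colData(co2)$bmi - 120
  r4 <- runGwis(co2, covariates = c("sex", "bmi"))
  expect_equal(r4$beta_int, r1$beta_int, tolerance = 1e-7)
})

test_that("null scan P values are uniform and planted signal wins", {
  # null calibration on a modest genome
  co <- simulateCohort(SimulationParams(nSamples = 800L, nVariants = 1000L,
                                        nCausal = 0L, seed = 10L))
  res <- runGwis(co, covariates = character(0))
  p <- res$p[res$converged]
  expect_gt(ks.test(p, "punif")$p.value, 0.001)

  # permuted outcomes: chance behaviour at the suggestive threshold
  runsClean <- 0L
  for (s in 1:100) {
    set.seed(s)
    cop <- co[sample(nrow(co), 200), ]
    colData(cop)$outcome <- sample(colData(cop)$outcome)
    rp <- runGwis(cop, covariates = character(0))
    if (!any(rp$p[rp$converged] < 1e-5)) runsClean <- runsClean + 1L
  }
  expect_gte(runsClean, 99L)

  # a strongly interacting variant attains the minimum P
  co2 <- simulateCohort(SimulationParams(nSamples = 5000L,
                                         nVariants = 30L, nCausal = 1L,
                                         betaI = -1, seed = 11L))
  res2 <- runGwis(co2, covariates = character(0))
  expect_identical(which.min(res2$p), 1L)
})

test_that("Wald P reconstruction from published OR and CI cells", {
  # top discovery interaction: OR 2.33 (1.61-3.38), printed P 7.08e-6
  p1 <- waldPFromOrCi(2.33, 1.61, 3.38)
  expect_lt(p1, 1e-5)
  expect_equal(p1, 7.8e-6, tolerance = 0.05)
  # replication cell OR 0.51 (0.34-0.77), printed P 1.49e-3
  p2 <- waldPFromOrCi(0.51, 0.34, 0.77)
  expect_lt(p2, 0.05)
  expect_equal(p2, 1.2e-3, tolerance = 0.05)
  # null effect
  expect_equal(waldPFromOrCi(1, 0.5, 2), 1)
  expect_error(waldPFromOrCi(2, 2.5, 3), "ciLow")
})

test_that("genomic lambda behaves as an inflation measure", {
  expect_equal(genomicLambda(rep(0.5, 10)), 1)
  set.seed(12)
  p <- runif(100000)
  lam <- genomicLambda(p)
  expect_gt(lam, 0.98)
  expect_lt(lam, 1.02)
  expect_gt(genomicLambda(p / 2), lam)
  expect_error(genomicLambda(c(0, 0.5)), "0, 1")

  qq <- qqCoordinates(p[1:100])
  expect_identical(nrow(qq), 100L)
  expect_true(all(diff(qq$observed) <= 0))
})

test_that("interaction CI covers a zero interaction at the nominal rate", {
  set.seed(13)
  n <- 783
  cover <- 0L
  reps <- 400
  for (r in seq_len(reps)) {
    g <- rbinom(n, 2, 0.49)
    e <- rnorm(n)
    y <- rbinom(n, 1, plogis(-0.32 + 0.17 * g + 0.97 * e))
    f <- fitInteractionModel(y, g, e)
    if (f$converged && f$ci_low <= 1 && f$ci_high >= 1)
      cover <- cover + 1L
  }
  expect_gt(cover / reps, 0.92)
  expect_lt(cover / reps, 0.985)
})
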