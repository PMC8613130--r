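test_that("the linear covariate generator hits its population moments", {
  set.seed(101)
  d <- studyDesign(1, J = 50000, n = 10)
  dat <- genCovariatesLinear(d)
  x <- dat$data$x; z <- dat$data$z
  ci <- as.integer(dat$cluster)
  expect_lt(abs(var(x) - 1), 0.01)
  expect_lt(abs(var(z) - 1), 0.02)   # only J level-2 draws
  expect_lt(abs(cor(x, z) - 0.20), 0.01)
  ## ICC via the balanced variance decomposition
  xb <- rowsum(x, ci)[, 1] / 10
  msw <- sum((x - xb[ci])^2) / (length(x) - 50000)
  s2b <- (10 * var(xb) - msw) / 10
  expect_lt(abs(s2b / (s2b + msw) - 0.20), 0.01)

  ## degenerate case: ICC 1 makes x constant within clusters
  d1 <- studyDesign(1, J = 50, n = 4, iccX = 1)
  dat1 <- genCovariatesLinear(d1)
  rng <- tapply(dat1$data$x, dat1$cluster, function(v) diff(range(v)))
  expect_true(all(rng == 0))
})

test_that("the quadratic covariate generator is centered with unit variance", {
  set.seed(102)
  d <- studyDesign(3, J = 200000, n = 1, w = 0.5)
  dat <- genCovariatesQuadratic(d)
  expect_lt(abs(mean(dat$data$x)), 0.01)
  expect_lt(abs(var(dat$data$x) - 1), 0.015)
})

test_that("outcome generation respects the target ICC of y", {
  set.seed(103)
  d <- studyDesign(1, J = 20000, n = 10)
  calib <- calibrateOutcomeVariances(d)
  expect_equal(calib$tau0sq, 0.0664, tolerance = 1e-10)  # closed form
  expect_equal(calib$sigma2, 0.56, tolerance = 1e-10)
  dat <- genOutcome(d, genCovariatesLinear(d), calib)
  y <- dat$data$y; ci <- as.integer(dat$cluster)
  expect_lt(abs(var(y) - 1), 0.02)
  yb <- rowsum(y, ci)[, 1] / 10
  msw <- sum((y - yb[ci])^2) / (length(y) - 20000)
  s2b <- (10 * var(yb) - msw) / 10
  expect_lt(abs(s2b / (s2b + msw) - 0.20), 0.015)

  ## all effects null and a vanishing ICC give (almost) pure level-1 noise
  d0 <- studyDesign(1, J = 2000, n = 10, iccY = 0.001, tau1sq = 0,
                    betas = c("(Intercept)" = 0, x = 0, z = 0, "x:z" = 0))
  dat0 <- genOutcome(d0, genCovariatesLinear(d0))
  y0 <- dat0$data$y; ci0 <- as.integer(dat0$cluster)
  yb0 <- rowsum(y0, ci0)[, 1] / 10
  msw0 <- sum((y0 - yb0[ci0])^2) / (length(y0) - 2000)
  s2b0 <- (10 * var(yb0) - msw0) / 10
  expect_lt(abs(s2b0 / (s2b0 + msw0)), 0.01)

  ## an unattainable ICC is refused with the feasible range
  expect_error(
    calibrateOutcomeVariances(
      studyDesign(1, iccY = 0.95, iccX = 0.1, tau1sq = 0.1)),
    "infeasible")
})

test_that("complete-data ML recovers the generating coefficients at scale", {
  set.seed(104)
  for (study in 1:3) {
    d <- studyDesign(study, J = 1000, n = 20)
    dat <- genOutcome(d, genCovariates(d))
    f <- fitSubstantive(dat, substantiveModel(d))
    expect_true(f$converged)
    ## each coefficient within its own sampling error of the truth
    expect_true(all(abs(f$coefficients - d$betas) <
                      4 * sqrt(f$variances) + 0.01))
    expect_equal(f$Tmat[2, 2], d$tau1sq, tolerance = 0.3)
  }
})

test_that("missingness propensity produces the designed proportions", {
  set.seed(105)
  g <- rep(1:1000, each = 100)
  d <- multilevelData(data.frame(g = g, x = rnorm(1e5), y = rnorm(1e5)),
                      cluster = "g", levels = c(x = 1, y = 1))
  m50 <- induceMissing(d, "x", lambda0 = 0, lambda1 = 0)
  expect_equal(mean(missingMask(m50)[, "x"]), 0.5, tolerance = 0.01)
  expect_equal(missingnessProbability(0), 0.5)

  ## MAR: the deletion mask correlates positively with y
  m70 <- induceMissing(d, "x", lambda0 = 0, lambda1 = 0.7)
  expect_gt(cor(missingMask(m70)[, "x"], d$data$y), 0.1)
  ## y itself is never deleted
  expect_false(anyNA(m70$data$y))
  expect_error(induceMissing(d, "x", 0, 1.2), "lambda1")
})

test_that("the study harness reproduces CD/LD equivalence under MCAR", {
  d <- studyDesign(1, J = 60, n = 10, lambda1 = 0)
  m <- runStudy(d, strategies = c("CD", "LD"), reps = 12, seed = 301)
  expect_s3_class(m, "mlMetrics")
  expect_equal(attr(m, "failed"), 0L)
  for (par in c("x", "x:z")) {
    cd <- m[m$strategy == "CD" & m$parameter == par, ]
    ld <- m[m$strategy == "LD" & m$parameter == par, ]
    joint <- sqrt(cd$relBiasMCSE^2 + ld$relBiasMCSE^2)
    expect_lt(abs(cd$relBias - ld$relBias), 3 * joint)
    ## CD is unbiased within Monte Carlo error
    expect_lt(abs(cd$relBias), 3 * cd$relBiasMCSE)
  }
  ## deterministic given the base seed
  m2 <- runStudy(d, strategies = c("CD", "LD"), reps = 12, seed = 301)
  expect_equal(as.data.frame(m), as.data.frame(m2))
})

test_that("study-3 missingness keeps its target proportion under MAR", {
  set.seed(107)
  d <- studyDesign(3, J = 4000, n = 20, lambda1 = 0.7)
  calib <- calibrateOutcomeVariances(d)
  dat <- genOutcome(d, genCovariates(d), calib)
  inc <- induceMissing(dat, "x", effectiveLambda0(d, calib), 0.7)
  expect_lt(abs(mean(missingMask(inc)[, "x"]) - 0.30), 0.02)
})
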