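test_that("log densities match an independent normal-pdf oracle", {
  d <- toyData(J = 1, n = 1, seed = 3)
  spec <- modelSpec("y", terms = list(), intercept = TRUE)
  m <- normalLevel1Model(spec, beta = d$data$y[1], sigma2 = 1)
  expect_equal(loglikRows(m, d), -0.5 * log(2 * pi), tolerance = 1e-12)

  ## 5-row toy against a hand-rolled loop oracle
  d5 <- toyData(J = 1, n = 5, seed = 4)
  spec5 <- parseFormula("y ~ 1 + x + z")
  beta <- c(0.2, -0.5, 0.8)
  m5 <- normalLevel1Model(spec5, beta, sigma2 = 0.7)
  mu <- beta[1] + beta[2] * d5$data$x + beta[3] * d5$data$z
  expect_equal(loglikRows(m5, d5), normLogLik(d5$data$y, mu, 0.7),
               tolerance = 1e-12)

  ## symmetry in the residual
  dp <- d5; dp$data$y <- mu + 0.37
  dm <- d5; dm$data$y <- mu - 0.37
  expect_equal(loglikRows(m5, dp), loglikRows(m5, dm), tolerance = 1e-12)
})

test_that("log densities add over disjoint cluster selections", {
  d <- toyData(J = 6, n = 4, seed = 5)
  spec <- parseFormula("y ~ 1 + x + (1 | g)")
  m <- normalLevel1Model(spec, beta = c(0.1, 0.3), sigma2 = 0.9,
                         Tmat = matrix(0.2), u = matrix(rnorm(6), 6, 1))
  total <- loglikRows(m, d)
  parts <- sum(vapply(1:6, function(j) loglikRows(m, d, clusters = j), 0))
  expect_equal(total, parts, tolerance = 1e-12)

  ## level-2 model: one density per cluster
  spec2 <- parseFormula("z ~ 1", level = 2)
  m2 <- normalLevel2Model(spec2, gamma = 0, sigma2 = 1)
  expect_equal(loglikRows(m2, d),
               sum(vapply(1:6, function(j) loglikRows(m2, d, clusters = j), 0)),
               tolerance = 1e-12)
})

test_that("model constructors reject invalid variances and dimensions", {
  spec <- parseFormula("y ~ 1 + x")
  expect_error(normalLevel1Model(spec, c(0, 0), sigma2 = 0), "variance")
  expect_error(normalLevel1Model(spec, c(0, 0, 0), sigma2 = 1), "length")
  specr <- parseFormula("y ~ 1 + x + (1 + x | g)")
  expect_error(
    normalLevel1Model(specr, c(0, 0), 1,
                      Tmat = matrix(c(1, 2, 0, 1), 2), u = matrix(0, 3, 2)),
    "symmetric")
})

test_that("fixed-only Gibbs chain matches the conjugate posterior", {
  ## with no random part the beta/sigma2 updates are ordinary-regression
  ## conjugate draws; compare long-run moments with the analytic posterior
  set.seed(11)
  n <- 40
  g <- rep(1:8, each = 5)
  x <- rnorm(n)
  y <- 0.5 + 1.2 * x + rnorm(n, 0, 0.6)
  d <- multilevelData(data.frame(g = g, x = x, y = y), cluster = "g",
                      levels = c(x = 1, y = 1))
  spec <- parseFormula("y ~ 1 + x")
  pr <- defaultPriors()

  ## analytic posterior: beta | y ~ t around OLS; sigma2 ~ IG(a + (n-p)/2, b + RSS/2)
  X <- cbind(1, x)
  XtXinv <- solve(crossprod(X))
  bhat <- XtXinv %*% crossprod(X, y)
  rss <- sum((y - X %*% bhat)^2)
  aPost <- pr$sigma_a + (n - 2) / 2
  bPost <- pr$sigma_b + rss / 2
  es2 <- bPost / (aPost - 1)                    # E[sigma2]
  vbeta <- es2 * diag(XtXinv)                   # Var(beta_k) = E[sigma2] (X'X)^-1

  m <- normalLevel1Model(spec, beta = c(0, 0), sigma2 = 1)
  nd <- 20000L
  draws <- matrix(NA_real_, nd, 3)
  set.seed(22)
  for (t in seq_len(nd)) {
    m <- gibbsUpdateLevel1(m, d, pr)
    draws[t, ] <- c(m$beta, m$sigma2)
  }
  keep <- draws[-(1:500), ]
  nk <- nrow(keep)
  for (k in 1:2) {
    se <- sd(keep[, k]) / sqrt(nk / 10)  # conservative ESS
    expect_lt(abs(mean(keep[, k]) - bhat[k]), 4 * se)
    expect_lt(abs(var(keep[, k]) - vbeta[k]), 0.3 * vbeta[k])
  }
  se3 <- sd(keep[, 3]) / sqrt(nk / 10)
  expect_lt(abs(mean(keep[, 3]) - es2), 4 * se3)
})

test_that("level-2 updates concentrate on the exact solution and grand mean", {
  set.seed(33)
  J <- 40
  g <- rep(1:J, each = 2)
  zj <- rnorm(J)
  w <- 0.3 + 0.9 * zj          # zero-residual level-2 relation
  d <- multilevelData(data.frame(g = g, z = zj[g], w = w[g]), cluster = "g",
                      levels = c(z = 2, w = 2))
  spec <- parseFormula("w ~ 1 + z", level = 2)
  m <- normalLevel2Model(spec, gamma = c(0, 0), sigma2 = 1)
  for (t in 1:300) m <- gibbsUpdateLevel2(m, d)
  expect_lt(m$sigma2, 1e-3)
  expect_equal(unname(m$beta), c(0.3, 0.9), tolerance = 1e-2)

  ## intercept-only: posterior mean of gamma ~ grand mean over clusters
  spec0 <- parseFormula("w ~ 1", level = 2)
  m0 <- normalLevel2Model(spec0, gamma = 0, sigma2 = 1)
  acc <- 0
  set.seed(34)
  for (t in 1:2000) {
    m0 <- gibbsUpdateLevel2(m0, d)
    if (t > 200) acc <- acc + m0$beta
  }
  expect_equal(acc / 1800, mean(w), tolerance = 0.05)
})

test_that("the random-slope Gibbs sampler recovers generating parameters", {
  set.seed(55)
  J <- 200; n <- 20
  g <- rep(1:J, each = n)
  x <- rnorm(J * n)
  u0 <- rnorm(J, 0, sqrt(0.3))
  u1 <- rnorm(J, 0, sqrt(0.1))
  y <- 1 + 0.5 * x + u0[g] + u1[g] * x + rnorm(J * n, 0, sqrt(0.5))
  d <- multilevelData(data.frame(g = g, x = x, y = y), cluster = "g",
                      levels = c(x = 1, y = 1))
  spec <- parseFormula("y ~ 1 + x + (1 + x | g)")
  m <- normalLevel1Model(spec, beta = c(0, 0), sigma2 = 1,
                         Tmat = diag(0.5, 2), u = matrix(0, J, 2))
  nd <- 1200L
  sums <- numeric(5)
  set.seed(56)
  for (t in seq_len(nd)) {
    m <- gibbsUpdateLevel1(m, d)
    if (t > 200)
      sums <- sums + c(m$beta, m$sigma2, m$Tmat[1, 1], m$Tmat[2, 2])
  }
  post <- sums / (nd - 200)
  expect_equal(post[1], 1, tolerance = 0.1)     # intercept
  expect_equal(post[2], 0.5, tolerance = 0.06)  # slope
  expect_equal(post[3], 0.5, tolerance = 0.05)  # sigma2
  ## the realized random-effect variances of this dataset, not the
  ## population values, are what the posterior concentrates on
  expect_lt(abs(post[4] - var(u0)), 0.06)       # tau0^2
  expect_lt(abs(post[5] - var(u1)), 0.03)       # tau1^2
})

test_that("updates are bit-identical under the same seed", {
  d <- toyData(J = 5, n = 4, seed = 6)
  spec <- parseFormula("y ~ 1 + x + (1 | g)")
  m0 <- normalLevel1Model(spec, c(0, 0), 1, Tmat = matrix(0.2),
                          u = matrix(0, 5, 1))
  set.seed(99); m1 <- gibbsUpdateLevel1(m0, d)
  set.seed(99); m2 <- gibbsUpdateLevel1(m0, d)
  expect_identical(m1, m2)
})

test_that("singleton clusters are handled by the cluster-effect update", {
  set.seed(8)
  d <- multilevelData(
    data.frame(g = c(1, 1, 1, 2), x = rnorm(4), y = rnorm(4)),
    cluster = "g", levels = c(x = 1, y = 1))
  spec <- parseFormula("y ~ 1 + x + (1 | g)")
  m <- normalLevel1Model(spec, c(0, 0), 1, Tmat = matrix(0.3),
                         u = matrix(0, 2, 1))
  expect_silent(for (t in 1:20) m <- gibbsUpdateLevel1(m, d))
  expect_true(is.finite(loglikRows(m, d)))
})
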