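test_that("sequence validation enforces the triangular structure", {
  xmod <- parseFormula("x ~ 1 + z + (1 | g)")
  ymod <- parseFormula("y ~ 1 + x + z + (1 | g)")
  expect_silent(sequenceSpec(list(xmod, ymod), incomplete = "x"))

  ## a covariate model may not condition on a later covariate
  xmod2 <- parseFormula("x ~ 1 + w + (1 | g)")
  wmod <- parseFormula("w ~ 1 + (1 | g)")
  expect_error(sequenceSpec(list(xmod2, wmod, ymod), incomplete = "x"),
               "not earlier in the sequence")
  ## nor on the outcome
  xmod3 <- parseFormula("x ~ 1 + y + (1 | g)")
  expect_error(sequenceSpec(list(xmod3, ymod), incomplete = "x"),
               "not earlier")
  ## incomplete variables need a model
  expect_error(sequenceSpec(list(ymod), incomplete = c("x", "y")),
               "no conditional model")
  ## self-conditioning is rejected
  expect_error(sequenceSpec(list(parseFormula("x ~ 1 + cmean(x)"), ymod),
                            incomplete = "x"),
               "conditions on itself")
})

test_that("default ordering puts level 2 first, then ascending missingness", {
  set.seed(2)
  g <- rep(1:20, each = 4)
  d0 <- data.frame(g = g, a = rnorm(80), b = rnorm(80), w = rnorm(20)[g],
                   y = rnorm(80))
  d0$a[1:40] <- NA               # 50% missing
  d0$b[1:8] <- NA                # 10% missing
  d0$w[d0$g <= 4] <- NA          # level-2, 20% of clusters
  d <- multilevelData(d0, cluster = "g",
                      levels = c(a = 1, b = 1, w = 2, y = 1))
  ymod <- parseFormula("y ~ 1 + a + b + w + (1 | g)")
  covs <- list(
    a = parseFormula("a ~ 1 + w + b + (1 | g)"),
    b = parseFormula("b ~ 1 + w + (1 | g)"),
    w = parseFormula("w ~ 1", level = 2))
  seqn <- defaultSequence(d, ymod, covs)
  expect_equal(vapply(seqn$models, `[[`, "", "outcome"),
               c("w", "b", "a", "y"))
})

test_that("initialization fills only missing cells, reproducibly", {
  d <- toyData(J = 4, n = 5, seed = 9, missing = 6)
  set.seed(1); c1 <- initializeMissing(d)
  set.seed(1); c2 <- initializeMissing(d)
  expect_identical(c1, c2)
  obs <- !missingMask(d)[, "x"]
  expect_identical(c1$x[obs], d$data$x[obs])
  expect_false(anyNA(c1$x))
  ## complete data pass through untouched
  dc <- toyData(J = 2, n = 3, seed = 10)
  expect_identical(initializeMissing(dc), as.list(dc$data))
  ## an all-missing column cannot be initialized
  dbad <- dc
  dbad$data$x[] <- NA
  dbad$miss[, "x"] <- TRUE
  expect_error(initializeMissing(dbad), "no observed cells")
})

test_that("MH log ratio vanishes for the identity proposal and factorizes", {
  d <- toyData(J = 3, n = 4, seed = 12, missing = 4)
  comp <- initializeMissing(d)
  xmod <- normalLevel1Model(parseFormula("x ~ 1"), beta = 0.2, sigma2 = 1.1)
  ymod <- normalLevel1Model(parseFormula("y ~ 1 + z"), beta = c(0, 0.4),
                            sigma2 = 0.8)
  j <- unique(as.integer(d$cluster)[missingMask(d)[, "x"]])[1]
  rows <- which(as.integer(d$cluster) == j & missingMask(d)[, "x"])
  cur <- comp$x[rows]
  expect_equal(mhLogRatio(list(xmod, ymod), d, j, "x", cur, completed = comp),
               0, tolerance = 1e-12)

  ## x appears in no other model: ratio reduces to its own-model difference
  prop <- cur + 0.5
  lr <- mhLogRatio(list(xmod, ymod), d, j, "x", prop, completed = comp)
  own <- sum(dnorm(prop, 0.2, sqrt(1.1), log = TRUE)) -
    sum(dnorm(cur, 0.2, sqrt(1.1), log = TRUE))
  expect_equal(lr, own, tolerance = 1e-12)
})

test_that("MH log ratio matches a brute-force density product on a toy", {
  ## single cluster, two rows, one missing x cell; the outcome model uses
  ## the manifest cluster mean, which must be recomputed under the proposal
  d0 <- data.frame(g = c(1, 1), x = c(NA, 0.3), y = c(0.5, -0.2))
  d <- multilevelData(d0, cluster = "g", levels = c(x = 1, y = 1))
  comp <- list(x = c(0.1, 0.3), y = c(0.5, -0.2))
  xmod <- normalLevel1Model(parseFormula("x ~ 1"), beta = 0.1, sigma2 = 0.8)
  ymod <- normalLevel1Model(parseFormula("y ~ 1 + x + cmean(x)"),
                            beta = c(0, 0.6, 0.4), sigma2 = 0.5)
  v0 <- 0.1; v1 <- -0.7
  lr <- mhLogRatio(list(xmod, ymod), d, 1, "x", v1, completed = comp)

  dens <- function(v) {
    xx <- c(v, 0.3)
    mu <- 0 + 0.6 * xx + 0.4 * mean(xx)
    sum(dnorm(xx, 0.1, sqrt(0.8), log = TRUE)) +
      sum(dnorm(c(0.5, -0.2), mu, sqrt(0.5), log = TRUE))
  }
  expect_equal(lr, dens(v1) - dens(v0), tolerance = 1e-10)
})

test_that("cluster-level accept rule has the Metropolis acceptance law", {
  set.seed(77)
  expect_true(all(smcmi:::.mhAccept(c(0, 0.3, 5))))
  M <- 0.3
  acc <- mean(replicate(20000, smcmi:::.mhAccept(log(M))))
  se <- sqrt(M * (1 - M) / 20000)
  expect_lt(abs(acc - M), 3 * se)
})

test_that("proposal adaptation is monotone and frozen after burn-in", {
  s <- c(1, 1, 1)
  up <- adaptProposals(s, rates = c(1, 1, 1))
  dn <- adaptProposals(s, rates = c(0, 0, 0))
  expect_true(all(up > s))
  expect_true(all(dn < s))
  expect_warning(frozen <- adaptProposals(s, rates = c(1, 1, 1),
                                          frozen = TRUE),
                 "frozen")
  expect_identical(frozen, s)
})

test_that("a complete dataset passes through the engine unchanged", {
  d <- toyData(J = 4, n = 4, seed = 20)
  seqn <- sequenceSpec(list(parseFormula("x ~ 1 + z + (1 | g)"),
                            parseFormula("y ~ 1 + x + z + (1 | g)")),
                       incomplete = character())
  imp <- smcImpute(d, seqn, burnIn = 20, nBetween = 5, m = 3, seed = 1)
  expect_length(imp$imputations, 3L)
  for (k in 1:3)
    expect_identical(imp$imputations[[k]], as.data.frame(d$data))
})

test_that("runs are deterministic given the seed and never touch observed cells", {
  d <- toyData(J = 6, n = 5, seed = 21, missing = 8)
  seqn <- sequenceSpec(list(parseFormula("x ~ 1 + z + (1 | g)"),
                            parseFormula("y ~ 1 + x + z + (1 | g)")),
                       incomplete = "x")
  i1 <- smcImpute(d, seqn, burnIn = 100, nBetween = 10, m = 4, seed = 42)
  i2 <- smcImpute(d, seqn, burnIn = 100, nBetween = 10, m = 4, seed = 42)
  expect_identical(i1$imputations, i2$imputations)
  expect_identical(i1$chain, i2$chain)

  obs <- !missingMask(d)[, "x"]
  before <- d$data$x[obs]
  for (k in 1:4)
    expect_identical(i1$imputations[[k]]$x[obs], before)
  ## and all non-target columns stay bit-identical
  for (k in 1:4) {
    expect_identical(i1$imputations[[k]]$y, d$data$y)
    expect_identical(i1$imputations[[k]]$z, d$data$z)
  }
  expect_gt(i1$acceptance[["x"]], 0)
})

test_that("rhat matches the textbook formula and flags disjoint chains", {
  c1 <- c(1.0, 1.4, 0.8, 1.2, 0.9, 1.1)
  c2 <- c(0.7, 1.3, 1.0, 1.5, 0.8, 1.0)
  ## independent textbook-formula oracle
  nIt <- 6
  W <- (var(c1) + var(c2)) / 2
  B <- nIt * var(c(mean(c1), mean(c2)))
  oracle <- sqrt(((nIt - 1) / nIt * W + B / nIt) / W)
  expect_equal(rhat(list(c1, c2)), oracle, tolerance = 1e-10)

  expect_equal(rhat(list(c1, c1)), sqrt((nIt - 1) / nIt), tolerance = 1e-12)
  expect_gt(rhat(list(rnorm(50), rnorm(50) + 100)), 10)
  expect_error(rhat(list(c1)), "2")
  expect_error(rhat(list(c1, c2[-1])), "equal length")
})

test_that("level-2 missing variables are imputed constant within clusters", {
  set.seed(30)
  g <- rep(1:10, each = 3)
  w <- rnorm(10)[g]
  d0 <- data.frame(g = g, w = w, y = rnorm(30) + 0.5 * w)
  d0$w[d0$g <= 3] <- NA
  d <- multilevelData(d0, cluster = "g", levels = c(w = 2, y = 1))
  seqn <- sequenceSpec(list(parseFormula("w ~ 1", level = 2),
                            parseFormula("y ~ 1 + w + (1 | g)")),
                       incomplete = "w")
  imp <- smcImpute(d, seqn, burnIn = 100, nBetween = 10, m = 3, seed = 2)
  for (k in 1:3) {
    wk <- imp$imputations[[k]]$w
    expect_true(all(tapply(wk, g, function(v) diff(range(v)) == 0)))
  }
})
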