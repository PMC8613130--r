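#' Monte Carlo study designs
#'
#' Encodes the generating processes of the three simulation studies: a
#' random-coefficients model with conflated effects (study 1), a
#' cluster-mean-centered model with separate level-1/level-2 effects
#' (study 2), and a model with quadratic effects and a nonlinear
#' covariate-covariate association (study 3). The defaults are the studies'
#' own conditions: unit-variance variables, slope variance 0.10 with
#' uncorrelated random effects, Cor(x, z) = .20 for the linear generators,
#' total R2 of x on z = .50 for the quadratic generator, and a 30% missing
#' proportion driven by a latent propensity depending on y.
#'
#' @param study 1, 2 or 3.
#' @param n level-1 sample size per cluster.
#' @param J number of clusters.
#' @param iccX,iccY intraclass correlations of x and y, in (0, 1).
#' @param rhoXZ correlation of x and z (studies 1-2).
#' @param r2XZ total variance fraction of x explained by z (study 3).
#' @param w weight of the quadratic part of the x-z association, in [0, 1].
#' @param betas named coefficient vector of the substantive model; defaults
#'   to the study's values.
#' @param tau1sq random-slope variance.
#' @param lambda0 intercept of the missingness propensity (a standard-normal
#'   quantile: the marginal missing proportion is `pnorm(lambda0)`);
#'   defaults to the 30% quantile.
#' @param lambda1 effect of y on missingness (0 = MCAR), |lambda1| <= 1.
#' @param missingVar variable receiving missing cells.
#' @export
studyDesign <- function(study = 1L, n = NULL, J = NULL,
                        iccX = 0.2, iccY = 0.2, rhoXZ = 0.2,
                        r2XZ = 0.5, w = 0, betas = NULL, tau1sq = 0.1,
                        lambda0 = stats::qnorm(0.30), lambda1 = 0,
                        missingVar = "x") {
  study <- as.integer(study)
  stopifnot(study %in% 1:3, iccX > 0, iccX <= 1, iccY > 0, iccY < 1,
            w >= 0, w <= 1, r2XZ >= 0, r2XZ < 1)
  if (abs(lambda1) > 1) stop("|lambda1| must be <= 1")
  if (is.null(n)) n <- if (study == 3L) 20L else 10L
  if (is.null(J)) J <- if (study == 3L) 1000L else 200L
  if (is.null(betas)) {
    betas <- switch(study,
      c("(Intercept)" = 0, "x" = 0.40, "z" = 0.20, "x:z" = 0.20),
      c("(Intercept)" = 0, "wdev(x)" = 0.40, "cmean(x)" = 0, "z" = 0.20,
        "wdev(x):z" = 0.20, "cmean(x):z" = 0),
      c("(Intercept)" = 0, "x" = 0.15, "z" = 0.15, "x:z" = 0.15,
        "x^2" = 0.15, "z^2" = 0.15))
  }
  d <- structure(list(study = study, n = as.integer(n), J = as.integer(J),
                      iccX = iccX, iccY = iccY, rhoXZ = rhoXZ,
                      r2XZ = r2XZ, w = w, betas = betas, tau1sq = tau1sq,
                      lambda0 = lambda0, lambda1 = lambda1,
                      missingVar = missingVar),
                 class = "mlStudyDesign")
  nm <- coefNames(substantiveModel(d))
  if (!identical(names(betas), nm))
    stop("betas must be named ", paste(nm, collapse = ", "))
  d
}

#' @export
print.mlStudyDesign <- function(x, ...) {
  cat("Study", x$study, "design: J =", x$J, ", n =", x$n,
      ", ICC(x) =", x$iccX, ", ICC(y) =", x$iccY, "\n")
  cat("  substantive model:", renderFormula(substantiveModel(x)), "\n")
  cat("  missingness: lambda0 =", round(x$lambda0, 3),
      "lambda1 =", x$lambda1, "\n")
  invisible(x)
}

#' Substantive analysis model of a study design
#' @param design an `mlStudyDesign`.
#' @export
substantiveModel <- function(design) {
  parseFormula(switch(design$study,
    "y ~ 1 + x + z + x:z + (1 + x | cluster)",
    "y ~ 1 + wdev(x) + cmean(x) + z + wdev(x):z + cmean(x):z + (1 + wdev(x) | cluster)",
    "y ~ 1 + x + z + x:z + x^2 + z^2 + (1 + x | cluster)"))
}

#' Conditional imputation model for the incomplete covariate
#'
#' A multilevel normal model for x given z with a random intercept; for the
#' quadratic generator of study 3 the model also carries the quadratic
#' z term, mirroring the nonlinear covariate association.
#' @param design an `mlStudyDesign`.
#' @export
covariateModel <- function(design) {
  parseFormula(switch(design$study,
    "x ~ 1 + z + (1 | cluster)",
    "x ~ 1 + z + (1 | cluster)",
    "x ~ 1 + z + z^2 + (1 | cluster)"))
}

## ---------------------------------------------------------------------------
## covariate generators

.mlDataFromColumns <- function(cluster, cols, levels) {
  d <- data.frame(cluster = cluster, cols, check.names = FALSE)
  multilevelData(d, cluster = "cluster", levels = levels)
}

#' Generate x and z from the linear (bivariate-normal) process
#'
#' x is the sum of a level-2 component with variance `iccX` and a level-1
#' component with variance `1 - iccX`; z is standard normal at level 2; the
#' level-2 components are jointly normal with covariance chosen so that
#' Cor(x, z) = `rhoXZ`. All variables have unit total variance.
#'
#' @param design an `mlStudyDesign` (studies 1-2).
#' @return An `mlData` with variables x (level 1) and z (level 2).
#' @export
genCovariatesLinear <- function(design) {
  J <- design$J; n <- design$n
  v2 <- design$iccX
  if (v2 < design$rhoXZ^2)
    stop("infeasible: need iccX >= rhoXZ^2 for the level-2 covariance")
  z <- stats::rnorm(J)
  xL2 <- design$rhoXZ * z + stats::rnorm(J, 0, sqrt(v2 - design$rhoXZ^2))
  ci <- rep(seq_len(J), each = n)
  x <- xL2[ci] + stats::rnorm(J * n, 0, sqrt(1 - design$iccX))
  .mlDataFromColumns(ci, list(x = x, z = z[ci]), c(x = 1L, z = 2L))
}

#' Generate x and z from the quadratic process
#'
#' z is standard normal at level 2; the level-2 part of x is a quadratic
#' regression on z, `phi0 + phi1 z + phi2 z^2 + eps`, with the phi
#' coefficients calibrated so that x has mean zero, the linear and quadratic
#' parts contribute fractions (1 - w, w) of the total `r2XZ`, and the two
#' residual components (level-2 eps, level-1 part) are shrunk
#' proportionally from `iccX (1 - r2XZ)` and `(1 - iccX)` so that
#' Var(x) = 1. At w = 0 this gives Cor(x, z) = sqrt(r2XZ); at w = 1 the
#' association is purely quadratic and Cor(x, z) = 0.
#'
#' @param design an `mlStudyDesign` (study 3).
#' @return An `mlData` with variables x (level 1) and z (level 2).
#' @export
genCovariatesQuadratic <- function(design) {
  J <- design$J; n <- design$n
  ph <- .quadraticPhis(design)
  z <- stats::rnorm(J)
  xL2 <- ph$phi0 + ph$phi1 * z + ph$phi2 * z^2 +
    stats::rnorm(J, 0, sqrt(ph$varEps))
  ci <- rep(seq_len(J), each = n)
  x <- xL2[ci] + stats::rnorm(J * n, 0, sqrt(ph$varL1))
  .mlDataFromColumns(ci, list(x = x, z = z[ci]), c(x = 1L, z = 2L))
}

.quadraticPhis <- function(design) {
  r2 <- design$r2XZ; w <- design$w; iccX <- design$iccX
  phi1 <- sqrt((1 - w) * r2)
  phi2 <- sqrt(w * r2 / 2)     # Var(phi2 z^2) = 2 phi2^2
  phi0 <- -phi2                # E[x] = phi0 + phi2 = 0
  resid0 <- c(eps = iccX * (1 - r2), L1 = 1 - iccX)
  shrink <- (1 - r2) / sum(resid0)
  list(phi0 = phi0, phi1 = phi1, phi2 = phi2,
       varEps = resid0[["eps"]] * shrink, varL1 = resid0[["L1"]] * shrink)
}

#' Generate covariates according to the design's study
#' @param design an `mlStudyDesign`.
#' @export
genCovariates <- function(design) {
  if (design$study == 3L) genCovariatesQuadratic(design)
  else genCovariatesLinear(design)
}

## ---------------------------------------------------------------------------
## outcome generation with ICC calibration

#' Residual and random-intercept variances matching the target ICC of y
#'
#' Solves for (tau0^2, sigma^2) so that the generating model's unconditional
#' variance decomposition has total variance 1 and a between-cluster share
#' equal to `iccY`, given the fixed slope variance `tau1sq` and uncorrelated
#' random effects. Studies 1-2 use exact normal-moment formulas; study 3
#' evaluates the decomposition by a large fixed-seed Monte Carlo draw of the
#' cluster-level components (deterministic; the user's RNG stream is left
#' untouched). When the systematic between-cluster variance already exceeds
#' `iccY` (as in the quadratic design, where the covariate calibration pins
#' the x-z correlation), the ICC is kept as the binding target and the total
#' variance of y is allowed to exceed 1 instead, with `tau0sq = 0`.
#'
#' @param design an `mlStudyDesign`.
#' @return list with `tau0sq`, `sigma2`, and the systematic between/within
#'   variances `v2sys`, `v1sys`.
#' @export
calibrateOutcomeVariances <- function(design) {
  b <- design$betas
  iccX <- design$iccX; rho <- design$rhoXZ; t1 <- design$tau1sq
  if (design$study == 1L) {
    v2 <- b[["x"]]^2 * iccX + b[["z"]]^2 + 2 * b[["x"]] * b[["z"]] * rho +
      b[["x:z"]]^2 * (iccX + rho^2) + t1 * iccX
    v1 <- (b[["x"]]^2 + b[["x:z"]]^2 + t1) * (1 - iccX)
    muY <- b[["(Intercept)"]] + b[["x:z"]] * rho
  } else if (design$study == 2L) {
    v2 <- b[["cmean(x)"]]^2 * iccX + b[["z"]]^2 +
      2 * b[["cmean(x)"]] * b[["z"]] * rho +
      b[["cmean(x):z"]]^2 * (iccX + rho^2)
    v1 <- (b[["wdev(x)"]]^2 + b[["wdev(x):z"]]^2 + t1) * (1 - iccX)
    muY <- b[["(Intercept)"]] + b[["cmean(x):z"]] * rho
  } else {
    mom <- .withPrivateRNG(186525, .study3Moments(design, 400000L))
    v2 <- mom$v2; v1 <- mom$v1; muY <- mom$muY
  }
  totalVar <- 1
  tau0sq <- design$iccY - v2
  sigma2 <- (1 - design$iccY) - v1
  if (tau0sq < 0) {
    ## the systematic between-cluster variance alone exceeds the target
    ## share; keep the ICC as the binding target and let the total variance
    ## of y grow: smallest feasible scaling has no intercept variance left
    totalVar <- v2 / design$iccY
    tau0sq <- 0
    sigma2 <- (1 - design$iccY) * totalVar - v1
  }
  if (sigma2 <= 0)
    stop(sprintf(paste0(
      "target ICC(y) = %.3f infeasible given the fixed slope variance; ",
      "feasible values lie below %.3f or in [%.3f, %.3f)"),
      design$iccY, v2 / (v2 + v1), v2, 1 - v1))
  list(tau0sq = tau0sq, sigma2 = sigma2, v2sys = v2, v1sys = v1,
       totalVar = totalVar, muY = muY)
}

.withPrivateRNG <- function(seed, expr) {
  ge <- globalenv()
  had <- exists(".Random.seed", envir = ge, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = ge, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = ge)
    else if (exists(".Random.seed", envir = ge, inherits = FALSE))
      rm(".Random.seed", envir = ge)
  })
  set.seed(seed)
  expr
}

## between/within systematic variances of the study-3 outcome model,
## estimated from M simulated clusters
.study3Moments <- function(design, M) {
  b <- design$betas
  ph <- .quadraticPhis(design)
  z <- stats::rnorm(M)
  xL2 <- ph$phi0 + ph$phi1 * z + ph$phi2 * z^2 +
    stats::rnorm(M, 0, sqrt(ph$varEps))
  u1 <- stats::rnorm(M, 0, sqrt(design$tau1sq))
  xL1 <- stats::rnorm(M, 0, sqrt(ph$varL1))
  y2 <- b[["x"]] * xL2 + b[["z"]] * z + b[["x:z"]] * xL2 * z +
    b[["x^2"]] * (xL2^2 + ph$varL1) + b[["z^2"]] * z^2 + u1 * xL2
  w1 <- b[["x"]] * xL1 + b[["x:z"]] * xL1 * z +
    b[["x^2"]] * (2 * xL2 * xL1 + xL1^2 - ph$varL1) + u1 * xL1
  list(v2 = stats::var(y2), v1 = stats::var(w1),
       muY = b[["(Intercept)"]] + mean(y2))
}

#' Propensity intercept giving the target marginal missing proportion
#'
#' `lambda0` is defined as the standard-normal quantile of the intended
#' missing proportion, which is exact when y is standard normal (the linear
#' designs). Under the quadratic design y has a nonzero mean and a total
#' variance above 1, so the literal intercept would overshoot the intended
#' proportion under MAR; this helper rescales it so that
#' `P(r > 0) = pnorm(lambda0)` continues to hold marginally.
#'
#' @param design an `mlStudyDesign`.
#' @param calib calibration from [calibrateOutcomeVariances()].
#' @export
effectiveLambda0 <- function(design, calib = NULL) {
  if (design$study != 3L) return(design$lambda0)
  if (is.null(calib)) calib <- calibrateOutcomeVariances(design)
  muY <- calib$muY %||% 0
  sdR <- sqrt(design$lambda1^2 * calib$totalVar + 1 - design$lambda1^2)
  design$lambda0 * sdR - design$lambda1 * muY
}

#' Simulate the outcome from the study's substantive model
#'
#' Builds y from the study's linear predictor (with manifest cluster means
#' for study 2) plus a random intercept, a random slope with variance
#' `tau1sq` (uncorrelated with the intercept), and level-1 noise, using the
#' calibrated variances from [calibrateOutcomeVariances()].
#'
#' @param design an `mlStudyDesign`.
#' @param object `mlData` with complete x and z from [genCovariates()].
#' @param calib optional precomputed calibration (list with tau0sq, sigma2).
#' @return The dataset with variable y added.
#' @export
genOutcome <- function(design, object, calib = NULL) {
  stopifnot(inherits(object, "mlData"))
  if (is.null(calib)) calib <- calibrateOutcomeVariances(design)
  ci <- as.integer(object$cluster)
  njs <- tabulate(ci)
  J <- length(njs)
  N <- length(ci)
  df <- as.list(object$data)
  b <- design$betas
  x <- df$x; z <- df$z
  u0 <- stats::rnorm(J, 0, sqrt(calib$tau0sq))
  u1 <- stats::rnorm(J, 0, sqrt(design$tau1sq))
  e <- stats::rnorm(N, 0, sqrt(calib$sigma2))
  y <- switch(design$study,
    b[["(Intercept)"]] + b[["x"]] * x + b[["z"]] * z + b[["x:z"]] * x * z +
      u0[ci] + u1[ci] * x + e,
    {
      xb <- .clusterMean(x, ci, njs)
      wd <- x - xb
      b[["(Intercept)"]] + b[["wdev(x)"]] * wd + b[["cmean(x)"]] * xb +
        b[["z"]] * z + b[["wdev(x):z"]] * wd * z + b[["cmean(x):z"]] * xb * z +
        u0[ci] + u1[ci] * wd + e
    },
    b[["(Intercept)"]] + b[["x"]] * x + b[["z"]] * z + b[["x:z"]] * x * z +
      b[["x^2"]] * x^2 + b[["z^2"]] * z^2 + u0[ci] + u1[ci] * x + e)
  .mlDataFromColumns(ci, c(df, list(y = y)),
                     c(object$levels, y = 1L))
}

#' Induce missingness through a latent propensity depending on y
#'
#' The propensity is `r = lambda0 + lambda1 y + v` with
#' `v ~ N(0, 1 - lambda1^2)`; a cell of the target variable is deleted iff
#' r > 0. With unit-variance y the propensity is standard normal, so the
#' marginal missing proportion is `pnorm(lambda0)` regardless of lambda1;
#' `lambda1 = 0` gives MCAR, larger values a y-dependent (MAR) mechanism.
#'
#' @param object an `mlData` containing y and the target variable.
#' @param target variable to receive missing cells.
#' @param lambda0 standard-normal quantile of the missing proportion.
#' @param lambda1 effect of y, |lambda1| <= 1.
#' @return The dataset with the target's missing cells masked.
#' @export
induceMissing <- function(object, target = "x",
                          lambda0 = stats::qnorm(0.30), lambda1 = 0) {
  stopifnot(inherits(object, "mlData"))
  if (abs(lambda1) > 1) stop("|lambda1| must be <= 1")
  if (!target %in% variableNames(object)) stop("unknown target variable")
  y <- object$data[["y"]]
  if (is.null(y)) {
    if (lambda1 != 0) stop("the propensity depends on y, which is absent")
    y <- 0
  }
  N <- nrow(object$data)
  r <- lambda0 + lambda1 * y +
    stats::rnorm(N, 0, sqrt(1 - lambda1^2))
  object$data[[target]][r > 0] <- NA
  object$miss[, target] <- object$miss[, target] | (r > 0)
  object
}

#' Analytic marginal missing proportion of the propensity model
#' @param lambda0 propensity intercept.
#' @export
missingnessProbability <- function(lambda0) stats::pnorm(lambda0)

## ---------------------------------------------------------------------------
## strategy comparison harness

#' True parameter values of a design (coefficients and slope variance)
#' @param design an `mlStudyDesign`.
#' @export
truthVector <- function(design) {
  c(design$betas, tau1sq = design$tau1sq)
}

.fitCI <- function(fit, level = 0.95) {
  zq <- stats::qnorm(1 - (1 - level) / 2)
  se <- sqrt(fit$variances)
  cbind(lower = fit$coefficients - zq * se,
        upper = fit$coefficients + zq * se)
}

.slopeVar <- function(Tmat) {
  if (length(Tmat) == 0L) return(NA_real_)
  Tmat[nrow(Tmat), ncol(Tmat)]
}

#' Run a Monte Carlo strategy comparison
#'
#' Per replication: generate covariates and outcome, induce missingness,
#' then analyze with each strategy -- CD (the complete data), LD (listwise
#' deletion), SMC (sequential-modeling imputation followed by Rubin
#' pooling) -- and record estimates and 95% interval coverage for the
#' substantive coefficients and the slope variance. Replications use the
#' deterministic seed sequence `seed + 1, ..., seed + reps`.
#'
#' @param design an `mlStudyDesign`.
#' @param strategies subset of `c("CD", "LD", "SMC")`.
#' @param reps number of replications.
#' @param seed base seed.
#' @param controls list overriding the sampler controls for the SMC arm
#'   (burnIn, nBetween, m, adaptEvery).
#' @return An `mlMetrics` data frame: relative bias (in %), RMSE and 95%
#'   coverage per parameter and strategy, each with its Monte Carlo SE;
#'   per-replication estimates are attached as attribute `"estimates"`.
#' @export
runStudy <- function(design, strategies = c("CD", "LD", "SMC"),
                     reps = 100L, seed = 1L,
                     controls = list()) {
  strategies <- match.arg(strategies, c("CD", "LD", "SMC"),
                          several.ok = TRUE)
  ctrl <- utils::modifyList(
    list(burnIn = 2000L, nBetween = 100L, m = 10L, adaptEvery = 50L),
    controls)
  spec <- substantiveModel(design)
  cmod <- covariateModel(design)
  calib <- calibrateOutcomeVariances(design)
  truth <- truthVector(design)
  pn <- names(truth)
  est <- array(NA_real_, c(reps, length(pn), length(strategies)),
               dimnames = list(NULL, pn, strategies))
  cov <- array(NA, c(reps, length(pn), length(strategies)),
               dimnames = list(NULL, pn, strategies))
  failed <- 0L

  for (r in seq_len(reps)) {
    set.seed(seed + r)
    res <- tryCatch({
      dat <- genOutcome(design, genCovariates(design), calib)
      inc <- induceMissing(dat, design$missingVar,
                           effectiveLambda0(design, calib), design$lambda1)
      out <- list()
      for (s in strategies) {
        if (s == "CD") {
          f <- fitSubstantive(dat, spec)
          ci95 <- .fitCI(f)
          out[[s]] <- list(
            est = c(f$coefficients, tau1sq = .slopeVar(f$Tmat)),
            hit = c(ci95[, 1L] <= truth[seq_len(nrow(ci95))] &
                      truth[seq_len(nrow(ci95))] <= ci95[, 2L],
                    tau1sq = NA))
        } else if (s == "LD") {
          f <- fitSubstantive(inc, spec)
          ci95 <- .fitCI(f)
          out[[s]] <- list(
            est = c(f$coefficients, tau1sq = .slopeVar(f$Tmat)),
            hit = c(ci95[, 1L] <= truth[seq_len(nrow(ci95))] &
                      truth[seq_len(nrow(ci95))] <= ci95[, 2L],
                    tau1sq = NA))
        } else {
          seqn <- defaultSequence(inc, spec,
                                  stats::setNames(list(cmod),
                                                  design$missingVar))
          imp <- smcImpute(inc, seqn, burnIn = ctrl$burnIn,
                           nBetween = ctrl$nBetween, m = ctrl$m,
                           adaptEvery = ctrl$adaptEvery)
          fits <- lapply(seq_len(ctrl$m),
                         function(k) fitSubstantive(completedData(imp, k), spec))
          pooled <- suppressMessages(poolFits(fits))
          hit <- coverageHit(pooled, truth[rownames(pooled)])
          vc <- attr(pooled, "varianceComponents")
          tl <- vc[[length(vc)]]  # last diagonal entry = slope variance
          out[[s]] <- list(
            est = c(stats::setNames(pooled$estimate, rownames(pooled)),
                    tau1sq = tl),
            hit = c(hit, tau1sq = NA))
        }
      }
      out
    }, error = function(e) NULL)
    if (is.null(res)) { failed <- failed + 1L; next }
    for (s in strategies) {
      est[r, , s] <- res[[s]]$est[pn]
      cov[r, , s] <- res[[s]]$hit[pn]
    }
  }

  rows <- list()
  for (s in strategies) for (k in seq_along(pn)) {
    e <- est[, k, s]
    e <- e[!is.na(e)]
    R <- length(e)
    th <- truth[[k]]
    err <- e - th
    rb <- if (th != 0) 100 * mean(err) / th else NA_real_
    rbse <- if (th != 0) 100 * stats::sd(e) / (abs(th) * sqrt(R)) else NA_real_
    rmse <- sqrt(mean(err^2))
    rmseSE <- if (rmse > 0) stats::sd(err^2) / (2 * rmse * sqrt(R)) else 0
    h <- cov[, k, s]
    h <- h[!is.na(h)]
    cv <- if (length(h)) 100 * mean(h) else NA_real_
    cvse <- if (length(h))
      100 * sqrt(mean(h) * (1 - mean(h)) / length(h)) else NA_real_
    rows[[length(rows) + 1L]] <- data.frame(
      strategy = s, parameter = pn[k], truth = th, estMean = mean(e),
      bias = mean(err), relBias = rb, relBiasMCSE = rbse,
      rmse = rmse, rmseMCSE = rmseSE,
      coverage = cv, coverageMCSE = cvse, reps = R)
  }
  out <- do.call(rbind, rows)
  attr(out, "design") <- design
  attr(out, "failed") <- failed
  attr(out, "estimates") <- est
  class(out) <- c("mlMetrics", "data.frame")
  out
}

#' @export
print.mlMetrics <- function(x, ...) {
  cat("Strategy comparison (", max(x$reps), " replications",
      if (attr(x, "failed") > 0) paste0(", ", attr(x, "failed"), " failed"),
      ")\n", sep = "")
  print(cbind(x[c("strategy", "parameter", "truth")],
              round(as.data.frame(x)[c("relBias", "rmse", "coverage")], 2)))
  invisible(x)
}
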