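#' Fit the substantive model by maximum likelihood
#'
#' Fits the declared mixed model on the dataset with lme4 (ML by default).
#' Rows with a missing value in any model variable are excluded before
#' anything else -- including before cluster means are computed -- so applying
#' this to incomplete data *is* the listwise-deletion comparator. Models
#' without a random part fall back to ordinary least squares.
#'
#' @param object an `mlData` object.
#' @param spec an `mlModelSpec` for a level-1 outcome.
#' @param method `"ML"` (default) or `"REML"`.
#' @return An `mlFit`: coefficient estimates with sampling variances,
#'   variance components (`Tmat`, `sigma2`), a convergence flag and the
#'   number of rows and clusters used. Singular or non-converged fits are
#'   reported through the flags, never as an error.
#' @export
fitSubstantive <- function(object, spec, method = c("ML", "REML")) {
  stopifnot(inherits(object, "mlData"), inherits(spec, "mlModelSpec"))
  method <- match.arg(method)
  .validateSpecAgainst(spec, object$levels)
  vars <- unique(c(spec$outcome, unlist(lapply(spec$terms, .termVars))))
  keep <- !rowSums(object$miss[, vars, drop = FALSE])
  if (!any(keep)) stop("no complete rows for the model variables")
  cl <- droplevels(object$cluster[keep])
  ci <- as.integer(cl)
  njs <- tabulate(ci)
  df <- lapply(object$data, `[`, keep)
  n <- sum(keep)
  X <- .designMatrixFast(spec, df, ci, njs, n)
  y <- df[[spec$outcome]]

  p <- ncol(X)
  cn <- coefNames(spec)
  r <- .nRandom(spec)
  if (r == 0L) {
    fit <- stats::lm.fit(X, y)
    res <- fit$residuals
    s2 <- sum(res^2) / n  # ML
    XtXinv <- chol2inv(chol(crossprod(X)))
    est <- stats::setNames(fit$coefficients, cn)
    v <- stats::setNames(s2 * diag(XtXinv), cn)
    return(structure(list(coefficients = est, variances = v,
                          Tmat = matrix(0, 0, 0), sigma2 = s2,
                          converged = TRUE, singular = FALSE,
                          nUsed = n, nClusters = length(njs), spec = spec),
                     class = "mlFit"))
  }

  dat <- as.data.frame(X[, (1L + spec$intercept):p, drop = FALSE])
  names(dat) <- paste0("X", seq_len(ncol(dat)))
  dat$.y <- y
  dat$.cl <- cl
  fixedCols <- names(dat)[seq_len(p - spec$intercept)]
  fixedStr <- paste(c(if (spec$intercept) "1" else "0", fixedCols),
                    collapse = " + ")
  ranCols <- fixedCols[spec$random]
  ranStr <- paste(c(if (spec$randomIntercept) "1" else "0", ranCols),
                  collapse = " + ")
  fml <- stats::as.formula(paste0(".y ~ ", fixedStr, " + (", ranStr, " | .cl)"))
  fit <- suppressWarnings(suppressMessages(
    lme4::lmer(fml, data = dat, REML = (method == "REML"),
               control = lme4::lmerControl(calc.derivs = FALSE,
                                           check.conv.singular = "ignore"))))
  msgs <- fit@optinfo$conv$lme4$messages
  converged <- is.null(msgs) || length(msgs) == 0L
  singular <- lme4::isSingular(fit, tol = 1e-5)
  est <- stats::setNames(as.numeric(lme4::fixef(fit)), cn)
  v <- stats::setNames(diag(as.matrix(stats::vcov(fit))), cn)
  vc <- lme4::VarCorr(fit)[[".cl"]]
  Tmat <- matrix(as.numeric(vc), nrow(vc))
  rlab <- c(if (spec$randomIntercept) "(Intercept)",
            vapply(spec$terms[spec$random], format, ""))
  dimnames(Tmat) <- list(rlab, rlab)
  structure(list(coefficients = est, variances = v, Tmat = Tmat,
                 sigma2 = stats::sigma(fit)^2, converged = converged,
                 singular = singular, nUsed = n, nClusters = length(njs),
                 spec = spec),
            class = "mlFit")
}

#' @export
print.mlFit <- function(x, ...) {
  cat("ML fit (", x$nUsed, " rows, ", x$nClusters, " clusters",
      if (!x$converged) ", NOT converged", ")\n", sep = "")
  print(round(cbind(estimate = x$coefficients,
                    se = sqrt(x$variances)), 4))
  invisible(x)
}

## stacked variance components of a fit, for across-imputation averaging
.varianceComponents <- function(fit) {
  out <- c(sigma2 = fit$sigma2)
  Tm <- fit$Tmat
  if (length(Tm)) {
    idx <- which(lower.tri(Tm, diag = TRUE), arr.ind = TRUE)
    tv <- Tm[lower.tri(Tm, diag = TRUE)]
    names(tv) <- paste0("tau[", idx[, 1L], ",", idx[, 2L], "]")
    out <- c(out, tv)
  }
  out
}

#' Pool estimates across imputations by Rubin's rules
#'
#' Pooled point estimate = mean of the per-imputation estimates; total
#' variance `T = Ubar + (1 + 1/m) B` with `Ubar` the mean within-imputation
#' variance and `B` the between-imputation sample variance. Degrees of
#' freedom follow Rubin (1987) with the Barnard-Rubin small-sample
#' adjustment given `dfCom` complete-data degrees of freedom; the 95%
#' interval is symmetric about the estimate on the t scale.
#'
#' @param estimates m x p matrix of per-imputation estimates (m >= 2).
#' @param variances m x p matrix of their sampling variances.
#' @param dfCom complete-data degrees of freedom for the Barnard-Rubin
#'   adjustment (scalar or per-parameter).
#' @param conf confidence level.
#' @return An `mlPooled` data frame: estimate, se, df, ciLower, ciUpper,
#'   and the variance decomposition (Ubar, B, total).
#' @export
rubinPool <- function(estimates, variances, dfCom = Inf, conf = 0.95) {
  estimates <- as.matrix(estimates)
  variances <- as.matrix(variances)
  m <- nrow(estimates)
  if (m < 2L) stop("pooling requires m >= 2 imputations")
  stopifnot(all(dim(estimates) == dim(variances)))
  qbar <- colMeans(estimates)
  ubar <- colMeans(variances)
  B <- apply(estimates, 2L, stats::var)
  Tv <- ubar + (1 + 1 / m) * B
  lam <- (1 + 1 / m) * B / Tv
  dfm <- ifelse(B > 0, (m - 1) * (1 + ubar / ((1 + 1 / m) * B))^2, Inf)
  dfObs <- (dfCom + 1) / (dfCom + 3) * dfCom * (1 - lam)
  df <- ifelse(is.finite(dfObs), 1 / (1 / dfm + 1 / dfObs), dfm)
  df <- pmax(df, 1e-8)
  a <- 1 - (1 - conf) / 2
  tq <- stats::qt(a, df)
  out <- data.frame(
    estimate = qbar, se = sqrt(Tv), df = df,
    ciLower = qbar - tq * sqrt(Tv), ciUpper = qbar + tq * sqrt(Tv),
    Ubar = ubar, B = B, total = Tv)
  rownames(out) <- colnames(estimates)
  attr(out, "m") <- m
  attr(out, "dfCom") <- dfCom
  class(out) <- c("mlPooled", "data.frame")
  out
}

#' Pool a list of fitted models
#'
#' Applies [rubinPool()] to the coefficient estimates of per-imputation
#' fits. Non-converged fits are dropped with a message; if more than 20%
#' are dropped the result carries a `flagged` attribute. Variance
#' components are averaged across imputations and attached as an attribute.
#'
#' @param fits list of `mlFit` objects from [fitSubstantive()].
#' @param dfCom complete-data df; default is (number of clusters - number of
#'   fixed effects), a conservative choice for cluster-level quantities.
#' @param conf confidence level.
#' @export
poolFits <- function(fits, dfCom = NULL, conf = 0.95) {
  ok <- vapply(fits, function(f) f$converged, NA)
  dropped <- sum(!ok)
  if (dropped > 0L)
    message(dropped, " non-converged fit(s) dropped from pooling")
  fits <- fits[ok]
  if (length(fits) < 2L) stop("fewer than 2 converged fits to pool")
  est <- do.call(rbind, lapply(fits, `[[`, "coefficients"))
  v <- do.call(rbind, lapply(fits, `[[`, "variances"))
  if (is.null(dfCom))
    dfCom <- max(fits[[1L]]$nClusters - length(fits[[1L]]$coefficients), 1L)
  out <- rubinPool(est, v, dfCom = dfCom, conf = conf)
  attr(out, "varianceComponents") <-
    colMeans(do.call(rbind, lapply(fits, .varianceComponents)))
  attr(out, "dropped") <- dropped
  attr(out, "flagged") <- dropped > 0.2 * length(ok)
  out
}

#' @export
print.mlPooled <- function(x, ...) {
  cat("Pooled estimates (m =", attr(x, "m"), "imputations)\n")
  print(round(as.data.frame(x)[, c("estimate", "se", "df",
                                   "ciLower", "ciUpper")], 4))
  vc <- attr(x, "varianceComponents")
  if (!is.null(vc)) {
    cat("variance components (averaged across imputations):\n")
    print(round(vc, 4))
  }
  invisible(x)
}

#' Does the pooled interval cover the generating value?
#'
#' Closed-interval convention: a truth exactly on a bound counts as covered.
#'
#' @param pooled an `mlPooled` object.
#' @param truth named (or positionally aligned) vector of generating values.
#' @return Named logical vector.
#' @export
coverageHit <- function(pooled, truth) {
  stopifnot(inherits(pooled, "mlPooled"))
  if (!is.null(names(truth))) truth <- truth[rownames(pooled)]
  stats::setNames(pooled$ciLower <= truth & truth <= pooled$ciUpper,
                  rownames(pooled))
}
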