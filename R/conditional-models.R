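#' Prior hyperparameters for the conditional models
#'
#' Regression coefficients carry flat priors; residual variances carry
#' inverse-gamma(eps, eps) priors; the random-effect covariance carries an
#' inverse-Wishart prior with `dim + t_df_add` degrees of freedom and scale
#' `t_scale * I`. The defaults are weakly informative and keep every update
#' in closed form.
#'
#' @param sigma_a,sigma_b inverse-gamma shape and rate for residual variances.
#' @param t_df_add degrees of freedom added to the random-effect dimension.
#' @param t_scale multiplier of the identity scale matrix.
#' @export
defaultPriors <- function(sigma_a = 1e-3, sigma_b = 1e-3,
                          t_df_add = 1, t_scale = 1e-3) {
  stopifnot(sigma_a > 0, sigma_b > 0, t_scale > 0)
  list(sigma_a = sigma_a, sigma_b = sigma_b,
       t_df_add = t_df_add, t_scale = t_scale)
}

#' Normal multilevel model for a level-1 variable
#'
#' The outcome in cluster j is normal around `X beta + Z u_j` with residual
#' variance `sigma2`; the cluster effects `u_j` are normal with covariance
#' `Tmat` and are carried explicitly (data augmentation) rather than
#' integrated out.
#'
#' @param spec an `mlModelSpec` with a level-1 outcome.
#' @param beta fixed coefficients, one per fixed term (intercept included).
#' @param sigma2 residual variance (> 0).
#' @param Tmat random-effect covariance (symmetric positive-semidefinite,
#'   dimension = number of random terms incl. random intercept).
#' @param u J x r matrix of current cluster effects.
#' @export
normalLevel1Model <- function(spec, beta, sigma2, Tmat = NULL, u = NULL) {
  stopifnot(inherits(spec, "mlModelSpec"), spec$level == 1L)
  p <- length(spec$terms) + spec$intercept
  if (length(beta) != p)
    stop("beta has length ", length(beta), ", expected ", p)
  if (!is.numeric(sigma2) || sigma2 <= 0) stop("non-positive variance")
  r <- .nRandom(spec)
  if (r > 0L) {
    Tmat <- as.matrix(Tmat)
    if (!all(dim(Tmat) == r)) stop("Tmat must be ", r, "x", r)
    if (max(abs(Tmat - t(Tmat))) > 1e-10) stop("Tmat must be symmetric")
    ev <- eigen(Tmat, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-10) stop("Tmat must be positive-semidefinite")
    if (is.null(u)) stop("u (J x r matrix of cluster effects) is required")
    u <- as.matrix(u)
    if (ncol(u) != r) stop("u must have ", r, " columns")
  } else {
    Tmat <- matrix(0, 0, 0); u <- NULL
  }
  structure(list(spec = spec, beta = as.numeric(beta), sigma2 = sigma2,
                 Tmat = Tmat, u = u, level = 1L),
            class = "mlCondModel")
}

#' Normal regression model for a level-2 variable
#'
#' @param spec an `mlModelSpec` with a level-2 outcome (no random part).
#' @param gamma coefficients, one per fixed term (intercept included).
#' @param sigma2 residual variance (> 0).
#' @export
normalLevel2Model <- function(spec, gamma, sigma2) {
  stopifnot(inherits(spec, "mlModelSpec"), spec$level == 2L)
  p <- length(spec$terms) + spec$intercept
  if (length(gamma) != p)
    stop("gamma has length ", length(gamma), ", expected ", p)
  if (!is.numeric(sigma2) || sigma2 <= 0) stop("non-positive variance")
  structure(list(spec = spec, beta = as.numeric(gamma), sigma2 = sigma2,
                 Tmat = matrix(0, 0, 0), u = NULL, level = 2L),
            class = "mlCondModel")
}

#' @export
print.mlCondModel <- function(x, ...) {
  cat(if (x$level == 1L) "Level-1" else "Level-2", "normal model:",
      renderFormula(x$spec), "\n")
  cat("  sigma2 =", signif(x$sigma2, 4), "\n")
  invisible(x)
}

## ---------------------------------------------------------------------------
## log densities

## per-row log densities for a level-1 model / per-cluster for a level-2 model
.rowLogLik <- function(model, df, ci, njs, n) {
  spec <- model$spec
  if (model$sigma2 <= 0) stop("non-positive variance")
  if (model$level == 1L) {
    X <- .designMatrixFast(spec, df, ci, njs, n)
    mu <- drop(X %*% model$beta)
    if (!is.null(model$u))
      mu <- mu + rowSums(.zMatrixFast(spec, df, ci, njs, n) *
                           model$u[ci, , drop = FALSE])
    stats::dnorm(df[[spec$outcome]], mu, sqrt(model$sigma2), log = TRUE)
  } else {
    idx1 <- match(seq_along(njs), ci)
    X <- .designMatrixFast(spec, df, ci, njs, n)[idx1, , drop = FALSE]
    mu <- drop(X %*% model$beta)
    stats::dnorm(df[[spec$outcome]][idx1], mu, sqrt(model$sigma2), log = TRUE)
  }
}

#' Sum of log densities over a row or cluster selection
#'
#' For level-1 models the mean includes the current cluster effects `u_j`;
#' for level-2 models the density is evaluated once per cluster. The result
#' is additive over disjoint selections.
#'
#' @param model an `mlCondModel`.
#' @param object an `mlData` object, complete for all model variables.
#' @param rows optional row indices (level-1 models).
#' @param clusters optional cluster labels or indices.
#' @export
loglikRows <- function(model, object, rows = NULL, clusters = NULL) {
  stopifnot(inherits(model, "mlCondModel"), inherits(object, "mlData"))
  ci <- as.integer(object$cluster)
  njs <- tabulate(ci)
  ll <- .rowLogLik(model, object$data, ci, njs, nrow(object$data))
  if (model$level == 1L) {
    keep <- rep(TRUE, length(ll))
    if (!is.null(clusters)) {
      cidx <- if (is.numeric(clusters)) as.integer(clusters)
              else match(clusters, levels(object$cluster))
      keep <- ci %in% cidx
    }
    if (!is.null(rows)) keep <- keep & seq_along(ll) %in% rows
    sum(ll[keep])
  } else {
    keep <- rep(TRUE, length(ll))
    if (!is.null(clusters)) {
      cidx <- if (is.numeric(clusters)) as.integer(clusters)
              else match(clusters, levels(object$cluster))
      keep <- seq_along(ll) %in% cidx
    }
    sum(ll[keep])
  }
}

## ---------------------------------------------------------------------------
## Gibbs updates (exact full conditionals, conjugate throughout)

.rinvwishart <- function(df, S) {
  W <- stats::rWishart(1L, df, chol2inv(chol(S)))[, , 1L]
  chol2inv(chol(W))
}

## draw u_j | beta, sigma2, T for all clusters; vectorized for r <= 2
.drawClusterEffects <- function(resid, Z, ci, J, sigma2, Tmat) {
  r <- ncol(Z)
  P <- tryCatch(chol2inv(chol(Tmat)),
                error = function(e) stop("singular random-effect covariance"))
  if (r == 1L) {
    z <- Z[, 1L]
    A <- rowsum(z * z, ci)[, 1L] / sigma2 + P[1L, 1L]
    b <- rowsum(z * resid, ci)[, 1L] / sigma2
    cbind(b / A + stats::rnorm(J) / sqrt(A))
  } else if (r == 2L) {
    z1 <- Z[, 1L]; z2 <- Z[, 2L]
    A11 <- rowsum(z1 * z1, ci)[, 1L] / sigma2 + P[1L, 1L]
    A12 <- rowsum(z1 * z2, ci)[, 1L] / sigma2 + P[1L, 2L]
    A22 <- rowsum(z2 * z2, ci)[, 1L] / sigma2 + P[2L, 2L]
    b1 <- rowsum(z1 * resid, ci)[, 1L] / sigma2
    b2 <- rowsum(z2 * resid, ci)[, 1L] / sigma2
    det <- A11 * A22 - A12 * A12
    if (any(det <= 0)) stop("singular precision matrix in cluster ",
                            which(det <= 0)[1L])
    m1 <- (A22 * b1 - A12 * b2) / det
    m2 <- (A11 * b2 - A12 * b1) / det
    L11 <- sqrt(A11); L21 <- A12 / L11; L22 <- sqrt(A22 - L21 * L21)
    e1 <- stats::rnorm(J); e2 <- stats::rnorm(J)
    x2 <- e2 / L22
    x1 <- (e1 - L21 * x2) / L11
    cbind(m1 + x1, m2 + x2)
  } else {
    u <- matrix(0, J, r)
    for (j in seq_len(J)) {
      rows <- which(ci == j)
      Zj <- Z[rows, , drop = FALSE]
      A <- crossprod(Zj) / sigma2 + P
      ch <- tryCatch(chol(A), error = function(e)
        stop("singular precision matrix in cluster ", j))
      m <- backsolve(ch, backsolve(ch, crossprod(Zj, resid[rows]) / sigma2,
                                   transpose = TRUE))
      u[j, ] <- m + backsolve(ch, stats::rnorm(r))
    }
    u
  }
}

.drawCoefficients <- function(X, y, sigma2) {
  XtX <- crossprod(X)
  ch <- tryCatch(chol(XtX), error = function(e)
    stop("singular precision matrix for fixed coefficients"))
  bhat <- backsolve(ch, backsolve(ch, crossprod(X, y), transpose = TRUE))
  drop(bhat) + sqrt(sigma2) * drop(backsolve(ch, stats::rnorm(ncol(X))))
}

.gibbsLevel1Fast <- function(model, df, ci, njs, n, priors) {
  spec <- model$spec
  y <- df[[spec$outcome]]
  X <- .designMatrixFast(spec, df, ci, njs, n)
  r <- .nRandom(spec)
  J <- length(njs)
  if (r > 0L) {
    Z <- .zMatrixFast(spec, df, ci, njs, n)
    resid <- y - drop(X %*% model$beta)
    u <- .drawClusterEffects(resid, Z, ci, J, model$sigma2, model$Tmat)
    yt <- y - rowSums(Z * u[ci, , drop = FALSE])
  } else { u <- NULL; yt <- y }
  beta <- .drawCoefficients(X, yt, model$sigma2)
  res <- yt - drop(X %*% beta)
  sigma2 <- 1 / stats::rgamma(1L, priors$sigma_a + n / 2,
                              priors$sigma_b + sum(res * res) / 2)
  Tmat <- model$Tmat
  if (r > 0L) {
    S <- diag(priors$t_scale, r) + crossprod(u)
    Tmat <- .rinvwishart(r + priors$t_df_add + J, S)
  }
  model$beta <- beta; model$sigma2 <- sigma2; model$Tmat <- Tmat; model$u <- u
  model
}

.gibbsLevel2Fast <- function(model, df, ci, njs, n, priors) {
  spec <- model$spec
  idx1 <- match(seq_along(njs), ci)
  X <- .designMatrixFast(spec, df, ci, njs, n)[idx1, , drop = FALSE]
  y <- df[[spec$outcome]][idx1]
  J <- length(idx1)
  beta <- .drawCoefficients(X, y, model$sigma2)
  res <- y - drop(X %*% beta)
  model$sigma2 <- 1 / stats::rgamma(1L, priors$sigma_a + J / 2,
                                    priors$sigma_b + sum(res * res) / 2)
  model$beta <- beta
  model
}

#' One Gibbs sweep for a level-1 conditional model
#'
#' Draws, in order, the cluster effects `u_j` (multivariate normal), the
#' fixed coefficients (multivariate normal), the residual variance
#' (inverse-gamma) and the random-effect covariance (inverse-Wishart), each
#' from its exact full conditional given the current completed data. The
#' update is deterministic given the R random seed.
#'
#' @param model an `mlCondModel` with `level == 1`.
#' @param object an `mlData` object, complete for all model variables.
#' @param priors see [defaultPriors()].
#' @return The updated model.
#' @export
gibbsUpdateLevel1 <- function(model, object, priors = defaultPriors()) {
  stopifnot(inherits(model, "mlCondModel"), model$level == 1L,
            inherits(object, "mlData"))
  ci <- as.integer(object$cluster)
  .gibbsLevel1Fast(model, object$data, ci, tabulate(ci),
                   nrow(object$data), priors)
}

#' One Gibbs sweep for a level-2 conditional model
#'
#' Conjugate normal / inverse-gamma update at one row per cluster.
#'
#' @inheritParams gibbsUpdateLevel1
#' @export
gibbsUpdateLevel2 <- function(model, object, priors = defaultPriors()) {
  stopifnot(inherits(model, "mlCondModel"), model$level == 2L,
            inherits(object, "mlData"))
  ci <- as.integer(object$cluster)
  .gibbsLevel2Fast(model, object$data, ci, tabulate(ci),
                   nrow(object$data), priors)
}
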