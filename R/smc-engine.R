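#' Declare the sequence of conditional models
#'
#' The joint distribution is factorized into conditional covariate models,
#' each conditioning only on variables placed earlier in the sequence, with
#' the substantive outcome model last. Every incomplete variable must own
#' exactly one conditional model; variables without a model are treated as
#' complete background predictors.
#'
#' @param models ordered list of `mlModelSpec`: covariate models first, the
#'   outcome model last.
#' @param incomplete character vector of variables with missing cells.
#' @return An `mlSequence` object.
#' @export
sequenceSpec <- function(models, incomplete = character()) {
  stopifnot(is.list(models), length(models) >= 1L)
  for (m in models) if (!inherits(m, "mlModelSpec"))
    stop("models must be mlModelSpec objects")
  outcomes <- vapply(models, `[[`, "", "outcome")
  if (anyDuplicated(outcomes))
    stop("each variable may own at most one conditional model")
  P <- length(models)
  modeled <- outcomes[-P]
  yvar <- outcomes[P]
  for (k in seq_len(P)) {
    preds <- unique(unlist(lapply(models[[k]]$terms, .termVars)))
    if (outcomes[k] %in% preds)
      stop("model for '", outcomes[k], "' conditions on itself")
    if (k < P) {
      later <- outcomes[seq.int(k, P - 1L)]  # own + later covariates
      bad <- intersect(preds, c(later, yvar))
      if (length(bad))
        stop("model for '", outcomes[k], "' conditions on '", bad[1L],
             "', which is not earlier in the sequence")
    }
  }
  miss <- setdiff(incomplete, c(modeled, yvar))
  if (length(miss))
    stop("incomplete variable '", miss[1L], "' has no conditional model")
  structure(list(models = models, incomplete = unique(incomplete)),
            class = "mlSequence")
}

#' @export
print.mlSequence <- function(x, ...) {
  cat("Sequence of", length(x$models), "conditional models:\n")
  for (m in x$models) cat("  ", renderFormula(m), "\n")
  if (length(x$incomplete))
    cat("incomplete:", paste(x$incomplete, collapse = ", "), "\n")
  invisible(x)
}

#' Default ordering of the conditional covariate models
#'
#' Covariate models are ordered with level-2 variables before level-1
#' variables and, within a level, by ascending percentage of missing data;
#' the outcome model closes the sequence.
#'
#' @param object an `mlData` object.
#' @param outcomeModel `mlModelSpec` of the substantive model.
#' @param covariateModels named list of `mlModelSpec` for the covariates
#'   (names = covariate variable).
#' @return An `mlSequence` with the incomplete set taken from the dataset.
#' @export
defaultSequence <- function(object, outcomeModel, covariateModels = list()) {
  stopifnot(inherits(object, "mlData"))
  vars <- names(covariateModels)
  if (length(vars)) {
    lev <- object$levels[vars]
    pmiss <- colMeans(object$miss)[vars]
    ord <- order(-lev, pmiss)
    covariateModels <- covariateModels[ord]
  }
  incomplete <- variableNames(object)[colSums(object$miss) > 0L]
  sequenceSpec(c(unname(covariateModels), list(outcomeModel)), incomplete)
}

#' Fill missing cells with draws from observed-cell moments
#'
#' Each missing cell is initialized with a normal draw using the mean and SD
#' of the variable's observed cells (level-2 variables get one draw per
#' cluster). Deterministic given the R random seed.
#'
#' @param object an `mlData` object.
#' @return A named list of completed numeric columns.
#' @export
initializeMissing <- function(object) {
  stopifnot(inherits(object, "mlData"))
  df <- as.list(object$data)
  ci <- as.integer(object$cluster)
  for (v in variableNames(object)) {
    mk <- object$miss[, v]
    if (!any(mk)) next
    obs <- df[[v]][!mk]
    if (length(obs) == 0L)
      stop("variable '", v, "' has no observed cells to initialize from")
    mu <- mean(obs)
    s <- if (length(obs) > 1L) stats::sd(obs) else 0
    if (object$levels[[v]] == 2L) {
      cl <- unique(ci[mk])
      draw <- stats::rnorm(length(cl), mu, s)
      df[[v]][mk] <- draw[match(ci[mk], cl)]
    } else {
      df[[v]][mk] <- stats::rnorm(sum(mk), mu, s)
    }
  }
  df
}

#' Metropolis-Hastings log ratio for one cluster and one variable
#'
#' Evaluates the log of the posterior-density ratio of proposed to current
#' values for the missing cells of `variable` in `cluster`, the quantity
#' whose exponential is the cluster-level MH ratio. The ratio multiplies the
#' cluster's likelihood contributions under (a) the variable's own
#' conditional model and (b) every model in which the variable appears as a
#' predictor, directly or through a derived term; cluster means, deviations,
#' interactions and powers involving the variable are recomputed under the
#' proposal before evaluation.
#'
#' @param models list of `mlCondModel` along the sequence, with current
#'   parameters.
#' @param object an `mlData` object carrying the missingness mask.
#' @param completed optional named list / data frame of current completed
#'   columns; defaults to the object's own data (which must then be
#'   complete).
#' @param cluster cluster label or index.
#' @param variable name of the incomplete variable.
#' @param proposal numeric vector covering exactly the missing cells of the
#'   variable in the cluster (a single value for a level-2 variable).
#' @return The log MH ratio (0 when the proposal equals the current values).
#' @export
mhLogRatio <- function(models, object, cluster, variable, proposal,
                       completed = NULL) {
  stopifnot(inherits(object, "mlData"))
  if (is.null(completed)) completed <- object$data
  df <- as.list(completed)
  if (anyNA(df[[variable]])) stop("completed data still has missing cells")
  if (!any(object$miss[, variable]))
    stop("variable '", variable, "' is not flagged incomplete")
  ci <- as.integer(object$cluster)
  njs <- tabulate(ci)
  n <- length(ci)
  j <- if (is.numeric(cluster)) as.integer(cluster)
       else match(cluster, levels(object$cluster))
  rows <- which(ci == j & object$miss[, variable])
  if (length(rows) == 0L)
    stop("cluster has no missing cells for '", variable, "'")
  if (object$levels[[variable]] == 2L) {
    if (length(proposal) != 1L)
      stop("a level-2 variable takes a single proposed value per cluster")
    proposal <- rep(proposal, length(rows))
  }
  if (length(proposal) != length(rows))
    stop("proposal must cover exactly the ", length(rows),
         " missing cells of '", variable, "' in the cluster")
  dep <- .dependentModels(lapply(models, `[[`, "spec"), variable)
  df2 <- df
  df2[[variable]][rows] <- proposal
  lr <- 0
  for (mi in dep) {
    m <- models[[mi]]
    ll1 <- .rowLogLik(m, df2, ci, njs, n)
    ll0 <- .rowLogLik(m, df, ci, njs, n)
    if (m$level == 1L) {
      sel <- ci == j
      lr <- lr + sum(ll1[sel]) - sum(ll0[sel])
    } else {
      lr <- lr + ll1[j] - ll0[j]
    }
  }
  lr
}

## models whose density involves variable q: its own model plus every model
## with q among the predictor variables; takes a list of mlModelSpec
.dependentModels <- function(specs, q) {
  which(vapply(specs, function(s) {
    s$outcome == q || q %in% unlist(lapply(s$terms, .termVars))
  }, NA))
}

## whole-cluster accept/reject given per-cluster log ratios
.mhAccept <- function(lr) {
  lr >= 0 | log(stats::runif(length(lr))) < lr
}

#' Adapt proposal scales toward a target acceptance band
#'
#' Robbins-Monro-style multiplicative adaptation: each per-cluster scale
#' factor is multiplied by `exp(rate - mid)` where `mid` is the middle of
#' the target band, so scales grow under high acceptance and shrink under
#' low acceptance. Adaptation is only valid during burn-in; once frozen the
#' call is a no-op with a warning, so the post-burn-in chain runs a fixed
#' kernel.
#'
#' @param scales numeric vector of positive per-cluster scale factors.
#' @param rates acceptance rates observed over the last window.
#' @param band target acceptance band (low, high).
#' @param frozen logical; `TRUE` after burn-in.
#' @export
adaptProposals <- function(scales, rates, band = c(0.3, 0.6), frozen = FALSE) {
  stopifnot(all(scales > 0), all(rates >= 0 & rates <= 1))
  if (frozen) {
    warning("proposal scales are frozen after burn-in; adaptation skipped")
    return(scales)
  }
  pmin(pmax(scales * exp(rates - mean(band)), 1e-6), 1e6)
}

#' Sequential-modeling multiple imputation
#'
#' Runs the Metropolis-within-Gibbs sampler over the declared sequence of
#' conditional models. Each iteration (i) updates every model's parameters
#' by their exact full conditionals given the current completed data and
#' (ii) for every incomplete variable draws cluster-level MH proposals for
#' its missing cells, accepting or rejecting all cells of a cluster jointly.
#' After burn-in a completed dataset is saved every `nBetween` iterations
#' until `m` datasets exist. Observed cells are never modified. With no
#' missing cells the engine degrades to pure Bayesian estimation and all
#' `m` datasets equal the input.
#'
#' @param object an `mlData` object.
#' @param sequence an `mlSequence`.
#' @param burnIn burn-in iterations (proposal adaptation happens only here).
#' @param nBetween iterations between saved datasets.
#' @param m number of imputations.
#' @param seed optional integer seed; all randomness flows through it.
#' @param adaptBand target acceptance band for the proposal adaptation.
#' @param adaptEvery adaptation window length (iterations).
#' @param priors see [defaultPriors()].
#' @param initialModels optional list of `mlCondModel` start values (one per
#'   sequence position); by default start values come from least squares on
#'   the initialized data.
#' @param updateParameters set `FALSE` to hold all model parameters fixed
#'   (a fixed-kernel MH chain over the missing cells only).
#' @param recordCells set `TRUE` to record the imputed cell values at every
#'   iteration (diagnostic; memory grows with iterations).
#' @return An `mlImputationSet`: completed datasets, split-chain Rhat for
#'   the outcome-model parameters, per-variable acceptance rates, controls.
#' @export
smcImpute <- function(object, sequence, burnIn = 2000L, nBetween = 100L,
                      m = 10L, seed = NULL, adaptBand = c(0.3, 0.6),
                      adaptEvery = 50L, priors = defaultPriors(),
                      initialModels = NULL, updateParameters = TRUE,
                      recordCells = FALSE) {
  stopifnot(inherits(object, "mlData"), inherits(sequence, "mlSequence"),
            burnIn >= 0L, nBetween >= 1L, m >= 1L)
  if (!is.null(seed)) set.seed(seed)

  ci <- as.integer(object$cluster)
  njs <- tabulate(ci)
  J <- length(njs)
  n <- length(ci)
  for (ms in sequence$models) .validateSpecAgainst(ms, object$levels)

  ## variables with actual missing cells must be flagged and modeled
  missingVars <- variableNames(object)[colSums(object$miss) > 0L]
  bad <- setdiff(missingVars, sequence$incomplete)
  if (length(bad))
    stop("variable '", bad[1L], "' has missing cells but is not in the sequence")

  df <- initializeMissing(object)

  models <- if (!is.null(initialModels)) initialModels
            else lapply(sequence$models, .initModel, df = df, ci = ci,
                        njs = njs, n = n, J = J)

  ## per-variable MH bookkeeping
  mh <- list()
  for (q in missingVars) {
    idx <- which(object$miss[, q])
    cellClus <- ci[idx]
    uclus <- unique(cellClus)
    obs <- object$data[[q]][!object$miss[, q]]
    tau0 <- if (length(obs) > 1L) stats::sd(obs) / 2 else 1
    if (tau0 == 0) tau0 <- 1
    mh[[q]] <- list(
      idx = idx, cellClus = cellClus, uclus = uclus,
      level = object$levels[[q]],
      affected = seq_len(J) %in% uclus,
      tau0 = tau0, fac = rep(1, J),
      accWin = integer(J), nWin = 0L,
      accTot = 0, nTot = 0,
      dep = .dependentModels(sequence$models, q))
  }

  outSpec <- sequence$models[[length(sequence$models)]]
  chainNames <- c(coefNames(outSpec), "sigma2",
                  if (.nRandom(outSpec) > 0L)
                    outer(seq_len(.nRandom(outSpec)),
                          seq_len(.nRandom(outSpec)),
                          function(i, k) paste0("T[", i, ",", k, "]"))[
                            lower.tri(diag(.nRandom(outSpec)), diag = TRUE)])
  total <- burnIn + m * nBetween
  chain <- matrix(NA_real_, total - burnIn, length(chainNames))
  colnames(chain) <- chainNames
  cells <- if (recordCells)
    matrix(NA_real_, total, sum(lengths(lapply(mh, `[[`, "idx")))) else NULL

  imputations <- vector("list", m)
  saved <- 0L
  adaptWarned <- FALSE

  for (t in seq_len(total)) {
    if (updateParameters) {
      for (k in seq_along(models)) {
        models[[k]] <- if (models[[k]]$level == 1L)
          .gibbsLevel1Fast(models[[k]], df, ci, njs, n, priors)
        else
          .gibbsLevel2Fast(models[[k]], df, ci, njs, n, priors)
      }
    }

    for (q in names(mh)) {
      info <- mh[[q]]
      cur <- df[[q]]
      prop <- cur
      if (info$level == 2L) {
        eps <- stats::rnorm(length(info$uclus)) * info$tau0 *
          info$fac[info$uclus]
        prop[info$idx] <- cur[info$idx] + eps[match(info$cellClus, info$uclus)]
      } else {
        prop[info$idx] <- cur[info$idx] +
          stats::rnorm(length(info$idx)) * info$tau0 * info$fac[info$cellClus]
      }
      df2 <- df
      df2[[q]] <- prop
      rowDiff <- numeric(n)
      clusDiff <- numeric(J)
      for (mi in info$dep) {
        mm <- models[[mi]]
        ll1 <- .rowLogLik(mm, df2, ci, njs, n)
        ll0 <- .rowLogLik(mm, df, ci, njs, n)
        if (mm$level == 1L) rowDiff <- rowDiff + (ll1 - ll0)
        else clusDiff <- clusDiff + (ll1 - ll0)
      }
      lr <- rowsum(rowDiff, ci)[, 1L] + clusDiff
      acc <- .mhAccept(lr) & info$affected
      if (any(acc)) {
        touch <- info$idx[acc[info$cellClus]]
        df[[q]][touch] <- prop[touch]
      }
      nacc <- sum(acc)
      info$accWin <- info$accWin + as.integer(acc)
      info$accTot <- info$accTot + nacc
      info$nTot <- info$nTot + length(info$uclus)
      mh[[q]] <- info
    }
    if (length(mh)) {
      if (t <= burnIn) {
        if (t %% adaptEvery == 0L) {
          for (q in names(mh)) {
            info <- mh[[q]]
            rates <- pmin(info$accWin / adaptEvery, 1)
            info$fac[info$uclus] <- adaptProposals(
              info$fac[info$uclus], rates[info$uclus], band = adaptBand)
            info$accWin <- integer(J)
            mh[[q]] <- info
          }
        }
      }
    }

    if (recordCells)
      cells[t, ] <- unlist(lapply(names(mh), function(q) df[[q]][mh[[q]]$idx]))

    if (t > burnIn) {
      om <- models[[length(models)]]
      Tv <- if (.nRandom(outSpec) > 0L)
        om$Tmat[lower.tri(om$Tmat, diag = TRUE)] else NULL
      chain[t - burnIn, ] <- c(om$beta, om$sigma2, Tv)
      if ((t - burnIn) %% nBetween == 0L) {
        saved <- saved + 1L
        imputations[[saved]] <- as.data.frame(df)
      }
    }
  }

  accRates <- vapply(mh, function(i) i$accTot / max(i$nTot, 1L), 0)
  rh <- .splitRhat(chain)
  structure(list(
    dataset = object,
    clusterName = object$clusterName %||% "cluster",
    imputations = imputations,
    rhat = rh,
    acceptance = accRates,
    proposalScales = lapply(mh, function(i) i$tau0 * i$fac),
    chain = chain,
    cellChain = cells,
    models = models,
    controls = list(burnIn = burnIn, nBetween = nBetween, m = m,
                    seed = seed, adaptBand = adaptBand,
                    adaptEvery = adaptEvery)),
    class = "mlImputationSet")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Extract one completed dataset from an imputation set
#'
#' @param imp an `mlImputationSet`.
#' @param k imputation index (1..m).
#' @return An `mlData` with the missing cells replaced by the k-th draw and
#'   an all-observed mask (the original mask lives in `imp$dataset`).
#' @export
completedData <- function(imp, k) {
  stopifnot(inherits(imp, "mlImputationSet"),
            k >= 1L, k <= length(imp$imputations))
  out <- imp$dataset
  out$data <- imp$imputations[[k]]
  out$miss[] <- FALSE
  out
}

.initModel <- function(spec, df, ci, njs, n, J) {
  X <- .designMatrixFast(spec, df, ci, njs, n)
  if (spec$level == 2L) {
    idx1 <- match(seq_len(J), ci)
    Xj <- X[idx1, , drop = FALSE]
    yj <- df[[spec$outcome]][idx1]
    fit <- stats::lm.fit(Xj, yj)
    s2 <- max(mean(fit$residuals^2), 1e-6)
    return(normalLevel2Model(spec, fit$coefficients, s2))
  }
  y <- df[[spec$outcome]]
  fit <- stats::lm.fit(X, y)
  beta <- fit$coefficients
  beta[is.na(beta)] <- 0
  s2 <- max(mean(fit$residuals^2), 1e-6)
  r <- .nRandom(spec)
  if (r > 0L)
    normalLevel1Model(spec, beta, s2, Tmat = diag(0.1 * s2 + 1e-3, r),
                      u = matrix(0, J, r))
  else
    normalLevel1Model(spec, beta, s2)
}

#' @export
print.mlImputationSet <- function(x, ...) {
  cat("Imputation set:", length(x$imputations), "completed datasets\n")
  if (length(x$acceptance))
    cat("mean MH acceptance:",
        paste(sprintf("%s=%.2f", names(x$acceptance), x$acceptance),
              collapse = ", "), "\n")
  cat("max split-chain Rhat:",
      round(max(x$rhat, na.rm = TRUE), 3), "\n")
  invisible(x)
}

#' Potential scale reduction (Rhat)
#'
#' Textbook between/within-chain variance ratio: with chains of length n,
#' `Rhat = sqrt(((n-1)/n * W + B/n) / W)` where `W` is the mean within-chain
#' variance and `B/n` the variance of the chain means.
#'
#' @param chains list of two or more numeric vectors of equal length.
#' @export
rhat <- function(chains) {
  stopifnot(is.list(chains), length(chains) >= 2L)
  len <- lengths(chains)
  if (length(unique(len)) != 1L) stop("chains must have equal length")
  nIt <- len[1L]
  W <- mean(vapply(chains, stats::var, 0))
  Bn <- stats::var(vapply(chains, mean, 0))
  if (W == 0) return(if (Bn == 0) 1 else Inf)
  sqrt(((nIt - 1) / nIt * W + Bn) / W)
}

## split each parameter's post-burn-in chain in half
.splitRhat <- function(chain) {
  nIt <- nrow(chain)
  if (is.null(nIt) || nIt < 4L)
    return(stats::setNames(rep(NA_real_, ncol(chain)), colnames(chain)))
  h <- nIt %/% 2L
  out <- vapply(seq_len(ncol(chain)), function(k) {
    rhat(list(chain[seq_len(h), k], chain[seq.int(nIt - h + 1L, nIt), k]))
  }, 0)
  stats::setNames(out, colnames(chain))
}
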