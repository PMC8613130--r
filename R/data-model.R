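#' Two-level datasets with explicit missingness
#'
#' `multilevelData()` wraps a long-format data frame (one row per level-1
#' unit) together with a cluster identifier, a level tag for every variable
#' (1 = varies within clusters, 2 = constant within clusters) and an explicit
#' mask of missing cells. Observed cells are immutable throughout sampling;
#' missing cells are the only ones an imputation engine may write.
#'
#' @param data data frame of numeric variables plus one cluster-id column.
#' @param cluster name of the cluster-id column.
#' @param levels optional named vector assigning level 1 or 2 to each
#'   variable; variables not named are assigned by inspection (a variable that
#'   is constant within every cluster over its observed cells is level 2).
#' @return An object of class `mlData` with components `data` (numeric
#'   columns, `NA` in missing cells), `cluster` (factor), `levels` (named
#'   integer vector) and `miss` (logical matrix, `TRUE` = missing).
#' @examples
#' d <- data.frame(g = c(1, 1, 2, 2), x = c(1, NA, 3, 4), z = c(5, 5, 6, 6))
#' md <- multilevelData(d, cluster = "g")
#' md$levels  # x is level 1, z level 2
#' @export
multilevelData <- function(data, cluster, levels = NULL) {
  stopifnot(is.data.frame(data))
  if (!cluster %in% names(data))
    stop("cluster column '", cluster, "' not found in data")
  cl <- data[[cluster]]
  if (anyNA(cl)) stop("cluster identifiers must not be missing")
  cl <- factor(cl, levels = unique(cl))
  vars <- setdiff(names(data), cluster)
  if (length(vars) == 0L) stop("no variables besides the cluster id")
  vals <- data[vars]
  for (v in vars) {
    if (!is.numeric(vals[[v]]))
      stop("variable '", v, "' is not numeric")
    vals[[v]] <- as.numeric(vals[[v]])
  }
  miss <- is.na(as.matrix(vals))
  dimnames(miss) <- list(NULL, vars)

  lev <- integer(length(vars))
  names(lev) <- vars
  for (v in vars) {
    if (!is.null(levels) && v %in% names(levels)) {
      lev[v] <- as.integer(levels[[v]])
      if (!lev[v] %in% 1:2) stop("level of '", v, "' must be 1 or 2")
    } else {
      lev[v] <- if (.constantWithinClusters(vals[[v]], cl)) 2L else 1L
    }
  }
  for (v in vars[lev == 2L]) {
    if (!.constantWithinClusters(vals[[v]], cl))
      stop("level-2 variable '", v,
           "' is not constant within clusters (over observed cells)")
    partial <- tapply(miss[, v], cl, function(m) any(m) && !all(m))
    if (any(partial))
      stop("level-2 variable '", v,
           "' is missing for only part of a cluster")
  }
  structure(
    list(data = vals, cluster = cl, clusterName = cluster,
         levels = lev, miss = miss),
    class = "mlData")
}

.constantWithinClusters <- function(v, cl) {
  ok <- !is.na(v)
  if (!any(ok)) return(TRUE)
  rng <- tapply(v[ok], cl[ok], function(u) diff(range(u)))
  all(is.na(rng) | rng == 0)
}

#' @export
print.mlData <- function(x, ...) {
  cat("Two-level dataset:", nrow(x$data), "rows,",
      nlevels(x$cluster), "clusters\n")
  pm <- round(100 * colMeans(x$miss), 1)
  info <- data.frame(level = x$levels, pct.missing = pm)
  print(info)
  invisible(x)
}

#' @export
dim.mlData <- function(x) dim(x$data)

#' Number of clusters
#' @param x an `mlData` object.
#' @export
nClusters <- function(x) nlevels(x$cluster)

#' Missingness mask
#' @param x an `mlData` object.
#' @return logical matrix, `TRUE` where a cell is missing.
#' @export
missingMask <- function(x) x$miss

#' Variable names of a two-level dataset
#' @param x an `mlData` object.
#' @export
variableNames <- function(x) names(x$data)


## ---------------------------------------------------------------------------
## Term algebra: a term is a product of transformed variables.  Transforms:
## identity, cluster mean (manifest, recomputed from current values),
## within-cluster deviation, integer power >= 2.

#' Construct a single factor of a term
#'
#' @param var variable name.
#' @param transform one of `"identity"`, `"cmean"` (manifest cluster mean),
#'   `"wdev"` (deviation from the manifest cluster mean), `"pow"`.
#' @param power integer exponent (>= 2), used only for `transform = "pow"`.
#' @export
termFactor <- function(var, transform = c("identity", "cmean", "wdev", "pow"),
                       power = NULL) {
  transform <- match.arg(transform)
  stopifnot(is.character(var), length(var) == 1L)
  if (transform == "pow") {
    if (is.null(power) || power < 2 || power != round(power))
      stop("power transform needs an integer exponent >= 2")
    power <- as.integer(power)
  } else power <- NULL
  structure(list(var = var, transform = transform, power = power),
            class = "mlTermFactor")
}

.factorLabel <- function(f) {
  switch(f$transform,
         identity = f$var,
         cmean = paste0("cmean(", f$var, ")"),
         wdev = paste0("wdev(", f$var, ")"),
         pow = paste0(f$var, "^", f$power))
}

#' Construct a term as a product of factors
#'
#' The value of the term is the row-wise product of its factors.
#'
#' @param ... factors built with [termFactor()], or bare variable names
#'   (shorthand for identity factors).
#' @return An object of class `mlTerm`.
#' @examples
#' termSpec(termFactor("x", "wdev"), "z")  # the cross-level product wdev(x):z
#' @export
termSpec <- function(...) {
  fs <- lapply(list(...), function(f) {
    if (is.character(f)) termFactor(f) else f
  })
  if (length(fs) == 0L) stop("a term needs at least one factor")
  for (f in fs) if (!inherits(f, "mlTermFactor")) stop("invalid term factor")
  structure(list(factors = fs), class = "mlTerm")
}

#' @export
format.mlTerm <- function(x, ...)
  paste(vapply(x$factors, .factorLabel, ""), collapse = ":")

#' @export
print.mlTerm <- function(x, ...) { cat(format(x), "\n"); invisible(x) }

.termVars <- function(term) unique(vapply(term$factors, `[[`, "", "var"))

## TRUE iff the term takes a single value per cluster
.termIsLevel2 <- function(term, levels) {
  all(vapply(term$factors, function(f) {
    if (f$transform %in% c("cmean")) TRUE
    else if (f$transform == "wdev") FALSE
    else levels[[f$var]] == 2L
  }, NA))
}

## fast path: df = named list of complete numeric columns, ci integer 1..J
.clusterMean <- function(v, ci, njs) {
  unname(rowsum(v, ci)[, 1L] / njs)[ci]
}

.termColumn <- function(term, df, ci, njs) {
  col <- NULL
  for (f in term$factors) {
    v <- df[[f$var]]
    if (is.null(v)) stop("unknown variable '", f$var, "'")
    b <- switch(f$transform,
                identity = v,
                cmean = .clusterMean(v, ci, njs),
                wdev = v - .clusterMean(v, ci, njs),
                pow = v^f$power)
    col <- if (is.null(col)) b else col * b
  }
  col
}

#' Evaluate a term on a dataset
#'
#' Cluster means and within-cluster deviations are *manifest*: they are
#' recomputed from the current values of the variable, so that imputing a cell
#' moves the cluster mean with it. All variables entering the term must be
#' complete (an imputed state); missing cells are an error.
#'
#' @param object an `mlData` object.
#' @param term an `mlTerm`.
#' @return numeric column of length `nrow(object$data)`.
#' @export
computeTerm <- function(object, term) {
  stopifnot(inherits(object, "mlData"), inherits(term, "mlTerm"))
  for (v in .termVars(term)) {
    if (!v %in% names(object$data)) stop("unknown variable '", v, "'")
    if (anyNA(object$data[[v]]))
      stop("variable '", v, "' has missing cells; terms require complete data")
  }
  ci <- as.integer(object$cluster)
  .termColumn(term, object$data, ci, tabulate(ci))
}


## ---------------------------------------------------------------------------
## Model specifications

#' Declare an outcome or covariate model
#'
#' A model specification names the outcome, its level, the ordered fixed
#' terms, and which of the fixed terms (plus the intercept) carry
#' cluster-varying coefficients. Level-2 models have no random part and all
#' their predictors must take a single value per cluster.
#'
#' @param outcome outcome variable name.
#' @param level level of the outcome (1 or 2).
#' @param terms list of `mlTerm` objects (fixed part, in declaration order).
#' @param intercept logical, include an intercept column.
#' @param random integer indices into `terms` whose coefficients vary across
#'   clusters.
#' @param randomIntercept logical, random intercept (level-1 models only).
#' @return An object of class `mlModelSpec`.
#' @export
modelSpec <- function(outcome, level = 1L, terms = list(), intercept = TRUE,
                      random = integer(), randomIntercept = FALSE) {
  stopifnot(is.character(outcome), length(outcome) == 1L)
  level <- as.integer(level)
  if (!level %in% 1:2) stop("outcome level must be 1 or 2")
  for (t in terms) if (!inherits(t, "mlTerm")) stop("terms must be mlTerm objects")
  random <- as.integer(random)
  if (length(random) && (any(random < 1L) || any(random > length(terms))))
    stop("random-term indices must point into the fixed terms")
  if (level == 2L && (length(random) || randomIntercept))
    stop("a level-2 model cannot have random terms")
  structure(
    list(outcome = outcome, level = level, terms = terms,
         intercept = isTRUE(intercept), random = random,
         randomIntercept = isTRUE(randomIntercept)),
    class = "mlModelSpec")
}

#' @export
print.mlModelSpec <- function(x, ...) {
  cat(renderFormula(x), "\n")
  invisible(x)
}

#' Coefficient names of a model specification
#' @param spec an `mlModelSpec`.
#' @export
coefNames <- function(spec) {
  nm <- vapply(spec$terms, format, "")
  if (spec$intercept) nm <- c("(Intercept)", nm)
  nm
}

.nRandom <- function(spec) length(spec$random) + spec$randomIntercept

.validateSpecAgainst <- function(spec, levels) {
  for (t in spec$terms)
    for (v in .termVars(t))
      if (!v %in% names(levels)) stop("unknown variable '", v, "'")
  if (!spec$outcome %in% names(levels))
    stop("unknown outcome '", spec$outcome, "'")
  if (spec$level == 2L) {
    if (levels[[spec$outcome]] != 2L)
      stop("outcome '", spec$outcome, "' is not a level-2 variable")
    for (t in spec$terms)
      if (!.termIsLevel2(t, levels))
        stop("term '", format(t), "' is not representable at level 2")
  }
  invisible(TRUE)
}

#' Fixed-effects design matrix of a model
#'
#' Columns follow the declaration order of the specification, with the
#' intercept column of ones first when present; duplicate terms yield
#' duplicate columns.
#'
#' @param object an `mlData` object with complete data for all model
#'   variables.
#' @param spec an `mlModelSpec`.
#' @return list with `X` (numeric matrix) and `names` (coefficient names).
#' @export
designMatrix <- function(object, spec) {
  stopifnot(inherits(object, "mlData"), inherits(spec, "mlModelSpec"))
  .validateSpecAgainst(spec, object$levels)
  ci <- as.integer(object$cluster)
  njs <- tabulate(ci)
  cols <- lapply(spec$terms, function(t) {
    for (v in .termVars(t))
      if (anyNA(object$data[[v]]))
        stop("variable '", v, "' has missing cells; terms require complete data")
    .termColumn(t, object$data, ci, njs)
  })
  if (spec$intercept) cols <- c(list(rep(1, nrow(object$data))), cols)
  X <- do.call(cbind, cols)
  colnames(X) <- coefNames(spec)
  list(X = X, names = coefNames(spec))
}

.designMatrixFast <- function(spec, df, ci, njs, n) {
  p <- length(spec$terms) + spec$intercept
  X <- matrix(0, n, p)
  j <- 0L
  if (spec$intercept) { j <- 1L; X[, 1L] <- 1 }
  for (t in spec$terms) {
    j <- j + 1L
    X[, j] <- .termColumn(t, df, ci, njs)
  }
  X
}

## random-effects design (level-1 models): intercept column then random terms
.zMatrixFast <- function(spec, df, ci, njs, n) {
  r <- .nRandom(spec)
  if (r == 0L) return(NULL)
  Z <- matrix(0, n, r)
  j <- 0L
  if (spec$randomIntercept) { j <- 1L; Z[, 1L] <- 1 }
  for (k in spec$random) {
    j <- j + 1L
    Z[, j] <- .termColumn(spec$terms[[k]], df, ci, njs)
  }
  Z
}


## ---------------------------------------------------------------------------
## CSV interface (long format, one header row, "" or "NA" = missing)

#' Read a long-format CSV as a two-level dataset
#'
#' @param path file path.
#' @param cluster cluster-id column name.
#' @param levels optional named level assignment, as in [multilevelData()].
#' @export
readMultilevelData <- function(path, cluster, levels = NULL) {
  d <- utils::read.csv(path, na.strings = c("", "NA"))
  multilevelData(d, cluster = cluster, levels = levels)
}

#' Write a set of imputations as one stacked CSV
#'
#' The completed datasets are stacked with an imputation-index column `.imp`
#' (0 = the original data with its missing cells) and a row index `.id`.
#'
#' @param imp an `mlImputationSet` from [smcImpute()].
#' @param path output file path.
#' @param includeOriginal prepend the incomplete original as `.imp = 0`.
#' @export
writeImputations <- function(imp, path, includeOriginal = TRUE) {
  stopifnot(inherits(imp, "mlImputationSet"))
  orig <- imp$dataset
  base <- data.frame(cluster = orig$cluster, orig$data, check.names = FALSE)
  names(base)[1L] <- imp$clusterName
  out <- list()
  if (includeOriginal)
    out[[1L]] <- data.frame(.imp = 0L, .id = seq_len(nrow(base)), base,
                            check.names = FALSE)
  for (k in seq_along(imp$imputations)) {
    b <- base
    b[names(imp$imputations[[k]])] <- imp$imputations[[k]]
    out[[length(out) + 1L]] <-
      data.frame(.imp = k, .id = seq_len(nrow(base)), b, check.names = FALSE)
  }
  utils::write.csv(do.call(rbind, out), path, row.names = FALSE, na = "")
  invisible(path)
}
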