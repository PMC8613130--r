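#' Parse a model formula into a specification
#'
#' The grammar mirrors mixed-model notation with two extra transforms:
#' `cmean(x)` is the manifest cluster mean of `x`, `wdev(x)` the deviation
#' from it, `x^k` an integer power (k >= 2), `:` a product of factors, and
#' `(terms | cluster)` the random part. `1` and `0` switch the intercept.
#' Random terms must also appear in the fixed part (the random intercept
#' excepted, which is implicit in the random part as in lme4).
#'
#' @param text formula string, e.g.
#'   `"y ~ 1 + wdev(x) + cmean(x) + z + wdev(x):z + (1 + wdev(x) | g)"`.
#' @param level level of the outcome variable (1 or 2); a level-2 model may
#'   not carry a random part.
#' @return An `mlModelSpec`; the cluster label of the random part is stored
#'   in attribute `"cluster"`.
#' @export
parseFormula <- function(text, level = 1L) {
  stopifnot(is.character(text), length(text) == 1L)
  raw <- text
  pos <- regexpr("~", text, fixed = TRUE)
  if (pos < 0) stop("formula needs '~' (in \"", raw, "\")")
  if (gregexpr("~", text, fixed = TRUE)[[1L]][1L] != pos ||
      length(gregexpr("~", text, fixed = TRUE)[[1L]]) != 1L)
    stop("formula must contain exactly one '~'")
  lhs <- trimws(substr(text, 1L, pos - 1L))
  rhs <- substr(text, pos + 1L, nchar(text))
  if (!grepl("^[A-Za-z.][A-Za-z0-9._]*$", lhs))
    stop("invalid outcome name '", lhs, "' at position 1")

  sp <- .splitRandomParts(rhs, offset = pos)
  if (length(sp$random) > 1L)
    stop("at most one random part is allowed")

  fixed <- .parseTermList(sp$fixed, offset = pos)
  spec <- NULL
  clusterName <- NULL
  if (length(sp$random) == 1L) {
    if (level == 2L) stop("a level-2 model cannot have a random part")
    rp <- sp$random[[1L]]
    bar <- .topLevelPositions(rp$text, "|")
    if (length(bar) != 1L)
      stop("random part needs exactly one '|' at position ", rp$pos)
    rterms <- .parseTermList(substr(rp$text, 1L, bar - 1L), offset = rp$pos,
                             interceptDefault = TRUE)
    clusterName <- trimws(substr(rp$text, bar + 1L, nchar(rp$text)))
    if (!grepl("^[A-Za-z.][A-Za-z0-9._]*$", clusterName))
      stop("invalid cluster name '", clusterName, "' at position ", rp$pos)
    labs <- vapply(fixed$terms, format, "")
    ridx <- integer(0)
    for (t in rterms$terms) {
      k <- match(format(t), labs)
      if (is.na(k))
        stop("random term '", format(t), "' does not appear in the fixed part")
      ridx <- c(ridx, k)
    }
    spec <- modelSpec(lhs, level = level, terms = fixed$terms,
                      intercept = fixed$intercept, random = ridx,
                      randomIntercept = rterms$intercept)
  } else {
    spec <- modelSpec(lhs, level = level, terms = fixed$terms,
                      intercept = fixed$intercept)
  }
  attr(spec, "cluster") <- clusterName
  spec
}

## find top-level occurrences of a single character, honouring parentheses
.topLevelPositions <- function(text, ch) {
  depth <- 0L
  out <- integer(0)
  cs <- strsplit(text, "")[[1L]]
  for (i in seq_along(cs)) {
    if (cs[i] == "(") depth <- depth + 1L
    else if (cs[i] == ")") depth <- depth - 1L
    else if (cs[i] == ch && depth == 0L) out <- c(out, i)
  }
  out
}

## separate "( ... | ... )" groups (random parts) from the fixed part
.splitRandomParts <- function(rhs, offset = 0L) {
  cs <- strsplit(rhs, "")[[1L]]
  depth <- 0L
  i <- 1L
  fixedChars <- character(0)
  random <- list()
  n <- length(cs)
  while (i <= n) {
    c1 <- cs[i]
    prev <- if (i > 1L) cs[i - 1L] else ""
    if (c1 == "(" && !grepl("[A-Za-z0-9._]", prev)) {
      ## grouping parenthesis: scan to its match
      j <- i; d <- 0L
      repeat {
        if (cs[j] == "(") d <- d + 1L
        if (cs[j] == ")") d <- d - 1L
        if (d == 0L) break
        j <- j + 1L
        if (j > n) stop("unbalanced parentheses at position ", offset + i)
      }
      inner <- paste(cs[(i + 1L):(j - 1L)], collapse = "")
      if (length(.topLevelPositions(inner, "|")) > 0L) {
        random[[length(random) + 1L]] <- list(text = inner, pos = offset + i)
        ## swallow a dangling '+' before the group
        fixedChars <- .dropTrailingPlus(fixedChars)
      } else {
        stop("parenthesized group without '|' at position ", offset + i,
             " (grouping is not part of the grammar)")
      }
      i <- j + 1L
    } else {
      fixedChars <- c(fixedChars, c1)
      i <- i + 1L
    }
  }
  list(fixed = paste(fixedChars, collapse = ""), random = random)
}

.dropTrailingPlus <- function(chars) {
  k <- length(chars)
  while (k > 0L && grepl("^\\s$", chars[k])) k <- k - 1L
  if (k > 0L && chars[k] == "+") k <- k - 1L
  chars[seq_len(k)]
}

.parseTermList <- function(text, offset = 0L, interceptDefault = TRUE) {
  pieces <- .splitTopLevel(text, "+")
  terms <- list()
  intercept <- interceptDefault
  sawOne <- FALSE
  for (p in pieces) {
    tok <- trimws(p$text)
    if (tok == "") next
    if (tok == "1") { intercept <- TRUE; sawOne <- TRUE; next }
    if (tok == "0" || tok == "-1") { intercept <- FALSE; next }
    terms[[length(terms) + 1L]] <- .parseTerm(tok, offset + p$pos)
  }
  if (!sawOne && interceptDefault) intercept <- intercept  # lme4-style default
  list(terms = terms, intercept = intercept)
}

.splitTopLevel <- function(text, ch) {
  cuts <- .topLevelPositions(text, ch)
  starts <- c(1L, cuts + 1L)
  ends <- c(cuts - 1L, nchar(text))
  lapply(seq_along(starts), function(k) {
    list(text = substr(text, starts[k], ends[k]), pos = starts[k])
  })
}

.parseTerm <- function(tok, pos) {
  parts <- .splitTopLevel(tok, ":")
  fs <- lapply(parts, function(p) .parseFactor(trimws(p$text), pos + p$pos - 1L))
  do.call(termSpec, fs)
}

.parseFactor <- function(tok, pos) {
  m <- regmatches(tok, regexec("^(cmean|wdev)\\(\\s*([A-Za-z.][A-Za-z0-9._]*)\\s*\\)$", tok))[[1L]]
  if (length(m) == 3L)
    return(termFactor(m[3L], transform = m[2L]))
  m <- regmatches(tok, regexec("^([A-Za-z.][A-Za-z0-9._]*)\\^([0-9]+)$", tok))[[1L]]
  if (length(m) == 3L) {
    k <- as.integer(m[3L])
    if (k < 2L) stop("power must be >= 2 in '", tok, "' at position ", pos)
    return(termFactor(m[2L], transform = "pow", power = k))
  }
  if (grepl("^[A-Za-z.][A-Za-z0-9._]*$", tok))
    return(termFactor(tok))
  stop("cannot parse factor '", tok, "' at position ", pos)
}

#' Render a model specification back to its formula string
#'
#' `parseFormula()` and `renderFormula()` round-trip: rendering a parsed
#' formula and parsing it again gives the same rendering.
#'
#' @param spec an `mlModelSpec`.
#' @param cluster cluster label for the random part; defaults to the label
#'   recorded by [parseFormula()], else `"cluster"`.
#' @export
renderFormula <- function(spec, cluster = NULL) {
  stopifnot(inherits(spec, "mlModelSpec"))
  if (is.null(cluster))
    cluster <- attr(spec, "cluster")
  if (is.null(cluster)) cluster <- "cluster"
  labs <- vapply(spec$terms, format, "")
  fixed <- c(if (spec$intercept) "1" else "0", labs)
  out <- paste0(spec$outcome, " ~ ", paste(fixed, collapse = " + "))
  if (.nRandom(spec) > 0L) {
    rl <- c(if (spec$randomIntercept) "1" else "0", labs[spec$random])
    out <- paste0(out, " + (", paste(rl, collapse = " + "), " | ", cluster, ")")
  }
  out
}
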