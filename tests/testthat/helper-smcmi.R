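## shared fixture builders (all data generated in code)

toyData <- function(J = 4, n = 3, seed = 1, missing = 0) {
  set.seed(seed)
  g <- rep(seq_len(J), each = n)
  z <- rnorm(J)
  d <- data.frame(g = g,
                  x = rnorm(J * n),
                  z = z[g],
                  y = rnorm(J * n))
  if (missing > 0) {
    idx <- sample(seq_len(J * n), missing)
    d$x[idx] <- NA
  }
  multilevelData(d, cluster = "g", levels = c(x = 1, z = 2, y = 1))
}

## independent normal log-density oracle (plain loop, no package code)
normLogLik <- function(y, mu, s2) {
  out <- 0
  for (i in seq_along(y))
    out <- out - 0.5 * log(2 * pi * s2) - (y[i] - mu[i])^2 / (2 * s2)
  out
}
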