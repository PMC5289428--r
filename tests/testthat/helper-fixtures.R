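# Small fixtures built in code, shared across test files.

# A tiny quiet bundle: no nuisance structure unless asked for, so planted
# effects can be checked exactly.
quietConfig <- function(..., seed) {
  defaults <- list(
    nSubjects = 40L, nSnps = 3L, nGenes = 30L,
    ageEffectSd = 0, yearEffectSd = 0, batchShiftSd = 0,
    subjectSd = 0, tissueShiftSd = 0,
    receptorShiftSd = 0, receptorDeFraction = 0,
    noiseSd = 0.5, seed = seed)
  do.call(simConfig, utils::modifyList(defaults, list(...)))
}

# Brute-force normal-equations OLS for one response: the independent
# oracle olsFit is checked against.
olsOracle <- function(y, X) {
  XtX <- t(X) %*% X
  beta <- solve(XtX, t(X) %*% y)
  res <- y - X %*% beta
  d <- nrow(X) - ncol(X)
  list(beta = drop(beta),
       s2 = if (d > 0) sum(res^2) / d else NA_real_,
       d = d,
       u = sqrt(diag(solve(XtX))))
}

# Brute-force BH step-up: q_(i) = min_{j>=i} p_(j) * m / j.
bhOracle <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- numeric(m)
  for (i in seq_len(m)) q[i] <- min(ps[i:m] * m / (i:m), 1)
  q[order(o)]
}

# Brute-force all-pairs Mann-Whitney AUC.
aucOracle <- function(pos, neg) {
  cnt <- 0
  for (a in pos) for (b in neg) cnt <- cnt + (a > b) + 0.5 * (a == b)
  cnt / (length(pos) * length(neg))
}

# Classical full-vs-reduced F from explicit residual sums of squares.
rssF <- function(y, Xfull, Xred) {
  rss <- function(X) {
    b <- solve(t(X) %*% X, t(X) %*% y)
    sum((y - X %*% b)^2)
  }
  r1 <- rss(Xfull); r0 <- rss(Xred)
  k <- ncol(Xfull) - ncol(Xred)
  d <- length(y) - ncol(Xfull)
  ((r0 - r1) / k) / (r1 / d)
}
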