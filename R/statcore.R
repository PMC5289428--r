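#' Gene-wise ordinary least squares against a shared design
#'
#' Fits `y_g = X b_g + e_g` for every row of `responses` by exact least
#' squares. Residual variance is `RSS / d` with `d = n - ncol(X)`; the
#' unscaled standard error factor of coefficient j is
#' `sqrt(diag((X'X)^{-1}))[j]`, so that `se(b_j) = u_j * s`. A saturated
#' fit (`d = 0`) is kept with `sigma2 = NA` rather than erroring, so
#' downstream moderation can still use the prior.
#'
#' @param responses numeric matrix genes x samples (a vector is treated as
#'   one gene). May contain `NA` only when `naAction = "complete.cases"`,
#'   in which case affected genes are refit on their complete cases and
#'   their `nObs`/`dfResidual` are reduced accordingly.
#' @param design numeric design matrix, samples x coefficients, with unique
#'   column names. Must be full column rank: aliased (linearly dependent)
#'   columns raise an error naming them.
#' @param naAction `"fail"` (default) or `"complete.cases"`.
#' @return a [GeneFit-class]
#' @examples
#' X <- cbind(intercept = 1, x = 0:2)
#' fit <- olsFit(rbind(g1 = c(1, 2, 3)), X)
#' coef(fit)          # (1, 1): perfect fit
#' @export
olsFit <- function(responses, design, naAction = c("fail", "complete.cases")) {
  naAction <- match.arg(naAction)
  if (is.null(dim(responses))) responses <- rbind(y = responses)
  responses <- as.matrix(responses)
  design <- as.matrix(design)
  if (is.null(colnames(design)) || anyDuplicated(colnames(design)))
    stop("design columns must be uniquely named")
  if (anyNA(design)) stop("design must not contain missing values")
  n <- nrow(design)
  p <- ncol(design)
  if (ncol(responses) != n)
    stop("responses must have one column per design row")
  qrX <- qr(design)
  if (qrX$rank < p) {
    aliased <- colnames(design)[qrX$pivot[(qrX$rank + 1L):p]]
    stop("design is rank deficient; aliased columns: ",
         paste(aliased, collapse = ", "))
  }
  hasNA <- anyNA(responses)
  if (hasNA && naAction == "fail")
    stop("responses contain missing values; use naAction = 'complete.cases'")

  C <- chol2inv(chol(crossprod(design)))
  dimnames(C) <- list(colnames(design), colnames(design))
  u <- sqrt(diag(C))
  d <- n - p

  ng <- nrow(responses)
  coefs <- matrix(NA_real_, ng, p, dimnames = list(rownames(responses),
                                                   colnames(design)))
  su <- matrix(rep(u, each = ng), ng, p, dimnames = dimnames(coefs))
  sigma2 <- rep(NA_real_, ng)
  dfres <- rep(as.numeric(d), ng)
  nObs <- rep(as.numeric(n), ng)

  ok <- if (hasNA) !apply(is.na(responses), 1L, any) else rep(TRUE, ng)
  if (any(ok)) {
    Y <- responses[ok, , drop = FALSE]
    B <- Y %*% design %*% C
    fitted <- B %*% t(design)
    rss <- rowSums((Y - fitted)^2)
    coefs[ok, ] <- B
    sigma2[ok] <- if (d > 0) rss / d else NA_real_
  }
  if (any(!ok)) {
    for (g in which(!ok)) {
      use <- !is.na(responses[g, ])
      Xg <- design[use, , drop = FALSE]
      qg <- qr(Xg)
      if (qg$rank < p)
        stop("gene '", rownames(responses)[g],
             "': design rank deficient after removing missing samples")
      Cg <- chol2inv(chol(crossprod(Xg)))
      bg <- drop(Cg %*% crossprod(Xg, responses[g, use]))
      rssg <- sum((responses[g, use] - drop(Xg %*% bg))^2)
      dg <- sum(use) - p
      coefs[g, ] <- bg
      su[g, ] <- sqrt(diag(Cg))
      sigma2[g] <- if (dg > 0) rssg / dg else NA_real_
      dfres[g] <- dg
      nObs[g] <- sum(use)
    }
  }
  # exact zero residual variance can come out as tiny negative rounding
  sigma2[!is.na(sigma2) & sigma2 < 0] <- 0
  new("GeneFit", coefficients = coefs, stdevUnscaled = su, sigma2 = sigma2,
      dfResidual = dfres, covUnscaled = C, nObs = nObs)
}

#' @describeIn olsFit coefficient matrix of a fit
#' @param object a [GeneFit-class]
#' @param ... ignored
#' @export
setMethod("coef", "GeneFit", function(object, ...) object@coefficients)

#' @describeIn olsFit display summary
#' @export
setMethod("show", "GeneFit", function(object) {
  cat("GeneFit:", nrow(object@coefficients), "responses x",
      ncol(object@coefficients), "coefficients; residual df",
      paste(range(object@dfResidual), collapse = "-"), "\n")
})

# Invert the trigamma function by Newton iteration on 1/trigamma (which is
# nearly linear); used by the moment-matching prior estimator.
trigammaInverse <- function(x) {
  y <- 0.5 + 1 / x            # asymptotic start
  for (i in 1:60) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2L)
    y <- y + dif
    if (max(abs(dif / y)) < 1e-10) break
  }
  y
}

#' Estimate the empirical-Bayes variance prior
#'
#' Moment-matches the marginal distribution of log sample variances against
#' the scaled-F marginal implied by a scaled inverse-chi-square prior on the
#' true gene variances: with `z = log(s^2)` and
#' `e = z - digamma(d/2) + log(d/2)`, the excess spread
#' `var(e) - mean(trigamma(d/2))` equals `trigamma(d0/2)`, solved for `d0`
#' by inverting the trigamma function, and `s0^2` follows from the mean of
#' `e`. When the observed spread does not exceed the sampling spread the
#' prior degrees of freedom are infinite (full shrinkage): `s0^2` is then
#' the common variance if the `s^2` are all equal, otherwise their mean.
#'
#' @param s2 either a [GeneFit-class] or a numeric vector of residual
#'   variances.
#' @param df residual degrees of freedom (scalar or per-gene vector);
#'   ignored when `s2` is a `GeneFit`.
#' @param minGenes minimum number of usable genes (positive variance,
#'   `df >= 1`); fewer is an error.
#' @return a [VariancePrior-class]
#' @examples
#' set.seed(1)
#' s2 <- 2 * 4 / rchisq(500, df = 4)   # scaled inverse-chi-square draws
#' estimateVariancePrior(s2, df = 10)
#' @export
estimateVariancePrior <- function(s2, df = NULL, minGenes = 10L) {
  if (methods::is(s2, "GeneFit")) {
    df <- s2@dfResidual
    s2 <- s2@sigma2
  }
  keep <- !is.na(s2) & rep_len(df, length(s2)) >= 1
  s2 <- s2[keep]
  df <- rep_len(df, length(keep))[keep]
  if (all(s2 == 0)) stop("degenerate variances: all residual variances are zero")
  pos <- s2 > 0
  s2 <- s2[pos]; df <- df[pos]
  if (length(s2) < minGenes)
    stop("too few genes with positive variance and df >= 1 (need ",
         minGenes, ", got ", length(s2), ")")
  z <- log(s2)
  e <- z - digamma(df / 2) + log(df / 2)
  emean <- mean(e)
  evar <- var(e) - mean(trigamma(df / 2))
  if (var(z) < 1e-25) {                 # all sample variances identical
    return(new("VariancePrior", dfPrior = Inf, varPrior = s2[[1L]]))
  }
  if (evar <= 0) {
    return(new("VariancePrior", dfPrior = Inf, varPrior = mean(s2)))
  }
  d0 <- 2 * trigammaInverse(evar)
  s02 <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  new("VariancePrior", dfPrior = d0, varPrior = s02)
}

#' Prior hyperparameter accessors
#' @param x a [VariancePrior-class]
#' @return `dfPrior`: prior degrees of freedom; `varPrior`: prior variance.
#' @name prior-accessors
NULL

#' @rdname prior-accessors
#' @export
dfPrior <- function(x) x@dfPrior

#' @rdname prior-accessors
#' @export
varPrior <- function(x) x@varPrior

# Posterior (shrunken) variances and total df for a fit under a prior.
posteriorVar <- function(fit, prior) {
  d0 <- prior@dfPrior
  s02 <- prior@varPrior
  d <- fit@dfResidual
  s2 <- fit@sigma2
  s2[is.na(s2)] <- 0      # saturated fits carry no variance information
  if (is.infinite(d0)) {
    list(s2post = rep(s02, length(s2)), dfTotal = rep(Inf, length(s2)))
  } else {
    list(s2post = (d0 * s02 + d * s2) / (d0 + d), dfTotal = d0 + d)
  }
}

#' Moderated t statistic for one coefficient
#'
#' Shrinks each gene's residual variance toward the prior,
#' `s~^2 = (d0*s0^2 + d*s^2) / (d0 + d)`, and tests the named coefficient
#' with `t~ = b / (u * s~)` on `d0 + d` degrees of freedom (two-sided p).
#' With `d0 = 0` this is the classical OLS t; with `d0 = Inf` the
#' denominator uses `s0^2` exactly and p-values come from the normal tail
#' (t with infinite df).
#'
#' @param fit a [GeneFit-class]
#' @param prior a [VariancePrior-class]; `priorZero()` gives the
#'   no-shrinkage limit.
#' @param coef name (or index) of the coefficient to test.
#' @return `data.frame` with columns `beta`, `t`, `p`, `dfTotal`, one row
#'   per gene.
#' @examples
#' X <- cbind(intercept = 1, x = c(0, 1, 2, 3))
#' fit <- olsFit(rbind(g = c(1, 2, 2, 5)), X)
#' moderatedT(fit, priorZero(), "x")
#' @export
moderatedT <- function(fit, prior, coef) {
  stopifnot(methods::is(fit, "GeneFit"), methods::is(prior, "VariancePrior"))
  if (is.character(coef) && !coef %in% colnames(fit@coefficients))
    stop("coefficient '", coef, "' not in fit")
  b <- fit@coefficients[, coef]
  u <- fit@stdevUnscaled[, coef]
  if (any(!is.finite(u) | u == 0))
    stop("coefficient not estimable: zero unscaled standard error")
  pv <- posteriorVar(fit, prior)
  tt <- b / (u * sqrt(pv$s2post))
  p <- 2 * pt(-abs(tt), df = pv$dfTotal)
  data.frame(beta = b, t = tt, p = p, dfTotal = pv$dfTotal,
             row.names = rownames(fit@coefficients))
}

#' Moderated F statistic for a joint test of several coefficients
#'
#' Tests `H0: b_J = 0` for the named coefficient subset J with
#' `F~ = b_J' (C_JJ)^{-1} b_J / (k * s~^2)`, where `C = (X'X)^{-1}`,
#' `k = |J|`, and `s~^2` is the shrunken variance. Numerator df is `k`,
#' denominator df `d0 + d`. With a single coefficient `F~ = t~^2`; with
#' `d0 = 0` it equals the classical full-vs-reduced F.
#'
#' Requires the shared-design covariance, so genes refit on complete cases
#' after missing values are rejected.
#'
#' @inheritParams moderatedT
#' @param coefs character vector of coefficient names (or indices).
#' @return `data.frame` with columns `F`, `p`, `dfNum`, `dfDen`.
#' @export
moderatedF <- function(fit, prior, coefs) {
  stopifnot(methods::is(fit, "GeneFit"), methods::is(prior, "VariancePrior"))
  if (is.character(coefs)) {
    bad <- setdiff(coefs, colnames(fit@coefficients))
    if (length(bad)) stop("unknown coefficients: ", paste(bad, collapse = ", "))
  }
  if (length(unique(fit@nObs)) > 1L)
    stop("moderated F requires a shared design (no per-gene complete-case fits)")
  CJJ <- fit@covUnscaled[coefs, coefs, drop = FALSE]
  Cinv <- solve(CJJ)
  B <- fit@coefficients[, coefs, drop = FALSE]
  k <- length(coefs)
  quad <- rowSums((B %*% Cinv) * B)
  pv <- posteriorVar(fit, prior)
  Fstat <- quad / (k * pv$s2post)
  p <- pf(Fstat, df1 = k, df2 = pv$dfTotal, lower.tail = FALSE)
  data.frame(F = Fstat, p = p, dfNum = k, dfDen = pv$dfTotal,
             row.names = rownames(fit@coefficients))
}

#' The no-shrinkage variance prior
#'
#' `d0 = 0` limit under which [moderatedT()] and [moderatedF()] reduce to
#' the classical OLS t and F. (`varPrior` is irrelevant at `d0 = 0`; a
#' placeholder of 1 is stored.)
#' @return a [VariancePrior-class] with `dfPrior` numerically zero.
#' @export
priorZero <- function() {
  # validity requires dfPrior > 0; the smallest positive double is an exact
  # algebraic zero in (d0*s02 + d*s2)/(d0 + d)
  new("VariancePrior", dfPrior = .Machine$double.xmin, varPrior = 1)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Step-up adjusted p-values (q-values): with p-values ranked ascending,
#' `q_(i) = min_{j >= i} p_(j) * m / j`, capped at 1. Ties share a rank and
#' therefore an adjusted value; the output is monotone non-decreasing in p
#' and invariant to input order.
#'
#' @param p numeric vector of p-values in `[0, 1]`, no missing values.
#' @return numeric vector of adjusted values, same length and order as `p`.
#' @examples
#' bhAdjust(c(0.01, 0.02, 0.03, 0.04))   # all 0.04
#' @export
bhAdjust <- function(p) {
  if (length(p) == 0L) return(numeric(0))
  if (anyNA(p) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1] with no missing values")
  m <- length(p)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  q <- pmin(1, cummin(p[o] * m / (m:1)))[ro]
  q
}

#' Spearman rank correlation
#'
#' Pearson correlation of average-ranked values (ties get average ranks).
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return correlation in `[-1, 1]`.
#' @examples
#' spearmanCorr(1:3, c(10, 20, 30))   # 1
#' @export
spearmanCorr <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L)
    stop("x and y must have equal length >= 3")
  if (anyNA(x) || anyNA(y)) stop("missing values not allowed")
  if (sd(x) == 0 || sd(y) == 0)
    stop("undefined correlation: constant vector")
  cor(x, y, method = "spearman")
}
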