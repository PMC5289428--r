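test_that("olsFit reproduces textbook least squares", {
  # perfect fit: zero residual variance, one residual df
  X <- cbind(intercept = 1, x = c(0, 1, 2))
  fit <- olsFit(rbind(g = c(1, 2, 3)), X)
  expect_equal(unname(coef(fit)[1, ]), c(1, 1))
  expect_equal(fit@sigma2, 0)
  expect_equal(fit@dfResidual, 1)

  # normal-equations oracle on a fixed instance
  X <- cbind(intercept = 1, x = 0:3)
  y <- c(1, 2, 2, 5)
  fit <- olsFit(rbind(g = y), X)
  orc <- olsOracle(y, X)
  expect_equal(unname(coef(fit)[1, ]), unname(orc$beta))
  expect_equal(fit@sigma2, orc$s2)

  # random small instances, 1e-10 relative agreement
  withr::with_seed(42, {
    for (rep in 1:20) {
      n <- sample(8:30, 1)
      p <- sample(2:6, 1)
      X <- cbind(1, matrix(rnorm(n * (p - 1)), n))
      colnames(X) <- paste0("c", seq_len(p))
      Y <- matrix(rnorm(3 * n), 3)
      fit <- olsFit(Y, X)
      for (g in 1:3) {
        orc <- olsOracle(Y[g, ], X)
        expect_equal(unname(coef(fit)[g, ]), unname(orc$beta),
                     tolerance = 1e-10)
        expect_equal(fit@sigma2[g], orc$s2, tolerance = 1e-10)
        expect_equal(unname(fit@stdevUnscaled[g, ]), unname(orc$u),
                     tolerance = 1e-10)
      }
    }
  })
})

test_that("olsFit rejects rank-deficient designs, naming aliased columns", {
  X <- cbind(intercept = 1, x = 1:4, x_copy = 1:4)
  expect_error(olsFit(rbind(g = rnorm(4)), X), "x_copy")
})

test_that("olsFit complete-case policy handles missing responses per gene", {
  X <- cbind(intercept = 1, x = rnorm(12))
  Y <- rbind(g1 = rnorm(12), g2 = c(NA, rnorm(11)))
  expect_error(olsFit(Y, X), "missing")
  fit <- olsFit(Y, X, naAction = "complete.cases")
  expect_equal(fit@nObs, c(12, 11))
  orc <- olsOracle(Y[2, -1], X[-1, ])
  expect_equal(unname(coef(fit)[2, ]), unname(orc$beta), tolerance = 1e-10)
  expect_equal(fit@dfResidual[2], 9)
})

test_that("variance prior recovers known hyperparameters from simulation", {
  # draws from the scaled inverse-chi-square prior with d0=4, s0^2=2, then
  # sampling noise at d=10; the generating parameters are the oracle
  withr::with_seed(7, {
    d0 <- 4; s02 <- 2; d <- 10
    trueVar <- d0 * s02 / rchisq(5000, df = d0)
    s2 <- trueVar * rchisq(5000, df = d) / d
    prior <- estimateVariancePrior(s2, df = d)
    expect_lt(abs(dfPrior(prior) - d0) / d0, 0.15)
    expect_lt(abs(varPrior(prior) - s02) / s02, 0.05)
  })
})

test_that("variance prior degenerate and boundary inputs follow the policy", {
  expect_error(estimateVariancePrior(rep(0, 20), df = 5), "degenerate")
  expect_error(estimateVariancePrior(c(1, 2), df = 5), "too few")
  # identical variances: full shrinkage onto that value
  prior <- estimateVariancePrior(rep(1.7, 50), df = 8)
  expect_equal(dfPrior(prior), Inf)
  expect_equal(varPrior(prior), 1.7)
})

test_that("moderated t matches the stated shrinkage arithmetic and limits", {
  X <- cbind(intercept = 1, x = c(-1.2, 0.3, 1.1, -0.5, 0.8, 1.9))
  withr::with_seed(3, Y <- matrix(rnorm(12 * 6), 12))
  fit <- olsFit(Y, X)

  # d0 = 0: ordinary OLS t exactly
  tt <- moderatedT(fit, priorZero(), "x")
  tOls <- coef(fit)[, "x"] / (fit@stdevUnscaled[, "x"] * sqrt(fit@sigma2))
  expect_equal(tt$t, tOls, tolerance = 1e-12)
  expect_equal(tt$dfTotal, fit@dfResidual)

  # stated arithmetic: s2=1, d=4, d0=4, s02=4 -> s~2 = 2.5, df = 8
  prior <- new("VariancePrior", dfPrior = 4, varPrior = 4)
  fit1 <- fit
  fit1@sigma2 <- rep(1, 12)
  fit1@dfResidual <- rep(4, 12)
  tt <- moderatedT(fit1, prior, "x")
  expect_equal(tt$t, coef(fit)[, "x"] / (fit@stdevUnscaled[, "x"] * sqrt(2.5)),
               tolerance = 1e-12)
  expect_equal(unique(tt$dfTotal), 8)

  # d0 = Inf: denominator uses s0^2 exactly, normal-tail p
  priorInf <- new("VariancePrior", dfPrior = Inf, varPrior = 4)
  tt <- moderatedT(fit, priorInf, "x")
  expect_equal(tt$t, coef(fit)[, "x"] / (fit@stdevUnscaled[, "x"] * 2),
               tolerance = 1e-12)
  expect_equal(tt$p, 2 * pnorm(-abs(tt$t)), tolerance = 1e-12)
})

test_that("moderated t agrees with limma's eBayes pipeline", {
  withr::with_seed(11, {
    n <- 20
    X <- cbind(intercept = 1, x = rnorm(n))
    Y <- matrix(rnorm(200 * n), 200) * rep(sqrt(0.5 + rexp(200)), n)
    fit <- olsFit(Y, X)
    prior <- estimateVariancePrior(fit)
    tt <- moderatedT(fit, prior, "x")
    lf <- limma::eBayes(limma::lmFit(Y, X))
    expect_equal(dfPrior(prior), lf$df.prior, tolerance = 1e-6)
    expect_equal(varPrior(prior), lf$s2.prior, tolerance = 1e-6)
    expect_equal(tt$t, unname(lf$t[, "x"]), tolerance = 1e-8)
    expect_equal(tt$p, unname(lf$p.value[, "x"]), tolerance = 1e-8)
  })
})

test_that("moderated t p-values are uniform under the global null", {
  withr::with_seed(19, {
    n <- 30
    X <- cbind(intercept = 1, x = rnorm(n))
    Y <- matrix(rnorm(2000 * n), 2000)
    fit <- olsFit(Y, X)
    tt <- moderatedT(fit, estimateVariancePrior(fit), "x")
    expect_gt(ks.test(tt$p, "punif")$p.value, 0.01)
  })
})

test_that("moderated F matches its classical and single-coefficient limits", {
  withr::with_seed(5, {
    n <- 24
    grp <- rep(1:4, each = 6)
    X <- cbind(intercept = 1, g2 = as.numeric(grp == 2),
               g3 = as.numeric(grp == 3), g4 = as.numeric(grp == 4))
    Y <- matrix(rnorm(10 * n), 10)
    fit <- olsFit(Y, X)

    # d0 = 0 equals the full-vs-reduced RSS F, gene by gene
    ff <- moderatedF(fit, priorZero(), c("g2", "g3", "g4"))
    for (g in 1:10) {
      expect_equal(ff$F[g],
                   rssF(Y[g, ], X, X[, 1, drop = FALSE]),
                   tolerance = 1e-10)
    }
    expect_equal(ff$dfNum[1], 3)

    # single coefficient: F = t^2
    prior <- estimateVariancePrior(fit)
    f1 <- moderatedF(fit, prior, "g2")
    t1 <- moderatedT(fit, prior, "g2")
    expect_equal(f1$F, t1$t^2, tolerance = 1e-10)

    # exact null: identical group means, zero noise
    Yc <- matrix(rep(rnorm(3), n), 3)
    fitc <- olsFit(Yc, X)
    fc <- moderatedF(fitc, new("VariancePrior", dfPrior = 4, varPrior = 1),
                     c("g2", "g3", "g4"))
    expect_equal(fc$F, rep(0, 3))
  })
})

test_that("BH adjustment equals brute-force step-up and is order invariant", {
  expect_equal(bhAdjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bhAdjust(0.37), 0.37)                 # m = 1
  expect_equal(bhAdjust(rep(0.2, 5)), rep(0.2, 5))   # all equal
  expect_equal(bhAdjust(numeric(0)), numeric(0))
  expect_error(bhAdjust(c(0.5, 1.2)), "0, 1")

  withr::with_seed(23, {
    for (rep in 1:200) {
      p <- runif(sample(1:40, 1))^sample(1:3, 1)
      q <- bhAdjust(p)
      expect_equal(q, bhOracle(p))
      expect_equal(q, p.adjust(p, "BH"))
      expect_true(all(q >= p - 1e-15))
      perm <- sample(length(p))
      expect_equal(bhAdjust(p[perm]), q[perm])
    }
  })
})

test_that("Spearman correlation handles monotone, reversed and tied data", {
  expect_equal(spearmanCorr(1:3, c(10, 20, 30)), 1)
  expect_equal(spearmanCorr(1:3, c(3, 2, 1)), -1)
  # tied data against manually assigned average ranks
  x <- c(1, 1, 2); y <- c(1, 2, 3)
  expect_equal(spearmanCorr(x, y),
               cor(c(1.5, 1.5, 3), c(1, 2, 3)))
  expect_error(spearmanCorr(c(1, 1, 1), 1:3), "constant")
  expect_error(spearmanCorr(1:2, 1:2), "length")
})
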