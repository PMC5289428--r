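test_that("Z-scoring standardizes rows and drops constant genes", {
  z <- zscoreStandardize(rbind(g = c(1, 2, 3)))
  expect_equal(unname(z[1, ]), c(-1, 0, 1))

  withr::with_seed(201, {
    m <- matrix(rnorm(50), 5, dimnames = list(paste0("g", 1:5), NULL))
    z <- zscoreStandardize(m)
    expect_equal(unname(rowMeans(z)), rep(0, 5), tolerance = 1e-12)
    expect_equal(unname(apply(z, 1, sd)), rep(1, 5), tolerance = 1e-12)
    # idempotence on an already standardized row
    expect_equal(zscoreStandardize(z), z, tolerance = 1e-12,
                 ignore_attr = TRUE)
  })

  m <- rbind(flat = rep(2, 6), ok = c(1, 4, 2, 8, 5, 7))
  expect_warning(z <- zscoreStandardize(m), "constant")
  expect_identical(attr(z, "dropped"), "flat")
  expect_identical(rownames(z), "ok")
})

test_that("stacked fQTL fit matches its algebraic special cases", {
  withr::with_seed(202, {
    n <- 40
    age <- rnorm(n, 60, 5); year <- rnorm(n, 2000, 3)

    # dosage constructed orthogonal to z rows and covariates -> beta3 = 0
    covs <- cbind(1, year - mean(year), age - mean(age))
    z <- matrix(rnorm(6 * n), 6, dimnames = list(paste0("g", 1:6), NULL))
    raw <- rbinom(n, 2, 0.4)
    Q <- qr.Q(qr(cbind(covs, t(z))))
    d <- raw - Q %*% crossprod(Q, raw)   # residualize against everything
    f <- fqtlFit(z, rownames(z), drop(d), ageDx = age, yearDx = year)
    expect_equal(f$beta, 0, tolerance = 1e-10)

    # every gene shifted +0.5 z-units per allele, no residual noise
    d <- rbinom(n, 2, 0.5)
    z0 <- matrix(0, 10, n, dimnames = list(paste0("g", 1:10), NULL))
    z1 <- z0 + rep(0.5 * d, each = 10)
    f <- fqtlFit(z1, rownames(z1), d, ageDx = age, yearDx = year)
    expect_equal(f$beta, 0.5, tolerance = 1e-10)
    expect_equal(f$df, 10 * n - 4)

    # stacked fit equals an explicit long-format lm
    z <- matrix(rnorm(5 * n), 5, dimnames = list(paste0("g", 1:5), NULL))
    d <- rbinom(n, 2, 0.3)
    f <- fqtlFit(z, rownames(z), d, ageDx = age, yearDx = year)
    long <- data.frame(y = as.vector(t(z)),
                       year = rep(year - mean(year), 5),
                       age = rep(age - mean(age), 5),
                       d = rep(d, 5))
    lf <- summary(lm(y ~ year + age + d, data = long))$coefficients
    expect_equal(f$beta, lf["d", "Estimate"], tolerance = 1e-10)
    expect_equal(f$t, lf["d", "t value"], tolerance = 1e-10)
    expect_equal(f$p, lf["d", "Pr(>|t|)"], tolerance = 1e-10)

    expect_error(fqtlFit(z, rownames(z), rep(1, n), age, year),
                 "monomorphic")
    expect_error(fqtlFit(z, c("g1", "zz"), d, age, year), "not in z")
  })
})

test_that("permutation FDR reproduces hand-counted tail ratios", {
  # two rounds: perm stats {0.5,1.5,2.5} and {0.2,0.4,2.6}
  fdr <- permutationFdr(c(3, 2, 1),
                        cbind(c(0.5, 1.5, 2.5), c(0.2, 0.4, 2.6)))
  # at t*=3: mean(0,0)/1 = 0; at t*=2: mean(1,1)/2 = 0.5; at t*=1:
  # mean(2,1)/3 = 0.5
  expect_equal(fdr, c(0, 0.5, 0.5))

  # permutation stats all below every observed statistic -> FDR 0
  expect_equal(permutationFdr(c(5, 4, 3), cbind(c(1, 2, 2), c(0, 1, 2))),
               rep(0, 3))

  # exchangeable null: median-ranked records get FDR near 1
  withr::with_seed(203, {
    obs <- abs(rnorm(200))
    perm <- matrix(abs(rnorm(200 * 400)), 200)
    fdr <- permutationFdr(obs, perm)
    expect_gt(median(fdr), 0.8)
    expect_true(all(fdr >= 0 & fdr <= 1))
    # monotone: larger statistic, no larger FDR
    o <- order(obs, decreasing = TRUE)
    expect_true(all(diff(fdr[o]) >= -1e-12))
  })
})

test_that("the identity permutation reproduces observed statistics exactly", {
  cfg <- quietConfig(nSubjects = 40L, pairedFraction = 0, nGenes = 60L,
                     nSnps = 2L, nGeneSets = 4L, setSizeRange = c(5L, 10L),
                     noiseSd = 1, seed = 204)
  bun <- simulateStudy(cfg)
  ids <- rownames(sampleInfo(bun))
  z <- zscoreStandardize(exprMatrix(bun))
  sets <- geneSets(bun)
  for (s in rownames(dosages(bun))) {
    d <- dosages(bun)[s, ]
    for (nm in names(sets)) {
      gs <- intersect(sets[[nm]], rownames(z))
      f1 <- fqtlFit(z, gs, d, sampleInfo(bun)$ageDx, sampleInfo(bun)$yearDx)
      f2 <- fqtlFit(z, gs, d[seq_along(d)], sampleInfo(bun)$ageDx,
                    sampleInfo(bun)$yearDx)
      expect_identical(f1$t, f2$t)
    }
  }
  # and the scan's internal permutation machinery agrees with fqtlFit
  res <- fqtlScan(bun, "tumor", B = 100, seed = 1)
  for (k in seq_len(nrow(res))) {
    gs <- intersect(sets[[res$set[k]]], rownames(z))
    ann <- sampleInfo(bun)
    tum <- rownames(ann)[ann$tissue == "tumor"]
    zt <- zscoreStandardize(exprMatrix(bun)[, tum])
    f <- fqtlFit(zt, gs, dosages(bun)[res$snp[k], tum],
                 ann[tum, "ageDx"], ann[tum, "yearDx"])
    expect_equal(res$t[k], f$t, tolerance = 1e-10)
    expect_equal(res$beta[k], f$beta, tolerance = 1e-10)
  }
})

test_that("beta3 flips sign exactly under dosage recoding 2-D", {
  cfg <- quietConfig(nSubjects = 50L, pairedFraction = 0, nGenes = 80L,
                     nSnps = 3L, nGeneSets = 5L, noiseSd = 1, seed = 205)
  bun <- simulateStudy(cfg)
  r1 <- fqtlScan(bun, "tumor", B = 100, seed = 2)
  bun2 <- bun
  bun2@dosage <- 2 - bun@dosage
  r2 <- fqtlScan(bun2, "tumor", B = 100, seed = 2)
  expect_equal(r2$beta, -r1$beta, tolerance = 1e-10)
  expect_equal(abs(r2$t), abs(r1$t), tolerance = 1e-10)
})

test_that("fQTL fit is invariant to gene order within a set", {
  withr::with_seed(206, {
    n <- 30
    z <- matrix(rnorm(8 * n), 8, dimnames = list(paste0("g", 1:8), NULL))
    d <- rbinom(n, 2, 0.4)
    age <- rnorm(n, 60); year <- rnorm(n, 2000)
    f1 <- fqtlFit(z, paste0("g", 1:8), d, age, year)
    f2 <- fqtlFit(z, paste0("g", sample(8)), d, age, year)
    expect_equal(f1$t, f2$t, tolerance = 1e-12)
  })
})

test_that("fqtlScan plants are detected and bookkeeping is consistent", {
  cfg <- quietConfig(
    nSubjects = 100L, pairedFraction = 0, nGenes = 200L, nSnps = 4L,
    nGeneSets = 8L, setSizeRange = c(8L, 15L), noiseSd = 1,
    mafRange = c(0.3, 0.5),
    fqtlEffects = data.frame(snp = "snp2", set = "set003", beta = 0.4),
    seed = 207)
  bun <- simulateStudy(cfg)
  res <- fqtlScan(bun, "tumor", B = 200, seed = 3)
  hit <- res[res$snp == "snp2" & res$set == "set003", ]
  expect_lt(hit$fdr, 0.10)
  expect_gt(hit$beta, 0.2)
  expect_equal(nrow(res), 4L * 8L)
  # sets below minSize are dropped with a log
  res2 <- fqtlScan(bun, "tumor", B = 100, seed = 3, minSize = 13L)
  expect_setequal(attr(res2, "droppedSets"),
                  names(which(lengths(geneSets(bun)) < 13L)))
  expect_setequal(unique(res2$set), names(which(lengths(geneSets(bun)) >= 13L)))
})
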