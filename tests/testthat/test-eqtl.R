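test_that("noiseless planted effect comes back exactly from the scan", {
  cfg <- quietConfig(
    noiseSd = 0, pairedFraction = 0, nGenes = 12L,
    eqtlEffects = data.frame(snp = "snp2", gene = "gene0007", beta = 0.7),
    seed = 101)
  bun <- simulateStudy(cfg)
  res <- eqtlScan(bun, "tumor", annotate = FALSE)
  hit <- res[res$snp == "snp2" & res$gene == "gene0007", ]
  expect_equal(hit$beta, 0.7, tolerance = 1e-10)
  expect_lt(hit$p, 1e-12)
})

test_that("per-SNP p-values are uniform on a global-null bundle", {
  cfg <- quietConfig(nSubjects = 150L, pairedFraction = 0, nSnps = 8L,
                     nGenes = 500L, noiseSd = 1,
                     mafRange = c(0.2, 0.5), seed = 102)
  bun <- simulateStudy(cfg)
  res <- eqtlScan(bun, "tumor", annotate = FALSE)
  ksOk <- vapply(split(res$p, res$snp), function(p)
    ks.test(p, "punif")$p.value > 0.01, logical(1))
  expect_gte(sum(ksOk), 7)   # allow one marginal SNP among eight
})

test_that("omitted covariate inflates the dosage effect; adjustment removes it", {
  # age drives expression AND is correlated with dosage: leaving age out
  # biases the dosage coefficient away from zero
  withr::with_seed(103, {
    n <- 200
    d <- rbinom(n, 2, 0.4)
    age <- 60 + 5 * d + rnorm(n, sd = 2)      # dosage-correlated age
    y <- 0.1 * age + rnorm(n, sd = 0.3)        # expression driven by age only
    ann <- data.frame(subject = paste0("s", 1:n), tissue = "tumor",
                      er = "+", pr = "+", ageDx = age,
                      yearDx = rep(2000, n), plate = 1L,
                      row.names = paste0("s", 1:n, "_T"))
    expr <- rbind(g1 = y)
    colnames(expr) <- rownames(ann)
    dos <- rbind(snpA = d)
    colnames(dos) <- rownames(ann)
    bun <- StudyBundle(expr, ann, dos,
                       snpCoords = data.frame(snp = "snpA", chrom = "chr1",
                                              pos = 100L),
                       geneCoords = data.frame(gene = "g1", chrom = "chr2",
                                               start = 1L, end = 10L))
    # olsFit needs >= 10 genes for the prior; test the design effect directly
    withAge <- coef(olsFit(expr, cbind(intercept = 1, ageDx = age,
                                       dosage = d)))[1, "dosage"]
    withoutAge <- coef(olsFit(expr, cbind(intercept = 1,
                                          dosage = d)))[1, "dosage"]
    expect_lt(abs(withAge), abs(withoutAge))
    expect_lt(abs(withAge), 0.1)
    expect_gt(abs(withoutAge), 0.3)
  })
})

test_that("scan results are invariant to gene and sample order", {
  cfg <- quietConfig(nSubjects = 50L, pairedFraction = 0, nGenes = 40L,
                     noiseSd = 1, seed = 104)
  bun <- simulateStudy(cfg)
  res <- eqtlScan(bun, "tumor", annotate = FALSE)
  gperm <- sample(nrow(bun@se))
  sperm <- sample(ncol(bun@se))
  res2 <- eqtlScan(bun[gperm, sperm], "tumor", annotate = FALSE)
  key <- function(r) r[order(r$snp, r$gene), c("snp", "gene", "beta", "t",
                                               "p", "q")]
  k1 <- key(res); k2 <- key(res2)
  rownames(k1) <- rownames(k2) <- NULL
  expect_equal(k1, k2, tolerance = 1e-9)
})

test_that("recoding dosage as 2-D flips only the sign of the effect", {
  cfg <- quietConfig(nSubjects = 60L, pairedFraction = 0, nGenes = 30L,
                     noiseSd = 1, seed = 105)
  bun <- simulateStudy(cfg)
  res <- eqtlScan(bun, "tumor", annotate = FALSE)
  bun2 <- bun
  bun2@dosage <- 2 - bun@dosage
  res2 <- eqtlScan(bun2, "tumor", annotate = FALSE)
  expect_equal(res2$beta, -res$beta, tolerance = 1e-9)
  expect_equal(res2$p, res$p, tolerance = 1e-9)
  expect_equal(res2$q, res$q, tolerance = 1e-9)
})

test_that("monomorphic SNPs are skipped with a log entry, not errored", {
  cfg <- quietConfig(nSubjects = 30L, pairedFraction = 0, nGenes = 20L,
                     seed = 106)
  bun <- simulateStudy(cfg)
  bun@dosage["snp1", ] <- 0
  res <- eqtlScan(bun, "tumor", annotate = FALSE)
  expect_identical(attr(res, "skipped"), "snp1")
  expect_false("snp1" %in% res$snp)
})

test_that("ER strata select the annotated samples and tiny strata error", {
  cfg <- quietConfig(nSubjects = 60L, pairedFraction = 0.5, nGenes = 15L,
                     erPosProp = 0.5, seed = 107)
  bun <- simulateStudy(cfg)
  ann <- sampleInfo(bun)
  res <- eqtlScan(bun, "er_pos", annotate = FALSE, covariates = "age")
  expect_equal(unique(res$n),
               sum(ann$tissue == "tumor" & ann$er == "+"))
  expect_error(eqtlScan(bun[, 1:4], "tumor"), "insufficient samples")
})

test_that("paired interaction scan recovers a noiseless tumor-only effect", {
  cfg <- quietConfig(
    nSubjects = 30L, pairedFraction = 1, nGenes = 12L, noiseSd = 0,
    subjectSd = 0.8, tissueShiftSd = 0.4,
    interactionEffects = data.frame(snp = "snp1", gene = "gene0003",
                                    delta = 0.8),
    seed = 108)
  bun <- simulateStudy(cfg)
  res <- pairedInteractionScan(bun, annotate = FALSE)
  hit <- res[res$snp == "snp1" & res$gene == "gene0003", ]
  expect_equal(hit$beta, 0.8, tolerance = 1e-9)
  # age/year constant within subject: absorbed by subject dummies
  res2 <- pairedInteractionScan(bun, covariates = c("age", "year"),
                                annotate = FALSE)
  expect_true(all(c("ageDx", "yearDx") %in% attr(res2, "aliased")))
  expect_equal(res2[res2$snp == "snp1" & res2$gene == "gene0003", "beta"],
               0.8, tolerance = 1e-9)
})

test_that("identical tumor and normal profiles give zero interaction", {
  cfg <- quietConfig(nSubjects = 20L, pairedFraction = 1, nGenes = 12L,
                     noiseSd = 0.5, subjectSd = 0.5, seed = 109)
  bun <- simulateStudy(cfg)
  expr <- exprMatrix(bun)
  ann <- sampleInfo(bun)
  # copy each subject's tumor profile onto its normal sample
  for (s in unique(ann$subject)) {
    cols <- rownames(ann)[ann$subject == s]
    tum <- cols[ann[cols, "tissue"] == "tumor"]
    expr[, cols] <- expr[, tum]
  }
  se <- bun@se
  SummarizedExperiment::assay(se, "exprs") <- expr
  bun@se <- se
  res <- pairedInteractionScan(bun, annotate = FALSE)
  expect_equal(max(abs(res$beta)), 0, tolerance = 1e-9)
})

test_that("unpaired subjects are excluded from the paired scan", {
  cfg <- quietConfig(nSubjects = 24L, pairedFraction = 0.5, nGenes = 12L,
                     seed = 110)
  bun <- simulateStudy(cfg)
  res <- pairedInteractionScan(bun, annotate = FALSE)
  expect_equal(unique(res$n), 2L * 12L)
  bun0 <- bun[, sampleInfo(bun)$tissue == "tumor"]
  expect_error(pairedInteractionScan(bun0), "no complete")
})

test_that("cis/trans labels follow chromosome and window rules", {
  snp <- GRanges(c(snpX = "chr14", snpY = "chr2", snpZ = "chr2"),
                 IRanges(start = c(69034682L, 5000000L, 1000500L), width = 1))
  names(snp) <- c("snpX", "snpY", "snpZ")
  gene <- GRanges(c(gA = "chr19", gB = "chr2", gC = "chr2"),
                  IRanges(start = c(100L, 11400000L, 1000000L),
                          end = c(2000L, 11450000L, 1002000L)))
  names(gene) <- c("gA", "gB", "gC")
  rec <- data.frame(snp = c("snpX", "snpY", "snpZ", "snpQ"),
                    gene = c("gA", "gB", "gC", "gA"))
  expect_message(out <- annotateCisTrans(rec, snp, gene, window = 1e6),
                 "unknown")
  # different chromosomes -> trans
  expect_equal(out$cisTrans[1], "trans")
  # same chromosome, 6.4 Mb separation, 1 Mb window -> trans
  expect_equal(out$cisTrans[2], "trans")
  # SNP inside the gene body -> cis at distance 0
  expect_equal(out$cisTrans[3], "cis")
  expect_equal(out$cisTrans[4], "unknown")
  # widening the window past the separation turns the 6.4 Mb pair cis
  out2 <- suppressMessages(annotateCisTrans(rec, snp, gene, window = 7e6))
  expect_equal(out2$cisTrans[2], "cis")
})
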