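# The two headline calibration studies, shared between the acceptance
# tests and ad-hoc exploration. Study conditions: n = 300 tumor samples,
# Gaussian noise SD 1, MAFs 0.1-0.5; eQTL grid 40 SNPs x 2000 genes with
# 5% of pairs carrying a 0.3-SD additive allelic effect; fQTL grid 20
# SNPs x 50 GO-sized gene sets (10-50 genes over 1500) with 3 planted
# set-level effects of 0.3 z-units per allele and B = 500 genotype
# permutations.

eqtlFdrReplicate <- function(seed, nSnps = 40L, nGenes = 2000L,
                             n = 300L, plantFrac = 0.05, beta = 0.3,
                             level = 0.10) {
  planted <- withr::with_seed(seed * 77L, {
    pairs <- expand.grid(snp = sprintf("snp%d", 1:nSnps),
                         gene = sprintf("gene%04d", 1:nGenes),
                         stringsAsFactors = FALSE)
    idx <- sample(nrow(pairs), round(plantFrac * nrow(pairs)))
    data.frame(pairs[idx, ], beta = beta)
  })
  cfg <- simConfig(nSubjects = n, pairedFraction = 0, nSnps = nSnps,
                   mafRange = c(0.1, 0.5), nGenes = nGenes, noiseSd = 1,
                   eqtlEffects = planted, seed = seed)
  bun <- simulateStudy(cfg)
  res <- eqtlScan(bun, "tumor", annotate = FALSE, fdrThreshold = level)
  scoreAgainstTruth(res, truthTable(bun), "eqtl")
}

fqtlFdrReplicate <- function(seed, nSnps = 20L, nSets = 50L,
                             nGenes = 1500L, n = 300L, nPlanted = 3L,
                             beta = 0.3, B = 500L, level = 0.10) {
  planted <- withr::with_seed(seed * 131L, {
    data.frame(snp = sample(sprintf("snp%d", 1:nSnps), nPlanted),
               set = sample(sprintf("set%03d", 1:nSets), nPlanted),
               beta = beta)
  })
  cfg <- simConfig(nSubjects = n, pairedFraction = 0, nSnps = nSnps,
                   mafRange = c(0.1, 0.5), nGenes = nGenes,
                   nGeneSets = nSets, setSizeRange = c(10L, 50L),
                   noiseSd = 1, fqtlEffects = planted, seed = seed)
  bun <- simulateStudy(cfg)
  res <- fqtlScan(bun, "tumor", B = B, seed = seed + 1000L,
                  fdrThreshold = level)
  scoreAgainstTruth(res, truthTable(bun), "fqtl")
}
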