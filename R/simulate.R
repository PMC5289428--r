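#' Build a simulation configuration
#'
#' Defaults emulate the archival FFPE breast-cancer study design: 376
#' postmenopausal cases, two thirds contributing a paired adjacent-normal
#' specimen, 71 GWAS risk SNPs with minor allele frequencies spanning
#' 0.015-0.50, nine assay plates with batch shifts, ER-positive proportion
#' about 0.79 among tumors, and unit-SD Gaussian expression noise on the
#' log scale. Gene count defaults to 2,000 (a desk-scale stand-in for the
#' array's ~26,000 transcript clusters).
#'
#' @param nSubjects number of subjects; every subject contributes a tumor
#'   sample.
#' @param pairedFraction fraction of subjects also contributing an
#'   adjacent-normal sample.
#' @param nSnps number of SNPs.
#' @param mafs per-SNP minor allele frequencies in (0, 0.5]; `NULL` draws
#'   them uniformly from `mafRange`.
#' @param mafRange range MAFs are drawn from when `mafs` is `NULL`.
#' @param dosageJitterSd SD of Gaussian jitter added to hard-call dosages
#'   (imputation-style continuous dosages), clipped to `[0, 2]`; 0 keeps
#'   hard calls.
#' @param nGenes number of genes (transcript clusters).
#' @param nGeneSets number of gene sets; 0 for none.
#' @param setSizeRange integer range of set sizes (genes drawn without
#'   replacement per set, sets may overlap).
#' @param baselineMean,baselineSd mean/SD of per-gene baseline expression
#'   (log2-scale, RMA-like).
#' @param ageEffectSd,yearEffectSd SD of per-gene linear age / year-of-
#'   diagnosis coefficients (log-expression units per year).
#' @param nPlates number of assay plates (samples assigned at random).
#' @param batchShiftSd SD of per-gene, per-plate batch shifts
#'   (log-expression units); 0 disables batch structure.
#' @param subjectSd SD of the per-subject, per-gene baseline shared by a
#'   subject's tumor and normal samples (what makes the paired fixed-effect
#'   model the right analysis).
#' @param tissueShiftSd SD of per-gene tumor-vs-normal mean differences.
#' @param erPosProp,prPosProp probability a subject's tumor is ER+/PR+.
#' @param receptorShiftSd SD of per-gene ER and PR shifts (applied to tumor
#'   samples of positive subjects).
#' @param receptorDeFraction fraction of genes carrying a receptor shift.
#' @param noiseSd residual Gaussian noise SD (log-expression units).
#' @param eqtlEffects `data.frame(snp, gene, beta)` of planted additive
#'   dosage effects (log-expression units per allele, both tissues).
#' @param interactionEffects `data.frame(snp, gene, delta)` of planted
#'   tumor-specific dosage effects (the tissue-by-dosage interaction).
#' @param fqtlEffects `data.frame(snp, set, beta)` of planted gene-set
#'   effects; every gene of the set is shifted by
#'   `beta * noiseSd * dosage` (so `beta` is in z-score units per allele
#'   when the residual SD dominates).
#' @param controlDelta positive-vs-negative control-probe separation, one
#'   value per sample or a scalar; expected AUC is `pnorm(delta / sqrt(2))`.
#'   Default 1.81 gives AUC ~0.90.
#' @param nControlProbes control probes per class per sample.
#' @param seed mandatory integer RNG seed.
#' @return a validated [SimConfig-class]
#' @seealso [simulateStudy()]
#' @export
simConfig <- function(nSubjects = 376L, pairedFraction = 250 / 376,
                      nSnps = 71L, mafs = NULL, mafRange = c(0.015, 0.5),
                      dosageJitterSd = 0,
                      nGenes = 2000L, nGeneSets = 0L,
                      setSizeRange = c(10L, 50L),
                      baselineMean = 7, baselineSd = 1,
                      ageEffectSd = 0.005, yearEffectSd = 0.01,
                      nPlates = 9L, batchShiftSd = 0.3,
                      subjectSd = 0.5, tissueShiftSd = 0.3,
                      erPosProp = 262 / 332, prPosProp = 0.7,
                      receptorShiftSd = 0.5, receptorDeFraction = 0.1,
                      noiseSd = 1,
                      eqtlEffects = NULL, interactionEffects = NULL,
                      fqtlEffects = NULL,
                      controlDelta = 1.81, nControlProbes = 100L,
                      seed) {
  if (missing(seed)) stop("seed is mandatory")
  if (is.null(eqtlEffects))
    eqtlEffects <- data.frame(snp = character(), gene = character(),
                              beta = numeric())
  if (is.null(interactionEffects))
    interactionEffects <- data.frame(snp = character(), gene = character(),
                                     delta = numeric())
  if (is.null(fqtlEffects))
    fqtlEffects <- data.frame(snp = character(), set = character(),
                              beta = numeric())
  new("SimConfig",
      nSubjects = as.integer(nSubjects), pairedFraction = pairedFraction,
      nSnps = as.integer(nSnps),
      mafs = if (is.null(mafs)) numeric() else mafs,
      mafRange = mafRange, dosageJitterSd = dosageJitterSd,
      nGenes = as.integer(nGenes), nGeneSets = as.integer(nGeneSets),
      setSizeRange = as.integer(setSizeRange),
      baselineMean = baselineMean, baselineSd = baselineSd,
      ageEffectSd = ageEffectSd, yearEffectSd = yearEffectSd,
      nPlates = as.integer(nPlates), batchShiftSd = batchShiftSd,
      subjectSd = subjectSd, tissueShiftSd = tissueShiftSd,
      erPosProp = erPosProp, prPosProp = prPosProp,
      receptorShiftSd = receptorShiftSd,
      receptorDeFraction = receptorDeFraction,
      noiseSd = noiseSd,
      eqtlEffects = eqtlEffects, interactionEffects = interactionEffects,
      fqtlEffects = fqtlEffects,
      controlDelta = controlDelta,
      nControlProbes = as.integer(nControlProbes),
      seed = as.integer(seed))
}

#' Simulate HWE genotype dosages
#'
#' Hard-call minor-allele dosages drawn per SNP as Binomial(2, MAF), i.e.
#' Hardy-Weinberg genotype frequencies `(1-p)^2, 2p(1-p), p^2`. Optional
#' Gaussian jitter (clipped to `[0, 2]`) mimics continuous imputed
#' dosages.
#'
#' @param n number of subjects (columns).
#' @param mafs numeric vector of minor allele frequencies in (0, 0.5].
#' @param seed integer seed (the draw is reproducible).
#' @param jitterSd SD of the imputation-style jitter; 0 keeps hard calls.
#' @return numeric matrix SNPs x subjects, rownames `snp1..`, values in
#'   `[0, 2]`.
#' @examples
#' d <- simulateGenotypes(5, mafs = c(0.1, 0.5), seed = 1)
#' @export
simulateGenotypes <- function(n, mafs, seed, jitterSd = 0) {
  if (any(mafs <= 0 | mafs > 0.5))
    stop("MAFs must lie in (0, 0.5]")
  withr::with_seed(seed, {
    d <- matrix(rbinom(length(mafs) * n, size = 2L,
                       prob = rep(mafs, each = n)),
                nrow = length(mafs), ncol = n, byrow = TRUE)
    if (jitterSd > 0) {
      d <- d + matrix(rnorm(length(d), 0, jitterSd), nrow(d))
      d[d < 0] <- 0
      d[d > 2] <- 2
    }
    dimnames(d) <- list(paste0("snp", seq_along(mafs)),
                        paste0("subj", seq_len(n)))
    storage.mode(d) <- "double"
    d
  })
}

#' Simulate control-probe signals
#'
#' Negative probes are `Normal(mu, 1)` and positive probes
#' `Normal(mu + delta, 1)` per sample, so the expected positive-vs-negative
#' AUC is `pnorm(delta / sqrt(2))`.
#'
#' @param delta per-sample separation (scalar recycled), `>= 0`.
#' @param nSamples number of samples.
#' @param nProbes probes per class per sample.
#' @param seed integer seed.
#' @param mu baseline signal level.
#' @return `list(pos =, neg =)` of probes x samples matrices.
#' @export
simulateControlProbes <- function(delta, nSamples, nProbes = 100L, seed,
                                  mu = 4) {
  if (any(delta < 0)) stop("delta must be non-negative")
  delta <- rep_len(delta, nSamples)
  withr::with_seed(seed, {
    neg <- matrix(rnorm(nProbes * nSamples, mu, 1), nProbes, nSamples)
    pos <- matrix(rnorm(nProbes * nSamples,
                        rep(mu + delta, each = nProbes), 1),
                  nProbes, nSamples)
    list(pos = pos, neg = neg)
  })
}

# Random gene/SNP coordinates on 22 synthetic autosomes (hg19-like scale)
# so cis/trans classification sees both same- and different-chromosome
# pairs. Assumes the RNG state of the caller.
randomCoords <- function(ids, width = 0L) {
  chrom <- paste0("chr", sample.int(22L, length(ids), replace = TRUE))
  start <- sample.int(2.4e8, length(ids), replace = TRUE)
  data.frame(id = ids, chrom = chrom, start = start,
             end = start + width, stringsAsFactors = FALSE)
}

#' Simulate a full study bundle with planted truth
#'
#' Generates genotypes, sample annotation, expression, gene sets and
#' control probes per the configuration and records every planted genetic
#' effect in the bundle's truth table. Expression is built additively on
#' the log scale:
#' baseline + age and year covariate terms + plate batch shift +
#' subject baseline (shared by a subject's tumor/normal pair) + tissue
#' shift + receptor-group shifts (tumors of ER+/PR+ subjects) + planted
#' dosage effects + planted tissue-by-dosage interactions + planted
#' gene-set effects + i.i.d. Gaussian noise.
#'
#' @param config a [SimConfig-class] from [simConfig()].
#' @return a [StudyBundle-class] carrying a truth table with one row per
#'   planted effect.
#' @examples
#' bun <- simulateStudy(simConfig(nSubjects = 30, nSnps = 3, nGenes = 50,
#'                                seed = 7))
#' bun
#' @export
simulateStudy <- function(config) {
  stopifnot(methods::is(config, "SimConfig"))
  validObject(config)
  co <- config
  withr::with_seed(co@seed, {
    nS <- co@nSubjects
    subjects <- sprintf("subj%03d", seq_len(nS))
    nPaired <- round(co@pairedFraction * nS)
    pairedSubj <- if (nPaired > 0) sort(sample.int(nS, nPaired)) else integer()

    sampleId <- c(paste0(subjects, "_T"),
                  if (length(pairedSubj)) paste0(subjects[pairedSubj], "_N"))
    sampSubj <- c(seq_len(nS), pairedSubj)
    tissue <- c(rep("tumor", nS), rep("normal", length(pairedSubj)))
    nSamp <- length(sampleId)

    mafs <- if (length(co@mafs)) co@mafs else
      runif(co@nSnps, co@mafRange[1L], co@mafRange[2L])
    subjDos <- simulateGenotypes(nS, mafs,
                                 seed = sample.int(.Machine$integer.max, 1L),
                                 jitterSd = co@dosageJitterSd)
    dosage <- subjDos[, sampSubj, drop = FALSE]
    colnames(dosage) <- sampleId
    snps <- rownames(dosage)

    ageDx <- sample(50:79, nS, replace = TRUE)
    yearDx <- sample(1990:2004, nS, replace = TRUE)
    er <- ifelse(runif(nS) < co@erPosProp, "+", "-")
    pr <- ifelse(runif(nS) < co@prPosProp, "+", "-")
    plate <- sample.int(co@nPlates, nSamp, replace = TRUE)

    ann <- data.frame(
      subject = subjects[sampSubj], tissue = tissue,
      er = er[sampSubj], pr = pr[sampSubj],
      ageDx = ageDx[sampSubj], yearDx = yearDx[sampSubj],
      plate = plate, row.names = sampleId, stringsAsFactors = FALSE)

    genes <- sprintf("gene%04d", seq_len(co@nGenes))
    geneCo <- randomCoords(genes, width = 20000L)
    names(geneCo)[1L] <- "gene"
    snpCo <- randomCoords(snps, width = 0L)[, 1:3]
    names(snpCo) <- c("snp", "chrom", "pos")

    sets <- list()
    if (co@nGeneSets > 0L) {
      sizes <- sample(co@setSizeRange[1L]:co@setSizeRange[2L],
                      co@nGeneSets, replace = TRUE)
      sets <- lapply(sizes, function(k) sample(genes, k))
      names(sets) <- sprintf("set%03d", seq_len(co@nGeneSets))
    }

    ng <- co@nGenes
    base <- rnorm(ng, co@baselineMean, co@baselineSd)
    ageCoef <- if (co@ageEffectSd > 0) rnorm(ng, 0, co@ageEffectSd) else numeric(ng)
    yearCoef <- if (co@yearEffectSd > 0) rnorm(ng, 0, co@yearEffectSd) else numeric(ng)
    plateShift <- if (co@batchShiftSd > 0)
      matrix(rnorm(ng * co@nPlates, 0, co@batchShiftSd), ng, co@nPlates)
    else matrix(0, ng, co@nPlates)
    tissueEff <- if (co@tissueShiftSd > 0) rnorm(ng, 0, co@tissueShiftSd) else numeric(ng)
    deGenes <- co@receptorDeFraction > 0 & co@receptorShiftSd > 0
    erEff <- prEff <- numeric(ng)
    if (deGenes) {
      pick <- runif(ng) < co@receptorDeFraction
      erEff[pick] <- rnorm(sum(pick), 0, co@receptorShiftSd)
      pick <- runif(ng) < co@receptorDeFraction
      prEff[pick] <- rnorm(sum(pick), 0, co@receptorShiftSd)
    }
    subjBase <- if (co@subjectSd > 0)
      matrix(rnorm(ng * nS, 0, co@subjectSd), ng, nS) else matrix(0, ng, nS)

    isTumor <- as.numeric(tissue == "tumor")
    ageC <- ann$ageDx - mean(ann$ageDx)
    yearC <- ann$yearDx - mean(ann$yearDx)

    expr <- matrix(base, ng, nSamp) +
      outer(ageCoef, ageC) +
      outer(yearCoef, yearC) +
      plateShift[, ann$plate, drop = FALSE] +
      subjBase[, sampSubj, drop = FALSE] +
      outer(tissueEff, isTumor) +
      outer(erEff, as.numeric(ann$er == "+") * isTumor) +
      outer(prEff, as.numeric(ann$pr == "+") * isTumor)
    dimnames(expr) <- list(genes, sampleId)

    checkRef <- function(df, col, universe, what) {
      bad <- setdiff(df[[col]], universe)
      if (length(bad))
        stop("planted effect references unknown ", what, ": ",
             paste(head(bad, 5L), collapse = ", "))
    }
    checkRef(co@eqtlEffects, "snp", snps, "SNP")
    checkRef(co@eqtlEffects, "gene", genes, "gene")
    checkRef(co@interactionEffects, "snp", snps, "SNP")
    checkRef(co@interactionEffects, "gene", genes, "gene")
    checkRef(co@fqtlEffects, "snp", snps, "SNP")
    checkRef(co@fqtlEffects, "set", names(sets), "gene set")

    for (k in seq_len(nrow(co@eqtlEffects))) {
      e <- co@eqtlEffects[k, ]
      expr[e$gene, ] <- expr[e$gene, ] + e$beta * dosage[e$snp, ]
    }
    for (k in seq_len(nrow(co@interactionEffects))) {
      e <- co@interactionEffects[k, ]
      expr[e$gene, ] <- expr[e$gene, ] +
        e$delta * dosage[e$snp, ] * isTumor
    }
    for (k in seq_len(nrow(co@fqtlEffects))) {
      e <- co@fqtlEffects[k, ]
      gs <- sets[[e$set]]
      expr[gs, ] <- expr[gs, ] +
        rep(e$beta * co@noiseSd * dosage[e$snp, ], each = length(gs))
    }

    if (co@noiseSd > 0)
      expr <- expr + matrix(rnorm(ng * nSamp, 0, co@noiseSd), ng, nSamp)

    cp <- simulateControlProbes(co@controlDelta, nSamp,
                                nProbes = co@nControlProbes,
                                seed = sample.int(.Machine$integer.max, 1L))
    colnames(cp$pos) <- colnames(cp$neg) <- sampleId
    rownames(cp$pos) <- paste0("pos", seq_len(co@nControlProbes))
    rownames(cp$neg) <- paste0("neg", seq_len(co@nControlProbes))

    truth <- rbind(
      if (nrow(co@eqtlEffects))
        data.frame(type = "eqtl", snp = co@eqtlEffects$snp,
                   target = co@eqtlEffects$gene,
                   value = co@eqtlEffects$beta),
      if (nrow(co@interactionEffects))
        data.frame(type = "interaction", snp = co@interactionEffects$snp,
                   target = co@interactionEffects$gene,
                   value = co@interactionEffects$delta),
      if (nrow(co@fqtlEffects))
        data.frame(type = "fqtl", snp = co@fqtlEffects$snp,
                   target = co@fqtlEffects$set,
                   value = co@fqtlEffects$beta))
    if (is.null(truth))
      truth <- data.frame(type = character(), snp = character(),
                          target = character(), value = numeric())

    StudyBundle(exprs = expr, sampleInfo = ann, dosage = dosage,
                snpCoords = snpCo, geneCoords = geneCo, geneSets = sets,
                controlPos = cp$pos, controlNeg = cp$neg, truth = truth)
  })
}
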