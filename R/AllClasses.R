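#' Per-gene ordinary least squares fits
#'
#' Container for gene-wise linear model fits against a shared design matrix,
#' the input to empirical-Bayes variance moderation. Mirrors the fields a
#' moderated t/F computation needs: coefficient estimates, unscaled standard
#' errors, residual variances and residual degrees of freedom.
#'
#' @slot coefficients numeric matrix, genes x coefficients.
#' @slot stdevUnscaled numeric matrix, genes x coefficients; the standard
#'   error of coefficient j for gene g is `stdevUnscaled[g, j] * sqrt(sigma2[g])`.
#' @slot sigma2 numeric vector of residual variances (RSS / df); `NA` when
#'   the residual degrees of freedom are zero (saturated fit).
#' @slot dfResidual numeric vector of residual degrees of freedom per gene.
#' @slot covUnscaled numeric matrix, the common unscaled coefficient
#'   covariance `(X'X)^{-1}` of the full design (used for joint F tests).
#' @slot nObs numeric vector, samples used per gene.
#'
#' @seealso [olsFit()], [moderatedT()], [moderatedF()]
#' @exportClass GeneFit
setClass("GeneFit",
  representation(
    coefficients = "matrix",
    stdevUnscaled = "matrix",
    sigma2 = "numeric",
    dfResidual = "numeric",
    covUnscaled = "matrix",
    nObs = "numeric"
  )
)

setValidity("GeneFit", function(object) {
  msg <- character()
  ng <- nrow(object@coefficients)
  p <- ncol(object@coefficients)
  if (!identical(dim(object@stdevUnscaled), c(ng, p)))
    msg <- c(msg, "stdevUnscaled dimensions must match coefficients")
  if (length(object@sigma2) != ng || length(object@dfResidual) != ng)
    msg <- c(msg, "sigma2 and dfResidual must have one entry per gene")
  if (any(object@sigma2 < 0, na.rm = TRUE))
    msg <- c(msg, "sigma2 must be non-negative")
  if (!identical(dim(object@covUnscaled), c(p, p)))
    msg <- c(msg, "covUnscaled must be p x p")
  if (length(msg)) msg else TRUE
})

#' Empirical-Bayes variance prior
#'
#' Hyperparameters of the scaled inverse-chi-square prior on gene-wise
#' residual variances: prior degrees of freedom `d0` and prior variance
#' `s0^2`. The posterior (shrunken) variance for a gene with sample variance
#' `s^2` on `d` residual df is `(d0*s0^2 + d*s^2) / (d0 + d)`. `d0 = Inf`
#' is the full-shrinkage sentinel (all genes share variance `s0^2`).
#'
#' @slot dfPrior positive numeric scalar, possibly `Inf`.
#' @slot varPrior positive numeric scalar (squared log-expression units).
#'
#' @seealso [estimateVariancePrior()]
#' @exportClass VariancePrior
setClass("VariancePrior",
  representation(dfPrior = "numeric", varPrior = "numeric")
)

setValidity("VariancePrior", function(object) {
  msg <- character()
  if (length(object@dfPrior) != 1L || is.na(object@dfPrior) || object@dfPrior <= 0)
    msg <- c(msg, "dfPrior must be a positive scalar (possibly Inf)")
  if (length(object@varPrior) != 1L || is.na(object@varPrior) || object@varPrior <= 0)
    msg <- c(msg, "varPrior must be a positive scalar")
  if (length(msg)) msg else TRUE
})

#' @describeIn VariancePrior-class display hyperparameters
#' @param object a `VariancePrior`
#' @export
setMethod("show", "VariancePrior", function(object) {
  cat("VariancePrior: d0 =", format(object@dfPrior),
      " s0^2 =", format(object@varPrior), "\n")
})

#' A named collection of gene sets
#'
#' Gene sets (e.g. GO Molecular Function terms) as a named list of gene
#' identifier vectors, with an optional provenance label and per-set
#' descriptions. Sets are non-empty; identifiers are resolved against an
#' expression matrix at analysis time.
#'
#' @slot sets named list of character vectors of gene ids.
#' @slot descriptions named character vector (may be empty).
#' @slot provenance single character label, e.g. `"GO Molecular Function"`.
#'
#' @seealso [readGeneSets()], [fqtlScan()]
#' @exportClass GeneSetCollection
setClass("GeneSetCollection",
  representation(sets = "list", descriptions = "character",
                 provenance = "character")
)

setValidity("GeneSetCollection", function(object) {
  msg <- character()
  if (length(object@sets) &&
      (is.null(names(object@sets)) || anyDuplicated(names(object@sets))))
    msg <- c(msg, "sets must be uniquely named")
  if (any(lengths(object@sets) == 0L))
    msg <- c(msg, "sets must be non-empty")
  if (length(msg)) msg else TRUE
})

#' Construct a GeneSetCollection
#'
#' @param sets named list of character vectors of gene ids; duplicate ids
#'   within a set are removed.
#' @param descriptions optional named character vector of set descriptions.
#' @param provenance character label recording where the sets came from.
#' @return a [GeneSetCollection-class]
#' @examples
#' gsc <- GeneSetCollection(list(setA = c("g1", "g2"), setB = c("g2", "g3")))
#' length(geneSets(gsc))
#' @export
GeneSetCollection <- function(sets, descriptions = character(),
                              provenance = NA_character_) {
  sets <- lapply(sets, function(g) unique(as.character(g)))
  new("GeneSetCollection", sets = sets,
      descriptions = descriptions, provenance = provenance)
}

#' @describeIn GeneSetCollection-class number of sets
#' @param x a `GeneSetCollection`
#' @export
setMethod("length", "GeneSetCollection", function(x) length(x@sets))

#' @describeIn GeneSetCollection-class set names
#' @export
setMethod("names", "GeneSetCollection", function(x) names(x@sets))

#' @describeIn GeneSetCollection-class display summary
#' @param object a `GeneSetCollection`
#' @export
setMethod("show", "GeneSetCollection", function(object) {
  cat("GeneSetCollection with", length(object@sets), "sets")
  if (!is.na(object@provenance)) cat(" (", object@provenance, ")", sep = "")
  cat("; sizes", min(lengths(object@sets)), "-", max(lengths(object@sets)), "\n")
})

#' Quality-control report
#'
#' One object type shared by the QC operators; each operator fills the
#' slots relevant to it and leaves the others empty.
#'
#' @slot sampleAuc named numeric, per-sample control-probe AUC.
#' @slot aucThreshold numeric scalar.
#' @slot aucPass named logical, pass/fail at the threshold.
#' @slot replicateMinCor named numeric, minimum pairwise Pearson r per
#'   replicate group.
#' @slot pcTested integer, PCs screened for batch association.
#' @slot pcPvalues numeric, one-way ANOVA p-value per tested PC.
#' @slot clippedPcs integer, indices of PCs removed / returned as covariates.
#' @slot mode character, `"clip"` or `"covariates"` for the PC adjustment.
#' @slot notes character vector of free-text log lines.
#'
#' @exportClass QcReport
setClass("QcReport",
  representation(
    sampleAuc = "numeric", aucThreshold = "numeric", aucPass = "logical",
    replicateMinCor = "numeric",
    pcTested = "integer", pcPvalues = "numeric", clippedPcs = "integer",
    mode = "character", notes = "character"
  ),
  prototype(
    sampleAuc = numeric(), aucThreshold = numeric(), aucPass = logical(),
    replicateMinCor = numeric(),
    pcTested = integer(), pcPvalues = numeric(), clippedPcs = integer(),
    mode = character(), notes = character()
  )
)

setValidity("QcReport", function(object) {
  msg <- character()
  if (length(object@sampleAuc) &&
      any(object@sampleAuc < 0 | object@sampleAuc > 1, na.rm = TRUE))
    msg <- c(msg, "AUC values must lie in [0, 1]")
  if (length(object@clippedPcs) &&
      length(object@pcTested) &&
      any(!object@clippedPcs %in% seq_len(object@pcTested)))
    msg <- c(msg, "clipped PCs must be among the tested PCs")
  if (length(msg)) msg else TRUE
})

#' @describeIn QcReport-class display summary
#' @param object a `QcReport`
#' @export
setMethod("show", "QcReport", function(object) {
  cat("QcReport\n")
  if (length(object@sampleAuc)) {
    cat("  control-probe AUC: ", length(object@sampleAuc), " samples, ",
        sum(!object@aucPass), " below ", object@aucThreshold, "\n", sep = "")
  }
  if (length(object@replicateMinCor)) {
    cat("  replicate groups:", length(object@replicateMinCor),
        " min pairwise r:", format(min(object@replicateMinCor), digits = 3), "\n")
  }
  if (length(object@pcTested)) {
    cat("  PCs tested:", object@pcTested, " clipped:",
        if (length(object@clippedPcs)) paste(object@clippedPcs, collapse = ",")
        else "none",
        " mode:", object@mode, "\n")
  }
  for (n in object@notes) cat("  note:", n, "\n")
})

#' Study bundle: expression, genotypes, annotations and planted truth
#'
#' The unit every pipeline stage consumes. Expression lives in a
#' [SummarizedExperiment::RangedSummarizedExperiment] (assay `"exprs"`,
#' log-scale genes x samples; `rowRanges` hold gene coordinates; `colData`
#' the sample annotation with columns `subject`, `tissue`
#' (`"tumor"`/`"normal"`), `er`, `pr` (`"+"`/`"-"`/`NA`), `ageDx`, `yearDx`,
#' `plate`). Allelic dosages (SNPs x samples, values in `[0, 2]`) and SNP
#' coordinates ride alongside, plus optional gene sets, control-probe
#' signal matrices, and — for synthetic bundles — the truth table of
#' planted effects.
#'
#' @slot se a `RangedSummarizedExperiment` with assay `"exprs"`.
#' @slot dosage numeric matrix SNPs x samples, entries in `[0, 2]`.
#' @slot snpCoords `GRanges`, one position per SNP, names = SNP ids.
#' @slot geneSets a [GeneSetCollection-class] (possibly empty).
#' @slot controlPos,controlNeg numeric matrices (probes x samples) of
#'   positive/negative control-probe signals, or `NULL`.
#' @slot truth `data.frame` of planted effects with columns `type`
#'   (`"eqtl"`, `"interaction"`, `"fqtl"`), `snp`, `target`, `value`;
#'   zero rows for real data.
#'
#' @seealso [StudyBundle()], [simulateStudy()]
#' @exportClass StudyBundle
setClass("StudyBundle",
  representation(
    se = "RangedSummarizedExperiment",
    dosage = "matrix",
    snpCoords = "GRanges",
    geneSets = "GeneSetCollection",
    controlPos = "ANY",
    controlNeg = "ANY",
    truth = "data.frame"
  )
)

setValidity("StudyBundle", function(object) {
  msg <- character()
  samp <- colnames(object@se)
  if (!identical(colnames(object@dosage), samp))
    msg <- c(msg, "dosage columns must match expression samples")
  if (any(object@dosage < 0 | object@dosage > 2, na.rm = TRUE))
    msg <- c(msg, "dosages must lie in [0, 2]")
  if (!identical(names(object@snpCoords), rownames(object@dosage)))
    msg <- c(msg, "snpCoords names must match dosage rows")
  for (nm in c("subject", "tissue", "ageDx", "yearDx", "plate")) {
    if (!nm %in% colnames(SummarizedExperiment::colData(object@se)))
      msg <- c(msg, paste0("sample annotation lacks column '", nm, "'"))
  }
  for (cp in c("controlPos", "controlNeg")) {
    m <- slot(object, cp)
    if (!is.null(m) && !identical(colnames(m), samp))
      msg <- c(msg, paste0(cp, " columns must match expression samples"))
  }
  if (nrow(object@truth)) {
    need <- c("type", "snp", "target", "value")
    if (!all(need %in% colnames(object@truth)))
      msg <- c(msg, "truth table must have columns type, snp, target, value")
    else if (!all(object@truth$snp %in% rownames(object@dosage)))
      msg <- c(msg, "truth table references unknown SNPs")
  }
  ti <- SummarizedExperiment::colData(object@se)$tissue
  if (!all(ti %in% c("tumor", "normal")))
    msg <- c(msg, "tissue must be 'tumor' or 'normal'")
  if (length(msg)) msg else TRUE
})

#' Construct a StudyBundle
#'
#' @param exprs numeric matrix, genes x samples, log-scale expression with
#'   row and column names.
#' @param sampleInfo `data.frame`/`DataFrame` with one row per sample
#'   (rownames = sample ids) and columns `subject`, `tissue`, `er`, `pr`,
#'   `ageDx`, `yearDx`, `plate`.
#' @param dosage numeric matrix, SNPs x samples, in `[0, 2]`.
#' @param snpCoords `GRanges` named by SNP id (width-1 positions), or a
#'   `data.frame` with columns `snp`, `chrom`, `pos` (1-based).
#' @param geneCoords `GRanges` named by gene id, or a `data.frame` with
#'   columns `gene`, `chrom`, `start`, `end` (1-based inclusive).
#' @param geneSets a [GeneSetCollection-class] or named list of gene-id
#'   vectors.
#' @param controlPos,controlNeg optional probes x samples matrices of
#'   control-probe signals.
#' @param truth optional planted-effect `data.frame` (see
#'   [StudyBundle-class]).
#' @return a validated [StudyBundle-class]
#' @export
StudyBundle <- function(exprs, sampleInfo, dosage, snpCoords, geneCoords,
                        geneSets = list(), controlPos = NULL,
                        controlNeg = NULL, truth = NULL) {
  exprs <- as.matrix(exprs)
  if (is.data.frame(snpCoords)) {
    snpCoords <- GenomicRanges::GRanges(
      seqnames = snpCoords$chrom,
      ranges = IRanges::IRanges(start = snpCoords$pos, width = 1L),
      snp = snpCoords$snp)
    names(snpCoords) <- snpCoords$snp
  }
  if (is.data.frame(geneCoords)) {
    geneCoords <- GenomicRanges::GRanges(
      seqnames = geneCoords$chrom,
      ranges = IRanges::IRanges(start = geneCoords$start,
                                end = geneCoords$end),
      gene = geneCoords$gene)
    names(geneCoords) <- geneCoords$gene
  }
  geneCoords <- geneCoords[rownames(exprs)]
  snpCoords <- snpCoords[rownames(dosage)]
  if (!methods::is(geneSets, "GeneSetCollection"))
    geneSets <- GeneSetCollection(as.list(geneSets))
  if (is.null(truth))
    truth <- data.frame(type = character(), snp = character(),
                        target = character(), value = numeric())
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(exprs = exprs),
    rowRanges = geneCoords,
    colData = S4Vectors::DataFrame(sampleInfo))
  new("StudyBundle", se = se, dosage = as.matrix(dosage),
      snpCoords = snpCoords, geneSets = geneSets,
      controlPos = controlPos, controlNeg = controlNeg, truth = truth)
}

#' @describeIn StudyBundle-class display summary
#' @param object a `StudyBundle`
#' @export
setMethod("show", "StudyBundle", function(object) {
  ann <- SummarizedExperiment::colData(object@se)
  cat("StudyBundle:", nrow(object@se), "genes x", ncol(object@se),
      "samples,", nrow(object@dosage), "SNPs\n")
  cat("  tissues:", sum(ann$tissue == "tumor"), "tumor /",
      sum(ann$tissue == "normal"), "normal;",
      length(unique(ann$subject)), "subjects\n")
  if (length(object@geneSets))
    cat("  gene sets:", length(object@geneSets), "\n")
  if (!is.null(object@controlPos))
    cat("  control probes:", nrow(object@controlPos), "pos /",
        nrow(object@controlNeg), "neg per sample\n")
  if (nrow(object@truth))
    cat("  planted truth:", nrow(object@truth), "effects (",
        paste(unique(object@truth$type), collapse = ", "), ")\n")
})

#' Simulation configuration
#'
#' All knobs of the synthetic-study generator. Defaults emulate the
#' archival FFPE breast-cancer study design the package targets:
#' postmenopausal cases with paired tumor / adjacent-normal tissue for a
#' subset of subjects, HWE genotype dosages at GWAS-panel minor allele
#' frequencies (0.015-0.50), age/year-of-diagnosis covariate effects,
#' assay-plate batch shifts visible on leading expression PCs, ER/PR
#' receptor-group mean differences in tumors, and control-probe signals of
#' configurable quality. See [simConfig()] for the field-by-field
#' description and defaults.
#'
#' @exportClass SimConfig
setClass("SimConfig",
  representation(
    nSubjects = "integer", pairedFraction = "numeric",
    nSnps = "integer", mafs = "numeric", mafRange = "numeric",
    dosageJitterSd = "numeric",
    nGenes = "integer", nGeneSets = "integer", setSizeRange = "integer",
    baselineMean = "numeric", baselineSd = "numeric",
    ageEffectSd = "numeric", yearEffectSd = "numeric",
    nPlates = "integer", batchShiftSd = "numeric",
    subjectSd = "numeric", tissueShiftSd = "numeric",
    erPosProp = "numeric", prPosProp = "numeric",
    receptorShiftSd = "numeric", receptorDeFraction = "numeric",
    noiseSd = "numeric",
    eqtlEffects = "data.frame", interactionEffects = "data.frame",
    fqtlEffects = "data.frame",
    controlDelta = "numeric", nControlProbes = "integer",
    seed = "integer"
  )
)

setValidity("SimConfig", function(object) {
  msg <- character()
  for (nm in c("nSubjects", "nSnps", "nGenes", "nPlates", "nControlProbes"))
    if (slot(object, nm) < 1L) msg <- c(msg, paste(nm, "must be positive"))
  if (length(object@mafs) &&
      any(object@mafs <= 0 | object@mafs > 0.5))
    msg <- c(msg, "MAFs must lie in (0, 0.5]")
  if (object@pairedFraction < 0 || object@pairedFraction > 1)
    msg <- c(msg, "pairedFraction must lie in [0, 1]")
  if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be non-negative")
  if (length(object@seed) != 1L || is.na(object@seed))
    msg <- c(msg, "seed is mandatory")
  if (any(object@controlDelta < 0))
    msg <- c(msg, "controlDelta must be non-negative")
  if (length(msg)) msg else TRUE
})

#' @describeIn SimConfig-class display summary
#' @param object a `SimConfig`
#' @export
setMethod("show", "SimConfig", function(object) {
  cat("SimConfig:", object@nSubjects, "subjects (",
      round(100 * object@pairedFraction), "% paired ),",
      object@nSnps, "SNPs,", object@nGenes, "genes,",
      object@nGeneSets, "gene sets; seed", object@seed, "\n")
  cat("  planted:", nrow(object@eqtlEffects), "eQTL,",
      nrow(object@interactionEffects), "interaction,",
      nrow(object@fqtlEffects), "fQTL effects\n")
})
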