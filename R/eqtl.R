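# Build the covariate part of a scan design from sample annotation:
# intercept, centered ageDx/yearDx, plate indicator dummies, optional PC
# score columns. Constant columns are dropped with a note (e.g. a single
# plate within a stratum).
covariateDesign <- function(ann, covariates = c("age", "year", "plate"),
                            pcs = NULL) {
  X <- cbind(intercept = rep(1, nrow(ann)))
  notes <- character()
  if ("age" %in% covariates) X <- cbind(X, ageDx = ann$ageDx - mean(ann$ageDx))
  if ("year" %in% covariates) X <- cbind(X, yearDx = ann$yearDx - mean(ann$yearDx))
  if ("plate" %in% covariates) {
    pl <- factor(ann$plate)
    if (nlevels(droplevels(pl)) > 1L) {
      mm <- model.matrix(~pl)[, -1L, drop = FALSE]
      colnames(mm) <- paste0("plate", levels(droplevels(pl))[-1L])
      X <- cbind(X, mm)
    } else notes <- c(notes, "plate constant within stratum; dummies dropped")
  }
  if (!is.null(pcs)) {
    pcs <- as.matrix(pcs)
    if (is.null(colnames(pcs))) colnames(pcs) <- paste0("PC", seq_len(ncol(pcs)))
    X <- cbind(X, pcs)
  }
  keep <- c(TRUE, apply(X[, -1L, drop = FALSE], 2L, sd) > 0)
  if (any(!keep))
    notes <- c(notes, paste("constant covariate dropped:",
                            paste(colnames(X)[!keep], collapse = ", ")))
  structure(X[, keep, drop = FALSE], notes = notes)
}

# Remove linearly dependent columns (QR with pivoting), protecting the
# named columns; returns the reduced matrix with a "dropped" attribute.
dropAliased <- function(X, protect = character()) {
  qrX <- qr(X)
  if (qrX$rank == ncol(X)) return(structure(X, dropped = character()))
  keep <- sort(qrX$pivot[seq_len(qrX$rank)])
  dropped <- colnames(X)[setdiff(seq_len(ncol(X)), keep)]
  if (any(protect %in% dropped))
    stop("column(s) of interest aliased: ",
         paste(intersect(protect, dropped), collapse = ", "))
  structure(X[, keep, drop = FALSE], dropped = dropped)
}

# Select the sample ids of a stratum from bundle annotation.
stratumSamples <- function(ann, stratum) {
  switch(stratum,
    tumor = rownames(ann)[ann$tissue == "tumor"],
    er_pos = rownames(ann)[ann$tissue == "tumor" & !is.na(ann$er) &
                             ann$er == "+"],
    er_neg = rownames(ann)[ann$tissue == "tumor" & !is.na(ann$er) &
                             ann$er == "-"],
    normal = rownames(ann)[ann$tissue == "normal"],
    stop("unknown stratum '", stratum, "'"))
}

#' Per-SNP, per-gene eQTL scan within a tissue stratum
#'
#' For each SNP, fits the additive-dosage linear model
#' `y_g = b0 + X b1 + b2 * D + e` across all genes (X holds age at
#' diagnosis, year of diagnosis, plate dummies, and any supplied PC
#' scores), estimates one empirical-Bayes variance prior from that SNP's
#' gene-wise fits, tests the dosage coefficient with the moderated t, and
#' applies Benjamini-Hochberg adjustment within the SNP's gene list
#' (per-SNP, per-tissue FDR). SNPs monomorphic within the stratum are
#' skipped and listed in the `"skipped"` attribute.
#'
#' @param bundle a [StudyBundle-class].
#' @param stratum `"tumor"`, `"er_pos"`, `"er_neg"` or `"normal"`.
#' @param covariates subset of `c("age", "year", "plate")` to adjust for.
#' @param pcs optional samples x k matrix of expression-PC scores (rownames
#'   = sample ids) to include as covariates, e.g. from [pcBatchAdjust()].
#' @param fdrThreshold records with `q <=` this are marked `significant`.
#' @param annotate add cis/trans labels from the bundle coordinates.
#' @param cisWindow window (bp) for the cis label, see [annotateCisTrans()].
#' @return `data.frame` with one row per (SNP, gene): `snp`, `gene`,
#'   `stratum`, `beta` (log-expression units per allele), `t`, `p`, `q`,
#'   `n`, `dfTotal`, `significant`, and (when `annotate`) `cisTrans` plus
#'   coordinates. Attribute `"skipped"` lists monomorphic SNPs.
#' @seealso [pairedInteractionScan()], [annotateCisTrans()]
#' @export
eqtlScan <- function(bundle, stratum = c("tumor", "er_pos", "er_neg", "normal"),
                     covariates = c("age", "year", "plate"), pcs = NULL,
                     fdrThreshold = 0.10, annotate = TRUE,
                     cisWindow = 1e6) {
  stratum <- match.arg(stratum)
  ann <- sampleInfo(bundle)
  ids <- stratumSamples(ann, stratum)
  if (length(ids) == 0L) stop("stratum '", stratum, "' is empty")
  expr <- exprMatrix(bundle)[, ids, drop = FALSE]
  dos <- dosages(bundle)[, ids, drop = FALSE]
  annS <- ann[ids, , drop = FALSE]
  if (!is.null(pcs)) pcs <- as.matrix(pcs)[ids, , drop = FALSE]
  X0 <- covariateDesign(annS, covariates, pcs)
  if (length(ids) < ncol(X0) + 2L)
    stop("insufficient samples in stratum '", stratum, "' (n = ",
         length(ids), ", covariates = ", ncol(X0), ")")

  skipped <- character()
  out <- vector("list", nrow(dos))
  for (s in seq_len(nrow(dos))) {
    d <- dos[s, ]
    if (var(d) == 0) {
      skipped <- c(skipped, rownames(dos)[s])
      next
    }
    X <- dropAliased(cbind(X0, dosage = d), protect = "dosage")
    fit <- olsFit(expr, X)
    prior <- estimateVariancePrior(fit)
    tt <- moderatedT(fit, prior, "dosage")
    q <- bhAdjust(tt$p)
    out[[s]] <- data.frame(
      snp = rownames(dos)[s], gene = rownames(expr), stratum = stratum,
      beta = tt$beta, t = tt$t, p = tt$p, q = q, n = length(ids),
      dfTotal = tt$dfTotal, significant = q <= fdrThreshold,
      row.names = NULL)
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(snp = character(), gene = character(),
                      stratum = character(), beta = numeric(), t = numeric(),
                      p = numeric(), q = numeric(), n = integer(),
                      dfTotal = numeric(), significant = logical())
  if (annotate && nrow(res))
    res <- annotateCisTrans(res, snpCoords(bundle), geneCoords(bundle),
                            window = cisWindow)
  attr(res, "skipped") <- skipped
  res
}

#' Paired tumor/normal genotype-by-tissue interaction scan
#'
#' Restricted to subjects contributing both a tumor and an adjacent-normal
#' sample, fits per SNP and gene a fixed-effect model with subject dummies,
#' a tissue indicator, and the tissue-by-dosage product; the coefficient of
#' interest is the product term (how the allelic effect differs between
#' tumor and normal tissue). Subject dummies absorb every between-subject
#' covariate, so age, year and the dosage main effect are aliased and
#' dropped (logged in the `"aliased"` attribute); plate is retained when it
#' varies within subjects. Moderated t and per-SNP BH as in [eqtlScan()].
#'
#' @inheritParams eqtlScan
#' @param covariates covariates to attempt in addition to subject dummies;
#'   aliased ones are dropped with a log entry.
#' @return `data.frame` as in [eqtlScan()] with `stratum =
#'   "tumor_vs_normal"`; `beta` is the interaction coefficient.
#' @export
pairedInteractionScan <- function(bundle, covariates = "plate",
                                  fdrThreshold = 0.10, annotate = TRUE,
                                  cisWindow = 1e6) {
  ann <- sampleInfo(bundle)
  tab <- table(factor(ann$subject),
               factor(ann$tissue, levels = c("tumor", "normal")))
  paired <- rownames(tab)[tab[, "tumor"] >= 1L & tab[, "normal"] >= 1L]
  if (length(paired) < 2L)
    stop("no complete tumor/normal pairs")
  ids <- rownames(ann)[ann$subject %in% paired]
  expr <- exprMatrix(bundle)[, ids, drop = FALSE]
  dos <- dosages(bundle)[, ids, drop = FALSE]
  annS <- ann[ids, , drop = FALSE]

  subj <- factor(annS$subject)
  Xsub <- model.matrix(~subj)[, -1L, drop = FALSE]
  colnames(Xsub) <- paste0("subj", levels(subj)[-1L])
  tumor <- as.numeric(annS$tissue == "tumor")
  X0 <- cbind(intercept = 1, Xsub, tissue = tumor)
  aliasedLog <- character()
  if ("age" %in% covariates) X0 <- cbind(X0, ageDx = annS$ageDx)
  if ("year" %in% covariates) X0 <- cbind(X0, yearDx = annS$yearDx)
  if ("plate" %in% covariates) {
    pl <- droplevels(factor(annS$plate))
    if (nlevels(pl) > 1L) {
      mm <- model.matrix(~pl)[, -1L, drop = FALSE]
      colnames(mm) <- paste0("plate", levels(pl)[-1L])
      X0 <- cbind(X0, mm)
    }
  }

  skipped <- character()
  out <- vector("list", nrow(dos))
  for (s in seq_len(nrow(dos))) {
    d <- dos[s, ]
    inter <- tumor * d
    if (var(d) == 0) {
      skipped <- c(skipped, rownames(dos)[s])
      next
    }
    X <- dropAliased(cbind(X0, tissue_dosage = inter),
                     protect = "tissue_dosage")
    aliasedLog <- union(aliasedLog, attr(X, "dropped"))
    fit <- olsFit(expr, X)
    prior <- estimateVariancePrior(fit)
    tt <- moderatedT(fit, prior, "tissue_dosage")
    q <- bhAdjust(tt$p)
    out[[s]] <- data.frame(
      snp = rownames(dos)[s], gene = rownames(expr),
      stratum = "tumor_vs_normal",
      beta = tt$beta, t = tt$t, p = tt$p, q = q,
      n = length(ids), dfTotal = tt$dfTotal,
      significant = q <= fdrThreshold, row.names = NULL)
  }
  res <- do.call(rbind, out)
  if (is.null(res)) stop("all SNPs monomorphic among paired subjects")
  if (annotate)
    res <- annotateCisTrans(res, snpCoords(bundle), geneCoords(bundle),
                            window = cisWindow)
  attr(res, "skipped") <- skipped
  attr(res, "aliased") <- aliasedLog
  res
}

#' Label SNP-gene records as cis or trans
#'
#' A record is `cis` iff SNP and gene share a chromosome and the distance
#' from the SNP to the nearest gene boundary is at most `window` base
#' pairs (0 for a SNP inside the gene body); otherwise `trans`. Records
#' whose SNP or gene lacks coordinates get `"unknown"` with a message.
#'
#' @param records `data.frame` with columns `snp` and `gene`.
#' @param snpCoords `GRanges` named by SNP id (width-1 positions).
#' @param geneCoords `GRanges` named by gene id.
#' @param window cis window in bp (default 1 Mb).
#' @return `records` with columns `cisTrans`, `snpChrom`, `snpPos`,
#'   `geneChrom`, `geneStart` appended.
#' @export
annotateCisTrans <- function(records, snpCoords, geneCoords, window = 1e6) {
  si <- match(records$snp, names(snpCoords))
  gi <- match(records$gene, names(geneCoords))
  known <- !is.na(si) & !is.na(gi)
  lab <- rep("unknown", nrow(records))
  snpChrom <- rep(NA_character_, nrow(records))
  snpPos <- rep(NA_integer_, nrow(records))
  geneChrom <- rep(NA_character_, nrow(records))
  geneStart <- rep(NA_integer_, nrow(records))
  if (any(known)) {
    sg <- snpCoords[si[known]]
    gg <- geneCoords[gi[known]]
    # distance() is NA across chromosomes, 0 on overlap, else the gap
    d <- suppressWarnings(GenomicRanges::distance(sg, gg))
    lab[known] <- ifelse(!is.na(d) & d <= window, "cis", "trans")
    snpChrom[known] <- as.character(GenomicRanges::seqnames(sg))
    snpPos[known] <- GenomicRanges::start(sg)
    geneChrom[known] <- as.character(GenomicRanges::seqnames(gg))
    geneStart[known] <- GenomicRanges::start(gg)
  }
  if (any(!known))
    message(sum(!known), " record(s) lack coordinates; labelled 'unknown'")
  records$cisTrans <- lab
  records$snpChrom <- snpChrom
  records$snpPos <- snpPos
  records$geneChrom <- geneChrom
  records$geneStart <- geneStart
  records
}
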