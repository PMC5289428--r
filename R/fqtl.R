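#' Gene-wise Z-score standardization
#'
#' Centers and scales each gene (row) across samples to mean 0 and sample
#' standard deviation 1 (n-1 denominator). Constant genes cannot be
#' standardized: they are dropped with a warning and recorded in the
#' `"dropped"` attribute.
#'
#' @param expr numeric matrix genes x samples (>= 2 columns).
#' @return the standardized matrix (possibly fewer rows), with attribute
#'   `"dropped"` naming removed genes.
#' @examples
#' zscoreStandardize(rbind(g = c(1, 2, 3)))   # (-1, 0, 1)
#' @export
zscoreStandardize <- function(expr) {
  if (ncol(expr) < 2L) stop("need at least 2 samples")
  mu <- rowMeans(expr)
  sdv <- sqrt(rowSums((expr - mu)^2) / (ncol(expr) - 1L))
  const <- sdv == 0
  if (any(const)) {
    warning(sum(const), " constant gene(s) dropped during Z-scoring")
  }
  z <- (expr[!const, , drop = FALSE] - mu[!const]) / sdv[!const]
  attr(z, "dropped") <- rownames(expr)[const]
  z
}

# Stacked gene-set regression sufficient statistics for one SNP.
# A: (X'X)^{-1} of the per-sample design; Xty: sets x p matrix of stacked
# X'y; zz: per-set sum of squared responses; m: set sizes; n: samples.
fqtlSolve <- function(G, A, Xty, zz, m, n) {
  p <- ncol(A)
  Beta <- (Xty %*% A) / m
  rss <- zz - 2 * rowSums(Beta * Xty) + m * rowSums((Beta %*% G) * Beta)
  df <- m * n - p
  rss[rss < 0] <- 0           # exact fits: guard rounding
  se3 <- sqrt(A[p, p] / m) * sqrt(rss / df)
  t3 <- Beta[, p] / se3
  list(beta = Beta[, p], t = t3, df = df)
}

#' Fit the stacked gene-set (fQTL) regression for one SNP and one set
#'
#' Stacks the Z-scored expression of every gene in the set over samples
#' into one response vector and fits a single OLS with intercept, year of
#' diagnosis, age at diagnosis (plus any extra covariates) and SNP dosage
#' repeated per gene. The dosage coefficient is the increase in mean
#' pathway Z-score per risk allele; its t statistic has
#' `setSize * n - p` degrees of freedom (p = 4 for the default
#' covariates). The model treats genes within the set as repeated measures
#' with a common variance.
#'
#' @param z Z-scored expression matrix (genes x samples), from
#'   [zscoreStandardize()].
#' @param set character vector of gene ids (must resolve in `z`).
#' @param dosage numeric dosage vector, one per sample, non-constant.
#' @param ageDx,yearDx numeric covariate vectors, one per sample.
#' @param extra optional samples x k matrix of additional covariates.
#' @return `list(beta =, t =, p =, df =, setSize =)`.
#' @examples
#' z <- matrix(rnorm(5 * 20), 5, dimnames = list(paste0("g", 1:5), NULL))
#' fqtlFit(z, paste0("g", 1:5), dosage = rbinom(20, 2, 0.3),
#'         ageDx = rnorm(20, 60), yearDx = rnorm(20, 2000))
#' @export
fqtlFit <- function(z, set, dosage, ageDx, yearDx, extra = NULL) {
  miss <- setdiff(set, rownames(z))
  if (length(miss))
    stop("gene ids not in z matrix: ", paste(head(miss, 5L), collapse = ", "))
  if (var(dosage) == 0) stop("monomorphic dosage")
  n <- ncol(z)
  covX <- cbind(intercept = 1, yearDx = yearDx - mean(yearDx),
                ageDx = ageDx - mean(ageDx))
  if (!is.null(extra)) covX <- cbind(covX, as.matrix(extra))
  X <- cbind(covX, dosage = dosage)
  G <- crossprod(X)
  A <- chol2inv(chol(G))
  Zs <- z[set, , drop = FALSE]
  sVec <- colSums(Zs)
  Xty <- rbind(drop(crossprod(X, sVec)))
  zz <- sum(Zs^2)
  m <- length(set)
  r <- fqtlSolve(G, A, Xty, zz, m, n)
  pval <- 2 * pt(-abs(r$t), df = r$df)
  list(beta = unname(r$beta), t = unname(r$t), p = unname(pval),
       df = r$df, setSize = m)
}

# Resolve a gene-set collection against the rows of a z matrix: drop
# unresolvable ids and sets falling below minSize; log counts.
resolveSets <- function(sets, geneIds, minSize = 5L) {
  resolved <- lapply(sets, function(g) intersect(g, geneIds))
  nDropped <- sum(lengths(sets) - lengths(resolved))
  keep <- lengths(resolved) >= minSize
  structure(resolved[keep],
            droppedGenes = nDropped,
            droppedSets = names(sets)[!keep])
}

#' Genotype-permutation FDR for fQTL statistics
#'
#' Tail-ratio FDR: for each record with observed statistic `t*`, the
#' estimated FDR is the average over permutation rounds of the number of
#' permuted statistics at or above `t*`, divided by the number of observed
#' statistics at or above `t*`, capped at 1. Monotonicity down the ranked
#' list is enforced by taking, for each record, the minimum estimate over
#' all records with a smaller or equal statistic.
#'
#' @param observed numeric vector of observed statistics (typically
#'   absolute t values), one per (SNP, set) record.
#' @param permStats numeric matrix with one column per permutation round,
#'   each column holding the recomputed statistics of all records under
#'   one genotype permutation.
#' @return numeric vector of FDR estimates in `[0, 1]`, aligned with
#'   `observed`.
#' @examples
#' permutationFdr(c(3, 2, 1),
#'                cbind(c(0.5, 1.5, 2.5), c(0.2, 0.4, 2.6)))
#' @export
permutationFdr <- function(observed, permStats) {
  permStats <- as.matrix(permStats)
  if (!all(is.finite(observed))) stop("observed statistics must be finite")
  B <- ncol(permStats)
  if (B < 1L) stop("need at least one permutation round")
  pool <- sort(as.numeric(permStats))
  # count of pooled permutation stats >= each observed value
  nGe <- length(pool) - findInterval(observed, pool, left.open = TRUE)
  obsSorted <- sort(observed)
  nObsGe <- length(observed) -
    findInterval(observed, obsSorted, left.open = TRUE)
  fdr <- pmin(1, (nGe / B) / nObsGe)
  # enforce monotonicity: larger statistics never get a larger FDR
  o <- order(observed, decreasing = TRUE)
  fdr[o] <- rev(cummin(rev(fdr[o])))
  fdr
}

#' Gene-set fQTL scan with genotype-permutation FDR
#'
#' Runs the stacked regression of [fqtlFit()] for every (SNP, gene set)
#' pair within a tissue stratum, then estimates FDR by permuting the
#' sample-to-genotype assignment `B` times — one shared permutation per
#' round across all SNPs, preserving both the expression correlation
#' structure and the inter-SNP correlation — and recomputing all
#' statistics. The permutation tail uses `|t|` (two-sided), pooled across
#' SNPs and sets within the stratum.
#'
#' @param bundle a [StudyBundle-class].
#' @param stratum `"tumor"`, `"er_pos"`, `"er_neg"` or `"normal"`.
#' @param sets optional [GeneSetCollection-class] or named list; defaults
#'   to the bundle's gene sets.
#' @param B number of permutation rounds (>= 100 recommended; fewer
#'   limits FDR resolution and triggers a warning).
#' @param seed integer seed for the permutations (mandatory).
#' @param minSize minimum resolvable genes per set (smaller sets skipped).
#' @param sharedPermutation one shared genotype permutation per round
#'   across SNPs (default); `FALSE` permutes independently per SNP.
#' @param extraCovariates optional samples x k covariate matrix (rownames
#'   = sample ids) added to the default intercept + year + age design.
#' @param fdrThreshold records with FDR `<=` this are marked `significant`.
#' @return `data.frame` with one row per (SNP, set): `snp`, `set`,
#'   `stratum`, `beta` (Z-score units per allele), `t`, `p`, `fdr`,
#'   `setSize`, `n`, `significant`. Attributes `"skipped"` (monomorphic
#'   SNPs), `"droppedSets"`, `"droppedGenes"`.
#' @export
fqtlScan <- function(bundle, stratum = c("tumor", "er_pos", "er_neg", "normal"),
                     sets = NULL, B = 1000L, seed, minSize = 5L,
                     sharedPermutation = TRUE, extraCovariates = NULL,
                     fdrThreshold = 0.10) {
  stratum <- match.arg(stratum)
  if (missing(seed)) stop("seed is mandatory")
  if (B < 100L) warning("B < 100 permutations gives coarse FDR resolution")
  ann <- sampleInfo(bundle)
  ids <- stratumSamples(ann, stratum)
  if (length(ids) < 8L) stop("insufficient samples in stratum '", stratum, "'")
  z <- zscoreStandardize(exprMatrix(bundle)[, ids, drop = FALSE])
  dos <- dosages(bundle)[, ids, drop = FALSE]
  annS <- ann[ids, , drop = FALSE]
  if (is.null(sets)) sets <- geneSets(bundle)
  if (methods::is(sets, "GeneSetCollection")) sets <- geneSets(sets)
  if (length(sets) == 0L) stop("no gene sets supplied")
  rs <- resolveSets(sets, rownames(z), minSize)
  if (length(rs) == 0L) stop("no gene set reaches minSize after resolution")

  n <- ncol(z)
  covX <- cbind(intercept = 1, yearDx = annS$yearDx - mean(annS$yearDx),
                ageDx = annS$ageDx - mean(annS$ageDx))
  if (!is.null(extraCovariates))
    covX <- cbind(covX, as.matrix(extraCovariates)[ids, , drop = FALSE])
  p <- ncol(covX) + 1L

  # per-set sufficient statistics, shared across SNPs and permutations
  setIdx <- lapply(rs, function(g) match(g, rownames(z)))
  m <- lengths(rs)
  Ssum <- do.call(rbind, lapply(setIdx, function(i)
    colSums(z[i, , drop = FALSE])))                      # sets x n
  zz <- vapply(setIdx, function(i) sum(z[i, ]^2), numeric(1))
  SsumCov <- Ssum %*% covX                               # sets x (p-1)
  covG <- crossprod(covX)

  poly <- rownames(dos)[apply(dos, 1L, var) > 0]
  skipped <- setdiff(rownames(dos), poly)
  if (length(poly) == 0L) stop("all SNPs monomorphic in stratum")
  nR <- length(poly) * length(rs)

  permIdx <- withr::with_seed(seed, {
    t(vapply(seq_len(B), function(b) sample.int(n), integer(n)))
  })                                                     # B x n
  if (!sharedPermutation) {
    permIdx <- withr::with_seed(seed, {
      lapply(poly, function(s)
        t(vapply(seq_len(B), function(b) sample.int(n), integer(n))))
    })
    names(permIdx) <- poly
  }

  snpStats <- function(d, SsumD, covD, d2) {
    # SsumD: sets x k matrix of set-summed permuted dosages; covD: (p-1) x k
    k <- ncol(SsumD)
    tmat <- matrix(NA_real_, length(rs), k)
    bmat <- matrix(NA_real_, length(rs), k)
    for (j in seq_len(k)) {
      G <- rbind(cbind(covG, covD[, j]), c(covD[, j], d2))
      A <- chol2inv(chol(G))
      Xty <- cbind(SsumCov, SsumD[, j])
      r <- fqtlSolve(G, A, Xty, zz, m, n)
      tmat[, j] <- r$t
      bmat[, j] <- r$beta
    }
    list(t = tmat, beta = bmat)
  }

  obsBeta <- obsT <- matrix(NA_real_, length(rs), length(poly),
                            dimnames = list(names(rs), poly))
  permT <- matrix(NA_real_, nR, B)
  for (si in seq_along(poly)) {
    d <- dos[poly[si], ]
    d2 <- sum(d^2)
    pm <- if (sharedPermutation) permIdx else permIdx[[poly[si]]]
    P <- t(matrix(d[pm], nrow(pm), ncol(pm)))            # n x B
    obs <- snpStats(d, cbind(Ssum %*% d), cbind(crossprod(covX, d)), d2)
    obsT[, si] <- obs$t[, 1L]
    obsBeta[, si] <- obs$beta[, 1L]
    per <- snpStats(d, Ssum %*% P, crossprod(covX, P), d2)
    rows <- (si - 1L) * length(rs) + seq_along(rs)
    permT[rows, ] <- abs(per$t)
  }

  records <- data.frame(
    snp = rep(poly, each = length(rs)),
    set = rep(names(rs), times = length(poly)),
    stratum = stratum,
    beta = as.numeric(obsBeta),
    t = as.numeric(obsT),
    setSize = rep(unname(m), times = length(poly)),
    n = n, row.names = NULL)
  records$p <- 2 * pt(-abs(records$t), df = records$setSize * n - p)
  records$fdr <- permutationFdr(abs(records$t), permT)
  records$significant <- records$fdr <= fdrThreshold
  attr(records, "skipped") <- skipped
  attr(records, "droppedSets") <- attr(rs, "droppedSets")
  attr(records, "droppedGenes") <- attr(rs, "droppedGenes")
  records
}
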