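#' Mann-Whitney AUC separating positive from negative control probes
#'
#' The probability that a random positive-probe signal exceeds a random
#' negative-probe signal, ties counted half:
#' `AUC = (#\{pos > neg\} + 0.5 * #\{ties\}) / (n_pos * n_neg)`, computed
#' through the rank-sum identity.
#'
#' @param pos,neg numeric vectors of control-probe signals (non-empty).
#' @return AUC in `[0, 1]`.
#' @examples
#' probeSignalAuc(c(3, 5), c(1, 4))   # 0.75
#' @export
probeSignalAuc <- function(pos, neg) {
  if (length(pos) == 0L || length(neg) == 0L)
    stop("pos and neg must be non-empty")
  if (anyNA(pos) || anyNA(neg)) stop("missing values not allowed")
  r <- rank(c(pos, neg))
  u <- sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2
  u / (length(pos) * length(neg))
}

#' Filter samples by control-probe AUC
#'
#' Computes the per-sample positive-vs-negative control-probe AUC and drops
#' samples whose AUC falls strictly below the threshold (a sample at
#' exactly the threshold is retained). Retained samples keep their
#' original order across all bundle components.
#'
#' @param bundle a [StudyBundle-class] carrying control-probe signals.
#' @param threshold AUC cutoff (default 0.55).
#' @return `list(bundle =, report =)` with the filtered
#'   [StudyBundle-class] and a [QcReport-class].
#' @export
filterSamplesByAuc <- function(bundle, threshold = 0.55) {
  cp <- controlProbes(bundle)
  if (is.null(cp))
    stop("bundle carries no control-probe signals")
  auc <- vapply(seq_len(ncol(cp$pos)), function(j)
    probeSignalAuc(cp$pos[, j], cp$neg[, j]), numeric(1))
  names(auc) <- colnames(cp$pos)
  pass <- auc >= threshold
  if (!any(pass)) stop("no samples remain after AUC filtering")
  report <- new("QcReport", sampleAuc = auc, aucThreshold = threshold,
                aucPass = pass,
                notes = if (all(pass)) character() else
                  paste0("removed ", sum(!pass), " sample(s) with AUC < ",
                         threshold))
  list(bundle = bundle[, which(pass)], report = report)
}

#' Minimum pairwise correlation within technical-replicate groups
#'
#' For each replicate group, the minimum over all pairwise Pearson
#' correlations of the member samples' expression profiles.
#'
#' @param expr numeric matrix genes x samples.
#' @param groups named list mapping replicate-group id to >= 2 sample ids
#'   (or column indices).
#' @return named numeric vector, one minimum pairwise r per group.
#' @export
replicateConcordance <- function(expr, groups) {
  if (any(lengths(groups) < 2L))
    stop("each replicate group needs at least 2 samples")
  vapply(groups, function(ids) {
    sub <- expr[, ids, drop = FALSE]
    if (any(apply(sub, 2L, sd) == 0))
      stop("constant expression column in replicate group")
    cc <- cor(sub)
    min(cc[lower.tri(cc)])
  }, numeric(1))
}

#' Principal-component batch adjustment
#'
#' Computes sample-space principal components of the row-centered
#' expression matrix, screens each of the first `nPcs` score vectors for
#' association with assay batch by one-way ANOVA, and removes every
#' associated component (`p < alpha`) by subtracting its rank-one
#' reconstruction (`mode = "clip"`), or leaves the matrix untouched and
#' returns the associated scores for use as regression covariates
#' (`mode = "covariates"`). With a single batch the input is returned
#' unchanged with a note.
#'
#' @param expr numeric matrix genes x samples.
#' @param batch vector of batch labels, one per sample (>= 2 levels for an
#'   adjustment to take place).
#' @param nPcs number of leading PCs to screen (default 50, truncated to
#'   `min(dim(expr)) - 1`).
#' @param alpha ANOVA significance cutoff for clipping (default 0.05).
#' @param mode `"clip"` (remove components from the matrix) or
#'   `"covariates"` (return scores, matrix unchanged).
#' @return `list(expr =, report =, scores =)`: the (possibly adjusted)
#'   matrix, a [QcReport-class], and the samples x k matrix of
#'   batch-associated PC scores (for covariate use; `NULL` when none).
#' @export
pcBatchAdjust <- function(expr, batch, nPcs = 50L, alpha = 0.05,
                          mode = c("clip", "covariates")) {
  mode <- match.arg(mode)
  batch <- as.factor(batch)
  if (length(batch) != ncol(expr))
    stop("one batch label per sample required")
  if (nlevels(droplevels(batch)) < 2L) {
    report <- new("QcReport", pcTested = 0L, mode = mode,
                  notes = "single batch: no adjustment performed")
    return(list(expr = expr, report = report, scores = NULL))
  }
  nPcs <- min(nPcs, min(dim(expr)) - 1L)
  ctr <- rowMeans(expr)
  X <- expr - ctr
  sv <- svd(X, nu = nPcs, nv = nPcs)
  scores <- sv$v * rep(sv$d[seq_len(nPcs)], each = nrow(sv$v))  # samples x k
  pvals <- vapply(seq_len(nPcs), function(k) {
    anova(lm(scores[, k] ~ batch))[["Pr(>F)"]][1L]
  }, numeric(1))
  clip <- which(pvals < alpha)
  adjusted <- expr
  if (length(clip) && mode == "clip") {
    recon <- sv$u[, clip, drop = FALSE] %*%
      (t(sv$v[, clip, drop = FALSE]) * sv$d[clip])
    adjusted <- expr - recon
  }
  report <- new("QcReport", pcTested = as.integer(nPcs), pcPvalues = pvals,
                clippedPcs = as.integer(clip), mode = mode,
                notes = if (length(clip)) character() else
                  "no batch-associated PCs at the given alpha")
  list(expr = adjusted, report = report,
       scores = if (length(clip)) {
         s <- scores[, clip, drop = FALSE]
         dimnames(s) <- list(colnames(expr), paste0("PC", clip))
         s
       } else NULL)
}
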