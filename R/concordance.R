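# Build the receptor-group dummy design: reference group ER-/PR- ("--"),
# indicators for "+-", "-+", "++". Samples with missing ER or PR excluded.
receptorDesign <- function(er, pr) {
  ok <- !is.na(er) & !is.na(pr)
  grp <- paste0(er[ok], pr[ok])
  X <- cbind(intercept = 1,
             `grp+-` = as.numeric(grp == "+-"),
             `grp-+` = as.numeric(grp == "-+"),
             `grp++` = as.numeric(grp == "++"))
  structure(X, keep = which(ok), groups = grp)
}

#' Per-gene receptor-status moderated F statistics
#'
#' For each gene, fits expression on a dummy 3-vector coding ER/PR group
#' membership (`+-`, `-+`, `++` against the `--` reference) and computes
#' the empirical-Bayes moderated F statistic for the joint null that all
#' three group coefficients are zero — a 3-d.f. test of equal mean
#' expression across hormone-receptor groups, the per-platform sensitivity
#' measure used for cross-platform adequacy ranking.
#'
#' @param expr numeric matrix genes x samples.
#' @param er,pr character vectors of `"+"`/`"-"` (or `NA`) per sample;
#'   samples missing either are excluded.
#' @param prior a [VariancePrior-class], or `NULL` to estimate one from
#'   the fits ([priorZero()] gives the classical F).
#' @param strict error (rather than warn) when a receptor group is empty.
#' @return `data.frame` with per-gene `F`, `p`, `dfNum`, `dfDen`.
#' @seealso [crossPlatformConcordance()]
#' @export
receptorFStats <- function(expr, er, pr, prior = NULL, strict = FALSE) {
  X <- receptorDesign(er, pr)
  keep <- attr(X, "keep")
  grp <- attr(X, "groups")
  missing <- setdiff(c("--", "+-", "-+", "++"), unique(grp))
  if (length(missing)) {
    msg <- paste("empty receptor group(s):", paste(missing, collapse = ", "))
    if (strict) stop(msg)
    warning(msg, "; reduced-df test")
    drop <- paste0("grp", setdiff(missing, "--"))
    X <- X[, setdiff(colnames(X), drop), drop = FALSE]
  }
  if (ncol(X) < 2L) stop("need at least 2 receptor groups")
  expr <- expr[, keep, drop = FALSE]
  fit <- olsFit(expr, X)
  if (is.null(prior)) prior <- estimateVariancePrior(fit)
  coefs <- setdiff(colnames(X), "intercept")
  ff <- moderatedF(fit, prior, coefs)
  data.frame(gene = rownames(expr), F = ff$F, p = ff$p,
             dfNum = ff$dfNum, dfDen = ff$dfDen, row.names = NULL)
}

#' Rank concordance of per-gene F statistics across two platforms
#'
#' Spearman correlation of two per-gene F vectors restricted to their
#' shared gene identifiers (case-sensitive exact matching).
#'
#' @param f1,f2 named numeric vectors of per-gene F statistics (names =
#'   gene ids), or `data.frame`s from [receptorFStats()] (columns `gene`,
#'   `F`).
#' @return `list(rho =, nShared =)`.
#' @export
crossPlatformConcordance <- function(f1, f2) {
  asVec <- function(f) {
    if (is.data.frame(f)) setNames(f$F, f$gene) else f
  }
  f1 <- asVec(f1); f2 <- asVec(f2)
  shared <- intersect(names(f1), names(f2))
  if (length(shared) < 3L)
    stop("fewer than 3 shared gene identifiers")
  list(rho = spearmanCorr(f1[shared], f2[shared]),
       nShared = length(shared))
}
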