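#' Accessors for StudyBundle components
#'
#' @param x a [StudyBundle-class]
#' @return `exprMatrix`: the genes x samples log-expression matrix;
#'   `dosages`: the SNPs x samples dosage matrix; `sampleInfo`: the sample
#'   annotation as a `data.frame` (rownames = sample ids); `snpCoords` /
#'   `geneCoords`: `GRanges`; `geneSets`: the [GeneSetCollection-class];
#'   `controlProbes`: `list(pos =, neg =)` matrices or `NULL`;
#'   `truthTable`: the planted-effect `data.frame`.
#' @name bundle-accessors
#' @examples
#' bun <- simulateStudy(simConfig(nSubjects = 20, nSnps = 2, nGenes = 10,
#'                                seed = 1))
#' dim(exprMatrix(bun))
#' head(sampleInfo(bun))
NULL

#' @rdname bundle-accessors
#' @export
setGeneric("exprMatrix", function(x) standardGeneric("exprMatrix"))

#' @rdname bundle-accessors
#' @export
setMethod("exprMatrix", "StudyBundle", function(x)
  SummarizedExperiment::assay(x@se, "exprs"))

#' @rdname bundle-accessors
#' @export
setGeneric("dosages", function(x) standardGeneric("dosages"))

#' @rdname bundle-accessors
#' @export
setMethod("dosages", "StudyBundle", function(x) x@dosage)

#' @rdname bundle-accessors
#' @export
setGeneric("sampleInfo", function(x) standardGeneric("sampleInfo"))

#' @rdname bundle-accessors
#' @export
setMethod("sampleInfo", "StudyBundle", function(x)
  as.data.frame(SummarizedExperiment::colData(x@se)))

#' @rdname bundle-accessors
#' @export
setGeneric("snpCoords", function(x) standardGeneric("snpCoords"))

#' @rdname bundle-accessors
#' @export
setMethod("snpCoords", "StudyBundle", function(x) x@snpCoords)

#' @rdname bundle-accessors
#' @export
setGeneric("geneCoords", function(x) standardGeneric("geneCoords"))

#' @rdname bundle-accessors
#' @export
setMethod("geneCoords", "StudyBundle", function(x)
  SummarizedExperiment::rowRanges(x@se))

#' @rdname bundle-accessors
#' @export
setGeneric("geneSets", function(x) standardGeneric("geneSets"))

#' @rdname bundle-accessors
#' @export
setMethod("geneSets", "StudyBundle", function(x) x@geneSets@sets)

#' @rdname bundle-accessors
#' @export
setMethod("geneSets", "GeneSetCollection", function(x) x@sets)

#' @rdname bundle-accessors
#' @export
setGeneric("controlProbes", function(x) standardGeneric("controlProbes"))

#' @rdname bundle-accessors
#' @export
setMethod("controlProbes", "StudyBundle", function(x) {
  if (is.null(x@controlPos)) NULL else list(pos = x@controlPos,
                                            neg = x@controlNeg)
})

#' @rdname bundle-accessors
#' @export
setGeneric("truthTable", function(x) standardGeneric("truthTable"))

#' @rdname bundle-accessors
#' @export
setMethod("truthTable", "StudyBundle", function(x) x@truth)

#' Subset a StudyBundle
#'
#' `bundle[i, j]` restricts to genes `i` and samples `j` (ids, indices or
#' logical). The dosage matrix, annotations and control probes follow the
#' sample subset; SNPs, gene sets and the truth table are kept as-is.
#' Retained samples keep their original relative order only if `j` is
#' given in that order.
#'
#' @param x a [StudyBundle-class]
#' @param i gene selector (missing = all)
#' @param j sample selector (missing = all)
#' @param ... ignored
#' @param drop ignored
#' @return a [StudyBundle-class]
#' @export
setMethod("[", c("StudyBundle", "ANY", "ANY"), function(x, i, j, ..., drop = FALSE) {
  if (missing(i)) i <- seq_len(nrow(x@se))
  if (missing(j)) j <- seq_len(ncol(x@se))
  se <- x@se[i, j]
  new("StudyBundle",
      se = se,
      dosage = x@dosage[, colnames(se), drop = FALSE],
      snpCoords = x@snpCoords,
      geneSets = x@geneSets,
      controlPos = if (is.null(x@controlPos)) NULL else
        x@controlPos[, colnames(se), drop = FALSE],
      controlNeg = if (is.null(x@controlNeg)) NULL else
        x@controlNeg[, colnames(se), drop = FALSE],
      truth = x@truth)
})

#' @rdname bundle-accessors
#' @export
setMethod("dim", "StudyBundle", function(x) dim(x@se))
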