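#' Score scan results against a planted-effect truth table
#'
#' Compares the `significant` flags of an [eqtlScan()],
#' [pairedInteractionScan()] or [fqtlScan()] result table with the truth
#' table of the synthetic bundle that produced it, yielding the realized
#' false-discovery proportion and the recovery power for the planted
#' effects of the matching type.
#'
#' @param records result `data.frame` with columns `snp`, `significant`,
#'   and `gene` (eQTL/interaction) or `set` (fQTL).
#' @param truth truth `data.frame` from [truthTable()].
#' @param type planted-effect type to score against: `"eqtl"`,
#'   `"interaction"` or `"fqtl"`.
#' @return `list(fdp =, power =, nFlagged =, nPlanted =)`; `fdp` is 0 when
#'   nothing is flagged, `power` is `NA` when nothing was planted.
#' @export
scoreAgainstTruth <- function(records, truth,
                              type = c("eqtl", "interaction", "fqtl")) {
  type <- match.arg(type)
  targetCol <- if (type == "fqtl") "set" else "gene"
  tr <- truth[truth$type == type, , drop = FALSE]
  key <- paste(tr$snp, tr$target)
  flagged <- records[records$significant, , drop = FALSE]
  fkey <- paste(flagged$snp, flagged[[targetCol]])
  list(fdp = if (nrow(flagged)) mean(!fkey %in% key) else 0,
       power = if (nrow(tr)) mean(key %in% fkey) else NA_real_,
       nFlagged = nrow(flagged),
       nPlanted = nrow(tr))
}
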