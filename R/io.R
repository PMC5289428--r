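# Full-precision numeric formatting so numeric TSVs round-trip exactly
# (17 significant digits uniquely identify a double).
fmtNum <- function(x) {
  out <- formatC(x, digits = 17, format = "g")
  out[is.na(x)] <- "NA"
  out
}

# Skip leading "#" comment lines (output-file provenance headers).
readTsv <- function(path, ...) {
  if (!file.exists(path)) stop("file not found: ", path)
  read.delim(path, sep = "\t", comment.char = "#", check.names = FALSE,
             stringsAsFactors = FALSE, ...)
}

#' Read / write an expression matrix TSV
#'
#' Tab-separated, first column `gene_id`, remaining columns one per sample
#' (header row = sample ids), numeric body. `"NA"` denotes a missing
#' value. Row and column order are preserved as on disk; duplicate gene
#' ids are rejected. `writeExpression` stores full precision so a
#' write/read round trip reproduces the matrix exactly.
#'
#' @param path file path.
#' @return `readExpression`: numeric matrix genes x samples.
#' @export
readExpression <- function(path) {
  df <- readTsv(path)
  if (colnames(df)[1L] != "gene_id")
    stop("expression TSV must start with a 'gene_id' column")
  ids <- as.character(df[[1L]])
  if (anyDuplicated(ids))
    stop("duplicate gene id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  body <- df[, -1L, drop = FALSE]
  for (j in seq_along(body)) {
    if (is.logical(body[[j]]) && all(is.na(body[[j]])))
      body[[j]] <- as.numeric(body[[j]])
    if (!is.numeric(body[[j]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(body[[j]]))) &
                     !is.na(body[[j]]) & body[[j]] != "NA")
      stop("non-numeric value in column '", colnames(body)[j],
           "', row ", if (length(bad)) bad[1L] else "?")
    }
  }
  m <- as.matrix(body)
  rownames(m) <- ids
  m
}

#' @rdname readExpression
#' @param expr numeric matrix genes x samples with dimnames.
#' @export
writeExpression <- function(expr, path) {
  df <- data.frame(gene_id = rownames(expr),
                   apply(expr, 2L, fmtNum),
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write allelic dosages
#'
#' TSV dialect: columns `snp_id`, `chrom`, `pos` (1-based), then one
#' column per sample with dosages in `[0, 2]`. VCF dialect: dosage taken
#' from the per-genotype `DS` FORMAT field, falling back to the `GT`
#' alternate-allele count when `DS` is absent (requires the
#' VariantAnnotation package).
#'
#' @param path file path.
#' @param format `"tsv"` or `"vcf"`.
#' @return `list(dosage =, coords =)`: SNPs x samples matrix and a
#'   `data.frame(snp, chrom, pos)`.
#' @export
readDosages <- function(path, format = c("tsv", "vcf")) {
  format <- match.arg(format)
  if (format == "vcf") return(readDosagesVcf(path))
  df <- readTsv(path)
  need <- c("snp_id", "chrom", "pos")
  if (!identical(colnames(df)[1:3], need))
    stop("dosage TSV must start with columns snp_id, chrom, pos")
  ids <- as.character(df$snp_id)
  if (anyDuplicated(ids))
    stop("duplicate SNP id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  m <- as.matrix(df[, -(1:3), drop = FALSE])
  rownames(m) <- ids
  if (any(m < 0 | m > 2, na.rm = TRUE))
    stop("dosage outside [0, 2]")
  list(dosage = m,
       coords = data.frame(snp = ids, chrom = as.character(df$chrom),
                           pos = as.integer(df$pos)))
}

readDosagesVcf <- function(path) {
  if (!requireNamespace("VariantAnnotation", quietly = TRUE))
    stop("reading VCF dosages requires the VariantAnnotation package")
  vcf <- VariantAnnotation::readVcf(path)
  gen <- VariantAnnotation::geno(vcf)
  if ("DS" %in% names(gen)) {
    m <- gen$DS
    mode(m) <- "numeric"
  } else if ("GT" %in% names(gen)) {
    gt <- gen$GT
    m <- apply(gt, c(1, 2), function(g) {
      if (is.na(g) || g %in% c(".", "./.", ".|.")) return(NA_real_)
      sum(as.integer(strsplit(g, "[/|]")[[1L]]) > 0L)
    })
  } else stop("VCF carries neither DS nor GT genotype fields")
  if (any(m < 0 | m > 2, na.rm = TRUE)) stop("dosage outside [0, 2]")
  rr <- SummarizedExperiment::rowRanges(vcf)
  rownames(m) <- names(rr)
  list(dosage = m,
       coords = data.frame(snp = names(rr),
                           chrom = as.character(GenomicRanges::seqnames(rr)),
                           pos = GenomicRanges::start(rr)))
}

#' @rdname readDosages
#' @param dosage SNPs x samples matrix.
#' @param coords `data.frame(snp, chrom, pos)` aligned with `dosage` rows.
#' @export
writeDosages <- function(dosage, coords, path) {
  df <- data.frame(snp_id = rownames(dosage),
                   chrom = coords$chrom[match(rownames(dosage), coords$snp)],
                   pos = coords$pos[match(rownames(dosage), coords$snp)],
                   apply(dosage, 2L, fmtNum),
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene sets from a GMT file
#'
#' Tab-separated lines: set name, description, then one or more gene ids.
#' Duplicate gene ids within a set are removed (count reported in a
#' message); duplicate set names are an error.
#'
#' @param path GMT file path.
#' @param provenance label stored on the collection.
#' @return a [GeneSetCollection-class]
#' @export
readGeneSets <- function(path, provenance = NA_character_) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 3L)
  if (length(bad))
    stop("GMT line ", bad[1L], " has fewer than 3 fields")
  nm <- vapply(parts, `[[`, character(1), 1L)
  if (anyDuplicated(nm))
    stop("duplicate gene-set name(s): ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  desc <- vapply(parts, `[[`, character(1), 2L)
  genes <- lapply(parts, function(x) x[-(1:2)])
  nd <- sum(lengths(genes) - lengths(lapply(genes, unique)))
  if (nd > 0) message(nd, " duplicate gene id(s) removed across sets")
  GeneSetCollection(setNames(genes, nm),
                    descriptions = setNames(desc, nm),
                    provenance = provenance)
}

#' @rdname readGeneSets
#' @param sets a [GeneSetCollection-class] or named list.
#' @export
writeGeneSets <- function(sets, path) {
  desc <- character()
  if (methods::is(sets, "GeneSetCollection")) {
    desc <- sets@descriptions
    sets <- geneSets(sets)
  }
  lines <- vapply(names(sets), function(nm) {
    d <- if (nm %in% names(desc)) desc[[nm]] else "na"
    paste(c(nm, d, sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read / write sample annotation TSV
#'
#' Columns: `sample_id`, `subject`, `tissue`, `er`, `pr`, `ageDx`,
#' `yearDx`, `plate`.
#'
#' @param path file path.
#' @return `readSampleInfo`: `data.frame` with rownames = sample ids.
#' @export
readSampleInfo <- function(path) {
  df <- readTsv(path, colClasses = c(er = "character", pr = "character"))
  need <- c("sample_id", "subject", "tissue", "er", "pr", "ageDx",
            "yearDx", "plate")
  miss <- setdiff(need, colnames(df))
  if (length(miss))
    stop("sample annotation lacks column(s): ", paste(miss, collapse = ", "))
  rownames(df) <- df$sample_id
  df[, setdiff(colnames(df), "sample_id"), drop = FALSE]
}

#' @rdname readSampleInfo
#' @param info annotation `data.frame` (rownames = sample ids).
#' @export
writeSampleInfo <- function(info, path) {
  df <- cbind(sample_id = rownames(info), info)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA")
  invisible(path)
}

#' Write a whole study bundle to a directory of plain-text files
#'
#' Files written: `expression.tsv`, `dosage.tsv`, `samples.tsv`,
#' `genes.tsv` (coordinates), `gene_sets.gmt` (if any),
#' `control_pos.tsv` / `control_neg.tsv` (if any), `truth.tsv` (if any).
#' [readStudyBundle()] reconstructs the bundle; numeric matrices
#' round-trip exactly.
#'
#' @param bundle a [StudyBundle-class].
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
writeStudyBundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(f) file.path(dir, f)
  writeExpression(exprMatrix(bundle), fp("expression.tsv"))
  sc <- snpCoords(bundle)
  writeDosages(dosages(bundle),
               data.frame(snp = names(sc),
                          chrom = as.character(GenomicRanges::seqnames(sc)),
                          pos = GenomicRanges::start(sc)),
               fp("dosage.tsv"))
  writeSampleInfo(sampleInfo(bundle), fp("samples.tsv"))
  gc <- geneCoords(bundle)
  write.table(data.frame(gene_id = names(gc),
                         chrom = as.character(GenomicRanges::seqnames(gc)),
                         start = GenomicRanges::start(gc),
                         end = GenomicRanges::end(gc)),
              fp("genes.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  if (length(geneSets(bundle)))
    writeGeneSets(bundle@geneSets, fp("gene_sets.gmt"))
  cp <- controlProbes(bundle)
  if (!is.null(cp)) {
    writeMat <- function(m, f) {
      df <- data.frame(probe_id = rownames(m), apply(m, 2L, fmtNum),
                       check.names = FALSE)
      write.table(df, fp(f), sep = "\t", quote = FALSE, row.names = FALSE)
    }
    writeMat(cp$pos, "control_pos.tsv")
    writeMat(cp$neg, "control_neg.tsv")
  }
  if (nrow(truthTable(bundle)))
    write.table(truthTable(bundle), fp("truth.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' @rdname writeStudyBundle
#' @return `readStudyBundle`: a [StudyBundle-class].
#' @export
readStudyBundle <- function(dir) {
  fp <- function(f) file.path(dir, f)
  expr <- readExpression(fp("expression.tsv"))
  dos <- readDosages(fp("dosage.tsv"))
  info <- readSampleInfo(fp("samples.tsv"))
  genes <- readTsv(fp("genes.tsv"))
  geneCo <- data.frame(gene = genes$gene_id, chrom = genes$chrom,
                       start = genes$start, end = genes$end)
  sets <- if (file.exists(fp("gene_sets.gmt")))
    readGeneSets(fp("gene_sets.gmt")) else list()
  readMat <- function(f) {
    df <- readTsv(fp(f))
    m <- as.matrix(df[, -1L, drop = FALSE])
    rownames(m) <- df[[1L]]
    m
  }
  cpPos <- if (file.exists(fp("control_pos.tsv"))) readMat("control_pos.tsv")
  cpNeg <- if (file.exists(fp("control_neg.tsv"))) readMat("control_neg.tsv")
  truth <- if (file.exists(fp("truth.tsv")))
    readTsv(fp("truth.tsv")) else NULL
  StudyBundle(exprs = expr, sampleInfo = info, dosage = dos$dosage,
              snpCoords = dos$coords, geneCoords = geneCo, geneSets = sets,
              controlPos = cpPos, controlNeg = cpNeg, truth = truth)
}

#' Write a results table with a provenance header
#'
#' Prepends `#`-prefixed header lines (package version, seed, config
#' hash) so identical runs produce byte-identical files, then the
#' tab-separated records.
#'
#' @param records results `data.frame`.
#' @param path output path.
#' @param seed seed used for the run (`NA` if none).
#' @param configHash optional config fingerprint (e.g.
#'   `tools::md5sum(configFile)`).
#' @return `path`, invisibly.
#' @export
writeResults <- function(records, path, seed = NA, configHash = NA) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste0("# transqtl version=", as.character(packageVersion("transqtl"))),
    paste0("# seed=", seed),
    paste0("# config=", configHash)), con)
  numCols <- vapply(records, is.numeric, logical(1))
  out <- records
  for (j in which(numCols)) out[[j]] <- fmtNum(records[[j]])
  write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
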