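Package: transqtl
Title: Trans-eQTL and Gene-Set Functional QTL Scans for Tumor Expression Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Per-SNP, per-gene expression quantitative trait locus (eQTL)
    scans with empirical-Bayes moderated t statistics and per-SNP
    Benjamini-Hochberg false discovery rate control; a paired tumor/normal
    genotype-by-tissue interaction scan; a gene-set "functional QTL" (fQTL)
    statistic that treats standardized expression of a gene set as repeated
    measures and assesses significance by genotype-permutation FDR; a
    cross-platform receptor-status concordance check for FFPE expression
    assays; and the accompanying sample-level quality control operators
    (control-probe AUC filtering, technical-replicate concordance,
    principal-component batch adjustment). A synthetic-data generator with
    a planted-effect truth table supports calibration and power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    withr
Suggests:
    testthat (>= 3.0.0),
    limma,
    fgsea,
    VariantAnnotation,
    optparse,
    yaml,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
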