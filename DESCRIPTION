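Package: lncqtl
Title: Long Non-Coding RNA Identification, Differential Expression and
    QTL Colocalization for Two-Breed RNA-Seq Designs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A tidy toolkit for the downstream analysis of long non-coding
    RNAs (lncRNAs) assembled from bulk RNA-seq of two contrasting animal
    breeds, modelled on lean-versus-obese pig adipose studies.  Implements
    the candidate filter cascade (length, exon count, read coverage, FPKM),
    the four-tool coding-potential intersection, positional classification
    into lincRNA, antisense, intronic and sense categories, replicate-free
    differential expression with fold-change and Benjamini-Hochberg
    thresholds, 100-kb cis target gene assignment, colocalization of
    differentially expressed features with quantitative trait locus (QTL)
    intervals scored as count per span, and hypergeometric term enrichment.
    A deterministic synthetic-data generator with planted ground truth
    makes the whole pipeline testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    stringr,
    rlang,
    ggplot2,
    generics,
    stats,
    utils,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
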