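#' Assign cis target genes within a fixed genomic window
#'
#' Pairs each lncRNA with every gene on the same chromosome whose body lies
#' within `window` bp of the lncRNA body (body-to-body gap, strand-agnostic
#' by default).  Overlapping pairs get distance 0.  `relation` records where
#' the gene sits relative to the lncRNA in genome coordinates: `upstream`
#' (lower coordinates), `downstream` (higher), or `overlapping`.  In
#' strand-aware mode upstream/downstream are flipped for minus-strand
#' lncRNAs.
#'
#' @param lncrnas Tibble with `transcript_id`, `chrom`, `start`, `end`
#'   (internal half-open coordinates) and, for strand-aware mode, `strand`.
#' @param genes Gene tibble with `gene_id`, `chrom`, `start`, `end`.
#' @param window Maximum body-to-body gap in bp (default 100 kb, the
#'   conventional cis-regulation search radius).
#' @param strand_aware Orient upstream/downstream by lncRNA strand.
#' @return A tibble `lncrna_id`, `gene_id`, `distance`, `relation`.
#' @export
assign_cis_targets <- function(lncrnas, genes, window = 100000,
                               strand_aware = FALSE) {
  if (window < 0) abort("`window` must be non-negative")
  .assert_cols(lncrnas, c("transcript_id", "chrom", "start", "end"), "lncrnas")
  .assert_cols(genes, c("gene_id", "chrom", "start", "end"), "genes")
  if (nrow(lncrnas) == 0 || nrow(genes) == 0) {
    return(tibble(lncrna_id = character(), gene_id = character(),
                  distance = numeric(), relation = character()))
  }
  gl <- GenomicRanges::GRanges(lncrnas$chrom,
                               IRanges::IRanges(lncrnas$start + 1L,
                                                lncrnas$end))
  gg <- GenomicRanges::GRanges(genes$chrom,
                               IRanges::IRanges(genes$start + 1L, genes$end))
  hits <- GenomicRanges::findOverlaps(gl, gg, maxgap = window,
                                      ignore.strand = TRUE)
  qi <- S4Vectors::queryHits(hits)
  si <- S4Vectors::subjectHits(hits)
  ls <- lncrnas$start[qi]; le <- lncrnas$end[qi]
  gs <- genes$start[si]; ge <- genes$end[si]
  overlap <- .intervals_overlap(ls, le, gs, ge)
  gap <- .interval_gap(ls, le, gs, ge)
  # disjoint intervals lie entirely on one side or the other
  rel <- dplyr::case_when(overlap ~ "overlapping",
                          ge <= ls ~ "upstream",
                          TRUE ~ "downstream")
  if (strand_aware) {
    .assert_cols(lncrnas, "strand", "lncrnas")
    minus <- lncrnas$strand[qi] == "-"
    rel[minus & rel == "upstream"] <- "tmp"
    rel[minus & rel == "downstream"] <- "upstream"
    rel[rel == "tmp"] <- "downstream"
  }
  tibble(lncrna_id = lncrnas$transcript_id[qi],
         gene_id = genes$gene_id[si],
         distance = as.numeric(gap),
         relation = rel) |>
    arrange(.data$lncrna_id, .data$distance, .data$gene_id)
}

#' Join lncRNA and gene differential-expression tables over cis pairs
#'
#' Restricts cis pairs to differentially expressed lncRNAs and decorates each
#' pair with fold changes and regulation direction for both sides, in the
#' style of a "DE lncRNAs and their target mRNAs" report table.
#'
#' @param pairs Output of [assign_cis_targets()].
#' @param lnc_de,gene_de `lnc_de` result tibbles (see [run_de()]) for
#'   lncRNAs and genes respectively.
#' @param genes_de_only Also drop pairs whose gene is not differentially
#'   expressed.  Default `FALSE` (all cis genes of a DE lncRNA are targets).
#' @return A tibble `lncrna_id`, `lnc_fold_change`, `lnc_status`, `gene_id`,
#'   `gene_fold_change`, `gene_status`, `distance`, `relation`.
#' @export
pair_de_tables <- function(pairs, lnc_de, gene_de, genes_de_only = FALSE) {
  .assert_cols(pairs, c("lncrna_id", "gene_id"), "pairs")
  .assert_cols(lnc_de, c("feature_id", "fold_change", "status"), "lnc_de")
  .assert_cols(gene_de, c("feature_id", "fold_change", "status"), "gene_de")
  out <- pairs |>
    inner_join(select(as_tibble(lnc_de), "feature_id",
                      lnc_fold_change = "fold_change", lnc_status = "status"),
               by = c(lncrna_id = "feature_id")) |>
    inner_join(select(as_tibble(gene_de), "feature_id",
                      gene_fold_change = "fold_change",
                      gene_status = "status"),
               by = c(gene_id = "feature_id")) |>
    filter(.data$lnc_status != "ns")
  if (genes_de_only) out <- filter(out, .data$gene_status != "ns")
  select(out, "lncrna_id", "lnc_fold_change", "lnc_status", "gene_id",
         "gene_fold_change", "gene_status", dplyr::any_of(c("distance",
                                                            "relation")))
}
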