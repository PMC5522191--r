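#' Map genomic features onto QTL regions
#'
#' A feature belongs to a QTL when its body overlaps the QTL interval by at
#' least one base (`mode = "any"`); `mode = "within"` requires the feature to
#' be fully contained.  One feature may belong to many QTLs.
#'
#' @param features Tibble with `feature_id`, `chrom`, `start`, `end`
#'   (internal half-open coordinates).
#' @param qtls QTL tibble from [read_qtl_table()] (uses `start0`/`end0`).
#' @param mode Overlap semantics.
#' @return A membership tibble `qtl_id`, `feature_id`, `trait`, `chrom`.
#' @export
map_to_qtl <- function(features, qtls, mode = c("any", "within")) {
  mode <- match.arg(mode)
  .assert_cols(features, c("feature_id", "chrom", "start", "end"), "features")
  .assert_cols(qtls, c("qtl_id", "chrom", "trait", "start0", "end0"), "qtls")
  if (nrow(features) == 0 || nrow(qtls) == 0) {
    return(tibble(qtl_id = integer(), feature_id = character(),
                  trait = character(), chrom = character()))
  }
  gf <- GenomicRanges::GRanges(features$chrom,
                               IRanges::IRanges(features$start + 1L,
                                                features$end))
  gq <- GenomicRanges::GRanges(qtls$chrom,
                               IRanges::IRanges(qtls$start0 + 1L, qtls$end0))
  hits <- GenomicRanges::findOverlaps(gf, gq,
                                      type = if (mode == "within") "within"
                                             else "any",
                                      ignore.strand = TRUE)
  tibble(qtl_id = qtls$qtl_id[S4Vectors::subjectHits(hits)],
         feature_id = features$feature_id[S4Vectors::queryHits(hits)],
         trait = qtls$trait[S4Vectors::subjectHits(hits)],
         chrom = qtls$chrom[S4Vectors::subjectHits(hits)]) |>
    arrange(.data$qtl_id, .data$feature_id)
}

#' Tally differentially expressed features by QTL trait
#'
#' For each trait, counts the distinct differentially expressed lncRNAs and
#' mRNAs overlapping any of the trait's QTL regions, split by regulation
#' direction.  A feature overlapping several QTL_IDs of one trait counts
#' once for that trait; a feature overlapping QTLs of several traits counts
#' once per trait.  `n_qtl_id` is the number of the trait's QTL_IDs
#' containing at least one DE lncRNA.
#'
#' @param lnc_map,mrna_map Membership tibbles from [map_to_qtl()] computed on
#'   lncRNAs and mRNAs (genes) respectively.
#' @param lnc_de,mrna_de `lnc_de` tibbles (see [run_de()]) supplying
#'   `status` per feature; only `up`/`down` features are counted.
#' @return A tibble `trait`, `n_qtl_id`, `lnc_total`, `lnc_up`, `lnc_down`,
#'   `mrna_total`, `mrna_up`, `mrna_down`.
#' @export
tally_by_trait <- function(lnc_map, mrna_map, lnc_de, mrna_de) {
  de_status <- function(de) {
    as_tibble(de) |>
      filter(.data$status != "ns") |>
      select("feature_id", "status")
  }
  one_class <- function(membership, de) {
    membership |>
      inner_join(de_status(de), by = "feature_id") |>
      distinct(.data$trait, .data$feature_id, .data$status) |>
      group_by(.data$trait) |>
      summarise(total = n(),
                up = sum(.data$status == "up"),
                down = sum(.data$status == "down"),
                .groups = "drop")
  }
  nq <- lnc_map |>
    inner_join(de_status(lnc_de), by = "feature_id") |>
    distinct(.data$trait, .data$qtl_id) |>
    count(.data$trait, name = "n_qtl_id")
  lnc <- one_class(lnc_map, lnc_de) |>
    rename(lnc_total = "total", lnc_up = "up", lnc_down = "down")
  mrna <- one_class(mrna_map, mrna_de) |>
    rename(mrna_total = "total", mrna_up = "up", mrna_down = "down")
  nq |>
    dplyr::full_join(lnc, by = "trait") |>
    dplyr::full_join(mrna, by = "trait") |>
    mutate(across(-"trait", ~ tidyr::replace_na(.x, 0L))) |>
    arrange(.data$trait)
}

#' Score QTL regions by DE-lncRNA density
#'
#' Each QTL_ID is scored as the number of differentially expressed lncRNAs
#' it contains divided by its span, `score = count / (end - start)` on the
#' printed 1-based coordinates.  The score is also formatted in scientific
#' notation with three significant digits for reporting.
#'
#' @param qtls QTL tibble from [read_qtl_table()].
#' @param counts Either a membership tibble from [map_to_qtl()] restricted
#'   to DE lncRNAs (distinct features counted per QTL_ID), or a tibble
#'   `qtl_id`, `de_lncrna_count`.
#' @return A tibble of class `lnc_qtl_scores`: `qtl_id`, `chrom`, `trait`,
#'   `symbol`, `start`, `end`, `de_lncrna_count`, `span`, `score`,
#'   `score_label`.
#' @export
score_qtl <- function(qtls, counts) {
  .assert_cols(qtls, c("qtl_id", "chrom", "trait", "start", "end"), "qtls")
  if ("de_lncrna_count" %in% names(counts)) {
    cnt <- select(counts, "qtl_id", "de_lncrna_count")
  } else {
    .assert_cols(counts, c("qtl_id", "feature_id"), "counts")
    cnt <- counts |>
      distinct(.data$qtl_id, .data$feature_id) |>
      count(.data$qtl_id, name = "de_lncrna_count")
  }
  out <- qtls |>
    select("qtl_id", "chrom", "trait",
           dplyr::any_of("symbol"), "start", "end") |>
    left_join(cnt, by = "qtl_id") |>
    mutate(
      de_lncrna_count = tidyr::replace_na(.data$de_lncrna_count, 0L),
      span = .data$end - .data$start,
      score = .data$de_lncrna_count / .data$span,
      score_label = .format_score(.data$score)
    )
  if (any(out$span <= 0)) abort("QTL span must be positive")
  class(out) <- c("lnc_qtl_scores", class(out))
  out
}

#' Rank QTL regions by score
#'
#' Orders score rows by descending score, breaking exact ties by ascending
#' QTL_ID, and keeps the top `top_n`.
#'
#' @param rows A [score_qtl()] result.
#' @param top_n Number of rows to keep (default 20).
#' @return The ordered, truncated tibble with a `rank` column prepended.
#' @export
rank_qtl <- function(rows, top_n = 20) {
  .assert_cols(rows, c("qtl_id", "score"), "rows")
  rows |>
    arrange(desc(.data$score), .data$qtl_id) |>
    slice_head(n = top_n) |>
    mutate(rank = row_number(), .before = 1)
}

#' lncRNA-mRNA pairs sharing a QTL region
#'
#' For every QTL_ID containing at least one differentially expressed lncRNA
#' and at least one differentially expressed mRNA, lists both feature sets —
#' candidate local regulatory relationships.
#'
#' @param lnc_map,mrna_map Membership tibbles from [map_to_qtl()] computed on
#'   DE features only.
#' @return A tibble `qtl_id`, `lncrna_ids` (list-column), `gene_ids`
#'   (list-column), `n_lnc`, `n_gene`.
#' @export
colocated_pairs <- function(lnc_map, mrna_map) {
  lnc <- lnc_map |>
    distinct(.data$qtl_id, .data$feature_id) |>
    group_by(.data$qtl_id) |>
    summarise(lncrna_ids = list(sort(.data$feature_id)), .groups = "drop")
  mrna <- mrna_map |>
    distinct(.data$qtl_id, .data$feature_id) |>
    group_by(.data$qtl_id) |>
    summarise(gene_ids = list(sort(.data$feature_id)), .groups = "drop")
  inner_join(lnc, mrna, by = "qtl_id") |>
    mutate(n_lnc = map_int(.data$lncrna_ids, length),
           n_gene = map_int(.data$gene_ids, length)) |>
    arrange(.data$qtl_id)
}
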