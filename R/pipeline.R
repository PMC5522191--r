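#' Run the full lncRNA downstream analysis pipeline
#'
#' Orchestrates every stage on one input bundle: candidate filtering,
#' coding-potential intersection, positional classification, differential
#' expression of lncRNAs and genes, cis target assignment, QTL
#' colocalization (trait tallies, count/span scores, ranking, co-located
#' pairs) and hypergeometric enrichment of the target genes.
#'
#' @param input Either a [simulate_dataset()] result or a directory
#'   containing the file layout written by [write_sim_dataset()]
#'   (`annotation.gtf`, `transcripts.gtf`, `expression.tsv`,
#'   `library_sizes.tsv`, `groups.tsv`, `coding_calls_<TOOL>.tsv`,
#'   `qtl_regions.tsv`, `term_map.tsv`).
#' @param out_dir Optional output directory; when given, every stage table
#'   is written as TSV together with a `manifest.tsv` recording the
#'   thresholds actually used.
#' @param filter Candidate filter thresholds ([filter_params()]).
#' @param de Differential-expression thresholds ([de_params()]).
#' @param window Cis target window in bp.
#' @param overlap_mode QTL overlap semantics (see [map_to_qtl()]).
#' @param top_n Rows kept by [rank_qtl()].
#' @param genes_de_only Restrict target pairs to DE genes.
#' @return A named list of stage results: `filtered`, `filter_tally`,
#'   `venn`, `records`, `category_summary`, `lnc_de`, `gene_de`,
#'   `target_pairs`, `target_table`, `lnc_qtl_map`, `gene_qtl_map`,
#'   `trait_tally`, `qtl_scores`, `qtl_top`, `colocated`, `enrichment`.
#' @export
run_pipeline <- function(input, out_dir = NULL,
                         filter = filter_params(), de = de_params(),
                         window = 100000, overlap_mode = c("any", "within"),
                         top_n = 20, genes_de_only = FALSE) {
  overlap_mode <- match.arg(overlap_mode)
  x <- if (inherits(input, "lnc_sim")) .inputs_from_sim(input)
       else .inputs_from_dir(input)

  # identification
  filtered <- filter_candidates(x$transcripts, x$expression, filter)
  calls_kept <- x$coding_calls |>
    filter(.data$transcript_id %in%
             filtered$transcript_id[filtered$pass])
  inter <- intersect_coding_calls(calls_kept)
  venn <- venn_counts(calls_kept)
  cand_ids <- inter$transcript_id[inter$is_candidate]
  candidates <- filtered |> filter(.data$transcript_id %in% cand_ids)
  records <- classify_lncrnas(candidates, x$genes) |>
    left_join(select(candidates, "transcript_id", "chrom", "strand",
                     "start", "end", "spliced_length"),
              by = "transcript_id")
  category_summary <- summarize_categories(records)

  # differential expression: lncRNA candidates at transcript level, genes by
  # summing their member transcripts
  lnc_expr <- x$expression |> filter(.data$feature_id %in% cand_ids)
  lnc_de <- run_de(lnc_expr, x$library_sizes, x$groups, params = de)
  gene_expr <- x$expression |>
    inner_join(x$tx2gene, by = c(feature_id = "transcript_id")) |>
    group_by(feature_id = .data$gene_id, .data$sample_id) |>
    summarise(fpkm = sum(.data$fpkm), fragments = sum(.data$fragments),
              .groups = "drop")
  gene_de <- run_de(gene_expr, x$library_sizes, x$groups, params = de)

  # cis targets of DE lncRNAs
  de_lnc_ids <- lnc_de$feature_id[lnc_de$status != "ns"]
  de_lnc_pos <- records |> filter(.data$transcript_id %in% de_lnc_ids)
  target_pairs <- assign_cis_targets(de_lnc_pos, x$genes, window = window)
  target_table <- pair_de_tables(target_pairs, lnc_de, gene_de,
                                 genes_de_only = genes_de_only)

  # QTL colocalization on DE features
  lnc_feats <- records |>
    filter(.data$transcript_id %in% de_lnc_ids) |>
    select(feature_id = "transcript_id", "chrom", "start", "end")
  de_gene_ids <- gene_de$feature_id[gene_de$status != "ns"]
  gene_feats <- x$genes |>
    filter(.data$gene_id %in% de_gene_ids) |>
    select(feature_id = "gene_id", "chrom", "start", "end")
  lnc_qtl_map <- map_to_qtl(lnc_feats, x$qtls, mode = overlap_mode)
  gene_qtl_map <- map_to_qtl(gene_feats, x$qtls, mode = overlap_mode)
  trait_tally <- tally_by_trait(lnc_qtl_map, gene_qtl_map, lnc_de, gene_de)
  qtl_scores <- score_qtl(x$qtls, lnc_qtl_map)
  qtl_top <- rank_qtl(qtl_scores, top_n = top_n)
  colocated <- colocated_pairs(lnc_qtl_map, gene_qtl_map)

  # enrichment of target genes among annotated genes
  background <- unique(x$term_map$gene_id)
  targets <- intersect(unique(target_table$gene_id), background)
  enrichment <- if (length(targets) > 0) {
    hypergeom_enrich(targets, x$term_map, background)
  } else {
    hypergeom_enrich(character(), x$term_map, background)
  }

  res <- list(filtered = filtered, filter_tally = attr(filtered, "tally"),
              venn = venn, records = records,
              category_summary = category_summary,
              lnc_de = lnc_de, gene_de = gene_de,
              target_pairs = target_pairs, target_table = target_table,
              lnc_qtl_map = lnc_qtl_map, gene_qtl_map = gene_qtl_map,
              trait_tally = trait_tally, qtl_scores = qtl_scores,
              qtl_top = qtl_top, colocated = colocated,
              enrichment = enrichment)
  if (!is.null(out_dir)) {
    .write_pipeline_outputs(res, out_dir, filter, de, window, overlap_mode,
                            top_n, genes_de_only)
  }
  res
}

.inputs_from_sim <- function(sim) {
  is_mrna <- startsWith(sim$transcripts$transcript_id, "MRNA")
  list(
    transcripts = sim$transcripts[!is_mrna, ],
    genes = sim$genes,
    tx2gene = sim$transcripts[is_mrna, c("transcript_id", "gene_id")],
    expression = sim$expression,
    library_sizes = sim$library_sizes,
    groups = sim$groups,
    coding_calls = sim$coding_calls,
    qtls = sim$qtls,
    term_map = sim$term_map
  )
}

.inputs_from_dir <- function(dir) {
  need <- c("annotation.gtf", "transcripts.gtf", "expression.tsv",
            "library_sizes.tsv", "groups.tsv", "qtl_regions.tsv",
            "term_map.tsv")
  paths <- file.path(dir, need)
  missing <- paths[!file.exists(paths)]
  if (length(missing) > 0) {
    abort(sprintf("missing input file(s): %s", paste(missing, collapse = ", ")))
  }
  call_files <- list.files(dir, pattern = "^coding_calls_.*\\.tsv$",
                           full.names = TRUE)
  if (length(call_files) == 0) {
    abort(sprintf("missing input file(s): %s",
                  file.path(dir, "coding_calls_<TOOL>.tsv")))
  }
  names(call_files) <- sub("^coding_calls_(.*)\\.tsv$", "\\1",
                           basename(call_files))
  anno <- read_gtf(file.path(dir, "annotation.gtf"))
  asm <- read_gtf(file.path(dir, "transcripts.gtf"))
  list(
    transcripts = asm$transcripts,
    genes = anno$genes,
    tx2gene = anno$transcripts[, c("transcript_id", "gene_id")],
    expression = readr::read_tsv(file.path(dir, "expression.tsv"),
                                 col_types = "ccdd", progress = FALSE),
    library_sizes = readr::read_tsv(file.path(dir, "library_sizes.tsv"),
                                    col_types = "cd", progress = FALSE),
    groups = readr::read_tsv(file.path(dir, "groups.tsv"), col_types = "cc",
                             progress = FALSE),
    coding_calls = read_coding_calls(call_files),
    qtls = read_qtl_table(file.path(dir, "qtl_regions.tsv")),
    term_map = readr::read_tsv(file.path(dir, "term_map.tsv"),
                               col_types = "ccc", progress = FALSE)
  )
}

.write_pipeline_outputs <- function(res, out_dir, filter, de, window,
                                    overlap_mode, top_n, genes_de_only) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(out_dir, f)
  flat <- function(df) {
    df <- as_tibble(df)
    list_cols <- names(df)[map_lgl(df, is.list)]
    for (col in list_cols) {
      df[[col]] <- map_chr(df[[col]], paste, collapse = ",")
    }
    df
  }
  readr::write_tsv(flat(select(res$filtered, -"exons")), p("filtered_transcripts.tsv"))
  readr::write_tsv(res$filter_tally, p("filter_tally.tsv"))
  readr::write_tsv(res$venn, p("venn_counts.tsv"))
  readr::write_tsv(res$records, p("lncrna_records.tsv"))
  readr::write_tsv(res$category_summary, p("category_summary.tsv"))
  readr::write_tsv(as_tibble(res$lnc_de), p("de_lncrna.tsv"))
  readr::write_tsv(as_tibble(res$gene_de), p("de_genes.tsv"))
  readr::write_tsv(res$target_pairs, p("target_pairs.tsv"))
  readr::write_tsv(res$target_table, p("target_table.tsv"))
  readr::write_tsv(res$trait_tally, p("trait_tally.tsv"))
  readr::write_tsv(as_tibble(res$qtl_scores), p("qtl_scores.tsv"))
  readr::write_tsv(as_tibble(res$qtl_top), p("qtl_top.tsv"))
  readr::write_tsv(flat(res$colocated), p("colocated_pairs.tsv"))
  readr::write_tsv(as_tibble(res$enrichment), p("enrichment.tsv"))
  manifest <- tibble(
    parameter = c("min_length", "min_exons", "min_coverage", "min_fpkm",
                  "fpkm_rule", "de_preset", "pseudocount", "q_threshold",
                  "fc_up", "fc_down", "inclusive_fc", "window",
                  "overlap_mode", "top_n", "genes_de_only"),
    value = as.character(c(filter$min_length, filter$min_exons,
                           filter$min_coverage, filter$min_fpkm,
                           filter$fpkm_rule, de$preset, de$pseudocount,
                           de$q_threshold, de$fc_up, de$fc_down,
                           de$inclusive_fc, window, overlap_mode, top_n,
                           genes_de_only))
  )
  readr::write_tsv(manifest, p("manifest.tsv"))
  invisible(out_dir)
}
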