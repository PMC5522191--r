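#' Candidate filter parameters
#'
#' Thresholds for the lncRNA candidate filter cascade.  A transcript is
#' retained only if its spliced length is strictly greater than `min_length`,
#' it has at least `min_exons` exons, its mean per-base fragment coverage is
#' at least `min_coverage`, and its FPKM passes `min_fpkm` under `fpkm_rule`
#' (`"max"`: expressed at `min_fpkm` in at least one sample; `"all"`: in
#' every sample).
#'
#' @param min_length Minimum spliced length in bp (strict `>`). Default 200,
#'   the conventional lncRNA length cutoff.
#' @param min_exons Minimum exon count (`>=`). Default 2, excluding
#'   single-exon assembly artefacts.
#' @param min_coverage Minimum mean per-base fragment coverage (`>=`).
#'   Default 3 reads.
#' @param min_fpkm Minimum FPKM (`>=`). Default 0.1.
#' @param fpkm_rule How the FPKM threshold is applied across samples.
#' @return A list of class `lnc_filter_params`.
#' @export
filter_params <- function(min_length = 200, min_exons = 2, min_coverage = 3,
                          min_fpkm = 0.1, fpkm_rule = c("max", "all")) {
  fpkm_rule <- match.arg(fpkm_rule)
  stopifnot(min_length > 0, min_exons > 0, min_coverage > 0, min_fpkm > 0)
  structure(list(min_length = min_length, min_exons = min_exons,
                 min_coverage = min_coverage, min_fpkm = min_fpkm,
                 fpkm_rule = fpkm_rule),
            class = "lnc_filter_params")
}

#' Apply the lncRNA candidate filter cascade
#'
#' Evaluates the four retention rules (length, exon count, read coverage,
#' FPKM) on every transcript.  Each rejected transcript is attributed to the
#' first rule it fails, in cascade order, so the per-rule tally sums to the
#' number of rejections.
#'
#' @param transcripts Transcript tibble (see [read_gtf()]); must carry
#'   `spliced_length`, `n_exons` and `fragment_coverage`.
#' @param expression Long expression tibble with columns `feature_id`,
#'   `sample_id`, `fpkm`.  Every transcript must have at least one row.
#' @param params A [filter_params()] object.
#' @return The transcript tibble with two added columns: `pass` (logical)
#'   and `fail_rule` (`"length"`, `"exons"`, `"coverage"`, `"fpkm"`, or `NA`
#'   for retained transcripts).  Attribute `tally` is a tibble of rejection
#'   counts per rule.
#' @export
filter_candidates <- function(transcripts, expression,
                              params = filter_params()) {
  .assert_cols(transcripts,
               c("transcript_id", "spliced_length", "n_exons",
                 "fragment_coverage"), "transcripts")
  .assert_cols(expression, c("feature_id", "sample_id", "fpkm"), "expression")
  no_expr <- setdiff(transcripts$transcript_id, expression$feature_id)
  if (length(no_expr) > 0) {
    abort(sprintf("transcript(s) without expression rows: %s",
                  paste(no_expr, collapse = ", ")))
  }
  agg <- if (params$fpkm_rule == "max") max else min
  fpkm_stat <- expression |>
    group_by(feature_id = .data$feature_id) |>
    summarise(fpkm_stat = agg(.data$fpkm), .groups = "drop")
  out <- transcripts |>
    left_join(fpkm_stat, by = c(transcript_id = "feature_id")) |>
    mutate(
      fail_rule = dplyr::case_when(
        .data$spliced_length <= params$min_length ~ "length",
        .data$n_exons < params$min_exons ~ "exons",
        .data$fragment_coverage < params$min_coverage ~ "coverage",
        .data$fpkm_stat < params$min_fpkm ~ "fpkm",
        TRUE ~ NA_character_
      ),
      pass = is.na(.data$fail_rule)
    ) |>
    select(-"fpkm_stat")
  tally <- tibble(rule = c("length", "exons", "coverage", "fpkm")) |>
    left_join(count(filter(out, !out$pass), .data$fail_rule),
              by = c(rule = "fail_rule")) |>
    mutate(n = tidyr::replace_na(.data$n, 0L))
  attr(out, "tally") <- tally
  out
}

#' Intersect four coding-potential verdicts
#'
#' A transcript is a lncRNA candidate if and only if all four classifiers
#' call it noncoding (the intersection of the four noncoding sets).
#'
#' @param calls Wide verdict tibble from [read_coding_calls()]
#'   (`transcript_id` plus one verdict column per tool).
#' @return The input with added columns `n_noncoding`, `noncoding_tools`
#'   (`"+"`-joined names of the tools calling noncoding) and `is_candidate`.
#' @seealso [venn_counts()] for the Venn-cell tally.
#' @export
intersect_coding_calls <- function(calls) {
  tools <- setdiff(names(calls), "transcript_id")
  if (length(tools) < 2) abort("`calls` must carry at least two tool columns")
  nc <- as.matrix(calls[tools]) == "noncoding"
  calls |>
    mutate(
      n_noncoding = rowSums(nc),
      noncoding_tools = apply(nc, 1, function(r) paste(tools[r], collapse = "+")),
      is_candidate = .data$n_noncoding == length(tools)
    )
}

#' Venn cell counts for the coding-potential intersection
#'
#' Counts transcripts in each of the 2^k - 1 nonempty cells of the Venn
#' diagram over the tools' noncoding sets (a transcript's cell is the exact
#' set of tools that called it noncoding); cells with no transcript are
#' reported with a zero count.
#'
#' @inheritParams intersect_coding_calls
#' @return A tibble with `cell` (e.g. `"CPC+CNCI"`), `n_tools`, `n`.
#' @export
venn_counts <- function(calls) {
  tools <- setdiff(names(calls), "transcript_id")
  res <- intersect_coding_calls(calls)
  subsets <- unlist(lapply(seq_along(tools), function(k) {
    combn(tools, k, paste, collapse = "+", simplify = FALSE)
  }))
  tibble(cell = unlist(subsets)) |>
    mutate(n_tools = stringr::str_count(.data$cell, stringr::fixed("+")) + 1L) |>
    left_join(count(filter(res, res$n_noncoding > 0), .data$noncoding_tools),
              by = c(cell = "noncoding_tools")) |>
    mutate(n = tidyr::replace_na(.data$n, 0L))
}

#' Classify lncRNA candidates by position relative to annotated genes
#'
#' Assigns each candidate one of four positional categories by precedence:
#' \enumerate{
#'   \item \strong{antisense} — at least one candidate exon overlaps an exon
#'     of a gene on the opposite strand;
#'   \item \strong{sense} — exonic overlap with a gene on the same strand;
#'   \item \strong{intronic} — the candidate lies entirely within a single
#'     intron of a gene (either strand, no exonic overlap);
#'   \item \strong{lincRNA} — no overlap with any gene body (intergenic).
#' }
#' When several genes satisfy the winning rule the nearest gene by midpoint
#' distance is reported, with ties broken by lexicographic `gene_id`.
#' Candidates on chromosomes absent from the annotation are classified
#' lincRNA with a warning.
#'
#' @param candidates Transcript tibble of lncRNA candidates.
#' @param genes Gene tibble (see [read_gtf()]); exon-union models.
#' @return A tibble `transcript_id`, `category` (factor with levels
#'   lincRNA, antisense, intronic, sense), `nearest_gene_id` (`NA` iff no
#'   gene lies on the candidate's chromosome).
#' @export
classify_lncrnas <- function(candidates, genes) {
  .assert_cols(candidates, c("transcript_id", "chrom", "strand", "start",
                             "end", "exons"), "candidates")
  .assert_cols(genes, c("gene_id", "chrom", "strand", "start", "end",
                        "exons"), "genes")
  lvls <- c("lincRNA", "antisense", "intronic", "sense")
  if (nrow(candidates) == 0) {
    return(tibble(transcript_id = character(),
                  category = factor(character(), levels = lvls),
                  nearest_gene_id = character()))
  }
  orphan <- setdiff(candidates$chrom, genes$chrom)
  if (length(orphan) > 0) {
    warn(sprintf("chromosome(s) absent from the annotation: %s; transcripts there classified lincRNA",
                 paste(orphan, collapse = ", ")))
  }

  t_ex <- candidates |>
    select("transcript_id", "chrom", "strand", "exons") |>
    tidyr::unnest("exons")
  g_ex <- genes |>
    select("gene_id", "chrom", g_strand = "strand", "exons") |>
    tidyr::unnest("exons")
  g_introns <- genes |>
    mutate(introns = map(.data$exons, function(e) {
      if (nrow(e) < 2) tibble(start = integer(), end = integer())
      else tibble(start = e$end[-nrow(e)], end = e$start[-1])
    })) |>
    select("gene_id", "chrom", "introns") |>
    tidyr::unnest("introns")

  # exon-exon overlaps, strand-blind; strand comparison decides the category
  ex_hits <- .overlap_pairs(t_ex, g_ex)
  ex_pairs <- if (nrow(ex_hits) == 0) {
    tibble(transcript_id = character(), gene_id = character(),
           antisense = logical())
  } else {
    ex_hits |>
      mutate(antisense = .data$strand != .data$g_strand) |>
      group_by(.data$transcript_id, .data$gene_id) |>
      summarise(antisense = any(.data$antisense), .groups = "drop")
  }

  # candidate envelope fully inside a single intron
  env <- candidates |> select("transcript_id", "chrom", "start", "end")
  in_hits <- .overlap_pairs(env, g_introns, type = "within")
  intronic_pairs <- distinct(in_hits, .data$transcript_id, .data$gene_id)

  pick_nearest <- function(tid, gids) {
    tr <- candidates[match(tid, candidates$transcript_id), ]
    g <- genes[match(gids, genes$gene_id), ]
    d <- abs((g$start + g$end) / 2 - (tr$start + tr$end) / 2)
    gids[order(d, gids)][1]
  }

  cat <- character(nrow(candidates))
  nearest <- rep(NA_character_, nrow(candidates))
  for (i in seq_len(nrow(candidates))) {
    tid <- candidates$transcript_id[i]
    ex_i <- ex_pairs[ex_pairs$transcript_id == tid, ]
    if (any(ex_i$antisense)) {
      cat[i] <- "antisense"
      nearest[i] <- pick_nearest(tid, ex_i$gene_id[ex_i$antisense])
    } else if (nrow(ex_i) > 0) {
      cat[i] <- "sense"
      nearest[i] <- pick_nearest(tid, ex_i$gene_id)
    } else {
      in_i <- intronic_pairs$gene_id[intronic_pairs$transcript_id == tid]
      if (length(in_i) > 0) {
        cat[i] <- "intronic"
        nearest[i] <- pick_nearest(tid, in_i)
      } else {
        cat[i] <- "lincRNA"
        same_chrom <- genes$gene_id[genes$chrom == candidates$chrom[i]]
        if (length(same_chrom) > 0) nearest[i] <- pick_nearest(tid, same_chrom)
      }
    }
  }
  tibble(transcript_id = candidates$transcript_id,
         category = factor(cat, levels = lvls),
         nearest_gene_id = nearest)
}

# overlap pairs between two half-open interval tables (columns chrom, start,
# end + carried metadata), via IRanges; returns the joined rows
.overlap_pairs <- function(a, b, type = "any") {
  if (nrow(a) == 0 || nrow(b) == 0) {
    out <- bind_cols(a[0, ], b[0, setdiff(names(b), names(a))])
    return(out)
  }
  gra <- GenomicRanges::GRanges(a$chrom,
                                IRanges::IRanges(a$start + 1L, a$end))
  grb <- GenomicRanges::GRanges(b$chrom,
                                IRanges::IRanges(b$start + 1L, b$end))
  suppressWarnings(
    hits <- GenomicRanges::findOverlaps(gra, grb, type = type,
                                        ignore.strand = TRUE)
  )
  bind_cols(
    a[S4Vectors::queryHits(hits), ],
    b[S4Vectors::subjectHits(hits), setdiff(names(b), names(a)), drop = FALSE]
  )
}

#' Summarize lncRNA positional categories
#'
#' Tallies classified lncRNA records per category and reports the share of
#' each category as a percentage rounded to two decimals.
#'
#' @param records Classification tibble from [classify_lncrnas()] (or any
#'   tibble with a `category` column).
#' @return A tibble `category`, `n`, `percent`, covering all four categories
#'   (zero-filled).  Attribute `total` carries the record count.
#' @export
summarize_categories <- function(records) {
  .assert_cols(records, "category", "records")
  if (nrow(records) == 0) abort("no records to summarize")
  lvls <- c("lincRNA", "antisense", "intronic", "sense")
  out <- tibble(category = factor(lvls, levels = lvls)) |>
    left_join(count(records, category = factor(.data$category, levels = lvls)),
              by = "category") |>
    mutate(n = tidyr::replace_na(.data$n, 0L),
           percent = round(100 * .data$n / sum(.data$n), 2))
  attr(out, "total") <- nrow(records)
  out
}
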