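#' Read transcript and gene models from a GTF file
#'
#' Parses a GTF file (1-based inclusive coordinates) into tidy transcript and
#' gene tables using 0-based half-open coordinates internally.  Exons are
#' grouped per transcript and sorted; gene models are reconstructed as the
#' union of the exons of their member transcripts (an exon-union envelope)
#' whenever the file carries `gene_id` attributes, whether or not explicit
#' `gene` feature rows are present.
#'
#' Cufflinks-style `cov` attributes on transcript rows, when present, are
#' carried through as `fragment_coverage` (mean reads per base over the
#' spliced transcript).
#'
#' @param path Path to a GTF file.
#' @return A list with two tibbles:
#'   \describe{
#'     \item{`transcripts`}{one row per transcript: `transcript_id`,
#'       `gene_id`, `chrom`, `strand`, `start`, `end` (0-based half-open
#'       envelope), `exons` (list-column of tibbles with `start`, `end`),
#'       `n_exons`, `spliced_length`, `fragment_coverage`.}
#'     \item{`genes`}{one row per gene: `gene_id`, `chrom`, `strand`,
#'       `start`, `end`, `exons` (merged exon union).}
#'   }
#' @export
read_gtf <- function(path) {
  if (!file.exists(path)) abort(sprintf("GTF file not found: %s", path))
  lines <- readr::read_lines(path)
  body <- !startsWith(lines, "#") & nzchar(lines)
  nfield <- stringr::str_count(lines[body], stringr::fixed("\t")) + 1L
  if (any(nfield != 9L)) {
    bad <- which(body)[which(nfield != 9L)[1]]
    abort(sprintf("malformed GTF line %d in %s: expected 9 tab-separated fields",
                  bad, path))
  }
  gr <- rtracklayer::import(path, format = "gtf")
  md <- S4Vectors::mcols(gr)
  if (!"transcript_id" %in% names(md)) {
    abort(sprintf("GTF file %s carries no transcript_id attributes", path))
  }
  ex <- gr[md$type == "exon"]
  if (length(ex) == 0) abort(sprintf("GTF file %s contains no exon records", path))

  exons <- tibble(
    transcript_id = S4Vectors::mcols(ex)$transcript_id,
    gene_id = as.character(S4Vectors::mcols(ex)$gene_id %||%
                             rep(NA_character_, length(ex))),
    chrom = as.character(GenomicRanges::seqnames(ex)),
    strand = as.character(GenomicRanges::strand(ex)),
    start = GenomicRanges::start(ex) - 1L,
    end = GenomicRanges::end(ex)
  ) |>
    arrange(.data$transcript_id, .data$start)

  transcripts <- exons |>
    tidyr::nest(exons = c("start", "end"),
                .by = c("transcript_id", "gene_id", "chrom", "strand")) |>
    mutate(
      start = map_int(.data$exons, ~ min(.x$start)),
      end = map_int(.data$exons, ~ max(.x$end)),
      n_exons = map_int(.data$exons, nrow),
      spliced_length = map_int(.data$exons, ~ sum(.x$end - .x$start))
    ) |>
    select("transcript_id", "gene_id", "chrom", "strand", "start", "end",
           "exons", "n_exons", "spliced_length")

  # coverage from transcript rows, if the dialect carries it
  cov <- rep(NA_real_, nrow(transcripts))
  tr_rows <- gr[md$type == "transcript"]
  if (length(tr_rows) > 0) {
    trm <- S4Vectors::mcols(tr_rows)
    if ("cov" %in% names(trm)) {
      cov_map <- setNames(suppressWarnings(as.numeric(trm$cov)), trm$transcript_id)
      cov <- unname(cov_map[transcripts$transcript_id])
    }
    # declared transcript envelopes must contain their exons
    decl <- tibble(
      transcript_id = trm$transcript_id,
      d_start = GenomicRanges::start(tr_rows) - 1L,
      d_end = GenomicRanges::end(tr_rows)
    )
    chk <- inner_join(transcripts, decl, by = "transcript_id") |>
      filter(.data$start < .data$d_start | .data$end > .data$d_end)
    if (nrow(chk) > 0) {
      abort(sprintf("exon outside declared transcript bounds for: %s",
                    paste(chk$transcript_id, collapse = ", ")))
    }
  }
  transcripts$fragment_coverage <- cov

  genes <- .genes_from_exons(exons)
  list(transcripts = transcripts, genes = genes)
}

.genes_from_exons <- function(exons) {
  ex <- exons |> filter(!is.na(.data$gene_id))
  if (nrow(ex) == 0) {
    return(tibble(gene_id = character(), chrom = character(),
                  strand = character(), start = integer(), end = integer(),
                  exons = list()))
  }
  ex |>
    group_by(.data$gene_id) |>
    summarise(
      chrom = first(.data$chrom),
      strand = first(.data$strand),
      exons = list(.merge_intervals(.data$start, .data$end)),
      .groups = "drop"
    ) |>
    mutate(
      start = map_int(.data$exons, ~ min(.x$start)),
      end = map_int(.data$exons, ~ max(.x$end))
    ) |>
    select("gene_id", "chrom", "strand", "start", "end", "exons")
}

# sorted union of possibly-overlapping half-open intervals
.merge_intervals <- function(start, end) {
  ir <- IRanges::reduce(IRanges::IRanges(start = start + 1L, end = end))
  tibble(start = IRanges::start(ir) - 1L, end = IRanges::end(ir))
}

#' Write transcript models to a GTF file
#'
#' Emits one `transcript` row and its `exon` rows per transcript, converting
#' the internal 0-based half-open coordinates back to the 1-based inclusive
#' GTF convention.  `fragment_coverage`, when present, is written as a
#' Cufflinks-style `cov` attribute so that [read_gtf()] round-trips it.
#'
#' @param transcripts Transcript tibble as returned by [read_gtf()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(transcripts, path) {
  .assert_cols(transcripts, c("transcript_id", "chrom", "strand", "exons"),
               "transcripts")
  rows <- pmap(transcripts, function(transcript_id, gene_id, chrom, strand,
                                     start, end, exons, fragment_coverage = NA,
                                     ...) {
    attr_tr <- sprintf('gene_id "%s"; transcript_id "%s";',
                       if (is.na(gene_id)) transcript_id else gene_id,
                       transcript_id)
    if (!is.na(fragment_coverage)) {
      attr_tr <- paste0(attr_tr, sprintf(' cov "%s";',
                                         format(fragment_coverage, digits = 10)))
    }
    tr <- sprintf("%s\tlncqtl\ttranscript\t%d\t%d\t.\t%s\t.\t%s",
                  chrom, start + 1L, end, strand, attr_tr)
    exl <- sprintf("%s\tlncqtl\texon\t%d\t%d\t.\t%s\t.\t%s",
                   chrom, exons$start + 1L, exons$end, strand,
                   sprintf('gene_id "%s"; transcript_id "%s";',
                           if (is.na(gene_id)) transcript_id else gene_id,
                           transcript_id))
    c(tr, exl)
  })
  readr::write_lines(unlist(rows), path)
  invisible(path)
}

#' Read a QTL interval table
#'
#' Reads a tab-separated table of quantitative trait locus records in the
#' Animal-QTLdb-like dialect (columns `QTL_ID`, `Chrome`/`Chromosome`,
#' `Trait`, `Name`, `Start`, `End`; synonyms matched case-insensitively,
#' order free).  Printed coordinates are 1-based inclusive and are kept as
#' printed in `start`/`end`; the equivalent 0-based half-open interval is
#' exposed as `start0`/`end0` for overlap computations.
#'
#' @param path Path to the TSV file.
#' @return A tibble with columns `qtl_id`, `chrom`, `trait`, `symbol`,
#'   `start`, `end`, `start0`, `end0`, one row per non-header line.
#' @export
read_qtl_table <- function(path) {
  if (!file.exists(path)) abort(sprintf("QTL table not found: %s", path))
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  synonyms <- list(
    qtl_id = c("qtl_id", "qtlid", "id"),
    chrom = c("chrome", "chromosome", "chrom", "chr"),
    trait = c("trait", "trait_name", "trait name"),
    symbol = c("name", "symbol"),
    start = "start",
    end = "end"
  )
  lower <- tolower(names(raw))
  idx <- map_int(synonyms, function(alts) {
    hit <- which(lower %in% alts)
    if (length(hit) == 0) NA_integer_ else hit[1]
  })
  if (any(is.na(idx))) {
    abort(sprintf("QTL table %s lacks column(s): %s", path,
                  paste(names(synonyms)[is.na(idx)], collapse = ", ")))
  }
  extra <- setdiff(seq_along(raw), idx)
  if (length(extra) > 0) {
    warn(sprintf("ignoring unknown column(s) in %s: %s", path,
                 paste(names(raw)[extra], collapse = ", ")))
  }
  qtl <- tibble(
    qtl_id = as.integer(raw[[idx[["qtl_id"]]]]),
    chrom = raw[[idx[["chrom"]]]],
    trait = raw[[idx[["trait"]]]],
    symbol = raw[[idx[["symbol"]]]],
    start = as.numeric(raw[[idx[["start"]]]]),
    end = as.numeric(raw[[idx[["end"]]]])
  )
  if (any(qtl$start >= qtl$end)) {
    bad <- qtl$qtl_id[qtl$start >= qtl$end]
    abort(sprintf("QTL region(s) with Start >= End: %s",
                  paste(bad, collapse = ", ")))
  }
  if (anyDuplicated(qtl$qtl_id)) {
    dup <- unique(qtl$qtl_id[duplicated(qtl$qtl_id)])
    abort(sprintf("duplicate QTL_ID(s): %s", paste(dup, collapse = ", ")))
  }
  qtl |> mutate(start0 = .data$start - 1, end0 = .data$end)
}

#' Read coding-potential verdicts from four classifier output tables
#'
#' Each classifier (by default CPC, CNCI, CPAT and Pfam) contributes a
#' two-column TSV (`transcript_id`, `verdict` with values `coding` or
#' `noncoding`).  Only transcripts present in all four files receive a call
#' set; transcripts missing from any file are unclassifiable and are
#' reported in the `missing` attribute rather than silently kept.
#'
#' @param paths Named character vector of four file paths; names are the
#'   tool names.
#' @return A tibble with `transcript_id` and one verdict column per tool.
#'   Attribute `missing` holds a tibble (`transcript_id`, `missing_from`) of
#'   transcripts absent from at least one file.
#' @export
read_coding_calls <- function(paths) {
  if (is.null(names(paths)) || any(!nzchar(names(paths)))) {
    abort("`paths` must be a named vector; names are the classifier names")
  }
  tools <- names(paths)
  tabs <- purrr::imap(paths, function(p, tool) {
    if (!file.exists(p)) abort(sprintf("coding-call file not found: %s", p))
    tb <- readr::read_tsv(p, col_types = "cc", progress = FALSE)
    names(tb) <- c("transcript_id", "verdict")
    bad <- setdiff(unique(tb$verdict), c("coding", "noncoding"))
    if (length(bad) > 0) {
      abort(sprintf("invalid verdict(s) in %s: %s", p,
                    paste(bad, collapse = ", ")))
    }
    tb
  })
  all_ids <- sort(unique(unlist(map(tabs, "transcript_id"))))
  wide <- tibble(transcript_id = all_ids)
  for (tool in tools) {
    m <- setNames(tabs[[tool]]$verdict, tabs[[tool]]$transcript_id)
    wide[[tool]] <- unname(m[wide$transcript_id])
  }
  missing <- wide |>
    tidyr::pivot_longer(-"transcript_id", names_to = "tool",
                        values_to = "verdict") |>
    filter(is.na(.data$verdict)) |>
    group_by(.data$transcript_id) |>
    summarise(missing_from = paste(.data$tool, collapse = ","),
              .groups = "drop")
  if (nrow(missing) > 0) {
    inform(sprintf(
      "%d transcript(s) missing from at least one coding-call file; excluded from candidacy",
      nrow(missing)))
  }
  complete <- wide |> filter(!.data$transcript_id %in% missing$transcript_id)
  attr(complete, "missing") <- missing
  complete
}

#' Average per-sample sequencing library metrics
#'
#' Computes the arithmetic mean of each library metric across samples, in the
#' style of the summary column of a sequencing-run QC table.  Metrics whose
#' name contains a percent sign are rounded to two decimals; all other
#' metrics are treated as counts and rounded to the nearest integer.
#'
#' @param metrics A tibble in long form (`sample_id`, `metric`, `value`) or
#'   wide form (`sample_id` plus one numeric column per metric).
#' @return A tibble with columns `metric` and `average`.
#' @export
summarize_libraries <- function(metrics) {
  if (all(c("sample_id", "metric", "value") %in% names(metrics))) {
    long <- metrics |> select("sample_id", "metric", "value")
    keys <- long |>
      group_by(.data$sample_id) |>
      summarise(k = paste(sort(.data$metric), collapse = "|"), .groups = "drop")
    if (length(unique(keys$k)) > 1) {
      abort("samples carry inconsistent metric keys")
    }
  } else {
    .assert_cols(metrics, "sample_id", "metrics")
    long <- metrics |>
      tidyr::pivot_longer(-"sample_id", names_to = "metric",
                          values_to = "value")
  }
  if (nrow(long) == 0) abort("no metrics supplied")
  long |>
    group_by(.data$metric) |>
    summarise(average = mean(.data$value), .groups = "drop") |>
    mutate(average = if_else(grepl("%", .data$metric),
                             round(.data$average, 2),
                             round(.data$average)))
}
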