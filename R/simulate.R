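#' Simulation configuration
#'
#' Parameters for the deterministic synthetic-data generator.  Defaults
#' describe a compact two-breed, single-library-per-condition design:
#' a small multi-chromosome genome with non-overlapping protein-coding
#' genes, lncRNAs planted to satisfy each positional category definition,
#' a log-normal FPKM distribution with planted two-log2-unit fold changes
#' on 10% of features, Poisson fragment counts at a per-library depth of
#' one million fragments, four coding-potential classifiers with
#' configurable error rates, and trait-linked QTL intervals.
#'
#' @param seed Integer seed; the same seed yields byte-identical outputs.
#' @param n_chromosomes,chrom_length Genome shape (chromosome count, length
#'   in bp).
#' @param n_genes Number of protein-coding genes, placed without overlap.
#' @param n_lncrna Named integer vector: planted lncRNAs per positional
#'   category (`lincRNA`, `antisense`, `intronic`, `sense`).
#' @param n_decoys Transcripts built to fail the candidate filter cascade,
#'   cycling over the four failure modes (short, single-exon, low coverage,
#'   low FPKM).
#' @param de_fraction Fraction of non-decoy features given a planted fold
#'   change.
#' @param planted_log2fc Absolute planted effect, in log2 units; sign drawn
#'   at random per DE feature.
#' @param fpkm_meanlog,fpkm_sdlog Log-normal baseline FPKM distribution
#'   (median `exp(fpkm_meanlog)` FPKM).
#' @param noise_sd Per-sample multiplicative expression noise, in log2
#'   units, around the planted mean.
#' @param library_size Total mapped fragments per library.
#' @param dispersion Negative-binomial dispersion for fragment counts;
#'   `NULL` (default) draws Poisson counts, under which the replicate-free
#'   exact test is correctly calibrated.
#' @param tools Names of the four coding-potential classifiers.
#' @param false_coding,false_noncoding Per-tool error rates (recycled):
#'   probability a truly noncoding transcript is called coding, and vice
#'   versa.
#' @param n_qtl,qtl_span Number of QTL intervals and the (min, max) span
#'   range in bp.
#' @param traits Trait names assigned to QTLs round-robin.
#' @param n_terms,term_size Number of annotation terms and the (min, max)
#'   range of genes per term.
#' @return A list of class `lnc_sim_config`.
#' @export
sim_config <- function(seed = 1,
                       n_chromosomes = 3, chrom_length = 5e6,
                       n_genes = 60,
                       n_lncrna = c(lincRNA = 40, antisense = 10,
                                    intronic = 10, sense = 20),
                       n_decoys = 16,
                       de_fraction = 0.1, planted_log2fc = 2,
                       fpkm_meanlog = log(40), fpkm_sdlog = 1,
                       noise_sd = 0.15,
                       library_size = 1e6, dispersion = NULL,
                       tools = c("CPC", "CNCI", "CPAT", "Pfam"),
                       false_coding = 0.05, false_noncoding = 0.05,
                       n_qtl = 30, qtl_span = c(5e4, 5e5),
                       traits = c("Average backfat thickness",
                                  "Abdominal fat weight",
                                  "Adipocyte diameter",
                                  "Abdominal fat percentage",
                                  "Arachidonic acid content",
                                  "Loin fat percentage"),
                       n_terms = 25, term_size = c(5, 25)) {
  stopifnot(
    de_fraction >= 0, de_fraction <= 1,
    all(false_coding >= 0 & false_coding <= 1),
    all(false_noncoding >= 0 & false_noncoding <= 1),
    chrom_length > 0, library_size > 0, length(tools) >= 2,
    qtl_span[1] > 0, qtl_span[2] >= qtl_span[1], qtl_span[2] < chrom_length
  )
  if (!all(c("lincRNA", "antisense", "intronic", "sense") %in%
           names(n_lncrna))) {
    abort("`n_lncrna` must name all four categories")
  }
  structure(
    list(seed = seed, n_chromosomes = n_chromosomes,
         chrom_length = chrom_length, n_genes = n_genes,
         n_lncrna = n_lncrna, n_decoys = n_decoys,
         de_fraction = de_fraction, planted_log2fc = planted_log2fc,
         fpkm_meanlog = fpkm_meanlog, fpkm_sdlog = fpkm_sdlog,
         noise_sd = noise_sd, library_size = library_size,
         dispersion = dispersion, tools = tools,
         false_coding = setNames(rep_len(false_coding, length(tools)), tools),
         false_noncoding = setNames(rep_len(false_noncoding, length(tools)),
                                    tools),
         n_qtl = n_qtl, qtl_span = qtl_span, traits = traits,
         n_terms = n_terms, term_size = term_size),
    class = "lnc_sim_config")
}

#' Simulate a two-condition expression table with planted fold changes
#'
#' Draws baseline FPKM values log-normally, plants a `planted_log2fc`-unit
#' effect (random sign) on a `de_fraction` of features in the numerator
#' condition, adds per-sample log-normal noise, and derives fragment counts
#' as Poisson (or negative-binomial) draws with mean
#' `FPKM * length * library_size / 1e9`.
#'
#' @param feature_ids Character vector of feature ids.
#' @param lengths Feature lengths in bp (recycled).
#' @param de_fraction,planted_log2fc,fpkm_meanlog,fpkm_sdlog,noise_sd,library_size,dispersion
#'   See [sim_config()].
#' @param baseline_fpkm Optional fixed baseline per feature, overriding the
#'   log-normal draw where not `NA`.
#' @param de_eligible Logical vector: features eligible for DE planting
#'   (default all).
#' @return A list: `expression` (long tibble `feature_id`, `sample_id`,
#'   `fpkm`, `fragments` for samples `L1`/`D1`), `library_sizes`, `groups`
#'   (`L1` is `luchuan`, `D1` is `duroc`), and `truth` (`feature_id`,
#'   `is_de`, `true_log2fc`, `true_status`).
#' @export
simulate_expression <- function(feature_ids, lengths = 1000,
                                de_fraction = 0.1, planted_log2fc = 2,
                                fpkm_meanlog = log(40), fpkm_sdlog = 1,
                                noise_sd = 0.15, library_size = 1e6,
                                dispersion = NULL, baseline_fpkm = NULL,
                                de_eligible = NULL) {
  nf <- length(feature_ids)
  lengths <- rep_len(lengths, nf)
  de_eligible <- de_eligible %||% rep(TRUE, nf)
  base <- rlnorm(nf, fpkm_meanlog, fpkm_sdlog)
  if (!is.null(baseline_fpkm)) {
    fixed <- !is.na(baseline_fpkm)
    base[fixed] <- baseline_fpkm[fixed]
  }
  n_de <- round(de_fraction * sum(de_eligible))
  de_idx <- sample(which(de_eligible), n_de)
  lfc <- numeric(nf)
  if (n_de > 0) {
    lfc[de_idx] <- planted_log2fc * sample(c(-1, 1), n_de, replace = TRUE)
  }
  draw_counts <- function(mu) {
    if (is.null(dispersion)) rpois(nf, mu)
    else rnbinom(nf, size = 1 / dispersion, mu = mu)
  }
  sim_sample <- function(lfc_applied) {
    fpkm <- base * 2^(lfc_applied + rnorm(nf, 0, noise_sd))
    frags <- draw_counts(fpkm * lengths * library_size / 1e9)
    list(fpkm = fpkm, fragments = frags)
  }
  luchuan <- sim_sample(lfc)
  duroc <- sim_sample(0)
  expression <- bind_rows(
    tibble(feature_id = feature_ids, sample_id = "L1",
           fpkm = luchuan$fpkm, fragments = luchuan$fragments),
    tibble(feature_id = feature_ids, sample_id = "D1",
           fpkm = duroc$fpkm, fragments = duroc$fragments)
  )
  list(
    expression = expression,
    library_sizes = tibble(sample_id = c("L1", "D1"),
                           library_size = library_size),
    groups = tibble(sample_id = c("L1", "D1"),
                    group = c("luchuan", "duroc")),
    truth = tibble(feature_id = feature_ids,
                   is_de = lfc != 0,
                   true_log2fc = lfc,
                   true_status = dplyr::case_when(lfc > 0 ~ "up",
                                                  lfc < 0 ~ "down",
                                                  TRUE ~ "ns"))
  )
}

# --- genome construction -----------------------------------------------------

.place_genes <- function(cfg) {
  chroms <- paste0("chr", rep_len(seq_len(cfg$n_chromosomes), cfg$n_genes))
  cursor <- setNames(rep(0, cfg$n_chromosomes),
                     paste0("chr", seq_len(cfg$n_chromosomes)))
  rows <- vector("list", cfg$n_genes)
  for (i in seq_len(cfg$n_genes)) {
    chrom <- chroms[i]
    gap <- runif(1, 30000, 60000)
    n_ex <- sample(3:7, 1)
    ex_len <- sample(150:400, n_ex, replace = TRUE)
    in_len <- if (n_ex > 1) sample(2000:8000, n_ex - 1, replace = TRUE)
              else integer()
    start <- floor(cursor[chrom] + gap)
    starts <- start + cumsum(c(0, head(ex_len, -1) + in_len))
    ends <- starts + ex_len
    if (max(ends) > cfg$chrom_length) {
      abort(sprintf("infeasible placement: gene %d exceeds chromosome %s",
                    i, chrom))
    }
    cursor[chrom] <- max(ends)
    rows[[i]] <- tibble(
      gene_id = sprintf("GENE%05d", i),
      chrom = chrom,
      strand = sample(c("+", "-"), 1),
      start = as.integer(starts[1]),
      end = as.integer(max(ends)),
      exons = list(tibble(start = as.integer(starts), end = as.integer(ends)))
    )
  }
  bind_rows(rows)
}

.intergenic_gaps <- function(genes, cfg, min_width = 5000, margin = 1000) {
  per_chrom <- split(genes[c("start", "end")], genes$chrom)
  gaps <- purrr::imap(per_chrom, function(b, ch) {
    b <- b[order(b$start), ]
    tibble(chrom = ch,
           start = c(0L, b$end + margin),
           end = c(b$start - margin, cfg$chrom_length))
  })
  bind_rows(gaps) |> filter(.data$end - .data$start >= min_width)
}

.make_exon_pair <- function(s1, e1, s2, e2) {
  tibble(start = as.integer(c(s1, s2)), end = as.integer(c(e1, e2)))
}

# one planted lncRNA of the requested category; returns exons + strand
.place_lncrna <- function(category, genes, gaps, cfg) {
  if (category %in% c("lincRNA", "decoy")) {
    g <- gaps[sample(nrow(gaps), 1), ]
    l1 <- sample(200:400, 1); intr <- sample(300:1500, 1)
    l2 <- sample(200:400, 1)
    span <- l1 + intr + l2
    s <- g$start + floor(runif(1, 0, max(1, g$end - g$start - span)))
    list(chrom = g$chrom, strand = sample(c("+", "-"), 1),
         exons = .make_exon_pair(s, s + l1, s + l1 + intr, s + l1 + intr + l2))
  } else if (category %in% c("antisense", "sense")) {
    gi <- sample(nrow(genes), 1)
    g <- genes[gi, ]
    ex <- g$exons[[1]]
    j <- sample(nrow(ex), 1)
    s1 <- ex$start[j] + sample(0:50, 1)           # overlaps gene exon j
    e1 <- s1 + 150 + sample(0:100, 1)
    s2 <- e1 + 300 + sample(0:500, 1)
    e2 <- s2 + 150 + sample(0:150, 1)
    strand <- if (category == "antisense") setdiff(c("+", "-"), g$strand)
              else g$strand
    list(chrom = g$chrom, strand = strand,
         exons = .make_exon_pair(s1, e1, s2, e2))
  } else if (category == "intronic") {
    repeat {
      gi <- sample(nrow(genes), 1)
      g <- genes[gi, ]
      ex <- g$exons[[1]]
      if (nrow(ex) < 2) next
      introns <- tibble(start = ex$end[-nrow(ex)], end = ex$start[-1])
      introns <- filter(introns, .data$end - .data$start >= 1500)
      if (nrow(introns) == 0) next
      intr <- introns[sample(nrow(introns), 1), ]
      s1 <- intr$start + 100
      break
    }
    list(chrom = g$chrom, strand = sample(c("+", "-"), 1),
         exons = .make_exon_pair(s1, s1 + 200, s1 + 500, s1 + 700))
  } else {
    abort(sprintf("unknown category: %s", category))
  }
}

# --- full dataset ------------------------------------------------------------

#' Generate a complete synthetic dataset with planted ground truth
#'
#' Builds, from one seeded generator, every input the pipeline consumes:
#' gene models, assembled lncRNA candidates planted to satisfy each
#' positional category under the classification definitions, filter-failing
#' decoy transcripts, a two-condition expression table with planted fold
#' changes, noisy verdicts from four coding-potential classifiers,
#' trait-linked QTL intervals, and a term-annotation map — together with
#' the planted truth needed for recovery tests.
#'
#' @param config A [sim_config()] object.
#' @return A list of class `lnc_sim` with elements `config`, `genes`,
#'   `transcripts` (lncRNAs, decoys and one mRNA per gene),
#'   `expression`, `library_sizes`, `groups`, `coding_calls`, `qtls`,
#'   `term_map`, and `truth` (list with `transcripts` and `qtl_members`
#'   tibbles).
#' @export
simulate_dataset <- function(config = sim_config()) {
  if (!inherits(config, "lnc_sim_config")) {
    abort("`config` must be created with sim_config()")
  }
  .with_seed(config$seed, .simulate_dataset_impl(config))
}

.simulate_dataset_impl <- function(cfg) {
  genes <- .place_genes(cfg)
  gaps <- .intergenic_gaps(genes, cfg)
  if (nrow(gaps) == 0) abort("infeasible placement: no intergenic room left")

  # planted lncRNAs
  cats <- rep(names(cfg$n_lncrna), cfg$n_lncrna)
  lnc_rows <- purrr::imap(cats, function(cat, i) {
    p <- .place_lncrna(cat, genes, gaps, cfg)
    tibble(transcript_id = sprintf("TCONS_%08d", i),
           gene_id = NA_character_, chrom = p$chrom, strand = p$strand,
           exons = list(p$exons), planted_category = cat,
           feature_type = "lncRNA")
  })

  # decoys engineered to fail one filter rule each, cycling over the modes
  modes <- rep_len(c("short", "single_exon", "low_coverage", "low_fpkm"),
                   cfg$n_decoys)
  decoy_rows <- purrr::imap(modes, function(mode, i) {
    p <- .place_lncrna("decoy", genes, gaps, cfg)
    ex <- p$exons
    if (mode == "short") {
      ex <- .make_exon_pair(ex$start[1], ex$start[1] + 80,
                            ex$start[2], ex$start[2] + 80)
    } else if (mode == "single_exon") {
      ex <- tibble(start = ex$start[1], end = ex$start[1] + 600L)
    }
    tibble(transcript_id = sprintf("DECOY_%04d", i),
           gene_id = NA_character_, chrom = p$chrom, strand = p$strand,
           exons = list(ex), planted_category = mode,
           feature_type = "decoy")
  })

  # one mRNA transcript per gene, inheriting the gene's exon structure
  mrna_rows <- pmap(genes, function(gene_id, chrom, strand, start, end,
                                    exons) {
    tibble(transcript_id = sub("GENE", "MRNA", gene_id), gene_id = gene_id,
           chrom = chrom, strand = strand, exons = list(exons),
           planted_category = NA_character_, feature_type = "mRNA")
  })

  transcripts <- bind_rows(bind_rows(lnc_rows), bind_rows(decoy_rows),
                           bind_rows(mrna_rows)) |>
    mutate(
      start = map_int(.data$exons, ~ min(.x$start)),
      end = map_int(.data$exons, ~ max(.x$end)),
      n_exons = map_int(.data$exons, nrow),
      spliced_length = map_int(.data$exons, ~ sum(.x$end - .x$start)),
      fragment_coverage = dplyr::case_when(
        .data$planted_category == "low_coverage" ~ 1,
        .data$feature_type == "mRNA" ~ round(runif(n(), 10, 80), 1),
        TRUE ~ round(runif(n(), 5, 50), 1)
      )
    )

  # expression with planted effects; low-FPKM decoys pinned below threshold
  baseline <- ifelse(transcripts$planted_category %in% "low_fpkm", 0.02,
                     NA_real_)
  expr <- simulate_expression(
    feature_ids = transcripts$transcript_id,
    lengths = transcripts$spliced_length,
    de_fraction = cfg$de_fraction, planted_log2fc = cfg$planted_log2fc,
    fpkm_meanlog = cfg$fpkm_meanlog, fpkm_sdlog = cfg$fpkm_sdlog,
    noise_sd = cfg$noise_sd, library_size = cfg$library_size,
    dispersion = cfg$dispersion, baseline_fpkm = baseline,
    de_eligible = transcripts$feature_type != "decoy"
  )

  # coding-potential verdicts with per-tool flips
  truly_coding <- transcripts$feature_type == "mRNA"
  calls <- tibble(transcript_id = transcripts$transcript_id)
  for (tool in cfg$tools) {
    flip <- runif(nrow(transcripts)) <
      ifelse(truly_coding, cfg$false_noncoding[tool], cfg$false_coding[tool])
    verdict <- ifelse(xor(truly_coding, flip), "coding", "noncoding")
    calls[[tool]] <- verdict
  }

  # QTL intervals, traits round-robin
  spans <- floor(runif(cfg$n_qtl, cfg$qtl_span[1], cfg$qtl_span[2]))
  qchrom <- paste0("chr", sample(cfg$n_chromosomes, cfg$n_qtl, replace = TRUE))
  qstart0 <- floor(runif(cfg$n_qtl, 0, cfg$chrom_length - spans))
  qtls <- tibble(
    qtl_id = 1000L + seq_len(cfg$n_qtl),
    chrom = qchrom,
    trait = rep_len(cfg$traits, cfg$n_qtl),
    symbol = sprintf("QTLSYM%03d", rep_len(seq_along(cfg$traits), cfg$n_qtl)),
    start = qstart0 + 1,
    end = qstart0 + spans,
    start0 = qstart0,
    end0 = qstart0 + spans
  )

  # term annotations over genes
  term_map <- bind_rows(lapply(seq_len(cfg$n_terms), function(t) {
    size <- sample(seq(cfg$term_size[1], cfg$term_size[2]), 1)
    tibble(term_id = sprintf("TERM%03d", t),
           term_name = sprintf("synthetic process %03d", t),
           gene_id = sort(sample(genes$gene_id, min(size, nrow(genes)))))
  }))

  # planted truth: QTL membership by direct interval arithmetic
  feats <- bind_rows(
    transcripts |>
      filter(.data$feature_type == "lncRNA") |>
      select(feature_id = "transcript_id", "chrom", "start", "end") |>
      mutate(feature_type = "lncRNA"),
    genes |>
      select(feature_id = "gene_id", "chrom", "start", "end") |>
      mutate(feature_type = "gene")
  )
  qtl_members <- inner_join(feats,
                            select(qtls, "qtl_id", "chrom", "start0", "end0"),
                            by = "chrom", relationship = "many-to-many") |>
    filter(.data$start < .data$end0 & .data$start0 < .data$end) |>
    select("qtl_id", "feature_id", "feature_type") |>
    arrange(.data$qtl_id, .data$feature_id)

  truth_tr <- transcripts |>
    select("transcript_id", "feature_type", "planted_category") |>
    mutate(truly_coding = .data$feature_type == "mRNA") |>
    left_join(rename(expr$truth, transcript_id = "feature_id"),
              by = "transcript_id")

  structure(
    list(config = cfg, genes = genes,
         transcripts = select(transcripts, -"planted_category",
                              -"feature_type"),
         expression = expr$expression, library_sizes = expr$library_sizes,
         groups = expr$groups, coding_calls = calls, qtls = qtls,
         term_map = term_map,
         truth = list(transcripts = truth_tr, qtl_members = qtl_members)),
    class = "lnc_sim")
}

#' Write a simulated dataset to disk as plain-text pipeline inputs
#'
#' Emits the standard file layout consumed by [run_pipeline()]:
#' `annotation.gtf` (gene models via their mRNA transcripts),
#' `transcripts.gtf` (assembled lncRNA candidates and decoys, with `cov`
#' attributes), `expression.tsv`, `library_sizes.tsv`, `groups.tsv`, one
#' `coding_calls_<TOOL>.tsv` per classifier, `qtl_regions.tsv` (1-based
#' printed coordinates), `term_map.tsv`, and the planted truth tables
#' `truth_transcripts.tsv` / `truth_qtl_members.tsv`.
#'
#' @param sim A [simulate_dataset()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_sim_dataset <- function(sim, dir) {
  stopifnot(inherits(sim, "lnc_sim"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(dir, f)

  is_mrna <- startsWith(sim$transcripts$transcript_id, "MRNA")
  write_gtf(sim$transcripts[is_mrna, ], p("annotation.gtf"))
  write_gtf(sim$transcripts[!is_mrna, ], p("transcripts.gtf"))
  readr::write_tsv(sim$expression, p("expression.tsv"))
  readr::write_tsv(sim$library_sizes, p("library_sizes.tsv"))
  readr::write_tsv(sim$groups, p("groups.tsv"))
  for (tool in setdiff(names(sim$coding_calls), "transcript_id")) {
    readr::write_tsv(
      tibble(transcript_id = sim$coding_calls$transcript_id,
             verdict = sim$coding_calls[[tool]]),
      p(sprintf("coding_calls_%s.tsv", tool)))
  }
  readr::write_tsv(
    sim$qtls |>
      select(QTL_ID = "qtl_id", Chrome = "chrom", Trait = "trait",
             Name = "symbol", Start = "start", End = "end"),
    p("qtl_regions.tsv"))
  readr::write_tsv(sim$term_map, p("term_map.tsv"))
  readr::write_tsv(sim$truth$transcripts, p("truth_transcripts.tsv"))
  readr::write_tsv(sim$truth$qtl_members, p("truth_qtl_members.tsv"))
  invisible(dir)
}
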