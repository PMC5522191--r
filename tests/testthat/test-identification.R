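test_that("the filter cascade attributes each rejection to its first failing rule", {
  tr <- dplyr::bind_rows(
    make_transcript("short", exons = cbind(0L, 150L)),             # length
    make_transcript("monoex", exons = cbind(0L, 900L)),            # exons
    make_transcript("lowcov", exons = cbind(c(0L, 500L), c(300L, 900L)),
                    coverage = 1),                                 # coverage
    make_transcript("lowexp", exons = cbind(c(0L, 500L), c(300L, 900L))),
    make_transcript("ok1", exons = cbind(c(0L, 500L), c(300L, 900L))),
    make_transcript("ok2", exons = cbind(c(0L, 500L), c(300L, 900L)))
  )
  expr <- make_expression(tr$transcript_id, fpkm_l = 5, fpkm_d = 5)
  expr$fpkm[expr$feature_id == "lowexp"] <- 0.01                   # fpkm
  out <- filter_candidates(tr, expr)
  expect_equal(sum(out$pass), 2)
  expect_setequal(out$transcript_id[out$pass], c("ok1", "ok2"))
  expect_equal(out$fail_rule[match(c("short", "monoex", "lowcov", "lowexp"),
                                   out$transcript_id)],
               c("length", "exons", "coverage", "fpkm"))
  tally <- attr(out, "tally")
  expect_equal(tally$n, c(1L, 1L, 1L, 1L))
})

test_that("length and exon thresholds follow the documented conventions", {
  # exactly 200 bp fails the strict > 200 rule; 201 passes
  tr <- dplyr::bind_rows(
    make_transcript("edge200", exons = cbind(c(0L, 300L), c(100L, 400L))),
    make_transcript("edge201", exons = cbind(c(0L, 300L), c(100L, 401L)))
  )
  expr <- make_expression(tr$transcript_id, fpkm_l = 5, fpkm_d = 5)
  out <- filter_candidates(tr, expr)
  expect_equal(out$pass, c(FALSE, TRUE))
  # min_exons is >=: a 3-exon transcript passes the default
  tr3 <- make_transcript("triple",
                         exons = cbind(c(0L, 300L, 700L), c(100L, 400L, 800L)))
  out3 <- filter_candidates(tr3, make_expression("triple", fpkm_l = 5))
  expect_true(out3$pass)
  expect_error(
    filter_candidates(tr3, make_expression("other")),
    "without expression rows")
})

test_that("relaxing any filter threshold never shrinks the retained set", {
  set.seed(11)
  tr <- rand_transcripts(100)
  tr$fragment_coverage <- runif(100, 0, 10)
  expr <- make_expression(tr$transcript_id,
                          fpkm_l = runif(100, 0, 2), fpkm_d = runif(100, 0, 2))
  base <- filter_candidates(tr, expr)
  for (relaxed in list(filter_params(min_length = 100),
                       filter_params(min_exons = 1),
                       filter_params(min_coverage = 1),
                       filter_params(min_fpkm = 0.01))) {
    out <- filter_candidates(tr, expr, relaxed)
    expect_true(all(base$transcript_id[base$pass] %in%
                    out$transcript_id[out$pass]))
  }
})

test_that("candidates are the four-way noncoding intersection and Venn cells add up", {
  tools <- c("CPC", "CNCI", "CPAT", "Pfam")
  calls <- tibble::tibble(
    transcript_id = c("a", "b", "c"),
    CPC = c("noncoding", "noncoding", "coding"),
    CNCI = c("noncoding", "noncoding", "coding"),
    CPAT = c("noncoding", "coding", "coding"),
    Pfam = c("noncoding", "noncoding", "coding")
  )
  out <- intersect_coding_calls(calls)
  expect_equal(out$is_candidate, c(TRUE, FALSE, FALSE))
  expect_equal(out$noncoding_tools[2], "CPC+CNCI+Pfam")

  set.seed(21)
  big <- tibble::tibble(transcript_id = sprintf("t%03d", 1:200))
  for (tool in tools) {
    big[[tool]] <- ifelse(runif(200) < 0.05, "coding", "noncoding")
  }
  res <- intersect_coding_calls(big)
  # brute-force set arithmetic
  sets <- lapply(tools, function(tl) big$transcript_id[big[[tl]] == "noncoding"])
  names(sets) <- tools
  expect_setequal(res$transcript_id[res$is_candidate],
                  Reduce(intersect, sets))
  vc <- venn_counts(big)
  expect_equal(nrow(vc), 15)
  for (i in seq_len(nrow(vc))) {
    cell_tools <- strsplit(vc$cell[i], "+", fixed = TRUE)[[1]]
    inside <- Reduce(intersect, sets[cell_tools])
    outside <- unique(unlist(sets[setdiff(tools, cell_tools)]))
    expect_equal(vc$n[i], length(setdiff(inside, outside)))
  }
  # every transcript noncoding somewhere falls in exactly one cell
  expect_equal(sum(vc$n), sum(res$n_noncoding > 0))
})

test_that("positional categories follow the precedence definitions", {
  genes <- make_gene("gA", strand = "+",
                     exons = cbind(c(1000L, 5000L, 12000L),
                                   c(2000L, 6000L, 13000L)))
  # opposite-strand transcript overlapping an exon -> antisense
  anti <- make_transcript("anti", strand = "-",
                          exons = cbind(c(1800L, 2500L), c(2100L, 2700L)))
  # same-strand overlap -> sense
  sens <- make_transcript("sens", strand = "+",
                          exons = cbind(c(1800L, 2500L), c(2100L, 2700L)))
  # fully inside intron 2 (6000-12000), same strand, no exon overlap -> intronic
  intr <- make_transcript("intr", strand = "+",
                          exons = cbind(c(7000L, 8000L), c(7400L, 8400L)))
  # spanning an intron but poking outside the gene -> neither intronic nor exonic
  far <- make_transcript("far", strand = "+",
                         exons = cbind(c(20000L, 21000L), c(20400L, 21400L)))
  out <- classify_lncrnas(dplyr::bind_rows(anti, sens, intr, far), genes)
  expect_equal(as.character(out$category),
               c("antisense", "sense", "intronic", "lincRNA"))
  expect_equal(unique(out$nearest_gene_id), "gA")

  # empty chromosome -> lincRNA with a warning, nearest gene NA
  lost <- make_transcript("lost", chrom = "chrX",
                          exons = cbind(0L, 1000L))
  expect_warning(res <- classify_lncrnas(lost, genes), "absent")
  expect_equal(as.character(res$category), "lincRNA")
  expect_true(is.na(res$nearest_gene_id))
})

test_that("classification agrees with the quadratic all-pairs oracle", {
  set.seed(31)
  genes <- rand_genes(40)
  cand <- rand_transcripts(300)
  got <- suppressWarnings(classify_lncrnas(cand, genes))
  want <- suppressWarnings(oracle_classify(cand, genes))
  expect_equal(as.character(got$category), want$category)
  expect_equal(got$nearest_gene_id, want$nearest_gene_id)
})

test_that("category summaries report counts and two-decimal percentages", {
  counts <- c(lincRNA = 2403, antisense = 252, intronic = 216, sense = 1997)
  records <- tibble::tibble(category = rep(names(counts), counts))
  out <- summarize_categories(records)
  # independent arithmetic
  expect_equal(out$percent, round(100 * counts / sum(counts), 2),
               ignore_attr = TRUE)
  expect_equal(sum(out$n), sum(counts))
  expect_lt(abs(sum(out$percent) - 100), 0.05)

  one <- summarize_categories(tibble::tibble(category = rep("sense", 5)))
  expect_equal(one$percent[one$category == "sense"], 100)
  expect_error(summarize_categories(tibble::tibble(category = character())),
               "no records")
})
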