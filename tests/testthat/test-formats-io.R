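test_that("read_gtf converts 1-based inclusive exons to half-open internals", {
  path <- withr::local_tempfile(fileext = ".gtf")
  writeLines(c(
    'chr1\tsrc\ttranscript\t100\t400\t.\t+\t.\tgene_id "g1"; transcript_id "t1"; cov "4.5";',
    'chr1\tsrc\texon\t100\t200\t.\t+\t.\tgene_id "g1"; transcript_id "t1";',
    'chr1\tsrc\texon\t301\t400\t.\t+\t.\tgene_id "g1"; transcript_id "t1";'
  ), path)
  got <- read_gtf(path)
  tr <- got$transcripts
  expect_equal(nrow(tr), 1)
  expect_equal(tr$exons[[1]]$start, c(99L, 300L))
  expect_equal(tr$exons[[1]]$end, c(200L, 400L))
  expect_equal(tr$spliced_length, 201L)
  expect_equal(tr$fragment_coverage, 4.5)
  # single-exon transcripts are retained at read time (filtering is later)
  writeLines(
    'chr2\tsrc\texon\t10\t500\t.\t-\t.\tgene_id "g2"; transcript_id "t2";',
    path)
  got2 <- read_gtf(path)
  expect_equal(got2$transcripts$n_exons, 1L)
})

test_that("read_gtf rejects malformed lines and stray exons by line number", {
  path <- withr::local_tempfile(fileext = ".gtf")
  writeLines(c(
    'chr1\tsrc\texon\t100\t200\t.\t+\t.\tgene_id "g1"; transcript_id "t1";',
    "chr1\tsrc\texon\t100"
  ), path)
  expect_error(read_gtf(path), "line 2")
  writeLines(c(
    'chr1\tsrc\ttranscript\t100\t200\t.\t+\t.\tgene_id "g1"; transcript_id "t1";',
    'chr1\tsrc\texon\t100\t300\t.\t+\t.\tgene_id "g1"; transcript_id "t1";'
  ), path)
  expect_error(read_gtf(path), "outside declared transcript")
})

test_that("a synthetic 50-transcript file survives a write/read round trip", {
  set.seed(404)
  tr <- rand_transcripts(50)
  path <- withr::local_tempfile(fileext = ".gtf")
  write_gtf(tr, path)
  back <- read_gtf(path)$transcripts |> dplyr::arrange(transcript_id)
  orig <- dplyr::arrange(tr, transcript_id)
  expect_equal(back$transcript_id, orig$transcript_id)
  expect_equal(back$chrom, orig$chrom)
  expect_equal(back$strand, orig$strand)
  expect_equal(back$start, orig$start)
  expect_equal(back$end, orig$end)
  expect_equal(back$spliced_length, orig$spliced_length)
  expect_equal(lapply(back$exons, as.data.frame),
               lapply(orig$exons, as.data.frame))
  expect_equal(back$fragment_coverage, orig$fragment_coverage)
})

test_that("gene models are reconstructed as exon-union envelopes", {
  path <- withr::local_tempfile(fileext = ".gtf")
  writeLines(c(
    'chr1\tsrc\texon\t100\t200\t.\t+\t.\tgene_id "g1"; transcript_id "t1";',
    'chr1\tsrc\texon\t150\t260\t.\t+\t.\tgene_id "g1"; transcript_id "t2";',
    'chr1\tsrc\texon\t500\t600\t.\t+\t.\tgene_id "g1"; transcript_id "t2";'
  ), path)
  g <- read_gtf(path)$genes
  expect_equal(nrow(g), 1)
  expect_equal(g$start, 99L)
  expect_equal(g$end, 600L)
  # overlapping exons of the two isoforms are merged
  expect_equal(as.data.frame(g$exons[[1]]),
               data.frame(start = c(99L, 499L), end = c(260L, 600L)))
})

test_that("read_qtl_table parses rows, keeps printed coordinates and validates", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "QTL_ID\tChrome\tTrait\tName\tStart\tEnd",
    "31542\t14\tArachidonic acid content\tFA-C20:4\t138365048\t138414114",
    "658\t10\tAverage backfat thickness\tBFT\t11227321\t11306620"
  ), path)
  q <- read_qtl_table(path)
  expect_equal(nrow(q), 2)
  expect_equal(q$qtl_id[1], 31542L)
  expect_equal(q$start[1], 138365048)
  expect_equal(q$end[1], 138414114)
  expect_equal(q$start0, q$start - 1)
  expect_equal(q$end0, q$end)

  # empty file with a header gives an empty table
  writeLines("QTL_ID\tChrome\tTrait\tName\tStart\tEnd", path)
  expect_equal(nrow(read_qtl_table(path)), 0)

  # shuffled columns honoring header names give the same regions
  writeLines(c(
    "End\tTrait\tQTL_ID\tName\tChrome\tStart",
    "11306620\tAverage backfat thickness\t658\tBFT\t10\t11227321"
  ), path)
  q2 <- read_qtl_table(path)
  expect_equal(q2$qtl_id, 658L)
  expect_equal(q2$start, 11227321)

  writeLines(c(
    "QTL_ID\tChrome\tTrait\tName\tStart\tEnd",
    "1\t1\tx\ts\t500\t400"
  ), path)
  expect_error(read_qtl_table(path), "Start >= End")
  writeLines(c(
    "QTL_ID\tChrome\tTrait\tName\tStart\tEnd",
    "1\t1\tx\ts\t100\t400",
    "1\t2\ty\ts\t100\t400"
  ), path)
  expect_error(read_qtl_table(path), "duplicate QTL_ID")
  writeLines(c(
    "QTL_ID\tChrome\tTrait\tName\tStart\tEnd\tExtra",
    "1\t1\tx\ts\t100\t400\tz"
  ), path)
  expect_warning(read_qtl_table(path), "unknown column")
})

test_that("coding-call readers keep only transcripts present in every file", {
  dir <- withr::local_tempdir()
  tools <- c("CPC", "CNCI", "CPAT", "Pfam")
  ids <- c("t1", "t2", "t3")
  for (tool in tools) {
    keep <- if (tool == "CPAT") c("t1", "t3") else ids  # t2 missing from CPAT
    readr::write_tsv(
      tibble::tibble(transcript_id = keep, verdict = "noncoding"),
      file.path(dir, paste0(tool, ".tsv")))
  }
  paths <- setNames(file.path(dir, paste0(tools, ".tsv")), tools)
  calls <- suppressMessages(read_coding_calls(paths))
  expect_setequal(calls$transcript_id, c("t1", "t3"))
  miss <- attr(calls, "missing")
  expect_equal(miss$transcript_id, "t2")
  expect_match(miss$missing_from, "CPAT")

  readr::write_tsv(tibble::tibble(transcript_id = "t1", verdict = "maybe"),
                   file.path(dir, "CPC.tsv"))
  expect_error(suppressMessages(read_coding_calls(paths)), "invalid verdict")
})

test_that("library summaries average per metric with type-aware rounding", {
  metrics <- tibble::tibble(
    sample_id = c("a", "b", "c"),
    `Clean Data` = c(100, 101, 101),
    `Q30 (%)` = c(95.111, 95.222, 95.333)
  )
  out <- summarize_libraries(metrics)
  expect_equal(out$average[out$metric == "Clean Data"], round(302 / 3))
  expect_equal(out$average[out$metric == "Q30 (%)"], round(95.222, 2))

  # permutation invariance over samples
  out2 <- summarize_libraries(metrics[c(3, 1, 2), ])
  expect_equal(out, out2)

  # identical values across samples pass through
  same <- tibble::tibble(sample_id = c("a", "b"), `N (%)` = c(0.01, 0.01))
  expect_equal(summarize_libraries(same)$average, 0.01)

  long_bad <- tibble::tibble(sample_id = c("a", "a", "b"),
                             metric = c("m1", "m2", "m1"),
                             value = c(1, 2, 3))
  expect_error(summarize_libraries(long_bad), "inconsistent metric keys")
})
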