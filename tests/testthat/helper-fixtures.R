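# Small in-code fixture builders shared by the tests.

make_transcript <- function(id, chrom = "chr1", strand = "+",
                            exons = cbind(c(0L), c(1000L)),
                            gene_id = NA_character_, coverage = 10) {
  ex <- tibble::tibble(start = as.integer(exons[, 1]),
                       end = as.integer(exons[, 2]))
  tibble::tibble(
    transcript_id = id, gene_id = gene_id, chrom = chrom, strand = strand,
    start = min(ex$start), end = max(ex$end), exons = list(ex),
    n_exons = nrow(ex), spliced_length = sum(ex$end - ex$start),
    fragment_coverage = coverage
  )
}

make_gene <- function(id, chrom = "chr1", strand = "+",
                      exons = cbind(c(0L), c(1000L))) {
  ex <- tibble::tibble(start = as.integer(exons[, 1]),
                       end = as.integer(exons[, 2]))
  tibble::tibble(gene_id = id, chrom = chrom, strand = strand,
                 start = min(ex$start), end = max(ex$end), exons = list(ex))
}

make_expression <- function(ids, fpkm_l = 10, fpkm_d = 10,
                            frag_l = 100, frag_d = 100) {
  dplyr::bind_rows(
    tibble::tibble(feature_id = ids, sample_id = "L1",
                   fpkm = rep_len(fpkm_l, length(ids)),
                   fragments = rep_len(frag_l, length(ids))),
    tibble::tibble(feature_id = ids, sample_id = "D1",
                   fpkm = rep_len(fpkm_d, length(ids)),
                   fragments = rep_len(frag_d, length(ids)))
  )
}

std_groups <- tibble::tibble(sample_id = c("L1", "D1"),
                             group = c("luchuan", "duroc"))
std_libs <- tibble::tibble(sample_id = c("L1", "D1"), library_size = 1e6)

# random interval features for the oracle property tests
rand_genes <- function(n, n_chrom = 5, chrom_len = 1e6) {
  rows <- lapply(seq_len(n), function(i) {
    n_ex <- sample(2:5, 1)
    ex_len <- sample(100:400, n_ex, replace = TRUE)
    in_len <- sample(500:5000, n_ex - 1, replace = TRUE)
    s <- sample.int(chrom_len, 1)
    starts <- s + cumsum(c(0, head(ex_len, -1) + in_len))
    make_gene(sprintf("G%04d", i),
              chrom = paste0("chr", sample.int(n_chrom, 1)),
              strand = sample(c("+", "-"), 1),
              exons = cbind(starts, starts + ex_len))
  })
  dplyr::bind_rows(rows)
}

rand_transcripts <- function(n, n_chrom = 5, chrom_len = 1e6) {
  rows <- lapply(seq_len(n), function(i) {
    n_ex <- sample(1:3, 1)
    ex_len <- sample(100:500, n_ex, replace = TRUE)
    in_len <- if (n_ex > 1) sample(200:3000, n_ex - 1, replace = TRUE)
              else integer()
    s <- sample.int(chrom_len, 1)
    starts <- s + cumsum(c(0, head(ex_len, -1) + in_len))
    make_transcript(sprintf("T%05d", i),
                    chrom = paste0("chr", sample.int(n_chrom, 1)),
                    strand = sample(c("+", "-"), 1),
                    exons = cbind(starts, starts + ex_len))
  })
  dplyr::bind_rows(rows)
}
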