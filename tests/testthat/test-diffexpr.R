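test_that("FPKM arithmetic is exact and guards degenerate inputs", {
  expect_equal(compute_fpkm(10, 2000, 1e6), 5)
  expect_equal(compute_fpkm(0, 2000, 1e6), 0)
  set.seed(41)
  frags <- rpois(50, 100); len <- sample(200:5000, 50); lib <- runif(50, 1e6, 1e8)
  expect_equal(compute_fpkm(frags, len, lib), oracle_fpkm(frags, len, lib))
  expect_error(compute_fpkm(1, 0, 1e6), "positive")
  expect_error(compute_fpkm(1, 100, 0), "positive")
})

test_that("gene FPKM sums member transcripts within samples", {
  tb <- tibble::tibble(gene_id = c("g1", "g1", "g2"), fpkm = c(1.5, 2.5, 7))
  out <- gene_fpkm(tb)
  expect_equal(out$fpkm[out$gene_id == "g1"], 4)
  expect_equal(out$fpkm[out$gene_id == "g2"], 7)
  set.seed(42)
  long <- tibble::tibble(
    gene_id = sample(sprintf("g%d", 1:10), 200, replace = TRUE),
    sample_id = sample(c("L1", "D1"), 200, replace = TRUE),
    fpkm = runif(200)
  )
  want <- aggregate(fpkm ~ gene_id + sample_id, long, sum)
  got <- gene_fpkm(long)
  merged <- merge(got, want, by = c("gene_id", "sample_id"))
  expect_equal(merged$fpkm.x, merged$fpkm.y)
})

test_that("fold changes use the pseudocount symmetrically", {
  expect_equal(fold_change(10, 5, 0), tibble::tibble(fold_change = 2, log2fc = 1))
  expect_equal(fold_change(0, 0, 0.5)$fold_change, 1)
  expect_equal(fold_change(0, 0, 0.5)$log2fc, 0)
  expect_equal(fold_change(5, 0, 0.01)$fold_change, 5.01 / 0.01)
})

test_that("the replicate-free exact conditional test matches enumeration", {
  expect_equal(de_pvalue(0, 0, 1e6, 1e6), 1)
  expect_equal(de_pvalue(10, 0, 1e6, 1e6), 2 * 0.5^10)
  set.seed(43)
  for (i in 1:25) {
    n <- sample(1:50, 1)
    x <- sample(0:n, 1)
    l1 <- runif(1, 5e5, 2e6); l2 <- runif(1, 5e5, 2e6)
    expect_equal(de_pvalue(x, n - x, l1, l2),
                 oracle_binom_p(x, n, l1 / (l1 + l2)),
                 tolerance = 1e-9)
  }
})

test_that("BH adjustment matches the independent step-up closed form", {
  expect_equal(bh_adjust(rep(0.02, 5)), rep(0.02, 5))
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  set.seed(44)
  for (i in 1:20) {
    p <- runif(sample(3:200, 1))
    q <- bh_adjust(p)
    expect_equal(q, oracle_bh(p))
    # monotone in p-rank, q equals p for the largest p
    o <- order(p)
    expect_true(all(diff(q[o]) >= -1e-12))
    expect_equal(q[o][length(p)], max(p))
  }
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
})

test_that("status calls respect both threshold presets and their boundaries", {
  res <- tibble::tibble(fold_change = c(2.5, 1.5, 0.4, 2.0, 0.4, 2.5),
                        q_value = c(0.001, 0.001, 0.04, 0.001, 0.005, 0.01))
  out_results <- call_de(res, de_params("results_text"))
  expect_equal(as.character(out_results$status),
               c("up", "ns", "down", "up", "down", "up"))
  out_methods <- call_de(res, de_params("methods_text"))
  # q = 0.04 misses Q < 0.01; FC exactly 2 misses the strict bound;
  # q exactly 0.01 misses the strict Q < 0.01
  expect_equal(as.character(out_methods$status),
               c("up", "ns", "ns", "ns", "down", "ns"))
  expect_error(de_params(fc_up = 3), "reciprocal")
})

test_that("swapping the two breeds maps up to down and inverts fold change", {
  set.seed(45)
  ids <- sprintf("f%03d", 1:100)
  expr <- make_expression(ids,
                          fpkm_l = rlnorm(100, 2, 1), fpkm_d = rlnorm(100, 2, 1),
                          frag_l = rpois(100, 50), frag_d = rpois(100, 50))
  fwd <- run_de(expr, std_libs, std_groups, "luchuan", "duroc")
  rev <- run_de(expr, std_libs, std_groups, "duroc", "luchuan")
  m <- match(fwd$feature_id, rev$feature_id)
  expect_equal(fwd$fold_change, 1 / rev$fold_change[m])
  expect_equal(fwd$p_value, rev$p_value[m])
  map <- c(up = "down", down = "up", ns = "ns")
  expect_equal(unname(map[as.character(fwd$status)]),
               as.character(rev$status[m]))
})

test_that("tidy and glance summarise a DE result faithfully", {
  expr <- make_expression(c("a", "b"), fpkm_l = c(50, 10), fpkm_d = c(1, 10),
                          frag_l = c(500, 100), frag_d = c(10, 100))
  de <- run_de(expr, std_libs, std_groups)
  td <- tidy(de)
  expect_false(inherits(td, "lnc_de"))
  expect_equal(nrow(td), 2)
  gl <- glance(de)
  expect_equal(gl$n_features, 2)
  expect_equal(gl$n_up + gl$n_down + gl$n_ns, 2)
  expect_equal(gl$preset, "results_text")
  expect_s3_class(autoplot(de), "ggplot")
})

test_that("external p-values can replace the built-in test", {
  expr <- make_expression(c("a", "b"))
  pv <- tibble::tibble(feature_id = c("a", "b"), p_value = c(0.001, 0.8))
  de <- run_de(expr, std_libs, std_groups, p_values = pv)
  expect_equal(de$p_value[match(c("a", "b"), de$feature_id)], c(0.001, 0.8))
  expect_error(run_de(expr, std_libs, std_groups,
                      p_values = pv[1, ]), "every feature")
})
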