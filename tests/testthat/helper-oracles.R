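# Independent brute-force oracles.  These deliberately share no code with
# the package internals: plain loops and closed forms only.

# half-open interval overlap
.ov <- function(s1, e1, s2, e2) s1 < e2 && s2 < e1

# quadratic positional classification following the category definitions
oracle_classify <- function(candidates, genes) {
  out <- character(nrow(candidates))
  nearest <- rep(NA_character_, nrow(candidates))
  nearest_among <- function(tr, gids) {
    g <- genes[match(gids, genes$gene_id), ]
    d <- abs((g$start + g$end) / 2 - (tr$start + tr$end) / 2)
    gids[order(d, gids)][1]
  }
  for (i in seq_len(nrow(candidates))) {
    tr <- candidates[i, ]
    tex <- tr$exons[[1]]
    anti <- character(); sens <- character(); intr <- character()
    gsame <- genes[genes$chrom == tr$chrom, ]
    for (j in seq_len(nrow(gsame))) {
      g <- gsame[j, ]
      gex <- g$exons[[1]]
      hit <- FALSE
      for (a in seq_len(nrow(tex))) {
        for (b in seq_len(nrow(gex))) {
          if (.ov(tex$start[a], tex$end[a], gex$start[b], gex$end[b])) {
            hit <- TRUE
          }
        }
      }
      if (hit) {
        if (g$strand != tr$strand) anti <- c(anti, g$gene_id)
        else sens <- c(sens, g$gene_id)
      } else if (nrow(gex) >= 2) {
        for (b in seq_len(nrow(gex) - 1)) {
          if (tr$start >= gex$end[b] && tr$end <= gex$start[b + 1]) {
            intr <- c(intr, g$gene_id)
          }
        }
      }
    }
    if (length(anti) > 0) {
      out[i] <- "antisense"; nearest[i] <- nearest_among(tr, anti)
    } else if (length(sens) > 0) {
      out[i] <- "sense"; nearest[i] <- nearest_among(tr, sens)
    } else if (length(intr) > 0) {
      out[i] <- "intronic"; nearest[i] <- nearest_among(tr, unique(intr))
    } else {
      out[i] <- "lincRNA"
      if (nrow(gsame) > 0) nearest[i] <- nearest_among(tr, gsame$gene_id)
    }
  }
  tibble::tibble(transcript_id = candidates$transcript_id,
                 category = out, nearest_gene_id = nearest)
}

# quadratic interval membership (feature body overlaps QTL by >= 1 bp)
oracle_qtl_members <- function(features, qtls) {
  rows <- list()
  for (i in seq_len(nrow(features))) {
    for (j in seq_len(nrow(qtls))) {
      if (features$chrom[i] == qtls$chrom[j] &&
          .ov(features$start[i], features$end[i],
              qtls$start0[j], qtls$end0[j])) {
        rows[[length(rows) + 1]] <- c(qtls$qtl_id[j], features$feature_id[i])
      }
    }
  }
  if (length(rows) == 0) return(character())
  sort(vapply(rows, paste, "", collapse = ":"))
}

# quadratic cis-pair search with body-to-body gaps
oracle_cis_pairs <- function(lncrnas, genes, window) {
  rows <- list()
  for (i in seq_len(nrow(lncrnas))) {
    for (j in seq_len(nrow(genes))) {
      if (lncrnas$chrom[i] != genes$chrom[j]) next
      ls <- lncrnas$start[i]; le <- lncrnas$end[i]
      gs <- genes$start[j]; ge <- genes$end[j]
      gap <- max(0, gs - le, ls - ge)
      if (gap > window) next
      rel <- if (.ov(ls, le, gs, ge)) "overlapping"
             else if (ge <= ls) "upstream" else "downstream"
      rows[[length(rows) + 1]] <-
        list(lncrna_id = lncrnas$transcript_id[i],
             gene_id = genes$gene_id[j], distance = gap, relation = rel)
    }
  }
  dplyr::bind_rows(rows)
}

# Benjamini-Hochberg step-up from the closed form:
# q_(i) = min_{j >= i} min(1, m * p_(j) / j) over the sorted p-values
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- rev(cummin(rev(pmin(1, m * p[o] / seq_len(m)))))
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

# upper-tail hypergeometric by exhaustive enumeration of draws (N <= 12)
oracle_hypergeom <- function(N, K, n, k) {
  pool <- c(rep(1, K), rep(0, N - K))
  draws <- utils::combn(N, n)
  hits <- apply(draws, 2, function(idx) sum(pool[idx]))
  mean(hits >= k)
}

# two-sided exact binomial p by minimum-likelihood enumeration
oracle_binom_p <- function(x, n, p) {
  if (n == 0) return(1)
  d <- stats::dbinom(0:n, n, p)
  sum(d[d <= d[x + 1] * (1 + 1e-7)])
}

# independent FPKM arithmetic
oracle_fpkm <- function(fragments, len, lib) {
  (fragments / (len / 1000)) / (lib / 1e6)
}
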