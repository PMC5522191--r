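#' Hypergeometric over-representation test of a gene set
#'
#' For each annotation term, tests whether the target gene set contains more
#' of the term's genes than expected by chance, with the upper-tail
#' hypergeometric probability
#' `P(X >= k | N, K, n)` where `N` is the background size, `K` the
#' background genes carrying the term, `n` the target-set size and `k` the
#' target genes carrying the term.  P-values are Benjamini-Hochberg adjusted
#' across the tested terms.  Terms are treated as flat sets — no ontology
#' propagation.
#'
#' @param targets Character vector of target gene ids (must be a subset of
#'   the background).
#' @param term_map Tibble `term_id`, `gene_id` and optionally `term_name`.
#' @param background Character vector of background gene ids.  Defaults to
#'   all genes with at least one term annotation.
#' @return A tibble of class `lnc_enrich`, one row per term with `K > 0`:
#'   `term_id`, `term_name`, `k`, `K`, `n`, `N`, `fold_enrichment`,
#'   `p_value`, `q_value`, ordered by `p_value`.
#' @export
hypergeom_enrich <- function(targets, term_map, background = NULL) {
  .assert_cols(term_map, c("term_id", "gene_id"), "term_map")
  targets <- unique(targets)
  background <- unique(background %||% term_map$gene_id)
  stray <- setdiff(targets, background)
  if (length(stray) > 0) {
    abort(sprintf("target gene(s) absent from the background: %s",
                  paste(stray, collapse = ", ")))
  }
  tm <- term_map |> filter(.data$gene_id %in% background)
  if (!"term_name" %in% names(tm)) tm$term_name <- tm$term_id
  tm <- distinct(tm, .data$term_id, .data$gene_id, .keep_all = TRUE)
  N <- length(background)
  n <- length(targets)
  out <- tm |>
    group_by(.data$term_id) |>
    summarise(
      term_name = first(.data$term_name),
      K = dplyr::n_distinct(.data$gene_id),
      k = sum(unique(.data$gene_id) %in% targets),
      .groups = "drop"
    ) |>
    filter(.data$K > 0) |>
    mutate(
      n = n, N = N,
      fold_enrichment = (.data$k / .data$n) / (.data$K / .data$N),
      p_value = phyper(.data$k - 1, .data$K, .data$N - .data$K, .data$n,
                       lower.tail = FALSE),
      q_value = bh_adjust(.data$p_value)
    ) |>
    select("term_id", "term_name", "k", "K", "n", "N", "fold_enrichment",
           "p_value", "q_value") |>
    arrange(.data$p_value, .data$term_id)
  class(out) <- c("lnc_enrich", class(out))
  out
}
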