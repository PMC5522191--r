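#' Tidy a differential-expression result
#'
#' @param x An `lnc_de` tibble from [run_de()].
#' @param ... Unused.
#' @return A plain tibble of the per-feature results.
#' @export
tidy.lnc_de <- function(x, ...) {
  out <- as_tibble(x)
  class(out) <- setdiff(class(out), "lnc_de")
  out
}

#' One-row summary of a differential-expression result
#'
#' @param x An `lnc_de` tibble from [run_de()].
#' @param ... Unused.
#' @return A one-row tibble: feature counts by status, the contrast and the
#'   thresholds used.
#' @export
glance.lnc_de <- function(x, ...) {
  p <- attr(x, "params")
  ct <- attr(x, "contrast")
  tibble(
    n_features = nrow(x),
    n_up = sum(x$status == "up"),
    n_down = sum(x$status == "down"),
    n_ns = sum(x$status == "ns"),
    numerator = unname(ct["numerator"]),
    denominator = unname(ct["denominator"]),
    preset = p$preset,
    q_threshold = p$q_threshold,
    fc_up = p$fc_up,
    fc_down = p$fc_down
  )
}

#' @rdname tidy.lnc_de
#' @export
tidy.lnc_enrich <- function(x, ...) {
  out <- as_tibble(x)
  class(out) <- setdiff(class(out), "lnc_enrich")
  out
}

#' One-row summary of an enrichment result
#'
#' @param x An `lnc_enrich` tibble from [hypergeom_enrich()].
#' @param alpha Q-value cutoff used to count significant terms.
#' @param ... Unused.
#' @return A one-row tibble: terms tested, significant terms, set sizes.
#' @export
glance.lnc_enrich <- function(x, alpha = 0.05, ...) {
  tibble(
    n_terms = nrow(x),
    n_significant = sum(x$q_value < alpha),
    n_targets = if (nrow(x) > 0) x$n[1] else 0L,
    n_background = if (nrow(x) > 0) x$N[1] else 0L
  )
}

#' Volcano plot of a differential-expression result
#'
#' @param object An `lnc_de` tibble from [run_de()].
#' @param ... Unused.
#' @return A ggplot: log2 fold change against -log10 q-value, coloured by
#'   up/down/ns status.
#' @export
autoplot.lnc_de <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$log2fc,
                                   y = -log10(.data$q_value),
                                   colour = .data$status)) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::scale_colour_manual(values = c(up = "#c0392b", down = "#2c7fb8",
                                            ns = "grey60")) +
    ggplot2::labs(x = "log2 fold change", y = "-log10 q-value",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Dot plot of an enrichment result
#'
#' @param object An `lnc_enrich` tibble from [hypergeom_enrich()].
#' @param top_n Terms shown, ordered by p-value.
#' @param ... Unused.
#' @return A ggplot: fold enrichment per term, point size the target-set
#'   hit count, colour the q-value.
#' @export
autoplot.lnc_enrich <- function(object, top_n = 20, ...) {
  df <- as_tibble(object) |>
    arrange(.data$p_value) |>
    slice_head(n = top_n) |>
    mutate(term_name = factor(.data$term_name,
                              levels = rev(unique(.data$term_name))))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$fold_enrichment,
                                   y = .data$term_name,
                                   size = .data$k, colour = .data$q_value)) +
    ggplot2::geom_point() +
    ggplot2::scale_colour_gradient(low = "#c0392b", high = "#2c7fb8") +
    ggplot2::labs(x = "fold enrichment", y = NULL, size = "hits",
                  colour = "q-value") +
    ggplot2::theme_minimal()
}

#' Bar chart of QTL scores
#'
#' @param object An `lnc_qtl_scores` tibble from [score_qtl()] (or
#'   [rank_qtl()]).
#' @param top_n QTL_IDs shown, highest score first.
#' @param ... Unused.
#' @return A ggplot of count/span scores per QTL_ID, coloured by trait.
#' @export
autoplot.lnc_qtl_scores <- function(object, top_n = 20, ...) {
  df <- as_tibble(object) |>
    arrange(desc(.data$score), .data$qtl_id) |>
    slice_head(n = top_n) |>
    mutate(qtl_id = factor(.data$qtl_id, levels = rev(unique(.data$qtl_id))))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$score, y = .data$qtl_id,
                                   fill = .data$trait)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "DE-lncRNA count / span (per bp)", y = "QTL_ID",
                  fill = NULL) +
    ggplot2::theme_minimal()
}

#' Bar chart of lncRNA positional categories
#'
#' @param summary A [summarize_categories()] result.
#' @return A ggplot of category counts, labelled with percentages.
#' @export
plot_category_summary <- function(summary) {
  ggplot2::ggplot(summary, ggplot2::aes(x = .data$category, y = .data$n,
                                        fill = .data$category)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f%%", .data$percent)),
                       vjust = -0.4, size = 3) +
    ggplot2::labs(x = NULL, y = "lncRNAs") +
    ggplot2::theme_minimal()
}
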