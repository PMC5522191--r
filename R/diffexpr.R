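#' Differential expression parameters
#'
#' Two named presets reflect the two threshold conventions in common use for
#' replicate-free breed contrasts:
#' \describe{
#'   \item{`results_text`}{FDR < 0.05 and fold change >= 2 (up) or <= 0.5
#'     (down); fold-change bounds inclusive.  The default.}
#'   \item{`methods_text`}{Q < 0.01 and |log2 fold change| > 1; fold-change
#'     bounds strict, so a feature at exactly fold change 2 is `ns`.}
#' }
#'
#' @param preset Which threshold convention to use.
#' @param pseudocount FPKM added to numerator and denominator before the
#'   ratio, keeping fold changes finite at zero expression.  Default 0.01.
#' @param q_threshold,fc_up,fc_down,inclusive_fc Override individual
#'   thresholds; defaults come from the preset.  `fc_up` must equal
#'   `1/fc_down`.
#' @return A list of class `lnc_de_params`.
#' @export
de_params <- function(preset = c("results_text", "methods_text"),
                      pseudocount = 0.01, q_threshold = NULL, fc_up = NULL,
                      fc_down = NULL, inclusive_fc = NULL) {
  preset <- match.arg(preset)
  def <- switch(preset,
    results_text = list(q_threshold = 0.05, fc_up = 2, fc_down = 0.5,
                        inclusive_fc = TRUE),
    methods_text = list(q_threshold = 0.01, fc_up = 2, fc_down = 0.5,
                        inclusive_fc = FALSE)
  )
  p <- list(
    preset = preset,
    pseudocount = pseudocount,
    q_threshold = q_threshold %||% def$q_threshold,
    fc_up = fc_up %||% def$fc_up,
    fc_down = fc_down %||% def$fc_down,
    inclusive_fc = inclusive_fc %||% def$inclusive_fc
  )
  stopifnot(p$q_threshold > 0, p$q_threshold < 1, p$pseudocount >= 0)
  if (abs(p$fc_up * p$fc_down - 1) > 1e-9) {
    abort("`fc_up` must be the reciprocal of `fc_down`")
  }
  structure(p, class = "lnc_de_params")
}

#' Fragments per kilobase of exon per million mapped fragments
#'
#' `FPKM = fragments * 1e9 / (spliced_length * library_size)`, the
#' length- and depth-normalised expression unit for paired-end RNA-seq.
#'
#' @param fragments Fragment count(s) mapped to the feature.
#' @param spliced_length Feature length(s) in bp (sum of exon lengths).
#' @param library_size Total mapped fragments in the library.
#' @return Numeric vector of FPKM values.
#' @export
compute_fpkm <- function(fragments, spliced_length, library_size) {
  if (any(spliced_length <= 0)) abort("`spliced_length` must be positive")
  if (any(library_size <= 0)) abort("`library_size` must be positive")
  if (any(fragments < 0)) abort("`fragments` must be non-negative")
  fragments * 1e9 / (spliced_length * library_size)
}

#' Gene-level FPKM by summing member transcripts
#'
#' Gene expression is the sum of the FPKM values of the gene's transcripts
#' (each transcript belongs to exactly one gene).
#'
#' @param transcript_fpkm Tibble with `gene_id`, `fpkm` and optionally
#'   `sample_id` (summed per gene within each sample when present).
#' @return Tibble of `gene_id` (and `sample_id`) with summed `fpkm`.
#' @export
gene_fpkm <- function(transcript_fpkm) {
  .assert_cols(transcript_fpkm, c("gene_id", "fpkm"), "transcript_fpkm")
  keys <- intersect(c("gene_id", "sample_id"), names(transcript_fpkm))
  transcript_fpkm |>
    group_by(across(dplyr::all_of(keys))) |>
    summarise(fpkm = sum(.data$fpkm), .groups = "drop")
}

#' Fold change between two expression values
#'
#' `FC = (fpkm_num + pseudocount) / (fpkm_den + pseudocount)`, with the
#' numerator conventionally the obese (Luchuan) breed and the denominator
#' the lean (Duroc) breed.
#'
#' @param fpkm_num,fpkm_den Non-negative expression values (vectorised).
#' @param pseudocount Stabilising offset added to both sides.
#' @return A tibble with `fold_change` and `log2fc`.
#' @export
fold_change <- function(fpkm_num, fpkm_den, pseudocount = 0.01) {
  if (any(fpkm_num < 0) || any(fpkm_den < 0)) abort("FPKM values must be >= 0")
  fc <- (fpkm_num + pseudocount) / (fpkm_den + pseudocount)
  tibble(fold_change = fc, log2fc = log2(fc))
}

#' Replicate-free exact conditional test for differential expression
#'
#' With a single library per condition, conditions on the total fragment
#' count of a feature: under the null of equal expression, the fragments
#' from condition 1 are Binomial(n = frag1 + frag2,
#' p = lib1 / (lib1 + lib2)).  Returns the two-sided exact binomial
#' p-value (minimum-likelihood method).  Features with zero total count get
#' p = 1.
#'
#' @param frag1,frag2 Per-feature fragment counts (vectorised).
#' @param lib1,lib2 Library sizes (total mapped fragments).
#' @return Numeric vector of p-values in (0, 1].
#' @export
de_pvalue <- function(frag1, frag2, lib1, lib2) {
  if (any(lib1 <= 0) || any(lib2 <= 0)) abort("library sizes must be positive")
  if (any(frag1 < 0) || any(frag2 < 0)) abort("counts must be non-negative")
  nvec <- frag1 + frag2
  pnull <- lib1 / (lib1 + lib2)
  if (length(pnull) == 1) pnull <- rep(pnull, length(nvec))
  mapply(function(x, n, p) {
    if (n == 0) return(1)
    binom.test(x, n, p)$p.value
  }, frag1, nvec, pnull)
}

#' Benjamini-Hochberg adjusted q-values
#'
#' Step-up false discovery rate adjustment, clipped to 1 and monotone in
#' p-value rank.
#'
#' @param p_values Numeric vector of p-values in \[0, 1\].
#' @return Adjusted q-values, same length and order as the input.
#' @export
bh_adjust <- function(p_values) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE)) {
    abort("p-values must lie in [0, 1]")
  }
  p.adjust(p_values, method = "BH")
}

#' Call up/down/ns status from fold change and q-value
#'
#' A feature is `up` when its fold change clears `fc_up` and its q-value is
#' below `q_threshold`; `down` symmetrically at `fc_down`; otherwise `ns`.
#' Whether the fold-change bound itself counts depends on the preset (see
#' [de_params()]).
#'
#' @param results Tibble with `fold_change` and `q_value` columns.
#' @param params A [de_params()] object.
#' @return `results` with a `status` factor column (`up`, `down`, `ns`).
#' @export
call_de <- function(results, params = de_params()) {
  .assert_cols(results, c("fold_change", "q_value"), "results")
  fc <- results$fold_change
  hit_up <- if (params$inclusive_fc) fc >= params$fc_up else fc > params$fc_up
  hit_dn <- if (params$inclusive_fc) fc <= params$fc_down else fc < params$fc_down
  sig <- results$q_value < params$q_threshold
  results |>
    mutate(status = factor(
      dplyr::case_when(sig & hit_up ~ "up", sig & hit_dn ~ "down",
                       TRUE ~ "ns"),
      levels = c("up", "down", "ns")))
}

#' Run the full differential-expression stage
#'
#' Aggregates expression per condition (mean FPKM over the condition's
#' samples; fragment counts and library sizes summed), computes fold change
#' numerator/denominator, the replicate-free exact conditional p-value,
#' Benjamini-Hochberg q-values, and up/down/ns calls.
#'
#' Externally computed p-values may be supplied per feature to replace the
#' built-in test (e.g. from a replicate-aware engine).
#'
#' @param expression Long tibble `feature_id`, `sample_id`, `fpkm`,
#'   `fragments`.
#' @param library_sizes Tibble `sample_id`, `library_size`.
#' @param groups Tibble `sample_id`, `group` mapping samples to the two
#'   conditions.
#' @param numerator,denominator Group labels forming the fold-change ratio
#'   numerator/denominator.
#' @param params A [de_params()] object.
#' @param p_values Optional tibble `feature_id`, `p_value` overriding the
#'   built-in test.
#' @return A tibble of class `lnc_de` with one row per feature:
#'   `feature_id`, `fpkm_num`, `fpkm_den`, `frag_num`, `frag_den`,
#'   `fold_change`, `log2fc`, `p_value`, `q_value`, `status`.
#' @export
run_de <- function(expression, library_sizes, groups,
                   numerator = "luchuan", denominator = "duroc",
                   params = de_params(), p_values = NULL) {
  .assert_cols(expression, c("feature_id", "sample_id", "fpkm", "fragments"),
               "expression")
  .assert_cols(library_sizes, c("sample_id", "library_size"), "library_sizes")
  .assert_cols(groups, c("sample_id", "group"), "groups")
  if (!all(c(numerator, denominator) %in% groups$group)) {
    abort("`numerator` and `denominator` must both appear in `groups$group`")
  }
  ann <- expression |>
    inner_join(groups, by = "sample_id") |>
    filter(.data$group %in% c(numerator, denominator))
  byg <- ann |>
    group_by(.data$feature_id, .data$group) |>
    summarise(fpkm = mean(.data$fpkm), fragments = sum(.data$fragments),
              .groups = "drop")
  libs <- library_sizes |>
    inner_join(groups, by = "sample_id") |>
    group_by(.data$group) |>
    summarise(library_size = sum(.data$library_size), .groups = "drop")
  lib_num <- libs$library_size[libs$group == numerator]
  lib_den <- libs$library_size[libs$group == denominator]

  wide <- byg |>
    tidyr::pivot_wider(names_from = "group",
                       values_from = c("fpkm", "fragments"), values_fill = 0)
  res <- tibble(
    feature_id = wide$feature_id,
    fpkm_num = wide[[paste0("fpkm_", numerator)]],
    fpkm_den = wide[[paste0("fpkm_", denominator)]],
    frag_num = wide[[paste0("fragments_", numerator)]],
    frag_den = wide[[paste0("fragments_", denominator)]]
  ) |>
    bind_cols(fold_change(wide[[paste0("fpkm_", numerator)]],
                          wide[[paste0("fpkm_", denominator)]],
                          params$pseudocount))
  if (is.null(p_values)) {
    res$p_value <- de_pvalue(res$frag_num, res$frag_den, lib_num, lib_den)
  } else {
    .assert_cols(p_values, c("feature_id", "p_value"), "p_values")
    res <- left_join(res, p_values, by = "feature_id")
    if (anyNA(res$p_value)) abort("`p_values` must cover every feature")
  }
  res$q_value <- bh_adjust(res$p_value)
  res <- call_de(res, params)
  class(res) <- c("lnc_de", class(res))
  attr(res, "params") <- params
  attr(res, "contrast") <- c(numerator = numerator, denominator = denominator)
  res
}
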