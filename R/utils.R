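# Internal helpers shared across modules.
#
# Coordinate convention: every interval inside the package is 0-based
# half-open [start, end).  External tables (GTF, QTL) are 1-based inclusive
# and are converted exactly once, at read/write time.

# 1-based inclusive -> 0-based half-open
.to0 <- function(start1, end1) list(start = start1 - 1L, end = end1)

# 0-based half-open -> 1-based inclusive
.to1 <- function(start0, end0) list(start = start0 + 1L, end = end0)

.assert_cols <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort(sprintf("`%s` is missing required column(s): %s",
                  what, paste(missing, collapse = ", ")))
  }
  invisible(df)
}

# GRanges from an internal half-open interval table; coordinates are shifted
# to 1-based only inside the GRanges container.
.as_granges <- function(df, id_col) {
  GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end),
    strand = if ("strand" %in% names(df)) df$strand else "*",
    id = df[[id_col]]
  )
}

# gap between two half-open intervals on the same chromosome (0 if they
# overlap or touch)
.interval_gap <- function(s1, e1, s2, e2) {
  pmax(0L, pmax(s2 - e1, s1 - e2))
}

.intervals_overlap <- function(s1, e1, s2, e2) {
  s1 < e2 & s2 < e1
}

# run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's stream afterwards so simulation is reproducible without touching
# global state
.with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# scientific notation with 3 significant digits, "6.11E-05" style
.format_score <- function(x) {
  ifelse(x == 0, "0", sprintf("%.2E", x))
}
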