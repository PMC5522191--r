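---
title: "Models and methods behind lncqtl"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind lncqtl}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lncqtl)
library(dplyr)
```

## The analysis this package implements

Contrasts between a lean and an obese pig breed (one RNA-seq library per
breed and tissue) are a common design for studying fat deposition, and the
downstream analysis of such experiments follows a well-established shape:
assembled transcripts are filtered to long non-coding RNA (lncRNA)
candidates, the candidates are certified noncoding by the consensus of
several coding-potential classifiers and classified by their position
relative to annotated genes, expression differences between the breeds are
called with fold-change and FDR thresholds, nearby protein-coding genes are
proposed as cis targets, and the differentially expressed features are
intersected with quantitative trait locus (QTL) intervals for fat-related
traits.  `lncqtl` implements that pipeline as composable, tested functions
over tidy tables, together with a seeded synthetic-data generator that
plants ground truth so every stage can be validated offline.

All intervals inside the package are 0-based half-open; external tables
(GTF, QTL) are 1-based inclusive and are converted exactly once at the I/O
boundary.  A single conversion point avoids the off-by-one drift that
plagues ad hoc interval code.

## Candidate filtering

A transcript is retained as a lncRNA candidate when

* spliced length $> 200$ bp (strict: a 200-bp transcript is not "long"),
* exon count $\ge 2$,
* mean per-base fragment coverage $\ge 3$, and
* FPKM $\ge 0.1$.

Two of these rules needed interpretation.  "Two exons" is applied as *at
least* two: requiring exactly two would discard the long multi-exon
isoforms that dominate real length distributions, and $\ge 2$ is the
conventional lncRNA-calling filter.  The coverage statistic is taken to be
mean per-base fragment coverage over the spliced transcript (the value
Cufflinks-style assemblers report as `cov`); per-exon and junction-based
variants exist in the wild but are not distinguishable from published
summary tables, so the simplest per-base definition is used.  The FPKM rule
is applied to the maximum over samples — a transcript convincingly
expressed anywhere is kept — with a per-sample (`"all"`) mode available via
`filter_params(fpkm_rule = "all")`.  Each rejected transcript is charged to
the *first* rule it fails, in the order above, so the rejection tally is a
partition of the rejected set.

## Coding-potential intersection

Four classifiers (CPC, CNCI, CPAT and Pfam by default) each deliver a
coding/noncoding verdict per transcript; a candidate survives only if all
four say noncoding.  `venn_counts()` reports the full lattice of
$2^4 - 1 = 15$ nonempty Venn cells for the usual intersection figure.
Transcripts missing from any classifier's output cannot be certified and
are excluded from candidacy; they are reported in the `missing` attribute
of `read_coding_calls()` rather than silently dropped, since partial tool
output usually signals an upstream problem.

## Positional classification

Categories are assigned by precedence:

1. **antisense** — exonic overlap with a gene on the opposite strand;
2. **sense** — exonic overlap with a gene on the same strand;
3. **intronic** — the transcript lies entirely within a single intron
   (either strand, no exonic overlap);
4. **lincRNA** — no overlap with any gene body.

"Adjacent" in the sense/antisense definitions is implemented as *overlap*,
not mere proximity; proximity-based sense/antisense calling would need a
distance parameter the definitions do not supply.  Exonic overlap is tested
exon-against-exon, so a transcript lying in an intron of one gene while its
exons overlap another gene's exons is classified by the overlap, not the
containment.  A transcript that overlaps a gene body without touching its
exons and without fitting inside a single intron (for example, poking out
of the gene's end from within an intron) falls through to lincRNA.  When
several genes satisfy the winning rule, the nearest gene by midpoint
distance is reported, with lexicographic `gene_id` as the deterministic
tie-break.  Gene models are exon-union envelopes over their isoforms, so
introns are maximal exon-free intervals of the locus.

Interval overlap is computed with `GenomicRanges`/`IRanges`; the test suite
checks the classifier (and the QTL and cis-target machinery below) against
independent quadratic brute-force oracles on over a thousand random
placements.

## Differential expression without replicates

Expression is quantified as FPKM,
$\mathrm{FPKM} = \frac{10^9 \cdot \text{fragments}}{\text{spliced length} \cdot \text{library size}},$
and gene-level expression is the sum of the gene's transcript FPKMs.
The fold change between breeds is
$\mathrm{FC} = \frac{\mathrm{FPKM}_{\text{num}} + c}{\mathrm{FPKM}_{\text{den}} + c}$
with pseudocount $c = 0.01$ FPKM, which keeps fold changes finite for
features silent in one breed (published tables report finite extreme fold
changes without stating their handling; 0.01 is small relative to any
expression level of interest and recovers the raw ratio elsewhere).

With one library per condition no dispersion can be estimated, so the
p-value engine is the exact conditional binomial test: conditional on the
total fragment count $n = x_1 + x_2$ of a feature, under the null of equal
expression $x_1 \sim \mathrm{Binomial}(n,\ \ell_1 / (\ell_1 + \ell_2))$
where $\ell_i$ are the library sizes.  The two-sided p-value uses the
minimum-likelihood convention of `binom.test()`.  This test is exactly
calibrated when counts are Poisson — which is how the default generator
draws them — and anti-conservative under overdispersion, which is why the
generator offers a negative-binomial mode for robustness checks and
`run_de()` accepts externally computed p-values per feature as a drop-in
replacement.  P-values are Benjamini–Hochberg adjusted (`p.adjust`).

Two threshold conventions ship as named presets because both are in common
use and they genuinely differ at the boundaries:

* `results_text` (default): $q < 0.05$ and $\mathrm{FC} \ge 2$ or
  $\le 0.5$ (inclusive bounds);
* `methods_text`: $q < 0.01$ and $|\log_2 \mathrm{FC}| > 1$ (strict
  bounds) — a feature at exactly FC 2, or exactly $q = 0.01$, is `ns`
  here.

## Cis targets and QTL colocalization

Cis targets are genes whose body lies within 100 kb of the lncRNA body on
the same chromosome — the conventional search radius for local regulation.
The gap is measured body-to-body (the definitions give no anchor such as a
TSS) and the window is strand-agnostic by default; `strand_aware = TRUE`
flips upstream/downstream for minus-strand lncRNAs but does not change
which pairs are found.

A feature belongs to a QTL when the bodies overlap by at least one base
(`mode = "within"` gives containment semantics instead).  Each QTL record
is scored as
$\text{score} = \frac{\#\,\text{DE lncRNAs in the interval}}{\text{span}},
\qquad \text{span} = \text{end} - \text{start}$
on the printed 1-based coordinates.  Using $\text{end}-\text{start}$
rather than $\text{end}-\text{start}+1$ is a deliberate, documented choice:
at the three significant figures used in reports the two are
indistinguishable for real QTL spans, and one convention must be fixed.
Scores are reported in scientific notation with three significant digits,
ranked descending with ties broken by ascending QTL_ID.

At the trait level a feature overlapping several QTL_IDs of one trait
counts once for that trait, while the same feature is counted again by
every QTL_ID it overlaps at the per-QTL level.  This de-duplication rule is
an assumption, not a reproduction claim: published trait tallies do not
state whether they count distinct features or sum over QTL_IDs, and the
two differ whenever QTL intervals of a trait overlap.

## Enrichment

The enrichment stage is a flat hypergeometric over-representation test:
$p = P(X \ge k)$ with $X \sim \mathrm{Hypergeom}(N, K, n)$, BH-adjusted
across terms.  The background defaults to all genes with at least one term
annotation (the least arbitrary choice when the true assay universe is
unknown) and is configurable.  No ontology-graph propagation or
elimination logic is attempted — term sets are treated as given, which is
the honest scope for a generic tool detached from any database version.

## The synthetic-data generator

`simulate_dataset()` emulates the *shapes* of a two-breed study: a small
genome (3 chromosomes of 5 Mb by default) with 60 non-overlapping
multi-exon genes; lncRNAs planted to satisfy each positional category by
construction (so classification recovery at zero noise must be 100%);
decoy transcripts that each fail exactly one filter rule; log-normal
baseline expression with a planted $|\log_2 \mathrm{FC}| = 2$ on 10% of
features; Poisson fragment counts at a depth of $10^6$ fragments per
library; four classifiers with 5% default error rates; and trait-linked
QTL intervals spanning 50–500 kb.

The baseline FPKM distribution is log-normal with median 40 FPKM
(`fpkm_meanlog = log(40)`, `fpkm_sdlog = 1`).  That scale was chosen by a
power calculation, not measured from data: with single Poisson libraries at
the simulated depth, a four-fold effect on a feature is detectable only
when the feature carries a few dozen fragments, and down-regulated features
carry roughly four-fold fewer total fragments than up-regulated ones.  The
median-40 baseline is the scale at which the planted effects attain the
detection power the design targets (about 90% recall) — i.e. the generator
emulates the *detectably expressed* stratum of a transcriptome, not the
shallow tail.  Per-sample multiplicative noise (`noise_sd`, default 0.15
log2 units) makes observed fold changes scatter around the planted effect;
setting it to zero yields exact planted ratios, which the recovery tests
exploit.

What the generator does **not** emulate — and hence what passing tests do
not establish about real data: overdispersed biological replication (unless
the negative-binomial mode is switched on), multi-isoform loci and
assembly uncertainty, correlated errors between coding-potential
classifiers (real CPC/CNCI/CPAT/Pfam disagreements are far from
independent), GC and length biases in fragment sampling, and the clustered,
overlapping structure of real QTL databases.  Recovery results on this
generator validate the *arithmetic and logic* of the pipeline, not the
biological error rates of any upstream tool.

Determinism is a contract: all randomness flows from the single `seed` in
`sim_config()`, the caller's RNG stream is saved and restored, and the same
seed yields byte-identical output files.

## Problem sizes used by the test suite

The shipped tests run the DE recovery at 2,000 features (200 planted
effects), the brute-force oracle comparisons at 1,000 random transcripts
against 150 genes and 40 QTL intervals, and the end-to-end pipeline at the
default generator scale (60 genes, 80 lncRNAs, 16 decoys, 30 QTLs).  These
sizes were picked so that stochastic checks have enough mass for stable
rates while the whole suite stays fast enough to run habitually.

## Worked example

```{r example}
sim <- simulate_dataset(sim_config(seed = 42))
res <- run_pipeline(sim)
res$category_summary
glance(res$lnc_de)
head(rank_qtl(res$qtl_scores, top_n = 5))
```

## Known limitations

* The replicate-free test inherits all caveats of single-library designs:
  it measures sampling noise, not biological variability, and its q-values
  should be read accordingly.
* Fold-change boundary behaviour differs between the two presets by
  design; pick the preset that matches the convention you report.
* Trans-target prediction by co-expression is out of scope — with two
  conditions there are not enough samples for meaningful correlation.
* The GTF reader covers the transcript/exon dialect with `gene_id` and
  `transcript_id` attributes (plus Cufflinks `cov`); GFF3 and exotic
  attribute schemes are not supported.
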