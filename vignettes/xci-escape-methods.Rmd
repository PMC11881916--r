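---
title: "Methods: allele-specific XCI escape calling, aging transitions and pseudobulk DE"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: allele-specific XCI escape calling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xciescape)
```

# The genetic model and what the package computes

In an F1 hybrid between *M. musculus* (the reference genome) and
*M. castaneus*, SNPs occur roughly every 264 bp, so a substantial fraction of
reads can be assigned to one parental genome. With nonrandom XCI the
castaneus X is always the inactive X (Xi): castaneus-assigned reads from an
X-linked gene are direct evidence of escape from silencing, while autosomal
reads split ~50/50 between strains apart from mapping bias. `xciescape` takes
two parallel cells × genes matrices of allele-assigned counts (active-X
strain and inactive-X strain) and computes escape calls, their change with
age, and allele-level differential expression.

# Escape model

For gene $g$ in a group (cell type × age), let $X_a$ and $X_i$ be the
normalized read sums assigned to the two strains. The escape proportion is

$$P_{esc} = \frac{X_i}{X_i + X_a}.$$

Read mapping is biased toward the better-curated reference genome, deflating
$X_i$. The correction uses the genome-wide autosomal ratio
$r = A_{Tcast}/A_{Tmus}$ (alternate over reference totals across all
autosomal genes), which estimates the bias factor because autosomal
transcription is balanced between strains:

$$P_{escadj} = \frac{P_{esc}}{P_{esc} + r\,(1 - P_{esc})}.$$

A 99% Wald interval uses the literal multiplier 2.575 (not 2.5758 — fidelity
to the procedure as printed):

$$P_{escadj} \pm 2.575\sqrt{\frac{P_{escadj}(1 - P_{escadj})}{X_i + X_a}},$$

clamped to $[0,1]$ for reporting; classification is unaffected by clamping
because the escapee rule uses a strict inequality at 0. A gene **escapes**
when the CI lower bound is $> 0$ (strict), $P_{escadj} > 0.05$ (strict), and
both $X_i$ and $X_a$ are at or above the depth threshold. The threshold is
the 5th percentile (linear interpolation between order statistics, the
`type = 7` quantile; the method is isolated in `depth_threshold()` and
configurable) of the pooled distribution of per-(gene × allele × cell type ×
age) X-linked normalized sums. Groups with $X_a$ below the threshold are
`not_assessable` — their age trends are not calculated rather than treated as
negative; groups with no assigned reads are `not_detected`.

Interpretation choices where the procedure is underdetermined, all isolated
behind arguments:

* **Normalization level.** "Normalized reads" is read as per-cell
  normalization to a common total (default 10,000), with one shared factor
  per cell across both alleles — the only choice that provably preserves
  within-cell allelic ratios. Escape proportions, adjusted values and
  statuses are invariant to the target (tested); only CI widths scale.
* **Bias-ratio scope.** The ratio is computed once from all cells
  (`bias_scope = "global"`); totals are described genome-wide without a
  per-group qualification. A `per_group` variant is exposed.
* **Depth-filter distribution.** The pooled (gene × cell type × age × allele)
  reading is adopted; alternatives (per-allele, per-cell-type pooling) would
  be straightforward variants of `depth_threshold()`. Because the pooled
  distribution is zero-filled, very sparse data can push the 5th percentile
  to 0, making the filter vacuous there — a faithful consequence of the rule,
  not a bug. Ties at the threshold pass ("lower than" is strict).
* **CI denominator.** Normalized sums, consistent with the inputs of
  $P_{esc}$.

The correction is a ratio-of-totals adjustment, not a per-read origin model,
so it is not exact: under one-directional flip bias $b$ the observed
proportion is $p(1-b)$ and the adjusted value works out to
$p(1+b)/(1+2pb)$, within 0.014 of truth for $b = 0.12$ over $p \in [0,1]$.
The tests assert recovery within 0.02 at deep counts.

# Aging transitions

Per (gene, cell type), young/old calls map to one category:
`not_assessable` if either call is not assessable or not detected (the state
propagates, never silently folds into inactive); `increased` iff escapee at
both ages **and** the old CI lower bound strictly exceeds the young CI upper
bound (CI separation alone never suffices); `maintained` for other
both-escapee pairs; `lost` (escapee → inactive); `new_escape` (inactive →
escapee); `inactive_both` otherwise. `summarize_sankey()` counts categories
per cell type with a conservation invariant; a gene counts as "detected" in
the weakest sense — any assigned reads in either age — which is configurable
via the stored statuses. Cross-cell-type patterns are `consistent:<category>`
or `mixed` after discarding uninformative records. Dot-plot statistics use
the fraction of cells with a nonzero Xi count and the mean of
log1p(normalized Xi count) over all group cells; the log1p-of-normalized mean
is this package's choice where the visual encoding was not numerically
defined. Paired escape changes use the standard paired two-tailed t test
(`stats::t.test`); zero-variance differences return a degenerate-test signal
instead of a p value.

# Differential expression and enrichment

DE features are (gene × allele) throughout — allele resolution is the point
of the design, at the cost of halving per-feature power. Counts are raw
integer pseudobulk sums per (cell type × sample); features are kept when
their total across samples is ≥ 10 **and** at least one sample holds ≥ 10
counts (the conjunctive reading makes both clauses of the filter constrain
and keeps the rule monotone in counts; an `every_sample` mode is exposed).
The negative-binomial Wald test on the age coefficient is delegated to
DESeq2 — the established pseudobulk count-model fitter — with `poscounts`
size factors (median-of-ratios over all-positive features can be undefined at
allele resolution), independent filtering and Cook's cutoff disabled so
Benjamini–Hochberg runs over all tested features within one cell-type
analysis (per-analysis families, not global). Significance is strict:
adjusted p < 0.05 and log2FC > 0.1 or < −0.1. Chromosome enrichment is a
Pearson χ² (1 df, no continuity correction — the common default for large
counts, configurable in principle) on significant vs expressed features, X vs
autosomes or one named autosome. Cell-type categories follow the ordered
rules: neuronal (≥ 2 of 5 neuronal types, ≤ 1 glial), glial (≥ 2 of 4 glial,
≤ 1 neuronal), multiple (≥ 2 types; direction conflicts here are excluded as
discordant), cell-type-specific.

# The synthetic-data generator

The generator emulates the study conditions, not any particular dataset: it
is the package's substrate for calibration and recovery testing.

Per cell and gene: total reads ~ NB(mean = depth × library factor ×
normalized gene rate, dispersion 0.3); allele-assignable reads are a binomial
thinning at the informative-read fraction; the strain of origin is binomial
with castaneus probability 0.5 (autosomes) or the gene's true escape
probability (X); mapping bias then flips castaneus-origin reads to the
reference independently with probability $b$. Flips are one-directional
toward the reference because the observed bias is toward the better-assembled
reference genome. Under this model the expected observed castaneus fraction
is $p(1-b)$ (the nominal denominator $p(1-b) + (1-p) + pb$ is identically 1 —
verified by enumeration in the tests), and the autosomal reference share is
$(1+b)/2$: the default $b = 0.12$ reproduces the canonical 56/44 autosomal
split exactly in expectation.

Default study-scale conditions (`default_sim_config()`): 6 hippocampal cell
types × 2 ages × 4 samples × 165 cells = 7,920 cells; 1,800 autosomal + 200
X genes; mean depth 2,000 reads/cell (typical snRNA-seq UMI scale);
informative-read fraction 0.3 (order of read length over the ~264 bp SNP
spacing, discounted for UMI collapsing); log-normal per-cell library factors
(sdlog 0.35) and per-(sample, gene) replicate noise (sdlog 0.1) so pseudobulk
replicates vary; per-gene log-normal expression rates (sdlog 1) with
per-cell-type modulation (sdlog 0.5). Baseline escape fraction 0.05 — the
middle of the 3–7% estimated for mouse — with escape probabilities uniform on
[0.08, 0.30]; baseline escapees are the first X genes by id so that
configurations can reference them. An Xist-like gene (rate 30, castaneus
probability 0.95) mimics the dominant Xi transcript and pulls the pooled
X-linked reference share toward the ~92/8 split seen in such designs (the
generator lands near 87/13, within the calibration band of > 85% reference).
Planted aging effects sit on genes boosted to rate 20 ("deep counts", so the
recovery criteria measure the method rather than sampling noise): 8
new-escape genes at probabilities 0.15–0.30, 4 lost-escape, 3
increased-escape (old probability 0.45–0.55, clearly CI-separated from any
young value ≤ 0.30), 6 autosomal active-allele log2 fold changes of ±2, and
2 Xi-allele fold changes of +2.

What the generator does **not** emulate — and hence what passing tests do not
show about real data: doublets and ambient RNA, per-gene SNP density (one
global informative fraction), positional/read-level structure, cell-type
abundance differences, bidirectional mapping bias, and any correlation
structure among genes. In particular, because bias only flips castaneus reads
toward the reference, truly silent X genes never receive Xi reads, so the
false-escapee control is conservative relative to data with reverse-direction
misassignment.

# Numerical and design notes

* Degenerate inputs: zero-total cells are dropped with a warning; an
  all-zero dataset, a 0-X-gene dataset (at the escape stage), empty
  enrichment margins, single-age DE designs and < 2-pair t tests all raise
  typed errors rather than producing numbers.
* Determinism: one integer seed drives truth construction (seed) and count
  sampling (seed + 1); identical configs give byte-identical bundles, and
  the bundle writer emits entries in a fixed order (Matrix Market integer
  coordinate format with the on-disk genes × cells orientation recorded in a
  header comment).
* Problem sizes in the test suite were chosen to make binomial/NB sampling
  error small relative to the asserted tolerances: 10,000 replicates for CI
  coverage (Monte-Carlo s.e. ≈ 0.1 pp against an exact enumeration oracle),
  ≥ 10⁴ pooled reads for proportion recovery, 48 planted gene × cell-type
  combinations each for escape-transition and fold-change recovery.
* The command-line surface is deliberately thin: the exported functions are
  the interface, `run_pipeline()` orchestrates the stages with a manifest
  and report, and `inst/scripts/run_pipeline.R` wraps it for shell use.

# Limitations

The Wald interval undercovers slightly near proportion boundaries and small
depths (the escapee rule's strict CI-lower-bound > 0 already guards the
p ≈ 0 regime); an exact or score interval would change calls near the
threshold. The bias correction assumes autosomal balance and a single global
bias factor; gene-specific bias (e.g. SNP-poor regions) is not modeled. DE
results are conditional on DESeq2's dispersion moderation; numerical parity
with other NB-Wald implementations is not a goal and the tests assert
simulation properties (type-I control, sign and magnitude recovery) instead.
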