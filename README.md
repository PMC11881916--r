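# xciescape

Allele-specific analysis of escape from X-chromosome inactivation (XCI) in
single-nucleus RNA-seq, across cell types and age.

## The problem

In XX cells one X chromosome is silenced (the inactive X, Xi), but a minority
of X-linked genes *escape* silencing and keep expressing from the Xi. In an
F1-hybrid mouse (*M. musculus* × *M. castaneus*) engineered for nonrandom XCI,
the castaneus X is always the Xi, so any read that maps to the castaneus
genome at an X-linked gene is direct evidence of escape. `xciescape`
implements the quantitative machinery this design calls for:

* **Escape quantification.** For each gene in each (cell type × age) group,
  with Xa and Xi the normalized read sums assigned to the two strain genomes,

  P_esc = Xi / (Xi + Xa)

  corrected for mapping bias toward the reference genome using the global
  autosomal strain ratio A_Tcast / A_Tmus:

  P_escadj = P_esc / (P_esc + (A_Tcast / A_Tmus) · (1 − P_esc))

  with a 99% Wald confidence interval

  P_escadj ± 2.575 · sqrt(P_escadj (1 − P_escadj) / (Xi + Xa)).

  A gene is an **escapee** when the CI lower bound is strictly above 0, the
  adjusted proportion is strictly above 0.05, and both allelic read sums are
  at or above the pooled 5th percentile of X allelic reads.
* **Aging transitions.** Per (gene, cell type), young/old escapee calls are
  classified as increased (escapee at both ages with disjoint CIs),
  maintained, lost, or new escape, plus Sankey-style counts, cross-cell-type
  consistency and paired t tests of escape change.
* **Differential expression.** Allele-level pseudobulk counts per
  (cell type × sample) are tested old vs young with a negative-binomial Wald
  test (via DESeq2), significance at adjusted p < 0.05 and |log2FC| > 0.1,
  and X-vs-autosome enrichment by Pearson χ².
* **Synthetic data.** A calibrated generator produces allele-resolved counts
  with planted escapees, aging effects, mapping bias and ground-truth tables,
  so every stage is testable without sequencing data.

Intended users: computational biologists analysing allele-resolved
single-cell/nucleus counts from hybrid crosses, and method developers who
need a transparent, fully tested reference implementation of escape calling.

## Worked example

```r
library(xciescape)

cfg <- sim_config(n_cell_types = 2, cells_per_type_per_sample = 60,
                  n_samples_per_age = 3, n_autosomal_genes = 200, n_x_genes = 40,
                  xist_like = TRUE,
                  aging_effects = list(aging_effect("geneX0005", "new_escape", 0.25)),
                  seed = 1)
sim <- simulate_study(cfg)
sim$dataset
#> allele_dataset: 720 cells x 241 genes
#>   X-linked genes: 41 | autosomal genes: 200
#>   assigned reads: xa-strain 277764 | xi-strain 181746
#>   cell types: CA1, CA3
#>   age groups: old=360, young=360

calls <- call_escape(sim$dataset)
calls
#> escape_calls: 41 X genes x 3 cell-type levels x 2 ages
#>   bias ratio 0.7866 | depth threshold(s) 0.00, 0.00
#>           age
#> status     old young
#>   escapee   12     9
#>   inactive 111   114

tr <- classify_transitions(calls)
subset(as.data.frame(tr), gene_id == "geneX0005" & cell_type == "all")[,
  c("gene_id", "young_status", "old_status", "old_p_escadj", "category")]
#>     gene_id young_status old_status old_p_escadj   category
#> 5 geneX0005     inactive    escapee    0.2639594 new_escape
```

The estimated bias ratio 0.7866 is close to its design value
(1 − b)/(1 + b) = 11/14 ≈ 0.786 for flip bias b = 0.12 — the autosomal 56/44
reference/alternate split. The gene planted to start escaping in old age
(true old escape probability 0.25) is silent in young, called an escapee in
old with adjusted escape 0.264, and classified `new_escape`. `run_pipeline()`
wraps the same steps (plus DE and enrichment) into TSV outputs with a
manifest and plain-text report; `plot(calls)` draws the per-gene CI panels.

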