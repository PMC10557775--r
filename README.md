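# circadiff

Differential circadian rhythmicity analysis for two-group time-course data.

`circadiff` is built for experiments in which the same system is driven
under two conditions — e.g. cultured fibroblasts synchronized with serum
from young versus old donors, sampled every 2 h across a circadian day —
and the question is which genes oscillate, in which condition, and how
their rhythm parameters change. It also covers the matching subject-level
analysis of wearable streams (actigraphy counts, heart rate).

## What it computes

All estimation rests on the fixed-period single-component cosinor
(period τ = 24 h, ω = 2π/τ):

```
y(t) = M + A·cos(ω(t − t_peak)) + ε
```

with MESOR `M` (rhythm-adjusted mean), amplitude `A`, and peak hour
(acrophase) `t_peak`. On top of it the package provides:

* **`cosinor_fit()`** — OLS cosinor per series; rhythmicity by the
  zero-amplitude F-test; `tidy()`, `glance()`, `autoplot()` methods.
* **`fit_joint_cosinor()` / `diff_rhythm_table()`** — the joint two-group
  model `y = (k + k₁G) + (α + α₁G)·cos(ω(t − (φ₀ + φ₁G)))`, giving Wald
  tests for the old-minus-young differences in MESOR (k₁), amplitude (α₁)
  and phase (φ₁, hours; positive = delay), with Benjamini–Hochberg
  q-values per parameter family across genes.
* **`fit_four_models()` / `classify_matrix()`** — four-model rhythmicity
  classification (rhythmic in both / young only / old only / neither) by
  normalized BIC (Schwarz) weights, class assigned when the best weight
  exceeds 0.75.
* **`categorize_genes()` / `export_subsets()`** — the q-value, sign and
  |log₂FC| rules that turn the above into seven enrichment-ready gene
  lists (loss/gain of rhythmicity, MESOR up/down, phase advance/delay,
  rhythmic-in-both).
* **`heatmap_normalize()`** — three-round display normalization
  (per-serum mean normalization → replicate collapse → per-group z-score).
* **`ranksum_exact()` and `kuiper_two_sample()`** — group tests for
  subject-level cosinor parameters: exact Wilcoxon rank-sum for MESOR and
  amplitude, and the circular two-sample Kuiper test (V = D⁺ + D⁻,
  relabeling bootstrap with p = (b+1)/(n_boot+1)) for peak hours.
* **`simulate_expression()` / `simulate_wearable()`** — synthetic-data
  generators emulating the two-group serum time-course design
  (2 groups × 4 sera × 14 timepoints at 2 h on the log10(1+count) scale)
  with planted ground truth, so the whole pipeline is testable offline.
* **`run_transcriptome()` / `run_wearable()`** — end-to-end drivers that
  write all result tables with seed/config-hash headers.

## Worked example

```r
library(circadiff)

sim     <- simulate_expression(sim_config(n_genes = 500, seed = 42))
diff    <- diff_rhythm_table(sim$expression, sim$samples)
weights <- classify_matrix(sim$expression, sim$samples)
table(weights$class)
#>         both      neither     old_only unclassified   young_only
#>           50          360           26           13           51
```

The generator planted 50 both-rhythmic, 50 young-only and 25 old-only
genes among 375 arrhythmic ones; the BIC-weight classifier recovers those
proportions, with a handful of genes left `unclassified` where no model
reaches weight 0.75. Zooming into one gene rhythmic in both groups:

```r
g <- sim$truth$gene_id[sim$truth$class == "both"][1]
y <- as.numeric(sim$expression[sim$expression$gene_id == g, -1])
fit_joint_cosinor(sim$samples$time_h, y, sim$samples$group)
#> Joint two-group cosinor fit (period 24 h, n = 112)
#>   MESOR      young 2.844  diff (old-young) -0.1329  p = 0.00246
#>   amplitude  young 0.5243  diff +0.02012  p = 0.736
#>   peak hour  young 23.82  diff -0.7742 h  p = 0.0805
```

The planted truth for this gene was MESOR 2.83 → 2.72 (a real −0.11 shift,
detected at p ≈ 0.002), a shared amplitude of 0.53 (no amplitude change,
p ≈ 0.74), and peaks at 23.8 h vs 23.0 h (a −0.8 h advance, borderline at
p ≈ 0.08). Categorization and gene-list export then follow:

```r
rec <- categorize_genes(diff, weights, q_cut = 0.05)
export_subsets(rec, "subsets/")       # seven one-ID-per-line files
autoplot(cosinor_fit(sim$samples$time_h[sim$samples$group == "young"],
                     y[sim$samples$group == "young"]))
```

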