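# chromdiverge

Chromatin accessibility differences between two species can be caused
locally (*cis*: a sequence change at the regulatory element) or at a
distance (*trans*: a change in the nuclear environment of transcription
factors that open chromatin).  F1 hybrids separate the two, because
both parental alleles share one nucleus: a *cis* change reproduces the
parental difference as allelic imbalance inside the hybrid, while a
*trans* change equalizes the hybrid alleles even though the parents
differ.

`chromdiverge` implements this inference for ATAC-seq counts from two
same-species crosses and one hybrid cross (with hybrid reads split by
parent-of-origin allele), across developmental stages with replicates.
It is aimed at evolutionary and regulatory genomicists who have a
peak-by-sample count table and want per-peak, per-stage calls of:

* **inheritance mode** — conserved, additive, maternal/paternal
  dominant, over/underdominant — from the hybrid total signal versus
  the two parents, and
* **regulatory mode** — conserved, cis, trans, cis+trans, cis×trans,
  compensatory — from three statistics: the parental log2 ratio
  `L_P`, the hybrid allelic log2 ratio `L_H`, and the ratio-divergence
  (trans) test `z = (L_P − L_H) / sqrt(se_P² + se_H²)`,

plus the **evolutionary effect size** `ES = log2(mean_mat/mean_pat)`
(pseudocounted), peak–gene association statistics (chi-squared with
Pearson residuals, Fisher exact, Welch/KS/ANOVA–Scheffé), FRIP scores,
and a negative-binomial simulator with known cis/trans ground truth so
every stage of the pipeline is testable without sequencing data.
Under the hood, per-peak group means are compared with moderated
plug-in negative-binomial Wald tests, BH-adjusted within each
(contrast, stage) family.

## Worked example

Simulate a realistic experiment (1,200 peaks, three stages, three
replicates per cross, depth 300, dispersion 0.05, 60% conserved peaks),
preprocess, and classify:

```r
library(chromdiverge)

truth <- make_truth(1200, seed = 1)          # default mode proportions
sim   <- simulate_counts(truth, simulation_design(seed = 2))
x     <- cpm_filter(sim$counts, sim$samples) # CPM >= 3 in >= 1/3 of libraries
x     <- normalize_counts(x, sim$samples)    # median-of-ratios size factors
x
#> atac_counts: 1200 peaks x 45 samples
#> size factors: set

res <- classify_all(x, sim$samples, alpha = 0.05)
subset(res$tallies, stage == "blastula" & classification == "regulatory")
#>     stage classification           mode   n proportion
#>  blastula     regulatory      conserved 668 0.55666667
#>  blastula     regulatory            cis 186 0.15500000
#>  blastula     regulatory          trans 168 0.14000000
#>  blastula     regulatory cis_plus_trans  32 0.02666667
#>  blastula     regulatory    cis_x_trans  39 0.03250000
#>  blastula     regulatory   compensatory  44 0.03666667
#>  blastula     regulatory      ambiguous  63 0.05250000
```

The tallies recover the generating proportions (60/15/15/3/3/4 percent)
closely; comparing calls against the simulated truth:

```r
m <- merge(res$calls, truth[, c("peak_id", "true_regulatory_mode")])
mean(m$regulatory_mode == m$true_regulatory_mode)
#> [1] 0.931
```

so 93% of (peak, stage) calls match the ground truth at these depths.
`count_mode_switches()`, `rank_by_effect()`, `nearest_gene()`,
`peaks_focused_test()` / `gene_focused_test()` /
`regmode_focused_test()`, `category_enrichment()` and `peak_density()`
take the analysis through mode switching, effect-size ranking and the
peak–gene association landscape.  `run_pipeline()` executes the whole
chain from a YAML config and writes every stage's TSV outputs plus a
JSON report and manifest; `inst/scripts/run-pipeline.R` wraps it for
the shell.

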