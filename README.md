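# hoxmeth

Tools for studying HOX-locus DNA methylation in IDH-mutant,
1p/19q-codeleted oligodendroglioma. Older patients with this tumor do
worse, and part of that risk tracks a molecular axis: methylation of the
*HOXD12* gene body. `hoxmeth` implements, as tested and reusable R
functions, the analysis machinery such a study needs:

* **Gene-body methylation signature** — per-sample signature
  `s = (β₁ + β₂ + β₃)/3` over the three *HOXD12* gene-body probes
  (cg23130254, cg03964958, cg03371669); hypermethylation threshold
  `t = (mean s | expression-negative + mean s | expression-positive)/2`,
  with the call *hypermethylated* iff `s > t` (strict). With group means
  0.3034 and 0.4121 the reported (truncated) threshold is **0.3577**.
  Includes the three-way probe screen (age Mann–Whitney, log-rank,
  multivariate Cox; all p < 0.05) that singles out the gene-body probes.
* **Pan-HOX consensus clustering** — pool gene-body probes of the 39
  HOXA–HOXD genes across cohorts, batch-adjust on the logit(β) scale,
  run many seeded 2-D UMAP embeddings with 2-means partitions, align
  labels across runs, and exclude samples whose *switch frequency*
  (fraction of runs disagreeing with the sample's majority label)
  strictly exceeds 10%. Differential methylation per probe (Welch t on
  logit β, BH-FDR) aggregated per gene and per HOX locus.
* **Single-nucleus cell states** — cluster nuclei; infer arm-level
  relative dosage from meta-cell expression against reference clusters;
  call a cluster *neoplastic* when 1p/19q loss with intact 1q/19p is
  universal (≥ 95% of meta-cells), excluding clusters where the evidence
  is mixed; type non-neoplastic clusters by marker panels; score cell
  states (OPC-like, Astro-like, Cycling, RE) with bin-matched control
  genes; assign states by a permutation test (default 100,000
  permutations, p floor 1/(n+1) ≈ 1e−5) gated at FDR < 0.0125 = 0.05/4,
  with "gradient" otherwise; stemness/lineage scores and sparse-marker
  prevalence contrasts.
* **Cohort statistics** — log-rank, Cox with sequential VIF > 10
  screening, Fisher's exact, Mann–Whitney, Pearson, BH-FDR,
  Shapiro–Wilk, Hartigan's dip (Monte Carlo calibrated); rule-based
  calls: 15q loss (more than half of 15q genes lost), *CDKN2A*
  homozygous deletion (GISTIC −2 in ≥ 2 of 3 versions), adjuvant therapy
  (labeled "ADJUVANT", or first treatment within 244 days of diagnosis).
* **Synthetic cohorts with planted truth** — seeded generators for a
  bulk cohort (bimodal age, logistic age→status link, group-specific
  probe Betas, exponential survival with a planted hazard ratio), a
  multi-batch 422-probe pan-HOX matrix with two planted clusters plus
  ambiguous samples, and single-nucleus counts with planted 1p/19q
  dosage loss, cell-type and cell-state programs, and a sparse
  HOXD12-like marker. Everything downstream is tested against these.

## Worked example

Generate a TCGA-sized synthetic cohort, compute signature calls, and test
their survival association:

```r
library(hoxmeth)
library(dplyr)

cohort <- gen_bulk_cohort(bulk_cohort_truth(n = 171, seed = 1))
calls  <- classify_signature(cohort$beta, cohort$expression)
calls
#> Signature calls: threshold 0.3573 (reported 0.3572)
#> # A tibble: 171 × 5
#>   sample_id signature threshold hypermethylated expression_status
#>   <chr>         <dbl>     <dbl> <lgl>           <chr>
#> 1 S0001         0.397     0.357 TRUE            positive
#> 2 S0002         0.257     0.357 FALSE           negative
#> 3 S0003         0.394     0.357 TRUE            positive
#> # ...
```

The threshold is the midpoint of this cohort's two status-group signature
means (here 0.3573; every cohort re-derives its own). Hypermethylated
patients die faster, and the effect survives adjustment for age and
grade:

```r
clin <- left_join(cohort$clinical,
                  select(as.data.frame(calls), sample_id, hypermethylated),
                  by = "sample_id")
logrank_test(clin, group = "hypermethylated")
#>   statistic    df        p    n1    n2 events1 events2
#> 1      66.8     1 3.03e-16    93    78      34      70

fit <- cox_ph(mutate(clin, hyper = as.integer(hypermethylated)),
              covariates = c("hyper", "age", "grade"))
tidy(fit)
#>   term  estimate    hr conf.low conf.high statistic       p.value
#> 1 hyper   1.42    4.14    2.62       6.55      6.09 0.00000000110
#> 2 age     0.0101  1.01    0.995      1.03      1.36 0.175
#> 3 grade   0.291   1.34    0.884      2.02      1.37 0.169
```

So in this synthetic cohort hypermethylation carries a hazard ratio of
4.1 (95% CI 2.6–6.6) independent of age and grade — the planted
association the generator encodes. `autoplot()` methods exist for
signature calls, consensus results and arm-dosage profiles, and
`tidy()`/`glance()` for fitted objects.

The pan-HOX and single-nucleus pipelines run the same way from generated
data; see the methods vignette (`vignettes/hoxmeth-methods.Rmd`) for the
models, parameter defaults and design decisions.

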