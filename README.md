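# crpmr

Two-sample Mendelian randomization (MR) analysis of the causal effect of
circulating C-reactive protein (CRP) on type 2 — and, as a specificity
check, type 1 — diabetes mellitus, working entirely from GWAS summary
statistics. The package is aimed at genetic epidemiologists who want the
full analysis (instrument selection, harmonization, pooling, heterogeneity,
pleiotropy and sensitivity diagnostics) reproducible offline: the published
per-variant CRP/T2DM and CRP/T1DM association tables ship as plain-text
fixtures, and a seeded synthetic-data generator provides datasets with
known causal effects for validation.

## The method

Each genetic variant *j* that robustly predicts CRP gives a **Wald ratio**
estimate of the causal effect of CRP (X) on disease (Y):

    β̂_XY,j = β_ZY,j / β_ZX,j ,    se(β̂_XY,j) = SE_ZY,j / |β_ZX,j|

where β_ZX is the per-allele effect on CRP and β_ZY the per-allele log
odds ratio of disease (delta-method SE, exposure-side uncertainty
ignored). Instruments must pass three filters: exposure association at
genome-wide significance (p < 5×10⁻⁸), no direct outcome association
(variants with outcome p < 0.05 are removed), and LD pruning (greedy,
keep-best-p, pairwise r² < 0.2).

The ratios are pooled by the **penalized robust inverse-variance weighted
(IVW)** estimator. Plain IVW is the precision-weighted mean with weights
w_j = β_ZX,j² / SE_ZY,j² — algebraically, the no-intercept weighted
regression of β_ZY on β_ZX. Penalization multiplies each weight by
min(1, 20·p_j), where p_j is the upper-tail χ²₁ probability of the
variant's heterogeneity contribution Q_j = w_j(β̂_XY,j − β̂_IVW)²;
robustness replaces the weighted mean with a Tukey-bisquare (c = 4.685)
iteratively reweighted fit. **Cochran's Q** quantifies heterogeneity,
**MR-Egger regression** (weighted fit with a free intercept after
orienting all β_ZX ≥ 0) estimates average directional pleiotropy as its
intercept, and **leave-one-out** re-estimation flags single-variant
dominance.

## Worked example

```r
library(crpmr)
report <- run_mr_pipeline(crp_fixture_path("crp_gwas"),
                          crp_fixture_path("t2dm_gwas"))
print(report)
```

```
Two-sample MR analysis report
  instruments: 4 kept, 1 excluded
Pooled MR estimate (ivw_penalized_robust), 4 variant(s)
  log-OR 0.108131 (SE 0.048900)
  OR 1.114194, 95% CI 1.012366 to 1.226265, p = 0.027
  penalty factors < 1: rs1183910 = 0.0344
Cochran's Q = 15.2615, df = 3, p = 0.00161
MR-Egger regression, 4 variants
  intercept 0.0178 (SE 0.0264), 95% CI -0.0959 to 0.1316, p = 0.57
  slope     -0.0066 (SE 0.1808), 95% CI -0.7845 to 0.7713, p = 0.974
```

Reading this: of the five genome-wide-significant CRP variants, rs4420638
is removed because it is itself associated with T2DM (p = 2×10⁻⁷), leaving
four instruments. Their ratio estimates are heterogeneous (Q = 15.3 on
3 df), driven by rs1183910, whose weight the penalization cuts ~29-fold.
The pooled odds ratio of 1.114 per unit CRP exposure (CI excluding 1)
indicates that genetically elevated CRP increases T2DM risk, while the
Egger intercept of 0.018 warns that some average directional pleiotropy
may remain. Running the same pipeline against the T1DM table
(`crp_fixture_path("t1dm_gwas")`, 3 instruments) gives OR 1.019 with a CI
spanning 1 — no evidence of an effect on type 1 diabetes.

The numbered scripts under `analysis/` run the complete T2DM and T1DM
analyses and a simulation study verifying, on synthetic summary statistics
with known truth, that IVW recovers a causal effect of 0.11 essentially
unbiasedly and that under directional pleiotropy the Egger intercept
recovers the pleiotropy while plain IVW is biased; each writes its tables
under `results/`.

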