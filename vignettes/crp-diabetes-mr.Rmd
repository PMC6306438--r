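---
title: "Methods: penalized robust IVW Mendelian randomization of CRP and diabetes"
author: "crpmr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: penalized robust IVW Mendelian randomization of CRP and diabetes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crpmr)
```

## The causal question and the instrumental-variable model

Observational associations between circulating C-reactive protein (CRP)
and type 2 diabetes (T2DM) are confounded by adiposity, insulin
resistance and other inflammatory traits. Mendelian randomization sides
with the genotype: because alleles are assigned at gametogenesis,
variants that raise CRP are (to first order) independent of those
confounders, and any effect they transmit to T2DM risk must flow through
CRP — provided they satisfy the three instrumental-variable conditions:
association with CRP, independence from confounders of the CRP–T2DM
relation, and no effect on T2DM except through CRP (exclusion
restriction).

In the two-sample design the variant–exposure associations
$(\hat\beta_{ZX,j}, \mathrm{SE}_{ZX,j})$ and variant–outcome associations
$(\hat\beta_{ZY,j}, \mathrm{SE}_{ZY,j})$ come from non-overlapping GWAS
samples and are combined purely at the summary level. Under a linear
causal effect $\theta$ and a valid instrument $j$,
$\beta_{ZY,j} = \theta\,\beta_{ZX,j}$, so each variant supplies a Wald
ratio $\hat\theta_j = \hat\beta_{ZY,j} / \hat\beta_{ZX,j}$.

## Instrument selection

Three filters, applied in order by `select_instruments()`, each logged
per variant:

1. exposure significance: keep variants with CRP p-value strictly below
   $5\times10^{-8}$;
2. outcome-association exclusion: remove variants with outcome p-value
   strictly below $0.05$ — such a variant plausibly acts on the disease
   through another path and would violate the exclusion restriction.
   Strict inequality matters at the margin: on the shipped T2DM table it
   removes rs4420638 ($p = 2\times10^{-7}$) while retaining rs1183910
   ($p = 0.059$);
3. LD pruning: correlated instruments double-count evidence, so
   candidates are ranked by ascending exposure p-value (ties broken
   lexicographically by rsID) and accepted greedily iff their $r^2$ with
   every already-accepted candidate is below `r2_max` (default 0.2).

The pruning rule is deterministic and guarantees that all kept pairs
respect the bound, that the strongest instrument always survives, and
that no excluded candidate could be re-admitted. It does **not**
guarantee monotonicity in `r2_max`: relaxing the threshold can admit a
higher-ranked candidate that then displaces several lower-ranked ones, so
the kept set (occasionally even its size) is not nested across
thresholds. The four distinct-locus CRP instruments are mutually
uncorrelated, so any sensible threshold is inert for the shipped data;
for new data the threshold, like both p-value cutoffs, is an explicit
argument of `select_instruments()` and `run_mr_pipeline()`.

Harmonization (`harmonize_tables()`) aligns the outcome to the exposure's
effect allele, negating the outcome beta when the allele pair is listed in
the opposite orientation. Palindromic variants (A/T, C/G) are kept with a
warning by default — the shipped instruments contain none, and inferring
strand from allele frequency is out of scope — with `drop` and `error`
policies available. Variants present in only one table are excluded with
a logged reason, never an error.

## Wald ratios and their standard errors

`wald_ratio()` uses the first-order delta-method standard error
$\mathrm{SE}(\hat\theta_j) = \mathrm{SE}_{ZY,j} / |\hat\beta_{ZX,j}|$,
which ignores exposure-side sampling error (the usual
no-measurement-error convention for strong instruments) and makes the
inverse-variance weight $w_j = \hat\beta_{ZX,j}^2 / \mathrm{SE}_{ZY,j}^2$.
An alternative sometimes written for this quantity,
$\mathrm{SE}_{ZY}/\mathrm{SE}_{ZX}$, is dimensionally inconsistent — it
does not scale with the exposure effect, and pooling with it cannot
reproduce the reference estimates for these data. It is available behind
`se_method = "ratio_of_se"` purely so its consequences can be audited;
nothing else in the package uses it.

## The IVW family

Plain IVW is the precision-weighted mean
$\hat\theta = \sum_j w_j \hat\theta_j / \sum_j w_j$, identical (and
asserted in the tests to $10^{-12}$) to the no-intercept weighted
regression of $\hat\beta_{ZY}$ on $\hat\beta_{ZX}$ with weights
$\mathrm{SE}_{ZY}^{-2}$. Two refinements, separately switchable through
`mr_pool()`'s method argument, address invalid instruments:

* **Penalization.** With reference $\hat\theta_{IVW}$ (the unpenalized,
  non-robust fit), each variant's heterogeneity contribution is
  $Q_j = w_j(\hat\theta_j - \hat\theta_{IVW})^2$ and its weight is
  multiplied by $\min(1,\ 20\,p_j)$, $p_j$ the upper-tail $\chi^2_1$
  probability of $Q_j$. Variants consistent with the consensus
  ($p_j \ge 0.05$) are untouched; outliers lose weight smoothly rather
  than by a hard exclusion. The constant 20 and the IVW (rather than
  Egger-residual) reference are the package's convention; on the T2DM
  instruments this penalizes rs1183910 by a factor 0.034.
* **Robustness.** The weighted mean is replaced by an iteratively
  reweighted least-squares fit with the Tukey bisquare loss, tuning
  $c = 4.685$ (95% Gaussian efficiency). Residuals are standardized by
  the square root of the current weights; the scale is re-estimated each
  iteration as the **zero-centered** median absolute deviation
  (consistency constant 1.4826) of the standardized residuals.
  Zero-centering is deliberate: residuals of a no-intercept fit are
  centered at zero by construction, and with as few as three or four
  instruments a median-centered MAD measures spread around whichever
  residual happens to be the median, badly misjudging the scale (it also
  fails to reproduce the reference T1DM estimate, where the three
  residuals are strongly asymmetric). Iteration stops when no coefficient
  moves by more than $10^{-10}$, with a 100-iteration cap (non-convergence
  warns and returns the last iterate with a flag). If the scale collapses
  to zero — a majority of points fits exactly — the exactly-fitting points
  keep full weight and any remaining point is treated as a gross outlier.

The headline `ivw_penalized_robust` method composes the two: penalty
factors from the IVW reference, then the robust fit on the penalized
weighted problem.

**Standard errors and intervals.** The pooled SE is fixed-effect,
$(\sum_j w_j f_j)^{-1/2}$, inflated by $\max(1, \hat\sigma)$ for the
penalized/robust variants — the multiplicative random-effects convention,
with $\hat\sigma$ the robust residual scale (or the classical weighted
residual SD for `ivw_penalized`). Never deflated: homogeneous data revert
to the fixed-effect SE. CIs use the normal 1.959964 multiplier; MR-Egger
uses $t_{n-2}$ throughout. This convention is conservative relative to
sandwich-type robust-regression SEs, which can be markedly narrower on
these data; point estimates, not interval widths, are the reproduction
target, and the per-variant penalty factors, robust weights and $Q_j$ are
all exposed (`forest_table()`) so any interval convention can be applied
downstream. With a single instrument the IVW family returns that
instrument's Wald estimate unchanged; MR-Egger refuses fewer than 3
variants, and Cochran's Q fewer than 2.

## MR-Egger regression

`egger_regression()` first orients every instrument so
$\hat\beta_{ZX,j} \ge 0$ (negating both betas where needed — the result
is invariant to the original allele orientation, which the tests assert
for arbitrary subsets), then fits
$\hat\beta_{ZY,j} = \theta_0 + \theta_1 \hat\beta_{ZX,j}$ with weights
$\mathrm{SE}_{ZY,j}^{-2}$, optionally multiplied by the same penalty
factors and/or under the same bisquare loss. Under the InSIDE condition
(direct effects independent of instrument strength) the slope $\theta_1$
is a pleiotropy-adjusted causal estimate and the intercept $\theta_0$
estimates the average directional pleiotropic effect; an intercept
bounded away from zero flags directional pleiotropy. An exactly-affine
configuration is recovered exactly (tested), and a design with all
oriented exposure betas equal is rejected as degenerate.

## Sensitivity analysis

`leave_one_out()` refits the requested estimator on every size-$(n-1)$
subset, recomputing penalty factors within each subset (each row is the
estimate one would have obtained had that variant never been selected),
and reports the influence $|\hat\theta_{-j} - \hat\theta_{full}|$ on the
log-OR scale plus the OR-scale difference for display. On the T2DM
instruments the two largest influences belong deterministically to
rs4537545 and rs7553007 — the two precise, mutually consistent
instruments that carry the pooled estimate — while removing the heavily
penalized rs1183910 moves the penalized estimate by less than 0.01
log-OR.

## The synthetic-data generator

`simulate_summary_stats()` draws, per variant, a true exposure effect
$b_j \sim N(0.15, 0.05^2)$ (resampled until $|b_j| > 10^{-3}$ so every
Wald ratio is defined — a generator constraint, documented rather than
silently fixed in the estimators), a direct effect
$\alpha_j \sim N(\mu_\alpha, \sigma_\alpha^2)$ independent of $b_j$
(InSIDE holds by construction), and observed summaries
$\hat\beta_{ZX,j} = b_j + N(0, 0.015^2)$,
$\hat\beta_{ZY,j} = \theta b_j + \alpha_j + N(0, 0.015^2)$. The defaults
($\theta = 0.11$, effect magnitudes and SEs like the shipped CRP
instruments) emulate the real analysis; outcome effects are simulated
directly on the log-OR scale, since a two-sample analysis consumes
nothing else. All draws for variant $j$ precede those for variant
$j+1$ in a single seeded stream, so growing $J$ preserves a common
prefix — convenient for debugging scaling behaviour. For the
directional-pleiotropy scenarios $\sigma_\alpha$ is fixed at 0.005: a
small spread about $\mu_\alpha = 0.02$ that keeps the scenario
recognisably "directional" while exercising the InSIDE independence.

What the generator deliberately does **not** emulate: LD between
instruments, sample overlap between the two GWAS, winner's-curse
selection of instruments, allele-frequency-dependent power, or
individual-level binary-trait artefacts. Passing recovery tests therefore
demonstrates correctness of the estimators under the stated model, not
robustness to those real-data complications.

`recovery_study()` wraps simulation → harmonization → selection (with
permissive thresholds, so every simulated variant is an instrument) →
estimation over a scenario grid and reports bias, empirical SE, RMSE,
95% CI coverage and rejection rate, with per-replicate estimates kept as
an attribute. Validation problem sizes were chosen once: $J = 50$–$100$
instruments, 200 replicates for bias/ordering checks and 500 for the
null-coverage check — large enough that the Monte-Carlo error on a bias
of interest (~0.001) is an order of magnitude below the 0.01 assertion
band, small enough that the whole suite runs in seconds.

## Known limitations

* The delta-method SE ignores exposure-side error; with weak instruments
  this understates per-variant uncertainty (no F-statistic correction is
  implemented, by scope).
* Penalization and robustness guard against outlying instruments, not
  against correlated pleiotropy violating InSIDE; the Egger intercept is
  itself reported with only $n-2$ degrees of freedom and is very
  imprecise at $n = 4$.
* P-values in the IVW family use the normal reference and the
  conservative SE convention above; on few instruments they should be
  read qualitatively. CI/SE conventions differ across MR software; point
  estimates agree.
* The exposure is treated as a single homogeneous trait on the scale of
  its GWAS betas ("per unit CRP exposure"); no multivariable or
  bidirectional extension is provided.
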