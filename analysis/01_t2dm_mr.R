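#!/usr/bin/env Rscript
# Causal effect of CRP on type 2 diabetes from the five published CRP
# instruments: selection, penalized robust IVW pooling, heterogeneity,
# MR-Egger pleiotropy check, and leave-one-out sensitivity.
# Writes results/t2dm/.

library(crpmr)

out_dir <- "results/t2dm"

report <- run_mr_pipeline(
  exposure = crp_fixture_path("crp_gwas"),
  outcome  = crp_fixture_path("t2dm_gwas"),
  methods  = c("ivw_penalized_robust", "ivw", "ivw_penalized", "ivw_robust")
)

print(report)
write_mr_report(report, out_dir)

pr <- report$pooled$ivw_penalized_robust
cat(sprintf("\nHeadline: OR %.6f (95%% CI %.6f to %.6f) per unit log-CRP, %d instruments\n",
            pr$or_, pr$ci_low, pr$ci_high, pr$n_variants))
cat(sprintf("rs1183910 penalty factor: %.4f (downweighted ~%.0f-fold)\n",
            pr$penalty_factors[["rs1183910"]], 1 / pr$penalty_factors[["rs1183910"]]))
cat(sprintf("Cochran's Q = %.2f (df %d, p = %.3g): the penalization is doing real work\n",
            report$heterogeneity$q_total, report$heterogeneity$df,
            report$heterogeneity$pvalue))
cat(sprintf("MR-Egger intercept %.4f: some average directional pleiotropy remains\n",
            report$egger$intercept))
loo <- report$loo
cat("Most influential instruments:",
    paste(loo$omitted_id[order(-loo$influence)][1:2], collapse = ", "), "\n")
cat("Tables written to", out_dir, "\n")
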