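#!/usr/bin/env Rscript
# Validation on synthetic summary statistics with known truth: does the
# estimator stack recover the causal effect, and does MR-Egger isolate
# directional pleiotropy where IVW is misled? Writes results/simulation/.

library(crpmr)

out_dir <- "results/simulation"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
seed <- 20260923

# Scenario A: a CRP-like causal effect (theta = 0.11), no pleiotropy,
# instrument counts bracketing the real analyses.
scen_a <- data.frame(theta = 0.11, n_variants = c(50, 100))
res_a <- recovery_study(scen_a, n_reps = 200, estimator = "ivw", seed = seed)
cat("Scenario A - IVW under a true effect of 0.11:\n")
print(res_a[, c("theta", "n_variants", "mean_estimate", "bias", "empirical_se",
                "rmse", "coverage", "rejection_rate")], digits = 3)
cat(sprintf("  max |bias| = %.4f; IVW recovers the effect essentially unbiasedly\n",
            max(abs(res_a$bias))))

# Scenario B: no causal effect but directional pleiotropy (mean direct
# effect 0.02). IVW mistakes pleiotropy for causation; the Egger slope
# does not, and its intercept estimates the pleiotropy itself.
scen_b <- data.frame(theta = 0, n_variants = 100,
                     pleiotropy_mean = 0.02, pleiotropy_sd = 0.005)
res_ivw <- recovery_study(scen_b, n_reps = 200, estimator = "ivw", seed = seed + 1)
res_egg <- recovery_study(scen_b, n_reps = 200, estimator = "egger", seed = seed + 1)
cat("\nScenario B - directional pleiotropy, no causal effect:\n")
cat(sprintf("  IVW bias %.4f vs Egger slope bias %.4f\n",
            res_ivw$bias, res_egg$bias))
cat(sprintf("  mean Egger intercept %.4f (truth 0.02)\n", res_egg$mean_intercept))

as_rows <- function(res, estimator) {
  cols <- c("theta", "n_variants", "pleiotropy_mean", "pleiotropy_sd",
            "mean_estimate", "bias", "empirical_se", "rmse", "coverage",
            "rejection_rate", "mean_intercept", "intercept_bias")
  for (cn in setdiff(cols, names(res))) res[[cn]] <- NA
  cbind(estimator = estimator, res[, cols])
}
all_res <- rbind(as_rows(res_a, "ivw"), as_rows(res_ivw, "ivw"),
                 as_rows(res_egg, "egger"))
write.table(format(all_res, digits = 6), file.path(out_dir, "recovery_metrics.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

# one example simulated dataset, written in the input dialect with its truth
sim <- simulate_summary_stats(simulation_config(n_variants = 50, seed = seed))
write_simulation(sim, file.path(out_dir, "example"))
cat("\nMetrics and an example simulated dataset written to", out_dir, "\n")
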