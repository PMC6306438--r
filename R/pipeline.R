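#' Run the full two-sample MR analysis
#'
#' End-to-end orchestration: read both summary-statistic tables, harmonize
#' them to a shared effect allele, select instruments (exposure
#' significance, outcome-association exclusion, optional LD pruning),
#' compute per-variant Wald ratios, pool them with every requested
#' estimator, and run Cochran's Q, MR-Egger regression (when at least 3
#' instruments remain) and the leave-one-out sensitivity analysis. Inputs
#' may be file paths or already-loaded data frames.
#'
#' @param exposure,outcome Paths to TSV files in the
#'   [read_summary_stats()] dialect, or canonical data frames.
#' @param ld Optional path to an LD table ([read_ld()]) or an
#'   [ld_matrix()]; `NULL` skips pruning.
#' @param p_exposure_max,p_outcome_min,r2_max Selection thresholds; the
#'   defaults (5e-8, 0.05, 0.2) mirror the CRP-diabetes analysis.
#' @param methods Character vector of [mr_pool()] methods to run; default
#'   the headline `"ivw_penalized_robust"`.
#' @param penalty_mult,tuning Estimator tuning, see [mr_pool()].
#' @param palindrome_policy Passed to [harmonize_tables()].
#' @param dialect Column dialect for reading the input files.
#' @param verbose Emit stage-level progress lines (counts in/out) to
#'   standard error? Default `TRUE`.
#' @return Object of class `mr_report`: a list with `provenance`
#'   (paths, thresholds, timestamp), `harmonized`, `exclusions` (combined
#'   unharmonizable + selection log), `instruments`, `wald` (forest table of
#'   the first requested method), `pooled` (named list of `mr_pooled`),
#'   `heterogeneity`, `egger` (or `NULL` with fewer than 3 instruments),
#'   and `loo`.
#' @export
#' @examples
#' rep <- run_mr_pipeline(crp_fixture_path("crp_gwas"),
#'                        crp_fixture_path("t2dm_gwas"), verbose = FALSE)
#' rep$pooled$ivw_penalized_robust
run_mr_pipeline <- function(exposure, outcome, ld = NULL,
                            p_exposure_max = 5e-8, p_outcome_min = 0.05,
                            r2_max = 0.2,
                            methods = "ivw_penalized_robust",
                            penalty_mult = 20, tuning = 4.685,
                            palindrome_policy = "keep",
                            dialect = default_dialect(), verbose = TRUE) {
  stopifnot(length(methods) >= 1L)
  say <- function(...) if (verbose) message("[crpmr] ", sprintf(...))
  t0 <- Sys.time()
  exp_path <- if (is.character(exposure)) exposure else "<data frame>"
  out_path <- if (is.character(outcome)) outcome else "<data frame>"
  if (is.character(exposure)) exposure <- read_summary_stats(exposure, dialect)
  if (is.character(outcome)) outcome <- read_summary_stats(outcome, dialect)
  if (is.character(ld)) ld <- read_ld(ld)
  say("read: %d exposure, %d outcome variants", nrow(exposure), nrow(outcome))

  h <- harmonize_tables(exposure, outcome, palindrome_policy)
  say("harmonize: %d shared variants, %d excluded", nrow(h),
      nrow(attr(h, "dropped")))

  sel <- withCallingHandlers(
    select_instruments(h, p_exposure_max, p_outcome_min, ld, r2_max),
    message = function(m) {
      if (verbose) message("[crpmr] ", conditionMessage(m), appendLF = FALSE)
      invokeRestart("muffleMessage")
    })
  exclusions <- rbind(attr(h, "dropped"), sel$log)
  say("select: %d instruments kept, %d excluded", nrow(sel$kept), nrow(exclusions))
  if (nrow(sel$kept) == 0L) {
    stop("no instruments survived selection; exclusion log:\n",
         paste(utils::capture.output(print(exclusions)), collapse = "\n"),
         call. = FALSE)
  }

  est <- wald_ratio(sel$kept)
  pooled <- lapply(stats::setNames(methods, methods), function(m)
    mr_pool(est, method = m, penalty_mult = penalty_mult, tuning = tuning))
  say("pool: %s", paste(sprintf("%s OR %.4f", methods,
                                vapply(pooled, `[[`, 0, "or_")), collapse = "; "))

  het <- if (nrow(est) >= 2L) cochran_q(est) else NULL
  egger <- if (nrow(sel$kept) >= 3L)
    egger_regression(sel$kept, penalized = TRUE, robust = TRUE,
                     penalty_mult = penalty_mult, tuning = tuning)
  else NULL
  if (is.null(egger)) say("egger: skipped (fewer than 3 instruments)")
  else say("egger: intercept %.4f (p = %.3g)", egger$intercept, egger$intercept_p)
  loo <- if (nrow(sel$kept) >= 2L)
    leave_one_out(sel$kept, method = methods[1],
                  penalty_mult = penalty_mult, tuning = tuning)
  else NULL
  say("done in %.2f s", as.numeric(difftime(Sys.time(), t0, units = "secs")))

  structure(list(
    provenance = list(
      exposure = exp_path, outcome = out_path,
      ld = if (is.null(ld)) NA_character_ else "supplied",
      p_exposure_max = p_exposure_max, p_outcome_min = p_outcome_min,
      r2_max = r2_max, methods = methods, penalty_mult = penalty_mult,
      tuning = tuning, palindrome_policy = palindrome_policy,
      timestamp = format(t0, "%Y-%m-%dT%H:%M:%S%z")),
    harmonized = h, exclusions = exclusions, instruments = sel$kept,
    wald = forest_table(est, pooled[[1]]), pooled = pooled,
    heterogeneity = het, egger = egger, loo = loo
  ), class = "mr_report")
}

#' @export
print.mr_report <- function(x, ...) {
  cat("Two-sample MR analysis report\n")
  cat(sprintf("  exposure: %s\n  outcome:  %s\n",
              x$provenance$exposure, x$provenance$outcome))
  cat(sprintf("  instruments: %d kept, %d excluded\n",
              nrow(x$instruments), nrow(x$exclusions)))
  for (p in x$pooled) print(p)
  if (!is.null(x$heterogeneity)) print(x$heterogeneity)
  if (!is.null(x$egger)) print(x$egger)
  invisible(x)
}

#' Write an analysis report to disk
#'
#' Emits the report's tables as TSV and/or a single JSON document:
#' `instruments.tsv`, `exclusions.tsv`, `wald_estimates.tsv`,
#' `pooled_estimates.tsv`, `leave_one_out.tsv` and `report.json`.
#'
#' @param report `mr_report` from [run_mr_pipeline()].
#' @param dir Output directory (created if absent).
#' @param format `"tsv"`, `"json"`, or both (default).
#' @return Character vector of written paths, invisibly.
#' @export
write_mr_report <- function(report, dir, format = c("tsv", "json")) {
  format <- match.arg(format, several.ok = TRUE)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  pooled_df <- do.call(rbind, lapply(report$pooled, function(p)
    data.frame(method = p$method, beta = p$beta, se = p$se, or_ = p$or_,
               ci_low = p$ci_low, ci_high = p$ci_high, pvalue = p$pvalue,
               n_variants = p$n_variants, residual_scale = p$residual_scale,
               stringsAsFactors = FALSE)))
  rownames(pooled_df) <- NULL
  if ("tsv" %in% format) {
    wt <- function(obj, name) {
      p <- file.path(dir, name)
      utils::write.table(obj, p, sep = "\t", quote = FALSE, row.names = FALSE,
                         fileEncoding = "UTF-8")
      p
    }
    paths <- c(paths,
               wt(as.data.frame(report$instruments), "instruments.tsv"),
               wt(report$exclusions, "exclusions.tsv"),
               wt(report$wald, "wald_estimates.tsv"),
               wt(pooled_df, "pooled_estimates.tsv"))
    if (!is.null(report$loo))
      paths <- c(paths, wt(as.data.frame(report$loo), "leave_one_out.tsv"))
  }
  if ("json" %in% format) {
    p <- file.path(dir, "report.json")
    doc <- list(
      provenance = report$provenance,
      instruments = report$instruments,
      exclusions = report$exclusions,
      wald = report$wald,
      pooled = pooled_df,
      heterogeneity = if (!is.null(report$heterogeneity))
        list(q_total = report$heterogeneity$q_total,
             df = report$heterogeneity$df,
             pvalue = report$heterogeneity$pvalue),
      egger = if (!is.null(report$egger))
        report$egger[c("intercept", "intercept_se", "intercept_ci_low",
                       "intercept_ci_high", "intercept_p", "slope",
                       "slope_se", "slope_p", "n_variants")],
      leave_one_out = if (!is.null(report$loo)) as.data.frame(report$loo)
    )
    jsonlite::write_json(doc, p, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows", na = "null")
    paths <- c(paths, p)
  }
  invisible(paths)
}
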