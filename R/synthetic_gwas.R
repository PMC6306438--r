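#' Configuration for the synthetic two-sample GWAS generator
#'
#' Parameters of the summary-statistic generating model (see
#' [simulate_summary_stats()]). Defaults emulate a CRP-like instrument set:
#' a causal log-OR of 0.11 per exposure unit, per-allele exposure effects
#' of the magnitude of the published CRP instruments (mean 0.15, SD 0.05),
#' estimation SEs near 0.015 on both sides, and no pleiotropy.
#'
#' @param n_variants Number of instruments J (>= 1).
#' @param theta True causal effect on the outcome, log-OR per exposure unit.
#' @param exposure_beta_mean,exposure_beta_sd Normal distribution of the
#'   true per-allele exposure effects b_j; draws are rejected until
#'   |b_j| > 1e-3 so every Wald ratio is defined (a generator constraint,
#'   not an estimator fix).
#' @param se_exposure,se_outcome Per-variant estimation SEs (scalars or
#'   length-J vectors), all > 0.
#' @param pleiotropy_mean,pleiotropy_sd Normal distribution of the direct
#'   (pleiotropic) effects alpha_j, drawn independently of b_j so the
#'   InSIDE condition holds by construction. `pleiotropy_sd` >= 0.
#' @param seed Integer seed for the single pseudo-random stream.
#' @return A validated list of class `sim_config`.
#' @export
simulation_config <- function(n_variants = 50L, theta = 0.11,
                              exposure_beta_mean = 0.15,
                              exposure_beta_sd = 0.05,
                              se_exposure = 0.015, se_outcome = 0.015,
                              pleiotropy_mean = 0, pleiotropy_sd = 0,
                              seed = 1L) {
  cfg <- list(n_variants = as.integer(n_variants), theta = theta,
              exposure_beta_mean = exposure_beta_mean,
              exposure_beta_sd = exposure_beta_sd,
              se_exposure = se_exposure, se_outcome = se_outcome,
              pleiotropy_mean = pleiotropy_mean,
              pleiotropy_sd = pleiotropy_sd, seed = as.integer(seed))
  if (cfg$n_variants < 1L) stop("n_variants must be >= 1", call. = FALSE)
  if (any(cfg$se_exposure <= 0) || any(cfg$se_outcome <= 0))
    stop("estimation SEs must be > 0", call. = FALSE)
  if (cfg$pleiotropy_sd < 0) stop("pleiotropy_sd must be >= 0", call. = FALSE)
  if (cfg$exposure_beta_sd < 0) stop("exposure_beta_sd must be >= 0", call. = FALSE)
  if (!all(length(cfg$se_exposure) %in% c(1L, cfg$n_variants),
           length(cfg$se_outcome) %in% c(1L, cfg$n_variants)))
    stop("SEs must be scalar or length n_variants", call. = FALSE)
  structure(cfg, class = "sim_config")
}

# ordered non-palindromic allele pairs the generator draws from
.allele_pairs <- matrix(c("A", "C", "A", "G", "C", "A", "C", "T",
                          "G", "A", "G", "T", "T", "C", "T", "G"),
                        ncol = 2, byrow = TRUE)

#' Simulate two-sample GWAS summary statistics
#'
#' Generates exposure and outcome association tables under a linear causal
#' model with optional pleiotropy. For each variant j, a true exposure
#' effect b_j ~ N(mean, sd^2) (resampled until |b_j| > 1e-3) and a direct
#' effect alpha_j ~ N(pleiotropy_mean, pleiotropy_sd^2) are drawn
#' independently (InSIDE satisfied); the observed summary statistics add
#' independent estimation noise:
#' beta_exposure_j = b_j + N(0, se_exposure^2) and
#' beta_outcome_j = theta * b_j + alpha_j + N(0, se_outcome^2).
#' P-values are two-sided normal tests of beta/se. Outcome betas are on the
#' log-OR scale directly; no individual-level data are simulated, matching
#' what a two-sample analysis consumes. Alleles come from non-palindromic
#' pairs. All draws for variant j precede those for variant j+1 in one
#' seeded stream, so enlarging J preserves the first variants verbatim.
#'
#' @param config A [simulation_config()].
#' @return List with elements `exposure` and `outcome` (canonical
#'   [read_summary_stats()] data frames, classes `variant_assoc`) and
#'   `truth` (list: `theta`, `pleiotropy_mean`, `b`, `alpha`, `config`).
#' @export
#' @examples
#' sim <- simulate_summary_stats(simulation_config(n_variants = 10, seed = 7))
#' head(sim$exposure)
simulate_summary_stats <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  J <- config$n_variants
  sx <- rep(config$se_exposure, length.out = J)
  sy <- rep(config$se_outcome, length.out = J)
  b <- alpha <- bx <- by <- eaf <- numeric(J)
  pair <- integer(J)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(config$seed)
  for (j in seq_len(J)) {
    repeat {
      b[j] <- stats::rnorm(1, config$exposure_beta_mean, config$exposure_beta_sd)
      if (abs(b[j]) > 1e-3) break
    }
    alpha[j] <- if (config$pleiotropy_sd > 0)
      stats::rnorm(1, config$pleiotropy_mean, config$pleiotropy_sd)
    else config$pleiotropy_mean
    bx[j] <- b[j] + stats::rnorm(1, 0, sx[j])
    by[j] <- config$theta * b[j] + alpha[j] + stats::rnorm(1, 0, sy[j])
    eaf[j] <- stats::runif(1, 0.05, 0.95)
    pair[j] <- sample.int(nrow(.allele_pairs), 1L)
  }
  ids <- sprintf("rs%07d", seq_len(J))
  base <- data.frame(
    variant_id = ids,
    chrom = as.character(rep_len(1:22, J)),
    pos = 1e5 * seq_len(J),
    effect_allele = .allele_pairs[pair, 1],
    other_allele = .allele_pairs[pair, 2],
    eaf = eaf, stringsAsFactors = FALSE
  )
  # clamp away from 0 so extreme z-scores still satisfy the p in (0,1] contract
  p2 <- function(z) pmax(2 * stats::pnorm(-abs(z)), .Machine$double.xmin)
  exposure <- cbind(base, data.frame(beta = bx, se = sx, pvalue = p2(bx / sx)))
  outcome <- cbind(base, data.frame(beta = by, se = sy, pvalue = p2(by / sy)))
  class(exposure) <- class(outcome) <- c("variant_assoc", "data.frame")
  list(exposure = exposure, outcome = outcome,
       truth = list(theta = config$theta,
                    pleiotropy_mean = config$pleiotropy_mean,
                    b = b, alpha = alpha, config = config))
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Write simulated summary statistics and their truth record
#'
#' Emits `<prefix>_exposure.tsv` and `<prefix>_outcome.tsv` in the standard
#' dialect plus a `<prefix>_truth.json` sidecar with the generating
#' parameters and true effects.
#'
#' @param sim Result of [simulate_summary_stats()].
#' @param prefix Output path prefix.
#' @return Character vector of the three paths, invisibly.
#' @export
write_simulation <- function(sim, prefix) {
  p1 <- paste0(prefix, "_exposure.tsv")
  p2 <- paste0(prefix, "_outcome.tsv")
  p3 <- paste0(prefix, "_truth.json")
  write_summary_stats(sim$exposure, p1)
  write_summary_stats(sim$outcome, p2)
  truth <- sim$truth
  truth$config <- unclass(truth$config)
  jsonlite::write_json(truth, p3, auto_unbox = TRUE, digits = NA)
  invisible(c(p1, p2, p3))
}

#' Parameter-recovery study over simulated scenarios
#'
#' For each scenario row, repeatedly simulates summary statistics, runs the
#' analysis pipeline (harmonization, instrument selection with permissive
#' thresholds so every simulated variant enters, then the requested
#' estimator) and aggregates recovery metrics for the causal effect -- and,
#' for MR-Egger, for the pleiotropy intercept.
#'
#' @param scenarios Data frame whose columns override
#'   [simulation_config()] arguments (e.g. `theta`, `n_variants`,
#'   `pleiotropy_mean`); one row per scenario.
#' @param n_reps Replicates per scenario (>= 1).
#' @param estimator `"ivw"`, `"ivw_penalized"`, `"ivw_robust"`,
#'   `"ivw_penalized_robust"`, or `"egger"`.
#' @param seed Integer master seed; per-replicate seeds are derived from it,
#'   so results are reproducible and independent of evaluation order.
#' @return Data frame, one row per scenario: the scenario parameters plus
#'   `mean_estimate`, `bias`, `empirical_se`, `rmse`, `coverage` (share of
#'   95% CIs covering theta), `rejection_rate` (share of p < 0.05), and for
#'   `estimator = "egger"` also `mean_intercept` and `intercept_bias`
#'   (against `pleiotropy_mean`). Per-replicate estimates are kept in the
#'   `"replicates"` attribute.
#' @export
#' @examples
#' recovery_study(data.frame(theta = 0.11), n_reps = 5, estimator = "ivw", seed = 1)
recovery_study <- function(scenarios, n_reps, estimator = "ivw_penalized_robust",
                           seed = 1L) {
  stopifnot(is.data.frame(scenarios), nrow(scenarios) >= 1L, n_reps >= 1L)
  estimator <- match.arg(estimator, c("ivw", "ivw_penalized", "ivw_robust",
                                      "ivw_penalized_robust", "egger"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  rep_seeds <- matrix(sample.int(.Machine$integer.max - 1L,
                                 nrow(scenarios) * n_reps),
                      nrow = nrow(scenarios))
  out <- vector("list", nrow(scenarios))
  reps_all <- vector("list", nrow(scenarios))
  for (s in seq_len(nrow(scenarios))) {
    args <- as.list(scenarios[s, , drop = FALSE])
    est <- se <- lo <- hi <- pv <- intc <- numeric(n_reps)
    for (r in seq_len(n_reps)) {
      cfg <- do.call(simulation_config, c(args, list(seed = rep_seeds[s, r])))
      sim <- simulate_summary_stats(cfg)
      h <- suppressMessages(harmonize_tables(sim$exposure, sim$outcome))
      sel <- suppressMessages(select_instruments(
        h, p_exposure_max = 1 - 1e-12, p_outcome_min = 1e-300))
      if (nrow(sel$kept) == 0L)
        stop(sprintf("scenario %d, replicate %d: no instruments survived selection",
                     s, r), call. = FALSE)
      if (estimator == "egger") {
        fit <- egger_regression(sel$kept)
        tq <- stats::qt(0.975, df = fit$n_variants - 2L)
        est[r] <- fit$slope; se[r] <- fit$slope_se
        lo[r] <- fit$slope_ci_low; hi[r] <- fit$slope_ci_high
        pv[r] <- fit$slope_p; intc[r] <- fit$intercept
      } else {
        fit <- mr_pool(wald_ratio(sel$kept), method = estimator)
        est[r] <- fit$beta; se[r] <- fit$se
        lo[r] <- fit$beta - 1.959964 * fit$se
        hi[r] <- fit$beta + 1.959964 * fit$se
        pv[r] <- fit$pvalue; intc[r] <- NA_real_
      }
    }
    theta <- if (!is.null(args$theta)) args$theta else formals(simulation_config)$theta
    metrics <- data.frame(
      scenario = s,
      mean_estimate = mean(est),
      bias = mean(est) - theta,
      empirical_se = if (n_reps > 1L) stats::sd(est) else 0,
      rmse = sqrt(mean((est - theta)^2)),
      coverage = mean(lo <= theta & theta <= hi),
      rejection_rate = mean(pv < 0.05)
    )
    if (estimator == "egger") {
      mu <- if (!is.null(args$pleiotropy_mean)) args$pleiotropy_mean else 0
      metrics$mean_intercept <- mean(intc)
      metrics$intercept_bias <- mean(intc) - mu
    }
    out[[s]] <- cbind(scenarios[s, , drop = FALSE], metrics)
    reps_all[[s]] <- data.frame(scenario = s, rep = seq_len(n_reps),
                                estimate = est, se = se, ci_low = lo,
                                ci_high = hi, pvalue = pv, intercept = intc)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "replicates") <- do.call(rbind, reps_all)
  attr(res, "estimator") <- estimator
  res
}
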