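#' Per-variant Wald ratio estimates
#'
#' For each harmonized variant the causal effect of the exposure on the
#' outcome is estimated as the ratio of the variant-outcome to the
#' variant-exposure association, beta_xy = beta_outcome / beta_exposure,
#' with the first-order delta-method standard error
#' se_xy = se_outcome / |beta_exposure| (exposure-side uncertainty ignored,
#' the usual no-measurement-error convention). The resulting inverse-variance
#' weight is se_xy^-2 = beta_exposure^2 / se_outcome^2.
#'
#' `se_method = "ratio_of_se"` instead computes se_xy = se_outcome /
#' se_exposure. That formula is dimensionally inconsistent (the SE no longer
#' scales with the exposure effect) and is provided only so the consequences
#' of using it can be audited; no other function in the package uses it.
#'
#' @param h `harmonized_variants` data frame.
#' @param se_method `"delta"` (default) or `"ratio_of_se"` (see above).
#' @return Data frame of class `wald_estimates` with columns `variant_id`,
#'   `beta_xy`, `se_xy`, `weight`.
#' @export
#' @examples
#' h <- read_paired_summary_stats(crp_fixture_path("crp_t2dm"))
#' wald_ratio(h)
wald_ratio <- function(h, se_method = c("delta", "ratio_of_se")) {
  se_method <- match.arg(se_method)
  if (nrow(h) == 0L) stop("no variants supplied", call. = FALSE)
  zero <- h$variant_id[h$beta_exposure == 0]
  if (length(zero) > 0L)
    stop("undefined Wald ratio: beta_exposure = 0 for ",
         paste(zero, collapse = ", "), call. = FALSE)
  se_xy <- switch(se_method,
                  delta = h$se_outcome / abs(h$beta_exposure),
                  ratio_of_se = h$se_outcome / h$se_exposure)
  out <- data.frame(variant_id = h$variant_id,
                    beta_xy = h$beta_outcome / h$beta_exposure,
                    se_xy = se_xy,
                    weight = se_xy^-2,
                    stringsAsFactors = FALSE)
  class(out) <- c("wald_estimates", "data.frame")
  out
}

#' Heterogeneity penalty factors
#'
#' Downweights variants whose ratio estimates are outliers relative to a
#' reference pooled estimate. Each variant's heterogeneity contribution is
#' Q_j = w_j (beta_j - reference)^2; its upper-tail chi-squared (1 df)
#' probability p_j yields the multiplier min(1, penalty_mult * p_j). A
#' variant consistent with the reference (p_j >= 1/penalty_mult) keeps its
#' full weight; a strongly heterogeneous one is downweighted in proportion
#' to how improbable its deviation is.
#'
#' @param estimates `wald_estimates` data frame.
#' @param reference_beta Pooled log-OR the deviations are measured against
#'   (by convention the unpenalized, non-robust IVW estimate).
#' @param penalty_mult Penalty multiplier, default 20.
#' @return Numeric vector of factors in (0, 1\], named by variant id, with
#'   attributes `q` (the Q_j) and `p` (their chi-squared tail probabilities).
#' @export
penalty_factors <- function(estimates, reference_beta, penalty_mult = 20) {
  stopifnot(is.finite(reference_beta), penalty_mult > 0)
  q <- estimates$weight * (estimates$beta_xy - reference_beta)^2
  p <- stats::pchisq(q, df = 1, lower.tail = FALSE)
  f <- pmin(1, penalty_mult * p)
  names(f) <- names(q) <- names(p) <- estimates$variant_id
  attr(f, "q") <- q
  attr(f, "p") <- p
  f
}

#' Tukey-bisquare robust weighted regression
#'
#' Iteratively reweighted least squares with the Tukey bisquare (biweight)
#' loss. At each iteration residuals are standardized by the prior weights,
#' a robust scale is taken as the zero-centered median absolute deviation
#' (consistency constant 1.4826) of those standardized residuals, and each
#' point receives the bisquare weight (1 - u^2)^2 for |u| < 1 (0 beyond),
#' u = r / (scale * tuning). Iteration stops when no coefficient moves by
#' more than `tol` or after `max_iter` iterations (then the last iterate is
#' returned with `converged = FALSE` and a warning). A zero scale (exact
#' fit) short-circuits with unit robust weights.
#'
#' @param x,y Numeric vectors (the predictor and response).
#' @param weights Prior (precision) weights, length of `x`.
#' @param include_intercept Fit an intercept? Needs >= 3 points if `TRUE`,
#'   >= 1 otherwise.
#' @param tuning Bisquare tuning constant c; the default 4.685 gives 95%
#'   efficiency at the Gaussian model.
#' @param tol Convergence tolerance on coefficients, default 1e-10.
#' @param max_iter Iteration cap, default 100.
#' @return List: `coefficients` (named `intercept`/`slope`, or `slope`
#'   only), `robust_weights` in \[0, 1\], `residual_scale` (robust scale of
#'   the standardized residuals at convergence), `fitted`, `residuals`,
#'   `converged`, `iterations`.
#' @export
robust_fit <- function(x, y, weights = rep(1, length(x)),
                       include_intercept = FALSE, tuning = 4.685,
                       tol = 1e-10, max_iter = 100L) {
  n <- length(x)
  stopifnot(length(y) == n, length(weights) == n, all(weights >= 0))
  if (include_intercept && n < 3L)
    stop("robust fit with intercept needs at least 3 points", call. = FALSE)
  if (!include_intercept && n < 1L)
    stop("robust fit needs at least 1 point", call. = FALSE)
  X <- if (include_intercept) cbind(intercept = 1, slope = x) else cbind(slope = x)
  wls <- function(w) {
    fit <- stats::lm.wfit(X, y, w)
    fit$coefficients
  }
  beta <- wls(weights)
  rw <- rep(1, n)
  scale <- 0
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    r <- sqrt(weights) * (y - drop(X %*% beta))
    scale <- stats::mad(r, center = 0)
    if (scale < 1e-12) {
      # a majority of points fits exactly; they keep full weight and any
      # remaining point with a nonzero residual is a gross outlier
      rw <- as.numeric(abs(r) < 1e-12)
      if (!all(rw == 1)) beta <- wls(weights * rw)
      converged <- TRUE
      break
    }
    u <- r / (scale * tuning)
    rw <- ifelse(abs(u) < 1, (1 - u^2)^2, 0)
    beta_new <- wls(weights * rw)
    if (max(abs(beta_new - beta)) < tol) {
      beta <- beta_new
      converged <- TRUE
      break
    }
    beta <- beta_new
  }
  if (!converged)
    warning("robust fit did not converge in ", max_iter,
            " iterations; returning last iterate", call. = FALSE)
  names(beta) <- colnames(X)
  list(coefficients = beta, robust_weights = rw, residual_scale = scale,
       fitted = drop(X %*% beta), residuals = y - drop(X %*% beta),
       converged = converged, iterations = iter)
}

.new_pooled <- function(method, beta, se, n, penalty_factors, robust_weights,
                        residual_scale) {
  z <- 1.959964
  structure(list(
    method = method, beta = beta, se = se, or_ = exp(beta),
    ci_low = exp(beta - z * se), ci_high = exp(beta + z * se),
    pvalue = 2 * stats::pnorm(-abs(beta / se)),
    n_variants = n, penalty_factors = penalty_factors,
    robust_weights = robust_weights, residual_scale = residual_scale
  ), class = "mr_pooled")
}

#' @export
print.mr_pooled <- function(x, ...) {
  cat(sprintf("Pooled MR estimate (%s), %d variant(s)\n", x$method, x$n_variants))
  cat(sprintf("  log-OR %.6f (SE %.6f)\n", x$beta, x$se))
  cat(sprintf("  OR %.6f, 95%% CI %.6f to %.6f, p = %.3g\n",
              x$or_, x$ci_low, x$ci_high, x$pvalue))
  if (any(x$penalty_factors < 1))
    cat("  penalty factors < 1: ",
        paste(sprintf("%s = %.3g", names(x$penalty_factors)[x$penalty_factors < 1],
                      x$penalty_factors[x$penalty_factors < 1]), collapse = ", "),
        "\n", sep = "")
  invisible(x)
}

#' Pool Wald ratios with the inverse-variance weighted estimator family
#'
#' Combines per-variant Wald ratios into one causal log-odds-ratio. The
#' plain IVW estimate is the precision-weighted mean
#' sum(w_j beta_j) / sum(w_j) with w_j = se_xy^-2, algebraically identical
#' to the no-intercept weighted regression of outcome betas on exposure
#' betas. The penalized variants first multiply each weight by the
#' heterogeneity factor of [penalty_factors()] (reference: the unpenalized
#' IVW estimate); the robust variants replace the weighted mean by a
#' Tukey-bisquare IRLS fit ([robust_fit()]) on the same weighted problem.
#'
#' Standard errors are fixed-effect, (sum of final weights)^-1/2, inflated
#' by max(1, residual_scale) for the penalized/robust variants
#' (multiplicative random-effects convention; the scale is [robust_fit()]'s
#' robust residual scale, or the classical weighted residual standard
#' deviation for `ivw_penalized`). The p-value is a two-sided normal test.
#' A single variant is returned as-is (its Wald ratio and SE).
#'
#' @param estimates `wald_estimates` data frame, at least one row.
#' @param method One of `"ivw"`, `"ivw_penalized"`, `"ivw_robust"`,
#'   `"ivw_penalized_robust"`.
#' @param penalty_mult Penalty multiplier passed to [penalty_factors()].
#' @param tuning Bisquare tuning constant for the robust variants.
#' @return An `mr_pooled` object: `method`, `beta`, `se`, `or_`, `ci_low`,
#'   `ci_high` (95%, normal), `pvalue`, `n_variants`, `penalty_factors`,
#'   `robust_weights`, `residual_scale`.
#' @export
#' @examples
#' h <- read_paired_summary_stats(crp_fixture_path("crp_t2dm"))
#' est <- wald_ratio(select_instruments(h)$kept)
#' mr_pool(est, method = "ivw_penalized_robust")
mr_pool <- function(estimates,
                    method = c("ivw_penalized_robust", "ivw", "ivw_penalized",
                               "ivw_robust"),
                    penalty_mult = 20, tuning = 4.685) {
  method <- match.arg(method)
  n <- nrow(estimates)
  if (is.null(n) || n < 1L) stop("at least one Wald estimate required", call. = FALSE)
  b <- estimates$beta_xy
  w <- estimates$weight
  ids <- estimates$variant_id
  beta_ivw <- sum(w * b) / sum(w)

  penalized <- method %in% c("ivw_penalized", "ivw_penalized_robust")
  robust <- method %in% c("ivw_robust", "ivw_penalized_robust")

  if (penalized) {
    f <- penalty_factors(estimates, beta_ivw, penalty_mult)
    attributes(f) <- list(names = names(f))
  } else {
    f <- stats::setNames(rep(1, n), ids)
  }
  wf <- w * f

  if (robust) {
    # regression form: response beta_j*sqrt(w_j), predictor sqrt(w_j), prior
    # weights f_j -- standardized residuals are sqrt(w_j f_j)(beta_j - slope)
    fit <- robust_fit(sqrt(w), b * sqrt(w), weights = f,
                      include_intercept = FALSE, tuning = tuning)
    beta <- unname(fit$coefficients["slope"])
    rw <- stats::setNames(fit$robust_weights, ids)
    scale <- fit$residual_scale
  } else {
    beta <- sum(wf * b) / sum(wf)
    rw <- stats::setNames(rep(1, n), ids)
    scale <- if (n > 1L) sqrt(sum(wf * (b - beta)^2) / (n - 1L)) else 0
  }
  se <- sum(wf)^-0.5
  if (method != "ivw") se <- se * max(1, scale)
  .new_pooled(method, beta, se, n, f, rw, scale)
}

#' Plain inverse-variance weighted estimate
#'
#' Convenience wrapper for `mr_pool(estimates, method = "ivw")`: the
#' fixed-effect precision-weighted mean of the Wald ratios, with
#' se = (sum of weights)^-1/2.
#'
#' @inheritParams mr_pool
#' @return An `mr_pooled` object.
#' @export
ivw <- function(estimates) mr_pool(estimates, method = "ivw")

#' Penalized robust inverse-variance weighted estimate
#'
#' Convenience wrapper for
#' `mr_pool(estimates, method = "ivw_penalized_robust")`: heterogeneity
#' penalized weights combined with Tukey-bisquare robust pooling. This is
#' the headline estimator of the CRP-diabetes analysis.
#'
#' @inheritParams mr_pool
#' @return An `mr_pooled` object.
#' @export
penalized_robust_ivw <- function(estimates, penalty_mult = 20, tuning = 4.685)
  mr_pool(estimates, method = "ivw_penalized_robust",
          penalty_mult = penalty_mult, tuning = tuning)

#' Cochran's Q heterogeneity statistic
#'
#' Q = sum over variants of w_j (beta_j - beta_IVW)^2, referred to the
#' upper tail of a chi-squared distribution with n - 1 degrees of freedom.
#' Large Q flags dispersion of the per-variant ratio estimates beyond what
#' their standard errors explain, e.g. from pleiotropic instruments.
#'
#' @param estimates `wald_estimates` data frame, at least two rows.
#' @return Object of class `mr_heterogeneity`: `q_total`, `df`, `pvalue`,
#'   `q_contributions` (named per-variant Q_j summing to `q_total`).
#' @export
cochran_q <- function(estimates) {
  n <- nrow(estimates)
  if (is.null(n) || n < 2L)
    stop("Cochran's Q needs at least 2 estimates", call. = FALSE)
  beta_ivw <- sum(estimates$weight * estimates$beta_xy) / sum(estimates$weight)
  qj <- stats::setNames(estimates$weight * (estimates$beta_xy - beta_ivw)^2,
                        estimates$variant_id)
  structure(list(q_total = sum(qj), df = n - 1L,
                 pvalue = stats::pchisq(sum(qj), df = n - 1L, lower.tail = FALSE),
                 q_contributions = qj),
            class = "mr_heterogeneity")
}

#' @export
print.mr_heterogeneity <- function(x, ...) {
  cat(sprintf("Cochran's Q = %.4f, df = %d, p = %.3g\n", x$q_total, x$df, x$pvalue))
  invisible(x)
}

#' MR-Egger regression
#'
#' Weighted linear regression of the outcome betas on the exposure betas
#' with an unconstrained intercept, after orienting every variant so that
#' its exposure beta is positive (both betas negated where needed; the fit
#' is invariant to the alleles' original orientation). The slope is a
#' causal-effect estimate that remains consistent under directional
#' pleiotropy provided pleiotropic effects are independent of instrument
#' strength (the InSIDE condition); the intercept estimates the average
#' directional (horizontal) pleiotropic effect, so an intercept bounded away
#' from zero is evidence of directional pleiotropy.
#'
#' Weights are se_outcome^-2, multiplied by the [penalty_factors()]
#' multipliers (computed against the unpenalized IVW reference) when
#' `penalized = TRUE`; with `robust = TRUE` the fit uses the Tukey-bisquare
#' IRLS of [robust_fit()]. Coefficient SEs are the fixed-effect weighted
#' least-squares SEs at the final weights, inflated by
#' max(1, residual_scale); inference uses a t distribution with n - 2 df
#' and the matching quantile for the 95% CIs.
#'
#' @param h `harmonized_variants` data frame with at least 3 rows.
#' @param penalized Apply heterogeneity penalty factors? Default `TRUE`.
#' @param robust Use the Tukey-bisquare robust fit? Default `TRUE`.
#' @param penalty_mult Penalty multiplier, default 20.
#' @param tuning Bisquare tuning constant, default 4.685.
#' @return Object of class `mr_egger`: `intercept`, `intercept_se`,
#'   `intercept_ci_low`, `intercept_ci_high`, `intercept_p`, `slope`,
#'   `slope_se`, `slope_ci_low`, `slope_ci_high`, `slope_p`,
#'   `residual_scale`, `n_variants`, `penalty_factors`, `robust_weights`.
#' @export
#' @examples
#' h <- read_paired_summary_stats(crp_fixture_path("crp_t2dm"))
#' egger_regression(select_instruments(h)$kept)
egger_regression <- function(h, penalized = TRUE, robust = TRUE,
                             penalty_mult = 20, tuning = 4.685) {
  n <- nrow(h)
  if (is.null(n) || n < 3L)
    stop("MR-Egger regression needs at least 3 variants", call. = FALSE)
  flip <- sign(h$beta_exposure)
  if (any(flip == 0))
    stop("beta_exposure = 0 is not a valid instrument (orientation undefined)",
         call. = FALSE)
  bx <- h$beta_exposure * flip
  by <- h$beta_outcome * flip
  sy <- h$se_outcome
  if (max(bx) - min(bx) < 1e-12)
    stop("degenerate design: all exposure betas equal after orientation",
         call. = FALSE)
  ids <- h$variant_id

  if (penalized) {
    est <- wald_ratio(h)
    beta_ivw <- sum(est$weight * est$beta_xy) / sum(est$weight)
    f <- penalty_factors(est, beta_ivw, penalty_mult)
    attributes(f) <- list(names = names(f))
  } else {
    f <- stats::setNames(rep(1, n), ids)
  }
  v <- f / sy^2

  if (robust) {
    fit <- robust_fit(bx, by, weights = v, include_intercept = TRUE,
                      tuning = tuning)
    coefs <- fit$coefficients
    rw <- stats::setNames(fit$robust_weights, ids)
    scale <- fit$residual_scale
    v_final <- v * fit$robust_weights
  } else {
    X <- cbind(1, bx)
    fit <- stats::lm.wfit(X, by, v)
    coefs <- c(intercept = fit$coefficients[[1]], slope = fit$coefficients[[2]])
    rw <- stats::setNames(rep(1, n), ids)
    r <- sqrt(v) * (by - drop(X %*% fit$coefficients))
    scale <- sqrt(sum(r^2) / (n - 2L))
    v_final <- v
  }
  X <- cbind(1, bx)
  xtvx_inv <- solve(crossprod(X, v_final * X))
  ses <- unname(sqrt(diag(xtvx_inv))) * max(1, scale)
  tq <- stats::qt(0.975, df = n - 2L)
  pt2 <- function(est, se) 2 * stats::pt(-abs(unname(est) / se), df = n - 2L)
  structure(list(
    intercept = unname(coefs["intercept"]), intercept_se = ses[1],
    intercept_ci_low = unname(coefs["intercept"]) - tq * ses[1],
    intercept_ci_high = unname(coefs["intercept"]) + tq * ses[1],
    intercept_p = pt2(coefs["intercept"], ses[1]),
    slope = unname(coefs["slope"]), slope_se = ses[2],
    slope_ci_low = unname(coefs["slope"]) - tq * ses[2],
    slope_ci_high = unname(coefs["slope"]) + tq * ses[2],
    slope_p = pt2(coefs["slope"], ses[2]),
    residual_scale = scale, n_variants = n,
    penalty_factors = f, robust_weights = rw
  ), class = "mr_egger")
}

#' @export
print.mr_egger <- function(x, ...) {
  cat(sprintf("MR-Egger regression, %d variants\n", x$n_variants))
  cat(sprintf("  intercept %.4f (SE %.4f), 95%% CI %.4f to %.4f, p = %.3g\n",
              x$intercept, x$intercept_se, x$intercept_ci_low,
              x$intercept_ci_high, x$intercept_p))
  cat(sprintf("  slope     %.4f (SE %.4f), 95%% CI %.4f to %.4f, p = %.3g\n",
              x$slope, x$slope_se, x$slope_ci_low, x$slope_ci_high, x$slope_p))
  invisible(x)
}

#' Per-variant forest table for a pooled fit
#'
#' Tabulates, for each instrument, the Wald ratio, its SE and weight, the
#' penalty factor, the robust weight and the Cochran Q contribution of a
#' pooled fit -- the tabular equivalent of a forest plot.
#'
#' @param estimates `wald_estimates` data frame.
#' @param pooled `mr_pooled` object fitted on `estimates`.
#' @return Data frame with columns `variant_id`, `beta_xy`, `se_xy`,
#'   `weight`, `penalty_factor`, `robust_weight`, `q_contribution`.
#' @export
forest_table <- function(estimates, pooled) {
  beta_ivw <- sum(estimates$weight * estimates$beta_xy) / sum(estimates$weight)
  data.frame(
    variant_id = estimates$variant_id,
    beta_xy = estimates$beta_xy, se_xy = estimates$se_xy,
    weight = estimates$weight,
    penalty_factor = unname(pooled$penalty_factors[estimates$variant_id]),
    robust_weight = unname(pooled$robust_weights[estimates$variant_id]),
    q_contribution = estimates$weight * (estimates$beta_xy - beta_ivw)^2,
    stringsAsFactors = FALSE
  )
}
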