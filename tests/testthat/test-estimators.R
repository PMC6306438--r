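# Frozen expectations below were computed by direct arithmetic on the
# published instrument rows (ratio, delta-method SE, weighted means).

test_that("Wald ratios follow the delta method, errors and flags included", {
  h <- t2dm_instruments()
  est <- wald_ratio(h)
  expect_equal(est$beta_xy[est$variant_id == "rs4537545"],
               -0.01980 / -0.108, tolerance = 1e-12)
  expect_equal(est$beta_xy[est$variant_id == "rs4537545"], 0.18333, tolerance = 1e-4)
  expect_equal(est$se_xy[est$variant_id == "rs4537545"],
               0.00991 / 0.108, tolerance = 1e-12)
  expect_equal(est$se_xy[est$variant_id == "rs4537545"], 0.09176, tolerance = 1e-4)
  expect_equal(est$beta_xy[est$variant_id == "rs1183910"], -0.21735, tolerance = 1e-4)
  expect_equal(est$weight, est$se_xy^-2)

  h0 <- make_harmonized(bx = 0.2, sy = 0.01)
  h0$beta_outcome <- 0
  expect_equal(wald_ratio(h0)$beta_xy, 0)

  hz <- make_harmonized(bx = c(0.2, 0), sy = 0.01)
  expect_error(wald_ratio(hz), "undefined.*rs002")

  # literal ratio-of-SE audit flag
  est2 <- wald_ratio(h, se_method = "ratio_of_se")
  expect_equal(est2$se_xy, h$se_outcome / h$se_exposure)
})

test_that("IVW is the precision-weighted mean and matches the WLS identity", {
  h <- t2dm_instruments()
  est <- wald_ratio(h)
  # brute-force oracle from the table rows
  w <- h$beta_exposure^2 / h$se_outcome^2
  b <- h$beta_outcome / h$beta_exposure
  fit <- ivw(est)
  expect_equal(fit$beta, oracle_weighted_mean(b, w), tolerance = 1e-14)
  expect_equal(fit$beta, 0.00877, tolerance = 1e-3)
  expect_equal(fit$se, sum(w)^-0.5, tolerance = 1e-14)
  expect_true(all(fit$penalty_factors == 1) && all(fit$robust_weights == 1))

  # IVW == no-intercept weighted regression of outcome on exposure betas
  wls <- lm(beta_outcome ~ beta_exposure - 1, data = h, weights = 1 / h$se_outcome^2)
  expect_equal(fit$beta, unname(coef(wls)), tolerance = 1e-12)

  # independent meta-analysis oracle: fixed-effect pooling of the ratios
  skip_if_not_installed("metafor")
  rma <- metafor::rma(yi = est$beta_xy, sei = est$se_xy, method = "FE")
  expect_equal(fit$beta, as.numeric(rma$beta), tolerance = 1e-10)
  expect_equal(fit$se, as.numeric(rma$se), tolerance = 1e-10)
})

test_that("IVW degenerate cases have their closed forms", {
  h1 <- make_harmonized(bx = 0.2, sy = 0.01, theta = 0.3)
  e1 <- wald_ratio(h1)
  f1 <- ivw(e1)
  expect_equal(f1$beta, e1$beta_xy)
  expect_equal(f1$se, e1$se_xy)

  h2 <- make_harmonized(bx = c(0.2, 0.2), sy = 0.01, theta = 0.3)
  f2 <- ivw(wald_ratio(h2))
  expect_equal(f2$beta, 0.3, tolerance = 1e-12)
  expect_equal(f2$se, (0.01 / 0.2) / sqrt(2), tolerance = 1e-12)

  expect_error(ivw(wald_ratio(t2dm_instruments()[0, ])), "no variants")
  expect_error(cochran_q(e1), "at least 2")
})

test_that("penalty factors follow the chi-squared tail rule", {
  h <- t2dm_instruments()
  est <- wald_ratio(h)
  ref <- oracle_weighted_mean(est$beta_xy, est$weight)
  f <- penalty_factors(est, ref)
  q <- attr(f, "q")
  expect_equal(unname(q["rs1183910"]), 9.83, tolerance = 1e-2)
  # oracle: chi-squared(1) survival function
  expect_equal(unname(f["rs1183910"]),
               min(1, 20 * pchisq(q[["rs1183910"]], 1, lower.tail = FALSE)))
  expect_lt(abs(unname(f["rs1183910"]) - 0.034), 1e-3)
  expect_equal(unname(f[c("rs6700896", "rs4537545", "rs7553007")]),
               rep(1, 3))  # p_j >= 1/20 clamps to 1

  # zero deviation -> factor exactly 1
  est0 <- est[1, ]
  f0 <- penalty_factors(est0, est0$beta_xy)
  expect_equal(as.numeric(f0), 1)
  expect_equal(unname(attr(f0, "q")), 0)
})

test_that("Cochran's Q decomposes and matches its closed forms", {
  h <- t2dm_instruments()
  q <- cochran_q(wald_ratio(h))
  expect_equal(q$q_total, sum(q$q_contributions))
  expect_equal(q$q_total, 15.3, tolerance = 1e-2)
  expect_equal(q$df, 3L)
  expect_true(all(q$q_contributions >= 0))

  # identical estimates: no dispersion
  hid <- make_harmonized(bx = c(0.2, 0.2), sy = 0.01, theta = 0.3)
  q0 <- cochran_q(wald_ratio(hid))
  expect_equal(q0$q_total, 0)
  expect_equal(q0$pvalue, 1)

  # n = 2 closed form: squared standardized difference at the harmonic weight
  h2 <- make_harmonized(bx = c(0.2, 0.1), sy = c(0.01, 0.02), theta = 0.3)
  h2$beta_outcome <- h2$beta_outcome + c(0.01, -0.02)
  e2 <- wald_ratio(h2)
  q2 <- cochran_q(e2)
  w <- e2$weight
  expect_equal(q2$q_total,
               (e2$beta_xy[1] - e2$beta_xy[2])^2 / (1 / w[1] + 1 / w[2]),
               tolerance = 1e-12)
})

test_that("robust fit is exact on clean data and bounds outlier influence", {
  # exactly collinear through the origin: zero residuals, all weights 1
  x <- c(0.1, 0.2, 0.3, 0.4)
  fit <- robust_fit(x, 0.25 * x, weights = c(1, 2, 3, 4))
  expect_equal(unname(fit$coefficients["slope"]), 0.25, tolerance = 1e-12)
  expect_equal(fit$robust_weights, rep(1, 4))
  expect_true(fit$converged)

  # one gross outlier among 20 collinear points
  set.seed(3)
  x <- runif(20, 0.5, 2)
  y <- 0.7 * x
  y[20] <- y[20] + 5
  fit <- robust_fit(x, y)
  expect_lt(fit$robust_weights[20], 0.05)
  clean <- sum(x[-20] * y[-20]) / sum(x[-20]^2)  # oracle: OLS on the 19 clean points
  expect_equal(unname(fit$coefficients["slope"]), clean, tolerance = 1e-3)

  skip_if_not_installed("MASS")
  rlm <- MASS::rlm(y ~ x - 1, psi = MASS::psi.bisquare, maxit = 100)
  expect_equal(unname(fit$coefficients["slope"]), unname(coef(rlm)),
               tolerance = 1e-2)
})

test_that("robust fit respects symmetry and its preconditions", {
  # symmetric +/- delta residuals: robust fit equals the ordinary fit
  x <- rep(c(1, 2, 3), each = 2)
  y <- 0.5 * x + rep(c(-0.1, 0.1), 3)
  fit <- robust_fit(x, y)
  ols <- sum(x * y) / sum(x^2)
  expect_equal(unname(fit$coefficients["slope"]), ols, tolerance = 1e-10)

  expect_error(robust_fit(1:2, 1:2, include_intercept = TRUE), "at least 3")
  expect_error(robust_fit(numeric(0), numeric(0)), "at least 1")
})

test_that("penalized robust IVW reduces to IVW on homogeneous instruments", {
  h <- make_harmonized(bx = c(0.1, 0.15, 0.2, 0.25), sy = 0.012, theta = 0.11)
  est <- wald_ratio(h)
  plain <- ivw(est)
  pr <- penalized_robust_ivw(est)
  expect_equal(pr$beta, plain$beta, tolerance = 1e-12)
  expect_equal(pr$penalty_factors, setNames(rep(1, 4), h$variant_id))
  # symmetric residuals with no heterogeneity flags: matches IVW within 1e-6
  h2 <- make_harmonized(bx = rep(c(0.2, 0.2), 3), sy = 0.02, theta = 0.11,
                        noise = rep(c(-0.004, 0.004), 3))
  pr2 <- mr_pool(wald_ratio(h2), method = "ivw_penalized_robust")
  expect_equal(pr2$beta, ivw(wald_ratio(h2))$beta, tolerance = 1e-6)
})

test_that("penalized IVW equals the brute-force penalized weighted mean", {
  for (h in list(t2dm_instruments(), as_harmonized(table2),
                 make_harmonized(bx = c(0.11, -0.2, 0.31), sy = c(0.01, 0.02, 0.015),
                                 theta = 0.2, noise = c(0.01, -0.03, 0)))) {
    est <- wald_ratio(h)
    b <- est$beta_xy; w <- est$weight
    ref <- oracle_weighted_mean(b, w)
    f_or <- pmin(1, 20 * pchisq(w * (b - ref)^2, 1, lower.tail = FALSE))
    fit <- mr_pool(est, method = "ivw_penalized")
    expect_equal(fit$beta, oracle_weighted_mean(b, w * f_or), tolerance = 1e-10)
  }
})

test_that("pooled estimates obey scale equivariance and sign antisymmetry", {
  h <- t2dm_instruments()
  for (m in c("ivw", "ivw_penalized", "ivw_robust", "ivw_penalized_robust")) {
    base <- mr_pool(wald_ratio(h), method = m)
    # OR/CI coherence
    expect_equal(base$or_, exp(base$beta))
    expect_equal(base$ci_low, exp(base$beta - 1.959964 * base$se))
    expect_equal(base$ci_high, exp(base$beta + 1.959964 * base$se))
    expect_true(base$ci_low < base$or_ && base$or_ < base$ci_high)

    # multiplying exposure betas and SEs by c divides the estimate by c
    hc <- h
    hc$beta_exposure <- h$beta_exposure * 3
    hc$se_exposure <- h$se_exposure * 3
    scaled <- mr_pool(wald_ratio(hc), method = m)
    expect_equal(scaled$beta, base$beta / 3, tolerance = 1e-7,
                 label = paste(m, "scale equivariance"))

    # negating outcome betas negates the pooled log-OR (OR -> 1/OR)
    hn <- h
    hn$beta_outcome <- -h$beta_outcome
    neg <- mr_pool(wald_ratio(hn), method = m)
    expect_equal(neg$beta, -base$beta, tolerance = 1e-10,
                 label = paste(m, "sign antisymmetry"))
    expect_equal(neg$or_, 1 / base$or_, tolerance = 1e-10)
  }
})
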