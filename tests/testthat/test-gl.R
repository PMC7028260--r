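test_that("gl_slope reduces to the closed form with one non-reference category", {
  d <- tibble::tibble(
    assigned_dose = c(5, 7), rr = c(1, exp(0.4)),
    ci_lower = c(NA, exp(0.4 - 1.959964 * 0.1)),
    ci_upper = c(NA, exp(0.4 + 1.959964 * 0.1)),
    is_reference = c(TRUE, FALSE)
  )
  fit <- gl_slope(d)
  expect_equal(fit$beta, 0.2, tolerance = 1e-9)
  expect_equal(fit$se_beta, 0.05, tolerance = 1e-9)
  expect_equal(fit$method, "two_point")
})

test_that("gl_slope is null on null data and matches IVW-WLS with diagonal C", {
  d <- tibble::tibble(
    assigned_dose = c(5, 6, 7, 8), rr = c(1, 1, 1, 1),
    ci_lower = c(NA, 0.8, 0.85, 0.9), ci_upper = c(NA, 1.25, 1 / 0.85, 1 / 0.9),
    is_reference = c(TRUE, FALSE, FALSE, FALSE)
  )
  expect_equal(gl_slope(d)$beta, 0, tolerance = 1e-12)

  # no counts at all -> independence covariance; oracle: weighted least
  # squares through the origin computed directly
  set.seed(7)
  x <- c(1.2, 2.1, 3.4)
  L <- c(0.2, 0.35, 0.6)
  se <- c(0.15, 0.12, 0.2)
  d2 <- tibble::tibble(
    assigned_dose = c(5, 5 + x), rr = c(1, exp(L)),
    ci_lower = c(NA, exp(L - 1.959964 * se)),
    ci_upper = c(NA, exp(L + 1.959964 * se)),
    is_reference = c(TRUE, FALSE, FALSE, FALSE)
  )
  fit <- gl_slope(d2)
  expect_equal(fit$cov_model, "independence")
  w <- 1 / se^2
  expect_equal(fit$beta, sum(w * x * L) / sum(w * x^2), tolerance = 1e-12)
  expect_equal(fit$se_beta, 1 / sqrt(sum(w * x^2)), tolerance = 1e-12)
})

test_that("the fitted-count covariance is SPD and tightens the GLS fit", {
  a <- c(50, 80, 120, 180); n <- rep(1000, 4)
  d <- counts_to_categories(a, n, doses = c(5, 6, 7, 8))
  fit <- gl_slope(d)
  expect_equal(fit$cov_model, "gl_fitted_counts")
  expect_true(fit$se_beta > 0)

  # reconstruct C exactly as the estimator builds it and check SPD
  eff <- effect_from_ci(d$rr[-1], d$ci_lower[-1], d$ci_upper[-1])
  ft <- remr:::gl_fitted_counts(d$rr[-1], d$total[-1], d$total[1], sum(d$cases))
  C <- diag(eff$se^2)
  C[upper.tri(C)] <- C[lower.tri(C)] <- 1 / ft$a0 - 1 / d$total[1]
  ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
  expect_true(all(ev > 0))
  # fitted reference cases respect the total-case margin
  expect_equal(ft$a0 * (1 + sum(d$rr[-1] * d$total[-1]) / d$total[1]),
               sum(d$cases), tolerance = 1e-6)
})

test_that("gl_slope recovers a known trend from simulated counts", {
  # one 4-category study, binomial sampling under a log-linear truth
  set.seed(11)
  doses <- c(5, 6.5, 8, 9.5)
  n <- rep(2000, 4)
  beta_true <- 0.15
  risk <- 0.05 * exp(beta_true * (doses - doses[1]))
  cases <- rbinom(4, n, risk)
  d <- counts_to_categories(cases, n, doses = doses)
  fit <- gl_slope(d)
  expect_lt(abs(fit$beta - beta_true), 2 * fit$se_beta)

  # repeated-sampling calibration: near-unbiased, CI coverage ~95%
  reps <- 500
  est <- matrix(NA_real_, reps, 2)
  set.seed(12)
  for (r in seq_len(reps)) {
    cases <- pmax(rbinom(4, n, risk), 1)
    dd <- counts_to_categories(cases, n, doses = doses)
    f <- gl_slope(dd)
    est[r, ] <- c(f$beta, f$se_beta)
  }
  bias <- mean(est[, 1]) - beta_true
  mc_se <- sd(est[, 1]) / sqrt(reps)
  expect_lt(abs(bias), 3 * mc_se)
  coverage <- mean(abs(est[, 1] - beta_true) <= 1.959964 * est[, 2])
  expect_gte(coverage, 0.92)
  expect_lte(coverage, 0.98)
})

test_that("per_unit_effects prefers reported values and falls back to GL", {
  eff <- per_unit_effects(table1_fixture())
  iguchi <- eff[eff$study_id == "iguchi", ]
  expect_equal(iguchi$beta, log(1.18))
  expect_equal(iguchi$se, (log(1.28) - log(1.09)) / (2 * 1.959964))
  expect_equal(iguchi$method, "reported")
  # every real study reports a per-1% value, so none fall back
  expect_true(all(eff$method == "reported"))
  # auxiliary category sets stay out unless requested
  expect_false(any(grepl("parox", eff$study_id)))
  expect_true(any(grepl("parox",
                        per_unit_effects(table1_fixture(),
                                         include_auxiliary = TRUE)$study_id)))

  # forced two-point path: single non-reference category, no per-unit value
  d <- minimal_table()[1:2, ]
  d$cases <- c(100, 150); d$total <- c(1000, 1000)
  two <- per_unit_effects(d)
  expect_equal(two$method, "two_point")

  # neither form available -> insufficient data
  d2 <- minimal_table()
  d2$per_unit_rr <- NA_real_
  d2$rr <- c(1, 1.2, 1.5)
  d2$cat_lower <- NA_real_; d2$cat_upper <- NA_real_   # no doses assignable
  expect_error(suppressWarnings(per_unit_effects(d2)),
               class = "remr_domain_error")
})
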