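test_that("rcs_basis matches the textbook natural-spline formula", {
  knots <- c(5.5, 7, 8.5)
  x <- c(5, 5.5, 6.2, 7, 7.9, 8.5, 9.4, 4.1, 10.3, 6.9)
  B <- rcs_basis(x, knots)
  expect_equal(dim(B), c(10, 2))
  expect_equal(B[, 1], x)

  # independent evaluation, written out long-hand
  t1 <- 5.5; t2 <- 7; t3 <- 8.5
  p3 <- function(u) ifelse(u > 0, u^3, 0)
  ref <- (p3(x - t1) -
            p3(x - t2) * (t3 - t1) / (t3 - t2) +
            p3(x - t3) * (t2 - t1) / (t3 - t2)) / (t3 - t1)^2
  expect_equal(B[, 2], ref, tolerance = 1e-10)

  # nonlinear column vanishes at and below the first knot
  expect_equal(rcs_basis(c(4, 5.5), knots)[, 2], c(0, 0))
  # linear tails: second differences vanish beyond the boundary knots
  lo <- rcs_basis(c(3, 3.5, 4), knots)[, 2]
  hi <- rcs_basis(c(9, 9.5, 10), knots)[, 2]
  expect_equal(diff(diff(lo)), 0, tolerance = 1e-10)
  expect_equal(diff(diff(hi)), 0, tolerance = 1e-10)

  # k knots -> k - 1 columns
  expect_equal(ncol(rcs_basis(x, c(5, 6, 7, 8, 9))), 4)
  expect_error(rcs_basis(x, c(5, 6)), class = "remr_domain_error")
  expect_error(rcs_basis(c(1, Inf), knots), class = "remr_domain_error")
})

test_that("a linear-only REMR fit collapses to pooled inverse-variance slopes", {
  # two-category studies, one observation each: the one-stage fit with a
  # linear basis must equal the fixed-effect pool of the per-study slopes
  set.seed(21)
  k <- 5
  ref_dose <- rep(5, k)
  dose <- 5 + runif(k, 1, 4)
  L <- 0.12 * (dose - ref_dose) + rnorm(k, 0, 0.05)
  se <- runif(k, 0.08, 0.3)
  tab <- purrr::map_dfr(seq_len(k), function(i) {
    d <- minimal_table()[1:2, ]
    d$study_id <- paste0("s", i); d$label <- paste0("S", i)
    d$cat_lower <- c(4.5, dose[i] - 0.5)
    d$cat_upper <- c(5.5, dose[i] + 0.5)
    d$rr <- c(1, exp(L[i]))
    d$ci_lower <- c(NA, exp(L[i] - 1.959964 * se[i]))
    d$ci_upper <- c(NA, exp(L[i] + 1.959964 * se[i]))
    d
  })
  fit <- fit_remr(tab, knots = "linear", min_categories = 1)
  slopes <- L / (dose - ref_dose)
  slope_se <- se / (dose - ref_dose)
  w <- 1 / slope_se^2
  # inverse-variance weighted regression through the origin on (x, L) pairs
  x <- dose - ref_dose
  expect_equal(unname(fit$coefficients["linear"]),
               sum((1 / se^2) * x * L) / sum((1 / se^2) * x^2),
               tolerance = 1e-12)
  # identical to the fixed-effect pooled two-point slope when x = 1 for all
  tab1 <- purrr::map_dfr(seq_len(k), function(i) {
    d <- minimal_table()[1:2, ]
    d$study_id <- paste0("u", i); d$label <- paste0("U", i)
    d$cat_lower <- c(4.5, 5.5); d$cat_upper <- c(5.5, 6.5)
    d$rr <- c(1, exp(L[i]))
    d$ci_lower <- c(NA, exp(L[i] - 1.959964 * se[i]))
    d$ci_upper <- c(NA, exp(L[i] + 1.959964 * se[i]))
    d
  })
  fit1 <- fit_remr(tab1, knots = "linear", min_categories = 1)
  fe <- pool(tibble::tibble(beta = L, se = se, label = paste0("u", 1:k)),
             method = "fixed")
  expect_equal(unname(fit1$coefficients["linear"]), fe$pooled_log_rr,
               tolerance = 1e-12)
})

test_that("predicted curves are anchored, coherent and reference-invariant", {
  nondm <- dplyr::filter(table1_fixture(), population == "no_known_diabetes")
  fit <- fit_remr(nondm)
  expect_equal(glance(fit)$n_clusters, 4)
  expect_equal(glance(fit)$n_obs, 12)

  cv <- predict_curve(fit, ref_dose = 5, from = 5, to = 9, step = 0.05)
  expect_equal(cv$rr[cv$dose == 5], 1)
  expect_equal(cv$lo[cv$dose == 5], 1)
  expect_equal(cv$hi[cv$dose == 5], 1)
  expect_true(all(cv$lo <= cv$rr + 1e-12 & cv$rr <= cv$hi + 1e-12))

  # anchor shifts the curve, not its shape: RR ratios between two doses do
  # not depend on the reference dose
  cv2 <- predict_curve(fit, ref_dose = 6, from = 5, to = 9, step = 0.05)
  r1 <- cv$rr[cv$dose == 8] / cv$rr[cv$dose == 7]
  r2 <- cv2$rr[cv2$dose == 8] / cv2$rr[cv2$dose == 7]
  expect_equal(r1, r2, tolerance = 1e-10)

  # closed form for a pure linear coefficient: RR(7) vs 5 at ln(1.15)/unit
  lin <- fit
  lin$coefficients <- c(linear = log(1.15))
  lin$basis <- function(d) matrix(d, ncol = 1, dimnames = list(NULL, "linear"))
  lin$robust_cov <- matrix(1e-6, 1, 1)
  cvl <- predict_curve(lin, ref_dose = 5, from = 5, to = 7, step = 0.5)
  expect_equal(cvl$rr[cvl$dose == 7], 1.15^2, tolerance = 1e-9)

  expect_warning(predict_curve(fit, ref_dose = 2), "outside")
})

test_that("threshold_dose requires persistent significance", {
  base <- tibble::tibble(
    dose = seq(5, 8, by = 0.05),
    rr = seq(1, 2, length.out = 61)
  )
  always <- structure(dplyr::mutate(base, lo = rr * 0.99 + 0.02, hi = rr * 1.1),
                      ref_dose = 5, class = c("dose_curve", "tbl_df", "tbl", "data.frame"))
  expect_equal(threshold_dose(always), 5.05)

  never <- structure(dplyr::mutate(base, lo = rr * 0.5, hi = rr * 1.1),
                     ref_dose = 5, class = c("dose_curve", "tbl_df", "tbl", "data.frame"))
  expect_true(is.na(threshold_dose(never)))

  # an isolated early crossing must not count
  dip <- dplyr::mutate(base, lo = ifelse(dose < 5.5 & dose > 5.2, 1.01,
                                         ifelse(dose > 7, 1.05, 0.9)),
                       hi = rr * 2)
  dip <- structure(dip, ref_dose = 5,
                   class = c("dose_curve", "tbl_df", "tbl", "data.frame"))
  expect_equal(threshold_dose(dip), 7.05)
})

test_that("the Wald nonlinearity test has power against a threshold truth", {
  cfg <- synthetic_config(n_studies = 8, n_per_category = 5000,
                          truth = "threshold", beta = 0.3, change_point = 6.3,
                          heterogeneity_sd = 0, seed = 77)
  res <- recovery_experiment(cfg, reps = 100, fit_spline = TRUE)
  expect_gte(res$summary$rejection_rate, 0.8)
})

test_that("identifiability is policed", {
  nondm <- dplyr::filter(table1_fixture(), population == "no_known_diabetes")
  expect_error(fit_remr(nondm, knots = c(4.8, 5.2, 5.6, 6.5, 7.5, 9)),
               class = "remr_identifiability_error")
  expect_error(fit_remr(dplyr::filter(nondm, study_id == "dublin")),
               class = "remr_insufficient_data_error")
})
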