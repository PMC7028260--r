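test_that("pool matches a direct evaluation of the DL formulas", {
  set.seed(3)
  for (k in c(2, 5, 9)) {
    y <- rnorm(k, 0.1, 0.3)
    s <- runif(k, 0.05, 0.4)
    fit <- pool(tibble::tibble(beta = y, se = s, label = letters[seq_len(k)]))

    # oracle: brute-force formula evaluation
    w <- 1 / s^2
    yfe <- sum(w * y) / sum(w)
    Q <- sum(w * (y - yfe)^2)
    tau2 <- max(0, (Q - (k - 1)) / (sum(w) - sum(w^2) / sum(w)))
    ws <- 1 / (s^2 + tau2)
    mu <- sum(ws * y) / sum(ws)
    expect_equal(fit$Q, Q, tolerance = 1e-12)
    expect_equal(fit$tau2, tau2, tolerance = 1e-12)
    expect_equal(fit$pooled_log_rr, mu, tolerance = 1e-12)
    expect_equal(fit$se, 1 / sqrt(sum(ws)), tolerance = 1e-12)
    expect_equal(fit$i2, max(0, (Q - (k - 1)) / Q) * 100, tolerance = 1e-10)

    # order invariance
    perm <- sample(k)
    fit2 <- pool(tibble::tibble(beta = y[perm], se = s[perm],
                                label = letters[perm]))
    expect_equal(fit2$pooled_log_rr, fit$pooled_log_rr)
    expect_equal(fit2$Q, fit$Q)

    # the random-effects CI is never narrower than the fixed-effect CI
    fe <- pool(tibble::tibble(beta = y, se = s, label = letters[seq_len(k)]),
               method = "fixed")
    expect_gte(fit$se, fe$se)
    expect_equal(fe$tau2, 0)
  }
})

test_that("degenerate pools behave as contracts demand", {
  one <- pool(tibble::tibble(beta = 0.25, se = 0.1, label = "only"))
  expect_equal(one$pooled_log_rr, 0.25)
  expect_equal(c(one$Q, one$i2, one$tau2), c(0, 0, 0))

  two <- pool(tibble::tibble(beta = c(0.1, 0.1), se = c(0.05, 0.05),
                             label = c("a", "b")))
  expect_equal(two$pooled_log_rr, 0.1)
  expect_equal(two$Q, 0)
  expect_equal(two$i2, 0)

  expect_error(pool(tibble::tibble(beta = numeric(), se = numeric(),
                                   label = character())),
               class = "remr_empty_error")
  expect_error(pool(tibble::tibble(beta = 1, se = 0, label = "x")),
               class = "remr_domain_error")

  td <- tidy(two)
  expect_equal(sum(td$weight_pct), 100)
  expect_named(glance(two),
               c("k", "rr", "ci_lower", "ci_upper", "Q", "df", "i2", "tau2",
                 "p_overall", "heterogeneity", "method"))
})

test_that("heterogeneity classification follows the I2 bands", {
  expect_equal(classify_heterogeneity(0), "low")
  expect_equal(classify_heterogeneity(49.99), "low")
  expect_equal(classify_heterogeneity(50), "moderate")
  expect_equal(classify_heterogeneity(52), "moderate")
  expect_equal(classify_heterogeneity(75), "moderate")
  expect_equal(classify_heterogeneity(79), "high")
  expect_error(classify_heterogeneity(-1), class = "remr_domain_error")
  expect_error(classify_heterogeneity(101), class = "remr_domain_error")
})

test_that("subgroup_pool and leave_one_out honour their contracts", {
  eff <- per_unit_effects(table1_fixture())
  af <- eff[eff$outcome == "AF", ]

  sg <- subgroup_pool(af, population)
  expect_setequal(sg$group, c("diabetes_or_IGT", "no_known_diabetes"))
  expect_equal(sg$k[sg$group == "diabetes_or_IGT"], 4)

  # a single-record group returns that record's estimate
  solo <- subgroup_pool(af[af$study_id == "iguchi", ], population)
  expect_equal(solo$rr, 1.18, tolerance = 1e-12)

  loo <- leave_one_out(af)
  expect_equal(nrow(loo), 9)
  expect_true(all(loo$k == 8))
  # two studies: each result is the other study alone
  two <- leave_one_out(af[af$study_id %in% c("iguchi", "latini"), ])
  expect_equal(two$rr[two$excluded == "Iguchi"], 1.11, tolerance = 1e-12)
  expect_equal(two$rr[two$excluded == "Latini"], 1.18, tolerance = 1e-12)
  expect_error(leave_one_out(af[1, ]), class = "remr_insufficient_data_error")
})

test_that("trim-and-fill finds nothing to impute in a symmetric funnel", {
  sym <- tibble::tibble(
    beta = 0.1 + c(-0.3, -0.2, -0.1, 0, 0.1, 0.2, 0.3),
    se = c(0.3, 0.25, 0.2, 0.1, 0.2, 0.25, 0.3),
    label = letters[1:7]
  )
  tf <- trim_and_fill(sym)
  expect_equal(tf$k0, 0)
  expect_equal(tf$adjusted$pooled_log_rr, pool(sym)$pooled_log_rr)
  expect_error(trim_and_fill(sym[1:2, ]),
               class = "remr_insufficient_data_error")
})

test_that("trim-and-fill detects one-sided suppression (conservatively)", {
  # symmetric 9-study set about 0; suppress the three largest effects.
  # The iterated R0 run estimator is conservative by construction
  # (k0 = run length - 1), so on the 6 remaining studies it settles at 2 of
  # the 3 suppressed studies; the adjusted pool must move back toward 0.
  full <- c(-2.0, -1.6, -1.2, -0.1, 0, 0.1, 1.2, 1.6, 2.0)
  obs <- tibble::tibble(
    beta = setdiff(full, c(1.2, 1.6, 2.0)),
    se = c(1, 1, 1, 0.05, 0.05, 0.05),
    label = letters[1:6]
  )
  tf <- trim_and_fill(obs, side = "left")
  expect_equal(tf$k0, 2)
  expect_equal(sum(tf$filled$imputed), 2)
  naive <- pool(obs)$pooled_log_rr
  expect_gt(tf$adjusted$pooled_log_rr, naive)
  expect_lt(abs(tf$adjusted$pooled_log_rr), abs(naive))
})
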