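#' Random-effects (DerSimonian-Laird) pooling of study effects
#'
#' Inverse-variance pooling of per-study log relative risks with the
#' moment-based DerSimonian-Laird estimate of between-study variance:
#' fixed-effect weights \eqn{w_i = 1/se_i^2}, Cochran
#' \eqn{Q = \sum w_i (y_i - \bar y_{FE})^2},
#' \eqn{\tau^2 = \max(0, (Q - df) / (\sum w - \sum w^2 / \sum w))},
#' random-effects weights \eqn{w_i^* = 1/(se_i^2 + \tau^2)}, and
#' \eqn{I^2 = \max(0, (Q - df)/Q) \times 100}. With `method = "fixed"`,
#' \eqn{\tau^2} is forced to zero.
#'
#' @param data A data frame with one row per study: a log-effect column, its
#'   standard error, and optionally a label (used in forest output).
#' @param effect,se,label Columns holding the log relative risk, its SE and
#'   the study label (tidy-eval; defaults `beta`, `se`, `label`).
#' @param method `"dl"` (random effects, default) or `"fixed"`.
#' @return A `meta_pool` object; see [tidy.meta_pool()], [glance.meta_pool()],
#'   [autoplot.meta_pool()].
#' @examples
#' table1_fixture() |>
#'   per_unit_effects() |>
#'   dplyr::filter(outcome == "POAF_CABG") |>
#'   pool()
#' @export
pool <- function(data, effect = beta, se = se, label = label,
                 method = c("dl", "fixed")) {
  method <- match.arg(method)
  d <- as_tibble(data)
  y <- rlang::eval_tidy(rlang::enquo(effect), d)
  s <- rlang::eval_tidy(rlang::enquo(se), d)
  lab <- tryCatch(rlang::eval_tidy(rlang::enquo(label), d),
                  error = function(e) NULL)
  if (is.null(lab)) lab <- d$study_id %||% paste0("study_", seq_along(y))
  if (length(y) == 0) {
    abort("No studies to pool.", class = "remr_empty_error")
  }
  if (anyNA(y) || anyNA(s) || any(s <= 0)) {
    abort("All effects need finite log_rr and se > 0.",
          class = "remr_domain_error")
  }
  k <- length(y)
  w <- 1 / s^2
  y_fe <- sum(w * y) / sum(w)
  Q <- sum(w * (y - y_fe)^2)
  df <- k - 1
  tau2 <- if (method == "fixed" || k == 1) 0 else {
    max(0, (Q - df) / (sum(w) - sum(w^2) / sum(w)))
  }
  ws <- 1 / (s^2 + tau2)
  mu <- sum(ws * y) / sum(ws)
  se_mu <- 1 / sqrt(sum(ws))
  i2 <- if (k == 1 || Q <= 0) 0 else max(0, (Q - df) / Q) * 100
  z <- mu / se_mu
  structure(
    list(
      k = k,
      pooled_log_rr = mu,
      se = se_mu,
      ci_lower = exp(mu - Z95 * se_mu),
      ci_upper = exp(mu + Z95 * se_mu),
      Q = Q, df = df, tau2 = tau2, i2 = i2,
      p_overall = 2 * stats::pnorm(-abs(z)),
      method = if (method == "dl") "DL_random" else "fixed",
      studies = tibble(
        label = as.character(lab), log_rr = y, se = s,
        weight = ws / sum(ws)
      )
    ),
    class = "meta_pool"
  )
}

#' @export
print.meta_pool <- function(x, ...) {
  cat(sprintf(
    "Pooled RR (%s, k = %d): %.2f [%.2f, %.2f]\n  Q = %.2f (df = %d), I2 = %.0f%% (%s), tau2 = %.4f, p = %.2g\n",
    x$method, x$k, exp(x$pooled_log_rr), x$ci_lower, x$ci_upper,
    x$Q, x$df, x$i2, classify_heterogeneity(x$i2), x$tau2, x$p_overall
  ))
  invisible(x)
}

#' @rdname pool
#' @param x A `meta_pool` object.
#' @param ... Unused.
#' @export
tidy.meta_pool <- function(x, ...) {
  dplyr::mutate(x$studies,
    rr = exp(.data$log_rr),
    ci_lower = exp(.data$log_rr - Z95 * .data$se),
    ci_upper = exp(.data$log_rr + Z95 * .data$se),
    weight_pct = 100 * .data$weight
  )
}

#' @rdname pool
#' @export
glance.meta_pool <- function(x, ...) {
  tibble(
    k = x$k, rr = exp(x$pooled_log_rr),
    ci_lower = x$ci_lower, ci_upper = x$ci_upper,
    Q = x$Q, df = x$df, i2 = x$i2, tau2 = x$tau2,
    p_overall = x$p_overall,
    heterogeneity = classify_heterogeneity(x$i2),
    method = x$method
  )
}

#' Classify an I-squared value
#'
#' Standard interpretation bands: low below 50%, moderate from 50% to 75%
#' (inclusive), high above 75%.
#'
#' @param i2 I-squared, in percent (0-100).
#' @return `"low"`, `"moderate"` or `"high"`.
#' @examples
#' classify_heterogeneity(52)
#' @export
classify_heterogeneity <- function(i2) {
  if (anyNA(i2) || any(i2 < 0) || any(i2 > 100)) {
    abort("i2 must be within [0, 100].", class = "remr_domain_error")
  }
  dplyr::case_when(
    i2 < 50 ~ "low",
    i2 <= 75 ~ "moderate",
    TRUE ~ "high"
  )
}

#' Pool within subgroups
#'
#' Splits the per-study effects by a grouping column and pools each
#' non-empty group separately.
#'
#' @param data Per-study effects as from [per_unit_effects()].
#' @param by Grouping column (tidy-eval), e.g. `population`, `outcome`,
#'   `adjusted`.
#' @inheritParams pool
#' @return A tibble with one row per group: the group label, and the pooled
#'   summary columns of [glance.meta_pool()] plus a `fit` list-column.
#' @examples
#' table1_fixture() |>
#'   per_unit_effects() |>
#'   dplyr::filter(outcome == "AF", !ami_cohort) |>
#'   subgroup_pool(population)
#' @export
subgroup_pool <- function(data, by, method = c("dl", "fixed")) {
  method <- match.arg(method)
  d <- as_tibble(data)
  g <- rlang::eval_tidy(rlang::enquo(by), d)
  if (anyNA(g)) {
    warn("Rows with missing group dropped from subgroup pooling.")
    d <- d[!is.na(g), ]
    g <- g[!is.na(g)]
  }
  purrr::imap_dfr(split(d, g), function(dd, grp) {
    fit <- pool(dd, method = method)
    dplyr::bind_cols(tibble(group = grp), glance(fit), tibble(fit = list(fit)))
  })
}

#' Leave-one-out sensitivity analysis
#'
#' Re-pools the effects excluding each study in turn, to detect dominance by
#' a single large or extreme study.
#'
#' @inheritParams pool
#' @return A tibble with one row per excluded study (`excluded`), with the
#'   pooled summary of the remaining `k - 1` studies.
#' @examples
#' table1_fixture() |>
#'   per_unit_effects() |>
#'   dplyr::filter(outcome == "AF") |>
#'   leave_one_out()
#' @export
leave_one_out <- function(data, effect = beta, se = se, label = label,
                          method = c("dl", "fixed")) {
  method <- match.arg(method)
  d <- as_tibble(data)
  if (nrow(d) < 2) {
    abort("Leave-one-out needs >= 2 studies.",
          class = "remr_insufficient_data_error")
  }
  y <- rlang::eval_tidy(rlang::enquo(effect), d)
  s <- rlang::eval_tidy(rlang::enquo(se), d)
  lab <- tryCatch(rlang::eval_tidy(rlang::enquo(label), d),
                  error = function(e) NULL)
  if (is.null(lab)) lab <- d$study_id %||% paste0("study_", seq_len(nrow(d)))
  tb <- tibble(beta = y, se = s, label = as.character(lab))
  purrr::map_dfr(seq_len(nrow(tb)), function(i) {
    fit <- pool(tb[-i, ], method = method)
    dplyr::bind_cols(tibble(excluded = tb$label[i]), glance(fit))
  })
}

#' Duval-Tweedie trim-and-fill adjustment
#'
#' Nonparametric funnel-asymmetry correction: iteratively trims the most
#' extreme effects on the suspected side using the R0 run estimator, then
#' fills mirrored counterparts and re-pools. `side = "right"` suspects an
#' excess of large positive effects.
#'
#' @inheritParams pool
#' @param side Side of the funnel suspected of holding the unmatched
#'   (published-only) studies: `"right"` or `"left"`.
#' @param max_iter Maximum trim iterations.
#' @return A list with `k0` (number of imputed studies), `adjusted` (the
#'   re-pooled `meta_pool` including mirrored effects) and `filled` (the
#'   augmented effect tibble).
#' @export
trim_and_fill <- function(data, effect = beta, se = se, label = label,
                          side = c("right", "left"), max_iter = 50) {
  side <- match.arg(side)
  d0 <- as_tibble(data)
  eq <- rlang::enquo(effect); sq <- rlang::enquo(se)
  y <- rlang::eval_tidy(eq, d0)
  s <- rlang::eval_tidy(sq, d0)
  lab <- tryCatch(as.character(rlang::eval_tidy(rlang::enquo(label), d0)),
                  error = function(e) NULL)
  if (is.null(lab)) lab <- d0$study_id %||% paste0("study_", seq_along(y))
  k <- length(y)
  if (k < 3) {
    abort("Trim-and-fill needs >= 3 studies.",
          class = "remr_insufficient_data_error")
  }
  if (side == "left") y <- -y
  k0 <- 0
  for (iter in seq_len(max_iter + 1)) {
    if (iter > max_iter) {
      abort("Trim-and-fill did not converge.", class = "remr_numerical_error")
    }
    keep <- seq_len(k - k0)
    ord <- order(y)
    y_trim <- y[ord][keep]
    s_trim <- s[ord][keep]
    w <- 1 / s_trim^2
    mu <- sum(w * y_trim) / sum(w)
    dev <- y - mu
    r <- rank(abs(dev), ties.method = "first")
    # R0: length of the rightmost run of positive deviations among the
    # largest absolute deviations, minus 1.
    signs <- sign(dev)[order(r, decreasing = TRUE)]
    run <- 0
    for (sgn in signs) {
      if (sgn > 0) run <- run + 1 else break
    }
    k0_new <- max(0, run - 1)
    if (k0_new == k0) break
    k0 <- k0_new
  }
  filled <- tibble(
    label = lab, log_rr = if (side == "left") -y else y, se = s,
    imputed = FALSE
  )
  if (k0 > 0) {
    ord <- order(y, decreasing = TRUE)
    mirror <- y[ord][seq_len(k0)]
    mirror_se <- s[ord][seq_len(k0)]
    y_mir <- 2 * mu - mirror
    filled <- dplyr::bind_rows(filled, tibble(
      label = paste0("filled_", seq_len(k0)),
      log_rr = if (side == "left") -y_mir else y_mir,
      se = mirror_se,
      imputed = TRUE
    ))
  }
  adjusted <- pool(filled, effect = log_rr, se = se, label = label)
  list(k0 = k0, adjusted = adjusted, filled = filled)
}
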