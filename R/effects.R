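# z multiplier for a 95% interval; qnorm(0.975) to the precision used
# throughout the package.
Z95 <- 1.959964

#' Convert a reported relative risk and 95% CI to a log-scale effect
#'
#' The standard error is recovered from the CI width on the natural-log
#' scale, `se = (ln(hi) - ln(lo)) / (2 * 1.959964)`; asymmetric printed
#' intervals are handled by the same symmetric-SE formula, keeping the point
#' estimate intact.
#'
#' @param rr,lo,hi Relative risk and 95% CI bounds, all positive with
#'   `lo <= rr <= hi`.
#' @return A one-row tibble with `log_rr`, `se` and `source = "reported"`.
#' @examples
#' effect_from_ci(0.89, 0.80, 0.98)
#' @export
effect_from_ci <- function(rr, lo, hi) {
  if (any(c(rr, lo, hi) <= 0) || anyNA(c(rr, lo, hi))) {
    abort("rr, lo, hi must all be positive.", class = "remr_domain_error")
  }
  if (any(lo > hi) || any(lo > rr) || any(rr > hi)) {
    abort("Need lo <= rr <= hi.", class = "remr_domain_error")
  }
  tibble(
    log_rr = log(rr),
    se = (log(hi) - log(lo)) / (2 * Z95),
    source = "reported"
  )
}

#' Relative risk from category counts
#'
#' Cumulative-incidence risk ratio of an exposed category against a
#' reference, with large-sample log-scale standard error
#' `sqrt(1/a - 1/n1 + 1/c - 1/n0)`. If any cell is zero, `continuity`
#' (default 0.5) is added to all four cells first.
#'
#' @param cases_exp,total_exp Cases and participants in the exposed category.
#' @param cases_ref,total_ref Cases and participants in the reference.
#' @param continuity Continuity correction used when a cell is zero.
#' @return A one-row tibble with `log_rr`, `se` and `source = "from_counts"`.
#' @examples
#' rr_from_counts(20, 100, 10, 100)
#' @export
rr_from_counts <- function(cases_exp, total_exp, cases_ref, total_ref,
                           continuity = 0.5) {
  if (any(c(total_exp, total_ref) <= 0)) {
    abort("Totals must be positive.", class = "remr_domain_error")
  }
  if (any(c(cases_exp, cases_ref) < 0)) {
    abort("Case counts must be non-negative.", class = "remr_domain_error")
  }
  zero <- cases_exp == 0 | cases_ref == 0 |
    cases_exp == total_exp | cases_ref == total_ref
  a <- cases_exp + ifelse(zero, continuity, 0)
  n1 <- total_exp + ifelse(zero, 2 * continuity, 0)
  c0 <- cases_ref + ifelse(zero, continuity, 0)
  n0 <- total_ref + ifelse(zero, 2 * continuity, 0)
  tibble(
    log_rr = log((a / n1) / (c0 / n0)),
    se = sqrt(1 / a - 1 / n1 + 1 / c0 - 1 / n0),
    source = "from_counts"
  )
}

#' Hamling pseudo-counts for reported relative risks
#'
#' Reconstructs effective category-level counts (cases and participants)
#' that simultaneously reproduce every reported relative risk, every
#' reported CI width (variance), and the study's crude case and non-case
#' totals. Two unknowns — the reference category's effective cases `a0` and
#' participants `n0` — pin down all other categories in closed form; they are
#' found by Newton iteration on the two margin constraints.
#'
#' @param rr,lo,hi Category relative risks and 95% CI bounds; the reference
#'   category carries `rr = 1` and `NA` bounds.
#' @param is_reference Logical flag marking the (single) reference category.
#' @param study_cases,study_total Crude number of cases and participants in
#'   the whole study (Hamling's margin constraints).
#' @param tol Convergence tolerance on the margin residuals.
#' @return A tibble with one row per category: `cases`, `total`, and the
#'   reproduced `rr` and `se`.
#' @references Hamling-style effective-count reconstruction for risk ratios.
#' @export
hamling_pseudocounts <- function(rr, lo, hi, is_reference,
                                 study_cases, study_total, tol = 1e-10) {
  k <- length(rr)
  stopifnot(length(is_reference) == k, sum(is_reference) == 1)
  if (k < 2) abort("Need >= 2 categories.", class = "remr_domain_error")
  if (is.na(study_cases) || is.na(study_total) || study_total <= study_cases) {
    abort("Crude study cases/total required (total > cases).",
          class = "remr_precondition_error")
  }
  ref <- which(is_reference)
  nonref <- setdiff(seq_len(k), ref)
  if (anyNA(rr[nonref]) || anyNA(lo[nonref]) || anyNA(hi[nonref])) {
    abort("All non-reference categories need rr and CI.",
          class = "remr_precondition_error")
  }
  v <- ((log(hi[nonref]) - log(lo[nonref])) / (2 * Z95))^2
  R <- rr[nonref]
  A <- study_cases
  B <- study_total - study_cases

  # Given (a0, n0): category i has risk p_i = R_i * a0/n0 and must satisfy
  # 1/a_i - 1/n_i = v_i - (1/a0 - 1/n0), with a_i = p_i * n_i, so
  # n_i = (1/p_i - 1)/(v_i - 1/a0 + 1/n0).
  cells <- function(a0, n0) {
    p <- R * a0 / n0
    vi <- v - 1 / a0 + 1 / n0
    if (any(p <= 0) || any(p >= 1) || any(vi <= 0)) return(NULL)
    ni <- (1 / p - 1) / vi
    ai <- p * ni
    list(a = ai, n = ni)
  }
  resid <- function(theta) {
    a0 <- exp(theta[1]); n0 <- a0 + exp(theta[2])
    cc <- cells(a0, n0)
    if (is.null(cc)) return(c(1e6, 1e6))
    c(sum(cc$a) + a0 - A,
      sum(cc$n - cc$a) + (n0 - a0) - B)
  }
  newton <- function(theta) {
    for (iter in 1:200) {
      r0 <- resid(theta)
      if (max(abs(r0)) < tol * max(1, A, B)) {
        return(list(theta = theta, converged = TRUE))
      }
      # numerical Jacobian
      J <- matrix(0, 2, 2)
      h <- 1e-6
      for (j in 1:2) {
        tp <- theta; tp[j] <- tp[j] + h
        J[, j] <- (resid(tp) - r0) / h
      }
      step <- tryCatch(solve(J, r0), error = function(e) NULL)
      if (is.null(step)) break
      # damped Newton
      lambda <- 1
      repeat {
        cand <- theta - lambda * step
        if (max(abs(resid(cand))) < max(abs(r0)) || lambda < 1e-6) break
        lambda <- lambda / 2
      }
      theta <- theta - lambda * step
    }
    list(theta = theta, converged = FALSE)
  }
  # The two margin constraints can admit more than one positive root; start
  # from several plausible reference-category sizes and keep the root whose
  # effective reference denominator is closest to an even category split.
  n0_even <- study_total / k
  crude_risk <- A / study_total
  roots <- list()
  for (n0_start in n0_even * c(1, 0.5, 2, 4)) {
    for (risk_start in pmin(pmax(crude_risk * c(1, 0.5, 2), 1e-4), 0.99)) {
      a0_start <- max(n0_start * risk_start, 1e-3)
      fit <- newton(c(log(a0_start), log(max(n0_start - a0_start, 1e-3))))
      if (fit$converged) roots <- c(roots, list(fit$theta))
    }
  }
  if (length(roots) == 0) {
    abort("Hamling pseudo-count solver did not converge.",
          class = "remr_numerical_error")
  }
  n0s <- vapply(roots, function(th) exp(th[1]) + exp(th[2]), numeric(1))
  theta <- roots[[which.min(abs(n0s - n0_even))]]
  a0 <- exp(theta[1]); n0 <- a0 + exp(theta[2])
  cc <- cells(a0, n0)
  cases <- numeric(k); totals <- numeric(k)
  cases[ref] <- a0; totals[ref] <- n0
  cases[nonref] <- cc$a; totals[nonref] <- cc$n
  tibble(
    cases = cases, total = totals,
    rr = (cases / totals) / (cases[ref] / totals[ref]),
    se = sqrt(pmax(0, 1 / cases - 1 / totals + 1 / cases[ref] - 1 / totals[ref]))
  )
}

#' Re-reference category effects via Hamling pseudo-counts
#'
#' Expresses every category's effect relative to a new reference category,
#' by first reconstructing pseudo-counts consistent with the reported
#' relative risks, CI widths and crude study margins
#' ([hamling_pseudocounts()]), then recomputing risk ratios against the new
#' reference. The new reference itself maps to `log_rr = 0, se = 0`.
#'
#' @inheritParams hamling_pseudocounts
#' @param new_reference Index of the category to re-reference against.
#' @return A tibble with one row per category: `log_rr`, `se`, `source`.
#' @export
hamling_reref <- function(rr, lo, hi, is_reference, new_reference,
                          study_cases, study_total) {
  k <- length(rr)
  stopifnot(new_reference >= 1, new_reference <= k)
  pc <- hamling_pseudocounts(rr, lo, hi, is_reference, study_cases, study_total)
  out <- rr_from_counts(pc$cases, pc$total,
                        pc$cases[new_reference], pc$total[new_reference],
                        continuity = 0)
  out$log_rr[new_reference] <- 0
  out$se[new_reference] <- 0
  out$source <- "hamling"
  out
}
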