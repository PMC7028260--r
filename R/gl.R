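#' Greenland-Longnecker trend estimate for one study
#'
#' Generalized-least-squares estimate of the per-unit log-linear trend from
#' a study's correlated category-specific log relative risks. Category
#' estimates that share a reference group are positively correlated; the
#' approximate covariance is built from fitted counts consistent with the
#' category margins and the reported relative risks. With per-category
#' totals unavailable, Hamling pseudo-counts stand in; with no counts at
#' all, the fit falls back to an independence (diagonal) covariance and says
#' so in `cov_model`.
#'
#' @param data Category rows for a single study: columns `assigned_dose`,
#'   `rr`, `ci_lower`, `ci_upper`, `is_reference`, optionally per-category
#'   `cases`/`total` and study-level `study_cases`/`study_total`.
#' @param center Logical; center doses at the reference category's dose
#'   (default `TRUE`; only the differences enter the estimate either way).
#' @return A one-row tibble: `beta` (log-RR per unit dose), `se_beta`,
#'   `method` (`"gl"` or `"two_point"`), `cov_model`.
#' @examples
#' d <- tibble::tibble(
#'   assigned_dose = c(5, 6, 7), rr = c(1, 1.2, 1.5),
#'   ci_lower = c(NA, 0.9, 1.1), ci_upper = c(NA, 1.6, 2.1),
#'   is_reference = c(TRUE, FALSE, FALSE)
#' )
#' gl_slope(d)
#' @export
gl_slope <- function(data, center = TRUE) {
  d <- as_tibble(data)
  need <- c("assigned_dose", "rr", "ci_lower", "ci_upper", "is_reference")
  missing_cols <- setdiff(need, names(d))
  if (length(missing_cols) > 0) {
    abort(paste0("gl_slope needs columns: ", paste(missing_cols, collapse = ", ")),
          class = "remr_schema_error")
  }
  d <- d[!is.na(d$assigned_dose) & (d$is_reference | !is.na(d$rr)), ]
  ref <- which(d$is_reference)
  if (length(ref) != 1) {
    abort("Exactly one reference category required.", class = "remr_domain_error")
  }
  nonref <- setdiff(seq_len(nrow(d)), ref)
  if (length(nonref) < 1) {
    abort("Need >= 1 non-reference category with rr.",
          class = "remr_insufficient_data_error")
  }
  eff <- effect_from_ci(d$rr[nonref], d$ci_lower[nonref], d$ci_upper[nonref])
  L <- eff$log_rr
  v <- eff$se^2
  x <- d$assigned_dose[nonref] - if (center) d$assigned_dose[ref] else 0

  cov_ref <- gl_reference_covariance(d, ref, nonref)
  C <- diag(v, nrow = length(v))
  if (!is.na(cov_ref$value) && length(nonref) > 1) {
    C[upper.tri(C)] <- cov_ref$value
    C[lower.tri(C)] <- cov_ref$value
  }
  Ci <- tryCatch(solve(C), error = function(e) {
    abort("Singular Greenland-Longnecker covariance matrix.",
          class = "remr_numerical_error")
  })
  xtCx <- drop(t(x) %*% Ci %*% x)
  if (xtCx <= 0) {
    abort("Degenerate dose design in gl_slope.", class = "remr_numerical_error")
  }
  beta <- drop(t(x) %*% Ci %*% L) / xtCx
  tibble(
    beta = beta,
    se_beta = sqrt(1 / xtCx),
    method = if (length(nonref) == 1) "two_point" else "gl",
    cov_model = cov_ref$model
  )
}

# Shared-reference covariance term 1/a0 - 1/n0 from fitted counts.
gl_reference_covariance <- function(d, ref, nonref) {
  k <- nrow(d)
  has_counts <- all(!is.na(d[["cases"]] %||% NA)) &&
    all(!is.na(d[["total"]] %||% NA))
  if (has_counts) {
    ft <- gl_fitted_counts(d$rr[nonref], d$total[nonref], d$total[ref],
                           sum(d$cases))
    return(list(value = 1 / ft$a0 - 1 / d$total[ref], model = "gl_fitted_counts"))
  }
  sc <- d[["study_cases"]] %||% NA
  st <- d[["study_total"]] %||% NA
  if (!anyNA(sc) && !anyNA(st)) {
    pc <- tryCatch(
      hamling_pseudocounts(d$rr, d$ci_lower, d$ci_upper, d$is_reference,
                           sc[1], st[1]),
      error = function(e) NULL
    )
    if (!is.null(pc)) {
      return(list(value = 1 / pc$cases[ref] - 1 / pc$total[ref],
                  model = "hamling_pseudocounts"))
    }
  }
  list(value = NA_real_, model = "independence")
}

# Fitted reference cases matching category totals, total cases and the
# reported RRs (cumulative-incidence form). Fixed-point iteration; the map
# is a contraction and in this parameterization converges in one step up to
# rounding, but the loop keeps the contract explicit.
gl_fitted_counts <- function(rr_nonref, n_nonref, n_ref, total_cases,
                             tol = 1e-8, max_iter = 200) {
  a0 <- total_cases * n_ref / (n_ref + sum(n_nonref))
  for (i in seq_len(max_iter)) {
    a0_new <- total_cases / (1 + sum(rr_nonref * n_nonref) / n_ref)
    if (abs(a0_new - a0) < tol) {
      return(list(a0 = a0_new, iterations = i))
    }
    a0 <- a0_new
  }
  abort("Fitted-count iteration did not converge.", class = "remr_numerical_error")
}

#' Per-unit effect for every study in a table
#'
#' The per-study log-linear effect per 1 unit of exposure used by the pooled
#' analyses. A study's reported per-unit relative risk takes precedence
#' (`method = "reported"`); otherwise the slope is reconstructed from its
#' category data by [gl_slope()] (`method = "gl"`, or `"two_point"` with a
#' single non-reference category).
#'
#' @param data A `study_table`.
#' @param rule [dose_rule()] used if doses are not yet assigned.
#' @param include_auxiliary Keep records flagged `auxiliary = TRUE`
#'   (secondary category sets of a study already represented by a pooled
#'   entry)? Default `FALSE`.
#' @return A tibble, one row per study: identifiers, `beta`, `se`, `method`,
#'   and the implied `rr`, `ci_lower`, `ci_upper` per unit.
#' @examples
#' per_unit_effects(table1_fixture()) |>
#'   dplyr::filter(outcome == "AF")
#' @export
per_unit_effects <- function(data, rule = dose_rule(),
                             include_auxiliary = FALSE) {
  x <- as_study_table(data)
  if (!"assigned_dose" %in% names(x)) {
    x <- assign_doses(x, rule)
  }
  recs <- study_records(x)
  if (!include_auxiliary && "auxiliary" %in% names(as_tibble(x))) {
    aux <- purrr::map_lgl(recs$data, ~ isTRUE(.x[["auxiliary"]][1]))
    recs <- recs[!aux, ]
  }
  purrr::pmap_dfr(recs, function(study_id, label, population, outcome,
                                 adjusted, data) {
    est <- per_unit_effect_one(data, study_id)
    tibble(
      study_id = study_id, label = label, population = population,
      outcome = outcome, adjusted = adjusted,
      ami_cohort = isTRUE(data[["ami_cohort"]][1]),
      beta = est$beta, se = est$se_beta, method = est$method,
      rr = exp(est$beta),
      ci_lower = exp(est$beta - Z95 * est$se_beta),
      ci_upper = exp(est$beta + Z95 * est$se_beta)
    )
  })
}

per_unit_effect_one <- function(d, study_id) {
  pu <- d[!is.na(d$per_unit_rr), ]
  if (nrow(pu) > 0) {
    eff <- effect_from_ci(pu$per_unit_rr[1], pu$per_unit_lo[1], pu$per_unit_hi[1])
    return(tibble(beta = eff$log_rr, se_beta = eff$se, method = "reported"))
  }
  cat_rows <- d[is_category_row(d), ]
  if (nrow(cat_rows) >= 2) {
    return(gl_slope(cat_rows))
  }
  abort(sprintf("Study '%s': no per-unit effect and insufficient category data.",
                study_id),
        class = "remr_insufficient_data_error")
}
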