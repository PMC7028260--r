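#' Linear (per-unit) dose-response meta-analysis report
#'
#' Orchestrates the per-unit pipeline for one outcome: per-study effects,
#' the overall random-effects pool, subgroup pools (by population and by
#' adjustment status), a leave-one-out table, and heterogeneity classes.
#' Every number in the report is the direct output of one package operation.
#'
#' @param data A `study_table` (default: the bundled HbA1c dataset).
#' @param outcome `"AF"` or `"POAF_CABG"`.
#' @param exclude Study ids to drop before the overall pool (subgroup and
#'   leave-one-out tables always start from the unexcluded set).
#' @param out_dir If non-`NULL`, write `report.json` and a forest-plot-ready
#'   `forest.csv` (label, rr, lo, hi, weight_pct) there.
#' @return A list: `effects`, `overall` (`meta_pool`), `subgroups_population`,
#'   `subgroups_adjusted`, `leave_one_out`, `sensitivity_excl_ami` (AF only).
#' @examples
#' rep <- run_linear_analysis(outcome = "POAF_CABG")
#' rep$overall
#' @export
run_linear_analysis <- function(data = table1_fixture(),
                                outcome = c("AF", "POAF_CABG"),
                                exclude = NULL, out_dir = NULL) {
  outcome <- match.arg(outcome)
  x <- as_study_table(data)
  eff <- per_unit_effects(x)
  eff <- eff[eff$outcome == outcome, ]
  if (!is.null(exclude)) eff <- eff[!eff$study_id %in% exclude, ]
  if (nrow(eff) == 0) {
    abort("No studies left after filtering.", class = "remr_empty_error")
  }
  overall <- pool(eff)
  report <- list(
    effects = eff,
    overall = overall,
    subgroups_population = subgroup_pool(eff, population),
    subgroups_adjusted = subgroup_pool(eff, adjusted),
    leave_one_out = if (nrow(eff) >= 2) leave_one_out(eff) else NULL,
    sensitivity_excl_ami = if (any(eff$ami_cohort)) {
      pool(eff[!eff$ami_cohort, ])
    } else NULL
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(
      report_json(report), file.path(out_dir, "report.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE
    )
    readr::write_csv(
      dplyr::select(tidy(overall), "label", "rr",
                    lo = "ci_lower", hi = "ci_upper", "weight_pct"),
      file.path(out_dir, "forest.csv")
    )
  }
  report
}

report_json <- function(report) {
  pool_json <- function(p) {
    if (is.null(p)) return(NULL)
    g <- glance(p)
    list(
      k = g$k, rr = g$rr, ci = c(g$ci_lower, g$ci_upper),
      Q = g$Q, df = g$df, i2 = g$i2, tau2 = g$tau2,
      p = g$p_overall, heterogeneity = g$heterogeneity,
      weights = stats::setNames(as.list(p$studies$weight), p$studies$label)
    )
  }
  list(
    overall = pool_json(report$overall),
    subgroups_population = purrr::map(
      stats::setNames(report$subgroups_population$fit,
                      report$subgroups_population$group), pool_json),
    subgroups_adjusted = purrr::map(
      stats::setNames(report$subgroups_adjusted$fit,
                      report$subgroups_adjusted$group), pool_json),
    leave_one_out = if (is.null(report$leave_one_out)) NULL else {
      purrr::pmap(report$leave_one_out,
                  function(excluded, k, rr, ci_lower, ci_upper, i2, ...) {
                    list(excluded = excluded, k = k, rr = rr,
                         ci = c(ci_lower, ci_upper), i2 = i2)
                  })
    },
    sensitivity_excl_ami = pool_json(report$sensitivity_excl_ami)
  )
}

#' Nonlinear (spline) dose-response analysis report
#'
#' Fits the one-stage robust-error meta-regression on category-level data
#' and extracts the pooled curve and its persistence threshold. Mirrors the
#' source analysis' restriction: with `population = "no_known_diabetes"`
#' (the default), records from diabetic populations are refused rather than
#' silently mixed in.
#'
#' @param data A `study_table` (default: the bundled HbA1c dataset).
#' @param population Population filter applied before fitting; `NULL` fits
#'   all records with usable category data.
#' @param knots,ref_dose,step Passed to [fit_remr()] / [predict_curve()].
#' @param exclude Study ids to drop before fitting.
#' @param out_dir If non-`NULL`, write `curve.csv` (dose, rr, lo, hi) and
#'   `spline.json` (knots, coefficients, p_nonlinear, threshold) there.
#' @return A list: `model` (`remr_fit`), `curve` (`dose_curve`), `threshold`,
#'   `p_nonlinear`.
#' @examples
#' rep <- run_nonlinear_analysis()
#' rep$threshold
#' @export
run_nonlinear_analysis <- function(data = table1_fixture(),
                                   population = "no_known_diabetes",
                                   knots = c(0.10, 0.50, 0.90),
                                   ref_dose = NULL, step = 0.01,
                                   exclude = NULL, out_dir = NULL) {
  x <- as_study_table(data)
  tb <- as_tibble(x)
  if (!is.null(population) && "diabetes_or_IGT" %in% population) {
    abort(paste(
      "The nonlinear model is restricted to populations without known",
      "diabetes: too few diabetic cohorts publish usable category-level",
      "data to identify a separate curve."),
      class = "remr_policy_error")
  }
  if (!is.null(population)) {
    if (!any(tb$population %in% population)) {
      abort(paste0("No records in population(s): ",
                   paste(population, collapse = ", ")),
            class = "remr_empty_error")
    }
    tb <- tb[tb$population %in% population, ]
  }
  if (!is.null(exclude)) tb <- tb[!tb$study_id %in% exclude, ]
  model <- fit_remr(tb, knots = knots)
  curve <- predict_curve(model, ref_dose = ref_dose, step = step)
  out <- list(
    model = model,
    curve = curve,
    threshold = attr(curve, "threshold"),
    p_nonlinear = model$p_nonlinear
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    readr::write_csv(dplyr::select(tibble::as_tibble(curve),
                                   "dose", "rr", "lo", "hi"),
                     file.path(out_dir, "curve.csv"))
    jsonlite::write_json(
      list(
        knots = model$knots,
        coefficients = as.list(model$coefficients),
        p_nonlinear = model$p_nonlinear,
        threshold = out$threshold,
        ref_dose = attr(curve, "ref_dose"),
        n_obs = model$n_obs, n_clusters = model$n_clusters
      ),
      file.path(out_dir, "spline.json"), auto_unbox = TRUE, digits = NA,
      pretty = TRUE
    )
  }
  out
}
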