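#' Dose-assignment rule for exposure categories
#'
#' Controls how a single exposure value (here HbA1c, %) is assigned to each
#' reported category. Closed intervals always take their midpoint and
#' single-value categories their stated value; the rule only decides
#' open-ended intervals. Under `"adjacent_width"` (the convention in
#' dose-response meta-analysis) an open-above category `> a` is assigned
#' `a + w/2` where `w` is the width of the nearest lower closed interval,
#' and an open-below category `< b` is assigned `b - w/2` from the nearest
#' higher closed interval. Under `"fixed_width"` the supplied `width` is used
#' instead of the adjacent interval's.
#'
#' @param open_interval_policy `"adjacent_width"` (default) or `"fixed_width"`.
#' @param width Assumed interval width for `"fixed_width"` (must be > 0).
#' @return A `dose_rule` list.
#' @export
dose_rule <- function(open_interval_policy = c("adjacent_width", "fixed_width"),
                      width = NULL) {
  open_interval_policy <- match.arg(open_interval_policy)
  if (open_interval_policy == "fixed_width") {
    if (is.null(width) || !is.numeric(width) || width <= 0) {
      abort("fixed_width policy requires width > 0.", class = "remr_domain_error")
    }
  }
  structure(list(open_interval_policy = open_interval_policy, width = width),
            class = "dose_rule")
}

#' Assign a dose to every exposure category
#'
#' Adds (or refreshes) an `assigned_dose` column on the category rows of a
#' study table: the single exposure value each category contributes to trend
#' estimation and spline fitting. Reference categories are dosed like any
#' other. Categories with neither bounds nor a point value (e.g. an unexposed
#' "Control" group) are left `NA` with a warning. The operation is
#' idempotent.
#'
#' @param data A `study_table` (or coercible data frame).
#' @param rule A [dose_rule()].
#' @return The input with an `assigned_dose` column filled on category rows.
#' @examples
#' assign_doses(table1_fixture()) |>
#'   dplyr::filter(study_id == "dublin") |>
#'   dplyr::select(cat_lower, cat_upper, cat_point, assigned_dose)
#' @export
assign_doses <- function(data, rule = dose_rule()) {
  x <- as_study_table(data)
  if (!inherits(rule, "dose_rule")) {
    abort("`rule` must be created by dose_rule().", class = "remr_domain_error")
  }
  tb <- as_tibble(x)
  tb$assigned_dose <- NA_real_
  for (id in unique(tb$study_id)) {
    rows <- which(tb$study_id == id & is_category_row(tb))
    if (length(rows) == 0) next
    tb$assigned_dose[rows] <- assign_doses_one(
      tb$cat_lower[rows], tb$cat_upper[rows], tb$cat_point[rows], rule, id
    )
  }
  new_study_table(tb, provenance = attr(x, "provenance"))
}

assign_doses_one <- function(lower, upper, point, rule, study_id) {
  k <- length(lower)
  dose <- rep(NA_real_, k)
  closed <- !is.na(lower) & !is.na(upper)
  widths <- ifelse(closed, upper - lower, NA_real_)
  dose[!is.na(point)] <- point[!is.na(point)]
  dose[closed] <- (lower[closed] + upper[closed]) / 2

  half_width <- function(i, direction) {
    if (rule$open_interval_policy == "fixed_width") return(rule$width / 2)
    # nearest closed interval on the stated side (categories are ordered)
    idx <- if (direction == "lower") {
      rev(seq_len(i - 1))
    } else if (i < k) {
      seq(i + 1, k)
    } else {
      integer(0)
    }
    w <- widths[idx][!is.na(widths[idx])]
    if (length(w) == 0) {
      abort(sprintf(
        "Study '%s': open-ended category has no adjacent closed interval; use dose_rule(\"fixed_width\", width).",
        study_id), class = "remr_unassignable_dose_error")
    }
    w[1] / 2
  }

  for (i in seq_len(k)) {
    if (!is.na(dose[i])) next
    if (!is.na(lower[i]) && is.na(upper[i])) {
      dose[i] <- lower[i] + half_width(i, "lower")
    } else if (is.na(lower[i]) && !is.na(upper[i])) {
      dose[i] <- upper[i] - half_width(i, "upper")
    } else {
      rlang::inform(sprintf(
        "Study '%s': category %d has no bounds or point value; assigned_dose left NA.",
        study_id, i))
    }
  }
  d <- dose[!is.na(dose)]
  if (length(d) > 1 && any(diff(d) <= 0)) {
    abort(sprintf(
      "Study '%s': assigned doses are not strictly increasing across ordered categories.",
      study_id), class = "remr_inconsistent_bounds_error")
  }
  dose
}
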