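#' @importFrom rlang .data abort warn %||%
#' @importFrom tibble tibble as_tibble
NULL

# Required input columns, in the canonical order (extra columns are kept).
study_table_cols <- c(
  "study_id", "label", "population", "outcome", "adjusted", "stratum",
  "cat_lower", "cat_upper", "cat_point", "cases", "total",
  "rr", "ci_lower", "ci_upper", "is_reference",
  "per_unit_rr", "per_unit_lo", "per_unit_hi"
)

populations <- c("diabetes_or_IGT", "no_known_diabetes", "mixed")
outcomes <- c("AF", "POAF_CABG")

new_study_table <- function(x, provenance = NA_character_) {
  x <- as_tibble(x)
  structure(x,
    class = c("study_table", class(x)),
    provenance = provenance
  )
}

#' Coerce a data frame to a validated study table
#'
#' A study table is a long-format tibble of study-level categorical
#' dose-response data: one row per exposure category per study, plus (or
#' instead) one row carrying the study's reported per-1-unit effect.
#' `as_study_table()` validates the invariants every analysis in the package
#' relies on; all other functions accept anything this coercion accepts.
#'
#' Rows belonging to one `study_id` form a study record. A record must carry
#' either a reported per-unit relative risk (`per_unit_rr` with CI) or at
#' least two categories with relative risks, one of them flagged as the
#' reference (`is_reference`, relative risk 1).
#'
#' @param x A data frame with at least the columns listed in
#'   [read_study_table()].
#' @param provenance Free-text description of where the data came from.
#' @return A `study_table` tibble (one row per category or per-unit entry).
#' @examples
#' tab <- table1_fixture()
#' as_study_table(tab)
#' @export
as_study_table <- function(x, provenance = NA_character_) {
  x <- as_tibble(x)
  missing_cols <- setdiff(study_table_cols, names(x))
  if (length(missing_cols) > 0) {
    abort(
      paste0("Missing required column(s): ", paste(missing_cols, collapse = ", ")),
      class = "remr_schema_error"
    )
  }
  if (nrow(x) == 0) {
    abort("Study table has no rows.", class = "remr_empty_error")
  }
  x$is_reference <- as_flag(x$is_reference)
  x$adjusted <- as_flag(x$adjusted)
  for (col in c("cat_lower", "cat_upper", "cat_point", "cases", "total",
                "rr", "ci_lower", "ci_upper",
                "per_unit_rr", "per_unit_lo", "per_unit_hi")) {
    x[[col]] <- as.numeric(x[[col]])
  }
  validate_study_table(x)
  new_study_table(x, provenance = provenance)
}

as_flag <- function(x) {
  if (is.logical(x)) return(x)
  tolower(as.character(x)) %in% c("true", "t", "1", "yes")
}

validate_study_table <- function(x) {
  bad <- function(id, field, msg) {
    abort(
      sprintf("Study '%s', field '%s': %s", id, field, msg),
      class = "remr_validation_error"
    )
  }
  if (anyNA(x$study_id) || any(x$study_id == "")) {
    abort("study_id must be non-missing for every row.",
          class = "remr_validation_error")
  }
  if (!all(x$population %in% populations)) {
    bad(x$study_id[!x$population %in% populations][1], "population",
        paste("must be one of", paste(populations, collapse = ", ")))
  }
  if (!all(x$outcome %in% outcomes)) {
    bad(x$study_id[!x$outcome %in% outcomes][1], "outcome",
        paste("must be one of", paste(outcomes, collapse = ", ")))
  }
  cat_rows <- is_category_row(x)
  cr <- x[cat_rows, ]
  both <- !is.na(cr$cat_lower) & !is.na(cr$cat_upper)
  if (any(both & cr$cat_lower >= cr$cat_upper)) {
    i <- which(both & cr$cat_lower >= cr$cat_upper)[1]
    bad(cr$study_id[i], "cat_lower/cat_upper", "lower bound must be below upper bound")
  }
  if (any(!is.na(cr$rr) & cr$rr <= 0)) {
    bad(cr$study_id[which(!is.na(cr$rr) & cr$rr <= 0)[1]], "rr", "must be positive")
  }
  ci_ok <- is.na(cr$rr) | is.na(cr$ci_lower) | is.na(cr$ci_upper) |
    (cr$ci_lower <= cr$rr & cr$rr <= cr$ci_upper)
  if (!all(ci_ok)) {
    bad(cr$study_id[which(!ci_ok)[1]], "ci_lower/ci_upper", "CI must bracket rr")
  }
  cnt <- !is.na(cr$cases) & !is.na(cr$total)
  if (any(cnt & (cr$cases < 0 | cr$cases > cr$total))) {
    bad(cr$study_id[which(cnt & (cr$cases < 0 | cr$cases > cr$total))[1]],
        "cases/total", "need 0 <= cases <= total")
  }
  for (id in unique(x$study_id)) {
    rows <- x[x$study_id == id, ]
    crows <- rows[is_category_row(rows), ]
    has_per_unit <- any(!is.na(rows$per_unit_rr))
    n_rr <- sum(!is.na(crows$rr))
    if (!has_per_unit && n_rr < 2) {
      bad(id, "per_unit_rr/categories",
          "need a per-unit effect or >= 2 categories with rr")
    }
    if (nrow(crows) > 0) {
      n_ref <- sum(crows$is_reference)
      if (n_ref != 1) {
        bad(id, "is_reference",
            sprintf("exactly one reference category required, found %d", n_ref))
      }
      ref_rr <- crows$rr[crows$is_reference]
      if (!is.na(ref_rr) && ref_rr != 1) {
        bad(id, "rr", "reference category must have rr = 1")
      }
    }
  }
  invisible(x)
}

is_category_row <- function(x) {
  !is.na(x$cat_lower) | !is.na(x$cat_upper) | !is.na(x$cat_point) |
    x$is_reference | !is.na(x$rr)
}

#' Read a study table from CSV
#'
#' The expected CSV dialect is comma-separated UTF-8 with a header row and one
#' exposure category (or one per-unit entry) per row. Required columns:
#' `study_id, label, population, outcome, adjusted, stratum, cat_lower,
#' cat_upper, cat_point, cases, total, rr, ci_lower, ci_upper, is_reference,
#' per_unit_rr, per_unit_lo, per_unit_hi`. Extra columns are preserved.
#' Interval bounds are numeric; en dashes in source tables must already be
#' split into the two bound columns.
#'
#' @param path Path to a CSV file.
#' @param schema Optional named character vector mapping required column names
#'   to the names actually used in the file, e.g. `c(study_id = "id")`.
#' @return A validated `study_table` tibble.
#' @seealso [as_study_table()], [write_study_table()], [table1_fixture()]
#' @export
read_study_table <- function(path, schema = NULL) {
  if (!file.exists(path)) {
    abort(paste0("File not found: ", path), class = "remr_io_error")
  }
  x <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (nrow(x) == 0) {
    abort("Input CSV has no data rows.", class = "remr_empty_error")
  }
  if (!is.null(schema)) {
    for (canon in names(schema)) {
      if (!schema[[canon]] %in% names(x)) {
        abort(paste0("Schema maps '", canon, "' to absent column '",
                     schema[[canon]], "'"), class = "remr_schema_error")
      }
      names(x)[names(x) == schema[[canon]]] <- canon
    }
  }
  as_study_table(x, provenance = path)
}

#' Write a study table to CSV
#'
#' @param x A `study_table` (or coercible data frame).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_study_table <- function(x, path) {
  x <- as_study_table(x)
  readr::write_csv(as_tibble(x), path, na = "")
  invisible(path)
}

#' Study-level HbA1c and atrial fibrillation dataset
#'
#' The hand-encoded study-level table the package was developed around:
#' 14 publications relating glycated hemoglobin (HbA1c, %) to incident atrial
#' fibrillation (AF) or to new-onset AF after coronary bypass surgery
#' (POAF_CABG), as printed in the source publications' summary table. One
#' cohort (Huxley) contributes separate diabetic and non-diabetic strata;
#' one (Sandhu) contributes paroxysmal and non-paroxysmal category sets kept
#' as auxiliary strata (`auxiliary = TRUE`) beside its single pooled per-1%
#' entry. The acute-myocardial-infarction cohort (Blasco) is flagged
#' `ami_cohort = TRUE` for sensitivity exclusion. `adjusted` is `FALSE` where
#' the source table lists no confounder adjustment. Study-level case and
#' participant totals are carried on every row as `study_cases`/`study_total`;
#' per-category counts were not published.
#'
#' The same data ship as a CSV at
#' `system.file("extdata", "hba1c_af_table1.csv", package = "remr")`.
#'
#' @return A validated `study_table` tibble.
#' @examples
#' tab <- table1_fixture()
#' dplyr::count(tab, outcome)
#' @export
table1_fixture <- function() {
  per_unit <- function(study_id, label, population, outcome, adjusted,
                       rr, lo, hi, cases, total, stratum = NA_character_,
                       ami = FALSE, aux = FALSE) {
    # capture before tibble() so its columns cannot mask the arguments
    p_rr <- rr; p_lo <- lo; p_hi <- hi; s_cases <- cases; s_total <- total
    tibble(
      study_id = study_id, label = label, population = population,
      outcome = outcome, adjusted = adjusted, stratum = stratum,
      cat_lower = NA_real_, cat_upper = NA_real_, cat_point = NA_real_,
      cases = NA_real_, total = NA_real_,
      rr = NA_real_, ci_lower = NA_real_, ci_upper = NA_real_,
      is_reference = FALSE,
      per_unit_rr = p_rr, per_unit_lo = p_lo, per_unit_hi = p_hi,
      cat_label = NA_character_, ami_cohort = ami, auxiliary = aux,
      study_cases = s_cases, study_total = s_total
    )
  }
  cats <- function(study_id, label, population, outcome, adjusted,
                   lower, upper, point, rr, lo, hi, ref, cases, total,
                   stratum = NA_character_, cat_label = NA_character_,
                   ami = FALSE, aux = FALSE) {
    s_cases <- cases; s_total <- total; c_label <- cat_label
    tibble(
      study_id = study_id, label = label, population = population,
      outcome = outcome, adjusted = adjusted, stratum = stratum,
      cat_lower = lower, cat_upper = upper, cat_point = point,
      cases = NA_real_, total = NA_real_,
      rr = rr, ci_lower = lo, ci_upper = hi, is_reference = ref,
      per_unit_rr = NA_real_, per_unit_lo = NA_real_, per_unit_hi = NA_real_,
      cat_label = c_label, ami_cohort = ami, auxiliary = aux,
      study_cases = s_cases, study_total = s_total
    )
  }
  x <- dplyr::bind_rows(
    ## --- POAF after CABG, per-1% entries ---
    per_unit("halkos", "Halkos", "mixed", "POAF_CABG", TRUE,
             0.89, 0.80, 0.98, 549, 3089),
    per_unit("matsuura", "Matsuura", "diabetes_or_IGT", "POAF_CABG", FALSE,
             0.87, 0.64, 1.19, 26, 101),
    cats("tsuruta", "Tsuruta", "diabetes_or_IGT", "POAF_CABG", FALSE,
         lower = c(NA, 6.5, 7.5), upper = c(6.5, 7.5, NA), point = NA_real_,
         rr = c(1, 0.89, 1.25), lo = c(NA, 0.36, 0.58), hi = c(NA, 2.21, 2.71),
         ref = c(TRUE, FALSE, FALSE), cases = 36, total = 305),
    per_unit("tsuruta", "Tsuruta", "diabetes_or_IGT", "POAF_CABG", FALSE,
             1.12, 0.76, 1.65, 36, 305),
    cats("kinoshita", "Kinoshita", "mixed", "POAF_CABG", TRUE,
         lower = c(3.8, 6.8), upper = c(5.6, 11.4), point = NA_real_,
         rr = c(1, 0.55), lo = c(NA, 0.35), hi = c(NA, 0.88),
         ref = c(TRUE, FALSE), cases = 159, total = 805),
    per_unit("kinoshita", "Kinoshita", "mixed", "POAF_CABG", TRUE,
             0.78, 0.63, 0.95, 159, 805),
    per_unit("surer", "Surer", "mixed", "POAF_CABG", FALSE,
             3.92, 1.92, 7.99, 12, 72),
    per_unit("abbaszadeh", "Abbaszadeh", "diabetes_or_IGT", "POAF_CABG", TRUE,
             1.06, 0.93, 1.20, 109, 708),
    ## --- incident AF ---
    cats("dublin", "Dublin", "no_known_diabetes", "AF", TRUE,
         lower = c(NA, NA, 7, 8, 9), upper = c(NA, 7, 8, 9, NA),
         point = c(5, NA, NA, NA, NA),
         rr = c(1, 1.06, 1.48, 1.46, 1.96),
         lo = c(NA, 0.74, 1.09, 1.02, 1.22),
         hi = c(NA, 1.51, 2.01, 2.08, 3.14),
         ref = c(TRUE, FALSE, FALSE, FALSE, FALSE), cases = 1410, total = 3613),
    per_unit("dublin", "Dublin", "no_known_diabetes", "AF", TRUE,
             1.14, 0.96, 1.35, 1410, 3613),
    per_unit("huxley_nondm", "Huxley", "no_known_diabetes", "AF", TRUE,
             1.05, 0.96, 1.15, 1311, 13025, stratum = "non-DM"),
    per_unit("huxley_dm", "Huxley", "diabetes_or_IGT", "AF", TRUE,
             1.13, 1.07, 1.20, 1311, 13025, stratum = "DM"),
    per_unit("iguchi", "Iguchi", "no_known_diabetes", "AF", TRUE,
             1.18, 1.09, 1.28, 1161, 52448),
    per_unit("turgut", "Turgut", "diabetes_or_IGT", "AF", TRUE,
             1.87, 0.747, 3.014, 81, 162),
    per_unit("latini", "Latini", "diabetes_or_IGT", "AF", TRUE,
             1.11, 0.91, 1.32, 613, 8943),
    per_unit("sandhu", "Sandhu", "no_known_diabetes", "AF", TRUE,
             1.08, 0.95, 1.22, 1039, 34720),
    cats("sandhu_parox", "Sandhu", "no_known_diabetes", "AF", TRUE,
         lower = c(NA, 4.84, 5.00, 5.19), upper = c(4.84, 5.00, 5.19, NA),
         point = NA_real_,
         rr = c(1, 0.90, 0.99, 0.76),
         lo = c(NA, 0.69, 0.77, 0.58), hi = c(NA, 1.17, 1.27, 1.00),
         ref = c(TRUE, FALSE, FALSE, FALSE), cases = 1039, total = 34720,
         stratum = "paroxysmal", aux = TRUE),
    cats("sandhu_nonparox", "Sandhu", "no_known_diabetes", "AF", TRUE,
         lower = c(NA, 4.84, 5.00, 5.19), upper = c(4.84, 5.00, 5.19, NA),
         point = NA_real_,
         rr = c(1, 1.30, 1.43, 1.48),
         lo = c(NA, 0.85, 0.96, 0.98), hi = c(NA, 1.97, 2.15, 2.22),
         ref = c(TRUE, FALSE, FALSE, FALSE), cases = 1039, total = 34720,
         stratum = "nonparoxysmal", aux = TRUE),
    cats("blasco", "Blasco", "no_known_diabetes", "AF", TRUE,
         lower = c(NA, 5.5, 6.4), upper = c(5.5, 6.4, NA), point = NA_real_,
         rr = c(1, 1.68, 29.74), lo = c(NA, 0.64, 10.79),
         hi = c(NA, 4.39, 81.94),
         ref = c(TRUE, FALSE, FALSE), cases = 12, total = 601, ami = TRUE),
    per_unit("blasco", "Blasco", "no_known_diabetes", "AF", TRUE,
             3.24, 2.41, 4.35, 12, 601, ami = TRUE),
    cats("dahlqvist", "Dahlqvist", "diabetes_or_IGT", "AF", TRUE,
         lower = c(NA, NA, 7.0, 7.8, 8.8, 9.7), upper = c(NA, 6.9, 7.8, 8.7, 9.6, NA),
         point = NA_real_,
         rr = c(1, 1.03, 1.11, 1.28, 1.40, 2.32),
         lo = c(NA, 0.84, 0.97, 1.12, 1.15, 1.80),
         hi = c(NA, 1.27, 1.28, 1.47, 1.69, 2.99),
         ref = c(TRUE, FALSE, FALSE, FALSE, FALSE, FALSE),
         cases = 1283, total = 216852,
         cat_label = c("Control", rep(NA_character_, 5))),
    per_unit("dahlqvist", "Dahlqvist", "diabetes_or_IGT", "AF", TRUE,
             1.14, 1.06, 1.24, 1283, 216852)
  )
  as_study_table(x, provenance = "hand-encoded study-level summary table")
}

#' Split a study table into per-study records
#'
#' @param x A `study_table`.
#' @return A tibble with one row per `study_id` and a `data` list-column of
#'   that study's rows (category and per-unit), plus its invariant
#'   descriptors.
#' @keywords internal
study_records <- function(x) {
  x <- as_study_table(x)
  as_tibble(x) |>
    dplyr::group_by(.data$study_id) |>
    dplyr::summarise(
      label = dplyr::first(.data$label),
      population = dplyr::first(.data$population),
      outcome = dplyr::first(.data$outcome),
      adjusted = dplyr::first(.data$adjusted),
      data = list(dplyr::pick(dplyr::everything())),
      .groups = "drop"
    )
}

#' @export
print.study_table <- function(x, ...) {
  prov <- attr(x, "provenance")
  cat(sprintf("# A study_table: %d rows, %d studies%s\n",
              nrow(x), length(unique(x$study_id)),
              if (is.na(prov %||% NA)) "" else paste0(" (", prov, ")")))
  NextMethod()
}
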