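# Build a categorical study table row-set from explicit counts: the
# count-based oracle used against Hamling / GL code paths.
counts_to_categories <- function(cases, totals, doses, ref = 1) {
  eff <- rr_from_counts(cases, totals, cases[ref], totals[ref])
  rr <- exp(eff$log_rr)
  lo <- exp(eff$log_rr - 1.959964 * eff$se)
  hi <- exp(eff$log_rr + 1.959964 * eff$se)
  rr[ref] <- 1
  lo[ref] <- NA_real_
  hi[ref] <- NA_real_
  tibble::tibble(
    assigned_dose = doses, rr = rr, ci_lower = lo, ci_upper = hi,
    is_reference = seq_along(cases) == ref,
    cases = as.numeric(cases), total = as.numeric(totals),
    study_cases = sum(cases), study_total = sum(totals)
  )
}

# Minimal valid one-study table for validation tests.
minimal_table <- function(rr_ref = 1) {
  tibble::tibble(
    study_id = "s1", label = "S1", population = "mixed", outcome = "AF",
    adjusted = TRUE, stratum = NA_character_,
    cat_lower = c(4, 5, 6), cat_upper = c(5, 6, 7), cat_point = NA_real_,
    cases = NA_real_, total = NA_real_,
    rr = c(rr_ref, 1.2, 1.5),
    ci_lower = c(NA, 0.9, 1.1), ci_upper = c(NA, 1.6, 2.1),
    is_reference = c(TRUE, FALSE, FALSE),
    per_unit_rr = NA_real_, per_unit_lo = NA_real_, per_unit_hi = NA_real_
  )
}
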