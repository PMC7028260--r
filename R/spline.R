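#' Restricted cubic spline basis
#'
#' Natural (restricted) cubic spline design: cubic between knots, linear
#' beyond the boundary knots. With `k` knots the basis has `k - 1` columns:
#' the identity (linear) term plus `k - 2` nonlinear terms
#' \deqn{f_j(x) = [(x - t_j)_+^3 - (x - t_{k-1})_+^3 (t_k - t_j)/(t_k - t_{k-1})
#'   + (x - t_k)_+^3 (t_{k-1} - t_j)/(t_k - t_{k-1})] / (t_k - t_1)^2}
#' for \eqn{j = 1, \dots, k - 2}, normalized so all columns share the scale
#' of `x`.
#'
#' @param x Doses at which to evaluate the basis.
#' @param knots At least 3 strictly increasing knot locations.
#' @return A numeric matrix with `length(x)` rows and `length(knots) - 1`
#'   columns; the first column is `x` itself.
#' @examples
#' rcs_basis(c(5, 6, 7, 8, 9), knots = c(5.5, 7, 8.5))
#' @export
rcs_basis <- function(x, knots) {
  knots <- sort(as.numeric(knots))
  k <- length(knots)
  if (k < 3) {
    abort("Restricted cubic splines need >= 3 knots.",
          class = "remr_domain_error")
  }
  if (any(diff(knots) <= 0)) {
    abort("Knots must be strictly increasing.", class = "remr_domain_error")
  }
  if (any(!is.finite(x))) {
    abort("Doses must be finite.", class = "remr_domain_error")
  }
  norm <- (knots[k] - knots[1])^2
  pos3 <- function(u) pmax(u, 0)^3
  out <- matrix(0, nrow = length(x), ncol = k - 1)
  out[, 1] <- x
  for (j in seq_len(k - 2)) {
    out[, j + 1] <- (
      pos3(x - knots[j]) -
        pos3(x - knots[k - 1]) * (knots[k] - knots[j]) / (knots[k] - knots[k - 1]) +
        pos3(x - knots[k]) * (knots[k - 1] - knots[j]) / (knots[k] - knots[k - 1])
    ) / norm
  }
  colnames(out) <- c("linear", if (k > 2) paste0("nonlin", seq_len(k - 2)))
  out
}

#' One-stage robust-error meta-regression (REMR) dose-response model
#'
#' Fits a dose-response curve to all category-level log relative risks of a
#' multi-study table in a single weighted least-squares regression. Each
#' study's reference category anchors its own categories: the covariates are
#' basis-function differences `basis(dose) - basis(reference dose)`, the
#' model has no intercept, and weights are inverse variances. Studies are
#' treated as clusters: the coefficient covariance is the cluster-robust
#' sandwich with CR1 small-sample scaling `g/(g - 1)`. The nonlinearity
#' p-value is a Wald test (F with `g - 1` denominator df) that all nonlinear
#' spline coefficients vanish.
#'
#' @param data A `study_table`; records contributing fewer than two dosed
#'   non-reference categories with relative risks are dropped.
#' @param knots Either explicit knot locations (length >= 3) or a numeric
#'   vector of probabilities for weighted dose percentiles (default
#'   `c(0.10, 0.50, 0.90)`, the Harrell convention). Use `knots = "linear"`
#'   for a linear-only (no spline) trend.
#' @param rule [dose_rule()] used if doses are not yet assigned.
#' @param min_categories Minimum non-reference categories per included study.
#' @return A `remr_fit` object with elements `knots`, `coefficients`,
#'   `robust_cov`, `n_obs`, `n_clusters`, `p_nonlinear`, `data` (the
#'   observation-level design) and `dose_span`.
#' @examples
#' nondm <- dplyr::filter(table1_fixture(), population == "no_known_diabetes",
#'                        !is.na(rr))
#' fit <- fit_remr(nondm)
#' glance(fit)
#' @export
fit_remr <- function(data, knots = c(0.10, 0.50, 0.90), rule = dose_rule(),
                     min_categories = 2) {
  x <- as_study_table(data)
  if (!"assigned_dose" %in% names(x)) x <- assign_doses(x, rule)
  tb <- as_tibble(x)

  obs <- purrr::map_dfr(split(tb, tb$study_id), function(d) {
    d <- d[is_category_row(d) & !is.na(d$assigned_dose), ]
    ref <- which(d$is_reference)
    if (length(ref) != 1) return(NULL)
    nr <- d[-ref, ]
    nr <- nr[!is.na(nr$rr) & !is.na(nr$ci_lower) & !is.na(nr$ci_upper), ]
    if (nrow(nr) < min_categories) return(NULL)
    eff <- effect_from_ci(nr$rr, nr$ci_lower, nr$ci_upper)
    tibble(
      study_id = d$study_id[1],
      dose = nr$assigned_dose,
      ref_dose = d$assigned_dose[ref],
      log_rr = eff$log_rr,
      se = eff$se
    )
  })
  if (nrow(obs) == 0 || length(unique(obs$study_id)) < 2) {
    abort("REMR needs >= 2 studies with >= 2 dosed non-reference categories.",
          class = "remr_insufficient_data_error")
  }

  linear_only <- identical(knots, "linear")
  if (linear_only) {
    knot_values <- numeric(0)
  } else if (all(knots >= 0 & knots <= 1) && length(knots) >= 3) {
    # Harrell convention: knots at quantiles of the observed dose
    # distribution (each category-level observation counted once)
    knot_values <- unname(stats::quantile(obs$dose, knots, type = 7))
    if (any(diff(knot_values) <= 0)) {
      abort("Dose percentiles gave tied knots; supply explicit knot locations.",
            class = "remr_domain_error")
    }
  } else {
    knot_values <- sort(as.numeric(knots))
  }

  basis <- function(d) {
    if (linear_only) matrix(d, ncol = 1, dimnames = list(NULL, "linear"))
    else rcs_basis(d, knot_values)
  }
  X <- basis(obs$dose) - basis(obs$ref_dose)
  y <- obs$log_rr
  w <- 1 / obs$se^2
  g <- length(unique(obs$study_id))
  p <- ncol(X)
  if (g <= p) {
    abort(sprintf("Only %d clusters for %d coefficients; model not identifiable.",
                  g, p), class = "remr_identifiability_error")
  }
  XtWX <- crossprod(X, w * X)
  bread <- tryCatch(solve(XtWX), error = function(e) {
    abort("Singular REMR design.", class = "remr_numerical_error")
  })
  b <- drop(bread %*% crossprod(X, w * y))
  e <- y - drop(X %*% b)
  meat <- matrix(0, p, p)
  for (id in unique(obs$study_id)) {
    i <- obs$study_id == id
    u <- crossprod(X[i, , drop = FALSE], (w * e)[i])
    meat <- meat + u %*% t(u)
  }
  V <- bread %*% meat %*% bread * g / (g - 1)
  V <- (V + t(V)) / 2

  p_nonlinear <- NA_real_
  if (p > 1) {
    nl <- 2:p
    wald <- drop(t(b[nl]) %*% solve(V[nl, nl, drop = FALSE]) %*% b[nl])
    p_nonlinear <- stats::pf(wald / length(nl), length(nl), g - 1,
                             lower.tail = FALSE)
  }

  structure(
    list(
      knots = knot_values,
      coefficients = stats::setNames(b, colnames(X)),
      robust_cov = V,
      n_obs = nrow(obs),
      n_clusters = g,
      p_nonlinear = p_nonlinear,
      data = obs,
      dose_span = range(obs$dose, obs$ref_dose),
      basis = basis
    ),
    class = "remr_fit"
  )
}

#' @export
print.remr_fit <- function(x, ...) {
  cat(sprintf(
    "REMR dose-response fit: %d observations in %d studies\n", x$n_obs,
    x$n_clusters))
  if (length(x$knots)) {
    cat("  knots:", paste(signif(x$knots, 4), collapse = ", "), "\n")
  } else {
    cat("  linear trend (no spline)\n")
  }
  cat("  coefficients:",
      paste(sprintf("%s = %.4f", names(x$coefficients), x$coefficients),
            collapse = ", "), "\n")
  if (!is.na(x$p_nonlinear)) {
    cat(sprintf("  Wald p (nonlinearity) = %.3g\n", x$p_nonlinear))
  }
  invisible(x)
}

#' @rdname fit_remr
#' @param x A `remr_fit`.
#' @param ... Unused.
#' @export
tidy.remr_fit <- function(x, ...) {
  tibble(
    term = names(x$coefficients),
    estimate = unname(x$coefficients),
    robust_se = sqrt(diag(x$robust_cov))
  )
}

#' @rdname fit_remr
#' @export
glance.remr_fit <- function(x, ...) {
  tibble(
    n_obs = x$n_obs, n_clusters = x$n_clusters,
    n_knots = length(x$knots), p_nonlinear = x$p_nonlinear
  )
}

#' Predict the pooled dose-response curve
#'
#' Evaluates the fitted curve on a dose grid, anchored at relative risk 1 at
#' `ref_dose`. Pointwise 95% CIs come from the delta method with the
#' cluster-robust covariance. Doses outside the span of the fitted data are
#' flagged, not refused.
#'
#' @param model A [fit_remr()] result.
#' @param ref_dose Anchor dose (predicted RR is exactly 1 there). Defaults to
#'   the lowest dose seen in the fit.
#' @param from,to,step Dose grid (defaults to the fitted span at 0.01 steps).
#' @return A `dose_curve` tibble: `dose`, `rr`, `lo`, `hi`, `extrapolated`,
#'   with the anchor dose and threshold (see [threshold_dose()]) as
#'   attributes.
#' @export
predict_curve <- function(model, ref_dose = NULL, from = NULL, to = NULL,
                          step = 0.01) {
  stopifnot(inherits(model, "remr_fit"))
  span <- model$dose_span
  ref_dose <- ref_dose %||% span[1]
  if (ref_dose < span[1] || ref_dose > span[2]) {
    warn(sprintf("ref_dose %.3g lies outside the fitted dose span [%.3g, %.3g].",
                 ref_dose, span[1], span[2]))
  }
  from <- from %||% span[1]
  to <- to %||% span[2]
  grid <- seq(from, to, by = step)
  Z <- model$basis(grid) - model$basis(rep(ref_dose, length(grid)))
  fit <- drop(Z %*% model$coefficients)
  se <- sqrt(pmax(0, rowSums((Z %*% model$robust_cov) * Z)))
  out <- tibble(
    dose = grid,
    rr = exp(fit),
    lo = exp(fit - Z95 * se),
    hi = exp(fit + Z95 * se),
    extrapolated = grid < span[1] | grid > span[2]
  )
  out <- structure(out, class = c("dose_curve", class(out)),
                   ref_dose = ref_dose)
  attr(out, "threshold") <- threshold_dose(out)
  out
}

#' Lowest dose with persistently significant risk elevation
#'
#' The smallest grid dose above the curve's anchor where the lower CI bound
#' exceeds 1 and stays above 1 through the end of the grid (isolated
#' crossings do not count). `NA` if no such dose exists.
#'
#' @param curve A [predict_curve()] result.
#' @return A dose (same units as the grid), or `NA`.
#' @export
threshold_dose <- function(curve) {
  ref_dose <- attr(curve, "ref_dose")
  above <- curve$dose > ref_dose & curve$lo > 1
  candidates <- which(above)
  if (length(candidates) == 0) return(NA_real_)
  # persistence: all grid doses from the candidate to the end must qualify
  tail_ok <- rev(cumprod(rev(curve$lo > 1 | curve$dose <= ref_dose))) == 1
  ok <- candidates[tail_ok[candidates]]
  if (length(ok) == 0) return(NA_real_)
  curve$dose[min(ok)]
}
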