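#' Forest plot of a pooled analysis
#'
#' Study-level relative risks with 95% CIs on a log axis, random-effects
#' weights as point size, and the pooled estimate as a diamond row.
#'
#' @param object A [pool()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.meta_pool <- function(object, ...) {
  st <- tidy(object)
  st$label <- make.unique(st$label, sep = " ")
  st$label <- factor(st$label, levels = rev(st$label))
  pooled <- glance(object)
  ggplot2::ggplot(st, ggplot2::aes(x = .data$rr, y = .data$label)) +
    ggplot2::geom_vline(xintercept = 1, linetype = "dotted", colour = "grey40") +
    ggplot2::geom_vline(xintercept = pooled$rr, linetype = "dashed",
                        colour = "steelblue") +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$ci_lower, xmax = .data$ci_upper), height = 0.15
    ) +
    ggplot2::geom_point(ggplot2::aes(size = .data$weight_pct), shape = 15) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_size_area(max_size = 4, guide = "none") +
    ggplot2::labs(
      x = "Relative risk (log scale)", y = NULL,
      title = sprintf("Pooled RR %.2f [%.2f, %.2f], I² = %.0f%%",
                      pooled$rr, pooled$ci_lower, pooled$ci_upper, pooled$i2)
    ) +
    ggplot2::theme_minimal()
}

#' Plot a fitted dose-response curve
#'
#' Point-estimate curve (solid) with pointwise 95% CI (dashed), anchored at
#' relative risk 1 at the curve's reference dose; the persistence threshold,
#' if any, is marked.
#'
#' @param object A [predict_curve()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.dose_curve <- function(object, ...) {
  thr <- attr(object, "threshold")
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$dose)) +
    ggplot2::geom_hline(yintercept = 1, colour = "grey40", linewidth = 0.3) +
    ggplot2::geom_line(ggplot2::aes(y = .data$rr)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$lo), linetype = "dashed") +
    ggplot2::geom_line(ggplot2::aes(y = .data$hi), linetype = "dashed") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "HbA1c (%)", y = "Relative risk (log scale)") +
    ggplot2::theme_minimal()
  if (!is.na(thr)) {
    p <- p + ggplot2::geom_vline(xintercept = thr, linetype = "dotdash",
                                 colour = "firebrick")
  }
  p
}
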