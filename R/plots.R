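#' Plot an L-curve
#'
#' Draws the step-function right boundary of an L-region on the unit
#' square (principal p-value on the x axis, covariate p-value on the y
#' axis), optionally on a log scale.
#'
#' @param object A `cfdr_lcurve` from [build_lcurve()].
#' @param log Use log10 axes?
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cfdr_lcurve <- function(object, log = FALSE, ...) {
  df <- tibble(p = rep(object$p_bound, each = 2),
               q = as.numeric(rbind(object$q_lo, object$q_hi)))
  gg <- ggplot2::ggplot(df, ggplot2::aes(x = .data$p, y = .data$q)) +
    ggplot2::geom_path() +
    ggplot2::labs(
      x = "principal p-value threshold",
      y = "covariate p-value",
      title = sprintf("L-curve at level %.3g", attr(object, "alpha"))
    ) +
    ggplot2::theme_minimal()
  if (log) {
    gg <- gg + ggplot2::scale_x_log10() + ggplot2::scale_y_log10()
  } else {
    gg <- gg + ggplot2::coord_cartesian(xlim = c(0, 1), ylim = c(0, 1))
  }
  gg
}

#' Plot v-values against principal p-values
#'
#' Shows how conditioning reweights the hypotheses: points below the
#' diagonal gained evidence from the covariate, points above lost it.
#'
#' @param object A `cfdr_vvalues` tibble from [cfdr_vvalues()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cfdr_vvalues <- function(object, ...) {
  ggplot2::ggplot(tibble(p = object$p, v = object$v, q = object$q),
                  ggplot2::aes(x = .data$p, y = .data$v,
                               colour = .data$q)) +
    ggplot2::geom_point(size = 0.6, alpha = 0.7) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "principal p-value", y = "v-value",
                  colour = "covariate q") +
    ggplot2::theme_minimal()
}

#' Plot benchmark FDR / TDR summaries
#'
#' @param results A tibble from [run_benchmark()].
#' @param metric `"fdr"` or `"tdr"`.
#' @return A ggplot object.
#' @export
plot_benchmark <- function(results, metric = c("fdr", "tdr")) {
  metric <- match.arg(metric)
  sm <- benchmark_summary(results)
  val <- if (metric == "fdr") sm$fdr else sm$tdr
  se <- if (metric == "fdr") sm$fdr_se else sm$tdr_se
  df <- tibble(method = sm$method, alpha = factor(sm$alpha),
               value = val, se = se)
  gg <- ggplot2::ggplot(df, ggplot2::aes(x = .data$method, y = .data$value,
                                         fill = .data$alpha)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$value - 2 * .data$se,
                   ymax = .data$value + 2 * .data$se),
      position = ggplot2::position_dodge(0.9), width = 0.2
    ) +
    ggplot2::labs(x = NULL, y = toupper(metric)) +
    ggplot2::theme_minimal()
  if (metric == "fdr") {
    lv <- unique(sm$alpha)
    gg <- gg + ggplot2::geom_hline(yintercept = lv, linetype = 2)
  }
  gg
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
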