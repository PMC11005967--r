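#' Plot a correlation sweep
#'
#' Two-panel figure: per-level Pearson correlation of V_xGy with COPP and
#' POPP (with the threshold dose marked), and the per-level p-value of the
#' correlation comparison.
#'
#' @param sweep a `correlation_sweep`, ideally after
#'   [compare_correlations()].
#' @param alpha significance level drawn on the p-value panel.
#' @return A ggplot object.
#' @export
plot_sweep <- function(sweep, alpha = 0.05) {
  stopifnot(inherits(sweep, "correlation_sweep"))
  df <- as.data.frame(sweep)
  long <- rbind(
    data.frame(dose_gy = df$dose_gy, r = df$r_copp, parameter = "COPP"),
    data.frame(dose_gy = df$dose_gy, r = df$r_popp, parameter = "POPP"))
  dth <- suppressWarnings(threshold_dose(sweep))
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$dose_gy, y = .data$r,
                                          colour = .data$parameter)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Dose level (Gy)", y = "Pearson R",
                  colour = NULL) +
    ggplot2::theme_minimal()
  if (!is.na(dth))
    p <- p + ggplot2::geom_vline(xintercept = dth, linetype = "dashed")
  if (!is.null(df$p_value)) {
    pv <- ggplot2::ggplot(df, ggplot2::aes(x = .data$dose_gy, y = .data$p_value)) +
      ggplot2::geom_line() +
      ggplot2::geom_hline(yintercept = alpha, linetype = "dotted") +
      ggplot2::scale_y_log10() +
      ggplot2::labs(x = "Dose level (Gy)", y = "p (difference)") +
      ggplot2::theme_minimal()
    return(list(correlation = p, p_value = pv))
  }
  p
}

#' Scatter of a dose-volume metric against a predictive parameter
#'
#' One regression panel: per-case metric against
#' COPP or POPP with the ordinary least-squares line.
#'
#' @param results per-case results table from [run_experiment()].
#' @param metric column name of the metric (e.g. `"v70_rectum"`).
#' @param predictor column name of the parameter (e.g. `"copp_rectum"`).
#' @return A ggplot object.
#' @export
plot_regression <- function(results, metric, predictor) {
  stopifnot(metric %in% names(results), predictor %in% names(results))
  fit <- linear_fit(results[[predictor]], results[[metric]])
  ggplot2::ggplot(results, ggplot2::aes(x = .data[[predictor]],
                                        y = .data[[metric]])) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(slope = fit$slope, intercept = fit$intercept) +
    ggplot2::labs(title = sprintf("R = %.3f (n = %d)", fit$pearson_r, fit$n)) +
    ggplot2::theme_minimal()
}
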