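#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

fit_plot_data <- function(observed, model_binned) {
  tibble::tibble(
    bin_mid = (observed$bin_start + observed$bin_end) / 2,
    observed = observed$percent,
    model = model_binned$percent
  )
}

plot_binned_comparison <- function(observed, model_binned, subtitle) {
  df <- fit_plot_data(observed, model_binned)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$bin_mid)) +
    ggplot2::geom_col(ggplot2::aes(y = .data$observed), fill = "grey70",
                      width = diff(df$bin_mid[1:2]) * 0.9) +
    ggplot2::geom_line(ggplot2::aes(y = .data$model), colour = "#C0392B",
                       linewidth = 0.8) +
    ggplot2::labs(
      x = "Somatic mutations per sample",
      y = "Percentage of samples",
      title = "Observed mutation burden vs fitted multi-hit model",
      subtitle = subtitle
    ) +
    ggplot2::theme_minimal()
}

#' Plot a fitted model over the observed burden distribution
#'
#' Bars: observed percentage of samples per 100-mutation bin. Line: the
#' fitted model's binned probability mass.
#'
#' @param object A `multihit_fit` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot multihit_fit
#' @export
autoplot.multihit_fit <- function(object, ...) {
  model_binned <- bin_model(object$best,
                            bin_width = object$settings$bin_width,
                            n_bins = object$settings$n_bins)
  plot_binned_comparison(
    object$observed, model_binned,
    sprintf("h = %d hits, k = %s combinations, RMSD = %.2f%%",
            object$best$h, format(object$best$k, digits = 2),
            object$rmsd_percent)
  )
}

#' Plot a fitted mixture over the observed burden distribution
#'
#' @param object A `multihit_mixture_fit` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot multihit_mixture_fit
#' @export
autoplot.multihit_mixture_fit <- function(object, ...) {
  b <- object$best
  model_binned <- bin_model(b, bin_width = object$settings$bin_width,
                            n_bins = object$settings$n_bins)
  plot_binned_comparison(
    object$observed, model_binned,
    sprintf("%g%% %d-hit + %g%% %d-hit, RMSD = %.2f%%",
            b$share_percent, b$component_i$h, 100 - b$share_percent,
            b$component_j$h, object$rmsd_percent)
  )
}

#' Plot the probability curves of a multi-hit model
#'
#' Shows `P_h`, the cumulative `P_k` and the per-mutation increment `P(m)`
#' (increment scaled to its own maximum for visibility) over `m`.
#'
#' @param params A [multihit_params()] object.
#' @param m_max Largest mutation count plotted (default 5000).
#' @return A ggplot object.
#' @export
plot_probability_curve <- function(params, m_max = 5000L) {
  curve <- evaluate_curve(params, m_max)
  long <- tidyr::pivot_longer(curve, c("p_h", "p_k", "p_increment"),
                              names_to = "quantity", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$m, y = .data$value)) +
    ggplot2::geom_line(colour = "#2C3E50") +
    ggplot2::facet_wrap(~ .data$quantity, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "Accumulated somatic mutations (m)", y = NULL,
                  title = sprintf("Multi-hit model curves (G = %.3g, h = %d, k = %.2g)",
                                  params$G, params$h, params$k)) +
    ggplot2::theme_minimal()
}
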