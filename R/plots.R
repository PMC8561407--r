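#' Bland-Altman plot of paired tidal volumes
#'
#' Plots the per-point difference against the pairwise mean, with the bias
#' and the 1.96-SD limits of agreement as horizontal lines.
#'
#' @param spiro Reference values (L or %).
#' @param rip Garment values on the same scale.
#' @param percent Plot the difference as a percentage of the reference?
#' @return A ggplot object.
#' @export
plot_bland_altman <- function(spiro, rip, percent = TRUE) {
  d <- if (percent) diff_tv_percent(spiro, rip) else spiro - rip
  ba <- bland_altman(d)
  df <- tibble(mean = (spiro + rip) / 2, diff = d)
  ylab <- if (percent) "difference (% of reference)" else "difference (L)"
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mean, y = .data$diff)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_hline(yintercept = ba$bias, linetype = "solid") +
    ggplot2::geom_hline(yintercept = ba$bias + c(-1, 1) * ba$loa_halfwidth,
                        linetype = "dashed") +
    ggplot2::labs(x = "mean of methods", y = ylab,
                  title = sprintf("bias %.2f, LOA half-width %.2f",
                                  ba$bias, ba$loa_halfwidth)) +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.rip_trace <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time_s, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (s)", y = sprintf("%s (%s)", object$channel, object$unit)) +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.rip_report <- function(object, ...) {
  ggplot2::ggplot(object$subject_agreement,
                  ggplot2::aes(x = .data$task, y = .data$bias)) +
    ggplot2::geom_hline(yintercept = c(-5, 5), linetype = "dashed") +
    ggplot2::geom_boxplot() +
    ggplot2::facet_wrap(~session, labeller = ggplot2::label_both) +
    ggplot2::labs(y = "per-subject bias (% of reference TV)", x = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
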