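## ggplot2 views ----------------------------------------------------------

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a period of interest
#'
#' ECG trace on the relative clock with CC episodes shaded and the
#' regular-analysis start marked at 0 s.
#'
#' @param object A `cpr_poi`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.cpr_poi <- function(object, ...) {
  df <- tibble::tibble(
    time = -30 + seq_along(object$samples) / object$fs,
    ecg = object$samples
  )
  ep <- object$timeline$cc_episodes
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$ecg))
  if (nrow(ep) > 0) {
    p <- p + ggplot2::geom_rect(
      data = ep,
      ggplot2::aes(xmin = .data$start, xmax = .data$stop,
                   ymin = -Inf, ymax = Inf),
      inherit.aes = FALSE, fill = "grey85"
    )
  }
  p +
    ggplot2::geom_line(linewidth = 0.25) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed") +
    ggplot2::labs(
      x = "time relative to regular AED analysis (s)",
      y = "ECG (µV)",
      title = sprintf("%s — %s (%s)", object$source, object$label,
                      shock_category(object$label))
    ) +
    ggplot2::theme_minimal()
}

#' Plot a sliding advice series
#'
#' Shock probability per decision time with the sHOT trend, mirroring
#' the per-case sliding-analysis views.
#'
#' @param object Advice tibble from [predict_sliding()] (one period).
#' @param threshold Optional decision threshold drawn as a reference
#'   line.
#' @param ... Unused.
#' @return A ggplot.
#' @export
plot_advice <- function(object, threshold = NULL, ...) {
  stopifnot(all(c("decision_time", "shot", "p_sh") %in% names(object)))
  long <- tidyr::pivot_longer(
    object[, c("decision_time", "shot", "p_sh")],
    cols = c("shot", "p_sh"),
    names_to = "quantity", values_to = "value"
  )
  long$quantity <- factor(long$quantity, levels = c("p_sh", "shot"),
                          labels = c("shock probability", "sHOT (s)"))
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$decision_time,
                                          y = .data$value)) +
    ggplot2::geom_col(width = 0.8) +
    ggplot2::facet_wrap(~quantity, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "decision time (s)", y = NULL) +
    ggplot2::theme_minimal()
  if (!is.null(threshold)) {
    p <- p + ggplot2::geom_hline(
      data = tibble::tibble(quantity = factor("shock probability",
                                              levels = levels(long$quantity)),
                            y = threshold),
      ggplot2::aes(yintercept = .data$y), linetype = "dashed"
    )
  }
  p
}

#' Plot performance tables
#'
#' Draws the per-class metric with its confidence band against either
#' the decision time or the sHOT stratum, depending on which column the
#' table carries.
#'
#' @param perf Output of [performance_by_time()] or
#'   [performance_by_shot()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
plot_performance <- function(perf, ...) {
  xcol <- if ("decision_time" %in% names(perf)) "decision_time" else "shot_bin"
  df <- perf[!is.na(perf$estimate), , drop = FALSE]
  ggplot2::ggplot(df, ggplot2::aes(x = .data[[xcol]],
                                   y = 100 * .data$estimate,
                                   group = .data$label)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = 100 * .data$lo,
                                      ymax = 100 * .data$hi),
                         alpha = 0.2) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_wrap(~label) +
    ggplot2::labs(
      x = if (xcol == "decision_time") "decision time (s)" else "sHOT stratum",
      y = "Se (VF) / Sp (others), %"
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
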