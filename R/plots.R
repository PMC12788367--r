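# ggplot2 views of the pipeline's result objects.

#' Plot a phase trace
#'
#' Raw and filtered nostril temperature over time with exhalation phases
#' shaded, in the style of a live monitoring panel.
#'
#' @param object A `phase_trace` from [detect_phases()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.phase_trace <- function(object, ...) {
  seg <- phase_segments(object)
  seg$t_start <- object$time_s[seg$start]
  seg$t_end <- object$time_s[seg$end]
  exhale <- seg[seg$label == 1L, ]
  offset <- mean(object$raw_c)
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$time_s))
  if (nrow(exhale) > 0) {
    p <- p + ggplot2::geom_rect(
      data = exhale,
      ggplot2::aes(xmin = .data$t_start, xmax = .data$t_end,
                   ymin = -Inf, ymax = Inf),
      inherit.aes = FALSE, fill = "orange", alpha = 0.25
    )
  }
  p +
    ggplot2::geom_line(ggplot2::aes(y = .data$raw_c), color = "darkgreen",
                       alpha = 0.6) +
    ggplot2::geom_line(ggplot2::aes(y = .data$filtered + offset),
                       color = "red") +
    ggplot2::labs(
      x = "time (s)", y = "nostril temperature (°C)",
      title = "Breathing phases (shaded: exhalation)",
      subtitle = "green: raw coldest-pixel signal; red: band-passed (re-centered)"
    ) +
    ggplot2::theme_minimal()
}

#' Plot an RR estimate
#'
#' Instantaneous, weighted, and final smoothed respiratory rate per
#' validated breath event.
#'
#' @param object An `rr_estimate` from [estimate_rr()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.rr_estimate <- function(object, ...) {
  ev <- object$events[object$events$valid & !object$events$warmup, ]
  if (nrow(ev) == 0) {
    stop("no valid inter-breath intervals to plot", call. = FALSE)
  }
  long <- tidyr::pivot_longer(
    ev[, c("time_s", "rr_inst", "rr_weighted", "rr_final")],
    cols = c("rr_inst", "rr_weighted", "rr_final"),
    names_to = "series", values_to = "bpm"
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time_s, y = .data$bpm,
                                     color = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::scale_color_manual(values = c(
      rr_inst = "grey60", rr_weighted = "steelblue", rr_final = "firebrick"
    )) +
    ggplot2::labs(x = "time (s)", y = "respiratory rate (BPM)",
                  title = "Respiratory rate per validated breath",
                  color = NULL) +
    ggplot2::theme_minimal()
}

#' Plot an evaluation report
#'
#' Estimated versus true rate per block with the identity line.
#'
#' @param object An `evaluation_report` from [evaluate_blocks()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.evaluation_report <- function(object, ...) {
  ggplot2::ggplot(object$per_block,
                  ggplot2::aes(x = .data$rate_true, y = .data$rr_est)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         color = "grey50") +
    ggplot2::geom_point(color = "firebrick") +
    ggplot2::labs(
      x = "reference rate (BPM)", y = "estimated rate (BPM)",
      title = sprintf("Block-level accuracy: MAE %.2f, RMSE %.2f BPM",
                      object$mae, object$rmse)
    ) +
    ggplot2::theme_minimal()
}
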