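# Diagnostic plots (ggplot2, optional).

#' @noRd
need_ggplot <- function() {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop_bad("ggplot2 is required for plotting")
  }
}

#' Plot a prediction-corrected VPC
#'
#' Observed 5/50/95th percentile lines per time-after-dose bin over the
#' simulation-based 95% confidence bands of the same percentiles.
#'
#' @param x a `pk_vpc` (see [pc_vpc()])
#' @param ... unused
#' @return a ggplot object
#' @export
plot.pk_vpc <- function(x, ...) {
  need_ggplot()
  d <- as.data.frame(x)
  d$mid <- (d$tad_lo + d$tad_hi) / 2
  ggplot2::ggplot(d, ggplot2::aes(x = .data$mid)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$p5_lo, ymax = .data$p5_hi),
                         fill = "steelblue", alpha = 0.25) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$p50_lo, ymax = .data$p50_hi),
                         fill = "firebrick", alpha = 0.25) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$p95_lo, ymax = .data$p95_hi),
                         fill = "steelblue", alpha = 0.25) +
    ggplot2::geom_line(ggplot2::aes(y = .data$obs_p50)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$obs_p5), linetype = 2) +
    ggplot2::geom_line(ggplot2::aes(y = .data$obs_p95), linetype = 2) +
    ggplot2::labs(x = "time after dose (h)",
                  y = "prediction-corrected concentration (ng/mL)")
}

#' Plot NPDE against time or population prediction
#'
#' @param x a `pk_npde` (see [npde()])
#' @param against `"TIME"` or `"DV"` on the x axis
#' @param ... unused
#' @return a ggplot object
#' @export
plot.pk_npde <- function(x, against = c("TIME", "DV"), ...) {
  need_ggplot()
  against <- match.arg(against)
  d <- as.data.frame(x)
  ggplot2::ggplot(d, ggplot2::aes(x = .data[[against]], y = .data$npde)) +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::geom_hline(yintercept = 0) +
    ggplot2::geom_hline(yintercept = c(-1.96, 1.96), linetype = 2) +
    ggplot2::labs(y = "NPDE")
}
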