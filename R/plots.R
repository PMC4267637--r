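#' Plot a bend-angle distribution
#'
#' Points are `-ln P` per bin against `theta` (or `theta^2` when
#' `linearized`, the coordinates in which a Gaussian WLC sample is a
#' straight line). An analytic WLC reference curve is overlaid when `lb`
#' is given.
#'
#' @param object A distribution tibble from [neg_log_distribution()].
#' @param linearized Plot against `theta^2`.
#' @param lb Optional persistence length (nm) for the analytic reference.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.wlc_distribution <- function(object, linearized = FALSE,
                                      lb = NULL, ...) {
  d <- tibble::as_tibble(object)
  d$x <- if (linearized) d$theta_sq else d$theta_rad
  xlab <- if (linearized) expression(theta^2 ~ (rad^2)) else
    expression(theta ~ (rad))
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$x, y = .data$neg_log_p)) +
    ggplot2::geom_point(shape = 1) +
    ggplot2::labs(x = xlab, y = expression(-ln ~ italic(P)(theta))) +
    ggplot2::theme_classic()
  if (!is.null(lb)) {
    L <- attr(object, "L_nm")
    bw <- attr(object, "bin_width")
    th <- seq(min(d$theta_rad), max(d$theta_rad), length.out = 200)
    ref <- tibble::tibble(
      x = if (linearized) th^2 else th,
      y = analytic_wlc_neglogp(th, L, lb,
                               folded = !attr(object, "signed")) - log(bw))
    p <- p + ggplot2::geom_line(data = ref,
                                ggplot2::aes(x = .data$x, y = .data$y))
  }
  p
}

#' Plot a height image, optionally with traces overlaid
#'
#' @param object An [afm_image()].
#' @param traces Optional contour tibble to overlay (grouped by
#'   `molecule_id`, or by `trace_id` when present).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.afm_image <- function(object, traces = NULL, ...) {
  H <- object$heights
  px <- object$pixel_size
  d <- expand.grid(y_nm = (seq_len(nrow(H)) - 1) * px,
                   x_nm = (seq_len(ncol(H)) - 1) * px)
  d$height_nm <- as.vector(H)
  p <- ggplot2::ggplot(d, ggplot2::aes(.data$x_nm, .data$y_nm,
                                       fill = .data$height_nm)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "height (nm)") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (nm)", y = "y (nm)") +
    ggplot2::theme_minimal()
  if (!is.null(traces)) {
    grp <- if ("trace_id" %in% names(traces)) "trace_id" else "molecule_id"
    p <- p + ggplot2::geom_path(
      data = traces,
      ggplot2::aes(.data$x_nm, .data$y_nm, group = .data[[grp]]),
      inherit.aes = FALSE, colour = "red", linewidth = 0.3)
  }
  p
}

#' Apparent persistence length against noise amplitude
#'
#' Summary figure of the bisector-noise experiment: apparent `lb` versus
#' shift amplitude, one line per tangent separation.
#'
#' @param estimates The `estimates` tibble from [run_noise_experiment()].
#' @return A ggplot object.
#' @export
plot_noise_summary <- function(estimates) {
  ggplot2::ggplot(estimates,
                  ggplot2::aes(x = .data$amplitude_nm, y = .data$lb_nm,
                               colour = factor(.data$L_nm),
                               group = interaction(.data$l0_nm,
                                                   .data$L_nm))) +
    ggplot2::geom_line() +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = .data$lb_nm - .data$stderr_nm,
      ymax = .data$lb_nm + .data$stderr_nm)) +
    ggplot2::labs(x = "shift amplitude (nm)",
                  y = expression(apparent ~ italic(l)[b] ~ (nm)),
                  colour = "L (nm)") +
    ggplot2::theme_classic()
}
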