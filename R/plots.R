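#' Plot a trajectory with an optional step fit
#'
#' On-axis and off-axis position versus time; when a `step_table` is
#' supplied its plateau means are overlaid as horizontal segments.
#'
#' @param object A `trajectory`.
#' @param steps Optional `step_table` from [find_steps()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
#' @method autoplot trajectory
autoplot.trajectory <- function(object, steps = NULL, ...) {
  long <- tidyr::pivot_longer(
    as_tibble(object), c("x_nm", "y_nm"),
    names_to = "axis", values_to = "position_nm")
  long$axis <- ifelse(long$axis == "x_nm", "on-axis", "off-axis")
  p <- ggplot2::ggplot(long,
                       ggplot2::aes(x = .data$t_s,
                                    y = .data$position_nm)) +
    ggplot2::geom_point(size = 0.4, alpha = 0.6) +
    ggplot2::facet_wrap(~axis, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "time (s)", y = "position (nm)")
  if (!is.null(steps)) {
    pl <- attr(steps, "plateaus")
    seg <- bind_rows(
      tibble(axis = "on-axis", t1 = pl$t_start_s, t2 = pl$t_end_s,
             pos = pl$mean_x_nm),
      tibble(axis = "off-axis", t1 = pl$t_start_s, t2 = pl$t_end_s,
             pos = pl$mean_y_nm))
    p <- p + ggplot2::geom_segment(
      data = seg,
      ggplot2::aes(x = .data$t1, xend = .data$t2, y = .data$pos,
                   yend = .data$pos),
      colour = "red", linewidth = 0.6, inherit.aes = FALSE)
  }
  p
}

#' Plot step-size distributions
#'
#' Histogram of on-axis and off-axis step sizes from a step table.
#'
#' @param object A `step_table`.
#' @param bin_nm Bin width, nm.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
#' @method autoplot step_table
autoplot.step_table <- function(object, bin_nm = 4, ...) {
  hist <- step_size_histogram(object, bin_nm)
  ggplot2::ggplot(hist, ggplot2::aes(x = .data$bin_center_nm,
                                     y = .data$count)) +
    ggplot2::geom_col(width = bin_nm * 0.9) +
    ggplot2::facet_wrap(~axis, ncol = 1) +
    ggplot2::labs(x = "step size (nm)", y = "count")
}

#' Plot a dose-response fit
#'
#' Data points (with error bars when `sd` is present) and the fitted
#' curve on a log-spaced concentration grid.
#'
#' @param object A converged `dose_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
#' @method autoplot dose_fit
autoplot.dose_fit <- function(object, ...) {
  dat <- object$data
  p <- ggplot2::ggplot(dat, ggplot2::aes(x = .data$concentration,
                                         y = .data$response)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "concentration (nM)", y = "response")
  if ("sd" %in% names(dat)) {
    p <- p + ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$response - .data$sd,
                   ymax = .data$response + .data$sd), width = 0)
  }
  if (object$converged) {
    pos <- dat$concentration[dat$concentration > 0]
    grid <- c(0, 10^seq(log10(min(pos)) - 0.3, log10(max(pos)) + 0.1,
                        length.out = 120))
    curve <- tibble(concentration = grid,
                    response = predict(object, grid))
    p <- p + ggplot2::geom_line(data = curve, colour = "steelblue")
  }
  p
}

#' Plot a decoration simulation
#'
#' Occupancy time series with the closed-form equilibrium as a reference
#' line.
#'
#' @param object A `decoration_sim`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
#' @method autoplot decoration_sim
autoplot.decoration_sim <- function(object, ...) {
  ggplot2::ggplot(object$series,
                  ggplot2::aes(x = .data$time_s, y = .data$occupancy)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = object$theta_eq,
                        linetype = "dashed", colour = "steelblue") +
    ggplot2::labs(x = "time (s)", y = "MAP7 occupancy")
}

#' Plot a kymograph
#'
#' @param object A `kymograph` from [make_kymograph()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
#' @method autoplot kymograph
autoplot.kymograph <- function(object, ...) {
  img <- unclass(object)
  df <- tidyr::expand_grid(line = seq_len(nrow(img)),
                           pixel = seq_len(ncol(img)))
  df$intensity <- img[cbind(df$line, df$pixel)]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pixel, y = .data$line,
                                   fill = .data$intensity)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_gradient(low = "black", high = "white") +
    ggplot2::labs(x = "position (pixels)", y = "time (lines)")
}

#' @importFrom rlang .data
NULL
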