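# ggplot2 views of the main result types.

#' Plot trajectories over the synaptic regions
#'
#' @param traj Trajectory tibble.
#' @param regions Optional region table; polygons are drawn underneath.
#' @return A ggplot.
#' @export
plot_trajectories <- function(traj, regions = NULL) {
  p <- ggplot2::ggplot()
  if (!is.null(regions) && nrow(regions) > 0) {
    polys <- dplyr::bind_rows(lapply(seq_len(nrow(regions)), function(i) {
      m <- as_ring(regions$polygon[[i]])
      tibble::tibble(region_id = regions$region_id[i],
                     x_um = m[, 1], y_um = m[, 2])
    }))
    p <- p + ggplot2::geom_polygon(
      data = polys,
      ggplot2::aes(.data$x_um, .data$y_um, group = .data$region_id),
      fill = "grey85", colour = "grey40")
  }
  p +
    ggplot2::geom_path(
      data = traj,
      ggplot2::aes(.data$x_um, .data$y_um, group = .data$track_id,
                   colour = factor(.data$track_id)),
      linewidth = 0.3, show.legend = FALSE) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (µm)", y = "y (µm)")
}

#' Plot per-trajectory and population MSD curves
#'
#' @param msd Output of [compute_msd()].
#' @param population Overlay the equal-weight population mean (default TRUE).
#' @return A ggplot.
#' @export
plot_msd <- function(msd, population = TRUE) {
  p <- ggplot2::ggplot(msd, ggplot2::aes(.data$lag_s, .data$msd_um2)) +
    ggplot2::geom_line(ggplot2::aes(group = .data$track_id),
                       alpha = 0.2, linewidth = 0.2) +
    ggplot2::labs(x = "time delay (s)", y = expression(MSD ~ (mu * m^2)))
  if (population) {
    p <- p + ggplot2::geom_line(data = population_msd(msd),
                                colour = "red", linewidth = 0.8)
  }
  p
}

#' Plot a drift path
#'
#' @param drift A `drift_path` from [estimate_drift()].
#' @return A ggplot of the cumulative x/y drift versus frame.
#' @export
plot_drift <- function(drift) {
  d <- tidyr::pivot_longer(drift, c("dx_um", "dy_um"),
                           names_to = "axis", values_to = "drift_um")
  ggplot2::ggplot(d, ggplot2::aes(.data$frame, .data$drift_um,
                                  colour = .data$axis)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "frame", y = "cumulative drift (µm)")
}

#' Plot a localization-density profile
#'
#' @param profile Output of [zone_density()] (bars) or
#'   [distance_histogram()] (counts).
#' @return A ggplot versus signed distance to the synaptic edge; the dashed
#'   line marks the edge.
#' @export
plot_density_profile <- function(profile) {
  ycol <- if ("density_per_um2" %in% names(profile)) "density_per_um2" else "count"
  ggplot2::ggplot(profile,
                  ggplot2::aes(.data$bin_center_nm, .data[[ycol]])) +
    ggplot2::geom_col(width = diff(profile$bin_center_nm[1:2]) * 0.9,
                      fill = "steelblue") +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed") +
    ggplot2::labs(x = "distance to synaptic edge (nm)",
                  y = if (ycol == "count") "localizations" else
                    expression(localizations / mu * m^2))
}

#' Plot D versus distance from the synaptic edge
#'
#' @param profile Output of [profile_D_vs_distance()].
#' @return A ggplot with 95% confidence intervals.
#' @export
plot_D_profile <- function(profile) {
  ggplot2::ggplot(profile, ggplot2::aes(.data$bin_center_um,
                                        .data$mean_D_um2_s)) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$ci_lo,
                                        ymax = .data$ci_hi), width = 0.02) +
    ggplot2::geom_point() + ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed") +
    ggplot2::labs(x = "distance to synaptic edge (µm)",
                  y = expression(D ~ (mu * m^2 / s)))
}

#' @export
autoplot.drift_path <- function(object, ...) plot_drift(object)

#' Autoplot a fitted model
#'
#' Draws the data points and the fitted curve of an FCS, Hill or
#' desensitization fit.
#'
#' @param object A `synaptrack_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.synaptrack_fit <- function(object, ...) {
  d <- object$data
  xcol <- names(d)[1]; ycol <- names(d)[2]
  d$.fitted <- object$fitted
  p <- ggplot2::ggplot(d, ggplot2::aes(.data[[xcol]], .data[[ycol]])) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_line(ggplot2::aes(y = .data$.fitted), colour = "red")
  if (inherits(object, "hill_fit")) p <- p + ggplot2::scale_x_log10()
  if (inherits(object, "fcs_fit")) p <- p + ggplot2::scale_x_log10()
  p
}
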