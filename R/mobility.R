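# Mean-square-displacement analysis: per-trajectory time-averaged MSD curves,
# the short-time diffusion coefficient from the first five lag points, mean
# frame-to-frame displacements, and mobility-vs-distance profiles.

#' Time-averaged MSD per trajectory
#'
#' For each trajectory and each lag k (in frames), averages the squared
#' displacement over all localized frame pairs (f, f + k). Pairs spanning
#' missed frames use the true frame difference, so trajectories with gaps
#' contribute to exactly the lags they support; lags with no pairs are
#' absent. Trajectories with fewer than `min_frames` localized frames are
#' dropped with a warning.
#'
#' @param traj Trajectory tibble (track_id, frame, x_um, y_um, optionally t_s).
#' @param max_lag Largest lag in frames (NULL = full span of each track).
#' @param frame_interval Frame interval in s (inferred from `t_s` if absent).
#' @param min_frames Minimum localized frames per trajectory (default 6).
#' @return Tibble: track_id, lag_frames, lag_s, msd_um2, n_pairs.
#' @export
compute_msd <- function(traj, max_lag = NULL, frame_interval = NULL,
                        min_frames = 6) {
  traj <- as_trajectories(traj)
  dt <- traj_dt(traj, frame_interval)
  lens <- dplyr::count(traj, .data$track_id)
  short <- lens$track_id[lens$n < min_frames]
  if (length(short) > 0) {
    warn(sprintf("excluding %d trajectories with fewer than %d localized frames",
                 length(short), min_frames))
    traj <- dplyr::filter(traj, !.data$track_id %in% short)
  }
  if (nrow(traj) == 0) {
    return(tibble::tibble(track_id = integer(), lag_frames = integer(),
                          lag_s = double(), msd_um2 = double(),
                          n_pairs = integer()))
  }
  one <- function(d) {
    f <- d$frame; x <- d$x_um; y <- d$y_um
    span <- max(f) - min(f)
    K <- if (is.null(max_lag)) span else min(max_lag, span)
    idx <- match(seq(min(f), max(f)), f)   # frame -> row, NA at gaps
    out <- vector("list", K)
    for (k in seq_len(K)) {
      i1 <- idx[seq_len(length(idx) - k)]
      i2 <- idx[seq_len(length(idx) - k) + k]
      ok <- !is.na(i1) & !is.na(i2)
      n <- sum(ok)
      if (n == 0) next
      sq <- (x[i2[ok]] - x[i1[ok]])^2 + (y[i2[ok]] - y[i1[ok]])^2
      out[[k]] <- tibble::tibble(lag_frames = k, msd_um2 = mean(sq),
                                 n_pairs = n)
    }
    dplyr::bind_rows(out)
  }
  res <- dplyr::group_modify(dplyr::group_by(traj, .data$track_id), ~ one(.x))
  res <- dplyr::ungroup(res)
  res$lag_s <- res$lag_frames * dt
  dplyr::select(res, "track_id", "lag_frames", "lag_s", "msd_um2", "n_pairs")
}

#' Short-time diffusion coefficient from an MSD curve
#'
#' Ordinary least squares of MSD versus lag time over the first five nonzero
#' lag points of each trajectory, with a free intercept that absorbs the
#' localization-noise offset; D = slope / 4 for 2D diffusion. Negative
#' slopes are retained (they are excluded from log-scale summaries
#' downstream). Trajectories with fewer than five usable lags are dropped.
#'
#' @param msd Output of [compute_msd()].
#' @param n_points Number of initial lag points to fit (default 5).
#' @return Tibble: track_id, D_um2_s, intercept_um2, n_fit_points.
#' @export
fit_diffusion <- function(msd, n_points = 5) {
  stopifnot(all(c("track_id", "lag_s", "msd_um2") %in% names(msd)))
  one <- function(d) {
    d <- dplyr::arrange(d, .data$lag_s)
    if (nrow(d) < n_points) return(NULL)
    d <- d[seq_len(n_points), ]
    fit <- lm(msd_um2 ~ lag_s, data = d)
    tibble::tibble(D_um2_s = unname(coef(fit)[2]) / 4,
                   intercept_um2 = unname(coef(fit)[1]),
                   n_fit_points = n_points)
  }
  res <- dplyr::group_modify(dplyr::group_by(msd, .data$track_id), ~ one(.x) %||%
                               tibble::tibble(D_um2_s = double(),
                                              intercept_um2 = double(),
                                              n_fit_points = integer()))
  dplyr::ungroup(res)
}

#' Population-averaged MSD curve
#'
#' Averages per-trajectory time-averaged MSD values at each lag with equal
#' weight per trajectory.
#'
#' @param msd Output of [compute_msd()].
#' @return Tibble: lag_frames, lag_s, msd_um2, n_tracks.
#' @export
population_msd <- function(msd) {
  dplyr::summarise(dplyr::group_by(msd, .data$lag_frames, .data$lag_s),
                   msd_um2 = mean(.data$msd_um2), n_tracks = dplyr::n(),
                   .groups = "drop")
}

#' Mean frame-to-frame displacement
#'
#' Mean Euclidean displacement over consecutive localized frame pairs (frame
#' difference exactly 1), reported both per frame (µm) and per second (µm/s).
#'
#' @param traj Trajectory tibble.
#' @param frame_interval Frame interval in s (inferred from `t_s` if absent).
#' @return Tibble: track_id, mean_disp_um, mean_disp_um_s, n_steps.
#' @export
mean_displacement <- function(traj, frame_interval = NULL) {
  traj <- as_trajectories(traj)
  dt <- traj_dt(traj, frame_interval)
  one <- function(d) {
    df <- diff(d$frame)
    step <- sqrt(diff(d$x_um)^2 + diff(d$y_um)^2)[df == 1]
    tibble::tibble(mean_disp_um = if (length(step)) mean(step) else NA_real_,
                   mean_disp_um_s = if (length(step)) mean(step) / dt else NA_real_,
                   n_steps = length(step))
  }
  dplyr::ungroup(dplyr::group_modify(dplyr::group_by(traj, .data$track_id),
                                     ~ one(.x)))
}

#' Diffusion coefficient versus distance from the synaptic edge
#'
#' Bins trajectories by the signed distance from their centroid to the edge
#' of the nearest synaptic region (100 nm bins by default) and reports the
#' per-bin mean D with a normal-theory 95% confidence interval. Empty bins
#' are absent from the output.
#'
#' @param estimates Output of [fit_diffusion()].
#' @param traj Trajectory tibble used for the estimates.
#' @param regions Region table from [delineate_regions()].
#' @param bin_width Bin width in µm (default 0.1 = 100 nm).
#' @return Tibble: bin_center_um, mean_D_um2_s, ci_lo, ci_hi, n_tracks.
#' @export
profile_D_vs_distance <- function(estimates, traj, regions, bin_width = 0.1) {
  traj <- as_trajectories(traj)
  cent <- dplyr::summarise(dplyr::group_by(traj, .data$track_id),
                           x = mean(.data$x_um), y = mean(.data$y_um),
                           .groups = "drop")
  nd <- nearest_edge_distance(cent$x, cent$y, regions)
  cent$dist_edge_um <- nd$dist_edge_um
  d <- dplyr::inner_join(estimates, cent[, c("track_id", "dist_edge_um")],
                         by = "track_id")
  d$bin <- floor(d$dist_edge_um / bin_width)
  out <- dplyr::summarise(
    dplyr::group_by(d, .data$bin),
    mean_D_um2_s = mean(.data$D_um2_s),
    se = sd(.data$D_um2_s) / sqrt(dplyr::n()),
    n_tracks = dplyr::n(), .groups = "drop"
  )
  out$bin_center_um <- (out$bin + 0.5) * bin_width
  out$ci_lo <- out$mean_D_um2_s - 1.96 * out$se
  out$ci_hi <- out$mean_D_um2_s + 1.96 * out$se
  dplyr::arrange(dplyr::select(out, "bin_center_um", "mean_D_um2_s",
                               "ci_lo", "ci_hi", "n_tracks"),
                 .data$bin_center_um)
}

#' Mean D grouped by synaptic-time fraction
#'
#' Groups diffusion estimates by the fraction of time each trajectory spent
#' in the synaptic region (bins from [bin_by_synaptic_fraction()]) and
#' reports per-bin mean D with 95% confidence intervals.
#'
#' @param estimates Output of [fit_diffusion()].
#' @param classifications Output of [classify_trajectories()] with a
#'   `frac_bin` column added by [bin_by_synaptic_fraction()].
#' @return Tibble: frac_bin, mean_D_um2_s, ci_lo, ci_hi, n_tracks.
#' @export
profile_D_vs_fraction <- function(estimates, classifications) {
  if (!"frac_bin" %in% names(classifications)) {
    abort("classifications must carry a 'frac_bin' column; see bin_by_synaptic_fraction()")
  }
  d <- dplyr::inner_join(estimates,
                         classifications[, c("track_id", "frac_bin")],
                         by = "track_id")
  out <- dplyr::summarise(
    dplyr::group_by(d, .data$frac_bin),
    mean_D_um2_s = mean(.data$D_um2_s),
    se = sd(.data$D_um2_s) / sqrt(dplyr::n()),
    n_tracks = dplyr::n(), .groups = "drop"
  )
  out$ci_lo <- out$mean_D_um2_s - 1.96 * out$se
  out$ci_hi <- out$mean_D_um2_s + 1.96 * out$se
  out
}
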