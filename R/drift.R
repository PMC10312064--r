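# Fiducial-free drift correction. Synaptic trajectories are spatially
# confined, so averaging frame-to-frame displacements across many
# simultaneously imaged particles isolates the common (stage/thermal) motion;
# the cumulative common motion is then subtracted from every trajectory,
# anchored to the first frame.

#' Estimate global lateral drift from a trajectory ensemble
#'
#' For every consecutive frame pair, the drift increment is the median (or
#' mean) over all trajectories localized in both frames of their
#' displacement; increments supported by fewer than `min_tracks` trajectories
#' are linearly interpolated from neighbouring supported increments and
#' flagged. The cumulative path is anchored to zero at the first frame. Only
#' gap-free (frame difference 1) displacements contribute, so trajectories
#' with missed detections never span their gaps.
#'
#' @param traj Trajectory tibble.
#' @param min_tracks Minimum trajectories per frame pair (default 10).
#' @param stat `"median"` (robust, default) or `"mean"`.
#' @param max_unsupported Error if more than this fraction of frame pairs
#'   lacks support (default 0.2) — such fields of view are excluded.
#' @return Tibble of class `drift_path`: frame, dx_um, dy_um (cumulative),
#'   n_tracks, interpolated.
#' @export
estimate_drift <- function(traj, min_tracks = 10,
                           stat = c("median", "mean"), max_unsupported = 0.2) {
  stat <- match.arg(stat)
  traj <- as_trajectories(traj)
  avg <- if (stat == "median") stats::median else base::mean
  steps <- dplyr::ungroup(dplyr::mutate(
    dplyr::group_by(traj, .data$track_id),
    dfr = .data$frame - dplyr::lag(.data$frame),
    ddx = .data$x_um - dplyr::lag(.data$x_um),
    ddy = .data$y_um - dplyr::lag(.data$y_um)
  ))
  steps <- dplyr::filter(steps, .data$dfr == 1)
  inc <- dplyr::summarise(dplyr::group_by(steps, .data$frame),
                          idx = avg(.data$ddx), idy = avg(.data$ddy),
                          n = dplyr::n(), .groups = "drop")
  f0 <- min(traj$frame); f1 <- max(traj$frame)
  frames <- seq(f0, f1)
  full <- tibble::tibble(frame = frames[-1])
  full <- dplyr::left_join(full, inc, by = "frame")
  full$n[is.na(full$n)] <- 0L
  unsupported <- full$n < min_tracks
  if (all(unsupported)) {
    abort("drift estimation failed: no frame pair has enough trajectories")
  }
  if (mean(unsupported) > max_unsupported) {
    abort(sprintf(
      "drift estimation failed: %.0f%% of frame pairs have < %d supporting trajectories",
      100 * mean(unsupported), min_tracks))
  }
  if (any(unsupported)) {
    sup <- which(!unsupported)
    full$idx[unsupported] <- approx(sup, full$idx[sup], xout = which(unsupported),
                                    rule = 2)$y
    full$idy[unsupported] <- approx(sup, full$idy[sup], xout = which(unsupported),
                                    rule = 2)$y
  }
  out <- tibble::tibble(
    frame = frames,
    dx_um = c(0, cumsum(full$idx)),
    dy_um = c(0, cumsum(full$idy)),
    n_tracks = c(NA_integer_, full$n),
    interpolated = c(FALSE, unsupported)
  )
  class(out) <- c("drift_path", class(out))
  out
}

#' Subtract an estimated drift path from trajectories
#'
#' The position at frame f becomes position − drift(f); frames and times are
#' unchanged. Every localized frame must be covered by the drift path.
#'
#' @param traj Trajectory tibble.
#' @param drift A `drift_path` from [estimate_drift()] (or a compatible
#'   tibble with frame, dx_um, dy_um).
#' @return Drift-corrected trajectory tibble.
#' @export
apply_drift_correction <- function(traj, drift) {
  traj <- as_trajectories(traj)
  i <- match(traj$frame, drift$frame)
  if (anyNA(i)) abort("drift path does not cover all frames present in the data")
  traj$x_um <- traj$x_um - drift$dx_um[i]
  traj$y_um <- traj$y_um - drift$dy_um[i]
  traj
}
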