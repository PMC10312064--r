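# Sorting trajectories into synaptic and extrasynaptic pools. Three
# geometric rules are supported: (1) more than half of a trajectory's
# localizations inside the marker-delineated region; (2) the same rule after
# expanding each region by a 120 nm perisynaptic annulus; (3) mean per-point
# distance to the nearest synapse center below 550 nm.

#' Classify trajectories as synaptic or extrasynaptic
#'
#' @param traj Trajectory tibble.
#' @param regions Region table from [delineate_regions()].
#' @param method 1, 2 or 3 (see Details).
#' @param buffer_um Perisynaptic expansion used by Method 2 (default 0.12).
#' @param center_cutoff_um Distance cutoff used by Method 3 (default 0.55).
#' @param method3_mode For Method 3, `"mean_point_distance"` (default:
#'   the mean over trajectory points of the distance to the nearest synapse
#'   center) or `"centroid"` (distance of the trajectory centroid to the
#'   nearest center).
#'
#' @details
#' Method 1 labels a trajectory synaptic when strictly more than 50% of its
#' localizations fall inside (or on the boundary of) any region; a
#' localization inside several overlapping regions counts once. Method 2
#' applies the same rule after buffering every region by `buffer_um`.
#' Method 3 ignores the region polygons and uses only the distance to the
#' nearest synapse center; a trajectory is synaptic when its mean point
#' distance (or centroid distance) is strictly below `center_cutoff_um`.
#' The synaptic fraction reported for Method 3 refers to the unbuffered
#' region geometry. `nearest_region` is the region with the smallest
#' center-to-centroid distance (ties: lower region id).
#'
#' @return Tibble: track_id, method, label, frac_synaptic, nearest_region,
#'   mean_dist_center_um, mean_dist_edge_um, n_localizations.
#' @export
classify_trajectories <- function(traj, regions, method = 1, buffer_um = 0.12,
                                  center_cutoff_um = 0.55,
                                  method3_mode = c("mean_point_distance",
                                                   "centroid")) {
  method3_mode <- match.arg(method3_mode)
  stopifnot(method %in% 1:3, nrow(regions) >= 1)
  traj <- as_trajectories(traj)
  if (nrow(traj) == 0) abort("cannot classify an empty trajectory table")
  geom <- if (method == 2) buffer_regions(regions, buffer_um) else regions

  inside <- rep(FALSE, nrow(traj))
  for (i in seq_len(nrow(geom))) {
    inside <- inside | points_in_ring(traj$x_um, traj$y_um,
                                      as_ring(geom$polygon[[i]]))
  }
  traj$inside <- inside
  # per-point distance to the nearest synapse center
  dc <- rep(Inf, nrow(traj))
  for (i in seq_len(nrow(regions))) {
    dc <- pmin(dc, sqrt((traj$x_um - regions$x_um[i])^2 +
                          (traj$y_um - regions$y_um[i])^2))
  }
  traj$dist_center <- dc
  ed <- nearest_edge_distance(traj$x_um, traj$y_um, regions)
  traj$dist_edge <- ed$dist_edge_um

  one <- function(d) {
    frac <- mean(d$inside)
    cx <- mean(d$x_um); cy <- mean(d$y_um)
    cd <- sqrt((regions$x_um - cx)^2 + (regions$y_um - cy)^2)
    nearest <- regions$region_id[which.min(cd)]
    m3 <- if (method3_mode == "mean_point_distance") mean(d$dist_center) else min(cd)
    label <- if (method %in% c(1, 2)) {
      if (frac > 0.5) "synaptic" else "extrasynaptic"
    } else {
      if (m3 < center_cutoff_um) "synaptic" else "extrasynaptic"
    }
    tibble::tibble(
      method = as.integer(method), label = label, frac_synaptic = frac,
      nearest_region = nearest, mean_dist_center_um = mean(d$dist_center),
      mean_dist_edge_um = mean(d$dist_edge), n_localizations = nrow(d)
    )
  }
  dplyr::ungroup(
    dplyr::group_modify(dplyr::group_by(traj, .data$track_id), ~ one(.x)))
}

#' Group trajectories by synaptic-time fraction
#'
#' Adds a `frac_bin` factor to a classification table, placing each
#' trajectory into the supplied (possibly irregular) percentage bins. A
#' literal fraction of 0 gets its own "0%" bin; all other bins are left-open
#' and right-closed, e.g. edges `c(0, 20, 80, 100)` give "0%", ">0-20%",
#' ">20-80%", ">80-100%".
#'
#' @param classifications Output of [classify_trajectories()].
#' @param bin_edges Increasing percentage edges starting at 0 and ending at
#'   100 (default 25% intervals).
#' @return The classification table with a `frac_bin` factor column.
#' @export
bin_by_synaptic_fraction <- function(classifications,
                                     bin_edges = c(0, 25, 50, 75, 100)) {
  stopifnot(bin_edges[1] == 0, tail(bin_edges, 1) == 100,
            all(diff(bin_edges) > 0))
  pct <- classifications$frac_synaptic * 100
  labs <- paste0(">", head(bin_edges, -1), "-", bin_edges[-1], "%")
  lev <- c("0%", labs)
  bin <- as.character(cut(pct, breaks = bin_edges, labels = labs,
                          include.lowest = FALSE, right = TRUE))
  bin[pct == 0] <- "0%"
  classifications$frac_bin <- factor(bin, levels = lev)
  classifications
}
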