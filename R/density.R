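# Localization-density analysis relative to the synaptic edge: signed
# distance-to-edge histograms and concentric-zone density profiles.

#' Histogram of localization distances to the synaptic edge
#'
#' For every localization, the signed Euclidean distance to the nearest
#' region edge is computed (negative inside the region) and binned.
#'
#' @param locs Localization/trajectory tibble with `x_um`, `y_um`.
#' @param regions Region table; at least one region is required.
#' @param bin_width Bin width in µm (default 0.025 = 25 nm).
#' @param range_um Optional c(min, max) signed-distance range; defaults to
#'   the data range.
#' @return Tibble: bin_center_nm, bin_lo_um, bin_hi_um, count.
#' @export
distance_histogram <- function(locs, regions, bin_width = 0.025,
                               range_um = NULL) {
  if (nrow(regions) == 0) abort("no regions: there is no reference edge")
  nd <- nearest_edge_distance(locs$x_um, locs$y_um, regions)
  d <- nd$dist_edge_um
  if (is.null(range_um)) range_um <- range(d)
  lo <- floor(range_um[1] / bin_width)
  hi <- ceiling(range_um[2] / bin_width)
  bins <- seq(lo, hi)
  idx <- floor(d / bin_width)
  idx <- idx[idx >= lo & idx < hi]
  counts <- tabulate(match(idx, head(bins, -1)), nbins = length(bins) - 1)
  tibble::tibble(
    bin_center_nm = (head(bins, -1) + 0.5) * bin_width * 1000,
    bin_lo_um = head(bins, -1) * bin_width,
    bin_hi_um = bins[-1] * bin_width,
    count = counts
  )
}

#' Localization density in concentric zones
#'
#' Assigns each localization to its nearest region (smallest absolute
#' distance to a region edge, ties by lower region id), bins it by signed
#' distance into that region's zone system, and reports, per ring index, the
#' pooled count across regions divided by the pooled ring area — the local
#' surface density in each 25 nm band. Localizations beyond the outermost
#' zone are returned in a `remainder` attribute rather than a ring.
#'
#' @param locs Localization/trajectory tibble with `x_um`, `y_um`.
#' @param zones A `zone_set` (from [build_zones()]) or a list of zone sets,
#'   one per region.
#' @param regions The region table the zones were built from.
#' @return Tibble: ring_index, inner_um, outer_um, bin_center_nm, count,
#'   area_um2, density_per_um2; attribute `remainder` holds the count of
#'   unassigned localizations.
#' @export
zone_density <- function(locs, zones, regions) {
  if (inherits(zones, "zone_set")) zones <- list(zones)
  step <- attr(zones[[1]], "step")
  nd <- nearest_edge_distance(locs$x_um, locs$y_um, regions)
  ztab <- dplyr::bind_rows(lapply(zones, function(z) {
    tibble::as_tibble(z[, c("region_id", "ring_index", "area_um2")])
  }))
  pooled <- dplyr::summarise(dplyr::group_by(ztab, .data$ring_index),
                             area_um2 = sum(.data$area_um2),
                             .groups = "drop")
  # a localization's ring index within its nearest region's zone system
  idx <- floor(nd$dist_edge_um / step)
  rng <- dplyr::summarise(dplyr::group_by(ztab, .data$region_id),
                          kmin = min(.data$ring_index),
                          kmax = max(.data$ring_index), .groups = "drop")
  m <- match(nd$region_id, rng$region_id)
  ok <- length(idx) > 0 & !is.na(m) &
    idx >= rng$kmin[m] & idx <= rng$kmax[m]
  ok[is.na(ok)] <- FALSE
  counts <- dplyr::count(
    tibble::tibble(ring_index = idx[which(ok)]), .data$ring_index)
  out <- dplyr::left_join(pooled, counts, by = "ring_index")
  out$n[is.na(out$n)] <- 0L
  out <- dplyr::transmute(
    out, ring_index = .data$ring_index,
    inner_um = .data$ring_index * step,
    outer_um = (.data$ring_index + 1) * step,
    bin_center_nm = (.data$ring_index + 0.5) * step * 1000,
    count = .data$n, area_um2 = .data$area_um2,
    density_per_um2 = ifelse(.data$area_um2 > 0, .data$n / .data$area_um2,
                             NA_real_)
  )
  attr(out, "remainder") <- sum(!ok)
  dplyr::arrange(out, .data$ring_index)
}
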