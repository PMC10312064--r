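# Subpixel delineation of synaptic regions from a scaffold-marker image, and
# the derived geometry: uniformly buffered (perisynaptic) regions and 25 nm
# concentric zone systems.

# --- separable image interpolation ------------------------------------------

keys_w <- function(s, a = -0.5) {
  s <- abs(s)
  ifelse(s <= 1, (a + 2) * s^3 - (a + 3) * s^2 + 1,
         ifelse(s < 2, a * s^3 - 5 * a * s^2 + 8 * a * s - 4 * a, 0))
}

# 1D resampling of the rows of a matrix at continuous center-index coords.
resample_rows <- function(m, cout, method) {
  n <- nrow(m)
  out <- matrix(0, length(cout), ncol(m))
  taps <- if (method == "bicubic") -1:2 else 0:1
  i0 <- floor(cout)
  for (t in taps) {
    idx <- pmin(pmax(i0 + t, 1), n)
    w <- if (method == "bicubic") keys_w(cout - (i0 + t)) else pmax(0, 1 - abs(cout - (i0 + t)))
    out <- out + m[idx, , drop = FALSE] * w
  }
  out
}

#' Upscale an image by smooth interpolation
#'
#' Separable bicubic (Keys/Catmull-Rom, default) or bilinear interpolation.
#' Output pixel (i, j) is centred at the continuous position
#' ((j - 0.5)/factor, (i - 0.5)/factor) in input-pixel units, so the µm
#' coordinate frame is preserved.
#'
#' @param img Numeric matrix (rows = y).
#' @param factor Integer oversampling factor.
#' @param method "bicubic" or "bilinear".
#' @return Upscaled matrix; `pixel_size` attribute, if present, is divided
#'   by the factor.
#' @export
upscale_image <- function(img, factor = 4, method = c("bicubic", "bilinear")) {
  method <- match.arg(method)
  stopifnot(factor >= 1, factor == round(factor))
  cy <- (seq_len(nrow(img) * factor) - 0.5) / factor + 0.5
  cx <- (seq_len(ncol(img) * factor) - 0.5) / factor + 0.5
  out <- resample_rows(img, cy, method)
  out <- t(resample_rows(t(out), cx, method))
  if (!is.null(attr(img, "pixel_size"))) {
    attr(out, "pixel_size") <- attr(img, "pixel_size") / factor
  }
  out
}

# 8-neighbour local maxima above a threshold; ties with neighbours are kept
# so that peaks centred on a pixel boundary (symmetric plateaus) are not
# missed. Returns row/col indices.
local_maxima <- function(img, threshold) {
  ny <- nrow(img); nx <- ncol(img)
  if (ny < 3 || nx < 3) return(cbind(row = integer(), col = integer()))
  core <- img[2:(ny - 1), 2:(nx - 1)]
  is_max <- core > threshold
  for (dy in -1:1) for (dx in -1:1) {
    if (dy == 0 && dx == 0) next
    is_max <- is_max & core >= img[2:(ny - 1) + dy, 2:(nx - 1) + dx]
  }
  w <- which(is_max, arr.ind = TRUE)
  cbind(row = w[, 1] + 1L, col = w[, 2] + 1L)
}

# Suppress plateau duplicates: keep the strongest peak within `radius`
# pixels of any already-kept peak.
suppress_close_peaks <- function(peaks, values, radius = 2) {
  if (nrow(peaks) <= 1) return(seq_len(nrow(peaks)))
  ord <- order(values, decreasing = TRUE)
  keep <- integer(0)
  for (i in ord) {
    if (length(keep) == 0 ||
        all((peaks[keep, 1] - peaks[i, 1])^2 +
              (peaks[keep, 2] - peaks[i, 2])^2 > radius^2)) {
      keep <- c(keep, i)
    }
  }
  sort(keep)
}

# Iterated intensity-weighted centroid in a (2h+1)^2 window; returns
# fractional (row, col). Window intensities are offset by the window minimum
# so the background does not pull the centroid to the window center.
refine_center <- function(img, row, col, half = 3, tol = 0.01, max_iter = 20) {
  r <- row; c <- col
  for (it in seq_len(max_iter)) {
    ri <- pmin(pmax(round(r) + (-half:half), 1), nrow(img))
    ci <- pmin(pmax(round(c) + (-half:half), 1), ncol(img))
    w <- img[ri, ci, drop = FALSE]
    w <- w - min(w)
    if (sum(w) == 0) break
    rn <- sum(rowSums(w) * ri) / sum(w)
    cn <- sum(colSums(w) * ci) / sum(w)
    shift <- sqrt((rn - r)^2 + (cn - c)^2)
    r <- rn; c <- cn
    if (shift < tol) break
  }
  c(row = r, col = c)
}

# Keep ring vertices at least `tol` apart (always keeps the first vertex).
thin_ring <- function(poly, tol) {
  if (tol <= 0 || nrow(poly) <= 16) return(poly)
  keep <- logical(nrow(poly)); keep[1] <- TRUE
  last <- poly[1, ]
  for (i in 2:nrow(poly)) {
    if (sqrt(sum((poly[i, ] - last)^2)) >= tol) {
      keep[i] <- TRUE
      last <- poly[i, ]
    }
  }
  if (sum(keep) < 3) return(poly)
  poly[keep, , drop = FALSE]
}

#' Delineate synaptic regions from a marker image
#'
#' Implements subpixel region delineation: the image is oversampled by a
#' smooth interpolation factor, local maxima above a robust
#' background-relative threshold (median + 4 MAD by default) are detected,
#' each center is refined to the converged intensity-weighted centroid of
#' its neighbourhood, the 8-connected component of oversampled pixels
#' brighter than `rel_threshold` times the (background-subtracted) center
#' brightness is grown from the center, and its boundary is traced as a
#' subpixel polygon in µm. Components touching the image border are dropped
#' with a warning.
#'
#' @param img Numeric matrix (rows = y, columns = x); single plane.
#' @param pixel_size Pixel size in µm (taken from the `pixel_size` attribute
#'   if missing).
#' @param oversample Oversampling factor (default 4).
#' @param rel_threshold Fraction of the center brightness defining the
#'   region edge (default 0.5).
#' @param interp "bicubic" (default) or "bilinear".
#' @param min_prominence Detection threshold above the image median, in
#'   intensity units; default 4 * MAD of the oversampled image.
#' @return Tibble: region_id, x_um, y_um (refined center), area_um2,
#'   polygon (list of vertex matrices, µm, counter-clockwise).
#' @export
delineate_regions <- function(img, pixel_size = NULL, oversample = 4,
                              rel_threshold = 0.5,
                              interp = c("bicubic", "bilinear"),
                              min_prominence = NULL) {
  interp <- match.arg(interp)
  pixel_size <- pixel_size %||% attr(img, "pixel_size")
  if (is.null(pixel_size)) abort("pixel_size must be supplied")
  os <- upscale_image(img, oversample, interp)
  px <- pixel_size / oversample
  bg <- median(os)
  os_sub <- os - bg
  prom <- min_prominence %||% {
    p <- 4 * mad(os)
    # noiseless images have MAD 0: fall back to a peak-relative threshold
    if (p <= 0) p <- 0.1 * (max(os) - bg)
    p
  }
  if (prom <= 1e-12 * max(abs(os), 1)) return(empty_regions())
  peaks <- local_maxima(os_sub, prom)
  if (nrow(peaks) == 0) return(empty_regions())
  ord <- order(os_sub[peaks], decreasing = TRUE)
  peaks <- peaks[ord, , drop = FALSE]

  claimed <- matrix(FALSE, nrow(os), ncol(os))
  xs <- (seq_len(ncol(os)) - 0.5) * px
  ys <- (seq_len(nrow(os)) - 0.5) * px
  out <- list()
  for (k in seq_len(nrow(peaks))) {
    if (claimed[peaks[k, 1], peaks[k, 2]]) next
    ctr <- refine_center(os_sub, peaks[k, 1], peaks[k, 2])
    cr <- pmin(pmax(round(ctr["row"]), 1), nrow(os))
    cc <- pmin(pmax(round(ctr["col"]), 1), ncol(os))
    level <- rel_threshold * os_sub[cr, cc]
    if (level <= 0) next
    mask <- os_sub > level
    labels <- EBImage::bwlabel(mask)
    lab <- labels[cr, cc]
    if (lab == 0) next
    comp <- labels == lab
    claimed <- claimed | comp
    touches <- any(comp[1, ]) || any(comp[nrow(comp), ]) ||
      any(comp[, 1]) || any(comp[, ncol(comp)])
    if (touches) {
      warn(sprintf("dropping region at (%.2f, %.2f) um: touches the image border",
                   (ctr["col"] - 0.5) * px, (ctr["row"] - 0.5) * px))
      next
    }
    cx <- (ctr["col"] - 0.5) * px
    cy <- (ctr["row"] - 0.5) * px
    # subpixel boundary: the level contour ring enclosing the center
    cl <- grDevices::contourLines(ys, xs, os_sub, levels = level)
    ring <- NULL; ring_area <- Inf
    for (seg in cl) {
      m <- cbind(seg$y, seg$x)      # contourLines' x runs along rows (our y)
      if (nrow(m) < 4) next
      if (sqrt(sum((m[1, ] - m[nrow(m), ])^2)) > 3 * px) next
      r <- as_ring(m)
      if (!mgcv::in.out(rbind(r, r[1, , drop = FALSE]), cbind(cx, cy))) next
      a <- abs(shoelace_area(r))
      if (a < ring_area) { ring <- r; ring_area <- a }
    }
    if (is.null(ring)) next
    ring <- thin_ring(ring, px / 2)
    out[[length(out) + 1L]] <- tibble::tibble(
      x_um = unname(cx), y_um = unname(cy),
      area_um2 = polygon_area(ring), polygon = list(as_ring(ring))
    )
  }
  if (length(out) == 0) return(empty_regions())
  res <- dplyr::bind_rows(out)
  res <- dplyr::arrange(res, .data$y_um, .data$x_um)
  dplyr::bind_cols(tibble::tibble(region_id = seq_len(nrow(res))), res)
}

empty_regions <- function() {
  tibble::tibble(region_id = integer(), x_um = double(), y_um = double(),
                 area_um2 = double(), polygon = list())
}

# Offset (dilate d > 0, erode d < 0) one polygon by level-set extraction
# from its Euclidean signed-distance field. Returns NULL when the erosion
# empties the polygon.
offset_ring <- function(poly, distance, step = NULL) {
  poly <- as_ring(poly)
  if (distance == 0) return(poly)
  field <- sdf_grid(poly, pad = max(distance, 0) + 0.02, step = step)
  ring <- sdf_outer_ring(field, distance)
  if (is.null(ring)) return(NULL)
  ring
}

#' Uniformly expand a synaptic region
#'
#' Dilates the region polygon by a disk of the given radius (the Minkowski
#' sum), implemented as the `distance` level set of the polygon's Euclidean
#' signed-distance field. The expansion is uniform in all directions; the
#' area strictly increases for positive distances.
#'
#' @param region One-row region table.
#' @param distance Expansion distance in µm (>= 0).
#' @return The region with updated polygon and area.
#' @export
buffer_region <- function(region, distance) {
  stopifnot(distance >= 0)
  if (distance == 0) return(region)
  ring <- offset_ring(region$polygon[[1]], distance)
  region$polygon[[1]] <- ring
  region$area_um2 <- polygon_area(ring)
  region
}

#' Buffer every region in a table
#'
#' @param regions Region table.
#' @param distance Expansion distance in µm (>= 0).
#' @return Region table with expanded polygons.
#' @export
buffer_regions <- function(regions, distance) {
  if (distance == 0) return(regions)
  for (i in seq_len(nrow(regions))) {
    regions[i, ] <- buffer_region(regions[i, ], distance)
  }
  regions
}

#' Concentric distance zones around a synaptic region
#'
#' Builds rings of constant signed-distance-to-edge width around (and
#' inside) a region: ring k covers signed distances [k step, (k+1) step),
#' with negative k inward. Inward rings stop when the eroded polygon
#' vanishes; outward rings extend to `max_out`. Ring areas come from the
#' same signed-distance field used for localization binning, so zone counts
#' divided by zone areas are consistent by construction.
#'
#' @param region One-row region table.
#' @param step Zone width in µm (default 0.025 = 25 nm).
#' @param max_out Outermost distance in µm (default 0.5).
#' @return Tibble of class `zone_set`: region_id, ring_index, inner_um,
#'   outer_um, area_um2, outer_ring (list; boundary polygon at the ring's
#'   outer level).
#' @export
build_zones <- function(region, step = 0.025, max_out = 0.5) {
  stopifnot(step > 0, max_out >= step)
  poly <- as_ring(region$polygon[[1]])
  field <- sdf_grid(poly, pad = max_out + 0.02)
  k_out <- floor(max_out / step + 1e-9) - 1L
  depth <- -min(field$z)
  k_in <- -ceiling(depth / step) - 1L
  ks <- seq(k_in, k_out)
  # one contour extraction per level serves both the areas and the rings
  info <- lapply(seq(k_in, k_out + 1L),
                 function(k) sdf_level_info(field, k * step))
  lev_area <- vapply(info, `[[`, numeric(1), "area")
  ring_area <- lev_area[-1] - lev_area[-length(lev_area)]
  rings <- lapply(info[-1], `[[`, "outer")
  out <- tibble::tibble(
    region_id = region$region_id[1] %||% 1L,
    ring_index = ks,
    inner_um = ks * step,
    outer_um = (ks + 1L) * step,
    area_um2 = pmax(ring_area, 0),
    outer_ring = rings
  )
  out <- out[out$area_um2 > 0 | (out$ring_index >= 0 & out$ring_index <= k_out), ]
  attr(out, "step") <- step
  attr(out, "max_out") <- max_out
  class(out) <- c("zone_set", class(out))
  out
}
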