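# Planar polygon utilities shared by the regions, classify and density modules.
# Polygons are open rings: an n x 2 matrix of (x, y) vertices in micrometres,
# positively (counter-clockwise) oriented; the closing edge is implicit.

# Signed shoelace area; positive for counter-clockwise rings.
shoelace_area <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  sum(x * yn - xn * y) / 2
}

#' Area of a polygon
#'
#' Shoelace formula on a vertex ring. Orientation is ignored; the absolute
#' area is returned.
#'
#' @param poly An n x 2 numeric matrix of (x, y) vertices in µm.
#' @return Area in µm².
#' @export
polygon_area <- function(poly) abs(shoelace_area(as_ring(poly)))

# Normalize a ring: matrix, >= 3 vertices, drop a duplicated closing vertex,
# enforce counter-clockwise orientation.
as_ring <- function(poly) {
  poly <- as.matrix(poly)[, 1:2, drop = FALSE]
  storage.mode(poly) <- "double"
  n <- nrow(poly)
  if (n >= 2 && isTRUE(all(poly[1, ] == poly[n, ]))) poly <- poly[-n, , drop = FALSE]
  if (nrow(poly) < 3) abort("a polygon needs at least 3 distinct vertices")
  if (shoelace_area(poly) < 0) poly <- poly[rev(seq_len(nrow(poly))), , drop = FALSE]
  unname(poly)
}

#' Regular polygon approximating a disk
#'
#' Convenience constructor used for circular fixtures and confinement
#' geometry.
#'
#' @param cx,cy Center in µm.
#' @param r Radius in µm.
#' @param n Number of vertices.
#' @return An n x 2 vertex matrix (counter-clockwise).
#' @export
disk_polygon <- function(cx, cy, r, n = 64) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  cbind(cx + r * cos(th), cy + r * sin(th))
}

# Unsigned Euclidean distance from points to the polygon boundary,
# vectorised over points; loops over edges (few) not points (many).
dist_to_ring <- function(px, py, poly) {
  n <- nrow(poly)
  x1 <- poly[, 1]; y1 <- poly[, 2]
  x2 <- c(x1[-1], x1[1]); y2 <- c(y1[-1], y1[1])
  d2 <- rep(Inf, length(px))
  for (e in seq_len(n)) {
    ex <- x2[e] - x1[e]; ey <- y2[e] - y1[e]
    len2 <- ex * ex + ey * ey
    if (len2 == 0) {
      dx <- px - x1[e]; dy <- py - y1[e]
    } else {
      t <- ((px - x1[e]) * ex + (py - y1[e]) * ey) / len2
      t <- pmin(1, pmax(0, t))
      dx <- px - (x1[e] + t * ex); dy <- py - (y1[e] + t * ey)
    }
    d2 <- pmin(d2, dx * dx + dy * dy)
  }
  sqrt(d2)
}

# TRUE for points inside or on the boundary of the ring.
points_in_ring <- function(px, py, poly, tol = 1e-12) {
  inside <- mgcv::in.out(rbind(poly, poly[1, , drop = FALSE]), cbind(px, py))
  # in.out excludes (some) boundary points; count the boundary as inside.
  on_edge <- dist_to_ring(px, py, poly) <= tol
  inside | on_edge
}

#' Signed distance from points to a region boundary
#'
#' Euclidean distance to the polygon edge, negative for points inside (or on)
#' the boundary and positive outside — the sign convention used for all
#' distance-to-edge histograms and zone profiles.
#'
#' @param x,y Point coordinates in µm (vectorised).
#' @param region A one-row region table (see [delineate_regions()]) or a raw
#'   vertex matrix.
#' @return Numeric vector of signed distances in µm.
#' @export
signed_distance <- function(x, y, region) {
  poly <- region_polygon(region)
  d <- dist_to_ring(x, y, poly)
  inside <- mgcv::in.out(rbind(poly, poly[1, , drop = FALSE]), cbind(x, y)) |
    d <= 1e-12
  ifelse(inside, -d, d)
}

# Extract the vertex ring from a region row / polygon matrix.
region_polygon <- function(region) {
  if (is.matrix(region)) return(as_ring(region))
  if (is.data.frame(region)) {
    if (!"polygon" %in% names(region) || nrow(region) != 1) {
      abort("expected a one-row region table with a 'polygon' column")
    }
    return(as_ring(region$polygon[[1]]))
  }
  as_ring(region)
}

#' Signed distance to the nearest region edge
#'
#' For each point, finds the region whose boundary is closest and returns the
#' signed distance to that boundary (negative inside). Ties are broken by the
#' lower region id.
#'
#' @param x,y Point coordinates in µm.
#' @param regions A region table with `region_id` and `polygon` columns.
#' @return A tibble with columns `region_id` and `dist_edge_um`.
#' @export
nearest_edge_distance <- function(x, y, regions) {
  stopifnot(nrow(regions) >= 1)
  npt <- length(x)
  best <- rep(Inf, npt); best_id <- rep(NA_integer_, npt); best_sd <- rep(NA_real_, npt)
  for (i in seq_len(nrow(regions))) {
    sdist <- signed_distance(x, y, regions[i, ])
    take <- abs(sdist) < best
    best[take] <- abs(sdist[take])
    best_sd[take] <- sdist[take]
    best_id[take] <- regions$region_id[i]
  }
  tibble::tibble(region_id = best_id, dist_edge_um = best_sd)
}

# --- level-set machinery -----------------------------------------------------
# A signed-distance field on a regular grid supports uniform polygon offsetting
# (Minkowski dilation/erosion by a disk): the offset of the region by distance
# d is exactly the sublevel set {signed distance <= d}. Contours are extracted
# by marching squares (grDevices::contourLines) with linear interpolation.

sdf_grid <- function(poly, pad, step = NULL, max_cells = 360L) {
  bb <- apply(poly, 2, range)
  x0 <- bb[1, 1] - pad; x1 <- bb[2, 1] + pad
  y0 <- bb[1, 2] - pad; y1 <- bb[2, 2] + pad
  ext <- max(x1 - x0, y1 - y0)
  if (is.null(step)) step <- max(ext / max_cells, 0.0015)
  xs <- seq(x0, x1, by = step)
  ys <- seq(y0, y1, by = step)
  gx <- rep(xs, times = length(ys))
  gy <- rep(ys, each = length(xs))
  z <- matrix(signed_distance(gx, gy, poly), nrow = length(xs), ncol = length(ys))
  list(x = xs, y = ys, z = z, step = step)
}

# All closed contour rings of the field at the given level, as vertex matrices.
sdf_level_rings <- function(field, level) {
  if (level <= min(field$z) || level >= max(field$z)) return(list())
  cl <- grDevices::contourLines(field$x, field$y, field$z, levels = level)
  rings <- list()
  for (seg in cl) {
    m <- cbind(seg$x, seg$y)
    closed <- nrow(m) > 3 &&
      sqrt(sum((m[1, ] - m[nrow(m), ])^2)) <= 2.5 * field$step
    if (closed) rings[[length(rings) + 1L]] <- m
  }
  rings
}

# Area of the sublevel set {sd <= level} and its outer boundary, from one
# contour extraction (even-odd ring nesting).
sdf_level_info <- function(field, level) {
  if (level <= min(field$z)) return(list(area = 0, outer = NULL))
  rings <- sdf_level_rings(field, level)
  if (length(rings) == 0) return(list(area = 0, outer = NULL))
  areas <- vapply(rings, function(r) abs(shoelace_area(as_ring(r))),
                  numeric(1))
  total <- 0
  for (i in seq_along(rings)) {
    # nesting depth: how many other rings contain this ring's first vertex
    depth <- 0L
    for (j in seq_along(rings)) {
      if (i == j) next
      if (mgcv::in.out(rbind(rings[[j]], rings[[j]][1, , drop = FALSE]),
                       rings[[i]][1, , drop = FALSE])) depth <- depth + 1L
    }
    total <- total + if (depth %% 2L == 0L) areas[i] else -areas[i]
  }
  list(area = total, outer = as_ring(rings[[which.max(areas)]]))
}

sdf_sublevel_area <- function(field, level) sdf_level_info(field, level)$area

# Largest ring of the sublevel set at `level` (the outer boundary); NULL if empty.
sdf_outer_ring <- function(field, level) sdf_level_info(field, level)$outer
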