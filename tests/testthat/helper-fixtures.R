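# Fixtures are built in code; no data files.

# Gaussian-spot image with pixel centers at (i - 0.5) * px.
make_gauss_img <- function(centers, sigma = 0.24, px = 0.08, nx = 100,
                           ny = 100, A = 1000, bg = 100) {
  xc <- (seq_len(nx) - 0.5) * px
  yc <- (seq_len(ny) - 0.5) * px
  img <- matrix(bg, ny, nx)
  for (k in seq_len(nrow(centers))) {
    img <- img + A * outer(exp(-(yc - centers[k, 2])^2 / (2 * sigma^2)),
                           exp(-(xc - centers[k, 1])^2 / (2 * sigma^2)))
  }
  attr(img, "pixel_size") <- px
  img
}

# One-row region table from a raw polygon.
region_from_poly <- function(poly, id = 1L) {
  poly <- synaptrack:::as_ring(poly)
  tibble::tibble(region_id = id, x_um = mean(poly[, 1]), y_um = mean(poly[, 2]),
                 area_um2 = polygon_area(poly), polygon = list(poly))
}

unit_square_region <- function(x0 = 0, y0 = 0, side = 1, id = 1L) {
  region_from_poly(matrix(c(x0, y0, x0 + side, y0, x0 + side, y0 + side,
                            x0, y0 + side), ncol = 2, byrow = TRUE), id)
}

disk_region <- function(cx, cy, r, id = 1L, n = 128) {
  reg <- region_from_poly(disk_polygon(cx, cy, r, n), id)
  reg$x_um <- cx; reg$y_um <- cy
  reg
}

# A trajectory fixed at (or hopping among) given points.
traj_at <- function(x, y, track_id = 1L, frame0 = 0L, dt = 0.05) {
  n <- max(length(x), length(y))
  x <- rep_len(x, n); y <- rep_len(y, n)
  f <- frame0 + seq_len(n) - 1L
  tibble::tibble(track_id = track_id, frame = f, t_s = f * dt,
                 x_um = x, y_um = y)
}

# Brute-force oracle for one frame-to-frame matching problem: enumerates
# every feasible partial matching and minimizes
#   sum(link costs) + b * (#unmatched points on either side),
# b = 1.05 * link_max^2, links beyond link_max forbidden.
oracle_match_cost <- function(x1, y1, x2, y2, link_max) {
  n1 <- length(x1); n2 <- length(x2)
  b <- 1.05 * link_max^2
  d2 <- outer(x1, x2, "-")^2 + outer(y1, y2, "-")^2
  best <- Inf
  rec <- function(i, used2, cost) {
    if (cost >= best) return()
    if (i > n1) {
      best <<- min(best, cost + b * sum(!used2))
      return()
    }
    rec(i + 1, used2, cost + b)            # row i unmatched
    for (j in seq_len(n2)) {
      if (!used2[j] && d2[i, j] <= link_max^2) {
        u <- used2; u[j] <- TRUE
        rec(i + 1, u, cost + d2[i, j])
      }
    }
  }
  if (n1 == 0) return(b * n2)
  rec(1, rep(FALSE, n2), 0)
  best
}

# Cost of the linker's matching under the same objective.
linker_match_cost <- function(x1, y1, x2, y2, link_max) {
  link <- synaptrack:::match_points(x1, y1, x2, y2, link_max)
  b <- 1.05 * link_max^2
  cost <- 0
  used2 <- rep(FALSE, length(x2))
  for (i in seq_along(link)) {
    if (is.na(link[i])) cost <- cost + b
    else {
      cost <- cost + (x1[i] - x2[link[i]])^2 + (y1[i] - y2[link[i]])^2
      used2[link[i]] <- TRUE
    }
  }
  cost + b * sum(!used2)
}
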