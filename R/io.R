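# File formats: trajectory/localization CSV, marker-image TIFF, region
# GeoJSON, fit/manifest JSON. All distances are micrometres on disk.

#' Write / read a trajectory table as CSV
#'
#' Columns: track_id, frame, t_s, x_um, y_um (extra columns are preserved).
#'
#' @param traj Trajectory tibble.
#' @param path File path.
#' @return `read_trajectories()` returns the trajectory tibble;
#'   `write_trajectories()` returns `path` invisibly.
#' @export
write_trajectories <- function(traj, path) {
  traj <- as_trajectories(traj)
  readr::write_csv(traj, path)
  invisible(path)
}

#' @rdname write_trajectories
#' @export
read_trajectories <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (nrow(df) == 0) {
    return(tibble::tibble(track_id = integer(), frame = integer(),
                          t_s = double(), x_um = double(), y_um = double()))
  }
  bad <- !complete.cases(df[, intersect(.traj_cols, names(df))])
  if (any(bad)) {
    abort(sprintf("malformed trajectory rows at lines: %s",
                  paste(which(bad) + 1L, collapse = ", ")))
  }
  df$track_id <- as.integer(df$track_id)
  df$frame <- as.integer(df$frame)
  as_trajectories(df)
}

#' Write / read a localization table as CSV
#'
#' Columns: frame, x_um, y_um, intensity, quality.
#'
#' @param locs Localization tibble.
#' @param path File path.
#' @export
write_localizations <- function(locs, path) {
  readr::write_csv(locs, path)
  invisible(path)
}

#' @rdname write_localizations
#' @export
read_localizations <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("frame", "x_um", "y_um")
  if (nrow(df) > 0 && !all(need %in% names(df))) {
    abort("localization CSV must contain frame, x_um, y_um")
  }
  if (nrow(df) > 0) df$frame <- as.integer(df$frame)
  tibble::as_tibble(df)
}

#' Write / read a single-plane image as TIFF
#'
#' Images are stored as 32-bit float TIFF; the µm pixel size is carried in
#' the X/Y resolution tags (pixels per cm).
#'
#' @param img Numeric matrix with a `pixel_size` attribute (µm), or supply
#'   `pixel_size`.
#' @param path File path.
#' @param pixel_size Pixel size in µm.
#' @export
write_marker_tiff <- function(img, path, pixel_size = NULL) {
  pixel_size <- pixel_size %||% attr(img, "pixel_size")
  if (is.null(pixel_size)) abort("pixel_size must be known to write a TIFF")
  res_ppcm <- 1e4 / pixel_size
  m <- matrix(as.numeric(img), nrow(img), ncol(img))
  tiff::writeTIFF(m / max(m, 1), path, bits.per.sample = 32L,
                  reduce = FALSE)
  # resolution tags are unreliable across writers; keep a JSON sidecar
  jsonlite::write_json(list(pixel_size_um = pixel_size, scale = max(m, 1)),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_marker_tiff
#' @export
read_marker_tiff <- function(path) {
  m <- tiff::readTIFF(path, as.is = FALSE)
  if (length(dim(m)) == 3) m <- m[, , 1]
  side <- paste0(path, ".json")
  if (file.exists(side)) {
    meta <- jsonlite::read_json(side)
    m <- m * meta$scale
    attr(m, "pixel_size") <- meta$pixel_size_um
  }
  m
}

#' Write / read synaptic regions as GeoJSON
#'
#' Each region is a Polygon feature (coordinates in µm) with `region_id`,
#' center and area properties. Ring winding is normalized to
#' counter-clockwise on read.
#'
#' @param regions Region table.
#' @param path File path.
#' @export
write_regions_geojson <- function(regions, path) {
  features <- lapply(seq_len(nrow(regions)), function(i) {
    poly <- as_ring(regions$polygon[[i]])
    ring <- rbind(poly, poly[1, , drop = FALSE])
    list(
      type = "Feature",
      properties = list(region_id = regions$region_id[i],
                        x_um = regions$x_um[i], y_um = regions$y_um[i],
                        area_um2 = regions$area_um2[i]),
      geometry = list(type = "Polygon",
                      coordinates = list(lapply(seq_len(nrow(ring)),
                                                function(k) ring[k, ])))
    )
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = features),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_regions_geojson
#' @export
read_regions_geojson <- function(path) {
  gj <- jsonlite::read_json(path)
  rows <- lapply(gj$features, function(f) {
    coords <- f$geometry$coordinates[[1]]
    poly <- do.call(rbind, lapply(coords, function(p) c(p[[1]], p[[2]])))
    poly <- as_ring(poly)                # normalizes winding
    tibble::tibble(region_id = as.integer(f$properties$region_id),
                   x_um = f$properties$x_um, y_um = f$properties$y_um,
                   area_um2 = f$properties$area_um2, polygon = list(poly))
  })
  dplyr::bind_rows(rows)
}

#' Write a model fit (or any result list) as JSON
#'
#' @param x A `synaptrack_fit` or a plain list.
#' @param path File path.
#' @export
write_fit_json <- function(x, path) {
  if (inherits(x, "synaptrack_fit")) {
    x <- list(model = class(x)[1], params = as.list(x$params),
              converged = x$converged)
  }
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
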