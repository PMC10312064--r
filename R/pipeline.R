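# End-to-end driver: detection (or pre-localized input) -> linking -> drift
# correction -> region delineation -> classification -> mobility -> kinetics
# -> density, with a machine-readable run manifest.

#' Run the full tracking-analysis pipeline
#'
#' Accepts either an image stack (detection + linking) or a pre-built
#' trajectory table, plus a synaptic-marker image, and runs every analysis
#' stage. Stage failures abort with a stage-tagged error; a drift-estimation
#' failure excludes the field of view (the standard exclusion rule for
#' fields with too few simultaneously tracked particles).
#'
#' @param trajectories Trajectory tibble (alternative to `stack`).
#' @param stack Image stack for [detect_spots()] (requires `link_cfg`).
#' @param marker_image Synaptic-marker image matrix (µm pixel size in its
#'   `pixel_size` attribute or via `pixel_size`).
#' @param link_cfg A [link_config()] (needed only with `stack`).
#' @param pixel_size Pixel size in µm of the marker image.
#' @param frame_interval Frame interval in s (default 0.05).
#' @param method Classification method, 1 (default), 2 or 3.
#' @param drift_correct Estimate and subtract ensemble drift (default TRUE).
#' @param min_drift_tracks Minimum tracks per frame pair for drift.
#' @param max_lag MSD lag cap in frames (default 10).
#' @param zone_max_out Outermost zone distance in µm (default 0.5).
#' @param seed Seed recorded in the manifest (the pipeline itself is
#'   deterministic).
#' @param out_dir Optional directory; when given, all result tables are
#'   written (CSV/GeoJSON/JSON) there.
#' @return List with trajectories, drift, regions, classifications,
#'   msd, diffusion, displacement, visits, kinetics, distance_hist,
#'   zone_density and manifest.
#' @export
run_pipeline <- function(trajectories = NULL, stack = NULL,
                         marker_image = NULL, link_cfg = NULL,
                         pixel_size = NULL, frame_interval = 0.05,
                         method = 1, drift_correct = TRUE,
                         min_drift_tracks = 10, max_lag = 10,
                         zone_max_out = 0.5, seed = NULL, out_dir = NULL) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("[stage %s] %s", name, conditionMessage(e)))
    })
  }
  if (is.null(trajectories) && is.null(stack)) {
    abort("supply either trajectories or an image stack")
  }
  if (is.null(marker_image)) {
    abort("a synaptic-marker image is required for region-dependent stages")
  }
  if (!is.null(stack)) {
    if (is.null(link_cfg)) abort("link_cfg is required to process an image stack")
    locs <- stage("detect", detect_spots(stack, link_cfg))
    trajectories <- stage("link",
                          link_trajectories(locs, link_cfg, frame_interval))
  }
  trajectories <- as_trajectories(trajectories)
  n_in <- dplyr::n_distinct(trajectories$track_id)

  drift <- NULL
  if (drift_correct) {
    drift <- stage("drift", estimate_drift(trajectories,
                                           min_tracks = min_drift_tracks))
    trajectories <- stage("drift", apply_drift_correction(trajectories, drift))
  }
  regions <- stage("regions",
                   delineate_regions(marker_image, pixel_size = pixel_size))
  if (nrow(regions) == 0) abort("[stage regions] no synaptic regions found")

  cls <- stage("classify",
               classify_trajectories(trajectories, regions, method = method))
  msd <- stage("mobility", compute_msd(trajectories, max_lag = max_lag,
                                       frame_interval = frame_interval))
  dif <- stage("mobility", fit_diffusion(msd))
  disp <- stage("mobility", mean_displacement(trajectories,
                                              frame_interval = frame_interval))
  visits <- stage("kinetics",
                  segment_visits(trajectories, regions,
                                 frame_interval = frame_interval))
  kin <- stage("kinetics", kinetics_summary(visits))
  dh <- stage("density", distance_histogram(trajectories, regions))
  zones <- stage("density", lapply(seq_len(nrow(regions)), function(i) {
    build_zones(regions[i, ], max_out = zone_max_out)
  }))
  zd <- stage("density", zone_density(trajectories, zones, regions))

  manifest <- list(
    package = "synaptrack",
    version = as.character(utils::packageVersion("synaptrack")),
    seed = seed, frame_interval = frame_interval, method = method,
    drift_correct = drift_correct, min_drift_tracks = min_drift_tracks,
    max_lag = max_lag, zone_max_out = zone_max_out,
    n_tracks_in = n_in,
    n_tracks_msd = dplyr::n_distinct(msd$track_id),
    n_tracks_kinetics_qualifying = sum(kin$qualifies),
    n_regions = nrow(regions)
  )
  manifest$config_hash <- rlang::hash(manifest)

  res <- list(trajectories = trajectories, drift = drift, regions = regions,
              classifications = cls, msd = msd, diffusion = dif,
              displacement = disp, visits = visits, kinetics = kin,
              distance_hist = dh, zone_density = zd, manifest = manifest)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_trajectories(trajectories, file.path(out_dir, "trajectories.csv"))
    readr::write_csv(cls, file.path(out_dir, "classifications.csv"))
    readr::write_csv(dif, file.path(out_dir, "diffusion.csv"))
    readr::write_csv(kin, file.path(out_dir, "kinetics.csv"))
    readr::write_csv(dh, file.path(out_dir, "distance_histogram.csv"))
    readr::write_csv(zd, file.path(out_dir, "zone_density.csv"))
    if (!is.null(drift)) readr::write_csv(drift, file.path(out_dir, "drift.csv"))
    write_regions_geojson(regions, file.path(out_dir, "regions.geojson"))
    write_fit_json(manifest, file.path(out_dir, "manifest.json"))
  }
  res
}
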