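# Synthetic-data generators: the "microscope" of the package. Every input the
# pipeline consumes (trajectories, marker images, FCS curves, dose-response
# data, desensitization traces, fixed-probe localizations) can be produced
# here with known ground truth.

#' Simulation configuration
#'
#' Bundles the generative parameters for two-dimensional receptor-tracking
#' simulations: Brownian motion with a state-dependent diffusion coefficient
#' (confined synaptic vs. free extrasynaptic), exponential (or fixed-length)
#' dwell times for synaptic/extrasynaptic switching, isotropic Gaussian
#' localization noise, per-frame missed detections, and global lateral drift.
#'
#' @param seed Integer RNG seed (mandatory; Mersenne-Twister).
#' @param frame_interval Frame interval in s.
#' @param n_frames Number of frames.
#' @param pixel_size Pixel size in µm (used by [simulate_marker_image()]).
#' @param field_size Field of view, c(width, height) in µm.
#' @param D_syn,D_extra Diffusion coefficients in µm²/s for the synaptic and
#'   extrasynaptic states.
#' @param dwell_syn,dwell_extra Mean dwell times in s of the two states.
#' @param loc_noise_sigma Per-axis localization noise SD in µm.
#' @param p_missed Per-frame missed-detection probability.
#' @param drift Drift specification: `list(mode = "none")`,
#'   `list(mode = "linear", rate = c(dx, dy))` (µm per frame),
#'   `list(mode = "sinusoidal", amplitude, period)` (µm, frames), or
#'   `list(mode = "path", path = <n_frames x 2 cumulative µm matrix>)`.
#' @param synapse_centers Matrix of synapse centers (x, y) in µm, or NULL for
#'   purely extrasynaptic (free) diffusion.
#' @param synapse_sigma Gaussian width (µm) of the marker-image spots.
#' @param confinement_radius Radius (µm) of the reflecting disk that confines
#'   synaptic motion around the synapse center.
#' @param deterministic_dwell If TRUE, every visit lasts exactly
#'   `round(dwell / frame_interval)` frames (alternating, starting
#'   extrasynaptic) instead of an exponential draw — used for exact kinetics
#'   fixtures.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(seed,
                       frame_interval = 0.05,
                       n_frames = 200,
                       pixel_size = 0.08,
                       field_size = c(20, 20),
                       D_syn = 0.002,
                       D_extra = 0.0037,
                       dwell_syn = 2,
                       dwell_extra = 1.5,
                       loc_noise_sigma = 0.007,
                       p_missed = 0,
                       drift = list(mode = "none"),
                       synapse_centers = NULL,
                       synapse_sigma = 0.24,
                       confinement_radius = 0.2,
                       deterministic_dwell = FALSE) {
  if (missing(seed) || !is.numeric(seed) || length(seed) != 1 || is.na(seed)) {
    abort("sim_config() requires an explicit integer seed")
  }
  if (frame_interval <= 0) abort("frame_interval must be > 0")
  if (n_frames < 1) abort("n_frames must be >= 1")
  if (pixel_size <= 0) abort("pixel_size must be > 0")
  if (D_syn < 0 || D_extra < 0) abort("diffusion coefficients must be >= 0")
  if (dwell_syn <= 0 || dwell_extra <= 0) abort("dwell times must be > 0")
  if (loc_noise_sigma < 0) abort("loc_noise_sigma must be >= 0")
  if (p_missed < 0 || p_missed >= 1) abort("p_missed must be in [0, 1)")
  if (confinement_radius <= 0) abort("confinement_radius must be > 0")
  if (!is.null(synapse_centers)) {
    synapse_centers <- matrix(as.numeric(synapse_centers), ncol = 2)
    if (any(synapse_centers[, 1] < 0 | synapse_centers[, 1] > field_size[1] |
            synapse_centers[, 2] < 0 | synapse_centers[, 2] > field_size[2])) {
      abort("synapse_centers must lie inside the field")
    }
  }
  structure(list(
    seed = as.integer(seed), frame_interval = frame_interval,
    n_frames = as.integer(n_frames), pixel_size = pixel_size,
    field_size = field_size, D_syn = D_syn, D_extra = D_extra,
    dwell_syn = dwell_syn, dwell_extra = dwell_extra,
    loc_noise_sigma = loc_noise_sigma, p_missed = p_missed, drift = drift,
    synapse_centers = synapse_centers, synapse_sigma = synapse_sigma,
    confinement_radius = confinement_radius,
    deterministic_dwell = deterministic_dwell
  ), class = "sim_config")
}

set_sim_seed <- function(seed) {
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")
}

# Cumulative drift path (n_frames x 2, µm), anchored to zero at frame 0.
drift_path_matrix <- function(drift, n_frames) {
  f <- seq_len(n_frames) - 1
  path <- switch(drift$mode %||% "none",
    none = matrix(0, n_frames, 2),
    linear = cbind(f * drift$rate[1], f * drift$rate[2]),
    sinusoidal = {
      ph <- drift$phase %||% (pi / 2)
      cbind(drift$amplitude * sin(2 * pi * f / drift$period),
            drift$amplitude * sin(2 * pi * f / drift$period + ph))
    },
    path = {
      stopifnot(nrow(drift$path) == n_frames)
      as.matrix(drift$path)
    },
    abort("unknown drift mode")
  )
  sweep(path, 2, path[1, ])
}

# Per-frame state labels ("S"/"E") from alternating dwells.
sim_state_sequence <- function(config) {
  n <- config$n_frames; dt <- config$frame_interval
  if (is.null(config$synapse_centers)) return(rep("E", n))
  if (config$deterministic_dwell) {
    states <- character(0); s <- "E"
    while (length(states) < n) {
      k <- round((if (s == "S") config$dwell_syn else config$dwell_extra) / dt)
      states <- c(states, rep(s, max(1, k)))
      s <- if (s == "S") "E" else "S"
    }
    return(states[seq_len(n)])
  }
  p_syn <- config$dwell_syn / (config$dwell_syn + config$dwell_extra)
  s <- if (runif(1) < p_syn) "S" else "E"
  t_end <- rexp(1, 1 / (if (s == "S") config$dwell_syn else config$dwell_extra))
  states <- character(n)
  for (f in seq_len(n)) {
    t <- (f - 1) * dt
    while (t >= t_end) {
      s <- if (s == "S") "E" else "S"
      t_end <- t_end + rexp(1, 1 / (if (s == "S") config$dwell_syn else config$dwell_extra))
    }
    states[f] <- s
  }
  states
}

# Visit list (state runs) of a label vector, 0-based frames.
runs_to_visits <- function(states, dt) {
  r <- rle(states)
  end <- cumsum(r$lengths) - 1L
  start <- end - r$lengths + 1L
  tibble::tibble(state = r$values, start_frame = start, end_frame = end,
                 n_frames = r$lengths, duration_s = r$lengths * dt)
}

#' Simulate tracked receptor trajectories
#'
#' Generates 2D Brownian trajectories with optional two-state
#' synaptic/extrasynaptic switching. Per-axis steps are drawn from
#' Normal(0, sqrt(2 D dt)); inside a synaptic visit the walk is radially
#' reflected at the confinement radius around the particle's synapse center.
#' Cumulative lateral drift is added to the true positions, localization
#' noise is added independently per frame (after drift, so fixed-probe runs
#' mimic immobile-probe calibration experiments), and frames are dropped
#' independently with probability `p_missed`.
#'
#' @param config A [sim_config()].
#' @param n_tracks Number of trajectories.
#' @return A list with `trajectories` (tibble: track_id, frame, t_s, x_um,
#'   y_um — observed frames only) and `ground_truth` (list with `states`
#'   per-frame truth, `visits`, `drift` and the config).
#' @export
simulate_trajectories <- function(config, n_tracks) {
  stopifnot(inherits(config, "sim_config"), n_tracks >= 1)
  set_sim_seed(config$seed)
  n <- config$n_frames; dt <- config$frame_interval
  drift <- drift_path_matrix(config$drift, n)
  centers <- config$synapse_centers
  R <- config$confinement_radius

  truth_list <- vector("list", n_tracks)
  obs_list <- vector("list", n_tracks)
  for (tr in seq_len(n_tracks)) {
    states <- sim_state_sequence(config)
    # starting point: synaptic tracks start at their synapse, free ones anywhere
    if (!is.null(centers)) {
      home <- ((tr - 1) %% nrow(centers)) + 1
      if (states[1] == "S") {
        start <- centers[home, ] + runif(2, -R / 2, R / 2)
      } else {
        start <- runif(2, 0, config$field_size)
      }
    } else {
      home <- NA_integer_
      start <- runif(2, 0, config$field_size)
    }
    x <- numeric(n); y <- numeric(n)
    x[1] <- start[1]; y[1] <- start[2]
    for (f in seq_len(n)[-1]) {
      sdd <- sqrt(2 * (if (states[f] == "S") config$D_syn else config$D_extra) * dt)
      x[f] <- x[f - 1] + rnorm(1, 0, sdd)
      y[f] <- y[f - 1] + rnorm(1, 0, sdd)
      if (states[f] == "S") {
        if (states[f - 1] != "S") {
          # entering a synapse: re-anchor to the nearest center
          d2 <- (centers[, 1] - x[f])^2 + (centers[, 2] - y[f])^2
          home <- which.min(d2)
        }
        dx <- x[f] - centers[home, 1]; dy <- y[f] - centers[home, 2]
        r <- sqrt(dx^2 + dy^2)
        if (r > R) {
          rr <- max(2 * R - r, 0.01 * R)   # radial reflection at the boundary
          x[f] <- centers[home, 1] + dx / r * rr
          y[f] <- centers[home, 2] + dy / r * rr
        }
      }
    }
    noise <- matrix(rnorm(2 * n, 0, config$loc_noise_sigma), n, 2)
    xo <- x + drift[, 1] + noise[, 1]
    yo <- y + drift[, 2] + noise[, 2]
    observed <- runif(n) >= config$p_missed
    truth_list[[tr]] <- tibble::tibble(
      track_id = tr, frame = seq_len(n) - 1L, state = states,
      x_true = x, y_true = y, observed = observed
    )
    obs_list[[tr]] <- tibble::tibble(
      track_id = tr, frame = (seq_len(n) - 1L)[observed],
      t_s = ((seq_len(n) - 1L) * dt)[observed],
      x_um = xo[observed], y_um = yo[observed]
    )
  }
  truth <- dplyr::bind_rows(truth_list)
  traj <- dplyr::bind_rows(obs_list)
  traj <- dplyr::filter(dplyr::group_by(traj, .data$track_id), dplyr::n() >= 2)
  traj <- dplyr::ungroup(traj)
  visits <- dplyr::group_modify(dplyr::group_by(truth, .data$track_id),
                                ~ runs_to_visits(.x$state, dt))
  list(
    trajectories = traj,
    ground_truth = list(states = truth, visits = dplyr::ungroup(visits),
                        drift = drift, config = config)
  )
}

#' Simulate a synaptic-marker image
#'
#' Renders the synapse centers of a configuration as isotropic Gaussian spots
#' (evaluated at pixel centers) over a constant background, optionally with
#' Poisson shot noise.
#'
#' @param config A [sim_config()] with `synapse_centers` (NULL gives a flat
#'   background image).
#' @param amplitude Peak amplitude of each spot (a.u.).
#' @param background Constant background level (a.u.).
#' @param poisson_noise If TRUE, pixel values are Poisson draws with the
#'   noiseless image as mean.
#' @return A numeric matrix (rows = y, columns = x) with attribute
#'   `pixel_size`; pixel (i, j) is centred at ((j - 0.5) px, (i - 0.5) px).
#' @export
simulate_marker_image <- function(config, amplitude = 1000, background = 100,
                                  poisson_noise = FALSE) {
  stopifnot(inherits(config, "sim_config"))
  px <- config$pixel_size
  nx <- ceiling(config$field_size[1] / px)
  ny <- ceiling(config$field_size[2] / px)
  xc <- (seq_len(nx) - 0.5) * px
  yc <- (seq_len(ny) - 0.5) * px
  img <- matrix(background, nrow = ny, ncol = nx)
  if (!is.null(config$synapse_centers)) {
    s2 <- config$synapse_sigma^2
    for (k in seq_len(nrow(config$synapse_centers))) {
      gx <- exp(-(xc - config$synapse_centers[k, 1])^2 / (2 * s2))
      gy <- exp(-(yc - config$synapse_centers[k, 2])^2 / (2 * s2))
      img <- img + amplitude * outer(gy, gx)
    }
  }
  if (poisson_noise) {
    set_sim_seed(config$seed + 1L)
    img <- matrix(rpois(length(img), img), nrow = ny, ncol = nx)
  }
  attr(img, "pixel_size") <- px
  img
}

#' Single-species FCS autocorrelation model
#'
#' `G(t) = 1 + (1/N) (1 + t/tau_D)^-1 (1 + S^-2 t/tau_D)^-1/2`, the
#' fluctuation autocorrelation of one freely diffusing species in a 3D
#' Gaussian focal volume with structure parameter S.
#'
#' @param t Lag times in s.
#' @param N Mean number of particles in the focal volume.
#' @param tau_D Mean transit (diffusion) time in s.
#' @param S Structure parameter (axial/lateral radius ratio).
#' @return G(t).
#' @export
fcs_model <- function(t, N, tau_D, S) {
  1 + (1 / N) * (1 + t / tau_D)^-1 * (1 + t / (tau_D * S^2))^-0.5
}

#' Simulate a noisy FCS autocorrelation curve
#'
#' @inheritParams fcs_model
#' @param lags Lag times in s.
#' @param noise_sd SD of i.i.d. Gaussian noise added to G.
#' @param seed Optional RNG seed.
#' @return Tibble with `lag_s`, `G`.
#' @export
simulate_fcs_curve <- function(N, tau_D, S, lags, noise_sd = 0, seed = NULL) {
  stopifnot(N > 0, tau_D > 0, S > 0, noise_sd >= 0)
  if (!is.null(seed)) set_sim_seed(seed)
  g <- fcs_model(lags, N, tau_D, S)
  if (noise_sd > 0) g <- g + rnorm(length(lags), 0, noise_sd)
  tibble::tibble(lag_s = lags, G = g)
}

#' Simulate Hill concentration-response data
#'
#' Responses follow `I = Imax / (1 + (EC50/conc)^h)` plus optional Gaussian
#' noise.
#'
#' @param Imax Maximal response (pA).
#' @param EC50 Half-maximal concentration (µM).
#' @param h Hill coefficient.
#' @param concentrations Agonist concentrations (µM).
#' @param noise_sd SD of additive Gaussian noise (pA).
#' @param seed Optional RNG seed.
#' @return Tibble with `conc_uM`, `I_pA`.
#' @export
simulate_dose_response <- function(Imax, EC50, h, concentrations,
                                   noise_sd = 0, seed = NULL) {
  stopifnot(Imax > 0, EC50 > 0, h > 0, all(concentrations > 0), noise_sd >= 0)
  if (!is.null(seed)) set_sim_seed(seed)
  i <- hill_model(concentrations, Imax, EC50, h)
  if (noise_sd > 0) i <- i + rnorm(length(i), 0, noise_sd)
  tibble::tibble(conc_uM = concentrations, I_pA = i)
}

#' Simulate a biexponential desensitization decay
#'
#' `I(t) = A_fast exp(-t/tau_fast) + A_slow exp(-t/tau_slow)` plus optional
#' Gaussian noise.
#'
#' @param tau_fast,tau_slow Time constants (ms).
#' @param A_fast,A_slow Component amplitudes (pA); may be zero.
#' @param times Sample times (ms).
#' @param noise_sd SD of additive Gaussian noise (pA).
#' @param seed Optional RNG seed.
#' @return Tibble with `t_ms`, `I_pA`.
#' @export
simulate_desens_trace <- function(tau_fast, A_fast, tau_slow, A_slow, times,
                                  noise_sd = 0, seed = NULL) {
  stopifnot(tau_fast > 0, tau_slow > 0, A_fast >= 0, A_slow >= 0, noise_sd >= 0)
  if (!is.null(seed)) set_sim_seed(seed)
  i <- A_fast * exp(-times / tau_fast) + A_slow * exp(-times / tau_slow)
  if (noise_sd > 0) i <- i + rnorm(length(i), 0, noise_sd)
  tibble::tibble(t_ms = times, I_pA = i)
}

#' Simulate repeated localizations of a fixed probe
#'
#' An immobile emitter localized with isotropic per-axis Gaussian noise —
#' the fixed-probe localization-error calibration experiment.
#'
#' @param sigma_um Per-axis localization SD in µm.
#' @param n_localizations Number of frames.
#' @param seed RNG seed.
#' @param center True position c(x, y) in µm.
#' @param frame_interval Frame interval in s.
#' @return Trajectory tibble (one track).
#' @export
simulate_fixed_probe <- function(sigma_um, n_localizations, seed,
                                 center = c(5, 5), frame_interval = 0.05) {
  stopifnot(sigma_um >= 0, n_localizations >= 1)
  set_sim_seed(seed)
  f <- seq_len(n_localizations) - 1L
  tibble::tibble(
    track_id = 1L, frame = f, t_s = f * frame_interval,
    x_um = center[1] + rnorm(n_localizations, 0, sigma_um),
    y_um = center[2] + rnorm(n_localizations, 0, sigma_um)
  )
}

#' Deterministic two-state kinetics fixture
#'
#' Builds trajectories with an exactly prescribed visit schedule (alternating
#' extrasynaptic/synaptic, starting and ending extrasynaptic) together with a
#' matching circular synaptic region, for exact tests of visit segmentation,
#' residence time and exchange rate. Synaptic frames sit at the region
#' center, extrasynaptic frames at a point well outside; optional jitter
#' stays far below the region radius so the schedule is never disturbed.
#'
#' @param n_tracks Number of trajectories.
#' @param syn_frames Length of every synaptic visit, in frames.
#' @param extra_frames Length of every extrasynaptic visit, in frames.
#' @param n_transitions Number of state transitions per trajectory (even).
#' @param frame_interval Frame interval in s.
#' @param region_radius Radius (µm) of the circular synaptic region.
#' @param center Region center (µm).
#' @param extra_offset Distance (µm) of extrasynaptic frames from the center.
#' @param jitter_um Optional per-axis jitter SD (µm); requires `seed`.
#' @param seed RNG seed used when `jitter_um > 0`.
#' @return List with `trajectories` and a one-row `regions` table.
#' @export
simulate_state_fixture <- function(n_tracks, syn_frames, extra_frames,
                                   n_transitions, frame_interval,
                                   region_radius = 0.3, center = c(5, 5),
                                   extra_offset = 1.5, jitter_um = 0,
                                   seed = NULL) {
  stopifnot(n_transitions %% 2 == 0, syn_frames >= 1, extra_frames >= 1)
  n_syn <- n_transitions / 2
  states <- rep("E", extra_frames)
  for (k in seq_len(n_syn)) {
    states <- c(states, rep("S", syn_frames), rep("E", extra_frames))
  }
  n <- length(states)
  if (jitter_um > 0) {
    if (is.null(seed)) abort("jitter_um > 0 requires a seed")
    set_sim_seed(seed)
  }
  mk <- function(tr) {
    x <- ifelse(states == "S", center[1], center[1] + extra_offset)
    y <- rep(center[2], n)
    if (jitter_um > 0) {
      x <- x + rnorm(n, 0, jitter_um)
      y <- y + rnorm(n, 0, jitter_um)
    }
    tibble::tibble(track_id = tr, frame = seq_len(n) - 1L,
                   t_s = (seq_len(n) - 1L) * frame_interval, x_um = x, y_um = y)
  }
  traj <- dplyr::bind_rows(lapply(seq_len(n_tracks), mk))
  poly <- disk_polygon(center[1], center[2], region_radius, n = 128)
  regions <- tibble::tibble(
    region_id = 1L, x_um = center[1], y_um = center[2],
    area_um2 = polygon_area(poly), polygon = list(poly)
  )
  list(trajectories = traj, regions = regions,
       states = tibble::tibble(frame = seq_len(n) - 1L, state = states))
}
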