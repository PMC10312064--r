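test_that("null ensembles give near-zero drift and zero paths are identities", {
  cfg <- sim_config(seed = 31, n_frames = 60, D_extra = 0,
                    loc_noise_sigma = 0.005, field_size = c(30, 30))
  sim <- simulate_trajectories(cfg, 50)
  dp <- estimate_drift(sim$trajectories)
  inc <- pmax(abs(diff(dp$dx_um)), abs(diff(dp$dy_um)))
  # per-increment error bound ~ 3 * sigma_step / sqrt(n); sigma_step = sigma*sqrt(2)
  expect_lt(max(inc), 3 * 0.005 * sqrt(2) * 1.3 / sqrt(50))
  zero <- dp
  zero$dx_um <- 0; zero$dy_um <- 0
  expect_equal(apply_drift_correction(sim$trajectories, zero),
               sim$trajectories)
})

test_that("linear drift is recovered within 10% and correction restores truth", {
  cfg <- sim_config(seed = 32, n_frames = 150, D_extra = 0.0037,
                    loc_noise_sigma = 0.007, field_size = c(40, 40),
                    drift = list(mode = "linear", rate = c(0.005, 0.003)))
  sim <- simulate_trajectories(cfg, 200)
  dp <- estimate_drift(sim$trajectories)
  true_last <- c(149 * 0.005, 149 * 0.003)
  expect_lt(abs(dp$dx_um[150] - true_last[1]) / true_last[1], 0.10)
  expect_lt(abs(dp$dy_um[150] - true_last[2]) / true_last[2], 0.10)
  # correcting with the true path restores true positions up to noise
  corr <- apply_drift_correction(
    sim$trajectories,
    tibble::tibble(frame = 0:149,
                   dx_um = sim$ground_truth$drift[, 1],
                   dy_um = sim$ground_truth$drift[, 2]))
  truth <- sim$ground_truth$states
  j <- dplyr::inner_join(corr, truth, by = c("track_id", "frame"))
  expect_lt(max(abs(j$x_um - j$x_true)), 5 * 0.007)
  # re-estimating drift after correction leaves only estimator noise
  dp2 <- estimate_drift(apply_drift_correction(sim$trajectories, dp))
  expect_lt(max(abs(c(dp2$dx_um, dp2$dy_um))), 0.03)
})

test_that("a sinusoidal drift path is recovered with sub-10 nm RMSE", {
  cfg <- sim_config(seed = 33, n_frames = 200, D_extra = 0.001,
                    loc_noise_sigma = 0.005, field_size = c(60, 60),
                    drift = list(mode = "sinusoidal", amplitude = 0.05,
                                 period = 200))
  sim <- simulate_trajectories(cfg, 500)
  dp <- estimate_drift(sim$trajectories, stat = "mean")
  truth <- sim$ground_truth$drift
  rmse <- sqrt(mean((dp$dx_um - truth[, 1])^2 + (dp$dy_um - truth[, 2])^2))
  expect_lt(rmse, 0.010)
})

test_that("median increments ignore a minority of stationary outlier tracks", {
  moving <- dplyr::bind_rows(lapply(1:7, function(id) {
    traj_at(1 + 0.01 * (0:20), 2, track_id = id)
  }))
  still <- dplyr::bind_rows(lapply(8:10, function(id) {
    traj_at(rep(5, 21), 5, track_id = id)
  }))
  dp <- estimate_drift(dplyr::bind_rows(moving, still), min_tracks = 1)
  expect_equal(diff(dp$dx_um), rep(0.01, 20), tolerance = 1e-12)
  expect_equal(dp$dy_um, rep(0, 21))
})

test_that("under-supported frame pairs are interpolated or fail the field", {
  base <- dplyr::bind_rows(lapply(1:12, function(id) {
    traj_at(1 + 0.002 * (0:30), 2, track_id = id)
  }))
  # remove all but 2 tracks on frames 10-12 -> those increments interpolate
  sparse <- base[!(base$frame %in% 10:12 & base$track_id > 2), ]
  dp <- estimate_drift(sparse, min_tracks = 10)
  expect_true(any(dp$interpolated))
  expect_equal(dp$dx_um[31], 0.002 * 30, tolerance = 1e-9)
  # too many unsupported pairs -> the field is excluded
  few <- base[base$track_id <= 3, ]
  expect_error(estimate_drift(few, min_tracks = 10), "drift estimation failed")
})

test_that("fixed-probe localization spread shrinks after drift correction", {
  cfg <- sim_config(seed = 34, n_frames = 120, D_extra = 0,
                    loc_noise_sigma = 0.006, field_size = c(30, 30),
                    drift = list(mode = "linear", rate = c(0.002, -0.001)))
  sim <- simulate_trajectories(cfg, 40)
  pooled_sd <- function(d) {
    s <- dplyr::summarise(dplyr::group_by(d, track_id),
                          v = (var(x_um) + var(y_um)) / 2)
    sqrt(mean(s$v))
  }
  pre <- pooled_sd(sim$trajectories)
  post <- pooled_sd(apply_drift_correction(sim$trajectories,
                                           estimate_drift(sim$trajectories)))
  expect_lt(post, pre)
  expect_equal(post, 0.006, tolerance = 0.15)
})
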