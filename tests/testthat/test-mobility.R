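test_that("MSD closed forms: constant, ballistic, and gap handling", {
  const <- traj_at(rep(1, 20), 2)
  m <- compute_msd(const)
  expect_true(all(m$msd_um2 == 0))

  s <- 0.03
  ball <- traj_at(s * (0:29), 1)
  mb <- compute_msd(ball)
  expect_equal(mb$msd_um2, (mb$lag_frames * s)^2, tolerance = 1e-12)

  # a gap contributes pairs at the true frame difference
  gap <- traj_at(s * c(0:9, 12:19), 1)
  gap$frame <- c(0:9, 12:19)
  gap$t_s <- gap$frame * 0.05
  gap$x_um <- s * gap$frame
  mg <- compute_msd(gap)
  expect_equal(mg$msd_um2, (mg$lag_frames * s)^2, tolerance = 1e-12)
  expect_false(any(mg$n_pairs == 0))
  expect_warning(compute_msd(traj_at(rep(1, 3), 1)), "excluding")
})

test_that("the first-five-lag fit is exact on analytic lines", {
  lag_s <- (1:8) * 0.05
  msd <- tibble::tibble(track_id = 1L, lag_frames = 1:8, lag_s = lag_s,
                        msd_um2 = 4 * 0.01 * lag_s, n_pairs = 100L)
  est <- fit_diffusion(msd)
  expect_equal(est$D_um2_s, 0.01, tolerance = 1e-12)
  expect_equal(est$intercept_um2, 0, tolerance = 1e-12)
  msd$msd_um2 <- 4 * 0.01 * lag_s + 0.002
  est2 <- fit_diffusion(msd)
  expect_equal(est2$D_um2_s, 0.01, tolerance = 1e-12)
  expect_equal(est2$intercept_um2, 0.002, tolerance = 1e-12)
  # too few lags -> excluded
  expect_equal(nrow(fit_diffusion(msd[1:4, ])), 0)
})

test_that("localization noise inflates the intercept, not the slope", {
  sigma <- 0.02
  cfg <- sim_config(seed = 51, n_frames = 200, D_extra = 0.01,
                    loc_noise_sigma = sigma, field_size = c(60, 60))
  sim <- simulate_trajectories(cfg, 300)
  msd <- compute_msd(sim$trajectories, max_lag = 5)
  est <- fit_diffusion(msd)
  expect_lt(abs(median(est$D_um2_s) - 0.01) / 0.01, 0.05)
  expect_equal(median(est$intercept_um2), 4 * sigma^2, tolerance = 0.25)
  # ensemble MSD at each lag matches 4 D t + 4 sigma^2 within 3 SE
  pop <- population_msd(msd)
  per_lag <- dplyr::summarise(
    dplyr::group_by(msd, lag_frames),
    se = sd(msd_um2) / sqrt(dplyr::n()))
  expected <- 4 * 0.01 * pop$lag_s + 4 * sigma^2
  expect_true(all(abs(pop$msd_um2 - expected) < 3 * per_lag$se))
})

test_that("mean displacement follows closed forms", {
  expect_equal(mean_displacement(traj_at(rep(1, 10), 1))$mean_disp_um, 0)
  d <- mean_displacement(traj_at(0.02 * (0:19), 1), frame_interval = 0.05)
  expect_equal(d$mean_disp_um, 0.02)
  expect_equal(d$mean_disp_um_s, 0.4)
  # pure localization noise: E|step| = sigma * sqrt(pi)
  sigma <- 0.01
  fp <- simulate_fixed_probe(sigma, 20000, seed = 52)
  md <- mean_displacement(fp)
  expect_equal(md$mean_disp_um, sigma * sqrt(pi), tolerance = 0.02)
})

test_that("confined motion bends the population MSD below the free line", {
  cfg <- sim_config(seed = 53, n_frames = 300, D_syn = 0.05,
                    dwell_syn = 1e6, dwell_extra = 0.01,
                    loc_noise_sigma = 0, field_size = c(10, 10),
                    synapse_centers = matrix(c(5, 5), 1),
                    confinement_radius = 0.2)
  # force all-synaptic start by seeding tracks at the synapse
  sim <- simulate_trajectories(cfg, 50)
  msd <- compute_msd(sim$trajectories, max_lag = 50)
  pop <- population_msd(msd)
  slope1 <- pop$msd_um2[pop$lag_frames == 1] / pop$lag_s[pop$lag_frames == 1]
  # at long lags the confined MSD saturates well below the initial-slope line
  long <- pop[pop$lag_frames == 50, ]
  expect_lt(long$msd_um2, 0.5 * slope1 * long$lag_s)
  expect_lt(long$msd_um2, 4 * 0.2^2)     # bounded by the confinement disk
})

test_that("D-versus-distance profiles rank confined below free pools", {
  dk <- disk_region(3, 3, 0.3)
  set.seed(54)
  slow <- dplyr::bind_rows(lapply(1:15, function(id) {
    traj_at(3 + cumsum(rnorm(60, 0, sqrt(2 * 0.002 * 0.05))),
            3 + cumsum(rnorm(60, 0, sqrt(2 * 0.002 * 0.05))), track_id = id)
  }))
  fast <- dplyr::bind_rows(lapply(16:30, function(id) {
    traj_at(5 + cumsum(rnorm(60, 0, sqrt(2 * 0.05 * 0.05))),
            3 + cumsum(rnorm(60, 0, sqrt(2 * 0.05 * 0.05))), track_id = id)
  }))
  traj <- dplyr::bind_rows(slow, fast)
  est <- fit_diffusion(compute_msd(traj, max_lag = 5))
  prof <- profile_D_vs_distance(est, traj, dk, bin_width = 0.1)
  inner <- prof$mean_D_um2_s[prof$bin_center_um < 0.2]
  outer <- prof$mean_D_um2_s[prof$bin_center_um > 1]
  expect_gt(min(outer), max(inner))
  # single-bin trivial case: one pool collapses to the ensemble mean
  prof1 <- profile_D_vs_distance(est[est$track_id <= 15, ], slow, dk,
                                 bin_width = 10)
  expect_equal(nrow(prof1), 1)
  expect_equal(prof1$mean_D_um2_s,
               mean(est$D_um2_s[est$track_id <= 15]))
})

test_that("MSD is invariant to rigid motions of the trajectory", {
  set.seed(55)
  tr <- traj_at(cumsum(rnorm(40, 0, 0.05)), cumsum(rnorm(40, 0, 0.05)))
  th <- 0.7
  rot <- tr
  rot$x_um <- cos(th) * tr$x_um - sin(th) * tr$y_um + 3
  rot$y_um <- sin(th) * tr$x_um + cos(th) * tr$y_um - 1
  expect_equal(compute_msd(rot)$msd_um2, compute_msd(tr)$msd_um2,
               tolerance = 1e-10)
})
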