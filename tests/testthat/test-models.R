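fcs_lags <- exp(seq(log(1e-6), log(0.1), length.out = 80))

test_that("noiseless FCS curves are recovered to high precision", {
  cu <- simulate_fcs_curve(5, 1e-3, 5, fcs_lags)
  fit <- fit_fcs(cu)
  expect_true(fit$converged)
  expect_equal(fit$params$N, 5, tolerance = 1e-6)
  expect_equal(fit$params$tau_D_s, 1e-3, tolerance = 1e-6)
  expect_equal(fit$params$S, 5, tolerance = 1e-4)
  expect_lt(max(abs(fit$fitted - cu$G)) / max(cu$G), 1e-10)
  # amplitude identity of the fitted model
  expect_equal(fcs_model(0, fit$params$N, fit$params$tau_D_s, fit$params$S),
               1 + 1 / fit$params$N)
})

test_that("dye calibration inverts omega^2 = 4 D tau_D", {
  tau_dye <- 2e-5
  dye <- simulate_fcs_curve(2, tau_dye, 5, fcs_lags)
  cal <- calibrate_focal_volume(dye, D_dye = 427)  # Rhodamine B, µm²/s
  expect_equal(cal$omega_um, sqrt(4 * 427 * tau_dye), tolerance = 1e-4)
  # sample D and Stokes-Einstein radius from a second curve
  samp <- fit_fcs(simulate_fcs_curve(5, 4e-3, 5, fcs_lags))
  res <- fcs_diffusion(samp, cal$omega_um, temperature_K = 298.15)
  expect_equal(res$D_um2_s, cal$omega_um^2 / (4 * 4e-3), tolerance = 1e-4)
  # dimensional check: D = 1 µm²/s at 25 °C in water -> R_H ~ 245.4 nm
  expect_equal(stokes_einstein_radius(1), 245.38, tolerance = 1e-3)
  expect_lt(stokes_einstein_radius(10), stokes_einstein_radius(1))
})

hill_response <- function(fit, conc) {
  fit$params$Imax / (1 + (fit$params$EC50_uM / conc)^fit$params$h)
}

test_that("Hill fits recover noiseless parameters exactly", {
  conc <- c(0.3, 1, 3, 10, 30, 100, 300)
  dr <- simulate_dose_response(850, 5.3, 1.2, conc)
  fit <- fit_hill(dr)
  expect_equal(fit$params$Imax, 850, tolerance = 1e-6)
  expect_equal(fit$params$EC50_uM, 5.3, tolerance = 1e-6)
  expect_equal(fit$params$h, 1.2, tolerance = 1e-6)
  # half-maximal response at EC50
  expect_equal(hill_response(fit, 5.3), 850 / 2, tolerance = 1e-6)
})

test_that("Hill fits are scale-equivariant and beat a brute-force grid", {
  conc <- c(0.3, 1, 3, 10, 30, 100, 300)
  noisy <- simulate_dose_response(100, 5.3, 1.2, conc, noise_sd = 5,
                                  seed = 81)
  fit <- fit_hill(noisy)
  scaled <- noisy
  scaled$I_pA <- scaled$I_pA * 3
  fit3 <- fit_hill(scaled)
  expect_equal(fit3$params$Imax, 3 * fit$params$Imax, tolerance = 1e-4)
  expect_equal(fit3$params$EC50_uM, fit$params$EC50_uM, tolerance = 1e-4)
  expect_equal(fit3$params$h, fit$params$h, tolerance = 1e-4)
  # brute-force oracle: dense (EC50, h) grid with Imax profiled analytically
  rss_at <- function(ec, h) {
    g <- 1 / (1 + (ec / noisy$conc_uM)^h)
    A <- sum(noisy$I_pA * g) / sum(g^2)
    sum((noisy$I_pA - A * g)^2)
  }
  grid <- expand.grid(ec = exp(seq(log(1), log(30), length.out = 120)),
                      h = seq(0.5, 2.5, length.out = 120))
  grid$rss <- mapply(rss_at, grid$ec, grid$h)
  top <- grid[which.min(grid$rss), ]
  fit_rss <- sum((noisy$I_pA - fit$fitted)^2)
  expect_lte(fit_rss, top$rss + 1e-9)
  expect_equal(fit$params$EC50_uM, top$ec, tolerance = 0.05)
  expect_equal(fit$params$h, top$h, tolerance = 0.05)
})

test_that("weighted desensitization constant follows the amplitude-weighted mean", {
  expect_equal(weighted_tau(100, 0, 400, 2), 400)
  expect_equal(weighted_tau(100, 2, 400, 1), 200)
  expect_equal(weighted_tau(120, 1.5, 480, 1.5), 300)
  tr <- simulate_desens_trace(100, 2, 400, 1, seq(0, 2000, 5))
  fit <- fit_desens(tr)
  expect_equal(fit$params$tau_fast_ms, 100, tolerance = 1e-4)
  expect_equal(fit$params$tau_slow_ms, 400, tolerance = 1e-4)
  expect_equal(fit$params$tau_des_ms, 200, tolerance = 1e-4)
})

test_that("fixed-probe localization error estimators recover the noise level", {
  same <- traj_at(rep(1, 100), 1)
  le0 <- localization_error(same)
  expect_equal(le0$sigma_nm, 0)
  fp <- simulate_fixed_probe(0.00662, 1200, seed = 82)
  le <- localization_error(fp)
  expect_equal(le$sigma_nm, 6.62, tolerance = 0.03)
  expect_equal(le$sigma_gauss_nm, 6.62, tolerance = 0.35)
  # anisotropic noise pools as sqrt((sx^2 + sy^2) / 2)
  set.seed(83)
  an <- tibble::tibble(track_id = 1, frame = 1:5000, t_s = 0,
                       x_um = rnorm(5000, 0, 0.012),
                       y_um = rnorm(5000, 0, 0.006))
  lea <- localization_error(an)
  expect_equal(lea$sigma_nm, sqrt((12^2 + 6^2) / 2), tolerance = 0.03)
  expect_error(localization_error(traj_at(rep(1, 10), 1)), "at least")
})

test_that("tidy and glance expose fit parameters and quality", {
  fit <- fit_hill(simulate_dose_response(100, 5, 1, c(0.5, 2, 5, 20, 50)))
  td <- tidy(fit)
  expect_setequal(td$term, c("Imax", "EC50", "h"))
  gl <- glance(fit)
  expect_true(gl$converged)
  expect_lt(gl$rss, 1e-10)
})
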