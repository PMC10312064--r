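# Closed-form auxiliary models: single-species FCS autocorrelation with
# focal-volume calibration and Stokes-Einstein radius, Hill
# concentration-response, biexponential desensitization with weighted time
# constant, and the fixed-probe localization-error estimators.

new_model_fit <- function(class, params, data, fitted, converged, extra = list()) {
  structure(c(list(params = params, data = data, fitted = fitted,
                   converged = converged), extra),
            class = c(class, "synaptrack_fit"))
}

#' @export
print.synaptrack_fit <- function(x, ...) {
  cat("<", class(x)[1], ">\n", sep = "")
  print(x$params, ...)
  invisible(x)
}

param_table <- function(fit) {
  est <- coef(fit)
  se <- tryCatch(sqrt(diag(vcov(fit))), error = function(e) rep(NA_real_, length(est)))
  tibble::tibble(term = names(est), estimate = unname(est),
                 std.error = unname(se))
}

#' Fit the single-species FCS autocorrelation model
#'
#' Nonlinear least squares of [fcs_model()] for (N, tau_D, S). Starting
#' values come from the curve itself: N from the zero-lag amplitude
#' (G(0) = 1 + 1/N), tau_D from the lag at which the excess correlation has
#' halved.
#'
#' @param curve Tibble with `lag_s`, `G` (at least 10 lags spanning tau_D).
#' @return An `fcs_fit` with `params` (N, tau_D, S) and convergence flag.
#' @export
fit_fcs <- function(curve) {
  stopifnot(all(c("lag_s", "G") %in% names(curve)))
  if (nrow(curve) < 10) abort("FCS fit needs at least 10 lags")
  g0 <- max(curve$G)
  n0 <- max(1 / max(g0 - 1, 1e-6), 1e-3)
  half <- 1 + (g0 - 1) / 2
  t0 <- curve$lag_s[which.min(abs(curve$G - half))]
  t0 <- max(t0, min(curve$lag_s[curve$lag_s > 0]))
  fit <- minpack.lm::nlsLM(
    G ~ fcs_model(lag_s, N, tau_D, S), data = curve,
    start = list(N = n0, tau_D = t0, S = 5),
    lower = c(1e-6, 1e-9, 1e-3), upper = c(Inf, Inf, 1e3),
    control = minpack.lm::nls.lm.control(maxiter = 500)
  )
  p <- coef(fit)
  converged <- fit$convInfo$isConv &&
    all(p > c(2e-6, 2e-9, 2e-3)) && all(p[3] < 9e2)
  if (!converged) warn("FCS fit did not converge cleanly or hit a bound")
  new_model_fit("fcs_fit",
                tibble::tibble(N = p[["N"]], tau_D_s = p[["tau_D"]], S = p[["S"]]),
                curve, stats::fitted(fit), converged, list(nls = fit))
}

#' Calibrate the confocal focal volume with a reference dye
#'
#' Fits the dye's autocorrelation curve and inverts `omega^2 = 4 D tau_D`
#' using the dye's known diffusion coefficient, yielding the lateral focal
#' radius omega and the structure parameter S.
#'
#' @param dye_curve Tibble with `lag_s`, `G` measured on the calibration dye.
#' @param D_dye Known dye diffusion coefficient in µm²/s (e.g. Rhodamine B,
#'   427 µm²/s).
#' @return List with `omega_um`, `S`, and the underlying `fcs_fit`.
#' @export
calibrate_focal_volume <- function(dye_curve, D_dye) {
  stopifnot(D_dye > 0)
  fit <- fit_fcs(dye_curve)
  omega <- sqrt(4 * D_dye * fit$params$tau_D_s)
  list(omega_um = omega, S = fit$params$S, fit = fit)
}

#' Diffusion coefficient and hydrodynamic radius from an FCS fit
#'
#' Converts a transit time to a diffusion coefficient via
#' `D = omega^2 / (4 tau_D)` and to a hydrodynamic radius via the
#' Stokes-Einstein relation `R_H = k_B T / (6 pi eta D)`.
#'
#' @param fit An `fcs_fit`.
#' @param omega_um Calibrated lateral focal radius in µm.
#' @param temperature_K Absolute temperature (default 298.15 K).
#' @param viscosity_Pa_s Solvent viscosity (default 8.9e-4 Pa s, water at
#'   25 °C).
#' @return Tibble: D_um2_s, R_H_nm, omega_um, tau_D_s, temperature_K,
#'   viscosity_Pa_s.
#' @export
fcs_diffusion <- function(fit, omega_um, temperature_K = 298.15,
                          viscosity_Pa_s = 8.9e-4) {
  stopifnot(inherits(fit, "fcs_fit"), omega_um > 0)
  D <- omega_um^2 / (4 * fit$params$tau_D_s)
  tibble::tibble(
    D_um2_s = D,
    R_H_nm = stokes_einstein_radius(D, temperature_K, viscosity_Pa_s),
    omega_um = omega_um, tau_D_s = fit$params$tau_D_s,
    temperature_K = temperature_K, viscosity_Pa_s = viscosity_Pa_s
  )
}

#' Stokes-Einstein hydrodynamic radius
#'
#' `R_H = k_B T / (6 pi eta D)`.
#'
#' @param D_um2_s Diffusion coefficient in µm²/s.
#' @param temperature_K Absolute temperature in K.
#' @param viscosity_Pa_s Viscosity in Pa s.
#' @return Hydrodynamic radius in nm.
#' @export
stokes_einstein_radius <- function(D_um2_s, temperature_K = 298.15,
                                   viscosity_Pa_s = 8.9e-4) {
  stopifnot(all(D_um2_s > 0), temperature_K > 0, viscosity_Pa_s > 0)
  kB <- 1.380649e-23                     # J/K
  D_m2 <- D_um2_s * 1e-12
  r_m <- kB * temperature_K / (6 * pi * viscosity_Pa_s * D_m2)
  r_m * 1e9
}

hill_model <- function(conc, Imax, EC50, h) {
  Imax / (1 + (EC50 / conc)^h)
}

#' Fit the Hill concentration-response model
#'
#' Nonlinear least squares of `I = Imax / (1 + (EC50/conc)^h)` with EC50
#' initialized on a log-spaced grid across the concentration range and
#' bounded fits (h in (0, 10], EC50 within 0.01-100 times the data range).
#' Warns when the concentrations do not span the fitted EC50.
#'
#' @param data Tibble with `conc_uM`, `I_pA` (at least 4 concentrations).
#' @return A `hill_fit` with `params` (Imax, EC50, h).
#' @export
fit_hill <- function(data) {
  stopifnot(all(c("conc_uM", "I_pA") %in% names(data)))
  if (nrow(data) < 4) abort("Hill fit needs at least 4 concentrations")
  rng <- range(data$conc_uM)
  lower <- c(Imax = 1e-12, EC50 = rng[1] * 0.01, h = 1e-3)
  upper <- c(Imax = Inf, EC50 = rng[2] * 100, h = 10)
  grid <- exp(seq(log(rng[1]), log(rng[2]), length.out = 7))
  best <- NULL; best_rss <- Inf
  for (ec in grid) {
    f <- tryCatch(minpack.lm::nlsLM(
      I_pA ~ hill_model(conc_uM, Imax, EC50, h), data = data,
      start = list(Imax = max(data$I_pA), EC50 = ec, h = 1),
      lower = lower, upper = upper,
      control = minpack.lm::nls.lm.control(maxiter = 500)
    ), error = function(e) NULL)
    if (!is.null(f)) {
      rss <- sum(stats::resid(f)^2)
      if (rss < best_rss) { best <- f; best_rss <- rss }
    }
  }
  if (is.null(best)) abort("Hill fit failed for every starting value")
  p <- coef(best)
  if (p[["EC50"]] < rng[1] || p[["EC50"]] > rng[2]) {
    warn("fitted EC50 lies outside the measured concentration range (extrapolation)")
  }
  new_model_fit("hill_fit",
                tibble::tibble(Imax = p[["Imax"]], EC50_uM = p[["EC50"]],
                               h = p[["h"]]),
                data, stats::fitted(best), best$convInfo$isConv,
                list(nls = best))
}

#' Fit a biexponential desensitization decay
#'
#' `I(t) = A_fast exp(-t/tau_fast) + A_slow exp(-t/tau_slow)` fitted with
#' log-spaced time-constant initialization and non-negative amplitudes; the
#' weighted time constant is reported alongside the components.
#'
#' @param trace Tibble with `t_ms`, `I_pA`.
#' @return A `desens_fit` with `params` (tau_fast, A_fast, tau_slow, A_slow,
#'   tau_des).
#' @export
fit_desens <- function(trace) {
  stopifnot(all(c("t_ms", "I_pA") %in% names(trace)))
  span <- diff(range(trace$t_ms))
  i0 <- max(trace$I_pA)
  taus <- exp(seq(log(span / 100), log(span), length.out = 5))
  best <- NULL; best_rss <- Inf
  for (tf in taus) for (ts in taus) {
    if (ts <= tf) next
    f <- tryCatch(minpack.lm::nlsLM(
      I_pA ~ A_fast * exp(-t_ms / tau_fast) + A_slow * exp(-t_ms / tau_slow),
      data = trace,
      start = list(tau_fast = tf, A_fast = i0 / 2, tau_slow = ts,
                   A_slow = i0 / 2),
      lower = c(1e-6, 0, 1e-6, 0),
      control = minpack.lm::nls.lm.control(maxiter = 500)
    ), error = function(e) NULL)
    if (!is.null(f)) {
      rss <- sum(stats::resid(f)^2)
      if (rss < best_rss) { best <- f; best_rss <- rss }
    }
  }
  if (is.null(best)) abort("biexponential fit failed for every starting value")
  p <- as.list(coef(best))
  if (p$tau_fast > p$tau_slow) {        # enforce fast <= slow labelling
    p <- list(tau_fast = p$tau_slow, A_fast = p$A_slow,
              tau_slow = p$tau_fast, A_slow = p$A_fast)
  }
  params <- tibble::tibble(
    tau_fast_ms = p$tau_fast, A_fast = p$A_fast,
    tau_slow_ms = p$tau_slow, A_slow = p$A_slow,
    tau_des_ms = weighted_tau(p$tau_fast, p$A_fast, p$tau_slow, p$A_slow)
  )
  new_model_fit("desens_fit", params, trace, stats::fitted(best),
                best$convInfo$isConv, list(nls = best))
}

#' Weighted desensitization time constant
#'
#' `tau_des = (tau_fast A_fast + tau_slow A_slow) / (A_fast + A_slow)`.
#'
#' @param tau_fast,tau_slow Component time constants (ms).
#' @param A_fast,A_slow Component amplitudes.
#' @return Weighted time constant (ms).
#' @export
weighted_tau <- function(tau_fast, A_fast, tau_slow, A_slow) {
  stopifnot(A_fast + A_slow > 0)
  (tau_fast * A_fast + tau_slow * A_slow) / (A_fast + A_slow)
}

#' Localization error of a fixed probe
#'
#' Primary estimator: the pooled per-axis standard deviation of repeated
#' localizations about their mean position,
#' `sigma = sqrt((sum (x - mean x)^2 + sum (y - mean y)^2) / (2n - 2))`.
#' An alternative estimator fits a Gaussian to the histogram of distances
#' from the mean position (the convention sometimes used for immobile-probe
#' calibrations); both are reported.
#'
#' @param locs Localization tibble with `x_um`, `y_um` of one fixed
#'   (drift-corrected) probe.
#' @param min_localizations Minimum number of localizations (default 50).
#' @param bins Histogram bins for the Gaussian-on-distances estimator.
#' @return Tibble: sigma_nm (pooled per-axis SD), sigma_gauss_nm,
#'   n_localizations.
#' @export
localization_error <- function(locs, min_localizations = 50, bins = 30) {
  n <- nrow(locs)
  if (n < min_localizations) {
    abort(sprintf("need at least %d localizations of the fixed probe",
                  min_localizations))
  }
  dx <- locs$x_um - mean(locs$x_um)
  dy <- locs$y_um - mean(locs$y_um)
  pooled <- sqrt((sum(dx^2) + sum(dy^2)) / (2 * n - 2))
  r <- sqrt(dx^2 + dy^2)
  sig_g <- NA_real_
  if (max(r) > 0) {
    h <- graphics::hist(r, breaks = bins, plot = FALSE)
    hd <- tibble::tibble(mids = h$mids, counts = h$counts)
    f <- tryCatch(minpack.lm::nlsLM(
      counts ~ A * exp(-(mids - mu)^2 / (2 * sig^2)), data = hd,
      start = list(A = max(hd$counts), mu = mean(r), sig = sd(r)),
      lower = c(0, 0, 1e-9)
    ), error = function(e) NULL)
    if (!is.null(f)) sig_g <- abs(coef(f)[["sig"]])
  }
  tibble::tibble(sigma_nm = pooled * 1000, sigma_gauss_nm = sig_g * 1000,
                 n_localizations = n)
}
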