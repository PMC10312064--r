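# Build a trajectory whose frames follow an explicit S/E label string over a
# unit-disk region at the origin: S frames at the center, E frames outside.
labelled_traj <- function(labels, dt = 0.05, drop_frames = integer(0)) {
  n <- length(labels)
  x <- ifelse(labels == "S", 0, 2)
  d <- tibble::tibble(track_id = 1L, frame = 0:(n - 1),
                      t_s = (0:(n - 1)) * dt, x_um = x, y_um = 0)
  d[!d$frame %in% drop_frames, ]
}
disk0 <- disk_region(0, 0, 0.5)

test_that("visits shorter than three frames are merged into the adjoining state", {
  lab <- c(rep("S", 10), rep("E", 2), rep("S", 10))
  v <- segment_visits(labelled_traj(lab), disk0, frame_interval = 0.05)
  expect_equal(nrow(v), 1)
  expect_equal(v$state, "S")
  expect_equal(v$n_frames, 22)
  expect_equal(v$duration_s, 22 * 0.05)
  expect_false(v$qualifies)

  lab5 <- c(rep("S", 10), rep("E", 5), rep("S", 10))
  v5 <- segment_visits(labelled_traj(lab5), disk0, frame_interval = 0.05)
  expect_equal(nrow(v5), 3)
  expect_equal(v5$n_transitions[1], 2)
})

test_that("missing frames inherit agreeing neighbours or split between them", {
  lab <- c(rep("S", 10), rep("S", 3), rep("S", 10))
  v <- segment_visits(labelled_traj(lab, drop_frames = 10:12), disk0,
                      frame_interval = 0.05)
  expect_equal(nrow(v), 1)
  expect_equal(v$n_frames, 23)
  lab2 <- c(rep("S", 10), rep("S", 4), rep("E", 10))
  v2 <- segment_visits(labelled_traj(lab2, drop_frames = 10:13), disk0,
                       frame_interval = 0.05)
  expect_equal(nrow(v2), 2)
  expect_equal(v2$n_frames, c(12, 12))   # 4-frame gap split at the midpoint
})

test_that("residence time averages uncensored synaptic visits", {
  # E5 S20 E5 S60 E5 at 50 ms: 4 transitions; synaptic visits 1 s and 3 s
  lab <- c(rep("E", 5), rep("S", 20), rep("E", 5), rep("S", 60), rep("E", 5))
  v <- segment_visits(labelled_traj(lab), disk0, frame_interval = 0.05)
  expect_true(v$qualifies[1])
  expect_equal(unname(residence_time(v)), 2.0)
  # censored boundary visits are excluded: make the first visit synaptic
  lab2 <- c(rep("S", 100), rep("E", 5), rep("S", 20), rep("E", 5),
            rep("S", 60), rep("E", 5))
  v2 <- segment_visits(labelled_traj(lab2), disk0, frame_interval = 0.05)
  expect_equal(unname(residence_time(v2)), 2.0)
  expect_equal(unname(residence_time(v2, include_censored = TRUE)),
               mean(c(5, 1, 3)))
})

test_that("exchange rate is transitions per observed duration", {
  fx <- simulate_state_fixture(3, syn_frames = 60, extra_frames = 55,
                               n_transitions = 6, frame_interval = 0.05)
  v <- segment_visits(fx$trajectories, fx$regions, frame_interval = 0.05)
  r <- exchange_rate(v)
  expect_equal(unname(r), rep(6 / 20, 3))
  # consistency identity: rate * duration = transitions, exactly
  ks <- kinetics_summary(v)
  expect_equal(ks$exchange_hz * ks$duration_s, ks$n_transitions)
  # same labels at doubled frame interval halve the rate
  v2 <- segment_visits(fx$trajectories, fx$regions, frame_interval = 0.10)
  expect_equal(unname(exchange_rate(v2)), rep(6 / 40, 3))
  # trajectories without transitions do not qualify
  lone <- segment_visits(labelled_traj(rep("S", 30)), disk0,
                         frame_interval = 0.05)
  expect_length(exchange_rate(lone), 0)
})

test_that("the deterministic fixture yields exact population medians", {
  fx <- simulate_state_fixture(50, syn_frames = 227, extra_frames = 100,
                               n_transitions = 6, frame_interval = 0.01)
  v <- segment_visits(fx$trajectories, fx$regions, frame_interval = 0.01)
  expect_identical(median(residence_time(v)), 227 * 0.01)
})

test_that("visit segmentation is stable under time reversal", {
  # isolated short excursions (each flanked by long runs) merge identically
  # regardless of the direction of time
  lab <- c(rep("S", 5), rep("E", 1), rep("S", 4), rep("E", 6), rep("S", 2),
           rep("E", 7), rep("S", 6), rep("E", 2), rep("S", 9))
  tr <- labelled_traj(lab)
  rv <- tr
  rv$x_um <- rev(tr$x_um); rv$y_um <- rev(tr$y_um)
  a <- segment_visits(tr, disk0, frame_interval = 0.05)
  b <- segment_visits(rv, disk0, frame_interval = 0.05)
  expect_equal(a$state, rev(b$state))
  expect_equal(a$n_frames, rev(b$n_frames))
})

test_that("stochastic two-state kinetics recover the mean synaptic dwell", {
  # exponential dwells with mu >> 3 frames; positions follow the true state
  # sequence so the check isolates segmentation/filtering bias (merging of
  # sub-3-frame excursions and exclusion of censored boundary visits)
  mu <- 2
  cfg <- sim_config(seed = 62, n_frames = 1500, frame_interval = 0.02,
                    dwell_syn = mu, dwell_extra = 2,
                    synapse_centers = matrix(c(5, 5), 1))
  sim <- simulate_trajectories(cfg, 120)
  truth <- sim$ground_truth$states
  traj <- tibble::tibble(
    track_id = truth$track_id, frame = truth$frame,
    t_s = truth$frame * 0.02,
    x_um = ifelse(truth$state == "S", 0, 2), y_um = 0
  )
  v <- segment_visits(traj, disk0, frame_interval = 0.02)
  res <- residence_time(v)
  expect_gt(length(res), 50)
  expect_lt(abs(mean(res) - mu) / mu, 0.10)
})

test_that("log summaries reject non-positive values and stabilize variance", {
  expect_error(log_summary(c(1, 0, 2)), "strictly positive")
  s <- log_summary(rep(3, 10))
  expect_equal(s$sd_log, 0)
  expect_equal(s$geo_mean, 3)
  set.seed(63)
  x <- exp(rnorm(100, mean = 1, sd = 0.5))
  ls <- log_summary(x)
  expect_equal(ls$geo_mean, exp(mean(log(x))))
  expect_gt(stats::shapiro.test(log(x))$p.value, 0.05)
})
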