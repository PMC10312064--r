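sq <- unit_square_region()

test_that("Method 1 applies the strict >50% rule to localizations", {
  all_in <- traj_at(rep(0.5, 10), 0.5)
  c1 <- classify_trajectories(all_in, sq, method = 1)
  expect_equal(c1$label, "synaptic")
  expect_equal(c1$frac_synaptic, 1)

  six_in <- traj_at(c(rep(0.5, 6), rep(2, 4)), 0.5)
  expect_equal(classify_trajectories(six_in, sq)$label, "synaptic")
  expect_equal(classify_trajectories(six_in, sq)$frac_synaptic, 0.6)

  five_in <- traj_at(c(rep(0.5, 5), rep(2, 5)), 0.5)
  expect_equal(classify_trajectories(five_in, sq)$label, "extrasynaptic")
})

test_that("Method 2's 120 nm perisynaptic buffer captures near-edge trajectories", {
  near <- traj_at(rep(1.1, 10), 0.5)       # 100 nm outside the right edge
  expect_equal(classify_trajectories(near, sq, method = 1)$label,
               "extrasynaptic")
  expect_equal(classify_trajectories(near, sq, method = 2)$label, "synaptic")
  far <- traj_at(rep(1.25, 10), 0.5)       # 250 nm outside
  expect_equal(classify_trajectories(far, sq, method = 2)$label,
               "extrasynaptic")
})

test_that("Method 3 uses a strict 550 nm mean-center-distance cutoff", {
  dk <- disk_region(0, 0, 0.2)
  at_center <- traj_at(rep(0, 10), 0)
  expect_equal(classify_trajectories(at_center, dk, method = 3)$label,
               "synaptic")
  at_550 <- traj_at(rep(0.55, 10), 0)  # exactly at the cutoff: not < 550 nm
  expect_equal(classify_trajectories(at_550, dk, method = 3)$label,
               "extrasynaptic")
  at_600 <- traj_at(rep(0.6, 10), 0)
  expect_equal(classify_trajectories(at_600, dk, method = 3)$label,
               "extrasynaptic")
  # centroid reading agrees on a symmetric trajectory
  sym <- traj_at(c(-0.2, 0.2), c(0, 0))
  m_mean <- classify_trajectories(sym, dk, method = 3)
  m_cent <- classify_trajectories(sym, dk, method = 3,
                                  method3_mode = "centroid")
  expect_equal(m_mean$label, "synaptic")
  expect_equal(m_cent$label, "synaptic")
})

test_that("methods nest: 1 within 2, and synaptic percentage orders 3 >= 2 >= 1", {
  # long dwells relative to the observation window give clearly synaptic or
  # clearly extrasynaptic tracks, the regime where the per-track ordering of
  # the three methods is well defined
  cfg <- sim_config(seed = 41, n_frames = 120, D_syn = 0.002,
                    D_extra = 0.05, dwell_syn = 100, dwell_extra = 100,
                    loc_noise_sigma = 0.005, field_size = c(10, 10),
                    synapse_centers = matrix(c(3, 3, 7, 7, 3, 7), 3,
                                             byrow = TRUE),
                    confinement_radius = 0.15)
  sim <- simulate_trajectories(cfg, 30)
  img <- simulate_marker_image(cfg)
  regions <- delineate_regions(img)
  cls <- lapply(1:3, function(m) {
    classify_trajectories(sim$trajectories, regions, method = m)
  })
  syn <- lapply(cls, function(d) d$track_id[d$label == "synaptic"])
  expect_true(all(syn[[1]] %in% syn[[2]]))
  expect_gte(length(syn[[3]]), length(syn[[2]]))
  expect_gte(length(syn[[2]]), length(syn[[1]]))
  # Method 1 agrees with the ground-truth majority state for >= 95% of tracks
  truth <- dplyr::summarise(
    dplyr::group_by(sim$ground_truth$states, track_id),
    true_label = ifelse(mean(state == "S") > 0.5, "synaptic", "extrasynaptic"))
  j <- dplyr::inner_join(cls[[1]], truth, by = "track_id")
  expect_gte(mean(j$label == j$true_label), 0.95)
})

test_that("classification is invariant to time reversal", {
  set.seed(5)
  tr <- traj_at(runif(20, 0, 2), runif(20, 0, 2))
  rev_tr <- tr
  rev_tr$x_um <- rev(tr$x_um); rev_tr$y_um <- rev(tr$y_um)
  for (m in 1:3) {
    a <- classify_trajectories(tr, sq, method = m)
    b <- classify_trajectories(rev_tr, sq, method = m)
    expect_equal(a$label, b$label)
    expect_equal(a$frac_synaptic, b$frac_synaptic)
  }
})

test_that("synaptic-fraction bins follow the left-open right-closed convention", {
  cls <- tibble::tibble(track_id = 1:5,
                        frac_synaptic = c(0, 0.2, 0.5, 0.81, 1))
  b <- bin_by_synaptic_fraction(cls, bin_edges = c(0, 20, 80, 100))
  expect_equal(as.character(b$frac_bin),
               c("0%", ">0-20%", ">20-80%", ">80-100%", ">80-100%"))
  # regular 25% intervals partition [0, 1]
  cls2 <- tibble::tibble(track_id = 1:101,
                         frac_synaptic = seq(0, 1, length.out = 101))
  b2 <- bin_by_synaptic_fraction(cls2)
  expect_true(all(!is.na(b2$frac_bin)))
})
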