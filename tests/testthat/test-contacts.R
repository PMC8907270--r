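test_that("mask decoding follows the episode conventions", {
  times <- seq(0, by = 2, length.out = 6)   # 2-min frames
  mask <- c(TRUE, TRUE, TRUE, FALSE, FALSE, TRUE)
  ep <- mask_episodes(mask, times, gap_tolerance = 0)
  expect_equal(nrow(ep), 2)
  expect_equal(ep$duration_min[1], 4)       # 3 frames spanning 4 min
  expect_equal(ep$duration_min[2], 2)       # single frame -> one interval
  ep2 <- mask_episodes(mask, times, gap_tolerance = 2)
  expect_equal(nrow(ep2), 1)
  expect_equal(ep2$start_min, 0)
  expect_equal(ep2$end_min, 10)
  # leading/trailing gaps are never bridged
  ep3 <- mask_episodes(c(FALSE, TRUE, TRUE, FALSE), 0:3, gap_tolerance = 5)
  expect_equal(nrow(ep3), 1)
  expect_equal(ep3$n_frames, 2)
})

test_that("a permanently touching orbit yields one full-length episode", {
  spec <- orbit_spec(R_mean = 100, R_sd = 0, v_theta_mean = 2,
                     v_theta_sd = 0, radial_noise_sd = 0,
                     angular_noise_sd = 0, reverse_turn_rate = 0,
                     duration = 300, n_cells = 1)
  tr <- generate_orbit_trajectories(spec, seed = 2)[[1]]
  ct <- detect_contacts(tr, mode = "distance", threshold_um = 120)
  expect_equal(nrow(ct), 1)
  expect_equal(ct$duration_min, 300)
  expect_true(ct$censored)
  # arclength = v_theta x duration for pure circular motion
  expect_equal(ct$arclength_um, 2 * 300, tolerance = 0.01)
})

test_that("distance mode requires a threshold without area columns", {
  tr <- list(normal = data.frame(time_min = 0:3, x_um = 0:3, y_um = 0),
             host = data.frame(time_min = 0:3, x_um = 0, y_um = 0))
  expect_error(detect_contacts(tr, mode = "distance"), "threshold_um")
  expect_error(detect_contacts(tr, mode = "bogus"))
})

test_that("gamma MLE recovers known laws", {
  d <- generate_contact_durations(3.17, 62.00, 1e4, seed = 7)
  f <- fit_gamma(d)
  expect_equal(f$alpha, 3.17, tolerance = 0.05)  # within 5%
  expect_equal(f$beta, 62.00, tolerance = 0.05)
  # fitted-law mean equals the sample mean within MLE tolerance
  expect_equal(f$mean, mean(d), tolerance = 0.01)
  # exponential sample: alpha ~ 1
  de <- generate_contact_durations(1, 80, 5e3, seed = 8)
  expect_equal(fit_gamma(de)$alpha, 1, tolerance = 0.08)
})

test_that("the reported gamma laws have the reported means", {
  # fitted experimental law: 4.22 x 69.75 = 294.3 ~ reported 294 min
  expect_equal(4.22 * 69.75, 294.3, tolerance = 1e-3)
  # CPM law: 3.17 x 62.00 = 196.5 ~ reported 196 min
  expect_equal(3.17 * 62.00, 196.5, tolerance = 1e-3)
})

test_that("degenerate duration inputs are rejected", {
  expect_error(fit_gamma(c(1, 2, 3)), "at least 5")
  expect_error(fit_gamma(c(1, 2, 3, -1, 5)), "positive")
  expect_error(fit_gamma(rep(7, 10)), "degenerate")
})

test_that("interface-mode detection finds the attached pair", {
  p <- cpm_params(E_sn = -20, V_target_sen_um2 = 3.4e4)
  run <- simulate_pair(p, n_mcs = 150, burn_in = 50, seed = 13,
                       record_contacts = TRUE)
  ct <- detect_contacts(run, mode = "interface")
  expect_gte(nrow(ct), 1)
  expect_equal(ct$normal_id[1], 2L)
  expect_equal(ct$sen_id[1], 1L)
  expect_true(all(ct$arclength_um >= 0))
})
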