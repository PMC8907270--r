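test_that("noise-free synthetic orbit reproduces circular kinematics exactly", {
  spec <- orbit_spec(R_mean = 100, R_sd = 0, v_theta_mean = 2,
                     v_theta_sd = 0, radial_noise_sd = 0,
                     angular_noise_sd = 0, reverse_turn_rate = 0,
                     duration = 200, n_cells = 1)
  tr <- generate_orbit_trajectories(spec, seed = 1)[[1]]
  pt <- unwrap_and_rectify(to_polar(tr$normal, tr$host))
  expect_close(pt$R_um, 100, 1e-9)
  sp <- angular_speed(pt)
  expect_close(abs(sp$omega), 0.02, 1e-9)           # omega = v/R
  vt <- tangential_speed(pt)
  expect_close(abs(vt$v_theta), 2, 1e-9)
})

test_that("trajectories have the requested frame structure", {
  spec <- orbit_spec(duration = 400, frame_interval = 1, n_cells = 3)
  trs <- generate_orbit_trajectories(spec, seed = 2)
  expect_length(trs, 3)
  expect_equal(nrow(trs[[1]]$normal), 401)
  expect_equal(trs[[1]]$host$x_um, rep(0, 401))
})

test_that("generator sample statistics converge to the cohort parameters", {
  spec <- orbit_spec(n_cells = 60)
  trs <- generate_orbit_trajectories(spec, seed = 3)
  R <- vapply(trs, function(x) attr(x, "R"), numeric(1))
  se <- spec$R_sd / sqrt(60)
  expect_lt(abs(mean(R) - 124.30), 3 * se + 0.5)  # slight truncation shift
  # larger cohort: both R and v within 3 se
  spec2 <- orbit_spec(n_cells = 1000)
  trs2 <- generate_orbit_trajectories(spec2, seed = 4)
  R2 <- vapply(trs2, function(x) attr(x, "R"), numeric(1))
  v2 <- vapply(trs2, function(x) attr(x, "v_theta"), numeric(1))
  expect_lt(abs(mean(R2) - spec2$R_mean), 3 * spec2$R_sd / sqrt(1000) + 0.5)
  expect_lt(abs(mean(v2) - spec2$v_theta_mean),
            3 * spec2$v_theta_sd / sqrt(1000) + 0.02)
  expect_true(all(R2 > 0))
})

test_that("generators are deterministic under a fixed seed", {
  spec <- orbit_spec(n_cells = 4, duration = 50)
  a <- generate_orbit_trajectories(spec, seed = 9)
  b <- generate_orbit_trajectories(spec, seed = 9)
  expect_identical(a[[2]]$normal, b[[2]]$normal)
  expect_identical(generate_contact_durations(3.17, 62, 10, seed = 1),
                   generate_contact_durations(3.17, 62, 10, seed = 1))
})

test_that("gamma duration sampler matches its law", {
  d <- generate_contact_durations(3.17, 62.00, 1e4, seed = 5)
  se <- sqrt(3.17) * 62 / sqrt(1e4)
  expect_lt(abs(mean(d) - 3.17 * 62.00), 3 * se)   # mean 196.54 min
  d1 <- generate_contact_durations(1, 100, 1e4, seed = 6)
  expect_equal(sd(d1) / mean(d1), 1, tolerance = 0.05)  # exponential cv
  expect_length(generate_contact_durations(2, 3, 0), 0)
  expect_error(generate_contact_durations(-1, 3, 5))
})
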