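test_that("polar decomposition handles fixed and moving hosts", {
  tr <- data.frame(time_min = 0:2, x_um = c(10, 0, -5), y_um = c(0, 10, 0))
  pt <- to_polar(tr, host = c(0, 0))
  expect_equal(pt$R_um, c(10, 10, 5))
  expect_equal(pt$theta_raw, c(0, pi / 2, pi))
  # translating both by a constant leaves the trace unchanged
  host <- data.frame(time_min = 0:2, x_um = rep(7, 3), y_um = rep(-3, 3))
  tr2 <- tr; tr2$x_um <- tr$x_um + 7; tr2$y_um <- tr$y_um - 3
  pt2 <- to_polar(tr2, host)
  expect_equal(pt2$R_um, pt$R_um)
  expect_equal(pt2$theta_raw, pt$theta_raw)
  expect_error(to_polar(data.frame(time_min = 0, x_um = 0, y_um = 0),
                        c(0, 0)), "coincident")
})

test_that("quarter-circle path spans pi/2 at constant radius", {
  tr <- circle_traj(R = 5, omega = pi / 2 / 100, n = 101)
  pt <- to_polar(tr)
  expect_close(pt$R_um, 5, 1e-9)
  expect_equal(max(pt$theta_raw) - min(pt$theta_raw), pi / 2,
               tolerance = 1e-9)
})

test_that("minimal-image wrapping restores periodic relative geometry", {
  # host at origin of a 600-um period; normal drifted one full period in x
  n <- data.frame(time_min = 0:1, x_um = c(50, 650), y_um = c(0, 0))
  h <- data.frame(time_min = 0:1, x_um = c(0, 0), y_um = c(0, 0))
  pt <- to_polar(n, h, period = c(600, 600))
  expect_equal(pt$R_um, c(50, 50))
})

test_that("unwrapping removes 2-pi jumps and rectification is idempotent", {
  tr <- circle_traj(R = 50, omega = 0.05, n = 300)  # crosses +-pi often
  pt <- unwrap_and_rectify(to_polar(tr))
  expect_true(all(abs(diff(pt$theta_unwrapped)) < pi / 2))
  # monotone input is unchanged by rectification
  expect_equal(pt$theta_rect, pt$theta_unwrapped, tolerance = 1e-12)
  twice <- unwrap_and_rectify(pt)
  expect_equal(twice$theta_rect, pt$theta_rect)
})

test_that("a mid-course chirality flip is rectified to the initial chirality", {
  n <- 400; flip_at <- 200; omega <- 0.03
  d <- c(rep(omega, flip_at), rep(-omega, n - flip_at))
  th <- cumsum(c(0, d))
  tr <- data.frame(time_min = 0:n, x_um = 80 * cos(th), y_um = 80 * sin(th))
  pt <- unwrap_and_rectify(to_polar(tr), window = 15)
  ref <- cumsum(c(0, rep(omega, n)))   # the no-flip orbit
  # agreement except within one window of the flip point
  err <- abs(diff(pt$theta_rect) - diff(ref))
  bad <- which(err > 1e-9)
  expect_true(all(abs(bad - flip_at) <= 15))
  sp <- angular_speed(pt)
  expect_equal(sp$omega_bar, omega, tolerance = 0.01)
})

test_that("angular and tangential speeds follow the reported arithmetic", {
  tr <- circle_traj(R = 124.30, omega = 1.79 / 124.30, n = 200)
  pt <- unwrap_and_rectify(to_polar(tr))
  sp <- angular_speed(pt)
  expect_equal(abs(sp$omega_bar), 0.0144, tolerance = 1e-3)  # A/R
  vt <- tangential_speed(pt)
  expect_equal(abs(vt$v_theta_bar), 1.79, tolerance = 1e-6)
  # chirality flip leaves |v_theta| unchanged
  trm <- circle_traj(R = 124.30, omega = 1.79 / 124.30, n = 200,
                     chirality = -1)
  vtm <- tangential_speed(unwrap_and_rectify(to_polar(trm)))
  expect_equal(abs(vtm$v_theta_bar), abs(vt$v_theta_bar))
  # stationary cell
  still <- data.frame(time_min = 0:10, x_um = rep(3, 11), y_um = rep(4, 11))
  ps <- unwrap_and_rectify(to_polar(still), window = 5)
  expect_equal(angular_speed(ps)$omega_bar, 0)
})

test_that("A/R fit recovers exact and generated cohorts", {
  R <- seq(60, 260, length.out = 10)
  exact <- data.frame(R_bar = R, omega_bar = 2 / R)
  f <- fit_A_over_R(exact)
  expect_equal(f$A, 2, tolerance = 1e-9)
  expect_lt(sum(residuals(f$fit)^2), 1e-18)
  expect_true(f$prefers_AR)
  # synthetic 60-cell cohort at the experimental parameters
  spec <- orbit_spec(n_cells = 60, duration = 400)
  trs <- generate_orbit_trajectories(spec, seed = 10)
  stats <- cohort_orbit_stats(trs)
  fc <- fit_A_over_R(stats)
  expect_true(fc$ci[1] <= 1.79 && 1.79 <= fc$ci[2] ||
                abs(fc$A - 1.79) < 0.15)
  # omega independent of R: the 1/R shape is not preferred
  withr::with_seed(1, {
    flat <- data.frame(R_bar = R, omega_bar = 0.01 + rnorm(10, 0, 1e-4))
  })
  expect_false(fit_A_over_R(flat)$prefers_AR)
  expect_error(fit_A_over_R(exact[1, , drop = FALSE]))
})

test_that("shape index has the textbook values", {
  expect_equal(shape_index(4, 8), 4)          # square of side 2
  expect_equal(shape_index(pi * 3^2, 2 * pi * 3), 2 * sqrt(pi))  # circle
  expect_equal(shape_index(c(1, 4), c(4, 8)), c(4, 4))
  expect_error(shape_index(0, 1))
})

test_that("uncalibrated tables are rejected rather than silently mixed", {
  expect_error(as_trajectory(data.frame(t = 0:2, x = 1:3, y = 1:3)),
               "uncalibrated")
  expect_error(as_trajectory(data.frame(time_min = c(0, 2, 1),
                                        x_um = 1:3, y_um = 1:3)),
               "increasing")
  expect_error(as_trajectory(data.frame(time_min = c(0, 1, 3),
                                        x_um = 1:3, y_um = 1:3)),
               "non-uniform")
})
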