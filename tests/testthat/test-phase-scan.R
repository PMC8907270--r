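fake_diagram <- function(f, E = seq(-60, -10, length.out = 11),
                         V = seq(1e4, 6e4, length.out = 11)) {
  m <- outer(E, V, f)
  structure(list(grid = list(E_sn_values = E, V_sen_values = V),
                 maps = list(obs = m)), class = "phase_diagram")
}

test_that("scan grids validate their axes", {
  expect_error(scan_grid(c(-10, -20), c(1, 2)), "increasing")
  expect_error(scan_grid(c(-20, -10), c(2, 1)), "increasing")
  g <- scan_grid(c(-20, -10), c(1e4, 2e4), replicates = 2, mcs = 10)
  expect_s3_class(g, "scan_grid")
})

test_that("a 1x1 grid aggregates replicate observables by their mean", {
  g <- scan_grid(-20, 3.4e4, replicates = 2, mcs = 60, burn_in = 20,
                 base_seed = 3)
  pd <- run_scan(g, cpm_params())
  long <- pd$replicates_long
  expect_equal(nrow(long), 2)
  expect_equal(pd$maps$omega_bar[1, 1], mean(long$omega_bar))
  expect_equal(pd$maps$R_bar[1, 1], mean(long$R_bar))
  expect_true(all(pd$dispersion$R_bar >= 0))
})

test_that("scans are deterministic and checkpoints resume identically", {
  g <- scan_grid(c(-30, -15), 2e4, replicates = 1, mcs = 40, burn_in = 10,
                 base_seed = 7)
  p1 <- run_scan(g, cpm_params())
  p2 <- run_scan(g, cpm_params())
  expect_identical(p1$maps, p2$maps)
  ckdir <- tempfile("ck")
  p3 <- run_scan(g, cpm_params(), checkpoint_dir = ckdir)
  expect_true(length(list.files(ckdir)) == 2)
  p4 <- run_scan(g, cpm_params(), checkpoint_dir = ckdir)  # resumes
  expect_equal(p3$maps$omega_bar, p4$maps$omega_bar, tolerance = 1e-12)
})

test_that("level curves match analytic contours within a grid cell", {
  # f(x, y) = x/10 + y/1e4: level set is a straight line
  pd <- fake_diagram(function(E, V) E / 10 + V / 1e4)
  # level chosen off the node values so no contour fuzz is applied
  lc <- extract_level_curve(pd, "obs", level = 0.26)
  expect_gte(length(lc$polylines), 1)
  pts <- do.call(rbind, lc$polylines)
  expect_close(pts$E_sn / 10 + pts$V_sen / 1e4, 0.26, 1e-6)
  expect_false(lc$degenerate)
  # monotone map: a single connected contour
  expect_length(lc$polylines, 1)
})

test_that("degenerate and out-of-range levels are flagged, not fatal", {
  pd <- fake_diagram(function(E, V) 0 * E + 1)
  expect_warning(lc <- extract_level_curve(pd, "obs", level = 5))
  expect_length(lc$polylines, 0)
  expect_true(lc$degenerate)
  pd2 <- fake_diagram(function(E, V) E)
  expect_warning(extract_level_curve(pd2, "obs", level = 100), "outside")
  expect_error(extract_level_curve(pd2, "nope", 1), "unknown")
})

test_that("level-curve intersection recovers exact crossings", {
  pdx <- fake_diagram(function(E, V) E)          # level curve E = -32.6
  pdy <- fake_diagram(function(E, V) V)          # level curve V = 2.26e4
  c1 <- extract_level_curve(pdx, "obs", -32.6, delta = 5)
  c2 <- extract_level_curve(pdy, "obs", 2.26e4, delta = 5e3)
  est <- intersect_levels(c1, c2)
  expect_true(est$identifiable)
  expect_equal(est$E_sn_hat, -32.6, tolerance = 1e-6)
  expect_equal(est$V_sen_hat, 2.26e4, tolerance = 1e-6)
  # the estimate lies inside the band-overlap uncertainty region
  ur <- est$uncertainty_region
  expect_true(est$E_sn_hat >= min(ur[, 1]) - 1e-6 &&
                est$E_sn_hat <= max(ur[, 1]) + 1e-6)
  expect_true(est$V_sen_hat >= min(ur[, 2]) - 1e-6 &&
                est$V_sen_hat <= max(ur[, 2]) + 1e-6)
})

test_that("parallel curves are reported as non-identifiable", {
  pd <- fake_diagram(function(E, V) E)
  c1 <- extract_level_curve(pd, "obs", -40)
  c2 <- extract_level_curve(pd, "obs", -20)
  est <- intersect_levels(c1, c2)
  expect_false(est$identifiable)
  expect_true(is.na(est$E_sn_hat))
  expect_gt(est$diagnostics$distance_scaled, 0)
})

test_that("monotonicity verdicts separate trends from noise", {
  inc <- fake_diagram(function(E, V) E / 10 + V / 1e4)
  rep <- monotonicity_report(inc, "obs")
  expect_equal(rep$verdict, c("increasing", "increasing"))
  dec <- fake_diagram(function(E, V) -E)
  expect_equal(monotonicity_report(dec, "obs")$verdict[1], "decreasing")
  withr::with_seed(2, {
    flat <- fake_diagram(function(E, V) rnorm(length(E)))
  })
  expect_true(all(monotonicity_report(flat, "obs")$verdict ==
                    "inconclusive"))
})
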