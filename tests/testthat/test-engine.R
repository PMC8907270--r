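single_cell_state <- function(p, side = 40L, area = 100L, seed = 1) {
  g <- matrix(0L, side, side)
  off <- lattice_disk_offsets(area)
  c0 <- side %/% 2
  g[cbind(c0 + off[, 1], c0 + off[, 2])] <- 1L
  withr::with_seed(seed, lattice_state(g, "normal", p))
}

test_that("identical seeds give bit-identical runs", {
  p <- cpm_params()
  st <- single_cell_state(p)
  r1 <- run_cpm(st, p, 100, seed = 99)
  r2 <- run_cpm(st, p, 100, seed = 99)
  expect_identical(r1$state$grid, r2$state$grid)
  expect_identical(r1$tracks, r2$tracks)
  r3 <- run_cpm(st, p, 100, seed = 100)
  expect_false(identical(r1$state$grid, r3$state$grid))
})

test_that("incremental caches agree with full recounts after a run", {
  p <- cpm_params(E_sn = -20)
  st <- build_pair(p, seed = 5)
  run <- run_cpm(st, p, 150, seed = 17)
  expect_silent(lattice_audit(run$state, tol = 1e-6))
  # site conservation
  expect_equal(sum(run$state$cells$area) + sum(run$state$grid == 0L),
               run$state$width * run$state$height)
  # strict tolerance over ~1000 attempts (cells well below half-domain)
  p2 <- cpm_params(area_target_normal = 12)
  g <- matrix(0L, 24, 24)
  off <- lattice_disk_offsets(12)
  g[cbind(12 + off[, 1], 12 + off[, 2])] <- 1L
  st2 <- withr::with_seed(1, lattice_state(g, "normal", p2))
  r2 <- run_cpm(st2, p2, 2, seed = 9)   # 2 x 576 attempts
  expect_silent(lattice_audit(r2$state, tol = 1e-9))
})

test_that("accepted-attempt dH equals brute-force Hamiltonian difference", {
  p <- cpm_params()
  st <- random_two_cell_state(p, seed = 2)
  run <- run_cpm(st, p, 1, seed = 4, audit = TRUE)
  expect_gt(nrow(run$attempts), 0)
  rep <- replay_attempts(st, run$attempts, p)
  acc <- !is.na(rep$dh_state_brute)
  expect_gt(sum(acc), 0)
  expect_close(rep$dh_state_engine[acc], rep$dh_state_brute[acc], 1e-9)
  # engine persistence component matches the reference implementation
  expect_close(rep$dh_persistence_engine, rep$dh_persistence_ref, 1e-9)
})

test_that("a non-motile cell at target geometry is statistically stationary", {
  # low-temperature limit: fluctuations cannot push the cell off target
  p <- cpm_params(S_normal = 0, temperature = 0.1)
  st <- single_cell_state(p)
  run <- run_cpm(st, p, 100, seed = 8)
  areas <- run$tracks$area
  expect_true(all(abs(areas - p$area_target_normal) <=
                    0.1 * p$area_target_normal))
})

test_that("self-propulsion makes motion persistent and superdiffusive", {
  p1 <- cpm_params()            # S = 2.8
  p0 <- cpm_params(S_normal = 0)
  st1 <- single_cell_state(p1, side = 60)
  st0 <- single_cell_state(p0, side = 60)
  r1 <- run_cpm(st1, p1, 500, seed = 42)
  r0 <- run_cpm(st0, p0, 500, seed = 42)
  disp <- function(r) {
    tr <- r$tracks
    sqrt((tail(tr$cx, 1) - tr$cx[1])^2 + (tail(tr$cy, 1) - tr$cy[1])^2)
  }
  expect_gt(disp(r1), 3 * disp(r0))
  msd_exponent <- function(r) {
    tr <- r$tracks
    lags <- c(10, 20, 50, 100, 200, 400)
    msd <- vapply(lags, function(L) {
      i <- seq_len(nrow(tr) - L)
      mean((tr$cx[i + L] - tr$cx[i])^2 + (tr$cy[i + L] - tr$cy[i])^2)
    }, numeric(1))
    unname(coef(lm(log(msd) ~ log(lags)))[2])
  }
  expect_gt(msd_exponent(r1), msd_exponent(r0) + 0.3)
  expect_gt(msd_exponent(r1), 1.3)   # superdiffusive
})

test_that("run-level dH report ranks perimeter > persistence > area at study parameters", {
  p <- cpm_params(E_sn = -20, V_target_sen_um2 = 3.4e4)
  run <- simulate_confluent(p, n_normal = 91, n_senescent = 1,
                            n_mcs = 200, burn_in = 50, seed = 31)
  rep <- dh_component_report(run)
  m <- setNames(rep$mean_abs, rep$component)
  expect_gt(m["perimeter"], m["persistence"])
  expect_gt(m["persistence"], m["area"])
})

test_that("polarity update in the engine matches the per-MCS rule", {
  p <- cpm_params(temperature = 1e-6, S_normal = 0)
  st <- single_cell_state(p, side = 20, area = 12)
  run <- run_cpm(st, p, 1, seed = 3)
  tr <- run$tracks
  dr <- c(diff(tr$cx), diff(tr$cy))
  p_expect <- update_polarity(c(st$cells$px, st$cells$py), dr, p$tau_memory)
  expect_equal(c(run$state$cells$px, run$state$cells$py), p_expect,
               tolerance = 1e-9)
})
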