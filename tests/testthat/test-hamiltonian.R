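# Reference Hamiltonian-change operations, checked against direct
# substitution and a loop-based brute-force oracle.

make_area_state <- function(area_a, area_b = NULL, p = cpm_params()) {
  # two horizontal bars of controlled areas touching at x = area_a
  W <- as.integer(area_a + max(0, area_b %||% 0) + 4)
  g <- matrix(0L, W, 8)
  g[seq_len(area_a), 4] <- 1L
  phen <- "normal"
  if (!is.null(area_b)) {
    g[area_a + seq_len(area_b), 4] <- 2L
    phen <- c("normal", "normal")
  }
  lattice_state(g, phen, p)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("area term follows direct substitution", {
  p <- cpm_params()
  # cell at A = 99 gains one medium site: (100-100)^2 - (100-99)^2 = -1
  st <- make_area_state(99)
  at <- copy_attempt(st, target_site = c(100, 4), source_site = c(99, 4))
  expect_equal(at$target_id, 0L); expect_equal(at$source_id, 1L)
  expect_equal(delta_h_area(st, at, p), -1)
  # cell at A = 100 gains one site: (100-101)^2 - 0 = +1
  st <- make_area_state(100)
  at <- copy_attempt(st, c(101, 4), c(100, 4))
  expect_equal(delta_h_area(st, at, p), 1)
  # A = 98 gains a site from B = 102: (1-4) + (1-4) = -6
  st <- make_area_state(98, 102)
  at <- copy_attempt(st, c(99, 4), c(98, 4))  # B's site taken by A
  expect_equal(at$target_id, 2L); expect_equal(at$source_id, 1L)
  expect_equal(delta_h_area(st, at, p), -6)
})

test_that("perimeter term matches a full-lattice recount", {
  p <- cpm_params()
  g <- matrix(0L, 10, 10)
  g[5, 5] <- 1L            # isolated 1-site cell, perimeter 4
  g[2:3, 2:3] <- 2L        # 2x2 square, perimeter 8
  st <- lattice_state(g, c("normal", "normal"), p)
  expect_equal(st$cells$perimeter, c(4, 8))
  # annex the 1-site cell into medium: its term goes (Pt-4)^2 -> (Pt-0)^2
  at <- copy_attempt(st, c(5, 5), c(5, 6))
  Pt <- p$perimeter_target_normal
  expect_equal(delta_h_perimeter(st, at, p), (Pt - 0)^2 - (Pt - 4)^2)
  # 2x2 square gains an adjacent site -> perimeter 10
  at2 <- copy_attempt(st, c(4, 2), c(3, 2))
  st2 <- apply_attempt(st, at2)
  expect_equal(st2$cells$perimeter[2], 10)
  expect_equal(delta_h_perimeter(st, at2, p),
               (Pt - 10)^2 - (Pt - 8)^2)
})

test_that("adhesion term equals brute-force H difference", {
  p <- cpm_params(E_sn = -20)
  st <- random_two_cell_state(p, seed = 7)
  # try every distinct-id Moore pair on the lattice
  checked <- 0
  for (x in seq_len(st$width)) for (y in seq_len(st$height)) {
    sx <- x %% st$width + 1
    at <- copy_attempt(st, c(x, y), c(sx, y))
    if (at$target_id == at$source_id) next
    dh <- delta_h_adhesion(st, at, p)
    h0 <- oracle_hamiltonian(st, p)
    st1 <- apply_attempt(st, at)
    h1 <- oracle_hamiltonian(st1, p)
    dh_constr <- delta_h_area(st, at, p) + delta_h_perimeter(st, at, p)
    expect_equal(dh + dh_constr, h1 - h0, tolerance = 1e-9)
    checked <- checked + 1
    if (checked >= 25) break
  }
  expect_gte(checked, 10)
})

test_that("single normal site flipping to medium has zero adhesion change", {
  p <- cpm_params()
  g <- matrix(0L, 8, 8); g[4, 4] <- 1L
  st <- lattice_state(g, "normal", p)
  at <- copy_attempt(st, c(4, 4), c(4, 5))
  expect_equal(delta_h_adhesion(st, at, p), 0)  # E_nm = E_mm = 0
})

test_that("persistence term: orthogonality, alignment, senescent zero", {
  p <- cpm_params()
  g <- matrix(0L, 20, 20)
  g[5:10, 5] <- 1L  # horizontal bar, area 6, centroid x = 7.5
  st <- lattice_state(g, "normal", p,
                      polarity = matrix(c(1, 0), ncol = 2))
  # gain at +x end: centroid shift along +x, p along +x
  at <- copy_attempt(st, c(11, 5), c(10, 5))
  A <- 6; xr <- 11; cx <- 7.5
  d_scaled <- A * ((cx * A + xr) / (A + 1) - cx)
  expect_equal(delta_h_persistence(st, at, p), -p$S_normal * d_scaled)
  # gain displaced only in y while p is along x: orthogonal -> 0
  sty <- lattice_state(g, "normal", p,
                       polarity = matrix(c(0, 1), ncol = 2))
  expect_equal(delta_h_persistence(sty, at, p), 0)
  # senescent cell: S = 0 regardless of geometry
  sts <- lattice_state(g, "senescent", p,
                       polarity = matrix(c(1, 0), ncol = 2))
  expect_equal(delta_h_persistence(sts, at, p), 0)
})

test_that("zero polarity contributes no persistence energy", {
  p <- cpm_params()
  g <- matrix(0L, 10, 10); g[4:6, 5] <- 1L
  st <- lattice_state(g, "normal", p, polarity = matrix(c(0, 0), ncol = 2))
  at <- copy_attempt(st, c(7, 5), c(6, 5))
  expect_equal(delta_h_persistence(st, at, p), 0)
})

test_that("metropolis rule: branches and acceptance frequency", {
  expect_true(all(metropolis_accept(rep(-5, 100), 10)))
  expect_true(all(metropolis_accept(rep(0, 100), 10)))   # dH = 0 convention
  withr::with_seed(42, {
    n <- 1e5
    f <- mean(metropolis_accept(rep(10, n), 10))
    se <- sqrt(exp(-1) * (1 - exp(-1)) / n)
    expect_lt(abs(f - exp(-1)), 3 * se)
  })
  expect_error(metropolis_accept(1, 0))
})

test_that("polarity update limits match the closed forms", {
  # tau = 1: full memory loss, p' = dr
  expect_equal(update_polarity(c(4, 0), c(0.5, -1), 1), c(0.5, -1))
  # direct substitution
  expect_equal(update_polarity(c(4, 0), c(0, 0), 4), c(3, 0))
  # tau -> infinity: p' -> p + dr
  expect_equal(update_polarity(c(1, 2), c(0.5, 0), 1e12), c(1.5, 2),
               tolerance = 1e-9)
  expect_error(update_polarity(c(1, 0), c(0, 0), 0.5))
})

test_that("total dH equals brute-force Hamiltonian difference on random states", {
  p <- cpm_params(E_sn = -20)
  for (seed in c(3, 11)) {
    st <- random_two_cell_state(p, seed = seed)
    withr::with_seed(seed, {
      for (k in 1:10) {
        x <- sample.int(st$width, 1); y <- sample.int(st$height, 1)
        dxy <- sample(c(-1, 0, 1), 2, replace = TRUE)
        if (all(dxy == 0)) dxy <- c(1, 0)
        sx <- (x + dxy[1] - 1) %% st$width + 1
        sy <- (y + dxy[2] - 1) %% st$height + 1
        at <- copy_attempt(st, c(x, y), c(sx, sy))
        if (at$target_id == at$source_id) next
        dh <- delta_h_total(st, at, p)
        comp <- attr(dh, "components")
        # state-function part vs oracle (persistence is path-dependent)
        st1 <- apply_attempt(st, at)
        expect_equal(sum(comp[c("area", "perimeter", "adhesion")]),
                     oracle_hamiltonian(st1, p) - oracle_hamiltonian(st, p),
                     tolerance = 1e-9)
      }
    })
  }
})

test_that("dh_component_report summarizes attempt logs", {
  log1 <- data.frame(dh_area = 1, dh_perimeter = 2, dh_adhesion = 3,
                     dh_persistence = 4)
  rep1 <- dh_component_report(log1)
  expect_equal(rep1$mean_abs[order(rep1$component)],
               c(3, 1, 2, 4)[order(c("adhesion", "area", "perimeter",
                                     "persistence"))])
  expect_equal(dh_component_report(log1)$component[1], "persistence")
  log0 <- data.frame(dh_area = 0, dh_perimeter = 0, dh_adhesion = 0,
                     dh_persistence = 0)
  expect_true(all(dh_component_report(log0)$mean_abs == 0))
  expect_error(dh_component_report(log1[0, ]), "empty")
})
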