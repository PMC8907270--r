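# Independent brute-force oracles and small fixtures.  The Hamiltonian
# oracle below recomputes every term from scratch with plain loops; it
# shares no code with the package's incremental or vectorized paths.

oracle_hamiltonian <- function(state, params) {
  g <- state$grid
  W <- nrow(g); H <- ncol(g)
  E <- adhesion_matrix(params)
  pcode <- c(0L, phenotype_code(state$cells$phenotype))  # index by id + 1
  h_area <- 0; h_perim <- 0; h_adh <- 0
  for (c in seq_len(nrow(state$cells))) {
    A <- 0; P <- 0
    for (x in seq_len(W)) for (y in seq_len(H)) {
      if (g[x, y] != c) next
      A <- A + 1
      nb <- c(g[x %% W + 1, y], g[(x - 2) %% W + 1, y],
              g[x, y %% H + 1], g[x, (y - 2) %% H + 1])
      P <- P + sum(nb != c)
    }
    h_area <- h_area + params$lambda_area *
      (state$cells$area_target[c] - A)^2
    h_perim <- h_perim + params$lambda_perimeter *
      (state$cells$perimeter_target[c] - P)^2
  }
  for (x in seq_len(W)) for (y in seq_len(H)) {
    a <- g[x, y]
    for (nb in list(g[x %% W + 1, y], g[x, y %% H + 1])) {
      if (nb != a) h_adh <- h_adh + E[pcode[a + 1L] + 1L, pcode[nb + 1L] + 1L]
    }
  }
  h_area + h_perim + h_adh
}

# small random mixture of two normal cells and medium on a periodic grid
random_two_cell_state <- function(params, side = 12L, seed = 1) {
  withr::with_seed(seed, {
    g <- matrix(0L, side, side)
    off <- lattice_disk_offsets(12)
    g[cbind((4 + off[, 1] - 1) %% side + 1, (4 + off[, 2] - 1) %% side + 1)] <- 1L
    off2 <- lattice_disk_offsets(10)
    g[cbind((9 + off2[, 1] - 1) %% side + 1, (9 + off2[, 2] - 1) %% side + 1)] <- 2L
    # roughen the boundary a little
    for (k in 1:15) {
      x <- sample.int(side, 1); y <- sample.int(side, 1)
      nx <- x %% side + 1
      g[x, y] <- g[nx, y]
    }
    p <- params
    lattice_state(g, c("normal", "normal"), p)
  })
}

# deterministic circular orbit trajectory (no noise)
circle_traj <- function(R = 100, omega = 0.02, n = 200, dt = 1,
                        theta0 = 0, chirality = 1) {
  t <- seq(0, by = dt, length.out = n)
  th <- theta0 + chirality * omega * t
  data.frame(time_min = t, cell_id = 1L, phenotype = "normal",
             x_um = R * cos(th), y_um = R * sin(th))
}

expect_close <- function(x, y, tol) expect_lt(max(abs(x - y)), tol)
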