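#' Describe a copy attempt
#'
#' A copy attempt proposes to copy the cell id at `source_site` onto
#' `target_site`.  The source must be one of the 8 Moore neighbors of the
#' target (with periodic wrapping).
#'
#' @param state a [lattice_state()].
#' @param target_site,source_site integer `c(x, y)` lattice coordinates
#'   (1-based).
#' @return object of class `copy_attempt` with the sites and the two ids.
#' @export
copy_attempt <- function(state, target_site, source_site) {
  W <- state$width; H <- state$height
  t <- as.integer(target_site); s <- as.integer(source_site)
  stopifnot(length(t) == 2, length(s) == 2,
            all(t >= 1), t[1] <= W, t[2] <= H,
            all(s >= 1), s[1] <= W, s[2] <= H)
  dx <- (s[1] - t[1] + W / 2) %% W - W / 2
  dy <- (s[2] - t[2] + H / 2) %% H - H / 2
  if (max(abs(c(dx, dy))) != 1)
    stop("source_site must be a Moore neighbor of target_site")
  structure(list(target_site = t, source_site = s,
                 target_id = state$grid[t[1], t[2]],
                 source_id = state$grid[s[1], s[2]]),
            class = "copy_attempt")
}

vn_neighbor_ids <- function(state, site) {
  W <- state$width; H <- state$height
  x <- site[1]; y <- site[2]
  c(state$grid[x %% W + 1, y], state$grid[(x - 2) %% W + 1, y],
    state$grid[x, y %% H + 1], state$grid[x, (y - 2) %% H + 1])
}

cell_field <- function(state, id, col) {
  if (id == 0L) return(NA_real_)
  state$cells[[col]][id]
}

#' Hamiltonian change of a copy attempt, by component
#'
#' `delta_h_area()`, `delta_h_perimeter()`, `delta_h_adhesion()` and
#' `delta_h_persistence()` compute the change each energy term would
#' undergo if the attempt were applied; `delta_h_total()` sums them.
#' These are the reference (plain R) implementations of the energies the
#' compiled engine maintains incrementally:
#' \deqn{H_{constr} = \lambda_A \sum_i (A^*_i - A_i)^2 +
#'       \lambda_P \sum_i (P^*_i - P_i)^2}
#' \deqn{H_{adh} = \sum_{edges} E_{\sigma_i,\sigma_j} (1 - \delta_{ij})}
#' (adhesion and perimeter both counted over von Neumann boundary
#' edges; copy-attempt sources come from the Moore neighborhood)
#' \deqn{\Delta H_{pers} = -S \sum_i \Delta x_i \cdot \hat p_i}
#' where \eqn{\Delta x_i} is the hypothetical center-of-mass shift of
#' cell `i` scaled by its area, i.e. the displacement the copied site
#' contributes (magnitude of order one lattice constant, the
#' convention of lattice persistent-motion plugins; an unscaled
#' centroid shift of order `1/A` would make the persistence term
#' negligible for 100-site cells at the stated `S` and `T`).
#' Medium (id 0) carries no area, perimeter or persistence
#' term; a cell whose polarity vector is exactly zero contributes no
#' persistence energy.
#'
#' @param state a [lattice_state()].
#' @param attempt a [copy_attempt()].
#' @param params a [cpm_params()].
#' @return a single energy value; `delta_h_total()` additionally carries
#'   a `"components"` attribute.
#' @export
delta_h_area <- function(state, attempt, params) {
  dh <- 0
  a <- attempt$target_id; b <- attempt$source_id
  if (a != 0L) {
    A <- cell_field(state, a, "area"); At <- cell_field(state, a, "area_target")
    dh <- dh + params$lambda_area * ((At - (A - 1))^2 - (At - A)^2)
  }
  if (b != 0L) {
    A <- cell_field(state, b, "area"); At <- cell_field(state, b, "area_target")
    dh <- dh + params$lambda_area * ((At - (A + 1))^2 - (At - A)^2)
  }
  dh
}

#' @rdname delta_h_area
#' @export
delta_h_perimeter <- function(state, attempt, params) {
  a <- attempt$target_id; b <- attempt$source_id
  nb <- vn_neighbor_ids(state, attempt$target_site)
  dPa <- 2 * sum(nb == a) - 4
  dPb <- 4 - 2 * sum(nb == b)
  dh <- 0
  if (a != 0L) {
    P <- cell_field(state, a, "perimeter")
    Pt <- cell_field(state, a, "perimeter_target")
    dh <- dh + params$lambda_perimeter * ((Pt - (P + dPa))^2 - (Pt - P)^2)
  }
  if (b != 0L) {
    P <- cell_field(state, b, "perimeter")
    Pt <- cell_field(state, b, "perimeter_target")
    dh <- dh + params$lambda_perimeter * ((Pt - (P + dPb))^2 - (Pt - P)^2)
  }
  dh
}

#' @rdname delta_h_area
#' @export
delta_h_adhesion <- function(state, attempt, params) {
  E <- adhesion_matrix(params)
  a <- attempt$target_id; b <- attempt$source_id
  nb <- vn_neighbor_ids(state, attempt$target_site)
  code <- function(id) if (id == 0L)
    0L else phenotype_code(state$cells$phenotype[id])
  pha <- code(a); phb <- code(b)
  dh <- 0
  for (qid in nb) {
    phq <- code(qid)
    if (qid != b) dh <- dh + E[phb + 1L, phq + 1L]
    if (qid != a) dh <- dh - E[pha + 1L, phq + 1L]
  }
  dh
}

#' @rdname delta_h_area
#' @export
delta_h_persistence <- function(state, attempt, params) {
  W <- state$width; H <- state$height
  x <- attempt$target_site[1]; y <- attempt$target_site[2]
  dh <- 0
  contrib <- function(id, gain) {
    A <- cell_field(state, id, "area")
    if (id == 0L || A == 0) return(0)
    S <- cell_field(state, id, "S")
    p <- c(cell_field(state, id, "px"), cell_field(state, id, "py"))
    nrm <- sqrt(sum(p^2))
    if (S == 0 || nrm < 1e-12) return(0)
    cx <- cell_field(state, id, "cx"); cy <- cell_field(state, id, "cy")
    xr <- cx + ((x - cx %% W + W / 2) %% W - W / 2)
    yr <- cy + ((y - cy %% H + H / 2) %% H - H / 2)
    if (gain) {
      dxv <- c((cx * A + xr) / (A + 1) - cx, (cy * A + yr) / (A + 1) - cy)
    } else {
      if (A == 1) return(0)  # cell vanishes; no defined centroid shift
      dxv <- c((cx * A - xr) / (A - 1) - cx, (cy * A - yr) / (A - 1) - cy)
    }
    # center-of-mass shift scaled by cell area (per-copied-site magnitude)
    -S * A * sum(dxv * p) / nrm
  }
  dh <- dh + contrib(attempt$target_id, gain = FALSE)
  dh <- dh + contrib(attempt$source_id, gain = TRUE)
  dh
}

#' @rdname delta_h_area
#' @export
delta_h_total <- function(state, attempt, params) {
  comp <- c(area = delta_h_area(state, attempt, params),
            perimeter = delta_h_perimeter(state, attempt, params),
            adhesion = delta_h_adhesion(state, attempt, params),
            persistence = delta_h_persistence(state, attempt, params))
  structure(sum(comp), components = comp)
}

#' Metropolis acceptance rule
#'
#' Accepts with probability 1 when \eqn{\Delta H \le 0} (the equality
#' case taken as the continuity limit of the negative branch) and with
#' probability \eqn{e^{-\Delta H / T}} otherwise.
#'
#' @param dH energy change (vectorized).
#' @param temperature fluctuation amplitude `T` (> 0).
#' @return logical vector of acceptances (draws from the session RNG).
#' @examples
#' metropolis_accept(-5, 10)        # TRUE
#' mean(metropolis_accept(rep(10, 1e4), 10))  # ~ exp(-1)
#' @export
metropolis_accept <- function(dH, temperature) {
  stopifnot(temperature > 0)
  dH <= 0 | runif(length(dH)) < exp(-dH / temperature)
}

#' Polarity memory update
#'
#' Once per MCS each cell's polarity is updated by its net centroid
#' displacement and a memory-loss term:
#' \eqn{p \leftarrow p + \Delta r - p/\tau}.  With \eqn{\tau = 1} the
#' polarity equals the last displacement; as \eqn{\tau \to \infty} the
#' polarity integrates the full path history.
#'
#' @param p polarity 2-vector (lattice units).
#' @param dr net centroid displacement over the MCS (2-vector).
#' @param tau_memory memory time in MCS (>= 1).
#' @return updated 2-vector.
#' @export
update_polarity <- function(p, dr, tau_memory) {
  if (tau_memory < 1) stop("tau_memory must be >= 1")
  stopifnot(length(p) == 2, length(dr) == 2)
  p + dr - p / tau_memory
}

#' Total Hamiltonian of a lattice state
#'
#' Sums the area and perimeter constraint terms and the adhesion energy
#' over the whole lattice (the persistence term is defined only for
#' changes, not as a state function).
#'
#' @param state a [lattice_state()].
#' @param params a [cpm_params()].
#' @return named numeric: `area`, `perimeter`, `adhesion`, `total`.
#' @export
hamiltonian_total <- function(state, params) {
  geo <- recount_geometry(state)
  ph <- phenotype_code(state$cells$phenotype)
  h_area <- params$lambda_area *
    sum((state$cells$area_target - geo$area)^2)
  h_perim <- params$lambda_perimeter *
    sum((state$cells$perimeter_target - geo$perimeter)^2)
  E <- adhesion_matrix(params)
  g <- state$grid
  W <- state$width; H <- state$height
  phen_grid <- matrix(0L, W, H)
  for (c in seq_len(nrow(state$cells))) phen_grid[g == c] <- ph[c]
  shift <- function(m, dx, dy)
    m[(seq_len(W) - 1 - dx) %% W + 1, (seq_len(H) - 1 - dy) %% H + 1,
      drop = FALSE]
  h_adh <- 0
  for (d in list(c(1, 0), c(0, 1))) {
    gs <- shift(g, d[1], d[2]); ps <- shift(phen_grid, d[1], d[2])
    sel <- g != gs
    h_adh <- h_adh + sum(E[cbind(phen_grid[sel] + 1L, ps[sel] + 1L)])
  }
  c(area = h_area, perimeter = h_perim, adhesion = h_adh,
    total = h_area + h_perim + h_adh)
}

#' Mean absolute Hamiltonian change by component
#'
#' Summarizes a copy-attempt log (or a completed run's accumulated
#' report) as the mean absolute magnitude of each \eqn{\Delta H}
#' component, ranked.  For the confluent parameter set the perimeter
#' constraint dominates, persistence comes second and the area
#' constraint is smallest.
#'
#' @param x a `cpm_run` (see [run_cpm()]) or a data.frame of logged
#'   attempts with columns `dh_area`, `dh_perimeter`, `dh_adhesion`,
#'   `dh_persistence`.
#' @return data.frame with `component`, `mean_abs`, ordered decreasing.
#' @export
dh_component_report <- function(x) {
  if (inherits(x, "cpm_run")) {
    r <- x$dh_report
    m <- c(area = r$area, perimeter = r$perimeter,
           adhesion = r$adhesion, persistence = r$persistence)
    if (!is.finite(r$n_evaluated) || r$n_evaluated == 0)
      stop("empty attempt log")
  } else {
    cols <- c("dh_area", "dh_perimeter", "dh_adhesion", "dh_persistence")
    if (!all(cols %in% names(x))) stop("not an attempt log")
    if (nrow(x) == 0) stop("empty attempt log")
    m <- vapply(x[cols], function(v) mean(abs(v)), numeric(1))
    names(m) <- sub("^dh_", "", cols)
  }
  out <- data.frame(component = names(m), mean_abs = unname(m))
  out[order(-out$mean_abs), ]
}
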