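#' Run the Cellular Potts dynamics
#'
#' Advances a [lattice_state()] by `n_mcs` Monte Carlo steps.  One MCS
#' performs as many copy attempts as there are lattice sites: a target
#' site is drawn uniformly, a source site uniformly from its Moore
#' neighborhood, and the copy is accepted by the Metropolis rule on the
#' total Hamiltonian change (area and perimeter constraints, adhesion,
#' persistence).  At the end of every MCS each cell's polarity is
#' updated from its net centroid displacement
#' (\eqn{\Delta p = \Delta r - p/\tau}).
#'
#' Centroids are tracked in unwrapped coordinates so trajectories can be
#' analysed without periodic jumps.  All randomness comes from a single
#' engine generator seeded by `seed`; identical inputs give bit-identical
#' results.
#'
#' @param state a [lattice_state()].
#' @param params a [cpm_params()].
#' @param n_mcs number of Monte Carlo steps.
#' @param seed integer seed for the engine RNG (mandatory).
#' @param record_every record per-cell tracks every this many MCS.
#' @param record_contacts if `TRUE`, record the normal-senescent
#'   boundary-edge counts at every recorded step (interface-mode contact
#'   detection input).
#' @param audit if `TRUE`, log every evaluated copy attempt (sites, ids,
#'   energy components, acceptance) up to `audit_max` rows; intended for
#'   small lattices and energy-bookkeeping checks.
#' @param audit_max maximum number of logged attempts.
#' @return object of class `cpm_run`: list with the final `state`,
#'   `tracks` (per-recorded-MCS cell table in lattice units), `contacts`,
#'   `dh_report`, `attempts`, `params`, and `seed`.
#' @export
run_cpm <- function(state, params, n_mcs, seed,
                    record_every = 1L, record_contacts = FALSE,
                    audit = FALSE, audit_max = 200000L) {
  stopifnot(inherits(state, "lattice_state"), inherits(params, "cpm_params"),
            n_mcs >= 0)
  if (missing(seed) || is.null(seed)) stop("an explicit `seed` is required")
  lattice_audit(state, tol = 1e-6)
  cells <- state$cells
  pcode <- phenotype_code(cells$phenotype)
  res <- cpm_run_cpp(
    state$grid, pcode,
    cells$area_target, cells$perimeter_target, cells$S,
    cells$px, cells$py,
    adhesion_matrix(params),
    params$lambda_area, params$lambda_perimeter,
    params$temperature, params$tau_memory,
    as.integer(n_mcs), as.numeric(seed),
    as.integer(state$mcs_elapsed),
    as.integer(record_every), record_contacts,
    audit, as.integer(audit_max))
  new_cells <- cells
  new_cells$area <- res$area
  new_cells$perimeter <- res$perimeter
  new_cells$cx <- res$cx
  new_cells$cy <- res$cy
  new_cells$px <- res$px
  new_cells$py <- res$py
  new_state <- structure(list(grid = res$grid, cells = new_cells,
                              width = state$width, height = state$height,
                              mcs_elapsed = res$mcs_elapsed),
                         class = "lattice_state")
  structure(list(
    state = new_state,
    tracks = as.data.frame(res$tracks),
    contacts = as.data.frame(res$contacts),
    dh_report = res$dh_report,
    attempts = as.data.frame(res$attempts),
    params = params,
    seed = seed
  ), class = "cpm_run")
}

#' @export
print.cpm_run <- function(x, ...) {
  cat(sprintf("cpm_run: %d cells, %d MCS elapsed, %d track rows (seed %s)\n",
              nrow(x$state$cells), x$state$mcs_elapsed, nrow(x$tracks),
              format(x$seed)))
  invisible(x)
}

#' Convert engine tracks to a physical-unit trajectory table
#'
#' Converts the lattice-unit per-MCS tracks of a [run_cpm()] result into
#' the canonical trajectory table: time in minutes, positions (unwrapped
#' centroids) and polarity in microns, areas in um^2.
#'
#' @param run a `cpm_run`.
#' @param params a [cpm_params()]; defaults to the run's own.
#' The physical perimeter applies the isotropic digital-contour
#' (Cauchy-Crofton) correction pi/4 to the boundary-edge count, the
#' standard unbiased length estimator for staircase boundaries.
#'
#' @return data.frame with columns `time_min`, `cell_id`, `phenotype`,
#'   `x_um`, `y_um`, `area_um2`, `perimeter_um`, `px_um`, `py_um`.
#' @export
tracks_to_table <- function(run, params = run$params) {
  tr <- run$tracks
  u <- params$site_to_um
  data.frame(
    time_min = tr$mcs * params$mcs_to_min,
    cell_id = tr$cell_id,
    phenotype = run$state$cells$phenotype[tr$cell_id],
    x_um = tr$cx * u,
    y_um = tr$cy * u,
    area_um2 = tr$area * params$um2_per_site,
    # staircase edge counts overestimate Euclidean contour length by 4/pi
    # for isotropically oriented boundaries (Cauchy-Crofton)
    perimeter_um = tr$perimeter * u * pi / 4,
    px_um = tr$px * u,
    py_um = tr$py * u,
    stringsAsFactors = FALSE
  )
}

#' Replay an audited attempt log against brute-force energies
#'
#' Starting from the pre-run state, applies each accepted attempt in an
#' audit log one at a time and returns, per attempt, the engine's
#' incremental \eqn{\Delta H} alongside the brute-force Hamiltonian
#' difference over the whole lattice (constraints + adhesion; the
#' path-dependent persistence component is reported separately from the
#' reference R implementation).
#'
#' @param state the state the audited run started from.
#' @param attempts the `attempts` data.frame of an audited [run_cpm()].
#' @param params a [cpm_params()].
#' @param n_max check at most this many attempts.
#' @return data.frame with columns `dh_engine`, `dh_state_brute`,
#'   `dh_state_engine`, `dh_persistence_engine`, `dh_persistence_ref`.
#' @export
replay_attempts <- function(state, attempts, params, n_max = nrow(attempts)) {
  st <- state
  n <- min(n_max, nrow(attempts))
  out <- data.frame(dh_engine = numeric(n), dh_state_brute = numeric(n),
                    dh_state_engine = numeric(n),
                    dh_persistence_engine = numeric(n),
                    dh_persistence_ref = numeric(n))
  h_before <- hamiltonian_total(st, params)[["total"]]
  for (i in seq_len(n)) {
    at <- attempts[i, ]
    attempt <- copy_attempt(st, c(at$x, at$y), c(at$sx, at$sy))
    if (attempt$target_id != at$target_id || attempt$source_id != at$source_id)
      stop("replay out of sync at attempt ", i)
    out$dh_engine[i] <- at$dh_area + at$dh_perimeter + at$dh_adhesion +
      at$dh_persistence
    out$dh_persistence_engine[i] <- at$dh_persistence
    out$dh_persistence_ref[i] <- delta_h_persistence(st, attempt, params)
    if (at$accepted == 1) {
      st <- apply_attempt(st, attempt, params)
      h_after <- hamiltonian_total(st, params)[["total"]]
      out$dh_state_brute[i] <- h_after - h_before
      out$dh_state_engine[i] <- at$dh_area + at$dh_perimeter + at$dh_adhesion
      h_before <- h_after
    } else {
      out$dh_state_brute[i] <- NA
      out$dh_state_engine[i] <- NA
    }
  }
  out
}

#' Apply a copy attempt to a lattice state
#'
#' Reference (non-incremental) application: flips the target site to the
#' source id and recounts all geometry.
#'
#' @param state a [lattice_state()].
#' @param attempt a [copy_attempt()].
#' @param params a [cpm_params()] (unused, kept for signature symmetry).
#' @return the updated `lattice_state`.
#' @export
apply_attempt <- function(state, attempt, params = NULL) {
  st <- state
  st$grid[attempt$target_site[1], attempt$target_site[2]] <-
    attempt$source_id
  geo <- recount_geometry(st)
  st$cells$area <- geo$area
  st$cells$perimeter <- geo$perimeter
  st$cells$cx <- geo$cx
  st$cells$cy <- geo$cy
  st
}
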