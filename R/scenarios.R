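#' Place a digitized disk of sites on a grid
#'
#' @param grid integer matrix to modify.
#' @param n_sites disk area in sites.
#' @param center `c(x, y)` lattice coordinates.
#' @param id cell id to write.
#' @return the modified grid.
#' @keywords internal
place_disk <- function(grid, n_sites, center, id) {
  W <- nrow(grid); H <- ncol(grid)
  off <- lattice_disk_offsets(n_sites)
  xs <- (center[1] - 1 + off[, 1]) %% W + 1
  ys <- (center[2] - 1 + off[, 2]) %% H + 1
  if (any(grid[cbind(xs, ys)] != 0L))
    stop("disk placement overlaps an existing cell")
  grid[cbind(xs, ys)] <- id
  grid
}

default_pair_domain <- function(params) {
  r_sen <- sqrt(params$area_target_sen / pi)
  r_norm <- sqrt(params$area_target_normal / pi)
  side <- max(2 * ceiling(1.15 * (r_sen + 2 * r_norm) + 8),
              ceiling(4.4 * r_sen))
  max(64L, as.integer(side))
}

# periodic centroid tracking requires every cell to span less than half
# the domain; reject geometries that violate it
check_half_domain <- function(params, domain) {
  r_sen <- sqrt(params$area_target_sen / pi)
  if (4.2 * r_sen > min(domain))
    stop("domain too small: the senescent cell diameter must stay below ",
         "half the domain for periodic centroid tracking")
  invisible(TRUE)
}

#' Build the heterotypic pair scenario
#'
#' Seeds one senescent cell as a lattice disk of its target area at the
#' domain center and one normal cell as a disk of its target area
#' touching the senescent boundary.  The state is returned un-relaxed;
#' drivers such as [simulate_pair()] apply a burn-in before measuring.
#'
#' @param params a [cpm_params()].
#' @param domain `c(width, height)` in sites, or a single side length;
#'   `NULL` picks a side comfortably holding both cells.
#' @param seed optional seed for the polarity initialization.
#' @return a [lattice_state()] with cell 1 = senescent, cell 2 = normal.
#' @export
build_pair <- function(params, domain = NULL, seed = NULL) {
  if (is.null(domain)) domain <- default_pair_domain(params)
  if (length(domain) == 1) domain <- c(domain, domain)
  W <- as.integer(domain[1]); H <- as.integer(domain[2])
  need <- params$area_target_sen + params$area_target_normal
  if (need > 0.6 * W * H)
    stop("domain too small for the requested target areas")
  check_half_domain(params, c(W, H))
  r_sen <- sqrt(params$area_target_sen / pi)
  r_norm <- sqrt(params$area_target_normal / pi)
  g <- matrix(0L, W, H)
  c_sen <- c(floor(W / 2), floor(H / 2))
  g <- place_disk(g, params$area_target_sen, c_sen, 1L)
  # closest non-overlapping placement, so the pair starts in contact
  for (off in floor(r_sen + r_norm) + 0:4) {
    g2 <- tryCatch(place_disk(g, params$area_target_normal,
                              c(c_sen[1] + off, c_sen[2]), 2L),
                   error = function(e) NULL)
    if (!is.null(g2)) { g <- g2; break }
  }
  if (is.null(g2)) stop("could not seed the normal cell next to the host")
  with_seed(seed,
    lattice_state(g, c("senescent", "normal"), params))
}

#' Build a confluent scenario
#'
#' Places `n_senescent` senescent disks (non-overlapping, at their
#' target areas) and tessellates every remaining site among `n_normal`
#' normal cells by nearest-seed assignment under the periodic metric, so
#' that the initial state has no medium sites and every cell is
#' contiguous.
#'
#' @param params a [cpm_params()].
#' @param n_normal,n_senescent cell counts.
#' @param domain `c(width, height)` or a side length; `NULL` picks the
#'   side whose area matches the summed target areas, making the stated
#'   cell counts confluent at their targets.
#' @param seed seed for senescent placement, normal seeds and polarity.
#' @param max_tries retries for non-overlapping senescent placement.
#' @return a [lattice_state()]; senescent cells get ids `1..n_senescent`.
#' @export
build_confluent <- function(params, n_normal = 91L, n_senescent = 1L,
                            domain = NULL, seed = NULL, max_tries = 200L) {
  stopifnot(n_normal >= 1, n_senescent >= 0)
  if (is.null(domain)) {
    side <- round(sqrt(n_normal * params$area_target_normal +
                       n_senescent * params$area_target_sen))
    domain <- c(side, side)
  }
  if (length(domain) == 1) domain <- c(domain, domain)
  W <- as.integer(domain[1]); H <- as.integer(domain[2])
  if (n_senescent > 0) check_half_domain(params, c(W, H))
  r_sen <- sqrt(params$area_target_sen / pi)
  with_seed(seed, {
    g <- matrix(0L, W, H)
    if (n_senescent > 0) {
      centers <- matrix(NA_real_, 0, 2)
      for (i in seq_len(n_senescent)) {
        placed <- FALSE
        for (try in seq_len(max_tries)) {
          cand <- c(sample.int(W, 1), sample.int(H, 1))
          ok <- TRUE
          if (nrow(centers)) {
            dx <- abs(centers[, 1] - cand[1]); dx <- pmin(dx, W - dx)
            dy <- abs(centers[, 2] - cand[2]); dy <- pmin(dy, H - dy)
            ok <- all(sqrt(dx^2 + dy^2) > 2 * r_sen + 3)
          }
          if (ok) {
            g <- place_disk(g, params$area_target_sen, cand, i)
            centers <- rbind(centers, cand)
            placed <- TRUE
            break
          }
        }
        if (!placed)
          stop("could not place senescent cells without overlap")
      }
    }
    free <- which(g == 0L)
    if (length(free) < n_normal)
      stop("domain too small for the requested cell counts")
    seeds <- sample(free, n_normal)
    sx <- (seeds - 1) %% W + 1; sy <- (seeds - 1) %/% W + 1
    fx <- (free - 1) %% W + 1; fy <- (free - 1) %/% W + 1
    dx <- abs(outer(fx, sx, "-")); dx <- pmin(dx, W - dx)
    dy <- abs(outer(fy, sy, "-")); dy <- pmin(dy, H - dy)
    nearest <- max.col(-(dx^2 + dy^2), ties.method = "first")
    g[free] <- n_senescent + nearest
    phen <- c(rep("senescent", n_senescent), rep("normal", n_normal))
    lattice_state(g, phen, params)
  })
}

#' Simulate the pair scenario
#'
#' Builds the pair state, relaxes it for `burn_in` MCS (not recorded),
#' then runs `n_mcs` measured MCS recording tracks (and optionally
#' interface contacts).
#'
#' @param params a [cpm_params()].
#' @param n_mcs measured Monte Carlo steps.
#' @param burn_in equilibration MCS excluded from measurement.
#' @param seed integer seed (drives initialization and both runs).
#' @param domain passed to [build_pair()].
#' @param record_every,record_contacts passed to [run_cpm()].
#' @return a `cpm_run` whose `tracks` cover only the measured window;
#'   the trajectory table in physical units is in `$table`.
#' @export
simulate_pair <- function(params, n_mcs = 2000L, burn_in = 100L, seed,
                          domain = NULL, record_every = 1L,
                          record_contacts = FALSE) {
  st <- build_pair(params, domain = domain, seed = derive_seed(seed, 1))
  if (burn_in > 0) {
    warm <- run_cpm(st, params, burn_in, seed = derive_seed(seed, 2),
                    record_every = max(1L, burn_in))
    st <- warm$state
  }
  run <- run_cpm(st, params, n_mcs, seed = derive_seed(seed, 3),
                 record_every = record_every,
                 record_contacts = record_contacts)
  run$table <- tracks_to_table(run)
  run
}

#' Simulate a confluent scenario
#'
#' @inheritParams simulate_pair
#' @param n_normal,n_senescent,domain passed to [build_confluent()].
#' @return a `cpm_run` with `$table`; interface contacts are recorded by
#'   default.
#' @export
simulate_confluent <- function(params, n_normal = 91L, n_senescent = 1L,
                               n_mcs = 3000L, burn_in = 100L, seed,
                               domain = NULL, record_every = 1L,
                               record_contacts = TRUE) {
  st <- build_confluent(params, n_normal = n_normal,
                        n_senescent = n_senescent, domain = domain,
                        seed = derive_seed(seed, 1))
  if (burn_in > 0) {
    warm <- run_cpm(st, params, burn_in, seed = derive_seed(seed, 2),
                    record_every = max(1L, burn_in))
    st <- warm$state
  }
  run <- run_cpm(st, params, n_mcs, seed = derive_seed(seed, 3),
                 record_every = record_every,
                 record_contacts = record_contacts)
  run$table <- tracks_to_table(run)
  run
}
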