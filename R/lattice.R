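#' Lattice disks
#'
#' `lattice_disk_offsets()` returns the `n` lattice offsets closest to the
#' origin (ties broken by angle), i.e. the digitized disk used to seed
#' cells and to define perimeter targets.  `disk_perimeter_edges()` counts
#' its von Neumann boundary edges.
#'
#' @param n_sites number of lattice sites.
#' @return `lattice_disk_offsets`: integer matrix with columns `dx`,
#'   `dy`; `disk_perimeter_edges`: a single number.
#' @keywords internal
#' @export
lattice_disk_offsets <- function(n_sites) {
  stopifnot(n_sites >= 1)
  r <- ceiling(sqrt(n_sites / pi)) + 2L
  xs <- seq.int(-r, r)
  off <- expand.grid(dx = xs, dy = xs)
  d2 <- off$dx^2 + off$dy^2
  ord <- order(d2, atan2(off$dy, off$dx))
  as.matrix(off[ord[seq_len(n_sites)], , drop = FALSE])
}

#' @rdname lattice_disk_offsets
#' @export
disk_perimeter_edges <- function(n_sites) {
  off <- lattice_disk_offsets(n_sites)
  key <- paste(off[, 1], off[, 2])
  nb <- 0L
  for (d in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
    nb <- nb + sum(!(paste(off[, 1] + d[1], off[, 2] + d[2]) %in% key))
  }
  nb
}

#' Construct a lattice state
#'
#' A `lattice_state` is the full configuration of the simulation: a
#' periodic 2D grid of cell ids (0 = medium) plus a per-cell table with
#' phenotype, constraint targets, persistence strength, polarity vector
#' and cached geometry (area in sites, perimeter in von Neumann boundary
#' edges, centroid in lattice coordinates).  Cached geometry is recomputed
#' from the grid on construction.
#'
#' @param grid integer matrix of cell ids; ids must be consecutive
#'   `1..K` (0 for medium), rows indexing x and columns y.
#' @param phenotype character vector of length `K` (`"normal"` or
#'   `"senescent"`), element `i` describing cell id `i`.
#' @param params a [cpm_params()] object used to assign targets and
#'   persistence strengths.
#' @param polarity optional K x 2 matrix of initial polarity vectors in
#'   lattice units; defaults to random unit vectors scaled to 0.01 (a
#'   negligible magnitude that only removes the zero-polarity
#'   singularity without biasing direction).
#' @param mcs_elapsed elapsed Monte Carlo steps.
#' @return object of class `lattice_state`: list with `grid`, `cells`
#'   (data.frame), `width`, `height`, `mcs_elapsed`.
#' @export
lattice_state <- function(grid, phenotype, params, polarity = NULL,
                          mcs_elapsed = 0L) {
  stopifnot(is.matrix(grid))
  storage.mode(grid) <- "integer"
  ids <- sort(unique(as.vector(grid)))
  ids <- ids[ids != 0L]
  K <- length(phenotype)
  if (K < 1L) stop("at least one cell is required")
  if (length(ids) && (min(ids) < 1L || max(ids) > K))
    stop("grid ids must be consecutive 1..K matching the phenotype vector")
  pcode <- phenotype_code(phenotype)
  if (any(pcode == 0L)) stop("medium is id 0 on the grid, not a cell")
  if (is.null(polarity)) {
    ang <- runif(K, 0, 2 * pi)
    polarity <- cbind(0.01 * cos(ang), 0.01 * sin(ang))
  }
  polarity <- matrix(as.numeric(polarity), ncol = 2)
  stopifnot(nrow(polarity) == K)
  cells <- data.frame(
    id = seq_len(K),
    phenotype = as.character(phenotype),
    area_target = ifelse(pcode == 1L, params$area_target_normal,
                         params$area_target_sen),
    perimeter_target = ifelse(pcode == 1L, params$perimeter_target_normal,
                              params$perimeter_target_sen),
    S = ifelse(pcode == 1L, params$S_normal, params$S_sen),
    px = polarity[, 1], py = polarity[, 2],
    stringsAsFactors = FALSE
  )
  st <- structure(list(grid = grid, cells = cells,
                       width = nrow(grid), height = ncol(grid),
                       mcs_elapsed = as.integer(mcs_elapsed)),
                  class = "lattice_state")
  st$cells <- cbind(st$cells, recount_geometry(st))
  st
}

#' @export
print.lattice_state <- function(x, ...) {
  n_med <- sum(x$grid == 0L)
  cat(sprintf("lattice_state: %d x %d periodic grid, %d cells (%s), %d medium sites, %d MCS elapsed\n",
              x$width, x$height, nrow(x$cells),
              paste(table(x$cells$phenotype), names(table(x$cells$phenotype)),
                    collapse = " + "),
              n_med, x$mcs_elapsed))
  invisible(x)
}

#' Recount cell geometry from the grid
#'
#' Full (non-incremental) recount of each cell's area, von Neumann
#' boundary-edge perimeter, and periodic centroid.  Used to initialize
#' cached geometry and as the independent check of the engine's
#' incremental bookkeeping.
#'
#' @param state a [lattice_state()].
#' @return data.frame with columns `area`, `perimeter`, `cx`, `cy`
#'   (lattice coordinates, unwrapped about each cell's first site).
#' @export
recount_geometry <- function(state) {
  g <- state$grid
  W <- state$width; H <- state$height
  K <- nrow(state$cells)
  shift <- function(m, dx, dy) {
    m[(seq_len(W) - 1 - dx) %% W + 1, (seq_len(H) - 1 - dy) %% H + 1,
      drop = FALSE]
  }
  diff_nb <- (g != shift(g, 1, 0)) + (g != shift(g, -1, 0)) +
    (g != shift(g, 0, 1)) + (g != shift(g, 0, -1))
  out <- data.frame(area = numeric(K), perimeter = numeric(K),
                    cx = rep(NA_real_, K), cy = rep(NA_real_, K))
  xs <- row(g); ys <- col(g)
  for (c in seq_len(K)) {
    sel <- g == c
    A <- sum(sel)
    out$area[c] <- A
    if (A == 0) { out$perimeter[c] <- 0; next }
    out$perimeter[c] <- sum(diff_nb[sel])
    x0 <- xs[sel][1]; y0 <- ys[sel][1]
    dx <- (xs[sel] - x0 + W / 2) %% W - W / 2
    dy <- (ys[sel] - y0 + H / 2) %% H - H / 2
    out$cx[c] <- x0 + mean(dx)
    out$cy[c] <- y0 + mean(dy)
  }
  out
}

#' Audit cached against recounted geometry
#'
#' Compares the cached per-cell area, perimeter and centroid in
#' `state$cells` with a full recount from the grid.
#'
#' @param state a [lattice_state()].
#' @param tol centroid tolerance (lattice units); integer counts must
#'   match exactly.
#' @return invisibly `TRUE`; stops with a message on any mismatch.
#' @export
lattice_audit <- function(state, tol = 1e-9) {
  rec <- recount_geometry(state)
  if (!isTRUE(all.equal(state$cells$area, rec$area, tolerance = 0)))
    stop("cache inconsistency: area")
  if (!isTRUE(all.equal(state$cells$perimeter, rec$perimeter, tolerance = 0)))
    stop("cache inconsistency: perimeter")
  live <- rec$area > 0
  # centroids are tracked unwrapped and may differ by whole periods
  dcx <- (state$cells$cx[live] - rec$cx[live]) %% state$width
  dcy <- (state$cells$cy[live] - rec$cy[live]) %% state$height
  dcx <- pmin(dcx, state$width - dcx)
  dcy <- pmin(dcy, state$height - dcy)
  if (any(dcx > tol) || any(dcy > tol))
    stop("cache inconsistency: centroid")
  n_sites <- state$width * state$height
  if (sum(rec$area) + sum(state$grid == 0L) != n_sites)
    stop("site conservation violated")
  invisible(TRUE)
}

#' Count connected fragments per cell
#'
#' Diagnostic for cell fragmentation (no connectivity constraint is
#' enforced by the dynamics): counts 4-connected components of each
#' cell's site set under periodic boundaries.
#'
#' @param state a [lattice_state()].
#' @return integer vector, one count per cell (0 for vanished cells).
#' @export
count_fragments <- function(state) {
  g <- state$grid
  W <- state$width; H <- state$height
  K <- nrow(state$cells)
  out <- integer(K)
  visited <- matrix(FALSE, W, H)
  for (c in seq_len(K)) {
    sel <- which(g == c)
    if (!length(sel)) next
    comp <- 0L
    remaining <- rep(TRUE, W * H)
    remaining[-sel] <- FALSE
    while (any(remaining)) {
      comp <- comp + 1L
      start <- which(remaining)[1]
      queue <- start
      remaining[start] <- FALSE
      while (length(queue)) {
        i <- queue[1]; queue <- queue[-1]
        x <- (i - 1) %% W + 1; y <- (i - 1) %/% W + 1
        nbs <- c((x %% W) + 1 + (y - 1) * W,
                 ((x - 2) %% W) + 1 + (y - 1) * W,
                 x + (y %% H) * W,
                 x + ((y - 2) %% H) * W)
        nbs <- nbs[remaining[nbs]]
        remaining[nbs] <- FALSE
        queue <- c(queue, nbs)
      }
    }
    out[c] <- comp
  }
  out
}
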