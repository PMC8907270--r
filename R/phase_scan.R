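#' Scan grid over the two control parameters
#'
#' @param E_sn_values strictly monotone vector of interfacial energies.
#' @param V_sen_values strictly monotone vector of senescent target
#'   areas (um^2).
#' @param replicates independent runs per grid point (>= 1).
#' @param mcs measured MCS per run.
#' @param burn_in equilibration MCS per run.
#' @param base_seed seed from which all per-run seeds are derived.
#' @return object of class `scan_grid`.
#' @export
scan_grid <- function(E_sn_values, V_sen_values, replicates = 8L,
                      mcs = 1000L, burn_in = 100L, base_seed = 1L) {
  stopifnot(length(E_sn_values) >= 1, length(V_sen_values) >= 1,
            replicates >= 1, mcs > 0)
  if (length(E_sn_values) > 1 && any(diff(E_sn_values) <= 0) ||
      length(V_sen_values) > 1 && any(diff(V_sen_values) <= 0))
    stop("grid axes must be strictly increasing")
  structure(list(E_sn_values = E_sn_values, V_sen_values = V_sen_values,
                 replicates = as.integer(replicates), mcs = as.integer(mcs),
                 burn_in = as.integer(burn_in), base_seed = base_seed),
            class = "scan_grid")
}

#' Orbital observables of a pair run
#'
#' Computes the per-run observables entering the phase diagrams: mean
#' angular speed (magnitude, rectified), mean pair distance, mean
#' tangential speed, and mean normal-cell shape index.  Statistics are
#' taken over the frames in which the two cells are in contact (share a
#' boundary edge), mirroring the experimental protocol in which
#' trajectories are measured while the cells form an attached pair;
#' detached excursions do not enter the averages.  Falls back to all
#' frames when no contact record is available.
#'
#' @param run a `cpm_run` from [simulate_pair()] (contact recording
#'   enables the in-contact conditioning).
#' @param window rectification window (frames).
#' @return named numeric: `omega_bar` (rad/min), `R_bar` (um),
#'   `v_theta_bar` (um/min), `p_bar`, `contact_fraction`.
#' @export
pair_observables <- function(run, window = 15L) {
  tab <- run$table
  if (is.null(tab)) tab <- tracks_to_table(run)
  normal <- tab[tab$phenotype == "normal", ]
  sen <- tab[tab$phenotype == "senescent", ]
  period <- c(run$state$width, run$state$height) * run$params$site_to_um
  tr <- to_polar(normal[, c("time_min", "x_um", "y_um")],
                 sen[, c("time_min", "x_um", "y_um")], period = period)
  tr <- unwrap_and_rectify(tr, window = window)
  sp <- angular_speed(tr)
  vt <- tangential_speed(tr)
  p <- shape_index(normal$area_um2, normal$perimeter_um)
  n_frames <- nrow(tr)
  if (nrow(run$contacts)) {
    mask <- contact_mask_for_cell(run, normal$cell_id[1])
    frac <- mean(mask)
  } else {
    mask <- rep(TRUE, n_frames)
    frac <- NA_real_
  }
  if (!any(mask)) mask <- rep(TRUE, n_frames)
  pair_mask <- mask[-n_frames] & mask[-1]
  if (!any(pair_mask)) pair_mask <- rep(TRUE, n_frames - 1)
  c(omega_bar = abs(mean(sp$omega[pair_mask])),
    R_bar = mean(tr$R_um[mask]),
    v_theta_bar = abs(mean(vt$v_theta[pair_mask])),
    p_bar = mean(p[mask]),
    contact_fraction = frac)
}

#' Run the two-parameter phase scan
#'
#' For every `(E_sn, V_target_sen)` grid point, runs `replicates`
#' independent pair simulations (distinct derived seeds), computes the
#' orbital observables of each replicate (mean angular speed, mean
#' pair distance, mean tangential speed, mean normal-cell shape index)
#' by the trajectory pipeline, and averages over replicates (time
#' average within a run first, then unweighted replicate mean).
#' Per-point results can be checkpointed to delimited files so an
#' interrupted scan resumes where it stopped.
#'
#' @param grid a [scan_grid()].
#' @param params baseline [cpm_params()]; `E_sn` and `V_target_sen_um2`
#'   are overridden per grid point.
#' @param domain lattice side for the pair runs; `NULL` sizes each
#'   point's domain automatically (largest senescent target governs).
#' @param window rectification window (frames).
#' @param checkpoint_dir optional directory for per-point checkpoint
#'   tables.
#' @param verbose print progress.
#' @return object of class `phase_diagram`: the grid, per-observable
#'   mean and sd matrices (`E_sn` rows, `V_sen` columns), and the long
#'   per-replicate table.
#' @export
run_scan <- function(grid, params = cpm_params(), domain = NULL,
                     window = 15L, checkpoint_dir = NULL, verbose = FALSE) {
  stopifnot(inherits(grid, "scan_grid"))
  obs_names <- c("omega_bar", "R_bar", "v_theta_bar", "p_bar")
  nE <- length(grid$E_sn_values); nV <- length(grid$V_sen_values)
  long <- list()
  if (!is.null(checkpoint_dir) && !dir.exists(checkpoint_dir))
    dir.create(checkpoint_dir, recursive = TRUE)
  for (i in seq_len(nE)) for (j in seq_len(nV)) {
    ck <- if (!is.null(checkpoint_dir))
      file.path(checkpoint_dir, sprintf("point_%02d_%02d.tsv", i, j)) else NULL
    if (!is.null(ck) && file.exists(ck)) {
      pt <- read.table(ck, header = TRUE, sep = "\t")
    } else {
      pars_ij <- cpm_params(
        E_sn = grid$E_sn_values[i],
        V_target_sen_um2 = grid$V_sen_values[j],
        lambda_area = params$lambda_area,
        lambda_perimeter = params$lambda_perimeter,
        area_target_normal = params$area_target_normal,
        perimeter_shape_factor = params$perimeter_shape_factor,
        E_nn = params$E_nn, E_nm = params$E_nm, E_sm = params$E_sm,
        E_mm = params$E_mm, S_normal = params$S_normal,
        tau_memory = params$tau_memory, temperature = params$temperature,
        mcs_to_min = params$mcs_to_min, site_to_um = params$site_to_um)
      pt <- do.call(rbind, lapply(seq_len(grid$replicates), function(r) {
        run <- simulate_pair(pars_ij, n_mcs = grid$mcs,
                             burn_in = grid$burn_in,
                             seed = derive_seed(grid$base_seed, i, j, r),
                             domain = domain, record_contacts = TRUE)
        ob <- pair_observables(run, window = window)
        data.frame(E_sn = grid$E_sn_values[i],
                   V_sen = grid$V_sen_values[j], replicate = r, t(ob))
      }))
      if (!is.null(ck))
        write.table(pt, ck, sep = "\t", row.names = FALSE, quote = FALSE)
    }
    long[[paste(i, j)]] <- pt
    if (verbose)
      message(sprintf("scan point E_sn = %g, V_sen = %g done",
                      grid$E_sn_values[i], grid$V_sen_values[j]))
  }
  long <- do.call(rbind, long)
  rownames(long) <- NULL
  maps <- list(); disp <- list()
  for (ob in obs_names) {
    m <- matrix(NA_real_, nE, nV); s <- matrix(NA_real_, nE, nV)
    for (i in seq_len(nE)) for (j in seq_len(nV)) {
      v <- long[[ob]][long$E_sn == grid$E_sn_values[i] &
                        long$V_sen == grid$V_sen_values[j]]
      m[i, j] <- mean(v); s[i, j] <- sd(v)
    }
    maps[[ob]] <- m; disp[[ob]] <- s
  }
  structure(list(grid = grid, maps = maps, dispersion = disp,
                 replicates_long = long),
            class = "phase_diagram")
}

#' @export
print.phase_diagram <- function(x, ...) {
  cat(sprintf("phase_diagram: %d x %d grid (E_sn x V_sen), %d replicates/point, observables: %s\n",
              length(x$grid$E_sn_values), length(x$grid$V_sen_values),
              x$grid$replicates, paste(names(x$maps), collapse = ", ")))
  invisible(x)
}

#' Extract a level curve from a phase diagram
#'
#' Marching-squares contour (bilinear interpolation on the gridded map)
#' of one observable at a given level, with optional band curves at
#' `level +/- delta`.
#'
#' @param diagram a [run_scan()] result, or a list with `grid` and
#'   `maps` of the same shape.
#' @param observable observable name.
#' @param level contour level in the observable's units.
#' @param delta half-width of the uncertainty band (same units), or
#'   `NULL` for no band.
#' @return object of class `level_curve`: list of polyline data.frames
#'   (`E_sn`, `V_sen`), plus `band_low`/`band_high` polyline lists and a
#'   `degenerate` flag for constant maps.
#' @export
extract_level_curve <- function(diagram, observable, level, delta = NULL) {
  map <- diagram$maps[[observable]]
  if (is.null(map)) stop("unknown observable: ", observable)
  g <- diagram$grid
  degenerate <- diff(range(map, na.rm = TRUE)) < 1e-12
  curve_at <- function(lv) {
    if (lv < min(map, na.rm = TRUE) || lv > max(map, na.rm = TRUE)) {
      warning(sprintf("level %g outside the %s map range [%g, %g]",
                      lv, observable, min(map, na.rm = TRUE),
                      max(map, na.rm = TRUE)))
      return(list())
    }
    cl <- grDevices::contourLines(x = g$E_sn_values, y = g$V_sen_values,
                                  z = map, levels = lv)
    lapply(cl, function(p) data.frame(E_sn = p$x, V_sen = p$y))
  }
  structure(list(observable = observable, level = level, delta = delta,
                 polylines = curve_at(level),
                 band_low = if (!is.null(delta)) curve_at(level - delta),
                 band_high = if (!is.null(delta)) curve_at(level + delta),
                 degenerate = degenerate),
            class = "level_curve")
}

segment_intersection <- function(p1, p2, p3, p4) {
  # p_i = c(x, y); returns intersection point of segments p1p2, p3p4 or NULL
  d1 <- p2 - p1; d2 <- p4 - p3
  den <- d1[1] * d2[2] - d1[2] * d2[1]
  if (abs(den) < 1e-300) return(NULL)
  t <- ((p3[1] - p1[1]) * d2[2] - (p3[2] - p1[2]) * d2[1]) / den
  u <- ((p3[1] - p1[1]) * d1[2] - (p3[2] - p1[2]) * d1[1]) / den
  if (t < 0 || t > 1 || u < 0 || u > 1) return(NULL)
  p1 + t * d1
}

polyline_intersections <- function(c1, c2, sx = 1, sy = 1) {
  pts <- list()
  for (a in c1) for (b in c2) {
    if (nrow(a) < 2 || nrow(b) < 2) next
    for (i in seq_len(nrow(a) - 1)) for (j in seq_len(nrow(b) - 1)) {
      p <- segment_intersection(
        c(a$E_sn[i] / sx, a$V_sen[i] / sy),
        c(a$E_sn[i + 1] / sx, a$V_sen[i + 1] / sy),
        c(b$E_sn[j] / sx, b$V_sen[j] / sy),
        c(b$E_sn[j + 1] / sx, b$V_sen[j + 1] / sy))
      if (!is.null(p)) pts[[length(pts) + 1]] <- p * c(sx, sy)
    }
  }
  if (!length(pts)) return(NULL)
  do.call(rbind, pts)
}

nearest_approach <- function(c1, c2, sx, sy) {
  a <- do.call(rbind, lapply(c1, function(p) cbind(p$E_sn, p$V_sen)))
  b <- do.call(rbind, lapply(c2, function(p) cbind(p$E_sn, p$V_sen)))
  d <- outer(a[, 1] / sx, b[, 1] / sx, "-")^2 +
    outer(a[, 2] / sy, b[, 2] / sy, "-")^2
  k <- which(d == min(d), arr.ind = TRUE)[1, ]
  list(distance_scaled = sqrt(min(d)), from = a[k[1], ], to = b[k[2], ])
}

#' Intersect two level curves into a parameter estimate
#'
#' Computes all pairwise segment intersections of the two level curves;
#' the estimate is the intersection nearest the centroid of the
#' band-curve intersections (the band-overlap region) when several
#' exist.  Axes are rescaled by the curve extents before distance
#' comparisons so the energy and area axes weigh equally.
#'
#' @param c1,c2 [extract_level_curve()] results.
#' @return object of class `energy_estimate`: `E_sn_hat`, `V_sen_hat`,
#'   `identifiable`, `intersections`, `uncertainty_region` (polygon of
#'   band intersections, possibly `NULL`), `diagnostics`.
#' @export
intersect_levels <- function(c1, c2) {
  if (!length(c1$polylines) || !length(c2$polylines))
    stop("both level curves must be non-empty")
  allpts <- function(cl) do.call(rbind, lapply(cl, as.matrix))
  ext <- rbind(allpts(c1$polylines), allpts(c2$polylines))
  sx <- max(diff(range(ext[, 1])), 1e-9)
  sy <- max(diff(range(ext[, 2])), 1e-9)
  pts <- polyline_intersections(c1$polylines, c2$polylines, sx, sy)
  band_pts <- NULL
  for (ca in list(c1$band_low, c1$band_high)) for (cb in list(c2$band_low, c2$band_high)) {
    if (is.null(ca) || is.null(cb) || !length(ca) || !length(cb)) next
    bp <- polyline_intersections(ca, cb, sx, sy)
    if (!is.null(bp)) band_pts <- rbind(band_pts, bp)
  }
  if (is.null(pts)) {
    return(structure(list(E_sn_hat = NA_real_, V_sen_hat = NA_real_,
                          identifiable = FALSE, intersections = NULL,
                          uncertainty_region = band_pts,
                          diagnostics = nearest_approach(c1$polylines,
                                                         c2$polylines,
                                                         sx, sy)),
                     class = "energy_estimate"))
  }
  ref <- if (!is.null(band_pts)) colMeans(band_pts) else colMeans(pts)
  d <- ((pts[, 1] - ref[1]) / sx)^2 + ((pts[, 2] - ref[2]) / sy)^2
  best <- pts[which.min(d), ]
  region <- NULL
  if (!is.null(band_pts) && nrow(band_pts) >= 3) {
    hull <- grDevices::chull(band_pts[, 1] / sx, band_pts[, 2] / sy)
    region <- band_pts[hull, , drop = FALSE]
  } else region <- band_pts
  structure(list(E_sn_hat = best[1], V_sen_hat = best[2],
                 identifiable = TRUE, intersections = pts,
                 uncertainty_region = region, diagnostics = NULL),
            class = "energy_estimate")
}

#' @export
print.energy_estimate <- function(x, ...) {
  if (x$identifiable)
    cat(sprintf("energy estimate: E_sn = %.2f, V_target_sen = %.3g um^2 (%d intersection%s)\n",
                x$E_sn_hat, x$V_sen_hat, nrow(x$intersections),
                if (nrow(x$intersections) > 1) "s" else ""))
  else
    cat(sprintf("non-identifiable: curves do not intersect (scaled nearest approach %.3g)\n",
                x$diagnostics$distance_scaled))
  invisible(x)
}

#' Per-axis monotonicity verdicts for a phase-diagram observable
#'
#' Spearman rank correlation of the observable along each axis at every
#' fixed value of the other axis, averaged, with a verdict at a stated
#' threshold on the mean correlation.
#'
#' @param diagram a [run_scan()] result (or compatible list).
#' @param observable observable name.
#' @param threshold verdict threshold on the mean |rho|.
#' @return data.frame with one row per axis: `axis`, `mean_rho`,
#'   `verdict` (`"increasing"`, `"decreasing"` or `"inconclusive"`).
#' @export
monotonicity_report <- function(diagram, observable, threshold = 0.6) {
  map <- diagram$maps[[observable]]
  if (is.null(map)) stop("unknown observable: ", observable)
  g <- diagram$grid
  rho_along <- function(axis) {
    if (axis == "E_sn") {
      if (length(g$E_sn_values) < 3) return(NA_real_)
      mean(apply(map, 2, function(col)
        suppressWarnings(cor(g$E_sn_values, col, method = "spearman"))),
        na.rm = TRUE)
    } else {
      if (length(g$V_sen_values) < 3) return(NA_real_)
      mean(apply(map, 1, function(row)
        suppressWarnings(cor(g$V_sen_values, row, method = "spearman"))),
        na.rm = TRUE)
    }
  }
  verdict <- function(r) {
    if (is.na(r)) "inconclusive"
    else if (r >= threshold) "increasing"
    else if (r <= -threshold) "decreasing"
    else "inconclusive"
  }
  rhos <- c(E_sn = rho_along("E_sn"), V_sen = rho_along("V_sen"))
  data.frame(axis = names(rhos), mean_rho = unname(rhos),
             verdict = vapply(rhos, verdict, character(1)),
             row.names = NULL)
}
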