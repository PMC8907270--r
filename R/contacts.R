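#' Decode a contact mask into episodes
#'
#' Converts a per-frame logical in-contact mask into maximal contiguous
#' episodes.  Out-of-contact gaps of at most `gap_tolerance` frames
#' between in-contact frames are bridged (transient boundary flicker).
#' A single-frame episode is assigned a duration of one frame interval.
#'
#' @param mask logical vector.
#' @param times frame time stamps (min), same length.
#' @param gap_tolerance frames of interruption to bridge.
#' @return data.frame `start_min`, `end_min`, `duration_min`,
#'   `n_frames`, `censored` (episode touches the first or last frame).
#' @export
mask_episodes <- function(mask, times, gap_tolerance = 0L) {
  stopifnot(length(mask) == length(times))
  if (!length(mask)) return(empty_episodes())
  m <- as.logical(mask)
  if (gap_tolerance > 0 && any(m)) {
    r <- rle(m)
    idx <- which(!r$values & r$lengths <= gap_tolerance)
    # bridge only interior gaps (flanked by contact on both sides)
    idx <- idx[idx > 1 & idx < length(r$values)]
    r$values[idx] <- TRUE
    m <- inverse.rle(r)
  }
  r <- rle(m)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- which(r$values)
  if (!length(keep)) return(empty_episodes())
  dt <- if (length(times) > 1) mean(diff(times)) else 1
  out <- data.frame(
    start_min = times[starts[keep]],
    end_min = times[ends[keep]],
    n_frames = r$lengths[keep]
  )
  out$duration_min <- pmax(out$end_min - out$start_min, dt)
  out$censored <- starts[keep] == 1 | ends[keep] == length(m)
  out[, c("start_min", "end_min", "duration_min", "n_frames", "censored")]
}

empty_episodes <- function() {
  data.frame(start_min = numeric(0), end_min = numeric(0),
             duration_min = numeric(0), n_frames = integer(0),
             censored = logical(0))
}

episode_arclength <- function(track, start_min, end_min) {
  sel <- track$time_min >= start_min & track$time_min <= end_min
  if (sum(sel) < 2) return(0)
  sum(sqrt(diff(track$x_um[sel])^2 + diff(track$y_um[sel])^2))
}

#' Detect normal-senescent contact episodes
#'
#' Two modes.  `"interface"` works on the boundary-edge record of a
#' lattice simulation (a [run_cpm()] with `record_contacts = TRUE`): a
#' normal cell is in contact with a senescent cell at a recorded step
#' when they share at least one von Neumann boundary edge.
#' `"distance"` works on trajectory tables: contact is declared when
#' the centroid distance falls below a threshold; if per-frame areas are
#' available the threshold defaults to the sum of equivalent-circle
#' radii plus a boundary tolerance, otherwise `threshold_um` must be
#' given.
#'
#' @param x for `"interface"`: a `cpm_run`; for `"distance"`: a list
#'   with trajectory data.frames `normal` and `host`.
#' @param mode `"interface"` or `"distance"`.
#' @param gap_tolerance frames of interruption to bridge (default 1 in
#'   interface mode: membrane fluctuation at `T = 10` causes frequent
#'   one-step boundary flicker; 0 in distance mode).
#' @param threshold_um distance-mode contact threshold; computed from
#'   areas when `NULL` and area columns are present.
#' @param boundary_tol_um added to the equivalent-radius threshold.
#' @param drop_censored drop episodes touching the record boundaries
#'   (their duration is not fully observed).
#' @return data.frame of contact records: `normal_id`, `sen_id`,
#'   `start_min`, `end_min`, `duration_min`, `arclength_um`, `censored`.
#' @export
detect_contacts <- function(x, mode = c("interface", "distance"),
                            gap_tolerance = NULL, threshold_um = NULL,
                            boundary_tol_um = 6, drop_censored = FALSE) {
  mode <- match.arg(mode)
  if (mode == "interface") {
    if (!inherits(x, "cpm_run"))
      stop("interface mode requires a cpm_run with recorded contacts")
    if (is.null(gap_tolerance)) gap_tolerance <- 1L
    con <- x$contacts
    if (!nrow(con))
      stop("no contact records: run with record_contacts = TRUE")
    tab <- x$table
    if (is.null(tab)) tab <- tracks_to_table(x)
    times <- sort(unique(tab$time_min))
    mcs_to_min <- x$params$mcs_to_min
    out <- list()
    for (key in unique(paste(con$normal_id, con$sen_id))) {
      ids <- as.integer(strsplit(key, " ")[[1]])
      sub <- con[con$normal_id == ids[1] & con$sen_id == ids[2], ]
      mask <- times %in% (sub$mcs * mcs_to_min)
      ep <- mask_episodes(mask, times, gap_tolerance)
      if (!nrow(ep)) next
      track <- tab[tab$cell_id == ids[1], ]
      ep$arclength_um <- vapply(seq_len(nrow(ep)), function(k)
        episode_arclength(track, ep$start_min[k], ep$end_min[k]),
        numeric(1))
      ep$normal_id <- ids[1]; ep$sen_id <- ids[2]
      out[[key]] <- ep
    }
    res <- if (length(out)) do.call(rbind, out) else
      cbind(empty_episodes(), arclength_um = numeric(0),
            normal_id = integer(0), sen_id = integer(0))
  } else {
    if (is.null(gap_tolerance)) gap_tolerance <- 0L
    normal <- as_trajectory(as.data.frame(x$normal))
    host <- as_trajectory(as.data.frame(x$host))
    if (nrow(host) != nrow(normal))
      stop("normal and host trajectories must share the time base")
    gap <- sqrt((normal$x_um - host$x_um)^2 + (normal$y_um - host$y_um)^2)
    if (is.null(threshold_um)) {
      if (is.null(normal$area_um2) || is.null(host$area_um2))
        stop("distance mode needs `threshold_um` when area columns are absent")
      threshold_um <- sqrt(normal$area_um2 / pi) + sqrt(host$area_um2 / pi) +
        boundary_tol_um
    }
    ep <- mask_episodes(gap < threshold_um, normal$time_min, gap_tolerance)
    if (nrow(ep)) {
      ep$arclength_um <- vapply(seq_len(nrow(ep)), function(k)
        episode_arclength(normal, ep$start_min[k], ep$end_min[k]),
        numeric(1))
      ep$normal_id <- normal$cell_id[1] %||% 1L
      ep$sen_id <- host$cell_id[1] %||% 2L
    } else {
      ep <- cbind(empty_episodes(), arclength_um = numeric(0),
                  normal_id = integer(0), sen_id = integer(0))
    }
    res <- ep
  }
  rownames(res) <- NULL
  if (drop_censored) res <- res[!res$censored, , drop = FALSE]
  res[, c("normal_id", "sen_id", "start_min", "end_min", "duration_min",
          "arclength_um", "n_frames", "censored")]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Maximum-likelihood gamma fit of contact durations
#'
#' Fits a gamma law (shape `alpha`, scale `beta` in minutes) to a set of
#' residence times by maximum likelihood with moment-based starting
#' values.
#'
#' @param durations positive durations (min), at least 5.
#' @return object of class `gamma_fit`: `alpha`, `beta`, `mean`
#'   (`alpha * beta`), `n`, `method`, `se` (shape/rate standard errors).
#' @export
fit_gamma <- function(durations) {
  durations <- as.numeric(durations)
  if (length(durations) < 5) stop("at least 5 durations are required")
  if (any(durations <= 0)) stop("durations must be positive")
  if (sd(durations) == 0) stop("degenerate input: all durations equal")
  # MLE is scale-equivariant: fit on mean-scaled data for stability
  sc <- mean(durations)
  z <- durations / sc
  m <- mean(z); v <- var(z)
  start <- list(shape = m^2 / v, rate = m / v)
  fit <- MASS::fitdistr(z, "gamma", start = start,
                        lower = c(1e-8, 1e-8))
  alpha <- unname(fit$estimate["shape"])
  beta <- sc / unname(fit$estimate["rate"])
  structure(list(alpha = alpha, beta = beta, mean = alpha * beta,
                 n = length(durations), method = "mle",
                 se = fit$sd, sample_mean = m),
            class = "gamma_fit")
}

#' @export
print.gamma_fit <- function(x, ...) {
  cat(sprintf("gamma fit (MLE, n = %d): alpha = %.3f, beta = %.2f min, mean = %.1f min\n",
              x$n, x$alpha, x$beta, x$mean))
  invisible(x)
}
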