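#' Validate a trajectory table
#'
#' Checks the canonical trajectory columns (`time_min`, `x_um`, `y_um`),
#' strictly increasing time stamps and a uniform frame interval.
#' Position columns without the `_um` suffix (for example raw lattice
#' coordinates) are rejected rather than silently mixed with calibrated
#' data.
#'
#' @param df data.frame.
#' @param tol relative tolerance on frame-interval uniformity.
#' @return `df`, invisibly classed `trajectory`.
#' @export
as_trajectory <- function(df, tol = 1e-6) {
  need <- c("time_min", "x_um", "y_um")
  if (!all(need %in% names(df))) {
    bare <- intersect(c("x", "y", "t", "x_site", "y_site"), names(df))
    if (length(bare))
      stop("uncalibrated position/time columns (", paste(bare, collapse = ", "),
           "): convert to physical units (time_min, x_um, y_um) first")
    stop("missing trajectory columns: ",
         paste(setdiff(need, names(df)), collapse = ", "))
  }
  t <- df$time_min
  if (length(t) > 1) {
    dt <- diff(t)
    if (any(dt <= 0)) stop("time stamps must be strictly increasing")
    if (diff(range(dt)) > tol * mean(dt))
      stop("non-uniform frame interval")
  }
  class(df) <- unique(c("trajectory", class(df)))
  invisible(df)
}

#' Polar decomposition of a trajectory about a host
#'
#' Expresses a normal-cell trajectory in the reference frame of its host
#' senescent cell: per-frame distance `R` and raw angle `theta_raw`
#' (atan2, in `(-pi, pi]`).  The host may be a moving per-frame centroid
#' (a trajectory on the same time base) or a fixed point.
#'
#' @param normal trajectory data.frame (`time_min`, `x_um`, `y_um`).
#' @param host either a trajectory data.frame on the same time base or
#'   a numeric `c(x_um, y_um)` fixed point.
#' @param period optional `c(Lx, Ly)` domain period (same units as the
#'   positions): the relative vector is wrapped to the minimal image,
#'   which is required for tracks recorded as unwrapped centroids on a
#'   periodic lattice.
#' @return object of class `polar_trace`: data.frame `time_min`, `R_um`,
#'   `theta_raw`.
#' @export
to_polar <- function(normal, host = c(0, 0), period = NULL) {
  normal <- as_trajectory(as.data.frame(normal))
  if (is.numeric(host) && length(host) == 2) {
    hx <- rep(host[1], nrow(normal)); hy <- rep(host[2], nrow(normal))
  } else {
    host <- as_trajectory(as.data.frame(host))
    if (nrow(host) != nrow(normal) ||
        max(abs(host$time_min - normal$time_min)) > 1e-9)
      stop("host and normal trajectories must share the same time base")
    hx <- host$x_um; hy <- host$y_um
  }
  dx <- normal$x_um - hx; dy <- normal$y_um - hy
  if (!is.null(period)) {
    stopifnot(length(period) == 2, all(period > 0))
    dx <- (dx + period[1] / 2) %% period[1] - period[1] / 2
    dy <- (dy + period[2] / 2) %% period[2] - period[2] / 2
  }
  R <- sqrt(dx^2 + dy^2)
  if (any(R == 0)) stop("coincident centroids: R = 0 at some frame")
  structure(data.frame(time_min = normal$time_min, R_um = R,
                       theta_raw = atan2(dy, dx)),
            class = c("polar_trace", "data.frame"))
}

#' Unwrap and chirality-rectify an angular trace
#'
#' First applies standard 2-pi unwrapping to `theta_raw`, then flips the
#' sign of angular increments within segments whose windowed mean
#' d(theta)/dt opposes the initial chirality, so that occasional abrupt
#' reverse turns are rectified into a monotone-trend angle.  Both the
#' unwrapped and the rectified angle are returned alongside the raw one.
#'
#' @param trace a [to_polar()] result (or any data.frame with
#'   `time_min` and `theta_raw`).
#' @param window smoothing window for the local trend, in frames.
#' @return the trace with columns `theta_unwrapped` and `theta_rect`
#'   added.
#' @export
unwrap_and_rectify <- function(trace, window = 15L) {
  stopifnot(nrow(trace) >= 2)
  window <- as.integer(window)
  if (window > nrow(trace))
    stop("window larger than the trace")
  th <- signal::unwrap(trace$theta_raw)
  d <- diff(th)
  w <- max(1L, min(window, length(d)))
  sm <- stats::filter(d, rep(1 / w, w), sides = 2)
  sm <- as.numeric(sm)
  # extend the centered moving average into the edges
  first_ok <- which(!is.na(sm))[1]
  last_ok <- tail(which(!is.na(sm)), 1)
  sm[seq_len(first_ok - 1)] <- sm[first_ok]
  if (last_ok < length(sm)) sm[(last_ok + 1):length(sm)] <- sm[last_ok]
  chir0 <- sign(mean(d[seq_len(min(w, length(d)))]))
  if (chir0 == 0) chir0 <- 1
  flip <- sign(sm) * chir0 < 0
  d_rect <- ifelse(flip, -d, d)
  trace$theta_unwrapped <- th
  trace$theta_rect <- th[1] + cumsum(c(0, d_rect))
  trace
}

#' Angular speed of a rectified trace
#'
#' Per-interval angular speed \eqn{\omega_k = \Delta\theta_k/\Delta t}
#' on the rectified angle, plus its time mean.
#'
#' @param trace a trace with `theta_rect` (see [unwrap_and_rectify()]).
#' @param dt frame interval (min); inferred from `time_min` if `NULL`.
#' @return list with `omega` (rad/min, per interval), `omega_bar`
#'   (time-mean), `dt`.
#' @export
angular_speed <- function(trace, dt = NULL) {
  if (is.null(trace$theta_rect))
    stop("trace must be rectified first (unwrap_and_rectify)")
  if (is.null(dt)) dt <- mean(diff(trace$time_min))
  if (dt <= 0) stop("dt must be positive")
  omega <- diff(trace$theta_rect) / dt
  list(omega = omega, omega_bar = mean(omega), dt = dt)
}

#' Tangential speed of a rectified trace
#'
#' Per-interval tangential speed \eqn{v_{\theta,k} = R_k \omega_k}
#' (with `R` taken at the interval midpoint), plus its time mean.
#'
#' @param trace a rectified trace with `R_um` and `theta_rect`.
#' @param dt frame interval (min); inferred if `NULL`.
#' @return list with `v_theta` (um/min), `v_theta_bar`.
#' @export
tangential_speed <- function(trace, dt = NULL) {
  sp <- angular_speed(trace, dt)
  Rmid <- (head(trace$R_um, -1) + tail(trace$R_um, -1)) / 2
  v <- Rmid * sp$omega
  list(v_theta = v, v_theta_bar = mean(v))
}

#' Fit the A/R law of angular speed
#'
#' Least-squares fit of \eqn{\omega = A/R} over per-cell time-averaged
#' pairs \eqn{(\bar R_i, \bar\omega_i)}; the constant `A` is the
#' tangential speed.  Also reports a comparison against an
#' R-independent (constant \eqn{\omega}) model as a shape diagnostic.
#'
#' @param per_cell data.frame with columns `R_bar` (um) and `omega_bar`
#'   (rad/min).
#' @param level confidence level for the interval.
#' @return object of class `AR_fit`: list with `A` (um/min), `ci`,
#'   `n`, `aic_AR`, `aic_const`, `prefers_AR`.
#' @export
fit_A_over_R <- function(per_cell, level = 0.95) {
  stopifnot(all(c("R_bar", "omega_bar") %in% names(per_cell)))
  if (nrow(per_cell) < 2) stop("at least 2 cells are required")
  if (any(per_cell$R_bar <= 0)) stop("R_bar must be positive")
  fit <- lm(omega_bar ~ 0 + I(1 / R_bar), data = per_cell)
  const <- lm(omega_bar ~ 1, data = per_cell)
  ci <- suppressWarnings(suppressMessages(confint(fit, level = level)))
  structure(list(A = unname(coef(fit)[1]), ci = as.numeric(ci),
                 n = nrow(per_cell),
                 aic_AR = AIC(fit), aic_const = AIC(const),
                 prefers_AR = AIC(fit) < AIC(const),
                 fit = fit),
            class = "AR_fit")
}

#' @export
print.AR_fit <- function(x, ...) {
  cat(sprintf("A/R fit: A = %.3f um/min (%.0f%% CI %.3f-%.3f), n = %d; 1/R shape %s\n",
              x$A, 95, x$ci[1], x$ci[2], x$n,
              if (x$prefers_AR) "preferred over constant" else "NOT preferred"))
  invisible(x)
}

#' Dimensionless cell shape index
#'
#' \eqn{p = \mathrm{perimeter} / \sqrt{\mathrm{area}}}; unit-consistent
#' inputs are required (both physical or both lattice units; with a
#' square-lattice calibration the two give identical values).  A square
#' gives 4, a smooth circle \eqn{2\sqrt\pi \approx 3.545}.
#'
#' @param area cell area (um^2 or sites); vectorized.
#' @param perimeter cell perimeter (um or edge count); vectorized.
#' @return shape index `p`.
#' @export
shape_index <- function(area, perimeter) {
  if (any(area <= 0)) stop("area must be positive")
  perimeter / sqrt(area)
}

#' Per-cell orbital statistics of a cohort
#'
#' Convenience wrapper running the polar pipeline (decomposition,
#' unwrap/rectify, angular and tangential speed) over a list of
#' normal/host trajectory pairs.
#'
#' @param pairs list of lists with elements `normal` and `host` (see
#'   [generate_orbit_trajectories()]), or of single trajectories with
#'   `host` given separately.
#' @param window rectification window (frames).
#' @return data.frame with one row per cell: `R_bar`, `omega_bar`
#'   (magnitude of the rectified mean, rad/min), `v_theta_bar` (um/min).
#' @export
cohort_orbit_stats <- function(pairs, window = 15L) {
  rows <- lapply(seq_along(pairs), function(i) {
    pr <- pairs[[i]]
    tr <- to_polar(pr$normal, pr$host)
    tr <- unwrap_and_rectify(tr, window = window)
    sp <- angular_speed(tr)
    vt <- tangential_speed(tr)
    data.frame(cell = i, R_bar = mean(tr$R_um),
               omega_bar = abs(sp$omega_bar),
               v_theta_bar = abs(vt$v_theta_bar))
  })
  do.call(rbind, rows)
}
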