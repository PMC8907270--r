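#' Contact-conditioned directional autocorrelation
#'
#' Computes the mean dot product \eqn{C(t) = \langle \hat u(t_0) \cdot
#' \hat u(t_0 + t) \rangle} of unit direction vectors separated by lag
#' `t`, averaged over admissible pairs (and over cells when a list is
#' given).  A direction vector (the unit frame-to-frame displacement) is
#' "in contact" when both of its endpoint frames are; a pair of vectors
#' enters the `contact` condition when both vectors are in contact, the
#' `no_contact` condition when both are out, and is dropped when mixed.
#'
#' @param traj a trajectory data.frame, or a list of them.
#' @param contact_mask per-frame logical mask (or list of masks)
#'   aligned with the trajectory frames; `NULL` for unconditioned.
#' @param condition `"all"`, `"contact"` or `"no_contact"`.
#' @param max_lag_frames largest lag evaluated.
#' @return data.frame with `lag_min`, `C`, `n_pairs` (lag 0 included,
#'   `C(0) = 1`).
#' @export
direction_autocorrelation <- function(traj, contact_mask = NULL,
                                      condition = c("all", "contact",
                                                    "no_contact"),
                                      max_lag_frames = 120L) {
  condition <- match.arg(condition)
  if (is.data.frame(traj)) traj <- list(traj)
  if (!is.null(contact_mask) && is.logical(contact_mask))
    contact_mask <- list(contact_mask)
  if (condition != "all" && is.null(contact_mask))
    stop("conditioned autocorrelation requires a contact mask")
  num <- numeric(max_lag_frames); cnt <- numeric(max_lag_frames)
  dt <- NULL
  for (ci in seq_along(traj)) {
    tr <- as_trajectory(as.data.frame(traj[[ci]]))
    if (is.null(dt)) dt <- mean(diff(tr$time_min))
    dx <- diff(tr$x_um); dy <- diff(tr$y_um)
    nrm <- sqrt(dx^2 + dy^2)
    ok <- nrm > 0
    ux <- ifelse(ok, dx / nrm, NA); uy <- ifelse(ok, dy / nrm, NA)
    nv <- length(ux)
    vec_contact <- NULL
    if (!is.null(contact_mask)) {
      m <- as.logical(contact_mask[[ci]])
      if (length(m) != nrow(tr))
        stop("contact mask length must equal the number of frames")
      vec_contact <- m[-length(m)] & m[-1]
    }
    for (lag in seq_len(min(max_lag_frames, nv - 1))) {
      i <- seq_len(nv - lag); j <- i + lag
      keep <- ok[i] & ok[j]
      if (condition == "contact") keep <- keep & vec_contact[i] & vec_contact[j]
      if (condition == "no_contact") keep <- keep & !vec_contact[i] & !vec_contact[j]
      if (!any(keep)) next
      num[lag] <- num[lag] + sum(ux[i][keep] * ux[j][keep] +
                                   uy[i][keep] * uy[j][keep])
      cnt[lag] <- cnt[lag] + sum(keep)
    }
  }
  lag_ok <- cnt > 0
  data.frame(
    lag_min = c(0, seq_len(max_lag_frames)[lag_ok] * dt),
    C = c(1, num[lag_ok] / cnt[lag_ok]),
    n_pairs = c(NA, cnt[lag_ok])
  )
}

#' Exponential persistence-time fit
#'
#' Least-squares fit of \eqn{C(t) = e^{-t/\tau}} to a directional
#' autocorrelation series over a lag window (default 2-200 min; the
#' zero/one-frame lags are excluded to avoid frame-noise bias).
#'
#' @param C_df a [direction_autocorrelation()] result (`lag_min`, `C`).
#' @param lag_window `c(min, max)` lags (min) entering the fit.
#' @return list with `tau` (min), `fit`, `rss`, `n_lags`.
#' @export
fit_persistence_time <- function(C_df, lag_window = c(2, 200)) {
  sel <- C_df$lag_min >= lag_window[1] & C_df$lag_min <= lag_window[2]
  d <- C_df[sel, ]
  if (nrow(d) < 4) stop("at least 4 lags are required in the window")
  pos <- d$C > 0
  tau0 <- if (sum(pos) >= 2)
    unname(-1 / coef(lm(log(d$C[pos]) ~ 0 + d$lag_min[pos]))[1]) else
      mean(d$lag_min)
  if (!is.finite(tau0) || tau0 <= 0) tau0 <- mean(d$lag_min)
  fit <- minpack.lm::nlsLM(C ~ exp(-lag_min / tau), data = d,
                           start = list(tau = tau0),
                           lower = 1e-6, control = list(maxiter = 200))
  list(tau = unname(coef(fit)["tau"]), fit = fit,
       rss = sum(residuals(fit)^2), n_lags = nrow(d))
}

#' Per-frame contact mask of a cell from interface records
#'
#' Builds the logical "in contact with any senescent cell" mask for one
#' normal cell over the recorded frames of a confluent run.
#'
#' @param run a [run_cpm()] result with recorded contacts.
#' @param cell_id normal-cell id.
#' @return logical vector aligned with the recorded frames.
#' @export
contact_mask_for_cell <- function(run, cell_id) {
  times <- sort(unique(run$tracks$mcs))
  sub <- run$contacts[run$contacts$normal_id == cell_id, ]
  times %in% sub$mcs
}

#' Contact-conditioned persistence times of a confluent run
#'
#' Convenience pipeline: builds per-normal-cell trajectories and contact
#' masks from a recorded confluent run, accumulates the directional
#' autocorrelation under both conditions, and fits the exponential
#' persistence time of each.
#'
#' @param run a [run_cpm()] result with recorded contacts.
#' @param lag_window lags (min) entering the exponential fits; the
#'   default starts above one 2-min frame to avoid frame-noise bias.
#' @param max_lag_frames largest autocorrelation lag evaluated.
#' @return list with `tau_contact`, `tau_no_contact`, `ratio`, and the
#'   two autocorrelation data.frames.
#' @export
persistence_times <- function(run, lag_window = c(4, 300),
                              max_lag_frames = 150L) {
  tab <- run$table
  if (is.null(tab)) tab <- tracks_to_table(run)
  ids <- run$state$cells$id[run$state$cells$phenotype == "normal"]
  trajs <- lapply(ids, function(id)
    tab[tab$cell_id == id, c("time_min", "x_um", "y_um")])
  masks <- lapply(ids, function(id) contact_mask_for_cell(run, id))
  Cc <- direction_autocorrelation(trajs, masks, condition = "contact",
                                  max_lag_frames = max_lag_frames)
  Cn <- direction_autocorrelation(trajs, masks, condition = "no_contact",
                                  max_lag_frames = max_lag_frames)
  fc <- fit_persistence_time(Cc, lag_window)
  fn <- fit_persistence_time(Cn, lag_window)
  list(tau_contact = fc$tau, tau_no_contact = fn$tau,
       ratio = fc$tau / fn$tau, C_contact = Cc, C_no_contact = Cn)
}
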