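#' Savitzky-Golay smoothing configuration
#'
#' @param order polynomial order `k` (default 4).
#' @param window window length `m` in samples (default 9; must be odd
#'   and larger than `order`).
#' @return object of class `smoothing_config`.
#' @export
smoothing_config <- function(order = 4, window = 9) {
  if (window %% 2 != 1 || window <= order)
    stop("window must be odd and larger than the polynomial order")
  structure(list(order = order, window = window), class = "smoothing_config")
}

#' Smooth a trajectory and derive speed and angular velocity
#'
#' Positions and the unit-circle components of the orientation are
#' smoothed with a Savitzky-Golay filter; speed comes from the
#' analytic derivative of the smoothed positions. The angular velocity
#' is computed from the derivatives of the smoothed circle components,
#' `omega = -thetadot_x / theta_y` or `thetadot_y / theta_x`, choosing
#' whichever denominator is larger in magnitude; the wrapped angle is
#' never differentiated directly, so headings near the 0/360 branch
#' cut are handled exactly. Samples within half a window of either end
#' are flagged invalid.
#'
#' @param trajectory data.frame with columns `t` (s, uniform), `x`,
#'   `y` (mm), `theta` (deg, 0 = upwind).
#' @param cfg a [smoothing_config()].
#' @return object of class `kinematics_trace`: data.frame with columns
#'   `t`, `x`, `y`, `theta`, `theta_plus`, `v` (mm/s), `omega`
#'   (deg/s), `valid`, and attribute `time_step`.
#' @export
smooth_and_differentiate <- function(trajectory, cfg = smoothing_config()) {
  n <- nrow(trajectory)
  if (n < cfg$window) stop("trajectory shorter than the smoothing window")
  dts <- diff(trajectory$t)
  dt <- stats::median(dts)
  if (any(abs(dts - dt) > 1e-6 * dt)) stop("non-uniform sampling")
  k <- cfg$order; m <- cfg$window
  sg <- function(z, deriv = 0) signal::sgolayfilt(z, p = k, n = m,
                                                  m = deriv, ts = dt)
  xs <- sg(trajectory$x); ys <- sg(trajectory$y)
  vx <- sg(trajectory$x, 1); vy <- sg(trajectory$y, 1)
  th <- trajectory$theta * pi / 180
  cx <- sg(cos(th)); cy <- sg(sin(th))
  dx <- sg(cos(th), 1); dy <- sg(sin(th), 1)
  omega_rad <- ifelse(abs(cy) >= abs(cx), -dx / cy, dy / cx)
  theta_s <- wrap360(atan2(cy, cx) * 180 / pi)
  half <- (m - 1) / 2
  valid <- rep(TRUE, n)
  valid[seq_len(half)] <- FALSE
  valid[(n - half + 1):n] <- FALSE
  out <- data.frame(t = trajectory$t, x = xs, y = ys, theta = theta_s,
                    theta_plus = theta_plus(theta_s),
                    v = sqrt(vx^2 + vy^2),
                    omega = omega_rad * 180 / pi, valid = valid)
  structure(out, time_step = dt, smoothing = cfg,
            class = c("kinematics_trace", "data.frame"))
}

#' Event detection configuration
#'
#' Thresholds and persistence minima for behavioral segmentation.
#'
#' @param stop_speed_threshold stop when `v` falls below this (mm/s).
#' @param stop_min_duration persistence for stop onsets/offsets (s).
#' @param turn_omega_threshold turn when `|omega|` exceeds this (deg/s).
#' @param turn_min_duration persistence for turns (s).
#' @param dtheta_window centered window over which the per-turn
#'   orientation change is measured (s); covers the full extent of a
#'   stereotyped saccade.
#' @return object of class `event_config`.
#' @export
event_config <- function(stop_speed_threshold = 2, stop_min_duration = 0.3,
                         turn_omega_threshold = 200,
                         turn_min_duration = 0.02,
                         dtheta_window = 0.2) {
  for (nm in c("stop_speed_threshold", "stop_min_duration",
               "turn_omega_threshold", "turn_min_duration", "dtheta_window"))
    check_scalar(get(nm), nm)
  structure(list(stop_speed_threshold = stop_speed_threshold,
                 stop_min_duration = stop_min_duration,
                 turn_omega_threshold = turn_omega_threshold,
                 turn_min_duration = turn_min_duration,
                 dtheta_window = dtheta_window), class = "event_config")
}

# signed orientation change between two samples, accumulated through
# per-step wrapped differences so multiples of 360 are kept
unwrapped_dtheta <- function(theta, i0, i1) {
  if (i1 <= i0) return(0)
  d <- diff(theta[i0:i1])
  d <- (d + 180) %% 360 - 180
  sum(d)
}

#' Segment a trace into stops, walks, and turns
#'
#' Stops are intervals where the speed stays below
#' `stop_speed_threshold` with the symmetric persistence rule (both
#' onset and offset must hold for `stop_min_duration`); walks are the
#' complement, so the two tile the valid timeline. Turns are intervals
#' where `|omega|` exceeds `turn_omega_threshold` for at least
#' `turn_min_duration`, restricted to walks. Each turn's signed
#' orientation change is measured over a centered `dtheta_window` (and
#' also onset-to-offset, reported as `dtheta_event`); its direction is
#' upwind if theta+ decreases over the window.
#'
#' @param trace a [smooth_and_differentiate()] result.
#' @param cfg an [event_config()].
#' @return object of class `event_series`: list with `turns`, `bouts`
#'   (data.frames), `state` (per-timestep `"walk"`/`"stop"`/NA), `t`,
#'   and `time_step`.
#' @export
detect_events <- function(trace, cfg = event_config()) {
  stopifnot(inherits(trace, "kinematics_trace"))
  dt <- attr(trace, "time_step")
  n <- nrow(trace)
  vidx <- which(trace$valid)
  state <- rep(NA_character_, n)
  turns <- data.frame(onset = numeric(0), offset = numeric(0),
                      midpoint = numeric(0), dtheta = numeric(0),
                      dtheta_event = numeric(0), direction = character(0))
  bouts <- data.frame(type = character(0), onset = numeric(0),
                      offset = numeric(0), duration = numeric(0))
  if (length(vidx) > 0) {
    rng <- vidx[1]:vidx[length(vidx)]
    stop_steps <- max(1L, round(cfg$stop_min_duration / dt))
    stopped <- apply_persistence(trace$v[rng] < cfg$stop_speed_threshold,
                                 stop_steps)
    state[rng] <- ifelse(stopped, "stop", "walk")
    b <- rle(stopped)
    ends <- cumsum(b$lengths); starts <- ends - b$lengths + 1L
    bouts <- data.frame(
      type = ifelse(b$values, "stop", "walk"),
      onset = trace$t[rng[starts]],
      offset = trace$t[rng[ends]] + dt,
      duration = b$lengths * dt)
    turn_steps <- max(1L, round(cfg$turn_min_duration / dt))
    turning <- apply_persistence(
      abs(trace$omega[rng]) > cfg$turn_omega_threshold, turn_steps)
    turning <- turning & !stopped   # turns lie within walks
    tr <- rle(turning)
    tends <- cumsum(tr$lengths); tstarts <- tends - tr$lengths + 1L
    keep <- which(tr$values)
    if (length(keep) > 0) {
      half_w <- round(cfg$dtheta_window / (2 * dt))
      rowsl <- lapply(keep, function(j) {
        i0 <- rng[tstarts[j]]; i1 <- rng[tends[j]]
        mid <- round((i0 + i1) / 2)
        w0 <- max(1L, mid - half_w); w1 <- min(n, mid + half_w)
        dth <- unwrapped_dtheta(trace$theta, w0, w1)
        dth_ev <- unwrapped_dtheta(trace$theta, i0, i1)
        dirn <- if (trace$theta_plus[w1] < trace$theta_plus[w0])
          "upwind" else "downwind"
        data.frame(onset = trace$t[i0], offset = trace$t[i1] + dt,
                   midpoint = trace$t[mid], dtheta = dth,
                   dtheta_event = dth_ev, direction = dirn)
      })
      turns <- do.call(rbind, rowsl)
      turns <- turns[abs(turns$dtheta) > 0, , drop = FALSE]
    }
  }
  structure(list(turns = turns, bouts = bouts, state = state,
                 t = trace$t, time_step = dt),
            class = "event_series")
}

#' @export
print.event_series <- function(x, ...) {
  cat(sprintf("<event_series> %d turns, %d walk bouts, %d stop bouts\n",
              nrow(x$turns), sum(x$bouts$type == "walk"),
              sum(x$bouts$type == "stop")))
  invisible(x)
}

#' Turn discreteness analysis
#'
#' Verifies that turns are discrete saccades rather than an artifact
#' of the angular-speed threshold: for each threshold, turns are
#' re-detected and the positive mode of the orientation-change
#' distribution is computed over a centered window of increasing
#' length. For genuinely discrete saccades the mode rises with the
#' window and plateaus once the window covers a whole saccade; for
#' continuous meandering it grows without plateau.
#'
#' @param trace a [smooth_and_differentiate()] result.
#' @param omega_thresholds angular-speed thresholds (deg/s).
#' @param windows window lengths (s).
#' @param cfg base [event_config()].
#' @return data.frame with columns `threshold`, `window`,
#'   `peak_angle` (deg; NA with fewer than 50 turns), `n_turns`.
#' @export
turn_discreteness_analysis <- function(trace,
                                       omega_thresholds = c(150, 200, 250),
                                       windows = seq(0.05, 0.35, by = 0.05),
                                       cfg = event_config()) {
  out <- list()
  for (thr in omega_thresholds) {
    for (w in windows) {
      c2 <- cfg; c2$turn_omega_threshold <- thr; c2$dtheta_window <- w
      ev <- detect_events(trace, c2)
      pk <- NA_real_
      if (nrow(ev$turns) >= 50) {
        pos <- ev$turns$dtheta
        dens <- stats::density(pos)
        sel <- dens$x > 0
        pk <- dens$x[sel][which.max(dens$y[sel])]
      }
      out[[length(out) + 1L]] <- data.frame(
        threshold = thr, window = w, peak_angle = pk,
        n_turns = nrow(ev$turns))
    }
  }
  do.call(rbind, out)
}

#' Empirical per-timestep transition rates
#'
#' Within each snippet made of one walk bout followed by one stop
#' bout, the empirical walk-to-stop rate is the reciprocal of that
#' walk's duration, held constant over the snippet; analogously the
#' stop-to-walk rate over each stop-then-walk snippet. Rates therefore
#' update at bout onsets.
#'
#' @param events an [detect_events()] result.
#' @return data.frame with columns `t`, `lambda_ws`, `lambda_sw`
#'   (NA outside defined snippets); zero rows if no complete pair
#'   exists.
#' @export
empirical_transition_rates <- function(events) {
  b <- events$bouts
  if (nrow(b) < 2L)
    return(data.frame(t = numeric(0), lambda_ws = numeric(0),
                      lambda_sw = numeric(0)))
  t <- events$t
  lws <- rep(NA_real_, length(t)); lsw <- rep(NA_real_, length(t))
  for (i in seq_len(nrow(b) - 1L)) {
    span <- t >= b$onset[i] & t < b$offset[i + 1]
    if (b$type[i] == "walk" && b$type[i + 1] == "stop")
      lws[span] <- 1 / b$duration[i]
    if (b$type[i] == "stop" && b$type[i + 1] == "walk")
      lsw[span] <- 1 / b$duration[i]
  }
  keep <- !is.na(lws) | !is.na(lsw)
  data.frame(t = t[keep], lambda_ws = lws[keep], lambda_sw = lsw[keep])
}
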