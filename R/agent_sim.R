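#' Agent parameters for the plume navigator
#'
#' A four-state virtual fly (walk, stop, instantaneous left/right
#' saccades) whose decisions are driven by the fitted stochastic
#' models: saccade times and sigmoid-biased directions from the turn
#' model, walk-to-stop transitions from `stop_spec`, and stop-to-walk
#' transitions from `walk_spec`. The defaults use the median fitted
#' parameters of the best models (last-encounter stopping,
#' accumulated-evidence walking).
#'
#' @param walk_speed walking speed (mm/s), default 10.1 (mean of
#'   tracked flies).
#' @param turn_params a [turn_model_params()].
#' @param stop_spec a [rate_model_spec()] with direction `walk_to_stop`.
#' @param walk_spec a [rate_model_spec()] with direction `stop_to_walk`.
#' @param antenna an [antenna_geometry()].
#' @param encounter_refractory minimum time between registered
#'   encounter onsets (s), default 0.1.
#' @param min_encounter_duration persistence required before an onset
#'   is registered (s), default 0.05; applied causally (the onset is
#'   logged at the first step of the qualifying excursion).
#' @param time_step s, default 1/90.
#' @return object of class `agent_params`.
#' @export
agent_params <- function(walk_speed = 10.1,
                         turn_params = turn_model_params(),
                         stop_spec = rate_model_spec(
                           "last_encounter", "walk_to_stop",
                           list(lambda0 = 0.78, dlambda = -0.61, tau = 0.25)),
                         walk_spec = rate_model_spec(
                           "accumulated_evidence", "stop_to_walk",
                           list(lambda0 = 0.29, dlambda = 0.41, tau = 0.52)),
                         antenna = antenna_geometry(),
                         encounter_refractory = 0.1,
                         min_encounter_duration = 0.05,
                         time_step = 1 / 90) {
  if (walk_speed < 0) stop("walk_speed must be non-negative")
  if (encounter_refractory < 0) stop("refractory must be non-negative")
  if (stop_spec$direction != "walk_to_stop" ||
      walk_spec$direction != "stop_to_walk")
    stop("stop_spec/walk_spec direction mismatch")
  structure(list(walk_speed = walk_speed, turn_params = turn_params,
                 stop_spec = stop_spec, walk_spec = walk_spec,
                 antenna = antenna,
                 encounter_refractory = encounter_refractory,
                 min_encounter_duration = min_encounter_duration,
                 time_step = time_step),
            class = "agent_params")
}

#' Arena configuration for agent simulations
#'
#' @param extent 2-vector (mm): downwind length and cross-wind width.
#' @param source_box_length downwind extent of the arrival box (mm).
#' @param source_box_width cross-wind extent of the arrival box (mm),
#'   centered on the source.
#' @param start_margin distance of the start line from the downwind
#'   wall (mm).
#' @return object of class `arena_config`.
#' @export
arena_config <- function(extent = c(300, 180), source_box_length = 20,
                         source_box_width = 20, start_margin = 5) {
  if (source_box_length > extent[1] || source_box_width > extent[2])
    stop("source box must fit inside the arena")
  structure(list(extent = extent, source_box_length = source_box_length,
                 source_box_width = source_box_width,
                 start_margin = start_margin),
            class = "arena_config")
}

# rate of a spec given the agents' internal sensory state; `a` is the
# spec's own evidence accumulator, `dT` the time since last onset,
# `d` the current above-threshold indicator
agent_rate <- function(spec, dT, a, d) {
  p <- spec$params
  switch(spec$family,
    last_encounter = p$lambda0 + p$dlambda * exp(-dT / p$tau),
    accumulated_evidence = if (spec$direction == "walk_to_stop")
      p$lambda0 + p$lambda1 / (1 + p$lambda2 * a)
      else p$lambda0 + p$dlambda * a,
    encounter_duration = p$lambda_enc * d + p$lambda_blank * (1 - d),
    constant = rep(p$lambda0, length(dT)))
}

spec_tau <- function(spec) {
  if (!is.null(spec$params$tau)) spec$params$tau else Inf
}

#' Run an ensemble of agents through a plume
#'
#' Agents start at random positions along the downwind wall with
#' uniform headings. Each step they sample their virtual antenna from
#' the plume (analytic field evaluation plus background noise),
#' register encounter onsets (threshold at `mean + 2.5 sd` of the
#' configured background, with causal persistence and a refractory
#' period), update their filtered signals and model rates, draw
#' stop/walk transitions and saccades, and advance while walking.
#' Agents reaching a wall are reflected. A field shorter than the
#' simulation is looped.
#'
#' @param plume a [plume_field()] (or a [plume_config()], in which
#'   case a field covering the run is simulated first).
#' @param params an [agent_params()].
#' @param arena an [arena_config()].
#' @param n_agents number of agents.
#' @param n_steps number of time steps.
#' @param seed integer seed.
#' @param keep_traces store per-step position/heading/signal/state
#'   matrices (needed by [occupancy_pdf()] trajectory filters).
#' @param antenna_samples evaluation points across the antenna ellipse.
#' @return object of class `agent_sim_result`.
#' @export
run_agents <- function(plume, params, arena = arena_config(),
                       n_agents = 500, n_steps = 5400, seed = 1L,
                       keep_traces = TRUE, antenna_samples = 3L) {
  if (inherits(plume, "plume_config"))
    plume <- plume_field(plume, n_steps * params$time_step, seed = seed)
  stopifnot(inherits(plume, "plume_field"), inherits(params, "agent_params"))
  cfg <- plume$config
  dt <- params$time_step
  if (abs(dt - plume$time_step) > 1e-12)
    stop("agent time step must match the plume frame interval")
  if (any(abs(arena$extent - cfg$arena_size) > 1e-9))
    stop("arena extent does not match the plume configuration")
  thr <- cfg$background_mean + 2.5 * cfg$background_noise_sd
  min_run <- max(1L, as.integer(ceiling(params$min_encounter_duration / dt - 1e-9)))
  refr_steps <- round(params$encounter_refractory / dt)
  tp <- params$turn_params
  tau_f <- tp$filter_tau
  tau_s <- spec_tau(params$stop_spec)
  tau_w <- spec_tau(params$walk_spec)
  qf <- exp(-dt / tau_f); qs <- exp(-dt / tau_s); qw <- exp(-dt / tau_w)

  set.seed(seed)
  x <- rep(arena$extent[1] - arena$start_margin, n_agents)
  y <- stats::runif(n_agents, -arena$extent[2] / 2, arena$extent[2] / 2)
  theta <- stats::runif(n_agents, 0, 360)
  walking <- rep(TRUE, n_agents)
  a_freq <- a_dur <- a_stop <- a_walk <- numeric(n_agents)
  run_len <- integer(n_agents)
  last_onset_step <- rep(-1e9, n_agents)
  onset_open <- rep(FALSE, n_agents)     # current excursion already logged
  arrived <- rep(FALSE, n_agents)
  arrival_time <- rep(NA_real_, n_agents)
  n_onsets <- integer(n_agents)
  n_turns <- n_up <- 0L
  bout_start <- rep(1L, n_agents)
  walk_durs <- list(); stop_durs <- list()
  occ_bin <- 1
  nx_occ <- ceiling(arena$extent[1] / occ_bin)
  ny_occ <- ceiling(arena$extent[2] / occ_bin)
  occ <- matrix(0, ny_occ, nx_occ)
  if (keep_traces) {
    TRX <- matrix(0, n_steps, n_agents); TRY <- TRX; TRTH <- TRX
    TRS <- TRX; TRW <- matrix(FALSE, n_steps, n_agents)
  }
  # antenna sample offsets in the (along, perpendicular) frame
  offs <- cbind(c(0, 0, 0), c(0, -0.6, 0.6) * params$antenna$semi_major)
  offs <- offs[seq_len(min(antenna_samples, 3L)), , drop = FALSE]
  half_y <- arena$extent[2] / 2

  for (i in seq_len(n_steps)) {
    frame <- (i - 1L) %% plume$n_frames + 1L
    h <- heading_vector(theta)
    ax <- x + params$antenna$offset * h[, 1]
    ay <- y + params$antenna$offset * h[, 2]
    pts <- matrix(0, n_agents * nrow(offs), 2)
    for (k in seq_len(nrow(offs))) {
      idx <- ((k - 1) * n_agents + 1):(k * n_agents)
      pts[idx, 1] <- ax + offs[k, 1] * h[, 1] - offs[k, 2] * h[, 2]
      pts[idx, 2] <- ay + offs[k, 1] * h[, 2] + offs[k, 2] * h[, 1]
    }
    sig <- field_intensity(plume, frame, pts)
    sig <- rowMeans(matrix(sig, n_agents)) +
      stats::rnorm(n_agents, cfg$background_mean, cfg$background_noise_sd)
    sig <- pmin(pmax(sig, 0), 255)
    above <- sig > thr
    run_len <- ifelse(above, run_len + 1L, 0L)
    onset_open <- onset_open & above
    new_onset <- above & !onset_open & run_len >= min_run &
      (i - last_onset_step) >= refr_steps
    if (any(new_onset)) {
      last_onset_step[new_onset] <- i
      onset_open[new_onset] <- TRUE
      n_onsets[new_onset] <- n_onsets[new_onset] + 1L
    }
    # filtered signals and evidence accumulators (unit jump per onset)
    a_freq <- a_freq * qf + new_onset
    a_dur <- a_dur * qf + above * dt
    a_stop <- a_stop * qs + new_onset
    a_walk <- a_walk * qw + new_onset
    w_freq <- a_freq / tau_f
    dT <- (i - last_onset_step) * dt

    lam_ws <- agent_rate(params$stop_spec, dT, a_stop, above)
    lam_sw <- agent_rate(params$walk_spec, dT, a_walk, above)
    u <- stats::runif(n_agents)
    to_stop <- walking & (u < dt * lam_ws)
    to_walk <- !walking & (u < dt * lam_sw)
    if (any(to_stop)) {
      walk_durs[[length(walk_durs) + 1L]] <- (i - bout_start[to_stop]) * dt
      bout_start[to_stop] <- i
    }
    if (any(to_walk)) {
      stop_durs[[length(stop_durs) + 1L]] <- (i - bout_start[to_walk]) * dt
      bout_start[to_walk] <- i
    }
    walking <- ifelse(walking, !to_stop, to_walk)

    lam_t <- full_turn_rate(tp, w_freq, a_dur)
    turn <- walking & (stats::runif(n_agents) < dt * lam_t)
    if (any(turn)) {
      k <- which(turn)
      mag <- draw_turn_magnitudes(tp, length(k))
      p_t <- if (!is.null(tp$fixed_p_upwind)) rep(tp$fixed_p_upwind, length(k))
        else upwind_turn_probability(a_freq[k], tp$alpha)
      up <- stats::runif(length(k)) < p_t
      s_up <- turn_mu_upwind(theta[k], 1)
      theta[k] <- wrap360(theta[k] + mag * ifelse(up, s_up, -s_up))
      n_turns <- n_turns + length(k); n_up <- n_up + sum(up)
    }
    jit <- walking & !turn
    if (any(jit) && tp$straight_jitter_sd > 0)
      theta[jit] <- wrap360(theta[jit] +
        stats::rnorm(sum(jit), 0, tp$straight_jitter_sd))

    h <- heading_vector(theta)
    # arrived agents keep moving; arrival is latched separately
    x_new <- x + ifelse(walking, params$walk_speed * dt * h[, 1], 0)
    y_new <- y + ifelse(walking, params$walk_speed * dt * h[, 2], 0)
    out_x <- x_new < 0 | x_new > arena$extent[1]
    out_y <- y_new < -half_y | y_new > half_y
    if (any(out_x)) {
      theta[out_x] <- wrap360(180 - theta[out_x])
      x_new[out_x] <- pmin(pmax(x_new[out_x], 0), arena$extent[1])
    }
    if (any(out_y)) {
      theta[out_y] <- wrap360(-theta[out_y])
      y_new[out_y] <- pmin(pmax(y_new[out_y], -half_y), half_y)
    }
    x <- x_new; y <- y_new
    hit <- !arrived & x <= arena$source_box_length &
      abs(y) <= arena$source_box_width / 2
    if (any(hit)) {
      arrived[hit] <- TRUE
      arrival_time[hit] <- i * dt
    }
    ix <- pmin(pmax(ceiling(x / occ_bin), 1L), nx_occ)
    iy <- pmin(pmax(ceiling((y + half_y) / occ_bin), 1L), ny_occ)
    lin <- (ix - 1L) * ny_occ + iy
    occ_add <- tabulate(lin, nbins = nx_occ * ny_occ)
    occ <- occ + matrix(occ_add, ny_occ, nx_occ)
    if (keep_traces) {
      TRX[i, ] <- x; TRY[i, ] <- y; TRTH[i, ] <- theta
      TRS[i, ] <- sig; TRW[i, ] <- walking
    }
  }
  # close censored bouts
  open_w <- (n_steps + 1L - bout_start)[walking] * dt
  open_s <- (n_steps + 1L - bout_start)[!walking] * dt
  structure(list(
    n_agents = n_agents, n_steps = n_steps, time_step = dt,
    arrived = arrived, arrival_time = arrival_time,
    n_onsets = n_onsets,
    walk_durations = unlist(walk_durs) %||% numeric(0),
    stop_durations = unlist(stop_durs) %||% numeric(0),
    censored_walk = open_w, censored_stop = open_s,
    n_turns = n_turns, n_upwind_turns = n_up,
    occupancy = list(counts = occ, bin = occ_bin,
                     x = seq(occ_bin / 2, by = occ_bin, length.out = nx_occ),
                     y = seq(-half_y + occ_bin / 2, by = occ_bin,
                             length.out = ny_occ)),
    traces = if (keep_traces)
      list(x = TRX, y = TRY, theta = TRTH, signal = TRS, walking = TRW),
    params = params, arena = arena, threshold = thr,
    plume_config = cfg
  ), class = "agent_sim_result")
}

#' @export
print.agent_sim_result <- function(x, ...) {
  cat(sprintf(
    "<agent_sim_result> %d agents x %d steps; %.1f%% arrived; %d turns\n",
    x$n_agents, x$n_steps, 100 * mean(x$arrived), x$n_turns))
  invisible(x)
}

#' Ablate one navigational component
#'
#' Replaces an encounter-modulated component with its ensemble
#' average from a reference (full-model) simulation, retaining the
#' overall bias but removing the dependence on encounters:
#' * `stop`: walk-to-stop rate set constant to the reciprocal of the
#'   exponential-fit timescale of the reference walk durations;
#' * `walk`: analogous from the reference stop durations;
#' * `turn`: the sigmoid replaced by the reference's overall fraction
#'   of upwind turns.
#'
#' @param params an [agent_params()].
#' @param component `"turn"`, `"stop"`, or `"walk"`.
#' @param reference an [run_agents()] result from the full model.
#' @return modified `agent_params`.
#' @export
ablate <- function(params, component = c("turn", "stop", "walk"), reference) {
  component <- match.arg(component)
  stopifnot(inherits(reference, "agent_sim_result"))
  if (component == "turn") {
    if (reference$n_turns == 0) stop("reference has no turns")
    params$turn_params$fixed_p_upwind <-
      reference$n_upwind_turns / reference$n_turns
  } else if (component == "stop") {
    if (length(reference$walk_durations) == 0)
      stop("reference has no completed walk bouts")
    params$stop_spec <- rate_model_spec(
      "constant", "walk_to_stop",
      list(lambda0 = 1 / mean(reference$walk_durations)))
  } else {
    if (length(reference$stop_durations) == 0)
      stop("reference has no completed stop bouts")
    params$walk_spec <- rate_model_spec(
      "constant", "stop_to_walk",
      list(lambda0 = 1 / mean(reference$stop_durations)))
  }
  params
}

#' Navigation performance relative to a control
#'
#' Fractional change in source arrivals, `100 (N_i - N_C) / N_C`, and
#' fractional reduction in mean arrival time, `100 (T_C - T_i) / T_C`,
#' with bootstrap standard errors (resampling agents with
#' replacement).
#'
#' @param result an [run_agents()] result.
#' @param control the control [run_agents()] result (same arena and
#'   plume).
#' @param n_boot bootstrap replicates, default 30.
#' @param seed bootstrap seed.
#' @return data.frame with rows `arrival_fraction` and `arrival_time`
#'   and columns `value`, `se` (percent). NA with a message when the
#'   control has no arrivals.
#' @export
performance_metrics <- function(result, control, n_boot = 30, seed = 1L) {
  if (!isTRUE(all.equal(result$arena$extent, control$arena$extent)))
    stop("results are from different arenas")
  Ni <- sum(result$arrived); Nc <- sum(control$arrived)
  if (Nc == 0) {
    message("control has no arrivals; metrics undefined")
    return(data.frame(metric = c("arrival_fraction", "arrival_time"),
                      value = NA_real_, se = NA_real_))
  }
  Ti <- mean(result$arrival_time[result$arrived])
  Tc <- mean(control$arrival_time[control$arrived])
  v1 <- 100 * (Ni - Nc) / Nc
  v2 <- 100 * (Tc - Ti) / Tc
  set.seed(seed)
  b1 <- b2 <- numeric(n_boot)
  for (b in seq_len(n_boot)) {
    ri <- sample.int(result$n_agents, replace = TRUE)
    rc <- sample.int(control$n_agents, replace = TRUE)
    ni <- sum(result$arrived[ri]); nc <- sum(control$arrived[rc])
    b1[b] <- if (nc > 0) 100 * (ni - nc) / nc else NA
    ti <- mean(result$arrival_time[ri][result$arrived[ri]])
    tc <- mean(control$arrival_time[rc][control$arrived[rc]])
    b2[b] <- if (is.finite(ti) && is.finite(tc) && tc > 0)
      100 * (tc - ti) / tc else NA
  }
  data.frame(metric = c("arrival_fraction", "arrival_time"),
             value = c(v1, v2),
             se = c(stats::sd(b1, na.rm = TRUE), stats::sd(b2, na.rm = TRUE)))
}

#' Occupancy probability density of an agent ensemble
#'
#' Position histogram on a 1 mm grid, normalized over visited bins,
#' after the trajectory filters used for arena occupancy maps:
#' trajectories shorter than 5 s, with mean speed below 2 mm/s, or
#' with net displacement below 50 mm are excluded. Unvisited bins are
#' NA (distinct from zero probability). Marginals are computed after
#' excluding the front of the arena near the source.
#'
#' @param result an [run_agents()] result with stored traces.
#' @param bin bin size (mm), default 1.
#' @param exclude_front downwind extent (mm) excluded from the
#'   marginals, default 20.
#' @param min_duration,min_speed,min_displacement trajectory filters.
#' @return list with `pdf` (matrix, NA where unvisited), `x`, `y`,
#'   `marginal_x`, `marginal_y`, `n_kept`; empty (with a warning) if
#'   all trajectories are filtered out.
#' @export
occupancy_pdf <- function(result, bin = 1, exclude_front = 20,
                          min_duration = 5, min_speed = 2,
                          min_displacement = 50) {
  stopifnot(inherits(result, "agent_sim_result"))
  if (is.null(result$traces))
    stop("occupancy_pdf needs traces; rerun with keep_traces = TRUE")
  dt <- result$time_step
  dur <- result$n_steps * dt
  X <- result$traces$x; Y <- result$traces$y
  n <- result$n_agents
  keep <- logical(n)
  for (j in seq_len(n)) {
    path <- sum(sqrt(diff(X[, j])^2 + diff(Y[, j])^2))
    disp <- sqrt((X[result$n_steps, j] - X[1, j])^2 +
                 (Y[result$n_steps, j] - Y[1, j])^2)
    keep[j] <- dur >= min_duration && path / dur >= min_speed &&
      disp >= min_displacement
  }
  if (!any(keep)) {
    warning("all trajectories filtered out")
    return(list(pdf = NULL, n_kept = 0L))
  }
  ext <- result$arena$extent
  xb <- seq(0, ext[1], by = bin); yb <- seq(-ext[2] / 2, ext[2] / 2, by = bin)
  h <- matrix(0, length(yb) - 1, length(xb) - 1)
  for (j in which(keep)) {
    ix <- pmin(pmax(findInterval(X[, j], xb, all.inside = TRUE), 1L),
               length(xb) - 1)
    iy <- pmin(pmax(findInterval(Y[, j], yb, all.inside = TRUE), 1L),
               length(yb) - 1)
    h <- h + matrix(tabulate((ix - 1L) * (length(yb) - 1) + iy,
                             nbins = length(h)), nrow(h))
  }
  pdf <- h / sum(h)
  pdf[h == 0] <- NA
  xc <- (xb[-1] + xb[-length(xb)]) / 2
  yc <- (yb[-1] + yb[-length(yb)]) / 2
  sel <- xc > exclude_front
  hz <- h; hz[is.na(hz)] <- 0
  mx <- colSums(h)[sel]; my <- rowSums(h[, sel, drop = FALSE])
  list(pdf = pdf, x = xc, y = yc,
       marginal_x = data.frame(x = xc[sel], p = mx / sum(mx)),
       marginal_y = data.frame(y = yc, p = my / sum(my)),
       n_kept = sum(keep))
}

#' Within-plume mask from a plume field
#'
#' Coarse noiseless intermittency map of the field: the fraction of
#' frames in which the packet intensity exceeds `k_sigma` background
#' SDs at each grid cell. Cells at or above `threshold` define the
#' "within-plume" region used for perceived-frequency statistics.
#'
#' @param field a [plume_field()].
#' @param grid_res grid resolution (mm), default 5.
#' @param threshold intermittency defining "within the plume".
#' @param k_sigma detection multiplier, default 2.5.
#' @return list with `mask` (logical matrix ny x nx), `intermittency`
#'   (matrix), `x`, `y` (cell centers), `res`.
#' @export
plume_mask <- function(field, grid_res = 5, threshold = 0.05,
                       k_sigma = 2.5) {
  cfg <- field$config
  xs <- seq(grid_res / 2, cfg$arena_size[1], by = grid_res)
  ys <- seq(-cfg$arena_size[2] / 2 + grid_res / 2, cfg$arena_size[2] / 2,
            by = grid_res)
  grid <- cbind(rep(xs, each = length(ys)), rep(ys, length(xs)))
  s <- field_point_series(field, grid)
  im <- matrix(colMeans(s > k_sigma * cfg$background_noise_sd),
               length(ys), length(xs))
  list(mask = im >= threshold, intermittency = im, x = xs, y = ys,
       res = grid_res)
}

#' Perceived encounter statistics of an agent ensemble
#'
#' Offline re-detection of encounters on the stored virtual-antenna
#' traces (Gaussian background from the plume configuration, 2.5
#' sigma threshold, symmetric minimum-duration rule), summarising
#' what the navigating agents perceived: the ensemble mean encounter
#' duration, and the ensemble mean encounter onset rate over
#' within-plume navigation time (steps spent inside the plume cone as
#' defined by a [plume_mask()]).
#'
#' @param result an [run_agents()] result with stored traces.
#' @param mask a [plume_mask()] for the plume the agents navigated;
#'   without it the onset rate is computed over all navigation time.
#' @param cfg an [encounter_config()].
#' @return list with `mean_duration` (s), `mean_frequency` (Hz, onsets
#'   per within-plume second), `durations` (pooled vector),
#'   `n_encounters`, `time_in_plume` (s).
#' @export
perceived_encounter_stats <- function(result, mask = NULL,
                                      cfg = encounter_config()) {
  stopifnot(inherits(result, "agent_sim_result"))
  if (is.null(result$traces)) stop("needs traces; rerun with keep_traces = TRUE")
  pc <- result$plume_config
  bg <- structure(list(mean = pc$background_mean,
                       sd = pc$background_noise_sd),
                  class = "background_model")
  dt <- result$time_step
  durations <- numeric(0)
  onsets_in <- 0; time_in <- 0
  for (j in seq_len(result$n_agents)) {
    tr <- signal_trace(result$traces$signal[, j], dt)
    enc <- detect_encounters(tr, bg, cfg)
    durations <- c(durations, enc$intervals$duration)
    if (is.null(mask)) {
      onsets_in <- onsets_in + sum(enc$w)
      time_in <- time_in + length(enc$w) * dt
    } else {
      ix <- pmin(pmax(ceiling(result$traces$x[, j] / mask$res), 1L),
                 length(mask$x))
      iy <- pmin(pmax(ceiling((result$traces$y[, j] +
                               pc$arena_size[2] / 2) / mask$res), 1L),
                 length(mask$y))
      inm <- mask$mask[cbind(iy, ix)]
      onsets_in <- onsets_in + sum(enc$w[inm])
      time_in <- time_in + sum(inm) * dt
    }
  }
  list(mean_duration = mean(durations),
       mean_frequency = onsets_in / time_in,
       durations = durations, n_encounters = length(durations),
       time_in_plume = time_in)
}
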