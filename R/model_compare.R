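#' Simulate walk/stop state sequences from a rate-model pair
#'
#' Per-step thinning of the two inhomogeneous Poisson processes: a
#' walking agent stops with probability `dt * lambda_ws(t)` and a
#' stopped agent resumes walking with probability `dt * lambda_sw(t)`.
#' Both rate traces depend only on the encounter train, so they are
#' precomputed and the states evolve jointly across trains.
#'
#' @param stop_spec a [rate_model_spec()] with direction
#'   `walk_to_stop`.
#' @param walk_spec a [rate_model_spec()] with direction
#'   `stop_to_walk`.
#' @param trains list of [encounter_series()] with equal length and
#'   time step.
#' @param start initial state, `"walk"` or `"stop"`.
#' @param seed integer seed.
#' @return list with `walking` (logical matrix `n_steps x n_trains`)
#'   and `time_step`.
#' @export
simulate_state_sequences <- function(stop_spec, walk_spec, trains,
                                     start = "walk", seed = 1L) {
  if (stop_spec$direction != "walk_to_stop")
    stop("stop_spec must have direction walk_to_stop")
  if (walk_spec$direction != "stop_to_walk")
    stop("walk_spec must have direction stop_to_walk")
  dt <- trains[[1]]$time_step
  n <- length(trains[[1]]$w)
  for (tr in trains)
    if (abs(tr$time_step - dt) > 1e-12 || length(tr$w) != n)
      stop("trains have mismatched time steps or lengths")
  m <- length(trains)
  set.seed(seed)
  walking <- matrix(FALSE, n, m)
  # exact inverse-CDF sampling of the per-step Bernoulli transition
  # chain: the transition into step i is decided with the rate at step
  # i (matching the likelihood's event terms), and the first step after
  # a bout onset at s that can carry a transition is s + 1. Cumulative
  # discrete hazards h_i = -log(1 - dt lambda_i) turn each bout into a
  # single exponential draw located by findInterval.
  for (j in seq_len(m)) {
    tr <- trains[[j]]
    cum_ws <- cumsum(-log1p(-dt * rate_trace(stop_spec, tr$w, tr$d, dt)))
    cum_sw <- cumsum(-log1p(-dt * rate_trace(walk_spec, tr$w, tr$d, dt)))
    s <- 1L
    cur <- (start == "walk")
    col <- logical(n)
    while (s <= n) {
      cum <- if (cur) cum_ws else cum_sw
      e <- stats::rexp(1)
      # first index i > s with cum[i] - cum[s] >= e
      nxt <- findInterval(cum[s] + e, cum, left.open = TRUE) + 1L
      end <- min(nxt - 1L, n)
      col[s:end] <- cur
      s <- end + 1L
      cur <- !cur
    }
    walking[, j] <- col
  }
  list(walking = walking, time_step = dt)
}

#' Simulate ground-truth-labeled behavior
#'
#' Couples the walk/stop rate models with the saccade model on given
#' encounter trains: states evolve by per-step thinning of the two
#' transition rates, and saccades (with sigmoid-biased direction) and
#' orientation jitter occur only during walks. Used to generate
#' labeled synthetic flies with known parameters for recovery tests.
#'
#' @param turn_params a [turn_model_params()].
#' @param stop_spec,walk_spec [rate_model_spec()] objects for
#'   `walk_to_stop` and `stop_to_walk`.
#' @param trains list of [encounter_series()].
#' @param seed integer seed.
#' @return object of class `ground_truth_behavior`: list with
#'   `walking` (matrix), `theta` (matrix), `turns` (data.frame),
#'   `trains`, `time_step`, and the generating parameters.
#' @export
simulate_ground_truth_behavior <- function(turn_params, stop_spec,
                                           walk_spec, trains, seed = 1L) {
  st <- simulate_state_sequences(stop_spec, walk_spec, trains,
                                 seed = derive_seed(seed, "states"))
  tm <- simulate_turn_ensemble(turn_params, trains,
                               walking = st$walking,
                               seed = derive_seed(seed, "turns"))
  structure(list(walking = st$walking, theta = tm$theta,
                 w_freq = tm$w_freq, turns = tm$turns, trains = trains,
                 time_step = st$time_step,
                 turn_params = turn_params, stop_spec = stop_spec,
                 walk_spec = walk_spec),
            class = "ground_truth_behavior")
}

#' Convert ground-truth behavior to bout data
#'
#' @param gt a [simulate_ground_truth_behavior()] result.
#' @return a [bout_data()].
#' @export
as_bout_data <- function(gt) {
  stopifnot(inherits(gt, "ground_truth_behavior"))
  seqs <- lapply(seq_along(gt$trains), function(j)
    list(walking = gt$walking[, j], w = gt$trains[[j]]$w,
         d = gt$trains[[j]]$d, dt = gt$time_step))
  bout_data(seqs, dt = gt$time_step)
}

#' Convert ground-truth behavior to turn-likelihood data
#'
#' Uses the generating turn labels (one turn step per saccade, with
#' its true direction), the trains' filtered signals, and per-step
#' orientation changes.
#'
#' @param gt a [simulate_ground_truth_behavior()] result.
#' @param filter_tau filter timescale (s) for `W_freq`/`W_dur`.
#' @return a [turn_likelihood_data()].
#' @export
as_turn_data <- function(gt, filter_tau = 2) {
  dt <- gt$time_step
  n <- nrow(gt$theta)
  seqs <- lapply(seq_along(gt$trains), function(j) {
    tr <- gt$trains[[j]]
    th <- gt$theta[, j]
    dth <- c(diff(th), 0)
    dth <- (dth + 180) %% 360 - 180
    turn <- rep(FALSE, n); upwind <- rep(NA, n)
    tj <- gt$turns[gt$turns$traj == j, ]
    turn[tj$step] <- TRUE
    upwind[tj$step] <- tj$upwind
    list(dtheta = dth, theta = th,
         w_freq = exp_filter(tr$w, dt, filter_tau) / filter_tau,
         w_dur = exp_filter(tr$d, dt, filter_tau) * dt,
         walking = gt$walking[, j], turn = turn, upwind = upwind, dt = dt)
  })
  turn_likelihood_data(seqs, dt = dt)
}

#' Classify encounter onsets as isolated or clump leaders
#'
#' An isolated onset has no other onset within `isolation_window` on
#' either side; a clump leader is the first onset of a group of at
#' least `clump_min` onsets within the following `clump_window`.
#'
#' @param enc an [encounter_series()].
#' @param isolation_window s, default 1.
#' @param clump_min minimum onsets per clump, default 3.
#' @param clump_window s, default 1.
#' @return list with integer step vectors `all`, `isolated`, `clump`.
#' @export
classify_onsets <- function(enc, isolation_window = 1, clump_min = 3,
                            clump_window = 1) {
  steps <- which(enc$w > 0)
  dt <- enc$time_step
  if (length(steps) == 0L)
    return(list(all = integer(0), isolated = integer(0), clump = integer(0)))
  t <- (steps - 1) * dt
  iso <- vapply(seq_along(steps), function(i)
    !any(abs(t[-i] - t[i]) <= isolation_window), logical(1))
  clump <- vapply(seq_along(steps), function(i) {
    ahead <- sum(t >= t[i] & t <= t[i] + clump_window)
    before <- any(t < t[i] & t >= t[i] - clump_window)
    ahead >= clump_min && !before
  }, logical(1))
  list(all = steps, isolated = steps[iso], clump = steps[clump])
}

# first event step strictly after each start step; NA when censored
time_to_next_event <- function(event_steps, start_steps, n_steps, dt) {
  if (length(start_steps) == 0L)
    return(data.frame(time = numeric(0), observed = logical(0)))
  idx <- findInterval(start_steps, event_steps) + 1L
  nxt <- ifelse(idx <= length(event_steps), event_steps[idx], NA_integer_)
  observed <- !is.na(nxt)
  time <- ifelse(observed, (nxt - start_steps) * dt,
                 (n_steps - start_steps) * dt)
  data.frame(time = pmax(time, dt / 2), observed = observed)
}

km_survival <- function(times, observed, grid) {
  if (length(times) == 0L) return(rep(NA_real_, length(grid)))
  fit <- survival::survfit(survival::Surv(times, observed) ~ 1)
  summary(fit, times = grid, extend = TRUE)$surv
}

#' Model-generated and observed transition statistics
#'
#' Reproduces the conditioned time-to-transition panels: for each
#' encounter train, a synthetic point process of transition decisions
#' is generated from the rate model (per-step thinning, as if the
#' agent were permanently exposed), and the time from each encounter
#' onset (all / isolated / clump leaders) to the next decision is
#' pooled across trains, together with a matched random-time baseline.
#' Kaplan-Meier survival curves handle censoring at train ends.
#'
#' @param spec a [rate_model_spec()] for the transition of interest.
#' @param trains list of [encounter_series()].
#' @param grid time grid (s) for the survival curves.
#' @param seed integer seed. The thinning uniforms are seeded per
#'   train (and repetition), not per model, so two models evaluated
#'   with the same seed see common random numbers - their discrepancy
#'   then reflects the rate functions, and identical models tie
#'   exactly.
#' @param event_steps optional list (per train) of observed transition
#'   steps; when supplied these are used instead of simulating from
#'   the model, which yields the observed-data version of the curves.
#' @param n_rep number of independent thinning repetitions pooled for
#'   the model curves (ignored for observed data).
#' @param state_mask optional list (per train) of logical vectors
#'   marking the steps spent in the exposure state; conditioning
#'   starts (onsets and random times) are restricted to these steps,
#'   mirroring how the observed curves condition on encounters
#'   received while actually exposed to the transition.
#' @return list with `curves` (data.frame: `time`, `condition`,
#'   `survival`) and `samples` (per-condition time/censoring tables).
#' @export
transition_statistics <- function(spec, trains,
                                  grid = seq(0.1, 10, by = 0.1),
                                  seed = 1L, event_steps = NULL,
                                  n_rep = 1L, state_mask = NULL) {
  dt <- trains[[1]]$time_step
  conds <- c("all", "isolated", "clump", "random")
  pooled <- stats::setNames(vector("list", length(conds)), conds)
  if (!is.null(event_steps)) n_rep <- 1L
  for (j in seq_along(trains)) {
    tr <- trains[[j]]
    n <- length(tr$w)
    lam <- if (is.null(event_steps)) rate_trace(spec, tr$w, tr$d, dt)
    cls <- classify_onsets(tr)
    if (!is.null(state_mask)) {
      msk <- which(state_mask[[j]])
      cls <- lapply(cls, function(v) intersect(v, msk))
    } else msk <- seq_len(n)
    set.seed(derive_seed(seed, paste0("rnd", j)))
    starts <- list(all = cls$all, isolated = cls$isolated,
                   clump = cls$clump,
                   random = if (length(msk) > 0)
                     sort(sample(msk, length(cls$all), replace = TRUE))
                   else integer(0))
    for (r in seq_len(n_rep)) {
      ev <- if (is.null(event_steps)) {
        set.seed(derive_seed(seed, sprintf("thin-%d-%d", j, r)))
        which(stats::runif(n) < dt * lam)
      } else event_steps[[j]]
      for (cn in conds) {
        res <- time_to_next_event(ev, starts[[cn]], n, dt)
        pooled[[cn]] <- rbind(pooled[[cn]], res)
      }
    }
  }
  curves <- do.call(rbind, lapply(conds, function(cn) {
    s <- pooled[[cn]]
    if (is.null(s) || nrow(s) < 5) {
      warning("too few conditioning events for condition '", cn, "'")
      return(NULL)
    }
    data.frame(time = grid, condition = cn,
               survival = km_survival(s$time, s$observed, grid))
  }))
  list(curves = curves, samples = pooled)
}

#' Encounter accumulation within bouts
#'
#' For completed bouts of the requested type, the number of encounter
#' onsets received during the bout and the within-bout onset rate,
#' binned by bout duration.
#'
#' @param walking logical matrix (steps x trains) of states.
#' @param trains matching list of [encounter_series()].
#' @param type `"walk"` or `"stop"`.
#' @param breaks bout-duration bin edges (s).
#' @return data.frame with `duration` (bin center), `mean_count`,
#'   `mean_rate` (Hz), `n_bouts`.
#' @export
bout_encounter_curve <- function(walking, trains, type = "walk",
                                 breaks = c(0, 1, 2, 3, 4, 6, 8, 12)) {
  dt <- trains[[1]]$time_step
  durs <- numeric(0); counts <- numeric(0)
  for (j in seq_len(ncol(walking))) {
    lab <- if (type == "walk") walking[, j] else !walking[, j]
    r <- rle(lab)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    keep <- which(r$values)
    # drop the final (censored) bout
    keep <- keep[ends[keep] < length(lab)]
    if (length(keep) == 0L) next
    w <- trains[[j]]$w
    durs <- c(durs, r$lengths[keep] * dt)
    counts <- c(counts, vapply(keep, function(k)
      sum(w[starts[k]:ends[k]]), numeric(1)))
  }
  bin <- cut(durs, breaks)
  mids <- (breaks[-1] + breaks[-length(breaks)]) / 2
  data.frame(duration = mids,
             mean_count = as.numeric(tapply(counts, bin, mean)),
             mean_rate = as.numeric(tapply(counts / durs, bin, mean)),
             n_bouts = as.numeric(table(bin)))
}

#' Panel statistics for a fitted stop/walk model pair
#'
#' Convenience wrapper producing the conditioned time-to-stop and
#' time-to-walk survival curves plus the bout encounter-accumulation
#' curves from model simulations on the supplied trains.
#'
#' @param stop_spec,walk_spec [rate_model_spec()] objects.
#' @param trains list of [encounter_series()].
#' @param seed integer seed.
#' @param grid survival-curve time grid (s).
#' @return list with `stop`, `walk` ([transition_statistics()]
#'   results) and `bout_curves` (walk/stop encounter accumulation).
#' @export
generate_model_statistics <- function(stop_spec, walk_spec, trains,
                                      seed = 1L,
                                      grid = seq(0.1, 10, by = 0.1)) {
  st <- simulate_state_sequences(stop_spec, walk_spec, trains,
                                 seed = derive_seed(seed, "panel-states"))
  walk_mask <- lapply(seq_along(trains), function(j) st$walking[, j])
  stop_mask <- lapply(seq_along(trains), function(j) !st$walking[, j])
  list(
    stop = transition_statistics(stop_spec, trains, grid,
                                 seed = derive_seed(seed, "panel-stop"),
                                 state_mask = walk_mask),
    walk = transition_statistics(walk_spec, trains, grid,
                                 seed = derive_seed(seed, "panel-walk"),
                                 state_mask = stop_mask),
    bout_curves = list(
      walk = bout_encounter_curve(st$walking, trains, "walk"),
      stop = bout_encounter_curve(st$walking, trains, "stop")))
}

observed_transition_steps <- function(sequences, direction) {
  lapply(sequences, function(s)
    transition_steps(s$walking, direction)$events)
}

#' Cross-validated comparison of fitted rate models
#'
#' Scores each fitted model on held-out sequences three ways: (i)
#' held-out log-likelihood - the cross-validation score used for
#' selection by default; (ii) the discrepancy between the
#' model-generated and observed conditioned time-to-transition
#' survival curves (summed squared deviation over the time grid and
#' the all/isolated/clump/random conditions), a quantitative surrogate
#' for judging the panel curves by eye; (iii) AIC and BIC from the
#' training log-likelihood. Exact ties in the selection score are
#' reported, not broken. Families that merely mimic the generating
#' model produce near-identical panel curves, so the likelihood is the
#' sharper selector; both scores are always reported.
#'
#' @param fits list of [fit_rate_model()] results, all with the same
#'   direction.
#' @param heldout a [bout_data()] disjoint from the training data.
#' @param grid survival-curve time grid (s).
#' @param seed integer seed for the model simulations.
#' @param n_rep thinning repetitions for the model curves.
#' @param selection `"heldout_logL"` (default) or `"discrepancy"`.
#' @return list with `table` (data.frame: family, heldout_logL,
#'   discrepancy, AIC, BIC), `selected` (family name), `tie` (logical).
#' @export
compare_models <- function(fits, heldout, grid = seq(0.1, 10, by = 0.1),
                           seed = 1L, n_rep = 3L,
                           selection = c("heldout_logL", "discrepancy")) {
  selection <- match.arg(selection)
  stopifnot(inherits(heldout, "bout_data"))
  direction <- unique(vapply(fits, function(f) f$direction, character(1)))
  if (length(direction) != 1L)
    stop("all fitted models must share a direction")
  trains <- lapply(heldout$sequences, function(s)
    encounter_series(s$d, s$dt, w = s$w))
  obs_steps <- observed_transition_steps(heldout$sequences, direction)
  mask <- lapply(heldout$sequences, function(s)
    if (direction == "walk_to_stop") s$walking else !s$walking)
  obs <- transition_statistics(fits[[1]]$spec, trains, grid,
                               seed = derive_seed(seed, "obs"),
                               event_steps = obs_steps, state_mask = mask)
  rows <- lapply(seq_along(fits), function(i) {
    f <- fits[[i]]
    ll <- bout_log_likelihood(f$spec, heldout)
    # same seed for every model: common random numbers in the thinning
    sim <- transition_statistics(f$spec, trains, grid,
                                 seed = derive_seed(seed, "sim"),
                                 n_rep = n_rep, state_mask = mask)
    merged <- merge(obs$curves, sim$curves,
                    by = c("time", "condition"), suffixes = c("_obs", "_sim"))
    disc <- sum((merged$survival_obs - merged$survival_sim)^2, na.rm = TRUE)
    data.frame(family = f$family, heldout_logL = ll, discrepancy = disc,
               AIC = 2 * f$n_params - 2 * f$logL,
               BIC = f$n_params * log(f$n_steps) - 2 * f$logL)
  })
  tab <- do.call(rbind, rows)
  score <- if (selection == "discrepancy") tab$discrepancy
           else -tab$heldout_logL
  best <- which(score == min(score))
  list(table = tab, selected = tab$family[best[1]], tie = length(best) > 1,
       selection = selection)
}
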