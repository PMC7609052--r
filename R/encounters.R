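#' Construct a signal trace
#'
#' A virtual-antenna intensity series on the camera's 8-bit scale,
#' sampled at a uniform time step.
#'
#' @param values numeric intensity series.
#' @param time_step sampling interval (s).
#' @param valid logical mask; invalid samples are excluded from event
#'   detection and break encounter intervals.
#' @return object of class `signal_trace`.
#' @export
signal_trace <- function(values, time_step, valid = NULL) {
  check_scalar(time_step, "time_step")
  values <- as.numeric(values)
  valid <- valid %||% rep(TRUE, length(values))
  stopifnot(length(valid) == length(values))
  if (any(valid & (!is.finite(values) | values < 0)))
    stop("signal values must be finite and non-negative where valid")
  structure(list(values = values, time_step = time_step, valid = valid),
            class = "signal_trace")
}

#' Fit a Gaussian background model to pooled signal values
#'
#' Camera shot noise makes the background signal Gaussian around a
#' positive mean. The fit is restricted to the dominant mode so that a
#' minority of above-background (odor) samples does not inflate the
#' estimate: starting from median/MAD estimates, the mean and SD are
#' re-estimated from samples within 3 SD of the current mean until
#' stable.
#'
#' @param traces a `signal_trace`, a list of them, or a numeric vector.
#' @return object of class `background_model` with fields `mean` and `sd`.
#' @export
fit_background <- function(traces) {
  x <- pool_signal_values(traces)
  if (length(x) < 100L) stop("need at least 100 valid samples to fit background")
  mu <- stats::median(x)
  s <- stats::mad(x)
  if (s == 0) stop("degenerate (constant) signal: background SD is zero")
  for (i in 1:10) {
    keep <- abs(x - mu) <= 3 * s
    mu_new <- mean(x[keep])
    s_new <- stats::sd(x[keep])
    if (is.na(s_new) || s_new == 0)
      stop("degenerate signal: background SD collapsed to zero")
    if (abs(mu_new - mu) < 1e-8 && abs(s_new - s) < 1e-8) break
    mu <- mu_new; s <- s_new
  }
  structure(list(mean = mu, sd = s), class = "background_model")
}

pool_signal_values <- function(traces) {
  if (inherits(traces, "signal_trace")) traces <- list(traces)
  if (is.numeric(traces)) return(traces[is.finite(traces)])
  unlist(lapply(traces, function(tr) tr$values[tr$valid]), use.names = FALSE)
}

#' Encounter detection configuration
#'
#' @param k_sigma threshold multiplier: an encounter requires the signal
#'   to exceed `mean + k_sigma * sd` of the background. Default 2.5.
#' @param min_encounter_duration minimum persistence (s) required for
#'   both encounter onsets and offsets. Default 0.05 (50 ms).
#' @return object of class `encounter_config`.
#' @export
encounter_config <- function(k_sigma = 2.5, min_encounter_duration = 0.05) {
  check_scalar(k_sigma, "k_sigma")
  check_scalar(min_encounter_duration, "min_encounter_duration")
  structure(list(k_sigma = k_sigma,
                 min_encounter_duration = min_encounter_duration),
            class = "encounter_config")
}

#' Construct an encounter series
#'
#' Holds the binary onset train `w(t)` (one unit impulse at the first
#' step of each encounter), the binary exposure vector `d(t)` (1 inside
#' encounters), and the interval table.
#'
#' @param d binary exposure vector.
#' @param dt time step (s).
#' @param w optional binary onset vector; derived from `d` if missing.
#' @param threshold intensity threshold used for detection (NA for
#'   synthetic trains).
#' @return object of class `encounter_series`.
#' @export
encounter_series <- function(d, dt, w = NULL, threshold = NA_real_) {
  d <- as.integer(as.logical(d))
  intervals <- intervals_from_binary(d, dt)
  if (is.null(w)) {
    w <- integer(length(d))
    if (nrow(intervals) > 0)
      w[round(intervals$onset / dt) + 1L] <- 1L
  } else {
    w <- as.integer(as.logical(w))
    stopifnot(length(w) == length(d))
  }
  structure(list(w = w, d = d, intervals = intervals, time_step = dt,
                 threshold_used = threshold),
            class = "encounter_series")
}

#' @export
print.encounter_series <- function(x, ...) {
  cat(sprintf(
    "<encounter_series> %d steps at dt = %.4g s; %d encounters, intermittency %.3g\n",
    length(x$d), x$time_step, nrow(x$intervals), mean(x$d)))
  invisible(x)
}

#' Detect odor encounters in a signal trace
#'
#' An encounter is a contiguous interval where the signal exceeds
#' `mean + k_sigma * sd` of the background. Both the onset and the
#' offset must persist for at least `min_encounter_duration`:
#' sub-minimum excursions above threshold are ignored and sub-minimum
#' dips below threshold are bridged, which suppresses false events from
#' measurement fluctuations. Invalid samples break intervals.
#'
#' @param trace a [signal_trace()].
#' @param bg a [fit_background()] model on the same intensity scale.
#' @param cfg an [encounter_config()].
#' @return an [encounter_series()].
#' @export
detect_encounters <- function(trace, bg, cfg = encounter_config()) {
  stopifnot(inherits(trace, "signal_trace"), inherits(bg, "background_model"))
  dt <- trace$time_step
  min_steps <- as.integer(ceiling(cfg$min_encounter_duration / dt - 1e-9))
  if (min_steps < 1L)
    stop("min_encounter_duration must be at least one time step")
  thr <- bg$mean + cfg$k_sigma * bg$sd
  above <- trace$values > thr & trace$valid
  # invalid samples must not be bridged: split the series at invalid runs
  d <- logical(length(above))
  valid_runs <- intervals_from_binary(trace$valid, 1)
  for (i in seq_len(nrow(valid_runs))) {
    idx <- (valid_runs$onset[i] + 1):valid_runs$offset[i]
    d[idx] <- apply_persistence(above[idx], min_steps)
  }
  encounter_series(d, dt, threshold = thr)
}

#' Exponentially filtered encounter signals
#'
#' Computes the three running sensory variables with a causal
#' exponential filter of timescale `tau`:
#' * `W_freq` (Hz): filtered onset train `w(t)`, normalized by `1/tau` so
#'   that a steady onset rate `r` gives `W_freq -> r`;
#' * `W_dur` (s): unnormalized filtered exposure `d(t)` (time-weighted, so
#'   `d == 1` gives `W_dur -> tau`);
#' * `W_conc`: unnormalized filtered raw signal `s(t)` (time-weighted).
#'
#' Filter state before the first sample is zero.
#'
#' @param enc an [encounter_series()].
#' @param trace optional [signal_trace()] aligned with `enc`; required
#'   for `W_conc`.
#' @param tau filter timescale (s), default 2.
#' @return object of class `filtered_signals` with fields `W_freq`,
#'   `W_dur`, `W_conc` (NULL if no trace), and `tau`.
#' @export
compute_filtered_signals <- function(enc, trace = NULL, tau = 2) {
  check_scalar(tau, "tau")
  dt <- enc$time_step
  if (!is.null(trace)) {
    stopifnot(inherits(trace, "signal_trace"))
    if (abs(trace$time_step - dt) > 1e-12)
      stop("trace and encounter series have inconsistent time steps")
    stopifnot(length(trace$values) == length(enc$w))
  }
  structure(list(
    W_freq = exp_filter(enc$w, dt, tau) / tau,
    W_dur = exp_filter(enc$d, dt, tau) * dt,
    W_conc = if (!is.null(trace)) exp_filter(trace$values, dt, tau) * dt,
    tau = tau, time_step = dt
  ), class = "filtered_signals")
}

#' Synthetic encounter-train configuration
#'
#' Driver for parameter-recovery experiments: encounter onsets are drawn
#' as a Bernoulli thinning of a Poisson process (at most one onset per
#' time step) and each onset is given a sampled duration.
#'
#' @param onset_rate Poisson onset rate (Hz), >= 0.
#' @param duration_sampler list with element `dist` (one of "constant",
#'   "exponential", "lognormal", "pareto") and the distribution's
#'   parameters: `value` (s) for constant; `mean` (s) for exponential;
#'   `meanlog`, `sdlog` for lognormal; `xmin` (s), `alpha` for Pareto.
#' @param total_time total duration (s).
#' @param time_step sampling interval (s), default 1/90.
#' @param seed integer seed.
#' @return object of class `encounter_train_config`.
#' @export
encounter_train_config <- function(onset_rate,
                                   duration_sampler = list(dist = "constant", value = 0.2),
                                   total_time = 60,
                                   time_step = 1 / 90,
                                   seed = 1L) {
  if (onset_rate < 0) stop("onset_rate must be non-negative")
  check_scalar(total_time, "total_time")
  check_scalar(time_step, "time_step")
  if (onset_rate > 0 && total_time < 1 / onset_rate)
    stop("total_time shorter than one expected inter-onset interval")
  structure(list(onset_rate = onset_rate, duration_sampler = duration_sampler,
                 total_time = total_time, time_step = time_step,
                 seed = as.integer(seed)),
            class = "encounter_train_config")
}

sample_durations <- function(sampler, n) {
  if (n == 0L) return(numeric(0))
  switch(sampler$dist,
    constant = rep(sampler$value, n),
    exponential = stats::rexp(n, rate = 1 / sampler$mean),
    lognormal = stats::rlnorm(n, sampler$meanlog, sampler$sdlog),
    pareto = sampler$xmin * stats::runif(n)^(-1 / sampler$alpha),
    stop("unknown duration distribution: ", sampler$dist)
  )
}

#' Generate a synthetic encounter train
#'
#' Onsets are Bernoulli draws with probability `onset_rate * dt` per
#' step; each onset opens an exposure interval of sampled duration
#' (at least one step). Overlapping intervals are merged into a single
#' encounter that keeps only the first onset.
#'
#' @param config an [encounter_train_config()].
#' @return an [encounter_series()].
#' @export
generate_encounter_train <- function(config) {
  stopifnot(inherits(config, "encounter_train_config"))
  dt <- config$time_step
  n <- round(config$total_time / dt)
  set.seed(config$seed)
  if (config$onset_rate == 0) {
    return(encounter_series(integer(n), dt, w = integer(n)))
  }
  p <- config$onset_rate * dt
  if (p > 1) stop("onset_rate too high for the time step")
  onset_steps <- which(stats::runif(n) < p)
  dur <- sample_durations(config$duration_sampler, length(onset_steps))
  if (any(dur <= 0)) stop("sampled durations must be positive")
  len <- pmax(1L, round(dur / dt))
  d <- logical(n)
  w <- integer(n)
  end_prev <- 0L
  for (i in seq_along(onset_steps)) {
    s <- onset_steps[i]
    e <- min(n, s + len[i] - 1L)
    # onsets inside or immediately adjacent to an open interval are merged
    if (i == 1L || s > end_prev + 1L) w[s] <- 1L
    d[s:e] <- TRUE
    end_prev <- max(end_prev, e)
  }
  encounter_series(d, dt, w = w)
}
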