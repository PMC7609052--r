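#' Stochastic saccade model parameters
#'
#' Walking flies reorient in discrete saccades: turn times follow a
#' Poisson process with base timescale `tau_turn`, turn magnitudes are
#' Gaussian (`turn_mean` +- `turn_sd` degrees, folded to be positive),
#' and the probability that a turn is directed upwind is a sigmoid of
#' the running encounter frequency with gain `alpha`. Between turns the
#' orientation performs small white jitter. Optional linear modulation
#' of the turn rate by `W_freq` and `W_dur` is carried by the inverse
#' timescales `1/tau_freq` and `1/tau_dur` (disabled by default via
#' infinite timescales).
#'
#' @param alpha sigmoid gain (1/Hz); 0 gives unbiased turns.
#' @param tau_turn base inter-turn timescale (s).
#' @param tau_freq,tau_dur optional rate-modulation timescales; `Inf`
#'   disables the corresponding term. May be negative when fitted.
#' @param turn_mean,turn_sd turn magnitude distribution (deg).
#' @param straight_jitter_sd orientation jitter between turns
#'   (deg per time step).
#' @param filter_tau encounter-frequency filter timescale (s).
#' @param fixed_p_upwind if non-NULL, overrides the sigmoid with a
#'   constant upwind probability (turn-ablated agents).
#' @return object of class `turn_model_params`.
#' @export
turn_model_params <- function(alpha = 0.242, tau_turn = 0.75,
                              tau_freq = Inf, tau_dur = Inf,
                              turn_mean = 30, turn_sd = 10,
                              straight_jitter_sd = 0.22,
                              filter_tau = 2, fixed_p_upwind = NULL) {
  check_scalar(tau_turn, "tau_turn")
  check_scalar(turn_mean, "turn_mean")
  if (turn_sd < 0) stop("turn_sd must be non-negative")
  if (!is.finite(alpha)) stop("alpha must be finite")
  structure(list(alpha = alpha, tau_turn = tau_turn, tau_freq = tau_freq,
                 tau_dur = tau_dur, turn_mean = turn_mean, turn_sd = turn_sd,
                 straight_jitter_sd = straight_jitter_sd,
                 filter_tau = filter_tau, fixed_p_upwind = fixed_p_upwind),
            class = "turn_model_params")
}

#' Sigmoidal upwind-turn probability
#'
#' `p_T = (1 + exp(-alpha * x))^-1`: 0.5 in the absence of encounters,
#' approaching 1 for frequent encounters when `alpha > 0`. Inside the
#' turn model `x` is the raw causal exponential filter of the onset
#' train (a unit jump per encounter, timescale `filter_tau`, steady
#' value `filter_tau` times the onset rate): with the default gain
#' this convention places the stationary orientation about 25 degrees
#' off upwind at 3 Hz, matching the model's published behavior.
#'
#' @param w_freq filtered encounter signal, non-negative.
#' @param alpha gain (reciprocal of the filter units).
#' @return probability in (0, 1).
#' @export
upwind_turn_probability <- function(w_freq, alpha) {
  if (any(w_freq < 0)) stop("w_freq must be non-negative")
  stats::plogis(alpha * w_freq)
}

#' Full turn rate
#'
#' `lambda_F = 1/tau_turn + W_freq/tau_freq + W_dur/tau_dur`.
#'
#' @param params a [turn_model_params()].
#' @param w_freq,w_dur filtered signals (may be vectors).
#' @return rate (1/s), strictly positive.
#' @export
full_turn_rate <- function(params, w_freq = 0, w_dur = 0) {
  lam <- 1 / params$tau_turn + w_freq / params$tau_freq +
    w_dur / params$tau_dur
  if (any(lam <= 0)) stop("turn rate must be strictly positive")
  lam
}

#' Classify a turn as upwind or downwind
#'
#' A turn is upwind if its signed orientation change reduces the
#' reflected orientation theta+: negative `dtheta` in the half-plane
#' `theta in (0, 180)`, positive in `(180, 360)`.
#'
#' @param theta heading at the turn (deg).
#' @param dtheta signed orientation change (deg).
#' @return logical vector.
#' @export
classify_turn_upwind <- function(theta, dtheta) {
  upper <- sin(theta * pi / 180) >= 0
  ifelse(upper, dtheta < 0, dtheta > 0)
}

turn_mu_upwind <- function(theta, turn_mean) {
  ifelse(sin(theta * pi / 180) >= 0, -turn_mean, turn_mean)
}

#' Assemble per-timestep turn-likelihood data
#'
#' @param sequences list; each element needs `dtheta` (deg per step),
#'   `theta` (deg, heading at the step), `w_freq` (Hz), optionally
#'   `w_dur` (s), `walking` (logical), `turn` (logical, TRUE at the
#'   single step carrying each detected turn), `upwind` (logical at
#'   turn steps; derived from `theta`/`dtheta` when absent), and `dt`.
#' @param dt default time step (s).
#' @return object of class `turn_likelihood_data`.
#' @export
turn_likelihood_data <- function(sequences, dt = 1 / 90) {
  sequences <- lapply(sequences, function(s) {
    s$dt <- s$dt %||% dt
    s$w_dur <- s$w_dur %||% rep(0, length(s$dtheta))
    s$walking <- s$walking %||% rep(TRUE, length(s$dtheta))
    if (is.null(s$upwind))
      s$upwind <- classify_turn_upwind(s$theta, s$dtheta)
    s
  })
  structure(list(sequences = sequences, dt = dt),
            class = "turn_likelihood_data")
}

#' Turn-model log-likelihood
#'
#' Mixture likelihood over walking steps. A step carrying an upwind
#' turn contributes `log(dt lambda_F) - dt lambda_F + log p_T +
#' log N(dtheta; mu_up, turn_sd)`; a downwind turn the analogous term
#' with `1 - p_T` and the opposite Gaussian mean; a straight step
#' contributes `-dt lambda_F + log N(dtheta; 0, jitter_sd)`. Only
#' walking steps enter. The Gaussian turn-magnitude means are
#' `-turn_mean` for headings in (0, 180) and `+turn_mean` in
#' (180, 360) for upwind turns (the signed change that reduces
#' theta+), and opposite for downwind turns.
#'
#' @param params a [turn_model_params()].
#' @param data a [turn_likelihood_data()].
#' @return scalar log-likelihood (0 for empty data).
#' @export
turn_log_likelihood <- function(params, data) {
  stopifnot(inherits(data, "turn_likelihood_data"))
  ll <- 0
  for (s in data$sequences) {
    wk <- which(s$walking)
    if (length(wk) == 0L) next
    lam <- full_turn_rate(params, s$w_freq[wk], s$w_dur[wk])
    dtl <- s$dt * lam
    turn <- s$turn[wk]
    p_t <- upwind_turn_probability(params$filter_tau * s$w_freq[wk][turn],
                                   params$alpha)
    up <- s$upwind[wk][turn]
    mu_up <- turn_mu_upwind(s$theta[wk][turn], params$turn_mean)
    mu <- ifelse(up, mu_up, -mu_up)
    ll <- ll - sum(dtl) +                      # survival factor, every step
      sum(log(dtl[turn])) +                    # turn occurrence
      sum(log(ifelse(up, p_t, 1 - p_t))) +     # turn direction
      sum(stats::dnorm(s$dtheta[wk][turn], mu, params$turn_sd, log = TRUE)) +
      sum(stats::dnorm(s$dtheta[wk][!turn], 0, params$straight_jitter_sd,
                       log = TRUE))
  }
  as.numeric(ll)
}

# sufficient statistics for the unmodulated (constant lambda_F) fit:
# the angle-density terms do not depend on the fitted (alpha, tau_turn)
turn_fit_stats <- function(data, ids, filter_tau = 2) {
  n_steps <- 0L
  wf <- list(); up <- list()
  for (s in data$sequences[ids]) {
    wk <- which(s$walking)
    n_steps <- n_steps + length(wk)
    t_idx <- wk[s$turn[wk]]
    wf[[length(wf) + 1L]] <- s$w_freq[t_idx]
    up[[length(up) + 1L]] <- s$upwind[t_idx]
  }
  list(n_steps = n_steps, x = filter_tau * unlist(wf),
       upwind = unlist(up), dt = data$dt)
}

turn_negloglik_fast <- function(par, st) {
  alpha <- par[1]; lam <- exp(par[2])
  dtl <- st$dt * lam
  n_turn <- length(st$x)
  lp <- stats::plogis(alpha * st$x, log.p = TRUE)
  lq <- stats::plogis(-alpha * st$x, log.p = TRUE)  # log(1 - p)
  ll <- -st$n_steps * dtl + n_turn * log(dtl) +
    sum(lp[st$upwind]) + sum(lq[!st$upwind])
  if (!is.finite(ll)) return(1e10)
  -ll
}

#' Fit the turn model over bootstrapped trajectory subsets
#'
#' Maximizes [turn_log_likelihood()] by L-BFGS-B with numerical
#' gradients on random subsets of the trajectories (20% each by
#' default), optimizing `alpha` directly and `log(1/tau_turn)` for the
#' positive timescale. With `fit_modulation = TRUE` the two linear
#' rate-modulation coefficients `1/tau_freq` and `1/tau_dur` are fitted
#' as well (unconstrained in sign). Returns the per-subset estimate
#' distribution and its medians.
#'
#' @param data a [turn_likelihood_data()].
#' @param n_subsets number of subsets (default 500).
#' @param subset_fraction fraction of trajectories per subset.
#' @param fit_modulation also fit `1/tau_freq`, `1/tau_dur`.
#' @param init named list of initial values (`alpha`, `tau_turn`).
#' @param seed integer seed.
#' @return object of class `turn_model_fit` with `estimates`,
#'   `medians`, `params` (a [turn_model_params()] at the medians) and
#'   `n_failed`.
#' @export
fit_turn_model <- function(data, n_subsets = 500, subset_fraction = 0.2,
                           fit_modulation = FALSE,
                           init = list(alpha = 0.1, tau_turn = 1),
                           filter_tau = 2, seed = 1L) {
  stopifnot(inherits(data, "turn_likelihood_data"))
  n_seq <- length(data$sequences)
  if (n_seq < 10L) stop("need at least 10 trajectories")
  set.seed(seed)
  n_take <- max(2L, round(subset_fraction * n_seq))
  pnames <- c("alpha", "tau_turn",
              if (fit_modulation) c("inv_tau_freq", "inv_tau_dur"))
  rows <- vector("list", n_subsets)
  for (b in seq_len(n_subsets)) {
    ids <- sample.int(n_seq, n_take)
    if (!fit_modulation) {
      st <- turn_fit_stats(data, ids, filter_tau)
      par0 <- c(init$alpha, log(1 / init$tau_turn))
      opt <- try(stats::optim(par0, turn_negloglik_fast, st = st,
                              method = "L-BFGS-B",
                              lower = c(-20, par0[2] - log(100)),
                              upper = c(20, par0[2] + log(100))),
                 silent = TRUE)
      rows[[b]] <- if (inherits(opt, "try-error"))
        c(NA, NA, converged = 0, logL = NA) else
        c(opt$par[1], exp(-opt$par[2]),
          converged = as.numeric(opt$convergence == 0), logL = -opt$value)
    } else {
      sub <- turn_likelihood_data(data$sequences[ids], dt = data$dt)
      nll <- function(par) {
        pr <- turn_model_params(alpha = par[1], tau_turn = exp(-par[2]),
                                tau_freq = 1 / par[3], tau_dur = 1 / par[4],
                                filter_tau = filter_tau)
        ll <- try(turn_log_likelihood(pr, sub), silent = TRUE)
        if (inherits(ll, "try-error") || !is.finite(ll)) 1e10 else -ll
      }
      par0 <- c(init$alpha, log(1 / init$tau_turn), 0.01, 0.01)
      opt <- try(stats::optim(par0, nll, method = "L-BFGS-B",
                              lower = c(-20, par0[2] - log(100), -10, -10),
                              upper = c(20, par0[2] + log(100), 10, 10)),
                 silent = TRUE)
      rows[[b]] <- if (inherits(opt, "try-error"))
        c(NA, NA, NA, NA, converged = 0, logL = NA) else
        c(opt$par[1], exp(-opt$par[2]), opt$par[3], opt$par[4],
          converged = as.numeric(opt$convergence == 0), logL = -opt$value)
    }
  }
  tab <- as.data.frame(do.call(rbind, rows))
  names(tab) <- c(pnames, "converged", "logL")
  tab$subset <- seq_len(n_subsets)
  ok <- tab$converged == 1 & !is.na(tab$converged)
  if (!any(ok)) stop("no subset converged")
  med <- lapply(tab[ok, pnames, drop = FALSE], stats::median)
  params <- turn_model_params(
    alpha = med$alpha, tau_turn = med$tau_turn,
    tau_freq = if (fit_modulation) 1 / med$inv_tau_freq else Inf,
    tau_dur = if (fit_modulation) 1 / med$inv_tau_dur else Inf)
  structure(list(estimates = tab, medians = med, params = params,
                 n_failed = sum(!ok)),
            class = "turn_model_fit")
}

#' @export
print.turn_model_fit <- function(x, ...) {
  cat(sprintf("<turn_model_fit> medians: %s (%d/%d subsets failed)\n",
              paste(names(x$medians), signif(unlist(x$medians), 3),
                    sep = "=", collapse = ", "),
              x$n_failed, nrow(x$estimates)))
  invisible(x)
}

#' Draw turn magnitudes
#'
#' Magnitudes are `|N(turn_mean, turn_sd^2)|` (folded normal; with the
#' default 30 +- 10 deg the folding correction is negligible). A zero
#' `turn_sd` gives exactly `turn_mean`.
#'
#' @param params a [turn_model_params()].
#' @param n number of draws.
#' @return positive magnitudes (deg).
#' @export
draw_turn_magnitudes <- function(params, n) {
  if (params$turn_sd == 0) return(rep(params$turn_mean, n))
  abs(stats::rnorm(n, params$turn_mean, params$turn_sd))
}

#' Simulate an ensemble of turn-model trajectories
#'
#' Forward simulation of the saccade model: at each step a turn occurs
#' with probability `dt * lambda_F`; its magnitude is drawn from the
#' turn-angle distribution and its direction is upwind with probability
#' `p_T(W_freq)` (reducing theta+; at exactly theta+ = 0 or 180 the
#' direction is uniform). Between turns the heading accumulates white
#' jitter. Turns only occur, and jitter is only applied, on walking
#' steps.
#'
#' @param params a [turn_model_params()].
#' @param trains list of [encounter_series()] (one per trajectory, all
#'   with the same time step and length).
#' @param theta0 initial headings (deg), recycled.
#' @param walking optional logical matrix `n_steps x n_traj`
#'   (default: always walking).
#' @param seed integer seed.
#' @return list with `theta` (matrix `n_steps x n_traj`, heading at
#'   each step), `w_freq` (same shape), and `turns` (data.frame:
#'   `traj`, `step`, `time`, `dtheta`, `upwind`).
#' @export
simulate_turn_ensemble <- function(params, trains, theta0 = NULL,
                                   walking = NULL, seed = 1L) {
  n_traj <- length(trains)
  dt <- trains[[1]]$time_step
  n_steps <- length(trains[[1]]$w)
  for (tr in trains)
    if (length(tr$w) != n_steps || abs(tr$time_step - dt) > 1e-12)
      stop("all trains must share length and time step")
  wf <- sapply(trains, function(tr)
    exp_filter(tr$w, dt, params$filter_tau) / params$filter_tau)
  wd <- sapply(trains, function(tr)
    exp_filter(tr$d, dt, params$filter_tau) * dt)
  set.seed(seed)
  theta0 <- theta0 %||% stats::runif(n_traj, 0, 360)
  theta0 <- rep_len(theta0, n_traj)
  if (is.null(walking)) walking <- matrix(TRUE, n_steps, n_traj)
  theta <- matrix(0, n_steps, n_traj)
  cur <- wrap360(theta0)
  turn_list <- vector("list", 256); n_turnrec <- 0L
  for (i in seq_len(n_steps)) {
    theta[i, ] <- cur
    wk <- walking[i, ]
    lam <- full_turn_rate(params, wf[i, ], wd[i, ])
    turn <- wk & (stats::runif(n_traj) < dt * lam)
    dth <- numeric(n_traj)
    if (any(turn)) {
      k <- which(turn)
      mag <- draw_turn_magnitudes(params, length(k))
      p_t <- if (!is.null(params$fixed_p_upwind))
        rep(params$fixed_p_upwind, length(k))
        else upwind_turn_probability(params$filter_tau * wf[i, k],
                                     params$alpha)
      up <- stats::runif(length(k)) < p_t
      s_up <- turn_mu_upwind(cur[k], 1)          # -1 in (0,180), +1 in (180,360)
      at_axis <- sin(cur[k] * pi / 180) == 0
      if (any(at_axis))
        s_up[at_axis] <- sample(c(-1, 1), sum(at_axis), replace = TRUE)
      dth[k] <- mag * ifelse(up, s_up, -s_up)
      n_turnrec <- n_turnrec + 1L
      if (n_turnrec > length(turn_list))
        turn_list <- c(turn_list, vector("list", length(turn_list)))
      turn_list[[n_turnrec]] <- data.frame(
        traj = k, step = i, time = (i - 1) * dt, dtheta = dth[k], upwind = up)
    }
    straight <- wk & !turn
    if (any(straight) && params$straight_jitter_sd > 0)
      dth[straight] <- stats::rnorm(sum(straight), 0,
                                    params$straight_jitter_sd)
    cur <- wrap360(cur + dth)
  }
  turns <- if (n_turnrec > 0)
    do.call(rbind, turn_list[seq_len(n_turnrec)])
  else data.frame(traj = integer(0), step = integer(0), time = numeric(0),
                  dtheta = numeric(0), upwind = logical(0))
  list(theta = theta, w_freq = wf, turns = turns, time_step = dt)
}

#' Simulate a single turn-model trajectory
#'
#' Convenience wrapper around [simulate_turn_ensemble()].
#'
#' @param params a [turn_model_params()].
#' @param encounters an [encounter_series()].
#' @param theta0 initial heading (deg).
#' @param seed integer seed.
#' @return list with `theta`, `w_freq` (vectors) and `turns`.
#' @export
simulate_turn_model <- function(params, encounters, theta0 = 90, seed = 1L) {
  out <- simulate_turn_ensemble(params, list(encounters), theta0, seed = seed)
  list(theta = out$theta[, 1], w_freq = out$w_freq[, 1], turns = out$turns,
       time_step = out$time_step)
}

#' Binned upwind orientation versus encounter frequency
#'
#' Bins the reflected orientation theta+ by `W_freq` over walking steps
#' and fits an ordinary least-squares line to the bin means (weighted
#' by bin occupancy) over the stated frequency range.
#'
#' @param theta headings (deg) or reflected orientations; values are
#'   reflected internally.
#' @param w_freq matching encounter frequencies (Hz).
#' @param walking logical mask (default all).
#' @param breaks bin edges (Hz).
#' @param fit_range frequency range for the regression line.
#' @return list with `curve` (data.frame: `w_freq`, `mean_theta_plus`,
#'   `se`, `n`), `slope`, `intercept`, `slope_se`.
#' @export
orientation_vs_frequency_curve <- function(theta, w_freq, walking = NULL,
                                           breaks = seq(0, 3.5, by = 0.25),
                                           fit_range = range(breaks)) {
  walking <- walking %||% rep(TRUE, length(theta))
  tp <- theta_plus(theta)[walking]
  wf <- w_freq[walking]
  bin <- cut(wf, breaks, include.lowest = TRUE)
  mids <- (breaks[-1] + breaks[-length(breaks)]) / 2
  agg_m <- tapply(tp, bin, mean)
  agg_s <- tapply(tp, bin, function(v) stats::sd(v) / sqrt(length(v)))
  agg_n <- tapply(tp, bin, length)
  curve <- data.frame(w_freq = mids, mean_theta_plus = as.numeric(agg_m),
                      se = as.numeric(agg_s), n = as.numeric(agg_n))
  curve <- curve[!is.na(curve$mean_theta_plus), , drop = FALSE]
  inr <- curve$w_freq >= fit_range[1] & curve$w_freq <= fit_range[2]
  fit <- stats::lm(mean_theta_plus ~ w_freq, data = curve[inr, ],
                   weights = curve$n[inr])
  list(curve = curve,
       slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       slope_se = summary(fit)$coefficients[2, 2])
}

#' Stationary mean orientation of the discrete turn chain
#'
#' Analytic oracle for the turn model at a fixed upwind probability
#' `p`: theta+ restricted to the grid `{0, 30, ..., 180}` performs a
#' nearest-neighbor walk (toward 0 with probability `p`) with
#' reflection at both ends. Returns the stationary mean of theta+.
#'
#' @param p upwind-turn probability.
#' @param step grid step in degrees (default 30).
#' @return stationary mean reflected orientation (deg).
#' @export
turn_chain_stationary_mean <- function(p, step = 30) {
  n <- round(180 / step) + 1L
  P <- matrix(0, n, n)
  P[1, 2] <- 1; P[n, n - 1] <- 1
  for (k in 2:(n - 1)) {
    P[k, k - 1] <- p
    P[k, k + 1] <- 1 - p
  }
  e <- eigen(t(P))
  v <- Re(e$vectors[, which.min(abs(e$values - 1))])
  pi_st <- v / sum(v)
  sum(pi_st * (seq_len(n) - 1) * step)
}
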