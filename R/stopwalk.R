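#' Inhomogeneous-Poisson rate model specification
#'
#' One of the competing rate models for walk/stop transitions. All
#' models map the encounter onset train `w(t)` and exposure `d(t)` to a
#' strictly positive transition rate:
#'
#' * `last_encounter`: `lambda(t) = lambda0 + dlambda * exp(-DT/tau)`
#'   where `DT` is the time since the most recent encounter onset
#'   (infinite before the first onset, so the rate starts at
#'   `lambda0`). The rate resets at every onset and relaxes back to
#'   baseline.
#' * `accumulated_evidence` (stop direction):
#'   `lambda(t) = lambda0 + lambda1 / (1 + lambda2 * A(t))` with `A`
#'   the raw causal exponential filter of the onset train (unit jump
#'   per onset).
#' * `accumulated_evidence` (walk direction):
#'   `lambda(t) = lambda0 + dlambda * A(t)`.
#' * `encounter_duration`: `lambda(t) = lambda_enc * d(t) +
#'   lambda_blank * (1 - d(t))`.
#' * `constant`: `lambda(t) = lambda0` (used for ablations and
#'   homogeneous controls).
#'
#' @param family one of `"last_encounter"`, `"accumulated_evidence"`,
#'   `"encounter_duration"`, `"constant"`.
#' @param direction `"walk_to_stop"` or `"stop_to_walk"`.
#' @param params named list of the family's parameters (see above):
#'   `lambda0`, `dlambda`, `tau` / `lambda0`, `lambda1`, `lambda2`,
#'   `tau` / `lambda_enc`, `lambda_blank` / `lambda0`.
#' @return object of class `rate_model_spec`.
#' @export
rate_model_spec <- function(family, direction, params) {
  family <- match.arg(family, c("last_encounter", "accumulated_evidence",
                                "encounter_duration", "constant"))
  direction <- match.arg(direction, c("walk_to_stop", "stop_to_walk"))
  p <- params
  ok <- switch(family,
    last_encounter = all(c("lambda0", "dlambda", "tau") %in% names(p)) &&
      p$lambda0 > 0 && p$tau > 0 && p$lambda0 + p$dlambda > 0,
    accumulated_evidence = if (direction == "walk_to_stop")
      all(c("lambda0", "lambda1", "lambda2", "tau") %in% names(p)) &&
        p$lambda0 > 0 && p$lambda1 > 0 && p$lambda2 > 0 && p$tau > 0
      else all(c("lambda0", "dlambda", "tau") %in% names(p)) &&
        p$lambda0 > 0 && p$dlambda > 0 && p$tau > 0,
    encounter_duration = all(c("lambda_enc", "lambda_blank") %in% names(p)) &&
      p$lambda_enc > 0 && p$lambda_blank > 0,
    constant = "lambda0" %in% names(p) && p$lambda0 > 0)
  if (!isTRUE(ok))
    stop("invalid or incomplete parameters for family '", family,
         "' (", direction, "): the rate must be strictly positive")
  structure(list(family = family, direction = direction, params = p),
            class = "rate_model_spec")
}

#' @export
print.rate_model_spec <- function(x, ...) {
  cat(sprintf("<rate_model_spec> %s (%s): %s\n", x$family, x$direction,
              paste(names(x$params), signif(unlist(x$params), 4),
                    sep = "=", collapse = ", ")))
  invisible(x)
}

#' Time since the most recent encounter onset
#'
#' @param w binary onset vector.
#' @param dt time step (s).
#' @return numeric vector; `Inf` before the first onset, 0 at onsets.
#' @export
time_since_onset <- function(w, dt) {
  n <- length(w)
  idx <- seq_len(n)
  last <- cummax(ifelse(w > 0, idx, 0L))
  out <- (idx - last) * dt
  out[last == 0L] <- Inf
  out
}

#' Evaluate a rate model along an encounter train
#'
#' @param spec a [rate_model_spec()].
#' @param w binary onset vector.
#' @param d binary exposure vector (same length).
#' @param dt time step (s).
#' @return numeric rate series (1/s), strictly positive.
#' @export
rate_trace <- function(spec, w, d, dt) {
  p <- spec$params
  lam <- switch(spec$family,
    last_encounter = {
      dT <- time_since_onset(w, dt)
      p$lambda0 + p$dlambda * exp(-dT / p$tau)
    },
    accumulated_evidence = {
      a <- exp_filter(w, dt, p$tau)
      if (spec$direction == "walk_to_stop")
        p$lambda0 + p$lambda1 / (1 + p$lambda2 * a)
      else p$lambda0 + p$dlambda * a
    },
    encounter_duration = p$lambda_enc * d + p$lambda_blank * (1 - d),
    constant = rep(p$lambda0, length(w)))
  if (any(lam <= 0)) stop("rate model produced a non-positive rate")
  lam
}

#' Assemble bout data from labeled sequences
#'
#' @param sequences list where each element has `walking` (logical per
#'   step), `w`, `d` (binary encounter vectors), and optionally `dt`.
#' @param dt time step (s) used when a sequence does not carry one.
#' @return object of class `bout_data`.
#' @export
bout_data <- function(sequences, dt = 1 / 90) {
  sequences <- lapply(sequences, function(s) {
    stopifnot(length(s$walking) == length(s$w), length(s$w) == length(s$d))
    s$dt <- s$dt %||% dt
    s
  })
  structure(list(sequences = sequences, dt = dt), class = "bout_data")
}

transition_steps <- function(walking, direction) {
  n <- length(walking)
  if (n < 2L) return(list(exposure = which(rep(FALSE, n)), events = integer(0)))
  if (direction == "walk_to_stop") {
    exposure <- which(walking)
    events <- which(!walking[-1] & walking[-n]) + 1L
  } else {
    exposure <- which(!walking)
    events <- which(walking[-1] & !walking[-n]) + 1L
  }
  list(exposure = exposure, events = events)
}

#' Log-likelihood of bout data under a rate model
#'
#' Per-step product form of the inhomogeneous-Poisson likelihood: every
#' step spent in the exposure state contributes a survival factor
#' `exp(-dt * lambda(t))`, and every observed transition contributes an
#' event factor `dt * lambda(t) * exp(-dt * lambda(t))` evaluated at
#' the first step of the new bout. Bouts censored by the end of a
#' sequence contribute survival factors only.
#'
#' @param spec a [rate_model_spec()].
#' @param data a [bout_data()].
#' @return scalar log-likelihood (0 for empty data).
#' @export
bout_log_likelihood <- function(spec, data) {
  stopifnot(inherits(data, "bout_data"))
  ll <- 0
  for (s in data$sequences) {
    ts <- transition_steps(s$walking, spec$direction)
    if (length(ts$exposure) == 0L && length(ts$events) == 0L) next
    lam <- rate_trace(spec, s$w, s$d, s$dt)
    dtl <- s$dt * lam
    if (max(dtl) > 0.5)
      warning("dt * lambda exceeds 0.5; the per-step Poisson ",
              "approximation is inaccurate")
    ll <- ll - sum(dtl[ts$exposure]) +
      sum(log(dtl[ts$events]) - dtl[ts$events])
  }
  ll
}

## ---- fitting ----

# transformed (log) parameterization per family; inverse timescales are
# optimized to avoid denominator singularities
rate_par_pack <- function(family, direction, p) {
  switch(family,
    last_encounter = log(c(p$lambda0, p$lambda0 + p$dlambda, 1 / p$tau)),
    accumulated_evidence = if (direction == "walk_to_stop")
      log(c(p$lambda0, p$lambda1, p$lambda2, 1 / p$tau))
      else log(c(p$lambda0, p$dlambda, 1 / p$tau)),
    encounter_duration = log(c(p$lambda_enc, p$lambda_blank)),
    constant = log(p$lambda0))
}

rate_par_unpack <- function(family, direction, par) {
  v <- exp(par)
  switch(family,
    last_encounter = list(lambda0 = v[1], dlambda = v[2] - v[1], tau = 1 / v[3]),
    accumulated_evidence = if (direction == "walk_to_stop")
      list(lambda0 = v[1], lambda1 = v[2], lambda2 = v[3], tau = 1 / v[4])
      else list(lambda0 = v[1], dlambda = v[2], tau = 1 / v[3]),
    encounter_duration = list(lambda_enc = v[1], lambda_blank = v[2]),
    constant = list(lambda0 = v[1]))
}

rate_par_names <- function(family, direction) {
  switch(family,
    last_encounter = c("lambda0", "dlambda", "tau"),
    accumulated_evidence = if (direction == "walk_to_stop")
      c("lambda0", "lambda1", "lambda2", "tau") else
      c("lambda0", "dlambda", "tau"),
    encounter_duration = c("lambda_enc", "lambda_blank"),
    constant = "lambda0")
}

# precompute everything the likelihood needs for a set of sequences;
# sufficient statistics make the per-evaluation cost independent of
# the number of time steps where the model structure allows it
prepare_rate_subset <- function(family, direction, sequences, dt) {
  pre <- list(family = family, direction = direction, dt = dt)
  if (family == "last_encounter") {
    # survival term: sum over exposure steps of exp(-DT/tau) reduces
    # to a weighted geometric series over the integer-lag histogram
    kmax <- 0L; n_inf <- 0L; n_expo <- 0L
    hist_acc <- numeric(0)
    dTv <- list()
    for (s in sequences) {
      ts <- transition_steps(s$walking, direction)
      dT <- time_since_onset(s$w, s$dt)
      dTe <- dT[ts$exposure]
      fin <- is.finite(dTe)
      n_inf <- n_inf + sum(!fin); n_expo <- n_expo + length(dTe)
      k <- round(dTe[fin] / s$dt) + 1L
      if (length(k) > 0) {
        if (max(k) > length(hist_acc))
          hist_acc <- c(hist_acc, numeric(max(k) - length(hist_acc)))
        tb <- tabulate(k, nbins = length(hist_acc))
        hist_acc <- hist_acc + tb
      }
      dTv[[length(dTv) + 1L]] <- dT[ts$events]
    }
    pre$lag_counts <- hist_acc        # counts for DT = 0, dt, 2 dt, ...
    pre$n_inf <- n_inf
    pre$n_exposure <- n_expo
    pre$dT_events <- unlist(dTv)
  } else if (family == "encounter_duration") {
    e1 <- e0 <- v1 <- v0 <- 0L
    for (s in sequences) {
      ts <- transition_steps(s$walking, direction)
      de <- s$d[ts$exposure]; dv <- s$d[ts$events]
      e1 <- e1 + sum(de); e0 <- e0 + sum(1 - de)
      v1 <- v1 + sum(dv); v0 <- v0 + sum(1 - dv)
    }
    pre$counts <- c(exp_enc = e1, exp_blank = e0, ev_enc = v1, ev_blank = v0)
  } else if (family == "constant") {
    n_exp <- 0L; n_ev <- 0L
    for (s in sequences) {
      ts <- transition_steps(s$walking, direction)
      n_exp <- n_exp + length(ts$exposure); n_ev <- n_ev + length(ts$events)
    }
    pre$n_exposure <- n_exp; pre$n_events <- n_ev
  } else if (family == "accumulated_evidence" &&
             direction == "stop_to_walk") {
    # the walk model is linear in the evidence A(t), so the survival
    # term needs only the onset/exposure lag cross-correlation and the
    # event terms only each event's list of preceding-onset lags
    lagN <- numeric(0); n_expo <- 0L
    ev_lags <- list(); ev_grp <- list(); n_ev <- 0L
    for (s in sequences) {
      ts <- transition_steps(s$walking, direction)
      n <- length(s$w)
      onsets <- which(s$w > 0)
      expo <- ts$exposure
      n_expo <- n_expo + length(expo)
      if (length(onsets) > 0 && length(expo) > 0) {
        # N_L = number of (onset, exposure-step) pairs at lag L >= 0,
        # via zero-padded FFT cross-correlation
        m <- 2L * n
        ind <- numeric(m); ind[expo] <- 1
        wo <- numeric(m); wo[onsets] <- 1
        cc <- Re(stats::fft(stats::fft(ind) * Conj(stats::fft(wo)),
                            inverse = TRUE)) / m
        cc <- round(cc[seq_len(n)])
        if (n > length(lagN)) lagN <- c(lagN, numeric(n - length(lagN)))
        lagN[seq_len(n)] <- lagN[seq_len(n)] + cc
      }
      for (e in ts$events) {
        n_ev <- n_ev + 1L
        os <- onsets[onsets <= e]
        if (length(os) > 0) {
          ev_lags[[length(ev_lags) + 1L]] <- e - os
          ev_grp[[length(ev_grp) + 1L]] <- rep(n_ev, length(os))
        }
      }
    }
    pre$lagN <- lagN
    pre$n_exposure <- n_expo
    pre$n_events <- n_ev
    pre$event_lags <- unlist(ev_lags) %||% integer(0)
    pre$event_group <- unlist(ev_grp) %||% integer(0)
  } else { # accumulated_evidence stop: nonlinear in A, keep sequences
    pre$sequences <- lapply(sequences, function(s) {
      ts <- transition_steps(s$walking, direction)
      list(w = s$w, exposure = ts$exposure, events = ts$events, dt = s$dt)
    })
  }
  pre
}

rate_negloglik <- function(par, pre) {
  p <- rate_par_unpack(pre$family, pre$direction, par)
  dt <- pre$dt
  ll <- switch(pre$family,
    last_encounter = {
      q <- exp(-dt / p$tau)
      kern <- q^(seq_along(pre$lag_counts) - 1L)
      sum_exp <- p$lambda0 * pre$n_exposure +
        p$dlambda * sum(pre$lag_counts * kern)
      lv <- p$lambda0 + p$dlambda * exp(-pre$dT_events / p$tau)
      if (any(lv <= 0) || p$lambda0 + p$dlambda <= 0) return(1e10)
      -dt * sum_exp + sum(log(dt * lv) - dt * lv)
    },
    encounter_duration = {
      cts <- pre$counts
      -dt * (cts["exp_enc"] * p$lambda_enc + cts["exp_blank"] * p$lambda_blank) +
        cts["ev_enc"] * (log(dt * p$lambda_enc) - dt * p$lambda_enc) +
        cts["ev_blank"] * (log(dt * p$lambda_blank) - dt * p$lambda_blank)
    },
    constant = -dt * pre$n_exposure * p$lambda0 +
      pre$n_events * (log(dt * p$lambda0) - dt * p$lambda0),
    accumulated_evidence = if (!is.null(pre$lagN)) {
      q <- exp(-dt / p$tau)
      kern <- q^(seq_along(pre$lagN) - 1L)
      sum_a <- sum(pre$lagN * kern)
      a_ev <- numeric(pre$n_events)
      if (length(pre$event_lags) > 0) {
        v <- rowsum(q^pre$event_lags, pre$event_group)
        a_ev[as.integer(rownames(v))] <- v[, 1]
      }
      lam_ev <- p$lambda0 + p$dlambda * a_ev
      -dt * (p$lambda0 * pre$n_exposure + p$dlambda * sum_a) +
        sum(log(dt * lam_ev) - dt * lam_ev)
    } else {
      tot <- 0
      for (s in pre$sequences) {
        a <- exp_filter(s$w, s$dt, p$tau)
        lam <- if (pre$direction == "walk_to_stop")
          p$lambda0 + p$lambda1 / (1 + p$lambda2 * a)
          else p$lambda0 + p$dlambda * a
        tot <- tot - s$dt * sum(lam[s$exposure]) +
          sum(log(s$dt * lam[s$events]) - s$dt * lam[s$events])
      }
      tot
    })
  if (!is.finite(ll)) return(1e10)
  -as.numeric(ll)
}

default_rate_inits <- function(family, direction, data) {
  pre <- prepare_rate_subset("constant", direction, data$sequences, data$dt)
  base <- max(pre$n_events, 1L) / max(pre$n_exposure * data$dt, data$dt)
  switch(family,
    last_encounter = list(lambda0 = base, dlambda = 0.5 * base, tau = 0.5),
    accumulated_evidence = if (direction == "walk_to_stop")
      list(lambda0 = base / 2, lambda1 = base, lambda2 = 1, tau = 0.5)
      else list(lambda0 = base, dlambda = base, tau = 0.5),
    encounter_duration = list(lambda_enc = base, lambda_blank = base),
    constant = list(lambda0 = base))
}

#' Fit a rate model by subset maximum likelihood
#'
#' Quasi-Newton (L-BFGS-B) maximization of [bout_log_likelihood()] on
#' random subsets of the sequences, on log-transformed parameters
#' (inverse timescales, so that timescale parameters enter the cost
#' linearly in the exponent). Box bounds span two orders of magnitude
#' around the initializer; estimates landing within 5% (of the log
#' range) of a bound are flagged as bound-hugging, a symptom that the
#' family cannot represent the data. Non-convergent subsets are
#' excluded from the medians and counted.
#'
#' @param family,direction as in [rate_model_spec()].
#' @param data a [bout_data()] with at least 20 observed transitions.
#' @param n_subsets number of random subsets (default 500).
#' @param subset_fraction fraction of sequences per subset (default 0.2).
#' @param inits optional named list of initial parameter values.
#' @param bound_decades half-width of the box bounds in decades
#'   (default 1, i.e. a two-decade range).
#' @param seed integer seed.
#' @return object of class `rate_model_fit`: per-subset estimate table,
#'   per-parameter medians, a `rate_model_spec` at the medians, and the
#'   full-data log-likelihood at the medians.
#' @export
fit_rate_model <- function(family, direction, data, n_subsets = 500,
                           subset_fraction = 0.2, inits = NULL,
                           bound_decades = 1, seed = 1L) {
  stopifnot(inherits(data, "bout_data"))
  n_seq <- length(data$sequences)
  pre_all <- prepare_rate_subset("constant", direction, data$sequences, data$dt)
  if (pre_all$n_events < 20L)
    stop("need at least 20 observed transitions to fit")
  inits <- inits %||% default_rate_inits(family, direction, data)
  par0 <- rate_par_pack(family, direction, inits)
  lb <- par0 - bound_decades * log(10)
  ub <- par0 + bound_decades * log(10)
  pnames <- rate_par_names(family, direction)
  set.seed(seed)
  n_take <- max(2L, round(subset_fraction * n_seq))
  rows <- vector("list", n_subsets)
  for (b in seq_len(n_subsets)) {
    ids <- sample.int(n_seq, n_take)
    pre <- prepare_rate_subset(family, direction, data$sequences[ids], data$dt)
    opt <- try(stats::optim(par0, rate_negloglik, pre = pre,
                            method = "L-BFGS-B", lower = lb, upper = ub,
                            control = list(maxit = 200)), silent = TRUE)
    if (inherits(opt, "try-error")) {
      rows[[b]] <- c(rep(NA_real_, length(pnames)), converged = 0,
                     at_bound = NA, logL = NA_real_)
      next
    }
    est <- rate_par_unpack(family, direction, opt$par)
    hug <- any(opt$par - lb < 0.05 * (ub - lb) |
               ub - opt$par < 0.05 * (ub - lb))
    rows[[b]] <- c(unlist(est[pnames]), converged = as.numeric(opt$convergence == 0),
                   at_bound = as.numeric(hug), logL = -opt$value)
  }
  tab <- as.data.frame(do.call(rbind, rows))
  names(tab) <- c(pnames, "converged", "at_bound", "logL")
  tab$subset <- seq_len(n_subsets)
  ok <- tab$converged == 1 & !is.na(tab$converged)
  if (!any(ok)) stop("no subset converged; fit failed")
  med <- lapply(tab[ok, pnames, drop = FALSE], stats::median)
  spec <- rate_model_spec(family, direction, med)
  pre_full <- prepare_rate_subset(family, direction, data$sequences, data$dt)
  ll_full <- -rate_negloglik(rate_par_pack(family, direction, med), pre_full)
  structure(list(family = family, direction = direction,
                 estimates = tab, medians = med, spec = spec,
                 n_failed = sum(!ok), frac_at_bound = mean(tab$at_bound[ok]),
                 logL = ll_full, n_params = length(pnames),
                 n_events = pre_all$n_events,
                 n_steps = pre_all$n_exposure + pre_all$n_events),
            class = "rate_model_fit")
}

#' @export
print.rate_model_fit <- function(x, ...) {
  cat(sprintf("<rate_model_fit> %s (%s): medians %s; %d/%d subsets failed, %.0f%% bound-hugging\n",
              x$family, x$direction,
              paste(names(x$medians), signif(unlist(x$medians), 3),
                    sep = "=", collapse = ", "),
              x$n_failed, nrow(x$estimates), 100 * x$frac_at_bound))
  invisible(x)
}
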