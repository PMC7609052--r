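# shared builders for synthetic fixtures; everything is generated in
# code at test time

DT <- 1 / 90

bg_model <- function(mean = 5, sd = 1) {
  structure(list(mean = mean, sd = sd), class = "background_model")
}

# square-pulse signal trace: background level plus pulses given as
# (onset_s, duration_s, level) rows
pulse_trace <- function(pulses, total = 5, base = 5, dt = DT) {
  n <- round(total / dt)
  v <- rep(base, n)
  for (i in seq_len(nrow(pulses))) {
    a <- round(pulses[i, 1] / dt) + 1
    b <- min(n, a + round(pulses[i, 2] / dt) - 1)
    v[a:b] <- pulses[i, 3]
  }
  signal_trace(v, dt)
}

# piecewise-constant-speed trajectory builder (uniform dt)
make_trajectory <- function(total = 10, speed = 10, theta = 90, dt = DT,
                            omega = 0) {
  t <- seq(0, total, by = dt)
  th <- (theta + omega * t) %% 360
  h <- heading_vector(th)
  x <- 100 + cumsum(c(0, speed * dt * h[-length(t), 1]))
  y <- 0 + cumsum(c(0, speed * dt * h[-length(t), 2]))
  data.frame(t = t, x = x, y = y, theta = th)
}

poisson_trains <- function(n, rate, total, dur = 0.02, seed0 = 1) {
  lapply(seq_len(n), function(i) generate_encounter_train(
    encounter_train_config(rate, list(dist = "constant", value = dur),
                           total_time = total, seed = seed0 + i)))
}

empty_trains <- function(n, total, dt = DT) {
  steps <- round(total / dt)
  lapply(seq_len(n), function(i)
    encounter_series(integer(steps), dt, w = integer(steps)))
}

fitted_stop_spec <- function() rate_model_spec(
  "last_encounter", "walk_to_stop",
  list(lambda0 = 0.78, dlambda = -0.61, tau = 0.25))

fitted_walk_spec <- function() rate_model_spec(
  "accumulated_evidence", "stop_to_walk",
  list(lambda0 = 0.29, dlambda = 0.41, tau = 0.52))

# labeled sequences from the generative stop/walk + turn models
make_bout_sequences <- function(n_seq, total, rate = 4, seed = 1,
                                stop_spec = fitted_stop_spec(),
                                walk_spec = fitted_walk_spec()) {
  trains <- poisson_trains(n_seq, rate, total, seed0 = seed * 1000)
  st <- simulate_state_sequences(stop_spec, walk_spec, trains, seed = seed)
  seqs <- lapply(seq_len(n_seq), function(j)
    list(walking = st$walking[, j], w = trains[[j]]$w, d = trains[[j]]$d,
         dt = DT))
  list(data = bout_data(seqs), trains = trains)
}

# brute-force product-form likelihood oracle, coded independently of
# the vectorized implementation
naive_bout_loglik <- function(spec, data) {
  total <- 0
  for (s in data$sequences) {
    lam <- rate_trace(spec, s$w, s$d, s$dt)
    for (i in seq_along(s$walking)) {
      exposure <- if (spec$direction == "walk_to_stop") s$walking[i]
                  else !s$walking[i]
      event <- if (i == 1) FALSE
               else if (spec$direction == "walk_to_stop")
                 !s$walking[i] && s$walking[i - 1]
               else s$walking[i] && !s$walking[i - 1]
      if (event)
        total <- total + log(s$dt * lam[i]) - s$dt * lam[i]
      else if (exposure)
        total <- total - s$dt * lam[i]
    }
  }
  total
}
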