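# independent, naively coded likelihood used as an oracle against the
# vectorized implementation
naive_turn_loglik <- function(params, data) {
  total <- 0
  for (s in data$sequences) {
    for (i in seq_along(s$dtheta)) {
      if (!s$walking[i]) next
      lam <- 1 / params$tau_turn + s$w_freq[i] / params$tau_freq +
        s$w_dur[i] / params$tau_dur
      if (s$turn[i]) {
        p_t <- 1 / (1 + exp(-params$alpha * params$filter_tau * s$w_freq[i]))
        mu_up <- if (sin(s$theta[i] * pi / 180) >= 0) -params$turn_mean
                 else params$turn_mean
        mu <- if (s$upwind[i]) mu_up else -mu_up
        pdir <- if (s$upwind[i]) p_t else 1 - p_t
        total <- total + log(s$dt * lam) - s$dt * lam + log(pdir) +
          dnorm(s$dtheta[i], mu, params$turn_sd, log = TRUE)
      } else {
        total <- total - s$dt * lam +
          dnorm(s$dtheta[i], 0, params$straight_jitter_sd, log = TRUE)
      }
    }
  }
  total
}

test_that("the sigmoid has its stated identities", {
  expect_equal(upwind_turn_probability(0, 0.242), 0.5)
  expect_equal(upwind_turn_probability(0, -3), 0.5)
  expect_equal(upwind_turn_probability(c(1, 5, 12), 0), rep(0.5, 3))
  # direct evaluation at a filtered signal value of 3
  expect_equal(upwind_turn_probability(3, 0.242), 1 / (1 + exp(-0.726)))
  # p(x; a) + p(x; -a) = 1
  x <- c(0.3, 1, 4, 9)
  expect_equal(upwind_turn_probability(x, 0.242) +
                 upwind_turn_probability(x, -0.242), rep(1, 4))
  expect_error(upwind_turn_probability(-1, 0.2), "non-negative")
})

test_that("the full turn rate composes base rate and modulation", {
  p0 <- turn_model_params(tau_turn = 0.75)
  expect_equal(full_turn_rate(p0, 2, 1), 1 / 0.75)  # modulation disabled
  pm <- turn_model_params(tau_turn = 0.75, tau_freq = 10, tau_dur = 5)
  expect_equal(full_turn_rate(pm, 2, 1), 1 / 0.75 + 0.2 + 0.2)
  expect_error(full_turn_rate(
    turn_model_params(tau_turn = 0.75, tau_freq = -0.1), 1, 0), "positive")
})

test_that("turn log-likelihood matches hand and brute-force oracles", {
  params <- turn_model_params(tau_turn = 0.75)
  # empty data
  expect_equal(turn_log_likelihood(params, turn_likelihood_data(list())), 0)

  # one straight step, hand-computable
  one <- turn_likelihood_data(list(list(
    dtheta = 0, theta = 90, w_freq = 0, w_dur = 0, walking = TRUE,
    turn = FALSE, upwind = NA, dt = 1 / 90)))
  hand <- -(1 / 90) * (4 / 3) + dnorm(0, 0, 0.22, log = TRUE)
  expect_equal(turn_log_likelihood(params, one), hand)

  # 10-step toy data against the independently coded product form
  set.seed(5)
  toy <- turn_likelihood_data(list(list(
    dtheta = c(0.1, -0.2, 28, 0, 0.3, -31, 0.05, -0.1, 0.2, 0),
    theta = seq(10, 340, length.out = 10),
    w_freq = runif(10, 0, 3), w_dur = runif(10, 0, 1),
    walking = rep(TRUE, 10),
    turn = c(F, F, T, F, F, T, F, F, F, F),
    upwind = c(NA, NA, TRUE, NA, NA, FALSE, NA, NA, NA, NA),
    dt = 1 / 90)))
  pm <- turn_model_params(alpha = 0.242, tau_turn = 0.75,
                          tau_freq = 8, tau_dur = 6)
  expect_equal(turn_log_likelihood(pm, toy), naive_turn_loglik(pm, toy),
               tolerance = 1e-10)
})

test_that("the fast fitting path agrees with the full likelihood", {
  set.seed(11)
  tp <- turn_model_params()
  trains <- poisson_trains(12, 3, 30, seed0 = 40)
  sim <- simulate_turn_ensemble(tp, trains, seed = 3)
  gt <- structure(list(walking = matrix(TRUE, nrow(sim$theta), 12),
                       theta = sim$theta, turns = sim$turns,
                       trains = trains, time_step = DT),
                  class = "ground_truth_behavior")
  td <- as_turn_data(gt)
  st <- plumewalk:::turn_fit_stats(td, 1:12, filter_tau = 2)
  for (par in list(c(0.242, log(1 / 0.75)), c(0, 0), c(0.5, log(2)))) {
    pr <- turn_model_params(alpha = par[1], tau_turn = exp(-par[2]))
    full <- turn_log_likelihood(pr, td)
    # the fast path drops the angle-density constants
    const <- full - (-plumewalk:::turn_negloglik_fast(
      c(pr$alpha, log(1 / pr$tau_turn)), st))
    if (!exists("const0")) const0 <- const
    expect_equal(const, const0, tolerance = 1e-8)
  }
})

test_that("simulation recovers its generating parameters", {
  set.seed(1)
  tp <- turn_model_params()
  n_traj <- 60
  rates <- runif(n_traj, 0.05, 10)
  trains <- lapply(seq_len(n_traj), function(i) generate_encounter_train(
    encounter_train_config(rates[i], list(dist = "constant", value = 0.02),
                           total_time = 60, seed = i)))
  sim <- simulate_turn_ensemble(tp, trains, seed = 11)
  gt <- structure(list(walking = matrix(TRUE, nrow(sim$theta), n_traj),
                       theta = sim$theta, turns = sim$turns,
                       trains = trains, time_step = DT),
                  class = "ground_truth_behavior")
  fit <- fit_turn_model(as_turn_data(gt), n_subsets = 60, seed = 3)
  expect_equal(fit$medians$alpha, 0.242, tolerance = 0.1)
  expect_equal(fit$medians$tau_turn, 0.75, tolerance = 0.1)

  # null recovery: alpha = 0 data gives a median gain straddling zero
  sim0 <- simulate_turn_ensemble(turn_model_params(alpha = 0), trains,
                                 seed = 12)
  gt0 <- structure(list(walking = matrix(TRUE, nrow(sim0$theta), n_traj),
                        theta = sim0$theta, turns = sim0$turns,
                        trains = trains, time_step = DT),
                   class = "ground_truth_behavior")
  fit0 <- fit_turn_model(as_turn_data(gt0), n_subsets = 40, seed = 4)
  spread <- quantile(fit0$estimates$alpha, c(0.1, 0.9), na.rm = TRUE)
  expect_lt(abs(fit0$medians$alpha), 0.03)
  expect_true(spread[1] < 0 && spread[2] > 0)
})

test_that("inter-turn intervals are exponential with mean tau_turn without odor", {
  tp <- turn_model_params(straight_jitter_sd = 0)
  trains <- empty_trains(30, 120)
  sim <- simulate_turn_ensemble(tp, trains, seed = 21)
  iti <- unlist(lapply(split(sim$turns$time, sim$turns$traj), diff))
  expect_gt(length(iti), 2000)
  expect_equal(mean(iti), 0.75, tolerance = 0.05)
  # exponential shape: CV near 1
  expect_equal(sd(iti) / mean(iti), 1, tolerance = 0.1)
})

test_that("the unbiased model has a uniform stationary reflected orientation", {
  tp <- turn_model_params(alpha = 0)
  trains <- poisson_trains(30, 3, 120, seed0 = 60)
  sim <- simulate_turn_ensemble(tp, trains, seed = 22)
  tail_part <- theta_plus(sim$theta[2000:nrow(sim$theta), ])
  expect_equal(mean(tail_part), 90, tolerance = 0.04)
})

test_that("simulation matches the discrete-chain stationary oracle at fixed drive", {
  # degenerate magnitudes and no jitter make the simulator the chain
  # degenerate magnitudes (exactly 30 deg), no jitter, and a constant
  # sigmoid drive make the simulator identical to the 7-state chain.
  # A train with an onset at every step drives the raw filter to the
  # steady value A = 1/(1 - exp(-dt/tau)); the gain is chosen so the
  # upwind probability is exactly p_fix at that plateau.
  p_fix <- 0.674
  dt <- DT
  n <- round(600 / dt)
  A <- 1 / (1 - exp(-dt / 2))
  tp <- turn_model_params(alpha = log(p_fix / (1 - p_fix)) / A,
                          turn_sd = 0, straight_jitter_sd = 0)
  w <- rep(1L, n)
  trains <- rep(list(encounter_series(w, dt, w = w)), 8)
  sim <- simulate_turn_ensemble(tp, trains, theta0 = 90, seed = 31)
  sim_mean <- mean(theta_plus(sim$theta[round(n / 10):n, ]))
  oracle <- turn_chain_stationary_mean(p_fix)
  expect_equal(sim_mean, oracle, tolerance = 0.05)
})

test_that("orientation declines with encounter frequency for positive gain", {
  tp <- turn_model_params()
  trains <- poisson_trains(20, 2.5, 90, seed0 = 80)
  sim <- simulate_turn_ensemble(tp, trains, seed = 41)
  burn <- 1500
  res <- orientation_vs_frequency_curve(
    as.vector(sim$theta[burn:nrow(sim$theta), ]),
    as.vector(sim$w_freq[burn:nrow(sim$w_freq), ]))
  expect_lt(res$slope, 0)
  # binned means non-increasing within sampling error
  mt <- res$curve$mean_theta_plus[res$curve$n > 200]
  expect_true(all(diff(mt) < 8))
  # ensemble determinism from the seed
  sim2 <- simulate_turn_ensemble(tp, trains, seed = 41)
  expect_identical(sim$theta, sim2$theta)
})

test_that("turn magnitudes have the configured folded-normal statistics", {
  set.seed(9)
  m <- draw_turn_magnitudes(turn_model_params(), 2e4)
  expect_true(all(m > 0))
  expect_equal(mean(m), 30, tolerance = 0.01)
  expect_equal(sd(m), 10, tolerance = 0.03)
})

test_that("rate-modulation coefficients straddle zero on unmodulated data", {
  set.seed(71)
  trains <- poisson_trains(20, 3, 40, seed0 = 700)
  sim <- simulate_turn_ensemble(turn_model_params(), trains, seed = 72)
  gt <- structure(list(walking = matrix(TRUE, nrow(sim$theta), 20),
                       theta = sim$theta, turns = sim$turns,
                       trains = trains, time_step = DT),
                  class = "ground_truth_behavior")
  fit <- fit_turn_model(as_turn_data(gt), n_subsets = 10,
                        subset_fraction = 0.3, fit_modulation = TRUE,
                        seed = 73)
  q_f <- range(fit$estimates$inv_tau_freq, na.rm = TRUE)
  q_d <- range(fit$estimates$inv_tau_dur, na.rm = TRUE)
  expect_true(q_f[1] < 0 && q_f[2] > 0)
  expect_true(q_d[1] < 0 && q_d[2] > 0)
  # base parameters still recovered
  expect_equal(fit$medians$tau_turn, 0.75, tolerance = 0.15)
})
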