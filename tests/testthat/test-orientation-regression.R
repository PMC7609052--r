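# piecewise-rate encounter train: the local onset rate switches every
# `segment` seconds, emulating a fly moving through plume regions of
# different density; durations are lognormal so frequency and duration
# decorrelate
piecewise_train <- function(total, segment = 10, seed = 1,
                            rate_range = c(0.1, 6)) {
  set.seed(seed)
  n_seg <- ceiling(total / segment)
  parts <- lapply(seq_len(n_seg), function(k) {
    r <- runif(1, rate_range[1], rate_range[2])
    dur_scale <- exp(runif(1, log(0.03), log(0.3)))
    tr <- generate_encounter_train(encounter_train_config(
      r, list(dist = "lognormal", meanlog = log(dur_scale), sdlog = 0.6),
      total_time = segment, seed = seed * 1000 + k))
    cbind(tr$w, tr$d)
  })
  m <- do.call(rbind, parts)
  encounter_series(m[, 2], DT, w = m[, 1] * (1 - c(0, m[-nrow(m), 2])))
}

# simulated flies with known turn dynamics on piecewise-rate trains
make_reg_sequences <- function(n_traj = 30, total = 60, alpha = 0.242,
                               seed = 1, with_signal = TRUE) {
  trains <- lapply(seq_len(n_traj), function(i)
    piecewise_train(total, seed = seed * 100 + i))
  sim <- simulate_turn_ensemble(turn_model_params(alpha = alpha), trains,
                                seed = seed + 7)
  set.seed(seed + 13)
  lapply(seq_len(n_traj), function(j) {
    tr <- trains[[j]]
    n <- length(tr$w)
    s <- NULL
    if (with_signal) {
      # per-encounter random amplitude so concentration decorrelates
      # from exposure
      amp <- numeric(n)
      iv <- tr$intervals
      for (k in seq_len(nrow(iv))) {
        a <- round(iv$onset[k] / DT) + 1; b <- round(iv$offset[k] / DT)
        amp[a:b] <- rlnorm(1, log(30), 0.8)
      }
      s <- pmax(5 + amp + rnorm(n, 0, 1), 0)
    }
    list(theta = sim$theta[, j], walking = rep(TRUE, n),
         enc = tr, s = s, dt = DT)
  })
}

test_that("trilinear regression matches a normal-equations oracle", {
  set.seed(3)
  n <- 100
  df <- data.frame(trajectory = rep(1:5, each = 20),
                   t = rep(1:20, 5),
                   theta_plus = NA,
                   W_freq = runif(n, 0, 4), W_dur = runif(n, 0, 2),
                   W_conc = runif(n, 0, 50),
                   since_onset = 1, w_freq_at_onset = 1)
  df$theta_plus <- 90 - 12 * scale(df$W_freq)[, 1] + rnorm(n, 0, 5)
  res <- trilinear_regression(df)
  # independently coded normal-equations solve on the standardized design
  Z <- cbind(1, scale(as.matrix(df[, c("W_freq", "W_dur", "W_conc")])))
  beta <- solve(t(Z) %*% Z, t(Z) %*% df$theta_plus)
  expect_equal(unname(res$coefficients$coef), as.numeric(beta),
               tolerance = 1e-8)
  # residuals orthogonal to regressors at machine precision
  r <- stats::residuals(res$fit)
  expect_lt(max(abs(t(Z) %*% r)), 1e-7)
  # standardization of the included steps
  expect_lt(abs(mean(scale(df$W_freq))), 1e-12)
})

test_that("trilinear regression identifies frequency as the sole driver", {
  seqs <- make_reg_sequences(seed = 11)
  ds <- regression_dataset(seqs)
  res <- trilinear_regression(ds)
  cf <- res$coefficients
  expect_lt(cf$coef[cf$term == "W_freq"], 0)
  expect_lt(cf$p[cf$term == "W_freq"], 1e-6)
  # frequency dominates the other sensory channels
  expect_gt(abs(cf$coef[cf$term == "W_freq"]) /
              max(abs(cf$coef[cf$term %in% c("W_dur", "W_conc")])), 3)
  expect_lt(res$condition_number, 10)
  expect_false(res$multicollinear)
})

test_that("engineered collinearity triggers the rank diagnostic", {
  set.seed(5)
  n <- 200
  df <- data.frame(trajectory = 1, t = 1:n, theta_plus = rnorm(n, 90, 10),
                   W_freq = runif(n), W_dur = NA, W_conc = runif(n),
                   since_onset = 1, w_freq_at_onset = 1)
  df$W_dur <- 2 * df$W_freq          # perfectly correlated
  expect_error(trilinear_regression(df), "rank|singular")
})

test_that("post-encounter orientation change is null for unbiased flies", {
  seqs0 <- make_reg_sequences(seed = 21, alpha = 0, n_traj = 40)
  res0 <- post_encounter_orientation_change(seqs0, seed = 2)
  expect_lt(max(abs(res0$mean_dtheta_plus[res0$n > 100])), 8)

  # biased flies: encounters followed by many others give stronger
  # upwind (negative) change than isolated ones, for downwind headings
  seqs <- make_reg_sequences(seed = 22, n_traj = 60)
  res <- post_encounter_orientation_change(seqs, seed = 3)
  down <- res$theta_bin > 90
  m4 <- mean(res$mean_dtheta_plus[res$partition == "4+" & down], na.rm = TRUE)
  m0 <- mean(res$mean_dtheta_plus[res$partition == "0" & down], na.rm = TRUE)
  expect_lt(m4, m0)
  expect_lt(m4, 0)
})

test_that("frequency-orientation slope decays with delay since the last encounter", {
  seqs <- make_reg_sequences(seed = 31, n_traj = 80, total = 90)
  ds <- regression_dataset(seqs)
  res <- orientation_vs_frequency_at_delay(ds, delays = c(0.25, 2, 6),
                                           half_width = 0.25)
  expect_lt(res$slope[1], 0)
  expect_lt(res$p[1], 0.05)
  # the dependence largely decays once the filter and the orientation
  # memory have relaxed
  expect_lt(abs(res$slope[3]), 0.5 * max(abs(res$slope)))
})

test_that("conditioning on duration preserves only the frequency dependence", {
  seqs <- make_reg_sequences(seed = 41, n_traj = 80, total = 90)
  ds <- regression_dataset(seqs)
  hold_dur <- conditioned_orientation_curves(ds, hold = "W_dur")
  expect_true(all(hold_dur$slopes$slope < 0))
  # reverse control: bias proportional to W_dur instead of W_freq
  set.seed(42)
  n_traj <- 60
  trains <- lapply(seq_len(n_traj), function(i) generate_encounter_train(
    encounter_train_config(runif(1, 0.1, 6),
                           list(dist = "exponential", mean = 0.15),
                           total_time = 60, seed = 4200 + i)))
  seqs2 <- lapply(seq_len(n_traj), function(j) {
    n <- length(trains[[j]]$w)
    wd <- exp_filter(trains[[j]]$d, DT, 2) * DT
    # deterministic stand-in: orientation tracks duration, not frequency
    list(theta = pmin(pmax(90 - 30 * wd + rnorm(n, 0, 5), 0), 180),
         walking = rep(TRUE, n), enc = trains[[j]], dt = DT)
  })
  ds2 <- regression_dataset(seqs2)
  hold_freq <- conditioned_orientation_curves(ds2, hold = "W_freq")
  expect_true(mean(hold_freq$slopes$slope < 0) >= 0.75)
})

test_that("post-encounter curves are reproducible from the baseline seed", {
  seqs <- make_reg_sequences(seed = 51, n_traj = 20)
  res1 <- post_encounter_orientation_change(seqs, seed = 4)
  res2 <- post_encounter_orientation_change(seqs, seed = 4)
  expect_identical(res1, res2)
})
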