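test_that("rate traces follow the stated formulas", {
  dt <- DT
  stop_spec <- fitted_stop_spec()
  # at an onset the stopping rate drops to lambda0 + dlambda = 0.17
  lam <- rate_trace(stop_spec, c(0, 1, 0, 0), c(0, 1, 0, 0), dt)
  expect_equal(lam[2], 0.17)
  # before any encounter the rate is the baseline
  expect_equal(lam[1], 0.78)
  # relaxation back to baseline with timescale tau
  expect_equal(lam[3], 0.78 - 0.61 * exp(-dt / 0.25))

  # no-odor limit for every family
  w0 <- integer(50); d0 <- integer(50)
  expect_true(all(rate_trace(stop_spec, w0, d0, dt) == 0.78))
  expect_true(all(rate_trace(fitted_walk_spec(), w0, d0, dt) == 0.29))
  ed <- rate_model_spec("encounter_duration", "walk_to_stop",
                        list(lambda_enc = 0.2, lambda_blank = 0.9))
  expect_true(all(rate_trace(ed, w0, d0, dt) == 0.9))
  expect_true(all(rate_trace(ed, w0, rep(1L, 50), dt) == 0.2))

  # accumulated evidence: hand-summed kernel for two onsets 0.1 s apart
  wk <- fitted_walk_spec()
  gap <- round(0.1 / dt)
  w <- integer(100); w[10] <- 1L; w[10 + gap] <- 1L
  lam_w <- rate_trace(wk, w, w, dt)
  a_expect <- 1 + exp(-gap * dt / 0.52)
  expect_equal(lam_w[10 + gap], 0.29 + 0.41 * a_expect, tolerance = 1e-12)

  # last-encounter rate is continuous between onsets and resets at them
  w2 <- integer(200); w2[50] <- 1L; w2[150] <- 1L
  lam2 <- rate_trace(stop_spec, w2, w2, dt)
  expect_equal(lam2[150], 0.17)
  expect_true(all(diff(lam2[51:149]) > 0))  # monotone relaxation

  expect_error(rate_model_spec("last_encounter", "walk_to_stop",
                               list(lambda0 = 0.1, dlambda = -0.2, tau = 1)),
               "positive")
})

test_that("bout log-likelihood matches closed forms and the product oracle", {
  dt <- DT
  spec <- rate_model_spec("constant", "walk_to_stop", list(lambda0 = 0.5))
  # one walk bout of 90 steps ending in a stop
  n <- 91
  seqs <- list(list(walking = c(rep(TRUE, 90), FALSE), w = integer(n),
                    d = integer(n), dt = dt))
  ll <- bout_log_likelihood(spec, bout_data(seqs, dt))
  expect_equal(ll, -(91) * dt * 0.5 + log(dt * 0.5))

  expect_equal(bout_log_likelihood(spec, bout_data(list(), dt)), 0)

  # brute-force oracle on generated data, all families
  made <- make_bout_sequences(4, 15, seed = 9)
  specs <- list(
    fitted_stop_spec(), fitted_walk_spec(),
    rate_model_spec("accumulated_evidence", "walk_to_stop",
                    list(lambda0 = 0.2, lambda1 = 0.6, lambda2 = 1.5,
                         tau = 0.4)),
    rate_model_spec("encounter_duration", "stop_to_walk",
                    list(lambda_enc = 0.8, lambda_blank = 0.25)))
  for (sp in specs)
    expect_equal(bout_log_likelihood(sp, made$data),
                 naive_bout_loglik(sp, made$data), tolerance = 1e-9)
})

test_that("bouts censored by the trajectory end contribute survival terms only", {
  dt <- DT
  spec <- fitted_stop_spec()
  # a walk that never ends: no event factor appears
  n <- 300
  w <- integer(n); w[100] <- 1L
  seqs <- list(list(walking = rep(TRUE, n), w = w, d = w, dt = dt))
  lam <- rate_trace(spec, w, w, dt)
  expect_equal(bout_log_likelihood(spec, bout_data(seqs, dt)),
               -dt * sum(lam))
  # the same walk ending in a stop adds exactly the event factor
  seqs2 <- list(list(walking = c(rep(TRUE, n - 1), FALSE), w = w, d = w,
                     dt = dt))
  expect_equal(bout_log_likelihood(spec, bout_data(seqs2, dt)),
               -dt * sum(lam) + log(dt * lam[n]))
})

test_that("expected transition counts match the integrated rate", {
  made <- make_bout_sequences(80, 30, seed = 17)
  spec <- fitted_stop_spec()
  dt <- DT
  n_events <- 0; expected <- 0
  for (s in made$data$sequences) {
    ts <- plumewalk:::transition_steps(s$walking, "walk_to_stop")
    lam <- rate_trace(spec, s$w, s$d, dt)
    n_events <- n_events + length(ts$events)
    expected <- expected + sum(lam[ts$exposure]) * dt
  }
  expect_lt(abs(n_events - expected), 4 * sqrt(expected))
})

test_that("subset MLE recovers generating parameters for both directions", {
  made <- make_bout_sequences(350, 30, seed = 21)
  f_stop <- fit_rate_model("last_encounter", "walk_to_stop", made$data,
                           n_subsets = 40, seed = 5)
  expect_equal(f_stop$medians$lambda0, 0.78, tolerance = 0.1)
  expect_equal(f_stop$medians$dlambda, -0.61, tolerance = 0.15)
  expect_equal(f_stop$medians$tau, 0.25, tolerance = 0.25)

  f_walk <- fit_rate_model("accumulated_evidence", "stop_to_walk",
                           made$data, n_subsets = 30, seed = 6)
  expect_equal(f_walk$medians$lambda0, 0.29, tolerance = 0.25)
  expect_equal(f_walk$medians$dlambda, 0.41, tolerance = 0.2)
  expect_equal(f_walk$medians$tau, 0.52, tolerance = 0.3)
})

test_that("fitting a mismatched family yields broad, bound-hugging estimates", {
  made <- make_bout_sequences(120, 30, seed = 23)
  f <- fit_rate_model("accumulated_evidence", "walk_to_stop", made$data,
                      n_subsets = 25, seed = 7)
  f_true <- fit_rate_model("last_encounter", "walk_to_stop", made$data,
                           n_subsets = 25, seed = 7)
  expect_gt(f$frac_at_bound, f_true$frac_at_bound)
  expect_gt(f$frac_at_bound, 0.2)
})

test_that("model statistics distinguish encounter-dependent stopping", {
  # sparse trains: at high encounter rates random times are themselves
  # always near an onset and the conditioning washes out
  made <- make_bout_sequences(60, 30, rate = 0.7, seed = 29)
  stats <- transition_statistics(fitted_stop_spec(), made$trains,
                                 grid = seq(0.2, 6, by = 0.2), seed = 3)
  cv <- stats$curves
  early <- cv$time <= 1.5
  surv_all <- cv$survival[cv$condition == "all" & early]
  surv_rand <- cv$survival[cv$condition == "random" & early]
  # walks persist longer after encounters than after random times over
  # the window where the rate dip acts (a few multiples of tau_s)
  expect_gt(mean(surv_all - surv_rand, na.rm = TRUE), 0.02)

  # constant-rate control: conditioned curves coincide with baselines
  stats0 <- transition_statistics(
    rate_model_spec("constant", "walk_to_stop", list(lambda0 = 0.6)),
    made$trains, grid = seq(0.2, 6, by = 0.2), seed = 4)
  cv0 <- stats0$curves
  early0 <- cv0$time <= 1.5
  d0 <- mean(cv0$survival[cv0$condition == "all" & early0] -
               cv0$survival[cv0$condition == "random" & early0],
             na.rm = TRUE)
  expect_lt(abs(d0), 0.03)
})

test_that("cross-validated comparison selects the generating family", {
  train <- make_bout_sequences(120, 30, seed = 31)
  held <- make_bout_sequences(80, 30, seed = 32)
  fits <- lapply(c("last_encounter", "accumulated_evidence",
                   "encounter_duration"), function(fam)
    fit_rate_model(fam, "walk_to_stop", train$data, n_subsets = 15,
                   seed = 8))
  cmp <- compare_models(fits, held$data, grid = seq(0.2, 6, by = 0.2),
                        seed = 9)
  expect_equal(cmp$selected, "last_encounter")
  expect_false(cmp$tie)
  expect_true(all(is.finite(cmp$table$AIC)))

  # two identical models: reported as a tie
  cmp2 <- compare_models(list(fits[[1]], fits[[1]]), held$data,
                         grid = seq(0.2, 6, by = 0.2), seed = 9)
  expect_true(cmp2$tie)
})

test_that("bout encounter accumulation rises with walk duration", {
  made <- make_bout_sequences(60, 30, seed = 37)
  st <- simulate_state_sequences(fitted_stop_spec(), fitted_walk_spec(),
                                 made$trains, seed = 11)
  curve <- bout_encounter_curve(st$walking, made$trains, "walk")
  ok <- !is.na(curve$mean_count) & curve$n_bouts > 20
  expect_gt(sum(ok), 2)
  expect_true(all(diff(curve$mean_count[ok]) > 0))
})

test_that("rate model YAML round-trips and fit tables are written", {
  spec <- fitted_walk_spec()
  path <- file.path(tempdir(), "spec.yaml")
  write_rate_model_yaml(spec, path)
  back <- read_rate_model_yaml(path)
  expect_equal(back$params, spec$params)
  expect_equal(back$family, spec$family)
})

test_that("constant rates give exponential bout durations and turns stay in walks", {
  lam <- 0.5
  cst_s <- rate_model_spec("constant", "walk_to_stop", list(lambda0 = lam))
  cst_w <- rate_model_spec("constant", "stop_to_walk", list(lambda0 = lam))
  steps <- round(2000 / DT)
  trains <- lapply(1:20, function(i)
    encounter_series(integer(steps), DT, w = integer(steps)))
  st <- simulate_state_sequences(cst_s, cst_w, trains, seed = 71)
  durs <- numeric(0)
  for (j in 1:20) {
    r <- rle(st$walking[, j])
    keep <- seq_along(r$lengths)
    keep <- keep[keep > 1 & keep < length(r$lengths)]  # completed bouts
    durs <- c(durs, r$lengths[keep] * DT)   # both states share the rate
  }
  expect_gt(length(durs), 1e4)
  expect_equal(mean(durs), 1 / lam, tolerance = 0.05)
  ks <- suppressWarnings(stats::ks.test(durs, "pexp", lam))
  expect_lt(ks$statistic, 0.02)

  # ground-truth behavior: turns occur only during walks
  gt <- simulate_ground_truth_behavior(
    turn_model_params(), fitted_stop_spec(), fitted_walk_spec(),
    poisson_trains(5, 2, 60, seed0 = 900), seed = 72)
  walk_at_turn <- mapply(function(tr, st) gt$walking[st, tr],
                         gt$turns$traj, gt$turns$step)
  expect_true(all(walk_at_turn))
})
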