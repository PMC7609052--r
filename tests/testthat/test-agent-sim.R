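small_field <- function(duration = 10, seed = 5, ...) {
  plume_field(plume_config(seed = seed, ...), duration)
}

test_that("agents with zero walk speed never move and never arrive", {
  fld <- small_field()
  par0 <- agent_params(walk_speed = 0)
  res <- run_agents(fld, par0, n_agents = 20, n_steps = 300, seed = 3)
  expect_true(all(res$traces$x == res$traces$x[1, 1]))
  expect_equal(sum(res$arrived), 0L)
})

test_that("the agent ensemble is reproducible from its seed", {
  fld <- small_field()
  p <- agent_params()
  r1 <- run_agents(fld, p, n_agents = 15, n_steps = 400, seed = 11)
  r2 <- run_agents(fld, p, n_agents = 15, n_steps = 400, seed = 11)
  expect_identical(r1$traces$x, r2$traces$x)
  expect_identical(r1$n_onsets, r2$n_onsets)
})

test_that("state bookkeeping partitions time and turns happen while walking", {
  fld <- small_field(duration = 20)
  res <- run_agents(fld, agent_params(), n_agents = 40, n_steps = 1800,
                    seed = 7)
  dt <- res$time_step
  # completed + censored bout durations account for every agent's time
  total <- sum(res$walk_durations, res$stop_durations,
               res$censored_walk, res$censored_stop)
  expect_equal(total, res$n_agents * res$n_steps * dt, tolerance = 1e-9)
  expect_gte(res$n_upwind_turns, 0)
  expect_lte(res$n_upwind_turns, res$n_turns)
  # occupancy counts every agent-step once
  expect_equal(sum(res$occupancy$counts), res$n_agents * res$n_steps)
})

test_that("a continuous high signal registers at most one onset per refractory", {
  # constant strong field: zero packets but background mean far above
  # the detection threshold is not possible, so instead saturate with a
  # dense overlap of giant packets
  cfg <- plume_config(packet_emission_rate = 80, packet_init_radius = 200,
                      packet_growth_rate = 0.1, packet_peak_intensity = 200,
                      intensity_decay_exponent = 0, emission_y_sd = 1,
                      packet_lateral_speed_sd = 0.1, seed = 9)
  fld <- plume_field(cfg, 5)
  res <- run_agents(fld, agent_params(), n_agents = 10, n_steps = 360,
                    seed = 13)
  # 360 steps = 4 s of continuous exposure; a contiguous excursion
  # registers one onset, and the 100 ms refractory caps re-crossings
  # caused by noise dips at one per 100 ms
  expect_true(all(res$n_onsets <= 40))
  expect_true(all(res$n_onsets >= 1))
})

test_that("turn ablation of an unbiased reference fixes p at about one half", {
  fld <- small_field(duration = 20)
  p0 <- agent_params(turn_params = turn_model_params(alpha = 0))
  ref <- run_agents(fld, p0, n_agents = 60, n_steps = 1800, seed = 17)
  abl <- ablate(p0, "turn", ref)
  expect_equal(abl$turn_params$fixed_p_upwind, 0.5, tolerance = 0.1)
})

test_that("stop ablation preserves overall stop prevalence", {
  fld <- small_field(duration = 30)
  p <- agent_params()
  ref <- run_agents(fld, p, n_agents = 80, n_steps = 2700, seed = 19)
  abl_par <- ablate(p, "stop", ref)
  expect_equal(abl_par$stop_spec$family, "constant")
  abl <- run_agents(fld, abl_par, n_agents = 80, n_steps = 2700, seed = 20)
  frac_ref <- sum(ref$stop_durations, ref$censored_stop) /
    (ref$n_agents * ref$n_steps * ref$time_step)
  frac_abl <- sum(abl$stop_durations, abl$censored_stop) /
    (abl$n_agents * abl$n_steps * abl$time_step)
  expect_equal(frac_abl, frac_ref, tolerance = 0.25)
})

test_that("performance metrics are zero against an identical control and match a tally", {
  fld <- small_field(duration = 30)
  # start halfway down the arena so arrivals occur within the short run
  ar <- arena_config(start_margin = 180)
  res <- run_agents(fld, agent_params(), ar, n_agents = 60, n_steps = 2700,
                    seed = 23)
  expect_gt(sum(res$arrived), 0)
  pm <- performance_metrics(res, res, n_boot = 10, seed = 1)
  expect_equal(pm$value, c(0, 0))
  # independent per-agent tally
  ctl <- run_agents(fld, agent_params(turn_params = turn_model_params(alpha = 0)),
                    ar, n_agents = 60, n_steps = 2700, seed = 24)
  if (sum(ctl$arrived) > 0) {
    pm2 <- performance_metrics(res, ctl, n_boot = 5, seed = 2)
    tally <- 100 * (sum(res$arrived) - sum(ctl$arrived)) / sum(ctl$arrived)
    expect_equal(pm2$value[1], tally)
  }
})

test_that("occupancy pdf applies the trajectory filters and normalizes", {
  fld <- small_field(duration = 30)
  res <- run_agents(fld, agent_params(), n_agents = 50, n_steps = 2700,
                    seed = 29)
  occ <- occupancy_pdf(res)
  if (occ$n_kept > 0) {
    expect_equal(sum(occ$pdf, na.rm = TRUE), 1, tolerance = 1e-9)
    expect_equal(sum(occ$marginal_x$p), 1, tolerance = 1e-9)
    expect_true(all(occ$marginal_x$x > 20))
  }
  # stationary agents are filtered out entirely
  res0 <- run_agents(fld, agent_params(walk_speed = 0), n_agents = 5,
                     n_steps = 2700, seed = 30)
  expect_warning(occ0 <- occupancy_pdf(res0), "filtered")
  expect_equal(occ0$n_kept, 0L)
})

test_that("short trajectories fall to the duration filter", {
  fld <- small_field(duration = 6)
  # 4 s run: excluded by the 5 s minimum; 6 s run passes
  res4 <- run_agents(fld, agent_params(), n_agents = 10, n_steps = 360,
                     seed = 31)
  expect_warning(o4 <- occupancy_pdf(res4), "filtered")
  res6 <- run_agents(fld, agent_params(), n_agents = 10, n_steps = 540,
                     seed = 31)
  o6 <- occupancy_pdf(res6, min_displacement = 20)
  expect_gt(o6$n_kept, 0)
})

test_that("uniform random positions give a flat occupancy pdf", {
  # synthetic result object with uniformly scattered positions
  set.seed(33)
  n_steps <- 4000; n_agents <- 5
  fake <- structure(list(
    n_agents = n_agents, n_steps = n_steps, time_step = 1 / 90,
    arena = arena_config(),
    traces = list(
      x = matrix(runif(n_steps * n_agents, 0, 300), n_steps),
      y = matrix(runif(n_steps * n_agents, -90, 90), n_steps))),
    class = "agent_sim_result")
  occ <- occupancy_pdf(fake, bin = 30, min_displacement = 0,
                       min_speed = 0)
  counts <- occ$pdf * n_steps * n_agents
  chi2 <- sum((counts - mean(counts))^2 / mean(counts))
  # 60 bins: chi-square well below a generous upper quantile
  expect_lt(chi2, qchisq(0.999, length(counts) - 1))
})

test_that("perceived encounter statistics are computed over the plume mask", {
  fld <- small_field(duration = 20)
  res <- run_agents(fld, agent_params(), n_agents = 30, n_steps = 1800,
                    seed = 37)
  msk <- plume_mask(fld, grid_res = 10)
  ps <- perceived_encounter_stats(res, msk)
  expect_gt(ps$n_encounters, 0)
  expect_gt(ps$mean_duration, 0.05)
  expect_lt(ps$mean_duration, 1)
  expect_true(is.finite(ps$mean_frequency))
  expect_gt(ps$time_in_plume, 0)
})
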