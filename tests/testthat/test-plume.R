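# plume statistics tests use short movies rendered over small windows
# so the whole file stays fast

test_that("a plume without packets is pure background noise", {
  cfg <- plume_config(packet_emission_rate = 1e-9, seed = 3)
  mov <- generate_plume_movie(cfg, duration = 12,
                              window = list(x = c(10, 40), y = c(-15, 15)),
                              pixel_size = 1)
  bg <- bg_model(cfg$background_mean, cfg$background_noise_sd)
  m <- intermittency_map(mov, bg, median_filter_mm = 1)
  # noise false positives at 2.5 sigma stay below 1% on average
  expect_lt(mean(m), 0.01)
  expect_lt(max(m), 0.025)
  tr <- movie_pixel_trace(mov, c(20, 0))
  e <- detect_encounters(tr, bg)
  expect_equal(nrow(e$intervals), 0L)
})

test_that("movie generation validates duration and is seed-deterministic", {
  cfg <- plume_config(seed = 5)
  expect_error(generate_plume_movie(cfg, duration = 0.123), "multiple")
  w <- list(x = c(10, 30), y = c(-10, 10))
  m1 <- generate_plume_movie(cfg, 2, window = w, pixel_size = 1)
  m2 <- generate_plume_movie(cfg, 2, window = w, pixel_size = 1)
  expect_identical(m1$frames, m2$frames)
})

test_that("centerline intermittency near the source lies in the reported band", {
  cfg <- plume_config(seed = 11)
  mov <- generate_plume_movie(cfg, duration = 60,
                              window = list(x = c(14, 26), y = c(-6, 6)),
                              pixel_size = 1)
  bg <- bg_model(cfg$background_mean, cfg$background_noise_sd)
  m <- intermittency_map(mov, bg, median_filter_mm = 2.3)
  iy <- which.min(abs(attr(m, "y") - 0))
  ix <- which.min(abs(attr(m, "x") - 20))
  expect_gte(m[iy, ix], 0.12)
  expect_lte(m[iy, ix], 0.39)
})

test_that("intermittency decays off-axis, by brute-force frame counting", {
  cfg <- plume_config(seed = 13)
  fld <- plume_field(cfg, 40)
  pts <- rbind(c(150, 0), c(150, 20), c(150, 40), c(150, 60))
  s <- field_point_series(fld, pts)
  thr <- 2.5 * cfg$background_noise_sd
  fr <- colMeans(s > thr)
  expect_true(all(diff(fr) < 0))
  expect_gt(fr[1], fr[2])
})

test_that("the intermittency map equals direct counting with a 1-pixel filter", {
  cfg <- plume_config(seed = 17)
  mov <- generate_plume_movie(cfg, duration = 12,
                              window = list(x = c(100, 120), y = c(-10, 10)),
                              pixel_size = 2)
  bg <- bg_model(cfg$background_mean, cfg$background_noise_sd)
  m <- intermittency_map(mov, bg, median_filter_mm = 2)  # 1 px kernel
  thr <- bg$mean + 2.5 * bg$sd
  direct <- apply(mov$frames > thr, c(1, 2), mean)
  expect_equal(unclass(m), direct, ignore_attr = TRUE, tolerance = 1e-6)
})

test_that("power-law tail fits recover synthetic exponents and flag exponentials", {
  set.seed(21)
  pareto <- 0.01 * runif(5000)^(-1 / 1.5)  # survival exponent -1.5
  fit <- powerlaw_tail_fit(pareto)
  expect_equal(fit$exponent, -2.5, tolerance = 0.12)
  expect_equal(fit$survival_exponent, -1.5, tolerance = 0.12)
  expect_false(fit$poor_fit)

  expo <- rexp(5000, 10)
  fit2 <- powerlaw_tail_fit(expo)
  expect_true(fit2$poor_fit)

  expect_true(is.na(powerlaw_tail_fit(rexp(10))$exponent))
})

test_that("per-point duration distributions span wide ranges in the plume", {
  cfg <- plume_config(seed = 23)
  fld <- plume_field(cfg, 60)
  trs <- field_signal_traces(fld, rbind(c(250, 0)), seed = 2)
  bg <- bg_model(cfg$background_mean, cfg$background_noise_sd)
  e <- detect_encounters(trs[[1]], bg,
                         encounter_config(min_encounter_duration = 1 / 90))
  durs <- e$intervals$duration
  gaps <- e$intervals$onset[-1] - e$intervals$offset[-nrow(e$intervals)]
  expect_gt(nrow(e$intervals), 50)
  # encounters and blanks jointly span at least two decades
  expect_gte(log10(max(durs) / min(durs)), 1.5)
  expect_gte(log10(max(c(durs, gaps)) / min(c(durs, gaps))), 2)
})

test_that("directional encounter probability matches ray geometry", {
  # single static blob directly upwind of the origin
  cfg <- plume_config(packet_emission_rate = 1e-9, background_noise_sd = 0.1,
                      seed = 31)
  mov <- generate_plume_movie(cfg, 2, window = list(x = c(120, 180),
                                                    y = c(-20, 20)),
                              pixel_size = 1)
  # paint a compact blob upwind of the origin; a 5-sigma threshold
  # keeps quantized background noise strictly below threshold
  xs <- mov$x; ys <- mov$y
  blob <- outer(ys, xs, function(y, x) 100 * exp(-((x - 135)^2 + y^2) / 18))
  mov$frames <- array(as.integer(pmin(
    rep(blob, dim(mov$frames)[3]) + as.vector(mov$frames), 255)),
    dim(mov$frames))
  bg <- bg_model(cfg$background_mean, 0.1)
  res <- directional_encounter_probability(
    mov, origin = c(150, 0), speed = 10, horizon = 1, bg = bg,
    cfg = encounter_config(k_sigma = 5),
    headings = c(0, 90, 180, 270))
  # heading 0 is upwind (-x): the walk enters the blob; others never do
  expect_equal(res$probability[res$heading == 0], 1)
  expect_equal(res$probability[res$heading == 180], 0)
  expect_equal(res$probability[res$heading == 90], 0)
})

test_that("virtual antenna extraction matches brute-force pixel averaging", {
  cfg <- plume_config(packet_emission_rate = 1e-9, background_noise_sd = 0.1,
                      seed = 33)
  mov <- generate_plume_movie(cfg, 3 / 90, window = list(x = c(90, 110),
                                                         y = c(-10, 10)),
                              pixel_size = 0.154)
  blob <- outer(mov$y, mov$x,
                function(y, x) 60 * exp(-((x - 100)^2 + (y - 2)^2) / 8))
  mov$frames <- array(as.integer(pmin(
    rep(blob, 3) + as.vector(mov$frames), 255)), dim(mov$frames))

  # uniform field: trace equals the constant regardless of pose
  mov_u <- mov
  mov_u$frames <- array(10L, dim(mov$frames))
  traj <- data.frame(t = (0:2) / 90, x = c(100, 100, 100),
                     y = c(0, 0, 0), theta = c(0, 90, 213))
  tr_u <- extract_virtual_antenna_signal(mov_u, traj)
  expect_true(all(tr_u$values == 10))

  # blob field: trace maximal when the patch center hits the blob center
  geo <- antenna_geometry()
  thetas <- seq(0, 350, by = 10)
  traj2 <- data.frame(t = rep(0, length(thetas)), x = 100, y = 0,
                      theta = thetas)
  traj2$t <- 0
  vals <- sapply(seq_along(thetas), function(i) {
    tt <- traj2[i, , drop = FALSE]; tt$t <- 0
    extract_virtual_antenna_signal(mov, tt, geo)$values
  })
  # blob center is 2 mm along +y; patch center lands there at theta = 90
  expect_equal(thetas[which.max(vals)], 90)

  # brute-force oracle at one pose
  h <- heading_vector(90)
  cx <- 100 + geo$offset * h[1]; cy <- 0 + geo$offset * h[2]
  px <- rep(mov$x, each = length(mov$y)); py <- rep(mov$y, length(mov$x))
  u <- (px - cx) * h[1] + (py - cy) * h[2]
  v <- -(px - cx) * h[2] + (py - cy) * h[1]
  inside <- (u / geo$semi_minor)^2 + (v / geo$semi_major)^2 <= 1
  fr1 <- mov$frames[, , 1]
  oracle <- mean(fr1[inside])   # both are y-fastest column-major
  got <- extract_virtual_antenna_signal(
    mov, data.frame(t = 0, x = 100, y = 0, theta = 90), geo)$values
  expect_equal(got, oracle, tolerance = 1e-12)
})

test_that("plume movies round-trip through the raw-u8 layout", {
  cfg <- plume_config(seed = 41)
  mov <- generate_plume_movie(cfg, 1, window = list(x = c(50, 70),
                                                    y = c(-8, 8)),
                              pixel_size = 1)
  path <- file.path(tempdir(), "movie-test")
  write_plume_movie(mov, path)
  back <- read_plume_movie(path)
  expect_equal(back$frames, mov$frames, ignore_attr = TRUE)
  expect_equal(back$frame_rate, mov$frame_rate)
  expect_equal(back$x, mov$x, tolerance = 1e-9)
})
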