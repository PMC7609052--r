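#' Synthetic plume configuration
#'
#' Parameters of the packet-based plume generator. The generator
#' emulates the wind-tunnel arena: a mean flow advects discrete odor
#' packets downwind from the source while stochastically alternating
#' lateral jets (a two-state telegraph process) sweep the plume from
#' side to side, producing a conical, highly intermittent plume.
#'
#' Coordinates: the source sits at the origin, `x` increases downwind
#' (arena `x` in `[0, arena_size[1]]`), `y` is centered on the source
#' (`[-arena_size[2]/2, arena_size[2]/2]`). All positions in mm.
#'
#' `packet_emission_rate`, `packet_growth_rate`, `packet_init_radius`,
#' `packet_peak_intensity`, `intensity_decay_exponent` and
#' `lateral_coupling` are calibration knobs: the defaults were fixed
#' once so that the plume statistics land in the regime of the imaged
#' smoke plume (centerline intermittency of a few tenths near the
#' source, heavy-tailed encounter/blank durations, and perceived
#' encounter statistics near 200 ms / 4 Hz for navigating agents).
#'
#' @param mean_flow_speed downwind advection speed (mm/s), default 150.
#' @param jet_switch_rate telegraph switching rate (1/s), default 10
#'   (100 ms correlation time).
#' @param jet_speed lateral jet speed (mm/s), default 1500.
#' @param lateral_coupling fraction of `jet_speed` transferred to the
#'   cross-wind drift of the packets.
#' @param packet_emission_rate Poisson packet emission rate (1/s).
#' @param packet_growth_rate packet radius growth (mm/s).
#' @param packet_init_radius packet radius at emission (mm).
#' @param packet_peak_intensity peak intensity of a fresh packet
#'   (8-bit scale units).
#' @param intensity_decay_exponent dilution exponent: peak intensity
#'   scales as `(r0 / r)^gamma`.
#' @param emission_y_sd SD of the lateral emission jitter (mm).
#' @param packet_lateral_speed_sd SD of the per-packet transverse
#'   drift speed (mm/s): each packet follows its own straight
#'   transverse ray, so the instantaneous plume is a cone full of
#'   independent filaments rather than a single coherent ribbon.
#' @param source_position 2-vector (mm), default `c(0, 0)`.
#' @param arena_size 2-vector (mm), default `c(300, 180)`.
#' @param frame_rate frames per second, default 90.
#' @param pixel_size rendered pixel size (mm), default 0.154.
#' @param background_mean mean background (shot-noise) intensity.
#' @param background_noise_sd SD of the background intensity.
#' @param seed integer seed.
#' @return object of class `plume_config`.
#' @export
plume_config <- function(mean_flow_speed = 150,
                         jet_switch_rate = 10,
                         jet_speed = 1500,
                         lateral_coupling = 0.01,
                         packet_emission_rate = 40,
                         packet_growth_rate = 1.5,
                         packet_init_radius = 1,
                         packet_peak_intensity = 70,
                         intensity_decay_exponent = 0.7,
                         emission_y_sd = 7,
                         packet_lateral_speed_sd = 8,
                         source_position = c(0, 0),
                         arena_size = c(300, 180),
                         frame_rate = 90,
                         pixel_size = 0.154,
                         background_mean = 5,
                         background_noise_sd = 1,
                         seed = 1L) {
  for (nm in c("mean_flow_speed", "jet_switch_rate", "jet_speed",
               "lateral_coupling", "packet_emission_rate",
               "packet_growth_rate", "packet_init_radius",
               "packet_peak_intensity", "frame_rate", "pixel_size",
               "background_noise_sd"))
    check_scalar(get(nm), nm)
  if (length(arena_size) != 2L || any(arena_size <= 0))
    stop("arena_size must be two positive lengths")
  structure(list(
    mean_flow_speed = mean_flow_speed, jet_switch_rate = jet_switch_rate,
    jet_speed = jet_speed, lateral_coupling = lateral_coupling,
    packet_emission_rate = packet_emission_rate,
    packet_growth_rate = packet_growth_rate,
    packet_init_radius = packet_init_radius,
    packet_peak_intensity = packet_peak_intensity,
    intensity_decay_exponent = intensity_decay_exponent,
    emission_y_sd = emission_y_sd,
    packet_lateral_speed_sd = packet_lateral_speed_sd,
    source_position = source_position, arena_size = arena_size,
    frame_rate = frame_rate, pixel_size = pixel_size,
    background_mean = background_mean,
    background_noise_sd = background_noise_sd,
    seed = as.integer(seed)
  ), class = "plume_config")
}

#' Simulate the packet state of a synthetic plume
#'
#' Draws the telegraph cross-wind velocity and the packet emission
#' times for `duration` seconds. The resulting `plume_field` supports
#' exact point evaluation of the noiseless intensity at any frame,
#' which is what the movie renderer and the agent simulator sample.
#'
#' @param config a [plume_config()].
#' @param duration simulated time (s); must be a multiple of the frame
#'   interval.
#' @param seed optional seed overriding `config$seed`.
#' @return object of class `plume_field`.
#' @export
plume_field <- function(config, duration, seed = NULL) {
  stopifnot(inherits(config, "plume_config"))
  check_scalar(duration, "duration")
  dt <- 1 / config$frame_rate
  n_frames <- duration * config$frame_rate
  if (abs(n_frames - round(n_frames)) > 1e-9)
    stop("duration must be a multiple of the frame interval")
  n_frames <- as.integer(round(n_frames))
  set.seed(seed %||% config$seed)

  # global two-state telegraph lateral velocity, one value per frame
  switch_p <- config$jet_switch_rate * dt
  flips <- stats::runif(n_frames) < switch_p
  state <- 2 * (cumsum(flips) %% 2) - 1
  if (stats::runif(1) < 0.5) state <- -state
  v_lat <- config$lateral_coupling * config$jet_speed * state
  y_lat <- cumsum(v_lat) * dt   # accumulated lateral displacement (mm)

  # Poisson packet emissions (at most one per frame)
  emit <- which(stats::runif(n_frames) < config$packet_emission_rate * dt)
  y0 <- stats::rnorm(length(emit), 0, config$emission_y_sd)
  vy <- stats::rnorm(length(emit), 0, config$packet_lateral_speed_sd)

  max_age <- (config$arena_size[1] + 6 * (config$packet_init_radius +
                config$packet_growth_rate * 3)) / config$mean_flow_speed
  structure(list(
    config = config, n_frames = n_frames, time_step = dt,
    emit_frame = emit, emit_y = y0, emit_vy = vy, y_lat = y_lat,
    max_age_frames = as.integer(ceiling(max_age / dt))
  ), class = "plume_field")
}

#' @export
print.plume_field <- function(x, ...) {
  cat(sprintf("<plume_field> %.3g s at %g Hz; %d packets emitted\n",
              x$n_frames * x$time_step, 1 / x$time_step,
              length(x$emit_frame)))
  invisible(x)
}

active_packets <- function(field, frame) {
  e <- field$emit_frame
  which(e <= frame & e > frame - field$max_age_frames)
}

#' Noiseless plume intensity at arbitrary points
#'
#' Sum-of-Gaussian-packets evaluation at one frame. Background noise is
#' not included; renderers and samplers add it.
#'
#' @param field a [plume_field()].
#' @param frame frame index (1-based).
#' @param points n x 2 matrix of (x, y) positions (mm).
#' @return numeric vector of intensities (length n).
#' @export
field_intensity <- function(field, frame, points) {
  points <- matrix(points, ncol = 2)
  cfg <- field$config
  idx <- active_packets(field, frame)
  out <- numeric(nrow(points))
  if (length(idx) == 0L) return(out)
  age <- (frame - field$emit_frame[idx]) * field$time_step
  px <- cfg$source_position[1] + age * cfg$mean_flow_speed
  py <- cfg$source_position[2] + field$emit_y[idx] +
    field$emit_vy[idx] * age +
    field$y_lat[frame] - field$y_lat[field$emit_frame[idx]]
  r <- cfg$packet_init_radius + cfg$packet_growth_rate * age
  amp <- cfg$packet_peak_intensity *
    (cfg$packet_init_radius / r)^cfg$intensity_decay_exponent
  dx2 <- outer(points[, 1], px, `-`)^2
  dy2 <- outer(points[, 2], py, `-`)^2
  contrib <- exp(-(dx2 + dy2) / rep(2 * r^2, each = nrow(points)))
  as.numeric(contrib %*% amp)
}

#' Noiseless intensity time series at fixed points
#'
#' Efficient per-packet accumulation of the full frame series at a
#' small set of fixed positions.
#'
#' @param field a [plume_field()].
#' @param points n x 2 matrix (mm).
#' @return matrix n_frames x n of intensities (no noise).
#' @export
field_point_series <- function(field, points) {
  points <- matrix(points, ncol = 2)
  cfg <- field$config
  n <- field$n_frames
  out <- matrix(0, n, nrow(points))
  dt <- field$time_step
  for (j in seq_along(field$emit_frame)) {
    f0 <- field$emit_frame[j]
    fr <- f0:min(n, f0 + field$max_age_frames)
    age <- (fr - f0) * dt
    px <- cfg$source_position[1] + age * cfg$mean_flow_speed
    py <- cfg$source_position[2] + field$emit_y[j] +
      field$emit_vy[j] * age +
      field$y_lat[fr] - field$y_lat[f0]
    r <- cfg$packet_init_radius + cfg$packet_growth_rate * age
    amp <- cfg$packet_peak_intensity *
      (cfg$packet_init_radius / r)^cfg$intensity_decay_exponent
    for (k in seq_len(nrow(points))) {
      d2 <- (points[k, 1] - px)^2 + (points[k, 2] - py)^2
      out[fr, k] <- out[fr, k] + amp * exp(-d2 / (2 * r^2))
    }
  }
  out
}

#' Signal traces at fixed plume positions
#'
#' Adds Gaussian background noise to [field_point_series()] and wraps
#' each column as a [signal_trace()], clamped to the 8-bit scale.
#'
#' @param field a [plume_field()].
#' @param points n x 2 matrix (mm).
#' @param seed seed for the noise draws.
#' @return list of [signal_trace()] objects.
#' @export
field_signal_traces <- function(field, points, seed = 1L) {
  cfg <- field$config
  s <- field_point_series(field, points)
  set.seed(seed)
  s <- s + matrix(stats::rnorm(length(s), cfg$background_mean,
                               cfg$background_noise_sd), nrow(s))
  s <- pmin(pmax(s, 0), 255)
  lapply(seq_len(ncol(s)), function(k) signal_trace(s[, k], field$time_step))
}

#' Render a plume movie
#'
#' Rasterizes a [plume_field()] (or simulates a new one from a config)
#' onto a pixel grid, adding Gaussian background noise and quantizing
#' to the 0-255 intensity scale. A spatial `window` can restrict
#' rendering to a sub-region of the arena; rendering the full arena at
#' the camera pixel size is rejected when the frame stack would be
#' unreasonably large.
#'
#' @param config a [plume_config()] or an existing [plume_field()].
#' @param duration movie length (s); must be a multiple of the frame
#'   interval. Ignored when `config` is already a field.
#' @param window optional list with `x = c(x0, x1)`, `y = c(y0, y1)`
#'   limits (mm); default the full arena.
#' @param pixel_size optional override of the configured pixel size.
#' @param seed optional seed override.
#' @param max_elements guard on `nx * ny * n_frames` (default 4e8).
#' @return object of class `plume_movie` with fields `frames`
#'   (array `ny x nx x n_frames`), `frame_rate`, `pixel_size`, `x`, `y`
#'   (pixel-center coordinates), and `source_position`.
#' @export
generate_plume_movie <- function(config, duration = NULL, window = NULL,
                                 pixel_size = NULL, seed = NULL,
                                 max_elements = 4e8) {
  if (inherits(config, "plume_field")) {
    field <- config
    config <- field$config
  } else {
    field <- plume_field(config, duration, seed = seed)
  }
  px <- pixel_size %||% config$pixel_size
  window <- window %||% list(
    x = c(0, config$arena_size[1]),
    y = c(-config$arena_size[2] / 2, config$arena_size[2] / 2))
  xs <- seq(window$x[1] + px / 2, window$x[2], by = px)
  ys <- seq(window$y[1] + px / 2, window$y[2], by = px)
  n_frames <- field$n_frames
  if (length(xs) * length(ys) * as.double(n_frames) > max_elements)
    stop("requested movie exceeds max_elements; render a window, ",
         "a coarser pixel size, or a shorter duration")
  grid <- cbind(rep(xs, each = length(ys)), rep(ys, length(xs)))
  frames <- array(0L, c(length(ys), length(xs), n_frames))
  set.seed(derive_seed(seed %||% config$seed, "movie-noise"))
  for (f in seq_len(n_frames)) {
    v <- field_intensity(field, f, grid) +
      stats::rnorm(nrow(grid), config$background_mean,
                   config$background_noise_sd)
    frames[, , f] <- as.integer(round(pmin(pmax(v, 0), 255)))
  }
  structure(list(frames = frames, frame_rate = config$frame_rate,
                 pixel_size = px, x = xs, y = ys,
                 source_position = config$source_position,
                 config = config),
            class = "plume_movie")
}

#' @export
print.plume_movie <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<plume_movie> %d x %d px, %d frames at %g Hz (%.3g mm/px)\n",
              d[2], d[1], d[3], x$frame_rate, x$pixel_size))
  invisible(x)
}

#' Nominal plume-cone half width
#'
#' Analytic envelope of the synthetic plume used to classify positions
#' as inside/outside the plume cone: packet radius at the downwind
#' transit time plus 2.5 lateral-dispersion SDs of the telegraph drift
#' (diffusivity `v_lat^2 / switch_rate`).
#'
#' @param config a [plume_config()].
#' @param x downwind distance(s) from the source (mm).
#' @return half width(s) in mm.
#' @export
plume_cone_halfwidth <- function(config, x) {
  t_transit <- pmax(x, 0) / config$mean_flow_speed
  v_lat <- config$lateral_coupling * config$jet_speed
  d_lat <- v_lat^2 / config$jet_switch_rate
  r <- config$packet_init_radius + config$packet_growth_rate * t_transit
  r + 2 * sqrt(2 * d_lat * t_transit +
               (config$packet_lateral_speed_sd * t_transit)^2) +
    config$emission_y_sd
}

movie_pixel_index <- function(movie, point) {
  ix <- which.min(abs(movie$x - point[1]))
  iy <- which.min(abs(movie$y - point[2]))
  c(iy, ix)
}

#' Intensity time series of the movie pixel nearest a point
#'
#' @param movie a [plume_movie()].
#' @param point 2-vector (mm).
#' @return a [signal_trace()].
#' @export
movie_pixel_trace <- function(movie, point) {
  ij <- movie_pixel_index(movie, point)
  signal_trace(movie$frames[ij[1], ij[2], ], 1 / movie$frame_rate)
}
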