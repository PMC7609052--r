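#' Virtual antenna geometry
#'
#' Elliptical sampling patch placed ahead of the head along the
#' heading, mirroring the imaging analysis: center offset 2.16 mm in
#' front of the body center, semi-major axis 0.77 mm oriented
#' perpendicular to the heading, semi-minor axis 0.23 mm along it
#' (patch area about 1.1 mm^2 at the camera resolution).
#'
#' @param offset distance of the patch center ahead of the body (mm).
#' @param semi_major semi-axis perpendicular to the heading (mm).
#' @param semi_minor semi-axis along the heading (mm).
#' @return object of class `antenna_geometry`.
#' @export
antenna_geometry <- function(offset = 2.16, semi_major = 0.77,
                             semi_minor = 0.23) {
  structure(list(offset = offset, semi_major = semi_major,
                 semi_minor = semi_minor),
            class = "antenna_geometry")
}

#' Heading unit vector
#'
#' Converts wind-relative headings (degrees, 0 = upwind) to arena unit
#' vectors. Wind blows from the source toward +x, so facing upwind
#' means pointing along -x: `h = (-cos(theta), sin(theta))`.
#' @param theta heading(s) in degrees.
#' @return n x 2 matrix of unit vectors.
#' @export
heading_vector <- function(theta) {
  th <- theta * pi / 180
  cbind(-cos(th), sin(th))
}

#' Extract the virtual-antenna signal from a plume movie
#'
#' For each trajectory sample the mean movie intensity over the pixels
#' inside the elliptical antenna patch is computed. Samples whose patch
#' leaves the rendered region are flagged invalid.
#'
#' @param movie a [plume_movie()].
#' @param trajectory data.frame with columns `t` (s, aligned with movie
#'   frames), `x`, `y` (mm), `theta` (deg, 0 = upwind).
#' @param antenna an [antenna_geometry()].
#' @return a [signal_trace()].
#' @export
extract_virtual_antenna_signal <- function(movie, trajectory,
                                           antenna = antenna_geometry()) {
  stopifnot(inherits(movie, "plume_movie"))
  n <- nrow(trajectory)
  dt <- 1 / movie$frame_rate
  frames <- round(trajectory$t / dt) + 1L
  if (any(abs(trajectory$t / dt - (frames - 1L)) > 1e-6))
    stop("trajectory timestamps do not align with movie frames")
  if (any(frames < 1L | frames > dim(movie$frames)[3]))
    stop("trajectory extends beyond the movie")
  vals <- rep(NA_real_, n)
  valid <- logical(n)
  h <- heading_vector(trajectory$theta)
  cx <- trajectory$x + antenna$offset * h[, 1]
  cy <- trajectory$y + antenna$offset * h[, 2]
  a <- antenna$semi_major; b <- antenna$semi_minor
  half <- max(a, b)
  for (i in seq_len(n)) {
    xi <- which(movie$x >= cx[i] - half & movie$x <= cx[i] + half)
    yi <- which(movie$y >= cy[i] - half & movie$y <= cy[i] + half)
    if (length(xi) == 0L || length(yi) == 0L) next
    # patch must lie inside the rendered region
    if (cx[i] - half < movie$x[1] - movie$pixel_size / 2 ||
        cx[i] + half > movie$x[length(movie$x)] + movie$pixel_size / 2 ||
        cy[i] - half < movie$y[1] - movie$pixel_size / 2 ||
        cy[i] + half > movie$y[length(movie$y)] + movie$pixel_size / 2) next
    px <- rep(movie$x[xi], each = length(yi)) - cx[i]
    py <- rep(movie$y[yi], length(xi)) - cy[i]
    # rotate into the antenna frame: u along heading, v perpendicular
    u <- px * h[i, 1] + py * h[i, 2]
    v <- -px * h[i, 2] + py * h[i, 1]
    inside <- (u / b)^2 + (v / a)^2 <= 1
    if (!any(inside)) next
    block <- movie$frames[yi, xi, frames[i]]
    vals[i] <- mean(block[inside])
    valid[i] <- TRUE
  }
  if (!any(valid)) {
    warning("antenna patch outside the rendered region for all samples")
    vals[] <- 0
  } else vals[!valid] <- 0
  signal_trace(vals, dt, valid = valid)
}

median_filter_frame <- function(mat, k) {
  if (k <= 1L) return(mat)
  if (requireNamespace("EBImage", quietly = TRUE)) {
    EBImage::medianFilter(mat / 255, floor(k / 2)) * 255
  } else {
    # plain fallback: k x k running median with edge replication
    ny <- nrow(mat); nx <- ncol(mat); hw <- floor(k / 2)
    out <- mat
    for (i in seq_len(ny)) {
      ri <- max(1, i - hw):min(ny, i + hw)
      for (j in seq_len(nx)) {
        rj <- max(1, j - hw):min(nx, j + hw)
        out[i, j] <- stats::median(mat[ri, rj])
      }
    }
    out
  }
}

#' Per-pixel intermittency map
#'
#' Fraction of frames in which each pixel is above the detection
#' threshold, after median-filtering each frame with a square spatial
#' filter (default 2.3 mm, matching the imaging analysis; a filter
#' size of one pixel reduces to direct frame counting).
#'
#' @param movie a [plume_movie()].
#' @param bg a [fit_background()] model.
#' @param cfg an [encounter_config()] (only `k_sigma` is used).
#' @param median_filter_mm side of the square median filter (mm).
#' @return matrix `ny x nx` of values in `[0, 1]`, with the movie's
#'   `x`/`y` coordinates attached as attributes.
#' @export
intermittency_map <- function(movie, bg, cfg = encounter_config(),
                              median_filter_mm = 2.3) {
  stopifnot(inherits(movie, "plume_movie"))
  n_frames <- dim(movie$frames)[3]
  if (n_frames / movie$frame_rate <= 10)
    stop("movie must be longer than 10 s for a stable intermittency map")
  thr <- bg$mean + cfg$k_sigma * bg$sd
  k <- round(median_filter_mm / movie$pixel_size)
  if (k %% 2 == 0) k <- k + 1L
  acc <- matrix(0, dim(movie$frames)[1], dim(movie$frames)[2])
  for (f in seq_len(n_frames)) {
    fr <- median_filter_frame(movie$frames[, , f], k)
    acc <- acc + (fr > thr)
  }
  m <- acc / n_frames
  attr(m, "x") <- movie$x
  attr(m, "y") <- movie$y
  m
}

#' Least-squares power-law fit to a duration tail
#'
#' Fits `log10(survival) ~ log10(duration)` by ordinary least squares
#' over the top `fit_decades` decades of the observed durations (the
#' empirical survival function is far less biased than binned
#' densities for heavy tails). The reported `exponent` is the DENSITY
#' exponent: a Pareto tail with survival exponent `-alpha` has density
#' exponent `-(alpha + 1)`, and `exponent = survival_exponent - 1`.
#' A quadratic curvature diagnostic flags samples that are not
#' power-law-like (e.g. exponential) as poor fits.
#'
#' @param durations positive durations (s).
#' @param fit_decades width of the tail fit window in decades.
#' @param n_bins log-spaced bins for the returned histogram table.
#' @param curvature_tol absolute quadratic coefficient (per decade^2)
#'   above which the fit is flagged as poor.
#' @return list with `exponent` (density convention),
#'   `survival_exponent`, `se`, `curvature`, `poor_fit`, `n`, and a
#'   log-binned density table `bins`; `exponent` is NA with fewer than
#'   50 durations.
#' @export
powerlaw_tail_fit <- function(durations, fit_decades = 1.5, n_bins = 24,
                              curvature_tol = 0.2) {
  durations <- durations[is.finite(durations) & durations > 0]
  n <- length(durations)
  if (n < 50L)
    return(list(exponent = NA_real_, survival_exponent = NA_real_,
                se = NA_real_, curvature = NA_real_,
                poor_fit = NA, n = n, bins = NULL))
  lo <- log10(min(durations)); hi <- log10(max(durations))
  if (hi - lo < 0.5)
    return(list(exponent = NA_real_, survival_exponent = NA_real_,
                se = NA_real_, curvature = NA_real_,
                poor_fit = TRUE, n = n, bins = NULL))
  x <- sort(durations)
  s <- 1 - (seq_along(x) - 0.5) / n
  keep <- log10(x) >= hi - fit_decades & s > 0
  if (sum(keep) < 10L)
    return(list(exponent = NA_real_, survival_exponent = NA_real_,
                se = NA_real_, curvature = NA_real_,
                poor_fit = TRUE, n = n, bins = NULL))
  lx <- log10(x[keep]); ls <- log10(s[keep])
  fit <- stats::lm(ls ~ lx)
  quad <- stats::lm(ls ~ lx + I(lx^2))
  curv <- unname(stats::coef(quad)[3])
  # log-binned histogram, for plotting and inspection
  edges <- 10^seq(lo, hi, length.out = n_bins + 1)
  edges[1] <- edges[1] * (1 - 1e-9)
  counts <- graphics::hist(durations, breaks = edges, plot = FALSE)$counts
  mids <- sqrt(edges[-1] * edges[-length(edges)])
  bins <- data.frame(duration = mids,
                     density = counts / (n * diff(edges)))
  surv_exp <- unname(stats::coef(fit)[2])
  list(exponent = surv_exp - 1,
       survival_exponent = surv_exp,
       se = summary(fit)$coefficients[2, 2],
       curvature = curv,
       poor_fit = abs(curv) > curvature_tol,
       n = n, bins = bins[bins$density > 0, ])
}

#' Encounter and blank duration distributions at fixed positions
#'
#' Extracts the pixel trace nearest each requested point, detects
#' encounters, and returns the duration samples together with
#' log-binned histograms and power-law tail fits for both encounter
#' and blank durations.
#'
#' @param movie a [plume_movie()].
#' @param points n x 2 matrix of positions (mm), inside the rendered
#'   region.
#' @param bg background model.
#' @param cfg an [encounter_config()].
#' @param fit_decades tail window passed to [powerlaw_tail_fit()].
#' @return list (one element per point) with `encounters`, `blanks`
#'   (duration vectors, s) and the two tail fits.
#' @export
duration_distributions <- function(movie, points, bg,
                                   cfg = encounter_config(),
                                   fit_decades = 1.5) {
  points <- matrix(points, ncol = 2)
  out <- vector("list", nrow(points))
  for (k in seq_len(nrow(points))) {
    p <- points[k, ]
    if (p[1] < min(movie$x) || p[1] > max(movie$x) ||
        p[2] < min(movie$y) || p[2] > max(movie$y))
      stop("point outside the rendered region")
    tr <- movie_pixel_trace(movie, p)
    enc <- detect_encounters(tr, bg, cfg)
    durs <- enc$intervals$duration
    gaps <- if (nrow(enc$intervals) > 1)
      enc$intervals$onset[-1] - enc$intervals$offset[-nrow(enc$intervals)]
    else numeric(0)
    out[[k]] <- list(
      point = p, encounters = durs, blanks = gaps,
      encounter_fit = powerlaw_tail_fit(durs, fit_decades),
      blank_fit = powerlaw_tail_fit(gaps, fit_decades))
  }
  out
}

#' Directional probability of an odor encounter
#'
#' For each heading, the fraction of start frames for which a straight
#' walk from `origin` at `speed` passes above-threshold signal within
#' `horizon` seconds. Near the plume centerline the profile is nearly
#' isotropic; near the edge it skews toward the centerline.
#'
#' @param movie a [plume_movie()].
#' @param origin 2-vector (mm); the whole ray must stay in the rendered
#'   region for every heading.
#' @param speed walking speed (mm/s), default 10.
#' @param horizon look-ahead (s), default 1.
#' @param bg background model.
#' @param cfg an [encounter_config()] (only `k_sigma` is used).
#' @param headings headings to probe (deg).
#' @param frame_stride start-frame subsampling stride.
#' @return data.frame with columns `heading` and `probability`.
#' @export
directional_encounter_probability <- function(movie, origin, speed = 10,
                                              horizon = 1, bg,
                                              cfg = encounter_config(),
                                              headings = seq(0, 345, by = 15),
                                              frame_stride = 3L) {
  stopifnot(inherits(movie, "plume_movie"))
  if (origin[1] < min(movie$x) || origin[1] > max(movie$x) ||
      origin[2] < min(movie$y) || origin[2] > max(movie$y))
    stop("origin outside the rendered region")
  dt <- 1 / movie$frame_rate
  n_ahead <- round(horizon / dt)
  n_frames <- dim(movie$frames)[3]
  thr <- bg$mean + cfg$k_sigma * bg$sd
  starts <- seq(1L, n_frames - n_ahead, by = frame_stride)
  prob <- numeric(length(headings))
  for (hidx in seq_along(headings)) {
    h <- heading_vector(headings[hidx])
    steps <- seq_len(n_ahead)
    px <- origin[1] + h[1] * speed * steps * dt
    py <- origin[2] + h[2] * speed * steps * dt
    if (any(px < min(movie$x) | px > max(movie$x) |
            py < min(movie$y) | py > max(movie$y)))
      stop("ray leaves the rendered region for heading ", headings[hidx])
    iy <- sapply(py, function(v) which.min(abs(movie$y - v)))
    ix <- sapply(px, function(v) which.min(abs(movie$x - v)))
    hit <- logical(length(starts))
    for (si in seq_along(starts)) {
      fr <- starts[si] + steps
      v <- movie$frames[cbind(iy, ix, fr)]
      hit[si] <- any(v > thr)
    }
    prob[hidx] <- mean(hit)
  }
  data.frame(heading = headings, probability = prob)
}
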