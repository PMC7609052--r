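#' Causal discrete exponential filter
#'
#' Applies the recursion `y[i] = x[i] + exp(-dt/tau) * y[i-1]` with zero
#' initial state, i.e. the discrete causal convolution of `x` with the
#' kernel `exp(-t/tau)` sampled at the step times. A unit impulse in `x`
#' therefore contributes exactly 1 at its own step and decays with
#' timescale `tau` afterwards.
#'
#' @param x numeric vector.
#' @param dt time step (s).
#' @param tau filter timescale (s), must be positive.
#' @return numeric vector of the same length as `x`.
#' @keywords internal
exp_filter <- function(x, dt, tau) {
  if (!is.numeric(tau) || length(tau) != 1L || !is.finite(tau) || tau <= 0)
    stop("tau must be a single positive number")
  if (length(x) == 0L) return(numeric(0))
  q <- exp(-dt / tau)
  as.numeric(stats::filter(x, q, method = "recursive"))
}

#' Persistence rule for binary event signals
#'
#' Symmetric hysteresis used for encounters, stops, and turns: an event
#' offset is only accepted if the signal stays below threshold for at
#' least `min_steps` (shorter dips are bridged), and an event onset is
#' only accepted if the signal stays above threshold for at least
#' `min_steps` (shorter excursions are dropped). Gaps are closed before
#' short runs are dropped, so two long excursions separated by a
#' sub-minimum dip merge into a single event.
#'
#' @param above logical vector (TRUE while the quantity is above threshold).
#' @param min_steps minimum run length, in samples, for both onset and offset.
#' @return logical vector of the same length.
#' @keywords internal
apply_persistence <- function(above, min_steps) {
  stopifnot(min_steps >= 1L)
  if (length(above) == 0L) return(logical(0))
  above[is.na(above)] <- FALSE
  if (min_steps > 1L) {
    # bridge sub-minimum dips (offset persistence), but never across the
    # series boundaries
    r <- rle(above)
    n <- length(r$lengths)
    if (n > 2L) {
      interior <- which(!r$values & r$lengths < min_steps)
      interior <- interior[interior > 1L & interior < n]
      r$values[interior] <- TRUE
    }
    above <- inverse.rle(r)
    # drop sub-minimum excursions (onset persistence)
    r <- rle(above)
    r$values[r$values & r$lengths < min_steps] <- FALSE
    above <- inverse.rle(r)
  }
  above
}

#' Convert a binary exposure vector to an interval table
#'
#' @param d logical/0-1 vector.
#' @param dt time step (s). Step `i` covers time `[(i-1) dt, i dt)`.
#' @return data.frame with columns `onset`, `offset` (s) and
#'   `duration` (s); one row per contiguous run of 1s.
#' @keywords internal
intervals_from_binary <- function(d, dt) {
  d <- as.logical(d)
  r <- rle(d)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  data.frame(
    onset = (starts[keep] - 1L) * dt,
    offset = ends[keep] * dt,
    duration = r$lengths[keep] * dt
  )
}

#' Derive a module-level seed from a global seed
#'
#' Deterministic fan-out rule: combines the global integer seed with a
#' short module label through a small multiplicative hash, keeping the
#' result inside the 32-bit integer range.
#'
#' @param seed integer global seed.
#' @param label character scalar naming the consumer.
#' @return integer seed.
#' @export
derive_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(label))
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((abs(seed) * 7919 + h * 104729) %% 2147483647L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

wrap360 <- function(theta) theta %% 360

#' Reflected upwind orientation
#'
#' Maps headings (degrees, 0 = upwind) to the deviation from upwind in
#' `[0, 180]` by reflecting over the wind axis.
#' @param theta heading in degrees.
#' @return numeric in `[0, 180]`.
#' @export
theta_plus <- function(theta) {
  th <- wrap360(theta)
  pmin(th, 360 - th)
}

check_scalar <- function(x, name, positive = TRUE, finite = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x))
    stop(sprintf("%s must be a single number", name))
  if (finite && !is.finite(x)) stop(sprintf("%s must be finite", name))
  if (positive && x <= 0) stop(sprintf("%s must be positive", name))
  invisible(x)
}
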