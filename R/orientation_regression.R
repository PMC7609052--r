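#' Assemble a per-timestep regression dataset
#'
#' Collects walking-step samples of the reflected orientation and the
#' three filtered sensory variables, with trajectory grouping for
#' block bootstraps.
#'
#' @param sequences list; each element needs `theta` (deg), `walking`,
#'   and an [encounter_series()] under `enc`, plus optionally a raw
#'   signal vector `s` for `W_conc`; `dt` per sequence.
#' @param tau filter timescale (s).
#' @param dt default time step.
#' @return data.frame with columns `trajectory`, `t`, `theta_plus`,
#'   `W_freq`, `W_dur`, `W_conc` (NA without signals), `since_onset`
#'   (s since the most recent onset), `w_freq_at_onset`.
#' @export
regression_dataset <- function(sequences, tau = 2, dt = 1 / 90) {
  rows <- lapply(seq_along(sequences), function(j) {
    s <- sequences[[j]]
    sdt <- s$dt %||% dt
    n <- length(s$theta)
    wfr <- exp_filter(s$enc$w, sdt, tau) / tau
    wdu <- exp_filter(s$enc$d, sdt, tau) * sdt
    wco <- if (!is.null(s$s)) exp_filter(s$s, sdt, tau) * sdt else
      rep(NA_real_, n)
    since <- time_since_onset(s$enc$w, sdt)
    last <- cummax(ifelse(s$enc$w > 0, seq_len(n), 0L))
    wf_at <- ifelse(last > 0, wfr[pmax(last, 1L)], NA_real_)
    keep <- which(s$walking)
    data.frame(trajectory = j, t = (keep - 1) * sdt,
               theta_plus = theta_plus(s$theta[keep]),
               W_freq = wfr[keep], W_dur = wdu[keep], W_conc = wco[keep],
               since_onset = since[keep], w_freq_at_onset = wf_at[keep])
  })
  do.call(rbind, rows)
}

#' Post-encounter orientation change
#'
#' Mean signed change of the reflected orientation over `window`
#' seconds after each encounter onset, binned by the orientation at
#' onset and partitioned by the number of further onsets within the
#' window (0, 1-3, 4+). A matched random-time baseline (uniform over
#' walking steps, equal in count) is computed the same way and
#' subtracted.
#'
#' @param sequences as in [regression_dataset()] (needs `theta`,
#'   `walking`, `enc`, `dt`).
#' @param window look-ahead (s), default 2.
#' @param breaks orientation-at-onset bin edges (deg).
#' @param seed seed for the random-time draws.
#' @return data.frame with `theta_bin` (center), `partition`,
#'   `mean_dtheta_plus` (baseline-subtracted), `n`.
#' @export
post_encounter_orientation_change <- function(sequences, window = 2,
                                              breaks = seq(0, 180, by = 30),
                                              seed = 1L) {
  set.seed(seed)
  onset_rows <- list(); base_rows <- list()
  for (s in sequences) {
    sdt <- s$dt %||% (1 / 90)
    n <- length(s$theta)
    lag <- round(window / sdt)
    onsets <- which(s$enc$w > 0)
    onsets <- onsets[onsets + lag <= n & s$walking[onsets]]
    tp <- theta_plus(s$theta)
    if (length(onsets) > 0) {
      later <- vapply(onsets, function(o)
        sum(s$enc$w[(o + 1):(o + lag)]), numeric(1))
      part <- cut(later, c(-0.5, 0.5, 3.5, Inf), labels = c("0", "1-3", "4+"))
      onset_rows[[length(onset_rows) + 1L]] <- data.frame(
        theta0 = tp[onsets], dtp = tp[onsets + lag] - tp[onsets],
        partition = as.character(part))
      rnd <- sample(which(s$walking[seq_len(n - lag)]), length(onsets),
                    replace = TRUE)
      base_rows[[length(base_rows) + 1L]] <- data.frame(
        theta0 = tp[rnd], dtp = tp[rnd + lag] - tp[rnd])
    }
  }
  if (length(onset_rows) == 0L) stop("no usable encounters")
  ev <- do.call(rbind, onset_rows)
  bl <- do.call(rbind, base_rows)
  if (nrow(ev) < 100) stop("need at least 100 encounters")
  mids <- (breaks[-1] + breaks[-length(breaks)]) / 2
  bbin <- cut(bl$theta0, breaks, include.lowest = TRUE)
  base_curve <- tapply(bl$dtp, bbin, mean)
  out <- list()
  for (p in c("0", "1-3", "4+")) {
    sub <- ev[ev$partition == p, ]
    if (nrow(sub) == 0L) next
    ebin <- cut(sub$theta0, breaks, include.lowest = TRUE)
    m <- tapply(sub$dtp, ebin, mean)
    out[[p]] <- data.frame(theta_bin = mids, partition = p,
                           mean_dtheta_plus = as.numeric(m - base_curve),
                           n = as.numeric(table(ebin)))
  }
  do.call(rbind, out)
}

#' Orientation versus encounter frequency at increasing delays
#'
#' For steps whose time since the most recent onset falls in each
#' delay bin, regresses the current reflected orientation on the
#' encounter frequency that prevailed at that onset. The slope decays
#' toward zero as the delay grows: the upwind bias is forgotten.
#'
#' @param dataset a [regression_dataset()].
#' @param delays delay-bin centers (s).
#' @param half_width delay-bin half width (s).
#' @return data.frame with `delay`, `slope`, `se`, `p`, `n`.
#' @export
orientation_vs_frequency_at_delay <- function(dataset,
                                              delays = c(0.25, 1, 2, 3, 5, 7),
                                              half_width = 0.25) {
  rows <- lapply(delays, function(d) {
    sub <- dataset[is.finite(dataset$since_onset) &
                   abs(dataset$since_onset - d) <= half_width &
                   !is.na(dataset$w_freq_at_onset), ]
    if (nrow(sub) < 20 || stats::sd(sub$w_freq_at_onset) == 0)
      return(data.frame(delay = d, slope = NA_real_, se = NA_real_,
                        p = NA_real_, n = nrow(sub)))
    fit <- summary(stats::lm(theta_plus ~ w_freq_at_onset, data = sub))
    data.frame(delay = d, slope = fit$coefficients[2, 1],
               se = fit$coefficients[2, 2], p = fit$coefficients[2, 4],
               n = nrow(sub))
  })
  do.call(rbind, rows)
}

#' Orientation curves with one sensory variable held fixed
#'
#' Disassociates encounter frequency and duration: within quantile
#' bins of the held variable, the reflected orientation is binned
#' against the free variable and a within-bin slope is reported.
#'
#' @param dataset a [regression_dataset()].
#' @param hold `"W_dur"` (curves against `W_freq`) or `"W_freq"`.
#' @param n_hold_bins quantile bins of the held variable.
#' @param n_free_bins bins of the free variable.
#' @param min_n minimum samples per held bin.
#' @return list with `curves` (data.frame: `hold_bin`, `free_value`,
#'   `mean_theta_plus`, `n`) and `slopes` (per held bin).
#' @export
conditioned_orientation_curves <- function(dataset, hold = c("W_dur", "W_freq"),
                                           n_hold_bins = 4, n_free_bins = 6,
                                           min_n = 200) {
  hold <- match.arg(hold)
  free <- if (hold == "W_dur") "W_freq" else "W_dur"
  hv <- dataset[[hold]]; fv <- dataset[[free]]
  qs <- unique(stats::quantile(hv, seq(0, 1, length.out = n_hold_bins + 1)))
  hb <- cut(hv, qs, include.lowest = TRUE)
  curves <- list(); slopes <- list()
  for (lev in levels(hb)) {
    sel <- which(hb == lev)
    if (length(sel) < min_n) next
    fb <- cut(fv[sel], n_free_bins)
    m <- tapply(dataset$theta_plus[sel], fb, mean)
    cen <- tapply(fv[sel], fb, mean)
    curves[[lev]] <- data.frame(hold_bin = lev,
                                free_value = as.numeric(cen),
                                mean_theta_plus = as.numeric(m),
                                n = as.numeric(table(fb)))
    fit <- summary(stats::lm(dataset$theta_plus[sel] ~ fv[sel]))
    slopes[[lev]] <- data.frame(hold_bin = lev,
                                slope = fit$coefficients[2, 1],
                                se = fit$coefficients[2, 2],
                                p = fit$coefficients[2, 4])
  }
  if (length(curves) == 0L) stop("no held bin reaches the occupancy threshold")
  list(curves = do.call(rbind, curves), slopes = do.call(rbind, slopes),
       hold = hold, free = free)
}

#' Trilinear regression of upwind orientation on the sensory variables
#'
#' Ordinary least squares of theta+ on standardized `W_freq`, `W_dur`,
#' and `W_conc` simultaneously, with two-tailed t-tests, the condition
#' number of the regressor moment matrix (values above 10 are flagged
#' as multicollinear), and optionally trajectory-level block-bootstrap
#' standard errors (per-timestep samples are autocorrelated, so the
#' plain t-test is optimistic; both are reported).
#'
#' @param dataset a [regression_dataset()] with non-NA `W_conc`.
#' @param n_boot block-bootstrap replicates (0 to skip).
#' @param seed bootstrap seed.
#' @return list with `coefficients` (data.frame: term, coef, se, t, p,
#'   boot_se), `condition_number`, `multicollinear`, `fit` (the `lm`).
#' @export
trilinear_regression <- function(dataset, n_boot = 0, seed = 1L) {
  vars <- c("W_freq", "W_dur", "W_conc")
  X <- dataset[, vars]
  if (any(!is.finite(as.matrix(X))))
    stop("regression dataset contains non-finite regressors")
  sds <- vapply(X, stats::sd, numeric(1))
  if (any(sds == 0)) stop("regressor with zero variance")
  Z <- scale(as.matrix(X))
  qrz <- qr(Z)
  if (qrz$rank < ncol(Z))
    stop("rank-deficient regressors: standardized moment matrix is singular")
  M <- crossprod(Z) / (nrow(Z) - 1)
  cond <- kappa(M, exact = TRUE)
  df <- data.frame(theta_plus = dataset$theta_plus, Z)
  fit <- stats::lm(theta_plus ~ W_freq + W_dur + W_conc, data = df)
  sm <- summary(fit)$coefficients
  boot_se <- rep(NA_real_, nrow(sm))
  if (n_boot > 0) {
    set.seed(seed)
    ids <- unique(dataset$trajectory)
    boots <- replicate(n_boot, {
      take <- sample(ids, length(ids), replace = TRUE)
      idx <- unlist(lapply(take, function(i) which(dataset$trajectory == i)))
      stats::coef(stats::lm(theta_plus ~ W_freq + W_dur + W_conc,
                            data = df[idx, ]))
    })
    boot_se <- apply(boots, 1, stats::sd)
  }
  list(coefficients = data.frame(term = rownames(sm), coef = sm[, 1],
                                 se = sm[, 2], t = sm[, 3], p = sm[, 4],
                                 boot_se = boot_se, row.names = NULL),
       condition_number = cond, multicollinear = cond > 10, fit = fit)
}
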