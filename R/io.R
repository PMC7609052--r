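#' Read and write trajectory tables
#'
#' Delimited text with columns `trajectory_id`, `t` (s), `x_mm`,
#' `y_mm`, `theta_deg`.
#'
#' @param path file path.
#' @param trajectories data.frame in the same layout.
#' @param sep field separator, default tab.
#' @return `read_trajectories` returns the data.frame.
#' @export
read_trajectories <- function(path, sep = "\t") {
  df <- utils::read.table(path, header = TRUE, sep = sep)
  need <- c("trajectory_id", "t", "x_mm", "y_mm", "theta_deg")
  if (!all(need %in% names(df)))
    stop("trajectory table must have columns: ", paste(need, collapse = ", "))
  df
}

#' @rdname read_trajectories
#' @export
write_trajectories <- function(trajectories, path, sep = "\t") {
  utils::write.table(trajectories, path, sep = sep, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Write an encounter series and its filtered signals
#'
#' Columns: `t` (s), `w` (onsets), `d` (exposure), `W_freq` (Hz),
#' `W_dur` (s), `W_conc` (intensity x s, NA when unavailable).
#'
#' @param enc an [encounter_series()].
#' @param filt a [compute_filtered_signals()] result.
#' @param path output path.
#' @export
write_encounter_table <- function(enc, filt, path) {
  n <- length(enc$w)
  df <- data.frame(t = (seq_len(n) - 1) * enc$time_step,
                   w = enc$w, d = enc$d,
                   W_freq = filt$W_freq, W_dur = filt$W_dur,
                   W_conc = filt$W_conc %||% rep(NA_real_, n))
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an encounter table back into a series and signals
#'
#' @param path file written by [write_encounter_table()].
#' @return list with `enc` and `signals` (data.frame).
#' @export
read_encounter_table <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  dt <- stats::median(diff(df$t))
  list(enc = encounter_series(df$d, dt, w = df$w),
       signals = df[, c("t", "W_freq", "W_dur", "W_conc")])
}

#' Serialize a rate-model spec to YAML
#'
#' @param spec a [rate_model_spec()].
#' @param path output path.
#' @export
write_rate_model_yaml <- function(spec, path) {
  yaml::write_yaml(list(family = spec$family, direction = spec$direction,
                        params = spec$params), path)
  invisible(path)
}

#' @rdname write_rate_model_yaml
#' @export
read_rate_model_yaml <- function(path) {
  x <- yaml::read_yaml(path)
  rate_model_spec(x$family, x$direction, x$params)
}

#' Write a subset-fit table and its YAML median summary
#'
#' @param fit a [fit_rate_model()] or [fit_turn_model()] result.
#' @param path base path; writes `<path>.tsv` and `<path>.yaml`.
#' @export
write_fit_tables <- function(fit, path) {
  utils::write.table(fit$estimates, paste0(path, ".tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  yaml::write_yaml(lapply(fit$medians, as.numeric), paste0(path, ".yaml"))
  invisible(path)
}

#' Persist a plume movie
#'
#' Plain two-file layout: `<path>.yaml` holds the metadata
#' (dimensions, frame rate, pixel size, coordinates, source position)
#' and `<path>.u8` holds the frames as raw unsigned bytes in
#' column-major (y, x, frame) order.
#'
#' @param movie a [plume_movie()].
#' @param path base path (without extension).
#' @export
write_plume_movie <- function(movie, path) {
  d <- dim(movie$frames)
  yaml::write_yaml(list(ny = d[1], nx = d[2], n_frames = d[3],
                        frame_rate = movie$frame_rate,
                        pixel_size = movie$pixel_size,
                        x0 = movie$x[1], y0 = movie$y[1],
                        source_position = as.numeric(movie$source_position)),
                   paste0(path, ".yaml"))
  con <- file(paste0(path, ".u8"), "wb")
  on.exit(close(con))
  writeBin(as.raw(pmin(pmax(movie$frames, 0L), 255L)), con)
  invisible(path)
}

#' @rdname write_plume_movie
#' @export
read_plume_movie <- function(path) {
  meta <- yaml::read_yaml(paste0(path, ".yaml"))
  n <- meta$ny * meta$nx * meta$n_frames
  con <- file(paste0(path, ".u8"), "rb")
  on.exit(close(con))
  v <- as.integer(readBin(con, "raw", n))
  structure(list(
    frames = array(v, c(meta$ny, meta$nx, meta$n_frames)),
    frame_rate = meta$frame_rate, pixel_size = meta$pixel_size,
    x = meta$x0 + (seq_len(meta$nx) - 1) * meta$pixel_size,
    y = meta$y0 + (seq_len(meta$ny) - 1) * meta$pixel_size,
    source_position = meta$source_position),
    class = "plume_movie")
}

#' Write an event table
#'
#' Columns: `type`, `onset_s`, `offset_s`, `dtheta_deg`.
#'
#' @param events an [detect_events()] result.
#' @param path output path.
#' @export
write_event_table <- function(events, path) {
  df <- rbind(
    data.frame(type = "turn", onset_s = events$turns$onset,
               offset_s = events$turns$offset,
               dtheta_deg = events$turns$dtheta),
    data.frame(type = events$bouts$type, onset_s = events$bouts$onset,
               offset_s = events$bouts$offset, dtheta_deg = NA_real_))
  df <- df[order(df$onset_s), ]
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Load a run configuration
#'
#' YAML with a top-level `seed` plus optional `plume`, `agent`,
#' `events`, `encounters` blocks overriding the corresponding config
#' defaults. Unknown fields are rejected.
#'
#' @param path YAML file.
#' @return list with validated config objects and the seed.
#' @export
load_run_config <- function(path) {
  x <- yaml::read_yaml(path)
  if (is.null(x$seed)) stop("run config must set a seed")
  known <- c("seed", "plume", "events", "encounters", "smoothing")
  extra <- setdiff(names(x), known)
  if (length(extra) > 0)
    stop("unknown config fields: ", paste(extra, collapse = ", "))
  list(seed = as.integer(x$seed),
       plume = do.call(plume_config, x$plume %||% list()),
       events = do.call(event_config, x$events %||% list()),
       encounters = do.call(encounter_config, x$encounters %||% list()),
       smoothing = do.call(smoothing_config, x$smoothing %||% list()))
}
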