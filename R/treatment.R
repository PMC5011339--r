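#' In-memory frame source
#'
#' A frame source is a zero-argument function returning the next
#' [complex_frame()] or `NULL` at end of stream; it abstracts the original
#' system's polling of the scanner's raw-data file. This constructor serves
#' a list of frames in order of their timestamps.
#'
#' @param frames List of [complex_frame()]s.
#' @return A frame-source function.
#' @export
frame_source_from_list <- function(frames) {
  stopifnot(all(vapply(frames, inherits, logical(1), "complex_frame")))
  ts <- vapply(frames, `[[`, numeric(1), "timestamp_s")
  frames <- frames[order(ts)]
  i <- 0L
  function() {
    i <<- i + 1L
    if (i > length(frames)) NULL else frames[[i]]
  }
}

#' Run the real-time treatment loop over a frame stream
#'
#' The complete per-frame chain of the original control software: skip the
#' dummy frames, take the next frame as baseline, then for every subsequent
#' frame compute the baseline-subtracted phase difference, convert to
#' temperature, optionally drift-correct, take the focal mean, accumulate
#' CEM43 dose, run the PID law, apply the dose shut-off and emit the drive
#' voltage. On stream end - or on any failure - a final 0 V is emitted
#' before returning (or propagating the error), mirroring the original
#' system's guaranteed output shut-down.
#'
#' @param frame_source Zero-argument function yielding [complex_frame()]s,
#'   `NULL` at end of stream (see [frame_source_from_list()]).
#' @param focus Focal [roi_rect()]/[roi_from_mask()] (label `"focus"`).
#' @param drift_ref Optional drift-reference ROI; `NULL` disables drift
#'   correction.
#' @param pid A [pid_params()] (carries the set point).
#' @param dose A [dose_params()].
#' @param dose_threshold_min Shut-off dose (equivalent minutes); `Inf`
#'   disables it.
#' @param cfg A [thermometry_config()].
#' @param dummy_frames Number of leading frames discarded to avoid
#'   steady-state artifacts. Default 2.
#' @param output_sink Function of one argument receiving each emitted
#'   voltage (the virtual function generator); `NULL` discards them.
#' @param collect_maps Keep the per-frame temperature maps as an attribute
#'   (`"maps"`) of the returned log.
#' @return A `sonication_log`: data frame with columns `timestamp_s`,
#'   `focal_mean_C`, `v_out`, `cem43_min`, `shutoff_flag`.
#' @export
run_treatment <- function(frame_source, focus, drift_ref = NULL,
                          pid = pid_params(), dose = dose_params(),
                          dose_threshold_min = Inf,
                          cfg = thermometry_config(),
                          dummy_frames = 2L,
                          output_sink = NULL, collect_maps = FALSE) {
  stopifnot(is.function(frame_source), inherits(focus, "roi"))
  emit <- function(v) if (!is.null(output_sink)) output_sink(v)
  rows <- list(); maps <- list(); drift_means <- numeric(0)
  ok <- FALSE
  on.exit(if (!ok) emit(0))   # guaranteed shut-down on any error path

  for (k in seq_len(dummy_frames)) {
    if (is.null(frame_source()))
      stop("frame stream ended during dummy frames")
  }
  baseline <- frame_source()
  if (is.null(baseline)) stop("frame stream ended before a baseline frame")

  pstate <- pid_state(t0_s = baseline$timestamp_s)
  acc <- dose_accumulator(dose_threshold_min)
  prev_dphi <- NULL

  repeat {
    fr <- frame_source()
    if (is.null(fr)) break
    dphi <- phase_difference(fr, baseline)
    if (cfg$unwrap_enabled) {
      dphi <- unwrap_temporal(dphi, prev_dphi)
      prev_dphi <- dphi
    }
    tmap <- phase_to_temperature(dphi, baseline, cfg,
                                 timestamp_s = fr$timestamp_s)
    if (!is.null(drift_ref)) {
      drift_means <- c(drift_means, roi_mean(tmap, drift_ref))
      tmap <- drift_correct(tmap, drift_ref)
    }
    focal <- tryCatch(roi_mean(tmap, focus), error = function(e) NA_real_)
    acc <- update_dose(acc, focal, fr$timestamp_s - pstate$prev_time_s, dose)
    st <- pid_step(pstate, pid, focal, fr$timestamp_s)
    pstate <- st$state
    v <- apply_dose_shutoff(st$v_out, acc)
    emit(v)
    rows[[length(rows) + 1L]] <- data.frame(
      timestamp_s = fr$timestamp_s, focal_mean_C = focal, v_out = v,
      cem43_min = acc$cem43_min, shutoff_flag = acc$reached)
    if (collect_maps) maps[[length(maps) + 1L]] <- tmap
  }
  emit(0)
  ok <- TRUE
  log <- do.call(rbind, rows)
  if (is.null(log))
    log <- data.frame(timestamp_s = numeric(0), focal_mean_C = numeric(0),
                      v_out = numeric(0), cem43_min = numeric(0),
                      shutoff_flag = logical(0))
  class(log) <- c("sonication_log", "data.frame")
  if (collect_maps) attr(log, "maps") <- maps
  if (!is.null(drift_ref)) attr(log, "drift_ref_mean_C") <- drift_means
  log
}

#' Summary metrics of a controlled sonication
#'
#' Precision and accuracy are computed from the initial temperature rise
#' onward, defined (as in the original validation) as the first frame at
#' which the focal mean crosses the set point: `overshoot_C` is the maximum
#' excursion above the set point, `post_sd_C` the standard deviation of the
#' error over the post-rise frames, and `post_rmse_C` its RMSE.
#'
#' @param log A `sonication_log`.
#' @param setpoint_C Set point used for the run (degC).
#' @return List with `t_cross_s`, `overshoot_C`, `post_sd_C`, `post_rmse_C`
#'   and `n_post` (number of post-rise frames). `t_cross_s` is `NA` (and the
#'   metrics `NA`) if the set point is never reached.
#' @export
summarize_sonication <- function(log, setpoint_C) {
  stopifnot(inherits(log, "sonication_log"))
  m <- log$focal_mean_C
  idx <- which(m >= setpoint_C)
  if (length(idx) == 0)
    return(list(t_cross_s = NA_real_, overshoot_C = NA_real_,
                post_sd_C = NA_real_, post_rmse_C = NA_real_, n_post = 0L))
  c0 <- idx[1]
  err <- m[c0:length(m)] - setpoint_C
  list(t_cross_s = log$timestamp_s[c0],
       overshoot_C = max(0, max(err)),
       post_sd_C = stats::sd(err),
       post_rmse_C = sqrt(mean(err^2)),
       n_post = length(err))
}

#' @export
print.sonication_log <- function(x, ...) {
  cat(sprintf("<sonication_log: %d frames, %.1f s, final dose %.3g CEM43 min%s>\n",
              nrow(x), if (nrow(x)) max(x$timestamp_s) else 0,
              if (nrow(x)) x$cem43_min[nrow(x)] else 0,
              if (nrow(x) && any(x$shutoff_flag)) ", dose shut-off reached" else ""))
  if (nrow(x)) print(utils::head(as.data.frame(x), 3))
  invisible(x)
}
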