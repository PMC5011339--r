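#' CEM43 dose parameters
#'
#' Thermal dose in cumulative equivalent minutes at 43 degC follows the
#' Sapareto-Dewey convention: each interval dt at absolute temperature T
#' contributes `R^(43 - T) * dt` equivalent minutes, with R = 0.5 at or above
#' the 43 degC breakpoint and R = 0.25 below it.
#'
#' @param r_above Rate base for T >= breakpoint. Default 0.5.
#' @param r_below Rate base for T < breakpoint. Default 0.25.
#' @param t_break_C Breakpoint temperature (degC). Default 43.
#' @param baseline_body_C Absolute temperature corresponding to a measured
#'   temperature rise of 0 (degC). Default 37 (core body temperature), so a
#'   rise of 6 degC sits exactly at the breakpoint; phantom work may set it
#'   to ambient.
#' @return An object of class `dose_params`.
#' @export
dose_params <- function(r_above = 0.5, r_below = 0.25, t_break_C = 43,
                        baseline_body_C = 37) {
  if (!(r_below > 0 && r_below <= r_above && r_above < 1))
    stop("need 0 < r_below <= r_above < 1")
  structure(list(r_above = r_above, r_below = r_below,
                 t_break_C = t_break_C, baseline_body_C = baseline_body_C),
            class = "dose_params")
}

#' Running CEM43 accumulator
#'
#' @param threshold_min Shut-off dose in equivalent minutes (> 0); `Inf`
#'   disables the dose-based shut-off.
#' @return An object of class `dose_accumulator` with fields `cem43_min`,
#'   `threshold_min` and the latched completion flag `reached`.
#' @export
dose_accumulator <- function(threshold_min = Inf) {
  if (threshold_min <= 0) stop("`threshold_min` must be positive")
  structure(list(cem43_min = 0, threshold_min = threshold_min,
                 reached = FALSE),
            class = "dose_accumulator")
}

#' Accumulate thermal dose over one frame
#'
#' Adds `R^(43 - T_abs) * dt_min` equivalent minutes, where
#' `T_abs = baseline_body_C + focal_dT_C`, and latches `reached` once the
#' accumulated dose crosses the threshold. The flag never reverts. A
#' non-finite temperature reading leaves the accumulator unchanged (the
#' frame is skipped).
#'
#' @param acc A [dose_accumulator()].
#' @param focal_dT_C Focal mean temperature rise for this frame (degC).
#' @param dt_s Frame duration (s, > 0).
#' @param params A [dose_params()].
#' @return The updated accumulator.
#' @export
update_dose <- function(acc, focal_dT_C, dt_s, params = dose_params()) {
  stopifnot(inherits(acc, "dose_accumulator"), inherits(params, "dose_params"))
  if (dt_s <= 0) stop("`dt_s` must be positive")
  if (!is.finite(focal_dT_C)) return(acc)  # skip frame, leave dose unchanged
  t_abs <- params$baseline_body_C + focal_dT_C
  r <- if (t_abs >= params$t_break_C) params$r_above else params$r_below
  acc$cem43_min <- acc$cem43_min + r^(params$t_break_C - t_abs) * dt_s / 60
  if (acc$cem43_min >= acc$threshold_min) acc$reached <- TRUE
  acc
}
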