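#' PID controller parameters
#'
#' Gains of the clamped PID law driving the transducer voltage,
#' `v = min(kp*e + ki*Int(e) + kd*de/dt, v_max)` with `e = setpoint -
#' measured` and the output floored at 0 V (negative drive is physically
#' meaningless). Defaults are the hand-tuned values of the original system:
#' Kp = 1e-3 V/degC, Kd = 5e-3 V s/degC, V_max = 70 mV (peak-to-peak at the
#' generator output, before amplification). The integral gain was published
#' as 1e-5 per sequence repeat; with the thermometry sequence's repetition
#' time TR = 30 ms this is 3.333e-4 V/(degC s), the convention used here
#' (`ki` is always in V per degC-second).
#'
#' @param kp Proportional gain (V/degC).
#' @param ki Integral gain (V per degC-second).
#' @param kd Derivative gain (V s/degC).
#' @param v_max Output clamp (V, > 0).
#' @param setpoint_C Desired temperature rise (degC).
#' @return An object of class `pid_params`.
#' @export
pid_params <- function(kp = 1e-3, ki = 1e-5 / 0.030, kd = 5e-3,
                       v_max = 0.070, setpoint_C = 6) {
  if (any(c(kp, ki, kd) < 0)) stop("gains must be >= 0")
  if (v_max <= 0) stop("`v_max` must be positive")
  structure(list(kp = kp, ki = ki, kd = kd, v_max = v_max,
                 setpoint_C = setpoint_C),
            class = "pid_params")
}

#' PID controller state
#'
#' The full error history enters only through the running integral plus the
#' last error, the standard incremental PID memory.
#'
#' @param t0_s Time origin of the controller (s); the first update at time t
#'   integrates over `t - t0_s`.
#' @return An object of class `pid_state`.
#' @export
pid_state <- function(t0_s = 0) {
  structure(list(integral_Cs = 0, prev_error_C = NA_real_,
                 prev_time_s = t0_s, last_v_out = 0),
            class = "pid_state")
}

#' One discrete PID update
#'
#' Rectangle-rule integral (`integral += e * dt`), backward-difference
#' derivative (`(e - e_prev)/dt`, zero on the first call), output clamped to
#' `[0, v_max]`. Anti-windup by conditional integration: while the clamp is
#' active and the error would push the output further into saturation, the
#' integral is frozen. A non-finite measurement retains the previous output
#' and leaves the state unchanged.
#'
#' @param state A [pid_state()].
#' @param params A [pid_params()].
#' @param measured_dT_C Measured focal temperature rise (degC).
#' @param t_s Current time (s); must exceed the state's previous time.
#' @return List with `v_out` (V) and the updated `state`.
#' @export
pid_step <- function(state, params, measured_dT_C, t_s) {
  stopifnot(inherits(state, "pid_state"), inherits(params, "pid_params"))
  if (!is.finite(measured_dT_C))
    return(list(v_out = state$last_v_out, state = state))
  dt <- t_s - state$prev_time_s
  if (!is.finite(dt) || dt <= 0)
    stop("non-monotonic time: t_s must exceed the previous update time")
  e <- params$setpoint_C - measured_dT_C
  deriv <- if (is.na(state$prev_error_C)) 0 else (e - state$prev_error_C) / dt
  int_new <- state$integral_Cs + e * dt
  raw <- params$kp * e + params$ki * int_new + params$kd * deriv
  if ((raw > params$v_max && e > 0) || (raw < 0 && e < 0)) {
    int_new <- state$integral_Cs  # freeze integral against windup
    raw <- params$kp * e + params$ki * int_new + params$kd * deriv
  }
  v <- min(max(raw, 0), params$v_max)
  state$integral_Cs <- int_new
  state$prev_error_C <- e
  state$prev_time_s <- t_s
  state$last_v_out <- v
  list(v_out = v, state = state)
}

#' Dose-based output shut-off
#'
#' Returns 0 V whenever the dose accumulator has latched its threshold,
#' otherwise passes the commanded voltage through. Because `reached` never
#' reverts, the shut-off is absorbing.
#'
#' @param v_out Commanded voltage (V).
#' @param acc A [dose_accumulator()].
#' @return Voltage actually sent to the generator (V).
#' @export
apply_dose_shutoff <- function(v_out, acc) {
  stopifnot(inherits(acc, "dose_accumulator"))
  if (isTRUE(acc$reached)) 0 else v_out
}
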