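#' Tissue parameters of the bioheat plant
#'
#' The virtual rig's plant solves the Pennes bioheat equation
#' `rho*c dT/dt = k lap(T) - rho*c*w*(T - Ta) + Q` for the temperature rise
#' T on a regular 3-D grid with insulated (zero-flux) boundaries. The
#' first-order loss coefficient `perfusion_s1` is the lumped Pennes term
#' `w_b*c_b/(rho*c)`; for non-perfused phantoms the same slot models
#' Newtonian heat exchange with the surrounding bath.
#'
#' @param conductivity_W_mK Thermal conductivity k (W/m/K). Default 0.6
#'   (agar/soft tissue).
#' @param vol_heat_capacity_J_m3K Volumetric heat capacity rho*c (J/m^3/K).
#'   Default 4.2e6.
#' @param perfusion_s1 First-order loss rate (1/s, >= 0).
#' @param arterial_dT_C Reference temperature rise of the perfusion sink
#'   (degC); usually 0.
#' @param domain_mm Edge lengths of the simulated box (mm), length 3.
#' @param grid_mm Isotropic voxel spacing (mm).
#' @return An object of class `tissue_params`.
#' @export
tissue_params <- function(conductivity_W_mK = 0.6,
                          vol_heat_capacity_J_m3K = 4.2e6,
                          perfusion_s1 = 0,
                          arterial_dT_C = 0,
                          domain_mm = c(12, 12, 12),
                          grid_mm = 0.5) {
  if (conductivity_W_mK <= 0 || vol_heat_capacity_J_m3K <= 0)
    stop("conductivity and heat capacity must be positive")
  if (perfusion_s1 < 0) stop("`perfusion_s1` must be >= 0")
  if (length(domain_mm) != 3L || any(domain_mm <= 0) || grid_mm <= 0)
    stop("invalid domain/grid specification")
  structure(list(conductivity_W_mK = conductivity_W_mK,
                 vol_heat_capacity_J_m3K = vol_heat_capacity_J_m3K,
                 perfusion_s1 = perfusion_s1,
                 arterial_dT_C = arterial_dT_C,
                 domain_mm = as.numeric(domain_mm),
                 grid_mm = grid_mm),
            class = "tissue_params")
}

#' Virtual transducer source model
#'
#' Deposited acoustic power is modelled as a 3-D Gaussian whose axis widths
#' are the transducer's focal full-widths-at-half-maximum and whose total
#' power is `power_gain_W_per_V2 * v^2 * duty` - intensity scales with
#' pressure squared and pressure with drive voltage. Default widths are the
#' 1.1 MHz focus (1.4 x 1.4 x 10 mm).
#'
#' @param focus_center_mm Focus position relative to the domain center (mm),
#'   length 3.
#' @param fwhm_mm Focal FWHM per axis (mm), length 3.
#' @param power_gain_W_per_V2 Deposited watts per squared drive volt.
#' @param duty Duty factor in `[0, 1]`.
#' @return An object of class `source_model`.
#' @export
source_model <- function(focus_center_mm = c(0, 0, 0),
                         fwhm_mm = c(1.4, 1.4, 10),
                         power_gain_W_per_V2 = 84,
                         duty = 1) {
  if (any(fwhm_mm <= 0)) stop("`fwhm_mm` must be positive")
  if (power_gain_W_per_V2 < 0) stop("`power_gain_W_per_V2` must be >= 0")
  if (duty < 0 || duty > 1) stop("`duty` must be in [0, 1]")
  structure(list(focus_center_mm = as.numeric(focus_center_mm),
                 fwhm_mm = as.numeric(fwhm_mm),
                 power_gain_W_per_V2 = power_gain_W_per_V2,
                 duty = duty),
            class = "source_model")
}

#' Grid node coordinates (mm from domain center) along one axis
#' @noRd
plant_axis <- function(extent_mm, grid_mm) {
  n <- as.integer(round(extent_mm / grid_mm)) + 1L
  (seq_len(n) - (n + 1) / 2) * grid_mm
}

#' Initial plant state
#'
#' @param tissue A [tissue_params()].
#' @return An object of class `plant_state` holding the 3-D temperature-rise
#'   field (all zero) and the elapsed time.
#' @export
plant_state <- function(tissue) {
  stopifnot(inherits(tissue, "tissue_params"))
  dims <- vapply(seq_len(3), function(a)
    length(plant_axis(tissue$domain_mm[a], tissue$grid_mm)), integer(1))
  structure(list(temperature_C = array(0, dims), time_s = 0),
            class = "plant_state")
}

#' Normalized deposition field of a source on a tissue grid
#'
#' Discretely normalized so that `sum(field) * voxel_volume == 1`; the
#' deposited power density is then `P * field` and total power is exactly P.
#'
#' @param tissue A [tissue_params()].
#' @param source A [source_model()].
#' @return 3-D array, 1/m^3.
#' @export
source_field <- function(tissue, source) {
  sig <- source$fwhm_mm / (2 * sqrt(2 * log(2)))   # FWHM -> sigma, mm
  h <- tissue$grid_mm
  # cell-integrated Gaussian weights (grid-refinement consistent)
  cellw <- function(x, s)
    stats::pnorm((x + h / 2) / s) - stats::pnorm((x - h / 2) / s)
  ax <- lapply(seq_len(3), function(a)
    plant_axis(tissue$domain_mm[a], tissue$grid_mm) - source$focus_center_mm[a])
  w <- outer(outer(cellw(ax[[1]], sig[1]), cellw(ax[[2]], sig[2])),
             cellw(ax[[3]], sig[3]))
  voxv <- (tissue$grid_mm * 1e-3)^3
  w / (sum(w) * voxv)
}

#' Maximum stable explicit timestep for the plant grid
#' @param tissue A [tissue_params()].
#' @return Timestep bound `grid^2 * rho*c / (6k)` in seconds.
#' @export
plant_stable_dt <- function(tissue) {
  h <- tissue$grid_mm * 1e-3
  h^2 * tissue$vol_heat_capacity_J_m3K / (6 * tissue$conductivity_W_mK)
}

#' Advance the bioheat plant
#'
#' Explicit finite-difference update over `dt_s`, internally sub-stepped so
#' every sub-step satisfies the stability bound [plant_stable_dt()].
#'
#' @param state A [plant_state()].
#' @param tissue A [tissue_params()].
#' @param source A [source_model()].
#' @param v_drive Drive voltage (V); deposited power is
#'   `gain * v^2 * duty`.
#' @param dt_s Interval to advance (s, > 0).
#' @param field Optional precomputed [source_field()] (cached by callers in
#'   tight loops).
#' @param substep Set `FALSE` to reject an unstable `dt_s` instead of
#'   sub-stepping.
#' @return The advanced `plant_state`.
#' @export
step_plant <- function(state, tissue, source, v_drive, dt_s,
                       field = NULL, substep = TRUE) {
  stopifnot(inherits(state, "plant_state"), inherits(tissue, "tissue_params"),
            inherits(source, "source_model"))
  if (dt_s <= 0) stop("`dt_s` must be positive")
  dt_max <- plant_stable_dt(tissue)
  nsub <- as.integer(ceiling(dt_s / dt_max - 1e-12))
  if (nsub > 1L && !substep)
    stop(sprintf("dt_s = %.3g s exceeds the stability bound %.3g s", dt_s, dt_max))
  dt_sub <- dt_s / nsub
  if (is.null(field)) field <- source_field(tissue, source)
  p_tot <- source$power_gain_W_per_V2 * v_drive^2 * source$duty
  dims <- dim(state$temperature_C)
  out <- .plant_step_cpp(as.numeric(state$temperature_C),
                         as.numeric(p_tot * field),
                         dims[1], dims[2], dims[3],
                         tissue$grid_mm * 1e-3,
                         tissue$conductivity_W_mK,
                         tissue$vol_heat_capacity_J_m3K,
                         tissue$perfusion_s1, tissue$arterial_dT_C,
                         dt_sub, nsub)
  state$temperature_C <- array(out, dims)
  state$time_s <- state$time_s + dt_s
  state
}

#' Total thermal energy of the plant above baseline
#'
#' `sum(T) * rho*c * voxel_volume`, in joules. With zero perfusion and the
#' insulated boundaries the explicit scheme conserves this quantity exactly
#' up to the injected power.
#'
#' @param state A [plant_state()].
#' @param tissue A [tissue_params()].
#' @return Scalar energy (J).
#' @export
plant_energy <- function(state, tissue) {
  sum(state$temperature_C) * tissue$vol_heat_capacity_J_m3K *
    (tissue$grid_mm * 1e-3)^3
}

#' Fit a lumped first-order response to a heating curve
#'
#' Least-squares fit of `T(t) = T_ss * (1 - exp(-t/tau))` to a
#' constant-drive focal heating curve, the standard lumped description of a
#' perfused plant. Useful for characterizing the rig's effective gain and
#' time constant, e.g. for controller tuning.
#'
#' @param time_s Time points (s).
#' @param temp_C Focal temperature rise at those times (degC).
#' @return List with `T_ss_C` (steady-state rise), `tau_s` (time constant)
#'   and the `fit` object.
#' @export
fit_first_order <- function(time_s, temp_C) {
  stopifnot(length(time_s) == length(temp_C), length(time_s) >= 5)
  resid_fn <- function(par)
    temp_C - par[1] * (1 - exp(-time_s / max(par[2], 1e-9)))
  # starting values: plateau from the curve tail, tau from the 63.2% crossing
  Tss0 <- max(temp_C)
  tau0 <- time_s[which(temp_C >= (1 - exp(-1)) * Tss0)[1]]
  if (is.na(tau0)) tau0 <- max(time_s) / 3
  fit <- minpack.lm::nls.lm(par = c(Tss = Tss0, tau = tau0), fn = resid_fn,
                            lower = c(0, 1e-9))
  co <- fit$par
  list(T_ss_C = unname(co["Tss"]), tau_s = unname(co["tau"]), fit = fit)
}
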