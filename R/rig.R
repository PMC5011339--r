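#' Virtual rig presets
#'
#' Bundled parameter sets for the virtual measurement chain, shipped as JSON
#' under `inst/extdata/presets/`:
#' \describe{
#'   \item{`"agar-phantom"`}{Agar-like tissue mimic. Conduction plus a
#'     first-order Newtonian loss to the surrounding bath (0.02 1/s); the
#'     source gain is calibrated so that a constant drive at the 70 mV clamp
#'     settles at a focal-mean rise of about 12 degC, keeping all set points
#'     of interest (2-10 degC) reachable below the clamp.}
#'   \item{`"mouse-tumor"`}{Perfused tumor preset (0.015 1/s baseline
#'     perfusion), same calibration rule.}
#' }
#'
#' @param name Preset name.
#' @return List with elements `tissue` ([tissue_params()]), `source`
#'   ([source_model()]) and `scanner` ([scanner_model()]).
#' @export
rig_preset <- function(name = c("agar-phantom", "mouse-tumor")) {
  name <- match.arg(name)
  path <- system.file("extdata", "presets", paste0(name, ".json"),
                      package = "mrgfus", mustWork = TRUE)
  p <- jsonlite::fromJSON(path)
  list(tissue = do.call(tissue_params, p$tissue),
       source = do.call(source_model, p$source),
       scanner = do.call(scanner_model, p$scanner))
}

#' Default focal ROI of a rig
#'
#' The 2.6 x 3.2 mm rectangle centered on the acoustic focus that the
#' original system used for the focal mean (it encompasses the focal FWHM).
#'
#' @param rig A [rig_preset()]-style list.
#' @return An [roi_rect()] with label `"focus"`.
#' @export
rig_focal_roi <- function(rig) {
  roi_rect(center_mm = rig$source$focus_center_mm[1:2],
           size_mm = c(2.6, 3.2),
           matrix_dim = rig$scanner$matrix_dim,
           fov_mm = rig$scanner$fov_mm, label = "focus")
}

#' Default drift-reference ROI of a rig
#'
#' A 4.6 x 4.6 mm square placed well away from the heated region.
#'
#' @param rig A [rig_preset()]-style list.
#' @param center_mm Center of the reference region, mm from image center.
#' @return An [roi_rect()] with label `"drift-reference"`.
#' @export
rig_drift_roi <- function(rig, center_mm = c(-18, -18)) {
  roi_rect(center_mm = center_mm, size_mm = c(4.6, 4.6),
           matrix_dim = rig$scanner$matrix_dim,
           fov_mm = rig$scanner$fov_mm, label = "drift-reference")
}

#' Closed-loop sonication on the virtual rig
#'
#' Wires the bioheat plant, the virtual transducer and the synthetic scanner
#' into [run_treatment()]: each commanded voltage drives the plant over the
#' next frame period, and each acquired frame is reconstructed into the
#' focal temperature feeding the controller. Deterministic given the
#' scanner's `rng_seed`.
#'
#' @param rig A [rig_preset()]-style list (`tissue`, `source`, `scanner`).
#' @param pid A [pid_params()] (carries the set point).
#' @param duration_s Duration of the controlled sonication (s).
#' @param dose A [dose_params()].
#' @param dose_threshold_min Dose shut-off threshold (equivalent minutes).
#' @param cfg A [thermometry_config()].
#' @param dummy_frames Leading frames discarded before the baseline.
#' @param focus Focal ROI; defaults to [rig_focal_roi()].
#' @param drift_ref Optional drift-reference ROI (e.g. [rig_drift_roi()]);
#'   `NULL` disables drift correction.
#' @param disturbances Optional data frame with columns `time_s`, `factor`,
#'   `duration_s`: over each `[time_s, time_s + duration_s)` window
#'   (relative to the start of controlled sonication) the plant's perfusion
#'   coefficient is multiplied by `factor`, emulating physiology-driven
#'   perfusion changes.
#' @param collect_maps Keep per-frame temperature maps on the returned log.
#' @return A `sonication_log` (see [run_treatment()]) with the true plant
#'   focal temperature recorded per frame in attribute `"plant_focal_C"`.
#' @export
run_virtual_sonication <- function(rig, pid = pid_params(), duration_s = 600,
                                   dose = dose_params(),
                                   dose_threshold_min = Inf,
                                   cfg = thermometry_config(),
                                   dummy_frames = 2L,
                                   focus = rig_focal_roi(rig),
                                   drift_ref = NULL,
                                   disturbances = NULL,
                                   collect_maps = FALSE) {
  tissue <- rig$tissue; source <- rig$source; scanner <- rig$scanner
  period <- scanner$frame_period_s
  n_treat <- as.integer(round(duration_s / period))
  n_total <- dummy_frames + 1L + n_treat
  fld <- source_field(tissue, source)

  state <- plant_state(tissue)
  last_v <- 0
  i <- 0L
  t_start <- (dummy_frames + 1L) * period  # first controlled plant step begins
  plant_focal <- numeric(0)
  focal_center <- source$focus_center_mm

  perfusion_at <- function(rel_t) {
    w <- tissue$perfusion_s1
    if (!is.null(disturbances)) {
      for (r in seq_len(nrow(disturbances))) {
        if (rel_t >= disturbances$time_s[r] &&
            rel_t < disturbances$time_s[r] + disturbances$duration_s[r])
          w <- w * disturbances$factor[r]
      }
    }
    w
  }

  src <- function() {
    if (i >= n_total) return(NULL)
    if (i > 0L) {
      tis <- tissue
      tis$perfusion_s1 <- perfusion_at(state$time_s - t_start)
      state <<- step_plant(state, tis, source, last_v, period, field = fld)
    }
    i <<- i + 1L
    if (i > dummy_frames + 1L)
      plant_focal <<- c(plant_focal, plant_focal_mean(state, tissue, scanner,
                                                      focal_center))
    acquire_frame(state, tissue, scanner, cfg, frame_index = i)
  }
  sink <- function(v) last_v <<- v

  log <- run_treatment(src, focus = focus, drift_ref = drift_ref, pid = pid,
                       dose = dose, dose_threshold_min = dose_threshold_min,
                       cfg = cfg, dummy_frames = dummy_frames,
                       output_sink = sink, collect_maps = collect_maps)
  attr(log, "plant_focal_C") <- plant_focal
  attr(log, "setpoint_C") <- pid$setpoint_C
  log
}

#' True (noise-free) focal-ROI mean of the plant field
#'
#' Slice-averages the plant temperature field over the scanner slice and
#' averages a 2.6 x 3.2 mm focal window - the ground truth behind the noisy
#' MR reading.
#'
#' @param state,tissue,scanner Rig components.
#' @param center_mm In-plane focus center (mm from domain center).
#' @return Scalar temperature rise (degC).
#' @export
plant_focal_mean <- function(state, tissue, scanner, center_mm = c(0, 0)) {
  zax <- plant_axis(tissue$domain_mm[3], tissue$grid_mm)
  sl <- slice_average(state$temperature_C, zax, tissue$grid_mm,
                      scanner$slice_center_mm, scanner$slice_thickness_mm)
  pxx <- pixel_axis(scanner$matrix_dim[1], scanner$fov_mm[1])
  pxy <- pixel_axis(scanner$matrix_dim[2], scanner$fov_mm[2])
  roi <- rig_focal_roi(list(source = list(focus_center_mm = c(center_mm, 0)),
                            scanner = scanner))
  Ax <- interp_matrix_cached(pxx, plant_axis(tissue$domain_mm[1], tissue$grid_mm))
  Ay <- interp_matrix_cached(pxy, plant_axis(tissue$domain_mm[2], tissue$grid_mm))
  img <- Ax %*% sl %*% t(Ay)
  mean(img[roi$mask])
}
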