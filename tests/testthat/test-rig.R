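test_that("zero field with no noise yields a uniform-phase frame and zero map", {
  rig <- make_test_rig(noise = 0)
  st <- plant_state(rig$tissue)
  f0 <- acquire_frame(st, rig$tissue, rig$scanner, frame_index = 1)
  f1 <- acquire_frame(st, rig$tissue, rig$scanner, frame_index = 2)
  expect_lt(diff(range(Arg(f0$data))), 1e-12)
  tm <- phase_to_temperature(phase_difference(f1, f0), f0)
  expect_equal(max(abs(tm$delta_T_C)), 0, tolerance = 1e-12)
})

test_that("thermometry recovers the slice-averaged plant field without noise", {
  rig <- make_test_rig(noise = 0, grid_mm = 0.5)
  st <- plant_state(rig$tissue)
  base <- acquire_frame(st, rig$tissue, rig$scanner, frame_index = 1)
  st2 <- step_plant(st, rig$tissue, rig$source, 0.06, 30)
  cur <- acquire_frame(st2, rig$tissue, rig$scanner, frame_index = 2)
  tm <- phase_to_temperature(phase_difference(cur, base), base)
  truth <- plant_focal_mean(st2, rig$tissue, rig$scanner)
  recon <- roi_mean(tm, rig_focal_roi(rig))
  expect_gt(truth, 1)                 # the spot actually heated
  expect_lt(abs(recon - truth), 1e-9) # inverse-map oracle
})

test_that("pure scanner drift is removed exactly by ROI drift correction", {
  rig <- make_test_rig(noise = 0)
  rig$scanner$drift_rate_rad_per_s <- 0.002
  st <- plant_state(rig$tissue)
  base <- acquire_frame(st, rig$tissue, rig$scanner, frame_index = 1)
  st$time_s <- 60   # one minute later, still unheated
  cur <- acquire_frame(st, rig$tissue, rig$scanner, frame_index = 2)
  tm <- phase_to_temperature(phase_difference(cur, base), base)
  expect_gt(abs(roi_mean(tm, rig_focal_roi(rig))), 0.5)  # drift visible
  tm2 <- drift_correct(tm, rig_drift_roi(rig))
  expect_equal(max(abs(tm2$delta_T_C)), 0, tolerance = 1e-9)
})

test_that("per-frame noise seeding gives deterministic, calibrated readings", {
  rig <- rig_preset("agar-phantom")
  st <- plant_state(rig$tissue)
  base <- acquire_frame(st, rig$tissue, rig$scanner, frame_index = 1)
  noise_off <- rig$scanner; noise_off$noise_sigma_phase_rad <- 0
  base0 <- acquire_frame(st, rig$tissue, noise_off, frame_index = 1)
  roi <- rig_focal_roi(rig)
  reads <- vapply(2:201, function(k) {
    fr <- acquire_frame(st, rig$tissue, rig$scanner, frame_index = k)
    roi_mean(phase_to_temperature(phase_difference(fr, base0), base0), roi)
  }, numeric(1))
  # focal-mean precision calibrated to 0.25 degC per frame
  expect_gt(stats::sd(reads), 0.25 * 0.8)
  expect_lt(stats::sd(reads), 0.25 * 1.2)
  # identical frame index + seed -> identical frame
  f5a <- acquire_frame(st, rig$tissue, rig$scanner, frame_index = 5)
  f5b <- acquire_frame(st, rig$tissue, rig$scanner, frame_index = 5)
  expect_identical(f5a$data, f5b$data)
  expect_false(identical(base$data, f5a$data))
})

test_that("closed loop settles at the set point without noise", {
  rig <- rig_preset("agar-phantom")
  rig$scanner$noise_sigma_phase_rad <- 0
  log <- run_virtual_sonication(rig, pid_params(setpoint_C = 6),
                                duration_s = 600)
  s <- summarize_sonication(log, 6)
  expect_false(is.na(s$t_cross_s))
  expect_lte(s$overshoot_C, 1)
  tail_mean <- mean(utils::tail(log$focal_mean_C, 20))
  expect_lt(abs(tail_mean - 6), 0.1)
  # voltage levels off below the clamp
  expect_lt(max(utils::tail(log$v_out, 20)), 0.070)
  expect_lt(diff(range(utils::tail(log$v_out, 20))), 0.005)
})

test_that("integral action nulls steady-state error across plant gains", {
  for (fac in c(0.5, 1, 1.5)) {
    rig <- rig_preset("agar-phantom")
    rig$scanner$noise_sigma_phase_rad <- 0
    rig$source$power_gain_W_per_V2 <- rig$source$power_gain_W_per_V2 * fac
    log <- run_virtual_sonication(rig, pid_params(setpoint_C = 6),
                                  duration_s = 420)
    expect_lt(abs(mean(utils::tail(log$focal_mean_C, 20)) - 6), 0.1)
  }
})

test_that("seeded virtual sonications are bit-identical", {
  rig <- rig_preset("agar-phantom")
  rig$scanner$rng_seed <- 42L
  l1 <- run_virtual_sonication(rig, pid_params(setpoint_C = 4), duration_s = 90)
  l2 <- run_virtual_sonication(rig, pid_params(setpoint_C = 4), duration_s = 90)
  expect_identical(l1$focal_mean_C, l2$focal_mean_C)
  expect_identical(l1$v_out, l2$v_out)
})

test_that("a perfusion step disturbance dips the focus and raises the voltage", {
  rig <- rig_preset("mouse-tumor")
  rig$scanner$noise_sigma_phase_rad <- 0
  dist <- data.frame(time_s = 240, factor = 2, duration_s = 30)
  log <- run_virtual_sonication(rig, pid_params(setpoint_C = 6),
                                duration_s = 420, disturbances = dist)
  idx <- which(log$timestamp_s - log$timestamp_s[1] >= 240 &
                 log$timestamp_s - log$timestamp_s[1] < 330)
  pre <- which(log$timestamp_s - log$timestamp_s[1] >= 200 &
                 log$timestamp_s - log$timestamp_s[1] < 240)
  dip <- 6 - min(log$focal_mean_C[idx])
  expect_gt(dip, 0.3)                         # visible transient dip
  expect_lt(dip, 1.2)
  expect_gt(max(log$v_out[idx]), max(log$v_out[pre]) + 0.002)  # voltage rises
  # recovery to the set point after the disturbance window
  expect_lt(abs(mean(utils::tail(log$focal_mean_C, 10)) - 6), 0.1)
})
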