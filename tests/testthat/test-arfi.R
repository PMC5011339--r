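test_that("eddy-current phase cancels per polarity", {
  set.seed(5)
  ph <- matrix(stats::runif(64, -pi, pi), 8, 8)
  fr <- arfi_frameset(ph, ph, ph, ph)      # FUS on == FUS off
  ec <- eddy_current_correct(fr)
  expect_equal(ec$dphi_plus, matrix(0, 8, 8))
  expect_equal(ec$dphi_minus, matrix(0, 8, 8))

  # injected common-mode eddy phase cancels exactly
  psi <- matrix(stats::runif(64, -2, 2), 8, 8)
  sig <- matrix(0.3, 8, 8)
  fr2 <- arfi_frameset(wrap_oracle(sig + psi), wrap_oracle(psi),
                       matrix(0, 8, 8), matrix(0, 8, 8))
  expect_equal(eddy_current_correct(fr2)$dphi_plus, sig, tolerance = 1e-12)

  # random inputs against the naive wrapped-subtraction oracle
  a <- matrix(stats::runif(64, -pi, pi), 8, 8)
  b <- matrix(stats::runif(64, -pi, pi), 8, 8)
  ec3 <- eddy_current_correct(arfi_frameset(a, b, b, a))
  expect_equal(ec3$dphi_plus, wrap_oracle(a - b), tolerance = 1e-12)
  expect_equal(ec3$dphi_minus, wrap_oracle(b - a), tolerance = 1e-12)

  expect_error(arfi_frameset(a, b, b, matrix(0, 4, 4)), "shape")
})

test_that("displacement scaling matches the rectangular-MEG relation", {
  meg <- meg_params(g_strength_T_per_m = 0.1, lobe_duration_s = 4e-3,
                    gamma_rad_per_sT = 2.6753e8)
  # frozen oracle: 0.2140 / (2 * 2.6753e8 * 0.1 * 0.004) = 1.000 um
  dm <- displacement_from_phase(matrix(0.2140 / 2, 2, 2),
                                matrix(-0.2140 / 2, 2, 2), meg)
  expect_lt(max(abs(dm$dx_m - 1.000e-6)), 1e-9)

  z <- matrix(0, 2, 2)
  expect_equal(displacement_from_phase(z, z, meg)$dx_m, z)

  meg_half <- meg_params(g_strength_T_per_m = 0.05, lobe_duration_s = 4e-3,
                         gamma_rad_per_sT = 2.6753e8)
  dm2 <- displacement_from_phase(matrix(0.107, 2, 2), matrix(-0.107, 2, 2),
                                 meg_half)
  expect_equal(dm2$dx_m, 2 * dm$dx_m, tolerance = 1e-12)

  expect_error(meg_params(g_strength_T_per_m = 0), "positive")
})

test_that("the full ARFI pipeline round-trips a known displacement field", {
  px <- (1:32 - 16.5) * 0.625
  field <- outer(exp(-px^2 / (2 * 1.274^2)), exp(-px^2 / (2 * 1.274^2))) * 1e-6
  for (seed in 1:3) {
    set.seed(seed)
    ep <- matrix(stats::runif(1024, -1, 1), 32, 32)
    em <- matrix(stats::runif(1024, -1, 1), 32, 32)
    fr <- synthesize_arfi_frames(field, eddy_plus = ep, eddy_minus = em)
    ec <- eddy_current_correct(fr)
    dm <- displacement_from_phase(ec$dphi_plus, ec$dphi_minus)
    expect_lt(max(abs(dm$dx_m - field)), 1e-12)
  }
})

test_that("swapping polarity labels negates the displacement map", {
  set.seed(8)
  field <- matrix(stats::rnorm(64, 0, 2e-7), 8, 8)
  fr <- synthesize_arfi_frames(field)
  ec <- eddy_current_correct(fr)
  d1 <- displacement_from_phase(ec$dphi_plus, ec$dphi_minus)
  d2 <- displacement_from_phase(ec$dphi_minus, ec$dphi_plus)
  expect_equal(d2$dx_m, -d1$dx_m, tolerance = 1e-15)
})

test_that("focal-spot metrics read peak and FWHM from the map", {
  px <- (1:65 - 33) * 0.625            # odd grid: one pixel at the center
  spot <- outer(exp(-px^2 / (2 * 1.274^2)), exp(-px^2 / (2 * 1.274^2)))
  dm <- structure(list(dx_m = spot * 1.0e-6, encoding_axis = "x"),
                  class = "displacement_map")
  m <- focal_spot_metrics(dm, pixel_mm = 0.625)
  expect_lt(abs(m$peak_displacement_m - 1.0e-6), 1e-9)
  # sigma = 1.274 mm -> FWHM = 2.3548 * 1.274 = 3.00 mm
  expect_lt(abs(m$fwhm_mm - 2 * sqrt(2 * log(2)) * 1.274), 0.05)

  # amplitude scaling leaves the FWHM unchanged
  dm5 <- dm; dm5$dx_m <- dm$dx_m * 5
  expect_lt(abs(focal_spot_metrics(dm5, 0.625)$fwhm_mm - m$fwhm_mm), 1e-9)

  # offset background is removed via the map median
  dmo <- dm; dmo$dx_m <- dm$dx_m + 3e-7
  mo <- focal_spot_metrics(dmo, 0.625)
  expect_lt(abs(mo$fwhm_mm - m$fwhm_mm), 0.625)   # within one pixel

  flat <- structure(list(dx_m = matrix(2e-7, 16, 16), encoding_axis = "x"),
                    class = "displacement_map")
  expect_error(focal_spot_metrics(flat, 0.625), "peak")
})
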