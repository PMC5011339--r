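test_that("phase_difference handles identity, offsets and random pairs", {
  f0 <- make_random_frame(8, seed = 11)
  expect_equal(phase_difference(f0, f0), matrix(0, 8, 8))

  b <- make_uniform_frame(0)
  c3 <- make_uniform_frame(0.3)
  expect_equal(phase_difference(c3, b), matrix(0.3, 8, 8), tolerance = 1e-12)

  # brute-force wrap oracle per pixel, immune to a global phase offset
  for (seed in 1:5) {
    set.seed(seed)
    pa <- matrix(stats::runif(64, -pi, pi), 8, 8)
    pb <- matrix(stats::runif(64, -pi, pi), 8, 8)
    off <- stats::runif(1, -pi, pi)
    fa <- make_uniform_frame(0); fa$data <- complex(modulus = 1, argument = pa + off); dim(fa$data) <- c(8, 8)
    fb <- make_uniform_frame(0); fb$data <- complex(modulus = 1, argument = pb + off); dim(fb$data) <- c(8, 8)
    expect_equal(phase_difference(fa, fb), wrap_oracle(pa - pb),
                 tolerance = 1e-10)
  }
})

test_that("phase_difference is antisymmetric and validates metadata", {
  fa <- make_random_frame(8, seed = 1)
  fb <- make_random_frame(8, seed = 2)
  d1 <- phase_difference(fa, fb)
  d2 <- phase_difference(fb, fa)
  # negation modulo the wrap at +/- pi
  expect_equal(wrap_oracle(d1 + d2), matrix(0, 8, 8), tolerance = 1e-10)

  expect_error(phase_difference(fa, make_random_frame(6)), "shape")
  fc <- make_random_frame(8, te_s = 0.012)
  expect_error(phase_difference(fa, fc), "echo time")
})

test_that("phase_to_temperature applies the PRF relation", {
  b <- make_uniform_frame(0)  # TE 10 ms, B0 4.7 T
  zero <- phase_to_temperature(matrix(0, 8, 8), b)
  expect_equal(zero$delta_T_C, matrix(0, 8, 8))

  # frozen oracle: dT = dphi / (2 pi * 42.576e6 * -1e-8 * 4.7 * 0.01)
  tm <- phase_to_temperature(matrix(-0.6287, 8, 8), b)
  expect_true(all(abs(tm$delta_T_C - 5.000) < 1e-3))

  # linearity
  dphi <- matrix(stats::runif(64, -0.5, 0.5), 8, 8)
  t1 <- phase_to_temperature(dphi, b)$delta_T_C
  t2 <- phase_to_temperature(2 * dphi, b)$delta_T_C
  expect_equal(t2, 2 * t1, tolerance = 1e-12)
})

test_that("PRF round trip recovers a known temperature field exactly", {
  b <- make_uniform_frame(0, n = 16)
  coef <- prf_rad_per_C(b$te_s, b$b0_T)
  for (seed in 1:3) {
    set.seed(seed)
    dT <- matrix(stats::runif(256, 0, 10), 16, 16)
    cur <- b
    cur$data <- complex(modulus = 1, argument = dT * coef)
    dim(cur$data) <- c(16, 16)
    rec <- phase_to_temperature(phase_difference(cur, b), b)
    expect_true(max(abs(rec$delta_T_C - dT)) < 1e-9)
  }
})

test_that("validity mask flags low-magnitude baseline pixels", {
  b <- make_uniform_frame(0, n = 10)
  mag <- matrix(1, 10, 10); mag[1:2, 1:2] <- 0.01  # air-like corner
  b$data <- mag * b$data
  tm <- phase_to_temperature(matrix(0, 10, 10), b)
  expect_false(any(tm$mask[1:2, 1:2]))
  expect_true(all(tm$mask[5:10, 5:10]))
})

test_that("drift correction removes uniform drift and is idempotent", {
  ref <- roi_rect(c(-10, -10), c(5, 5), c(16, 16), c(60, 60),
                  label = "drift-reference")
  tm <- make_tmap(matrix(0.8, 16, 16))
  out <- drift_correct(tm, ref)
  expect_equal(out$delta_T_C, matrix(0, 16, 16), tolerance = 1e-12)

  # Gaussian hot spot + offset: spot preserved, injected offset removed
  px <- (1:16 - 8.5) * 60 / 16
  spot <- outer(exp(-px^2 / 4), exp(-px^2 / 4)) * 6
  tm2 <- make_tmap(spot + 0.5)
  out2 <- drift_correct(tm2, ref)
  resid <- out2$delta_T_C - spot
  expect_true(max(abs(resid)) < 1e-3)  # ref region sees ~0 of the spot

  # idempotence: a map whose ref mean is already 0 is unchanged
  out3 <- drift_correct(out2, ref)
  expect_equal(out3$delta_T_C, out2$delta_T_C, tolerance = 1e-12)

  # empty effective reference rejected
  tm3 <- tm; tm3$mask[] <- FALSE
  expect_error(drift_correct(tm3, ref), "valid")
  expect_error(drift_correct(tm, roi_rect(c(0, 0), c(5, 5), c(16, 16),
                                          c(60, 60), label = "focus")),
               "drift-reference")
})

test_that("roi_mean matches a naive per-pixel loop", {
  roi <- roi_rect(c(0, 0), c(10, 10), c(12, 12), c(60, 60))
  tm <- make_tmap(matrix(6, 12, 12))
  expect_equal(roi_mean(tm, roi), 6)

  chk <- make_tmap(matrix(c(0, 2), 12, 12))  # checkerboard columns 0/2
  expect_equal(roi_mean(chk, roi), 1)

  set.seed(42)
  rnd <- make_tmap(matrix(stats::rnorm(144), 12, 12))
  acc <- 0; n <- 0
  for (i in 1:12) for (j in 1:12) if (roi$mask[i, j]) {
    acc <- acc + rnd$delta_T_C[i, j]; n <- n + 1
  }
  expect_equal(roi_mean(rnd, roi), acc / n, tolerance = 1e-12)

  nomask <- rnd; nomask$mask[] <- FALSE
  expect_error(roi_mean(nomask, roi), "valid")
})

test_that("mm-specified ROIs resolve to whole pixels (minimum 1)", {
  # 2.6 x 3.2 mm at 0.625 mm pitch -> 4 x 5 pixels
  roi <- roi_rect(c(0, 0), c(2.6, 3.2), c(96, 96), c(60, 60))
  expect_equal(sum(roi$mask), 20)
  expect_equal(range(rowSums(roi$mask)[rowSums(roi$mask) > 0]), c(5, 5))
  # sub-pixel request still yields one pixel
  tiny <- roi_rect(c(0, 0), c(0.1, 0.1), c(96, 96), c(60, 60))
  expect_equal(sum(tiny$mask), 1)
})

test_that("focal-mean noise shrinks as 1/sqrt(n_pixels)", {
  n <- 12; sigma <- 0.14
  b <- make_uniform_frame(0, n = n)
  roi1 <- roi_from_mask({m <- matrix(FALSE, n, n); m[6, 6] <- TRUE; m}, "focus")
  m16 <- matrix(FALSE, n, n); m16[4:7, 4:7] <- TRUE
  roi16 <- roi_from_mask(m16, "focus")
  reps <- 800
  set.seed(7)
  v1 <- v16 <- numeric(reps)
  for (r in seq_len(reps)) {
    z <- b$data + matrix(complex(real = stats::rnorm(n * n, 0, sigma),
                                 imaginary = stats::rnorm(n * n, 0, sigma)),
                         n, n)
    cur <- b; cur$data <- z
    tm <- phase_to_temperature(phase_difference(cur, b), b)
    v1[r] <- roi_mean(tm, roi1); v16[r] <- roi_mean(tm, roi16)
  }
  ratio <- stats::sd(v1) / stats::sd(v16)
  expect_gt(ratio, 4 * 0.85)   # 1/sqrt(16) scaling within sampling error
  expect_lt(ratio, 4 * 1.15)
})

test_that("temporal unwrapping follows large inter-frame phase jumps", {
  prev <- matrix(3.0, 4, 4)
  cur <- matrix(-3.1, 4, 4)   # physically 3.18 rad, wrapped
  un <- unwrap_temporal(cur, prev)
  expect_equal(un, matrix(-3.1 + 2 * pi, 4, 4))
  expect_equal(unwrap_temporal(cur, NULL), cur)
})
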