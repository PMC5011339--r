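# Fixtures are generated in code; nothing is read from disk.

# Small, fast rig for structural tests: coarse grid, small matrix, no noise.
make_test_rig <- function(noise = 0, grid_mm = 1, matrix_dim = c(48, 48),
                          perfusion = 0.02, gain = 85.77, seed = 1L) {
  list(tissue = tissue_params(perfusion_s1 = perfusion, grid_mm = grid_mm),
       source = source_model(power_gain_W_per_V2 = gain),
       scanner = scanner_model(noise_sigma_phase_rad = noise,
                               matrix_dim = matrix_dim,
                               rng_seed = seed))
}

# Uniform-phase complex frame.
make_uniform_frame <- function(phase = 0, n = 8, mag = 1, te_s = 0.010,
                               timestamp_s = 0, b0_T = 4.7) {
  complex_frame(matrix(mag * complex(modulus = 1, argument = phase), n, n),
                te_s = te_s, timestamp_s = timestamp_s, b0_T = b0_T,
                fov_mm = c(60, 60))
}

# Random complex frame with unit magnitude and uniform random phase.
make_random_frame <- function(n = 8, te_s = 0.010, timestamp_s = 0,
                              seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ph <- matrix(stats::runif(n * n, -pi, pi), n, n)
  complex_frame(matrix(complex(modulus = 1, argument = ph), n, n),
                te_s = te_s, timestamp_s = timestamp_s, fov_mm = c(60, 60))
}

# Brute-force wrap of an angle difference into (-pi, pi].
wrap_oracle <- function(x) {
  while (any(x > pi)) x[x > pi] <- x[x > pi] - 2 * pi
  while (any(x <= -pi)) x[x <= -pi] <- x[x <= -pi] + 2 * pi
  x
}

# A full-image temperature_map with all pixels valid (for unit tests that
# bypass the reconstruction chain).
make_tmap <- function(delta, timestamp_s = 0) {
  structure(list(delta_T_C = delta,
                 mask = matrix(TRUE, nrow(delta), ncol(delta)),
                 timestamp_s = timestamp_s),
            class = "temperature_map")
}
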