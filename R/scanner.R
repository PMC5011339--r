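#' Synthetic MR scanner model
#'
#' Generates complex thermometry frames from the plant's temperature field:
#' the field is averaged through the slice thickness, mapped to phase by the
#' inverse PRF relation, and overlaid with a spatially uniform drift phase
#' `drift_rate_rad_per_s * t` plus per-pixel complex Gaussian noise. Noise is
#' re-seeded deterministically per frame from `rng_seed + frame index`.
#'
#' The default phase noise (0.1406 rad) is chosen so that the mean
#' temperature over the default 2.6 x 3.2 mm focal ROI (20 pixels at
#' 0.625 mm pitch) has a per-frame standard deviation of 0.25 degC - the
#' thermometry precision of the original system; see
#' [phase_noise_for_focal_sd()].
#'
#' @param noise_sigma_phase_rad Per-pixel phase noise std (rad, >= 0).
#' @param drift_rate_rad_per_s Spatially uniform field-drift rate (rad/s).
#' @param slice_center_mm Through-plane slice center, mm from domain center.
#' @param slice_thickness_mm Slice thickness (mm). Default 3.
#' @param frame_period_s Frame period (s). Default 3.
#' @param matrix_dim Image matrix, length 2. Default `c(96, 96)`.
#' @param fov_mm In-plane field of view (mm). Default `c(60, 60)`.
#' @param te_s Echo time (s). Default 10 ms.
#' @param b0_T Field strength (T). Default 4.7.
#' @param rng_seed Integer seed governing all scanner noise.
#' @param support `"fov"` (object fills the field of view; unit magnitude
#'   everywhere) or `"domain"` (unit magnitude only over the simulated
#'   thermal domain's footprint, 5% elsewhere).
#' @return An object of class `scanner_model`.
#' @export
scanner_model <- function(noise_sigma_phase_rad = 0.1406,
                          drift_rate_rad_per_s = 0,
                          slice_center_mm = 0,
                          slice_thickness_mm = 3,
                          frame_period_s = 3,
                          matrix_dim = c(96, 96),
                          fov_mm = c(60, 60),
                          te_s = 0.010,
                          b0_T = 4.7,
                          rng_seed = 1L,
                          support = c("fov", "domain")) {
  if (noise_sigma_phase_rad < 0) stop("noise std must be >= 0")
  if (frame_period_s <= 0) stop("`frame_period_s` must be positive")
  if (slice_thickness_mm <= 0) stop("`slice_thickness_mm` must be positive")
  if (te_s <= 0) stop("`te_s` must be positive")
  if (b0_T <= 0) stop("`b0_T` must be positive")
  structure(list(noise_sigma_phase_rad = noise_sigma_phase_rad,
                 drift_rate_rad_per_s = drift_rate_rad_per_s,
                 slice_center_mm = slice_center_mm,
                 slice_thickness_mm = slice_thickness_mm,
                 frame_period_s = frame_period_s,
                 matrix_dim = as.integer(matrix_dim),
                 fov_mm = as.numeric(fov_mm),
                 te_s = te_s, b0_T = b0_T,
                 rng_seed = as.integer(rng_seed),
                 support = match.arg(support)),
            class = "scanner_model")
}

#' Phase noise giving a target focal-mean temperature precision
#'
#' Inverts the noise propagation through the PRF relation and ROI averaging:
#' `sigma_phi = sd_C * |dphi/dT| * sqrt(n_pixels)`.
#'
#' @param sd_C Target per-frame standard deviation of the ROI-mean
#'   temperature (degC).
#' @param n_pixels Number of pixels averaged in the ROI.
#' @param te_s,b0_T Acquisition parameters.
#' @param cfg A [thermometry_config()].
#' @return Per-pixel phase noise std (rad).
#' @export
phase_noise_for_focal_sd <- function(sd_C, n_pixels, te_s = 0.010, b0_T = 4.7,
                                     cfg = thermometry_config()) {
  sd_C * abs(prf_rad_per_C(te_s, b0_T, cfg)) * sqrt(n_pixels)
}

#' Partial-volume-weighted mean over the through-plane slice window
#'
#' Each grid layer contributes by the overlap of its voxel extent with the
#' slice window, so the effective slice profile is independent of the grid
#' spacing.
#' @noRd
slice_average <- function(temp, zax, h, center, thickness) {
  z0 <- center - thickness / 2
  z1 <- center + thickness / 2
  w <- pmax(0, pmin(zax + h / 2, z1) - pmax(zax - h / 2, z0))
  zsel <- which(w > 0)
  if (length(zsel) == 0) return(NULL)
  d <- dim(temp)
  m <- temp[, , zsel, drop = FALSE]
  dim(m) <- c(d[1] * d[2], length(zsel))
  matrix(as.vector(m %*% (w[zsel] / sum(w[zsel]))), d[1], d[2])
}

.interp_cache <- new.env(parent = emptyenv())

#' Bilinear interpolation weights from grid nodes to pixel centers (memoized)
#' @noRd
interp_matrix_cached <- function(px_mm, node_mm) {
  key <- paste(c(length(px_mm), px_mm[1], px_mm[2], length(node_mm),
                 node_mm[1], node_mm[2]), collapse = "|")
  A <- .interp_cache[[key]]
  if (is.null(A)) {
    A <- interp_matrix(px_mm, node_mm)
    .interp_cache[[key]] <- A
  }
  A
}

#' Pixel-sampling weights from grid voxels to image pixels
#'
#' Each image pixel reads the area average of the field over its footprint
#' (the in-plane partial-volume effect), computed from the overlap of the
#' pixel extent with each voxel extent. Pixels outside the simulated domain
#' read zero. Grid-consistent: refining the plant grid leaves the sampling
#' operator's action on a smooth field unchanged to second order.
#' @noRd
interp_matrix <- function(px_mm, node_mm) {
  n <- length(node_mm)
  h <- node_mm[2] - node_mm[1]
  pw <- if (length(px_mm) > 1) px_mm[2] - px_mm[1] else h
  A <- matrix(0, length(px_mm), n)
  for (p in seq_along(px_mm)) {
    ov <- pmax(0, pmin(node_mm + h / 2, px_mm[p] + pw / 2) -
                  pmax(node_mm - h / 2, px_mm[p] - pw / 2))
    A[p, ] <- ov / pw
  }
  A
}

#' Pixel-center coordinates (mm from image center)
#' @noRd
pixel_axis <- function(n, fov) (seq_len(n) - (n + 1) / 2) * fov / n

#' Acquire one synthetic thermometry frame from the plant
#'
#' Averages the temperature-rise field through the slice thickness, samples
#' it bilinearly at the image pixel centers, converts to phase with the
#' inverse PRF relation and adds drift and complex Gaussian noise.
#'
#' @param state A [plant_state()].
#' @param tissue The [tissue_params()] defining the plant grid geometry.
#' @param scanner A [scanner_model()].
#' @param cfg A [thermometry_config()].
#' @param frame_index Frame counter used both for the timestamp metadata and
#'   for per-frame noise seeding.
#' @return A [complex_frame()].
#' @export
acquire_frame <- function(state, tissue, scanner, cfg = thermometry_config(),
                          frame_index = 0L) {
  stopifnot(inherits(state, "plant_state"), inherits(scanner, "scanner_model"))
  zax <- plant_axis(tissue$domain_mm[3], tissue$grid_mm)
  sl <- slice_average(state$temperature_C, zax, tissue$grid_mm,
                      scanner$slice_center_mm, scanner$slice_thickness_mm)
  if (is.null(sl))
    stop("imaging slice does not intersect the simulated domain")

  Ax <- interp_matrix_cached(pixel_axis(scanner$matrix_dim[1], scanner$fov_mm[1]),
                             plant_axis(tissue$domain_mm[1], tissue$grid_mm))
  Ay <- interp_matrix_cached(pixel_axis(scanner$matrix_dim[2], scanner$fov_mm[2]),
                             plant_axis(tissue$domain_mm[2], tissue$grid_mm))
  dT_img <- Ax %*% sl %*% t(Ay)

  phase <- dT_img * prf_rad_per_C(scanner$te_s, scanner$b0_T, cfg) +
    scanner$drift_rate_rad_per_s * state$time_s
  mag <- matrix(1, scanner$matrix_dim[1], scanner$matrix_dim[2])
  if (scanner$support == "domain") {
    inx <- abs(pixel_axis(scanner$matrix_dim[1], scanner$fov_mm[1])) <=
      tissue$domain_mm[1] / 2
    iny <- abs(pixel_axis(scanner$matrix_dim[2], scanner$fov_mm[2])) <=
      tissue$domain_mm[2] / 2
    mag <- 0.05 + 0.95 * (outer(inx, iny) * 1)
  }
  z <- mag * complex(modulus = 1, argument = phase)
  if (scanner$noise_sigma_phase_rad > 0) {
    z <- z + with_frame_seed(scanner$rng_seed, frame_index, {
      s <- scanner$noise_sigma_phase_rad
      matrix(complex(real = stats::rnorm(length(z), 0, s),
                     imaginary = stats::rnorm(length(z), 0, s)),
             nrow = nrow(z))
    })
  }
  complex_frame(z, te_s = scanner$te_s, timestamp_s = state$time_s,
                b0_T = scanner$b0_T, fov_mm = scanner$fov_mm)
}

#' Evaluate an expression under a per-frame derived RNG seed
#' @noRd
with_frame_seed <- function(base_seed, frame_index, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed((as.integer(base_seed) + as.integer(frame_index)) %% 2147483647L)
  expr
}
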