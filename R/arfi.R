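#' Motion-encoding gradient parameters
#'
#' Parameters of the bipolar MEG used for MR-ARFI displacement encoding. The
#' displacement relation `dx = dphi / (2 * gamma * G * l)` treats each
#' gradient lobe as a rectangle (the trapezoids' rise time is negligible
#' against the lobe duration); `l` is the duration of a single lobe.
#' Defaults follow the ARFI protocol: G = 10 G/cm = 0.1 T/m, l = 4 ms, and
#' gamma in angular units (2*pi x 42.576 MHz/T) because the phase accrual is
#' angular.
#'
#' @param g_strength_T_per_m Gradient lobe amplitude (T/m, > 0).
#' @param lobe_duration_s Single-lobe duration (s, > 0).
#' @param gamma_rad_per_sT Gyromagnetic ratio (rad/s/T, > 0).
#' @return An object of class `meg_params`.
#' @export
meg_params <- function(g_strength_T_per_m = 0.1,
                       lobe_duration_s = 4e-3,
                       gamma_rad_per_sT = 2 * pi * 42.576e6) {
  if (any(c(g_strength_T_per_m, lobe_duration_s, gamma_rad_per_sT) <= 0))
    stop("all MEG parameters must be strictly positive")
  structure(list(g_strength_T_per_m = g_strength_T_per_m,
                 lobe_duration_s = lobe_duration_s,
                 gamma_rad_per_sT = gamma_rad_per_sT),
            class = "meg_params")
}

#' Bundle the four ARFI phase images
#'
#' ARFI acquisition runs the sequence at both MEG polarities, each with the
#' FUS pulse on and off; the off images carry the same eddy-current phase
#' and serve as its reference.
#'
#' @param plus_on,plus_off,minus_on,minus_off Phase matrices (rad),
#'   identical shapes.
#' @return An object of class `arfi_frameset`.
#' @export
arfi_frameset <- function(plus_on, plus_off, minus_on, minus_off) {
  imgs <- list(plus_on = plus_on, plus_off = plus_off,
               minus_on = minus_on, minus_off = minus_off)
  dims <- lapply(imgs, dim)
  if (!all(vapply(imgs, is.matrix, logical(1))) ||
      !all(vapply(dims, identical, logical(1), dims[[1]])))
    stop("the four phase images must be matrices of identical shape")
  structure(imgs, class = "arfi_frameset")
}

#' Eddy-current correction of ARFI phase images
#'
#' Per MEG polarity, subtracts the FUS-off phase from the FUS-on phase
#' (wrapped to (-pi, pi]): eddy-current phase is common to both and cancels
#' exactly, leaving only the displacement-encoded phase.
#'
#' @param frames An [arfi_frameset()].
#' @return List with `dphi_plus` and `dphi_minus` phase maps (rad).
#' @export
eddy_current_correct <- function(frames) {
  stopifnot(inherits(frames, "arfi_frameset"))
  list(dphi_plus = wrap_phase(frames$plus_on - frames$plus_off),
       dphi_minus = wrap_phase(frames$minus_on - frames$minus_off))
}

#' Displacement map from polarity-difference phase
#'
#' Applies `dx = dphi / (2 * gamma * G * l)` per pixel, with
#' `dphi = wrap(dphi_plus - dphi_minus)`.
#'
#' @param dphi_plus,dphi_minus Eddy-corrected phase maps per polarity (rad).
#' @param meg A [meg_params()].
#' @param encoding_axis Label of the encoding direction.
#' @return An object of class `displacement_map` with fields `dx_m` (signed
#'   metres) and `encoding_axis`.
#' @export
displacement_from_phase <- function(dphi_plus, dphi_minus,
                                    meg = meg_params(),
                                    encoding_axis = "acoustic-axis") {
  stopifnot(inherits(meg, "meg_params"),
            identical(dim(dphi_plus), dim(dphi_minus)))
  dphi <- wrap_phase(dphi_plus - dphi_minus)
  dx <- dphi / (2 * meg$gamma_rad_per_sT * meg$g_strength_T_per_m *
                  meg$lobe_duration_s)
  structure(list(dx_m = dx, encoding_axis = encoding_axis),
            class = "displacement_map")
}

#' Linear-interpolated FWHM of a 1-D profile around its peak
#' @noRd
profile_fwhm <- function(profile, peak_idx, spacing) {
  half <- profile[peak_idx] / 2
  # right crossing
  right <- NA_real_
  for (i in peak_idx:(length(profile) - 1L)) {
    if (profile[i] >= half && profile[i + 1L] < half) {
      right <- i + (profile[i] - half) / (profile[i] - profile[i + 1L])
      break
    }
  }
  left <- NA_real_
  for (i in peak_idx:2L) {
    if (profile[i] >= half && profile[i - 1L] < half) {
      left <- i - (profile[i] - half) / (profile[i] - profile[i - 1L])
      break
    }
  }
  if (is.na(left) || is.na(right))
    stop("half-maximum crossing not found (profile does not fall below half max)")
  (right - left) * spacing
}

#' Peak displacement and focal-spot FWHM
#'
#' Subtracts the map median (background), locates the dominant positive
#' peak, and measures the full width at half maximum of the 1-D profiles
#' through the peak along both in-plane axes by linear interpolation between
#' the half-maximum crossings.
#'
#' @param dmap A [displacement_from_phase()] result.
#' @param pixel_mm Pixel spacing, scalar or length-2 (mm).
#' @return List with `peak_displacement_m`, `fwhm_mm` (mean of the two
#'   axes) and `fwhm_mm_axes` (per-axis).
#' @export
focal_spot_metrics <- function(dmap, pixel_mm) {
  stopifnot(inherits(dmap, "displacement_map"))
  if (length(pixel_mm) == 1L) pixel_mm <- rep(pixel_mm, 2L)
  img <- dmap$dx_m - stats::median(dmap$dx_m)
  pk <- which(img == max(img), arr.ind = TRUE)[1, ]
  if (max(img) <= 0 || diff(range(img)) == 0)
    stop("no dominant positive peak in the displacement map")
  f1 <- profile_fwhm(img[, pk[2]], pk[1], pixel_mm[1])
  f2 <- profile_fwhm(img[pk[1], ], pk[2], pixel_mm[2])
  list(peak_displacement_m = max(img),
       fwhm_mm = mean(c(f1, f2)),
       fwhm_mm_axes = c(f1, f2))
}

#' Synthesize ARFI phase images from a displacement field
#'
#' Inverse of the reconstruction chain, for testing and demos: encodes a
#' displacement field into the four polarity/FUS phase images, optionally
#' injecting a common-mode eddy-current phase per polarity.
#'
#' @param dx_m Displacement field (m), matrix.
#' @param meg A [meg_params()].
#' @param eddy_plus,eddy_minus Eddy-current phase maps added to both the on
#'   and off image of the respective polarity (rad; scalar or matrix).
#' @return An [arfi_frameset()].
#' @export
synthesize_arfi_frames <- function(dx_m, meg = meg_params(),
                                   eddy_plus = 0, eddy_minus = 0) {
  enc <- meg$gamma_rad_per_sT * meg$g_strength_T_per_m * meg$lobe_duration_s
  zero <- matrix(0, nrow(dx_m), ncol(dx_m))
  arfi_frameset(plus_on = wrap_phase(dx_m * enc + eddy_plus + zero),
                plus_off = wrap_phase(eddy_plus + zero),
                minus_on = wrap_phase(-dx_m * enc + eddy_minus + zero),
                minus_off = wrap_phase(eddy_minus + zero))
}
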