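---
title: "Models and methods behind mrgfus"
author: "mrgfus authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind mrgfus}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`mrgfus` re-implements, in software only, the measurement and control chain
of a preclinical MR-guided focused ultrasound (MRgFUS) hyperthermia system:
PRF-shift MR thermometry, CEM43 thermal-dose accounting, a clamped PID
controller driving the transducer voltage, and MR-ARFI displacement
reconstruction. Because no magnet or transducer is attached, the package
ships a *virtual rig* — a Pennes bioheat plant, a virtual transducer and a
synthetic MR scanner — that closes the loop for testing, teaching and
controller prototyping. This vignette records the models, the parameter
choices, and the design decisions that were genuinely open.

## PRF-shift thermometry

The water proton resonance frequency falls linearly with temperature, about
$\alpha = -0.01$ ppm/°C. Between a baseline gradient-echo image and a later
frame, a temperature rise $\Delta T$ appears as a phase change, and the map
is reconstructed as

$$\Delta T = \frac{\Delta\varphi}{2\pi\,\gamma\,\alpha\,B_0\,\mathrm{TE}},$$

with $\gamma = 42.576$ MHz/T. Both constants are configurable
(`thermometry_config()`): they are standard literature values, and at the
default 4.7 T and TE = 10 ms the coefficient is $-0.1257$ rad/°C, so a 6 °C
hyperthermic rise stays far inside one phase cycle. For that reason
per-pixel temporal unwrapping exists (`unwrap_enabled`) but is off by
default.

Two implementation choices matter for robustness:

* The phase difference is taken as the argument of the complex-conjugate
  product of the two frames, never as a subtraction of two angle images —
  the latter wraps spuriously whenever the operands straddle $\pm\pi$.
* A validity mask flags pixels whose *baseline magnitude* falls below 10 %
  of the image's 95th-percentile magnitude. Low-signal (air) pixels
  otherwise show large apparent temperature excursions; masking them keeps
  ROI statistics meaningful.

Scanner field drift adds a slow, spatially uniform phase ramp that is
indistinguishable from heating. `drift_correct()` subtracts the mean
apparent temperature over a reference ROI placed away from the focus;
subtraction is done in temperature units, which under the linear PRF map is
equivalent to subtracting in phase units (the two would differ only if
unwrapping intervened between the steps). The correction is exact for any
uniform drift and idempotent.

ROIs can be given as masks or as center + size in millimetres; mm sizes are
resolved to whole pixels (nearest integer, minimum 1). At the default
60 mm / 96-pixel geometry (0.625 mm pitch) the system's 2.6 × 3.2 mm focal
ROI becomes 4 × 5 pixels.

## CEM43 thermal dose

Dose is accumulated in cumulative equivalent minutes at 43 °C following the
Sapareto–Dewey convention: an interval $\Delta t$ at absolute temperature
$T$ contributes $R^{(43 - T)}\,\Delta t$, with $R = 0.5$ at or above the
43 °C breakpoint and $R = 0.25$ below. The package maps the measured rise
to absolute temperature with a configurable baseline (37 °C by default, so
a Δ6 °C target sits exactly at the breakpoint; phantom work may use
ambient). Dose uses the drift-corrected focal *mean* — a scalar per frame —
matching the treatment loop; spatial dose-volume maps are out of scope. The
accumulator latches a `reached` flag at the configured threshold; the flag
never reverts, and `apply_dose_shutoff()` forces the commanded voltage to
zero from that frame onward while imaging (and dose bookkeeping) continue.
No default threshold is shipped: it is a per-study clinical decision, so the
configuration requires it explicitly whenever shut-off is wanted.

## The PID law and its discretization

The controller output is

$$V_\mathrm{out} = \min\!\Big\{K_p e(t) + K_i \!\int_0^t\! e(\tau)\,d\tau +
K_d \frac{de}{dt},\; V_\mathrm{max}\Big\},$$

with error $e$ = set point − measured rise (heating demands positive
voltage). Discretization is the plainest consistent one at the 3 s frame
period: rectangle-rule integral, backward-difference derivative (zero on
the first sample). Two clamps are applied: the documented upper limit
$V_\mathrm{max}$ (70 mV before amplification, a cavitation/skin-burn/
hardware limit), and a floor at 0 V, since negative drive is physically
meaningless.

**Integral-gain units.** The published tuned gains are $K_p = 10^{-3}$ V/°C,
$K_d = 5\times10^{-3}$ V·s/°C and $K_i = 10^{-5}$ *per sequence repeat*.
`pid_params()` always takes $K_i$ in V/(°C·s); the default converts the
per-repeat figure with the thermometry sequence's repetition time
TR = 30 ms, i.e. $K_i = 10^{-5}/0.030 = 3.33\times10^{-4}$ V/(°C·s). This
reading is adopted because it is the only one under which the published
gains reproduce the documented closed-loop behavior: the voltage ramps to
its working level within seconds, the focus reaches the set point in one to
two minutes and the voltage then levels off below the clamp. Interpreting
the repeat as the 3 s frame instead makes the integral two orders of
magnitude weaker, and the loop cannot reach any set point within a 10-min
sonication.

**Anti-windup** is by conditional integration: the integral increment is
discarded whenever the clamped output is saturated and the error would push
it further into saturation. During start-up this pins the integral just
below the value that would exceed $V_\mathrm{max}$, which is what produces
the soft landing at the set point; without it, a 10–20 min run that starts
saturated would overshoot badly. The full error history enters only through
the running integral and the last error — the standard incremental PID
memory.

A non-finite focal reading (e.g. an all-masked ROI) retains the previous
voltage and leaves the controller state untouched; the frame is skipped in
the dose accumulation as well. Any failure of the treatment loop emits a
final 0 V before propagating — the software equivalent of the original
system's guaranteed generator shut-down.

## The virtual rig

### Plant

The tissue stand-in solves the Pennes bioheat equation for the temperature
rise $T(\mathbf{x}, t)$,

$$\rho c\,\frac{\partial T}{\partial t} = k\nabla^2 T -
\rho c\, w\,(T - T_a) + Q,$$

by explicit finite differences on a regular 3-D grid (default 12 mm cube at
0.5 mm spacing) with insulated boundaries, sub-stepped to the stability
bound $\Delta t \le h^2 \rho c / 6k$. The replicated-edge Laplacian
telescopes to zero over the box, so with $w = 0$ the scheme conserves
energy exactly — the test suite checks the deposited energy bookkeeping to
floating-point accuracy. Defaults mimic agar/soft tissue: $k = 0.6$ W/m/K,
$\rho c = 4.2\times10^6$ J/m³/K.

The first-order loss coefficient $w$ plays two roles. In the
`"mouse-tumor"` preset it is blood perfusion (0.015 s⁻¹ baseline). In the
`"agar-phantom"` preset it is a Newtonian loss to the surrounding bath
(0.02 s⁻¹): a phantom on a water-coupled delivery table is not adiabatic,
and without some loss the insulated box is a pure integrator — it has no
steady state, a constant drive heats it indefinitely, and a
proportional–integral controller on an integrating plant necessarily
produces a slow overshoot hump that no power calibration removes. The loss
rate gives the focal response a time constant of tens of seconds, matching
the "steady state within a few minutes" character of the real system.

### Source and calibration

Deposited power is a 3-D Gaussian with the transducer's focal FWHM
(1.4 × 1.4 × 10 mm at 1.1 MHz), discretized by cell-integrated Gaussian
weights so the total deposited power is exact on any grid. Power scales as
voltage squared (intensity ∝ pressure², pressure ∝ drive), times a duty
factor. Each preset's `power_gain_W_per_V2` is calibrated once so that a
constant drive at the 70 mV clamp settles at a focal-mean rise of ≈12 °C
(agar 84.66, mouse 75.75 W/V²); every set point of interest (2–10 °C) is
then reachable below the clamp, and the controller's working voltages land
in the tens of millivolts, as in the original system's recordings.

### Scanner

`acquire_frame()` inverts the thermometry chain: the plant field is
averaged through the 3 mm slice with through-plane partial-volume weights,
sampled onto the 96 × 96 / 60 mm image by in-plane pixel-area averaging
(an MR pixel reads the mean of its footprint, not a point sample — this
also keeps the focal reading grid-consistent: halving the plant grid moves
the 10-min focal reading by under 1 %), converted to phase by the inverse
PRF relation, and overlaid with an optional uniform drift ramp plus
per-pixel complex Gaussian noise. Noise is re-seeded deterministically per
frame from `rng_seed + frame index`, so any frame can be regenerated in
isolation and whole runs are bit-reproducible.

The default phase noise, 0.1406 rad per pixel, is derived
(`phase_noise_for_focal_sd()`) so the 20-pixel focal-ROI mean has a
per-frame standard deviation of 0.25 °C — the thermometry precision the
original system reported. The magnitude support defaults to the full field
of view (the phantom is larger than the simulated thermal box); a
`"domain"` support is available for exercising the low-signal mask.

### What the rig does and does not emulate

The rig reproduces the *measurement statistics* (noise level, drift, frame
timing, ROI geometry) and a *plausible thermal response* around the focus.
It does not model acoustic propagation (standing waves, refraction,
nonlinearity), cavitation, skin heating, motion, the multi-timescale
response of a real perfused tumor, or the true thermal properties of the
original graphite-agar phantom, which were never measured. Closed-loop
results on the rig therefore validate the *software* — reconstruction
correctness, controller logic, dose bookkeeping, shut-off behavior — under
realistic statistics; they are not a physical prediction for any particular
animal or phantom.

## MR-ARFI reconstruction

Displacement encoding uses a bipolar motion-encoding gradient (MEG);
treating each lobe as a rectangle (rise time ≈52 µs against a 4 ms lobe),
the displacement is

$$\Delta x = \frac{\Delta\varphi}{2\,\gamma\,G\,l},$$

with $\gamma$ in angular units (2π × 42.576 MHz/T), $G$ the lobe amplitude
(10 G/cm = 0.1 T/m) and $l$ the *single-lobe* duration (4 ms; the quoted
8 ms is the total bipolar duration). Eddy-current phase is removed per
polarity by subtracting the FUS-off from the FUS-on image — the eddy phase
is common mode and cancels exactly — and the two polarities are then
subtracted and scaled. Focal-spot metrics take the map's dominant positive
peak after median-background subtraction; FWHM is read off the two in-plane
profiles through the peak by linear interpolation between the half-maximum
crossings, which is how spot widths are conventionally measured and is
robust to pixelation.

## Numerical choices and degenerate inputs

* Phase maps live in $(-\pi, \pi]$; the wrap convention maps $-\pi$ to
  $+\pi$.
* The explicit plant scheme sub-steps automatically; passing
  `substep = FALSE` turns an unstable request into an error instead.
* `fit_first_order()` characterizes a heating curve by
  $T_{ss}(1 - e^{-t/\tau})$ via Levenberg–Marquardt with closed-form
  starting values (plateau and 63.2 % crossing). On the diffusion plant the
  first minute is conduction-dominated and not first-order; fits intended
  to recover the lumped parameters should start after it.
* Degenerate inputs — empty ROIs, all-masked references, mismatched frame
  geometry, non-positive TE or field strength, non-monotonic controller
  time — are rejected with descriptive errors; non-finite *measurements*
  during a run are skipped and the loop carries on, because a treatment
  loop must not die on one bad frame.

## Problem sizes used in validation

The shipped validation replicates the system's protocols at desk scale on
the default rig: ten-minute closed-loop sonications at set points 2, 4, 6,
8 and 10 °C (ten seeds each, 3 s frames, 0.25 °C focal noise), and a
twelve-minute perfused run with 30 s perfusion-doubling disturbances at 4,
7 and 10 min. Overshoot, post-rise error standard deviation and RMSE are
measured from the first crossing of the set point, exactly as in the
original validation. `scripts/acceptance.R` recomputes all of these from
scratch on the installed package.

## Known limitations

* Single-slice thermometry only; no fat-referenced, motion-robust or
  volumetric reconstruction.
* The controller is single-point (focal mean); no multi-point or
  volumetric control, and no auto-tuning.
* The virtual function generator is an in-process callback; the TCP/IP
  protocol of a physical generator is an adapter port left unimplemented.
* NIfTI magnitude/phase pairs plus a JSON sidecar replace the original
  scanner-proprietary raw format; a reader for the latter would be an
  extension point.
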