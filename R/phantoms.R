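#' Specification for a synthetic flow-waveform pair
#'
#' Parameters of a pulsatile flow phantom: a half-sine systolic pulse on a
#' constant baseline, sampled on a uniform grid over one cardiac cycle. The
#' default 9 ms spacing matches the temporal resolution of retrospectively
#' gated phase-contrast cine imaging (2 x repetition time). The systolic
#' lobe spans `[systole_onset, systole_onset + upstroke_duration]` with its
#' peak at the midpoint, so the rising limb (the upstroke proper) occupies
#' the first half.
#'
#' @param rr_interval Cardiac cycle length, ms.
#' @param sample_spacing Sampling interval, ms (default 9).
#' @param systole_onset Start of the systolic lobe, ms.
#' @param upstroke_duration Total width of the half-sine lobe, ms; in
#'   (0, rr_interval).
#' @param peak_flow Peak flow, ml/s.
#' @param baseline_flow Baseline (diastolic) flow, ml/s.
#' @param true_delay Ground-truth transit delay of the distal curve, ms
#'   (>= 0); must leave the delayed pulse inside the cycle window.
#' @param attenuation Multiplier in (0, 1] applied to the distal pulse above
#'   baseline (shape-preserving propagation).
#' @param noise_sd SD of i.i.d. Gaussian noise added per sample, ml/s.
#' @param seed Integer RNG seed for the noise.
#' @return A validated list of class `waveform_spec`.
#' @export
waveform_spec <- function(rr_interval = 900, sample_spacing = 9,
                          systole_onset = 60, upstroke_duration = 300,
                          peak_flow = 400, baseline_flow = 5,
                          true_delay = 20, attenuation = 1,
                          noise_sd = 0, seed = 1L) {
  stopifnot_scalar(sample_spacing, "sample_spacing", lower = 0, strict_lower = TRUE)
  stopifnot_scalar(rr_interval, "rr_interval", lower = 0, strict_lower = TRUE)
  stopifnot_scalar(upstroke_duration, "upstroke_duration",
                   lower = 0, upper = rr_interval,
                   strict_lower = TRUE, strict_upper = TRUE)
  stopifnot_scalar(systole_onset, "systole_onset", lower = 0)
  stopifnot_scalar(true_delay, "true_delay", lower = 0)
  stopifnot_scalar(attenuation, "attenuation", lower = 0, upper = 1,
                   strict_lower = TRUE)
  stopifnot_scalar(noise_sd, "noise_sd", lower = 0)
  if (peak_flow <= baseline_flow) stop("'peak_flow' must exceed 'baseline_flow'")
  structure(as.list(environment()), class = "waveform_spec")
}

# continuous-time half-sine systolic pulse on a constant baseline
half_sine_flow <- function(t, onset, duration, peak, baseline) {
  u <- (t - onset) / duration
  pulse <- ifelse(u > 0 & u < 1, sin(pi * u), 0)
  baseline + (peak - baseline) * pulse
}

#' Generate a proximal/distal flow-waveform pair with known transit delay
#'
#' The proximal waveform is the half-sine pulse of the spec; the distal
#' waveform is the same continuous-time pulse shifted by `true_delay` and
#' attenuated above baseline, both sampled on the same grid, with optional
#' i.i.d. Gaussian noise. Generation is bit-reproducible under the spec's
#' seed.
#'
#' @param spec A [waveform_spec].
#' @return List with elements `proximal` and `distal` ([flow_waveform]s) and
#'   `true_delay` (ms).
#' @export
make_waveform_pair <- function(spec) {
  if (!inherits(spec, "waveform_spec")) stop("'spec' must be a waveform_spec")
  if (spec$true_delay >=
      spec$rr_interval - spec$systole_onset - spec$upstroke_duration) {
    stop("true_delay too large: the delayed pulse would leave the cycle window")
  }
  n <- ceiling(spec$rr_interval / spec$sample_spacing)
  t <- spec$sample_spacing * (0:(n - 1L))
  prox <- half_sine_flow(t, spec$systole_onset, spec$upstroke_duration,
                         spec$peak_flow, spec$baseline_flow)
  shifted <- half_sine_flow(t - spec$true_delay, spec$systole_onset,
                            spec$upstroke_duration, spec$peak_flow,
                            spec$baseline_flow)
  dist <- spec$baseline_flow + spec$attenuation * (shifted - spec$baseline_flow)
  if (spec$noise_sd > 0) {
    noise <- with_seed(spec$seed, stats::rnorm(2L * n, sd = spec$noise_sd))
    prox <- prox + noise[seq_len(n)]
    dist <- dist + noise[n + seq_len(n)]
  }
  list(proximal = flow_waveform(t, prox, "proximal"),
       distal = flow_waveform(t, dist, "distal"),
       true_delay = spec$true_delay)
}

#' Specification for a pulsating-lumen phantom
#'
#' A smooth single-peak cross-sectional-area curve over one cardiac cycle
#' with known minimal area and known ground-truth distensibility, so the
#' downstream distensibility estimate can be checked against truth.
#'
#' @param a_min Minimal lumen area, mm^2 (> 0).
#' @param target_distensibility Ground-truth distensibility in
#'   10^-3 mmHg^-1 (>= 0).
#' @param pulse_pressure Pulse pressure used to invert the distensibility
#'   formula, mmHg (> 0).
#' @param phases Cardiac phases per cycle (default 25, >= 3).
#' @param noise_sd SD of Gaussian noise added per phase, mm^2.
#' @param seed Integer RNG seed for the noise.
#' @return A validated list of class `lumen_spec`.
#' @export
lumen_spec <- function(a_min = 250, target_distensibility = 4,
                       pulse_pressure = 50, phases = 25L, noise_sd = 0,
                       seed = 1L) {
  stopifnot_scalar(a_min, "a_min", lower = 0, strict_lower = TRUE)
  stopifnot_scalar(target_distensibility, "target_distensibility", lower = 0)
  stopifnot_scalar(pulse_pressure, "pulse_pressure", lower = 0, strict_lower = TRUE)
  phases <- as.integer(phases)
  if (phases < 3L) stop("'phases' must be >= 3")
  stopifnot_scalar(noise_sd, "noise_sd", lower = 0)
  structure(as.list(environment()), class = "lumen_spec")
}

#' Generate a lumen area curve with known distensibility
#'
#' Inverts the distensibility formula: the maximal area is
#' `a_min * (1 + D * pulse_pressure)` with D on its natural mmHg^-1 scale.
#' The profile is a squared half-sine normalized so the minimum and maximum
#' are attained exactly; [distensibility()] on the noise-free curve
#' recovers the target to floating-point accuracy.
#'
#' @param spec A [lumen_spec].
#' @param location Anatomic label carried into the curve.
#' @return An [area_curve] with attributes `a_min_true`, `a_max_true`,
#'   `distensibility_true` (10^-3 mmHg^-1).
#' @export
make_area_curve <- function(spec, location = "phantom") {
  if (!inherits(spec, "lumen_spec")) stop("'spec' must be a lumen_spec")
  a_max <- spec$a_min *
    (1 + spec$target_distensibility * 1e-3 * spec$pulse_pressure)
  n <- spec$phases
  s <- sin(pi * (0:(n - 1L)) / (n - 1L))^2
  s <- s / max(s)  # pin the peak so a_max is attained exactly
  areas <- spec$a_min + (a_max - spec$a_min) * s
  if (spec$noise_sd > 0) {
    areas <- areas + with_seed(spec$seed, stats::rnorm(n, sd = spec$noise_sd))
    areas <- pmax(areas, 0.01 * spec$a_min)
  }
  curve <- area_curve(areas, location)
  attr(curve, "a_min_true") <- spec$a_min
  attr(curve, "a_max_true") <- a_max
  attr(curve, "distensibility_true") <- spec$target_distensibility
  curve
}

#' Specification for an ellipsoidal chamber-stack phantom
#'
#' An ellipsoid with semi-axes `(a, b, c)` is sliced perpendicular to the
#' `c` axis at `slice_thickness` spacing; each slice emits an elliptical
#' contour polygon. The analytic volume `4/3 pi a b c scale^3` per phase is
#' recorded as ground truth for checking Simpson's-rule volumetry.
#'
#' @param semi_axes Numeric length-3, semi-axes in mm (all > 0).
#' @param slice_thickness Slice spacing in mm (default 6, > 0).
#' @param vertices_per_contour Vertices per elliptical contour (>= 8).
#' @param phases Number of cardiac phases (>= 1).
#' @param volume_time_profile Per-phase linear scale factors (numeric,
#'   length `phases`, all > 0); the phase-`p` ellipsoid has semi-axes scaled
#'   by `profile[p]`. Default: constant 1.
#' @param seed Integer RNG seed (reserved for optional contour jitter).
#' @return A validated list of class `ellipsoid_spec`.
#' @export
ellipsoid_spec <- function(semi_axes = c(20, 20, 30), slice_thickness = 6,
                           vertices_per_contour = 64L, phases = 1L,
                           volume_time_profile = NULL, seed = 1L) {
  semi_axes <- as.numeric(semi_axes)
  if (length(semi_axes) != 3L || any(!is.finite(semi_axes)) ||
      any(semi_axes <= 0)) {
    stop("'semi_axes' must be 3 positive numbers")
  }
  stopifnot_scalar(slice_thickness, "slice_thickness", lower = 0,
                   strict_lower = TRUE)
  vertices_per_contour <- as.integer(vertices_per_contour)
  if (vertices_per_contour < 8L) stop("'vertices_per_contour' must be >= 8")
  phases <- as.integer(phases)
  if (phases < 1L) stop("'phases' must be >= 1")
  if (is.null(volume_time_profile)) volume_time_profile <- rep(1, phases)
  volume_time_profile <- as.numeric(volume_time_profile)
  if (length(volume_time_profile) != phases ||
      any(volume_time_profile <= 0)) {
    stop("'volume_time_profile' must give a positive scale per phase")
  }
  structure(as.list(environment()), class = "ellipsoid_spec")
}

#' Generate an ellipsoidal contour stack with analytic ground-truth volume
#'
#' @param spec An [ellipsoid_spec].
#' @param structure Structure label for the emitted contours (default
#'   `"LA"`).
#' @return A [contour_set] with attribute `volume_true_ml` (numeric, one
#'   analytic volume per phase).
#' @export
make_ellipsoid_stack <- function(spec, structure = "LA") {
  if (!inherits(spec, "ellipsoid_spec")) stop("'spec' must be an ellipsoid_spec")
  a <- spec$semi_axes[1]; b <- spec$semi_axes[2]; c_ <- spec$semi_axes[3]
  th <- spec$slice_thickness
  m <- spec$vertices_per_contour
  ang <- 2 * pi * (0:(m - 1L)) / m
  rows <- vector("list", 0L)
  for (p in seq_len(spec$phases)) {
    s <- spec$volume_time_profile[p]
    cp <- c_ * s
    kmax <- max(0L, ceiling(cp / th) - 1L)
    zs <- th * (-kmax:kmax)
    zs <- zs[abs(zs) < cp]           # at least z = 0 always survives
    if (!length(zs)) zs <- 0
    for (j in seq_along(zs)) {
      f <- sqrt(max(0, 1 - (zs[j] / cp)^2))
      rows[[length(rows) + 1L]] <- data.frame(
        structure = structure, slice_index = j, phase = p,
        vertex_index = seq_len(m),
        x_mm = a * s * f * cos(ang), y_mm = b * s * f * sin(ang)
      )
    }
  }
  cs <- contour_set(do.call(rbind, rows), slice_thickness_mm = th)
  attr(cs, "volume_true_ml") <-
    4 / 3 * pi * a * b * c_ * spec$volume_time_profile^3 / 1000
  cs
}

#' Canonical bi-phasic left-atrial volume profile
#'
#' A smooth LA volume-versus-phase curve through the three landmark volumes:
#' the cycle starts at the minimum (ventricular end-diastole), fills to the
#' maximum during ventricular systole, empties passively to a diastasis
#' plateau, rises slightly to the pre-atrial-contraction shoulder, and the
#' atrial kick returns it to the minimum. The shoulder is a genuine local
#' maximum so [la_landmarks()] recovers all three phases.
#'
#' @param vol_max,vol_ac,vol_min Landmark volumes (ml),
#'   `vol_max > vol_ac > vol_min >= 0`.
#' @param phases Number of cardiac phases (>= 8, default 25).
#' @param dip_frac Depth of the diastasis dip below `vol_ac`, as a fraction
#'   of the total excursion (default 0.04).
#' @return Numeric vector of volumes with attribute `landmarks` (list of
#'   true `phase_max`, `phase_ac`, `phase_min`).
#' @export
make_la_profile <- function(vol_max, vol_ac, vol_min, phases = 25L,
                            dip_frac = 0.04) {
  phases <- as.integer(phases)
  if (phases < 8L) stop("'phases' must be >= 8")
  if (!(vol_max > vol_ac && vol_ac > vol_min && vol_min >= 0)) {
    stop("need vol_max > vol_ac > vol_min >= 0")
  }
  ease <- function(from, to, k) {
    from + (to - from) * 0.5 * (1 - cos(pi * seq(0, 1, length.out = k)))
  }
  i_max <- max(3L, round(0.32 * phases))
  i_ac <- min(phases - 2L, round(0.72 * phases))
  i_dip <- i_max + max(1L, (i_ac - i_max) %/% 2L)
  dip <- min(dip_frac * (vol_max - vol_min), 0.45 * (vol_ac - vol_min))
  v_dip <- vol_ac - dip
  v <- c(
    ease(vol_min, vol_max, i_max),
    ease(vol_max, v_dip, i_dip - i_max + 1L)[-1L],
    ease(v_dip, vol_ac, i_ac - i_dip + 1L)[-1L],
    ease(vol_ac, vol_min, phases - i_ac + 1L)[-1L]
  )
  attr(v, "landmarks") <- list(phase_max = i_max, phase_ac = i_ac,
                               phase_min = phases)
  v
}
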