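---
title: "Methods: CMR biomarkers of aortic stiffness and left-heart function"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: CMR biomarkers of aortic stiffness and left-heart function}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vesselpulse)
```

This vignette is the package's own account of the models and procedures it
implements, the choices made where the methodology was genuinely open, and
what its synthetic-data tests do and do not demonstrate about real data.

## The measurement problem

After surgical repair of aortic coarctation the aorta often remains stiffer
than normal, and chronically increased afterload is suspected to impair
left-ventricular diastolic function long before systolic indices change.
CMR quantifies both sides of this relationship without ionizing radiation:
arterial stiffness through pulse wave velocity (PWV) and regional
distensibility, and diastolic function through left-atrial (LA) volumes and
emptying fractions. `vesselpulse` implements this biomarker panel for the
two raw-data forms such studies export: sampled flow-versus-time curves from
phase-contrast (PC) cine imaging and planar contour polygons traced on cine
or dark-blood images. Image acquisition, DICOM handling and the manual
contouring itself are out of scope; contours and flow curves are the inputs.

## Transit time and pulse wave velocity

Two flow curves are acquired a known centerline distance Δx apart; the wave
arrives at the distal plane Δt later, and PWV = Δx/Δt. Δt is estimated by
normalized cross-correlation around the systolic upstrokes, with these
numerical choices:

* **Support of the correlation.** The upstroke window runs from the foot
  (the latest crossing of `baseline + foot_fraction · (peak − baseline)`
  before the global maximum; `foot_fraction` defaults to 0.1 because the
  literature leaves the start of the upstroke undefined) to the peak.
  Correlating the *bare* upstroke is ill-conditioned: after mean
  subtraction and amplitude normalization a near-linear rising limb matches
  a shifted copy of itself at almost any lag, so even 1% noise produces
  multi-millisecond errors. The correlation support is therefore the
  upstroke window padded by one window length of pre-onset baseline and
  half a window length of early downstroke (`pad_pre`, `pad_post`): the
  onset corner and the peak turnover anchor the lag. The support
  deliberately stops short of the full downstroke — in vivo the distal
  downstroke is reshaped by wave reflections, which is the reason
  upstroke-based methods exist — so the phantom-measured accuracy is not
  bought by features that would be unreliable in real curves.
* **Noise handling.** Both curves receive the same zero-phase 3-point
  moving average (`smooth_window = 3`). A symmetric filter applied
  identically to both waveforms shifts neither, so the delay estimate is
  unbiased; it roughly halves the noise-driven error at the 9 ms temporal
  resolution typical of retrospectively gated PC imaging. The baseline
  used for foot detection is the median of the lowest quartile of pre-peak
  samples — identical to the minimum on clean curves, but not dragged down
  by single noisy samples.
* **Sub-sample refinement.** Curves are resampled by cubic splines on a
  grid refined by `interp_factor` (default 16, i.e. 0.56 ms at 9 ms
  sampling); the discrete correlation peak is refined by a quadratic fit
  through its neighbors. When the discrete peak is numerically perfect
  (correlation 1 within 1e−12) refinement is skipped, so integer-sample
  shifts are recovered exactly. Linear interpolation was tried first and
  rejected: its systematic "sag" between samples differs between the two
  curves for non-integer delays and biased the estimate by 1–2 ms.
* **Search range and guards.** Only positive lags up to `max_lag` (default
  100 ms, covering PWV ≥ 1 m/s over path lengths ≤ 0.3 m) are searched;
  the distal wave physically trails the proximal one. Ties break toward
  the smallest lag. A peak at the search boundary and a peak correlation
  below 0.5 raise warnings; a peak at or below zero lag is an error.

On noise-free phantoms the estimator recovers delays of 5–45 ms at 9 ms
sampling to better than 0.3%; at a signal-to-noise ratio of 20 the median
PWV error across that delay range is about 8% (both recomputed by
`scripts/acceptance.R`).

## Distensibility

Distensibility is the relative lumen area change per unit pulse pressure,

$$D = \frac{A_{max} - A_{min}}{A_{min}\,(P_{sys} - P_{dia})},$$

reported in 10⁻³ mmHg⁻¹. Areas come from the shoelace formula on contour
polygons (orientation-independent, simplicity-checked); the extremes are
taken on the raw per-phase area curve by default, with an optional cyclic
moving average for noisy planimetry — smoothing narrows the extremes, so it
is off unless requested. One cuff blood pressure per subject is assumed
(whether the source protocol re-measured BP per cine is not documented).
Body surface area uses the Mosteller formula, √(h·w/3600) — a concrete
choice the source methodology leaves open; Du Bois is available and the
pediatric validity of Mosteller motivated the default.

## Chamber volumetrics

"Simpson's rule" in cardiac MR means summing planimetered slice areas times
slice spacing, not the quadrature rule of the same name; `simpson_volume()`
implements exactly that, with a configurable inter-slice gap (default 0)
and an error — never a silent zero — for a phase without contours.

The three LA landmark phases are found on the volume-versus-phase curve:
the global maximum (pre-mitral-opening), the global minimum occurring after
it (mitral closure), and the pre-atrial-contraction shoulder as the last
interior local maximum between them. Young or sedated subjects can show a
fused diastasis with no shoulder; a fallback then takes the flattest point
of the emptying limb from mid-diastole on, and flags the result. The six LA
parameters follow from the landmark volumes; two algebraic identities hold
exactly and are enforced by tests: total emptying = passive + contractile
volume, and the reservoir fraction equals
$100\,[1 - (1 - \mathrm{LAEF}_{pass}/100)(1 - \mathrm{LAEF}_{contr}/100)]$.
LV stroke volume, ejection fraction, and mass ((epi − endo volume) × 1.05
g/ml, the standard myocardial density, which the source methodology does
not state) complete the panel; volumes and mass are BSA-indexed.

## Carotid wall morphometry

Wall area is the outer-contour area minus the inner (lumen) area. The
clinical protocol measures thickness "at two positions" per vessel, which
is under-specified for software: the reproducible analogue implemented here
casts rays from the inner contour's centroid at evenly spaced angles
(default 2, configurable upward) and averages the inner-to-outer boundary
distance. For concentric circular phantoms every position returns
R_out − R_in, so the position count is immaterial; for eccentric rings dense
sampling converges to the analytic mean radial gap.

## Cohort statistics

Group comparisons use the Mann-Whitney U test with midrank ties: exact
enumeration when n + m ≤ 12 without ties, otherwise the normal
approximation with tie and continuity corrections (delegated to
`stats::wilcox.test`, which implements precisely these variants; an
all-identical degenerate input returns p = 1 with a flag). Correlations are
Spearman's rank method with the t-approximation p-value. Adult hypertension
staging uses the European task-force bands (stage 1: 140–159 and/or 90–99
mmHg; stage 2: 160–179 and/or 100–109 mmHg; the higher component stage
wins). Pediatric percentile staging is out of scope because it requires
external reference tables.

Distensibility across the four aortic locations is modeled with a
random-intercept linear mixed-effects model (lme4, REML by default):

$$D_{ij} = \beta_0 + \beta_1\,\mathrm{ageRepair}_i +
\beta_2\,\mathrm{ageMRI}_i + \mathrm{location}_j + b_i + \varepsilon_{ij},$$

with treatment contrasts against the descending aorta at the diaphragm (the
location least affected by coarctation). Both ages enter because patients
repaired later also tend to be older at imaging; the model separates the
two. P-values are two-sided Wald tests with residual degrees of freedom
(n_obs − n_fixed). This df choice is flagged deliberately: p-values near
0.05 can flip under Satterthwaite or Kenward-Roger corrections, and the
simulation-based coverage check (≈92–95% for nominal 95% intervals at 50
subjects × 4 locations) is the package's evidence that the approximation is
adequate at this design size. With the random-intercept variance at zero
the fit reproduces OLS to numerical precision.

## The synthetic-data generator

Every estimator is exercised against phantoms with known ground truth:

* **Flow pairs** — a half-sine systolic lobe on a constant baseline. The
  lobe spans `[systole_onset, systole_onset + upstroke_duration]` with the
  peak at the midpoint; the distal curve is the continuous-time pulse
  shifted by `true_delay` and attenuated above baseline (shape-preserving
  propagation, matching the assumption of the cross-correlation method;
  upstroke broadening is deliberately not simulated). Defaults: 9 ms
  sampling, 900 ms cycle, peak 400 ml/s on a 5–6 ml/s baseline.
* **Lumen pulsation** — a squared-half-sine area profile normalized so the
  minimum and maximum are attained exactly, with
  `A_max = A_min(1 + D · PP)`; the distensibility estimate on a noise-free
  curve recovers the target to floating point.
* **Chamber stacks** — ellipsoids sliced perpendicular to their long axis
  at the slice thickness, emitting elliptical polygons; the analytic volume
  4/3·π·a·b·c·scale³ is recorded per phase. The canonical LA
  volume-time profile passes exactly through Vmax, the pre-contraction
  shoulder Vac (a genuine local maximum above a shallow diastasis dip) and
  Vmin.
* **Cohorts** — per-subject latent biomarkers drawn from group-specific
  truncated normals (physiologic floors; truncation via the CDF map keeps
  the copula intact), linked by a Gaussian copula so requested Spearman
  correlations are induced (the published associations are rank
  correlations, hence a copula rather than linear correlation). Group
  means and SDs default to the published patient/control summaries
  (n = 51/54, carotid substudy 11/13). LA and LV volumes are parameterized
  through their components (Vmin, contractile, passive; ESV, SV) so the
  landmark ordering holds by construction — the component means reproduce
  the published derived values exactly, at the cost of slightly different
  marginal SDs for the composite volumes. Ages are printed as medians with
  ranges in the source; a truncated normal approximating that location and
  spread is used, a documented simplification. With `materialize = TRUE`
  each subject's latent values are turned into raw waveforms and contours,
  so the whole pipeline runs end to end against known truth.

What passing these tests shows: the estimators are correct, unbiased and
appropriately precise *for data of this form* — shape-preserving wave
propagation, elliptical cross-sections, Gaussian noise, normal-ish
biomarker distributions. What they do not show: robustness to arrhythmia,
flow curves distorted by reflections or breathing, non-elliptical atria,
contouring error structure, or missing-data patterns of real studies.
Cohort-level checks (group separation on arch PWV, the age-at-repair
association) are properties of the simulation parameters, not reproductions
of any real cohort's values — no subject-level data are available, so the
published summaries serve only as simulation inputs.

## Problem sizes and reproducibility

The test suite and the acceptance script size their Monte-Carlo studies at
500 phantom waveforms for the noise study, 200 replicate cohorts for the
power and coverage checks, 10 000 random triples for the atrial identity,
and a fully materialized 10-subject cohort for the end-to-end round trip —
sizes at which the checked proportions are stable to a few percent while a
complete run stays in the minutes range on one core. All generators are
seeded and bit-reproducible; `run_cohort()` reruns byte-identically for a
fixed seed and configuration, and every missing value in a report is
logged, never silently imputed.

## Known limitations

* The transit-time estimator assumes a single systolic pulse per cycle;
  curves with prominent early reflections inside the correlation support
  will bias Δt.
* Carotid transit distances are short (≈4–5 cm), so delays approach the
  sub-sample regime and PWV errors of ~10% occur even on clean phantoms at
  high PWV; path-length uncertainty would add to this on real data.
* The Wald/residual-df p-values of the mixed model are approximate; for
  borderline effects a likelihood-ratio or Kenward-Roger check is advisable.
* Hypertension staging covers adults only.
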