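test_that("waveform pair generator encodes the requested delay on the grid", {
  # integer-sample shift: distal equals proximal shifted by whole grid steps
  sp <- waveform_spec(true_delay = 18, sample_spacing = 9, noise_sd = 0)
  pair <- make_waveform_pair(sp)
  n <- length(pair$proximal$flow)
  expect_equal(pair$distal$flow[3:n], pair$proximal$flow[1:(n - 2)])

  # identity case
  sp0 <- waveform_spec(true_delay = 0, attenuation = 1, noise_sd = 0)
  pair0 <- make_waveform_pair(sp0)
  expect_identical(pair0$distal$flow, pair0$proximal$flow)

  # fractional shift agrees with the closed-form continuous pulse at t - 4.5
  sp5 <- waveform_spec(true_delay = 4.5, noise_sd = 0)
  pair5 <- make_waveform_pair(sp5)
  want <- oracle_half_sine(pair5$distal$times - 4.5, sp5$systole_onset,
                           sp5$upstroke_duration, sp5$peak_flow,
                           sp5$baseline_flow)
  expect_equal(pair5$distal$flow, want, tolerance = 1e-12)

  # a delay that would push the pulse out of the cycle window is rejected
  expect_error(
    make_waveform_pair(waveform_spec(rr_interval = 500, systole_onset = 60,
                                     upstroke_duration = 300,
                                     true_delay = 150)),
    "leave the cycle")
})

test_that("waveform generation is bit-reproducible under a seed", {
  a <- make_waveform_pair(waveform_spec(noise_sd = 10, seed = 42))
  b <- make_waveform_pair(waveform_spec(noise_sd = 10, seed = 42))
  c_ <- make_waveform_pair(waveform_spec(noise_sd = 10, seed = 43))
  expect_identical(a$proximal$flow, b$proximal$flow)
  expect_identical(a$distal$flow, b$distal$flow)
  expect_false(identical(a$proximal$flow, c_$proximal$flow))
})

test_that("lumen phantom inverts the distensibility formula", {
  cv <- make_area_curve(lumen_spec(a_min = 250, target_distensibility = 4,
                                   pulse_pressure = 50, noise_sd = 0))
  ex <- area_extremes(cv)
  expect_equal(unname(ex["a_min"]), 250)
  expect_equal(unname(ex["a_max"]), 300)

  # rigid vessel: constant curve
  rigid <- make_area_curve(lumen_spec(target_distensibility = 0))
  expect_equal(diff(range(rigid$areas)), 0)

  # noise-free round trip through the downstream estimator, across the
  # published range of targets
  for (target in c(3, 4.5, 6.8, 9)) {
    cv <- make_area_curve(lumen_spec(a_min = 180, target_distensibility = target,
                                     pulse_pressure = 47, noise_sd = 0))
    ex <- area_extremes(cv)
    d <- distensibility(ex["a_min"], ex["a_max"], blood_pressure(117, 70))
    expect_equal(d$distensibility, target, tolerance = 1e-12)
  }
})

test_that("ellipsoid stack records the analytic volume and converges", {
  sp <- ellipsoid_spec(semi_axes = c(20, 20, 30), slice_thickness = 6)
  st <- make_ellipsoid_stack(sp)
  v_true <- 4 / 3 * pi * 20 * 20 * 30 / 1000
  expect_equal(attr(st, "volume_true_ml"), v_true, tolerance = 1e-12)

  # Simpson volume converges to the closed form as slices thin
  err <- vapply(c(6, 3, 1), function(th) {
    s <- make_ellipsoid_stack(ellipsoid_spec(semi_axes = c(20, 20, 30),
                                             slice_thickness = th))
    abs(simpson_volume(s, "LA", 1) - v_true) / v_true
  }, numeric(1))
  expect_true(all(diff(err) < 0))  # monotone improvement
  expect_lt(err[3], 0.01)

  # degenerate flat ellipsoid still emits the center slice
  tiny <- make_ellipsoid_stack(ellipsoid_spec(semi_axes = c(20, 20, 2),
                                              slice_thickness = 6))
  expect_gte(nrow(tiny), 8)
  expect_equal(unique(tiny$slice_index), 1)
})

test_that("cohort draws match requested moments and degenerate cases", {
  pars <- cohort_defaults()
  spec <- cohort_spec(n_patients = 200, n_controls = 200, params = pars,
                      seed = 11)
  co <- make_cohort(spec, materialize = FALSE)
  pat <- co$truth[co$subjects$group == "patient", ]
  # sample mean within 3 SE of the requested mean (floors barely truncate)
  for (nm in c("pwv_arch_ms", "la_vmin_i", "lv_sv_i")) {
    mu <- pars$patient_mean[pars$name == nm]
    sdv <- pars$patient_sd[pars$name == nm]
    expect_lt(abs(mean(pat[[nm]]) - mu), 3 * sdv / sqrt(nrow(pat)))
  }

  # SD = 0 collapses the draw to the mean
  pars0 <- pars
  pars0$patient_sd[pars0$name == "hr_bpm"] <- 0
  co0 <- make_cohort(cohort_spec(n_patients = 10, n_controls = 5,
                                 params = pars0, seed = 2),
                     materialize = FALSE)
  hr <- co0$truth$hr_bpm[co0$subjects$group == "patient"]
  expect_true(all(hr == pars0$patient_mean[pars0$name == "hr_bpm"]))

  # absent correlation knob leaves parameters uncorrelated
  co1 <- make_cohort(cohort_spec(n_patients = 1000, n_controls = 2,
                                 correlations = list(), seed = 5),
                     materialize = FALSE)
  pat1 <- co1$truth[co1$subjects$group == "patient", ]
  expect_lt(abs(spearman_rank(pat1$pwv_arch_ms, pat1$lv_sv_i)$rho), 0.1)

  # requested rank correlation is induced
  co2 <- make_cohort(cohort_spec(n_patients = 1000, n_controls = 2, seed = 6),
                     materialize = FALSE)
  pat2 <- co2$truth[co2$subjects$group == "patient", ]
  expect_lt(abs(spearman_rank(pat2$age_repair_y, pat2$pwv_dao_ms)$rho - 0.33),
            0.1)

  # an infeasible correlation matrix is rejected
  bad <- cohort_spec(correlations = list(
    list(a = "pwv_arch_ms", b = "pwv_dao_ms", rho = 0.99),
    list(a = "pwv_arch_ms", b = "lv_sv_i", rho = 0.99),
    list(a = "pwv_dao_ms", b = "lv_sv_i", rho = -0.99)))
  expect_error(make_cohort(bad, materialize = FALSE), "infeasible correlation")

  # seeded cohorts are bit-reproducible
  ca <- make_cohort(cohort_spec(n_patients = 5, n_controls = 5, seed = 9),
                    materialize = FALSE)
  cb <- make_cohort(cohort_spec(n_patients = 5, n_controls = 5, seed = 9),
                    materialize = FALSE)
  expect_identical(ca$truth, cb$truth)
  expect_identical(ca$subjects, cb$subjects)
})

test_that("canonical LA profile passes through its landmark volumes", {
  v <- make_la_profile(95, 64, 49, phases = 25)
  lm <- attr(v, "landmarks")
  expect_equal(v[lm$phase_max], 95)
  expect_equal(v[lm$phase_ac], 64)
  expect_equal(v[lm$phase_min], 49)
  expect_equal(max(v), 95)
  expect_equal(min(v), 49)
})
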