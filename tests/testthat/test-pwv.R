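make_pair <- function(...) make_waveform_pair(waveform_spec(...))

test_that("upstroke window spans foot to peak", {
  pair <- make_pair(true_delay = 0, noise_sd = 0)
  w <- pair$proximal
  win <- extract_upstroke(w, foot_fraction = 0.1)
  # peak of the half-sine lobe: onset + duration/2
  expect_equal(unname(win["end"]), w$times[which.max(w$flow)])
  # 10% crossing of the closed-form pulse: onset + (T/pi) asin(0.1)
  t_cross <- 60 + 300 / pi * asin(0.1)
  expect_lt(abs(win["start"] - t_cross), w$spacing)
  expect_lt(win["start"], win["end"])

  # monotone ramp over the whole cycle: window from the foot crossing to
  # the last sample (the ramp has no flat baseline, so the robust floor
  # sits in the lower part of the ramp)
  t <- seq(0, 891, by = 9)
  ramp <- flow_waveform(t, seq(0, 100, length.out = length(t)))
  wr <- extract_upstroke(ramp, 0.1, smooth_window = 1)
  expect_equal(unname(wr["end"]), t[length(t)])
  expect_gt(wr["start"], 0.05 * 891)
  expect_lt(wr["start"], 0.35 * 891)

  # flat curve has no upstroke
  expect_error(extract_upstroke(flow_waveform(t, rep(5, length(t)))),
               "no systolic upstroke")
})

test_that("upstroke foot detection is stable under noise", {
  ref <- extract_upstroke(make_pair(noise_sd = 0)$proximal)
  hits <- vapply(1:200, function(s) {
    w <- make_waveform_pair(
      waveform_spec(noise_sd = 20, seed = s))$proximal  # SNR 20
    win <- extract_upstroke(w)
    abs(win["start"] - ref["start"]) <= w$spacing
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("transit time recovers integer-sample shifts exactly", {
  for (d in c(9, 18, 36, 90)) {
    pair <- make_pair(true_delay = d, noise_sd = 0)
    est <- transit_time(pair$proximal, pair$distal)
    expect_equal(est$delta_t, d, tolerance = 1e-9)
    expect_equal(est$peak_correlation, 1, tolerance = 1e-12)
  }
})

test_that("transit time resolves sub-sample shifts and ignores amplitude", {
  pair <- make_pair(true_delay = 4.5, noise_sd = 0)
  est <- transit_time(pair$proximal, pair$distal, interp_factor = 16)
  expect_lt(abs(est$delta_t - 4.5), 0.5)

  att <- make_pair(true_delay = 20, noise_sd = 0, attenuation = 0.7)
  expect_lt(abs(transit_time(att$proximal, att$distal)$delta_t - 20), 0.5)

  # scaling either waveform leaves the delay unchanged
  sc <- att
  sc$distal$flow <- sc$distal$flow * 3.7
  expect_equal(transit_time(att$proximal, att$distal)$delta_t,
               transit_time(sc$proximal, sc$distal)$delta_t)
})

test_that("transit time is shift-equivariant in the common time origin", {
  pair <- make_pair(true_delay = 22.5, noise_sd = 0)
  base <- transit_time(pair$proximal, pair$distal)$delta_t
  shift_wave <- function(w, off) flow_waveform(w$times + off, w$flow, w$site)
  moved <- transit_time(shift_wave(pair$proximal, 37),
                        shift_wave(pair$distal, 37))$delta_t
  expect_equal(moved, base, tolerance = 1e-9)
})

test_that("bias across physiologic delays is small at 9 ms sampling", {
  errs <- vapply(seq(5, 45, by = 5), function(d) {
    pair <- make_pair(true_delay = d, noise_sd = 0, attenuation = 0.85)
    abs(transit_time(pair$proximal, pair$distal,
                     interp_factor = 8)$delta_t - d)
  }, numeric(1))
  expect_lt(median(errs), 1)
})

test_that("degenerate lags are flagged or rejected", {
  # best lag at the search boundary raises a flag
  pair <- make_pair(true_delay = 40, noise_sd = 0)
  expect_warning(est <- transit_time(pair$proximal, pair$distal, max_lag = 30),
                 "boundary")
  expect_true("lag at search boundary" %in% est$flags)

  # a distal wave that leads the proximal wave has no positive-lag peak
  lead <- make_pair(true_delay = 25, noise_sd = 0)
  expect_error(transit_time(lead$distal, lead$proximal),
               "non-physiologic delay")
})

test_that("PWV formula and phantom round trip", {
  expect_equal(pulse_wave_velocity(30, delta_x = 0.12)$pwv, 4.0)
  expect_equal(pulse_wave_velocity(25, delta_x = 0.10)$pwv, 4.0)
  expect_error(pulse_wave_velocity(0, 0.1), "zero transit time")
  expect_error(pulse_wave_velocity(-3, 0.1), "zero transit time")

  # ground-truth 5 m/s phantom: dx = 0.10 m, delay 20 ms, 9 ms sampling
  pair <- make_pair(true_delay = 20, noise_sd = 0, attenuation = 0.85)
  est <- transit_time(pair$proximal, pair$distal, interp_factor = 16)
  pwv <- pulse_wave_velocity(est, 0.10, "aortic arch")
  expect_rel_error(pwv$pwv, 5.0, 0.05)
})
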