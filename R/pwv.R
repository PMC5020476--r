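#' Locate the systolic upstroke window of a flow waveform
#'
#' The upstroke runs from the "foot" of the systolic pulse to its peak. The
#' window end is the time of the global flow maximum; the start is the latest
#' time before the peak at which the flow crosses
#' `baseline + foot_fraction * (peak - baseline)`. The baseline is a robust
#' floor of the pre-peak region -- the median of its lowest quartile, which
#' equals the minimum on clean curves but is not dragged down by single
#' noisy samples. The crossing time is refined by linear interpolation
#' between samples.
#'
#' @param w A [flow_waveform].
#' @param foot_fraction Fraction of pulse height defining the foot, in
#'   (0, 0.5). Default 0.1.
#' @param smooth_window Odd width of a zero-phase moving average applied
#'   before detection (default 3, matching [transit_time()]); 1 disables.
#'   Being symmetric, the filter does not move the foot.
#' @return Named numeric vector `c(start = , end = )` in ms; the window
#'   always spans at least two sample intervals.
#' @export
extract_upstroke <- function(w, foot_fraction = 0.1, smooth_window = 3L) {
  if (!inherits(w, "flow_waveform")) stop("'w' must be a flow_waveform")
  stopifnot_scalar(foot_fraction, "foot_fraction", lower = 0, upper = 0.5,
                   strict_lower = TRUE, strict_upper = TRUE)
  smooth_window <- as.integer(smooth_window)
  if (smooth_window < 1L || smooth_window %% 2L == 0L) {
    stop("'smooth_window' must be a positive odd integer")
  }
  if (smooth_window > 1L) {
    w$flow <- as.numeric(stats::filter(
      w$flow, rep(1 / smooth_window, smooth_window), sides = 2,
      circular = TRUE))
  }
  i_pk <- which.max(w$flow)
  peak <- w$flow[i_pk]
  pre <- w$flow[seq_len(i_pk)]
  baseline <- stats::median(pre[pre <= stats::quantile(pre, 0.25)])
  if (peak <= baseline) stop("no systolic upstroke: flat flow curve")
  thr <- baseline + foot_fraction * (peak - baseline)
  start <- w$times[1]
  if (i_pk > 1L) {
    below <- which(w$flow[seq_len(i_pk - 1L)] <= thr)
    if (length(below)) {
      i <- max(below)  # latest pre-peak sample at or below the foot level
      f0 <- w$flow[i]; f1 <- w$flow[i + 1L]
      start <- if (f1 > f0) {
        w$times[i] + (thr - f0) / (f1 - f0) * (w$times[i + 1L] - w$times[i])
      } else {
        w$times[i]
      }
    }
  }
  end <- w$times[i_pk]
  if (end - start < 2 * w$spacing) {
    start <- max(w$times[1], end - 2 * w$spacing)
  }
  c(start = start, end = end)
}

#' Transit time between proximal and distal flow waveforms
#'
#' Estimates the delay of the distal flow curve relative to the proximal one
#' by normalized cross-correlation around their systolic upstrokes, the
#' standard approach for wave transit time in phase-contrast MR. Both curves
#' first receive an identical zero-phase moving average (optional). The
#' proximal upstroke window -- padded by a stretch of pre-onset baseline and
#' a short piece of early downstroke, whose corners anchor the lag -- is
#' resampled by cubic-spline interpolation onto a grid refined by
#' `interp_factor`; for every candidate lag in `(0, max_lag]` the distal
#' curve is sampled on the same (shifted) grid and the Pearson correlation
#' of the mean-subtracted, amplitude-normalized segments is computed, so
#' distal attenuation is irrelevant. The lag maximizing the correlation is
#' refined below the grid spacing by quadratic interpolation around the
#' discrete peak (skipped when the discrete peak is already a numerically
#' perfect match). Ties are broken toward the smallest lag; negative lags
#' are excluded because the distal wave physically trails the proximal
#' wave.
#'
#' @param prox,dist [flow_waveform]s on the same sampling grid.
#' @param interp_factor Integer >= 1; grid refinement factor (default 16).
#' @param max_lag Largest lag searched, ms (default 100; covers pulse wave
#'   velocities >= 1 m/s over path lengths up to 0.3 m).
#' @param foot_fraction Passed to [extract_upstroke()].
#' @param smooth_window Odd width of a zero-phase moving average applied
#'   identically to both waveforms before matching (default 3); 1 disables.
#'   A symmetric filter shifts neither waveform, so the delay is unbiased.
#' @param pad_pre,pad_post Extension of the correlation support below the
#'   upstroke foot and beyond the peak, in upstroke-window lengths.
#' @return Object of class `transit_estimate`: `delta_t` (ms),
#'   `peak_correlation`, `window_prox` and `window_dist` (upstroke windows,
#'   ms), and `flags` (character; may contain `"lag at search boundary"` or
#'   `"poor waveform similarity"`, each also raised as a warning).
#' @seealso [pulse_wave_velocity()]
#' @export
transit_time <- function(prox, dist, interp_factor = 16L, max_lag = 100,
                         foot_fraction = 0.1, smooth_window = 3L,
                         pad_pre = 1, pad_post = 0.5) {
  if (!inherits(prox, "flow_waveform") || !inherits(dist, "flow_waveform")) {
    stop("'prox' and 'dist' must be flow_waveform objects")
  }
  interp_factor <- as.integer(interp_factor)
  if (interp_factor < 1L) stop("'interp_factor' must be >= 1")
  stopifnot_scalar(max_lag, "max_lag", lower = 0, strict_lower = TRUE)
  if (length(prox$times) != length(dist$times) ||
      max(abs(prox$times - dist$times)) > 1e-6 * prox$spacing) {
    stop("proximal and distal waveforms must share one sampling grid")
  }

  smooth_window <- as.integer(smooth_window)
  if (smooth_window < 1L || smooth_window %% 2L == 0L) {
    stop("'smooth_window' must be a positive odd integer")
  }
  if (smooth_window > 1L) {
    # identical zero-phase (symmetric) moving average on both curves:
    # suppresses sample noise without shifting either waveform
    sm <- function(x) as.numeric(stats::filter(
      x, rep(1 / smooth_window, smooth_window), sides = 2, circular = TRUE))
    prox$flow <- sm(prox$flow)
    dist$flow <- sm(dist$flow)
  }

  win_p <- extract_upstroke(prox, foot_fraction, smooth_window = 1L)
  win_d <- extract_upstroke(dist, foot_fraction, smooth_window = 1L)

  pfun <- stats::splinefun(prox$times, prox$flow, method = "fmm")
  dfun <- stats::splinefun(dist$times, dist$flow, method = "fmm")

  # The correlation support is the proximal upstroke window padded by
  # `pad_pre` window lengths of baseline below the foot and `pad_post`
  # window lengths beyond the peak: the onset corner and the peak turnover
  # anchor the lag, which an isolated (near-linear) rising limb does not --
  # a shifted ramp still correlates perfectly with itself.
  h <- prox$spacing / interp_factor
  len <- win_p["end"] - win_p["start"]
  t0 <- max(prox$times[1], win_p["start"] - pad_pre * len)
  t1 <- min(prox$times[length(prox$times)], win_p["end"] + pad_post * len)
  tgrid <- seq(t0, t1, by = h)
  p <- pfun(tgrid)
  p <- p - mean(p)
  sp <- sqrt(sum(p^2))
  if (sp == 0) stop("no systolic upstroke: flat proximal segment")
  p <- p / sp

  lags <- h * seq_len(max(1L, floor(max_lag / h)))
  # one interpolation call for all (time, lag) queries, then reshape
  q <- rep(tgrid, times = length(lags)) + rep(lags, each = length(tgrid))
  # hold the distal curve at its last sample beyond the recorded cycle
  dmat <- matrix(dfun(pmin(q, dist$times[length(dist$times)])),
                 nrow = length(tgrid))
  dmat <- sweep(dmat, 2L, colMeans(dmat))
  dn <- sqrt(colSums(dmat^2))
  r <- as.vector(crossprod(p, dmat)) / dn
  r[!is.finite(r)] <- -Inf

  if (all(r == -Inf)) stop("non-physiologic delay: no usable lag")
  k <- which.max(r)  # which.max takes the first max: smallest-lag tie-break
  best <- lags[k]
  peak_r <- r[k]

  flags <- character()
  if (k == length(lags)) flags <- c(flags, "lag at search boundary")

  # quadratic refinement of the discrete peak (skipped for a numerically
  # perfect match, where the discrete lag is already exact)
  refined <- best
  if (peak_r < 1 - 1e-12) {
    cm <- if (k > 1L) {
      r[k - 1L]
    } else {
      d0 <- dfun(tgrid)
      d0 <- d0 - mean(d0)
      c0 <- sum(p * d0) / sqrt(sum(d0^2))
      if (is.finite(c0)) c0 else -Inf
    }
    cp <- if (k < length(lags)) r[k + 1L] else -Inf
    den <- cm - 2 * peak_r + cp
    if (is.finite(cm) && is.finite(cp) && den < 0) {
      off <- 0.5 * (cm - cp) / den * h
      off <- max(-h, min(h, off))
      refined <- best + off
    }
    if (refined <= 0) {
      stop("non-physiologic delay: correlation peak at or below zero lag")
    }
  }

  if (peak_r < 0.5) flags <- c(flags, "poor waveform similarity")
  for (f in flags) warning(f, call. = FALSE)

  structure(
    list(delta_t = unname(refined), peak_correlation = unname(peak_r),
         window_prox = win_p, window_dist = win_d,
         interp_factor = interp_factor, lag_step = h, flags = flags),
    class = "transit_estimate"
  )
}

#' @method print transit_estimate
#' @export
print.transit_estimate <- function(x, ...) {
  cat(sprintf("<transit_estimate> dt = %.2f ms (peak r = %.3f)\n",
              x$delta_t, x$peak_correlation))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}

#' Pulse wave velocity from transit time and path length
#'
#' PWV = delta_x / delta_t, with the centerline path length delta_x in metres
#' and the transit time delta_t converted from ms to s. Higher PWV indicates
#' a stiffer vessel segment.
#'
#' @param est A [transit_estimate], or a bare positive transit time in ms.
#' @param delta_x Centerline path length between the two flow planes, m (> 0).
#' @param segment Segment label (`"aortic arch"`, `"descending aorta"`,
#'   `"carotid"`, ...).
#' @return Object of class `pwv_result` with `pwv` (m/s), `delta_x`,
#'   `delta_t` and `segment`. Use `$pwv` or `as.numeric()` for the value.
#' @examples
#' pulse_wave_velocity(30, delta_x = 0.12)$pwv  # 4.0 m/s
#' @export
pulse_wave_velocity <- function(est, delta_x, segment = "unknown") {
  dt <- if (inherits(est, "transit_estimate")) est$delta_t else as.numeric(est)
  if (!is.finite(dt) || dt <= 0) stop("negative or zero transit time")
  stopifnot_scalar(delta_x, "delta_x", lower = 0, strict_lower = TRUE)
  structure(list(pwv = delta_x / (dt / 1000), delta_x = delta_x,
                 delta_t = dt, segment = as.character(segment)),
            class = "pwv_result")
}

#' @method print pwv_result
#' @export
print.pwv_result <- function(x, ...) {
  cat(sprintf("<pwv> %s: %.2f m/s (dx = %.3f m, dt = %.2f ms)\n",
              x$segment, x$pwv, x$delta_x, x$delta_t))
  invisible(x)
}

#' @export
as.numeric.pwv_result <- function(x, ...) x$pwv
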