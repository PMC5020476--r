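#' Construct a flow waveform
#'
#' A flow-versus-time curve sampled at one vessel site, as exported from
#' phase-contrast cine imaging. Times must be strictly increasing and
#' uniformly spaced; this is the substrate for transit-time estimation.
#'
#' @param times Sample times in milliseconds; strictly increasing, uniform
#'   spacing (relative tolerance 1e-6), at least 10 samples.
#' @param flow Flow in ml/s, one finite value per sample.
#' @param site Label for the measurement site (e.g. `"ascending aorta"`).
#' @return An object of class `flow_waveform`: a list with elements
#'   `times`, `flow`, `site`, and `spacing` (the sample spacing in ms).
#' @examples
#' t <- seq(0, 900, by = 9)
#' w <- flow_waveform(t, 5 + 300 * pmax(0, sin(pi * (t - 50) / 280)), "AAo")
#' print(w)
#' @export
flow_waveform <- function(times, flow, site = "unknown") {
  times <- as.numeric(times)
  flow <- as.numeric(flow)
  if (length(times) < 10L) {
    stop("flow waveform needs at least 10 samples, got ", length(times))
  }
  if (length(flow) != length(times)) {
    stop("'times' and 'flow' must have equal length")
  }
  if (!all(is.finite(times)) || !all(is.finite(flow))) {
    stop("flow waveform contains non-finite values")
  }
  dt <- diff(times)
  if (any(dt <= 0)) stop("'times' must be strictly increasing")
  spacing <- mean(dt)
  if (max(abs(dt - spacing)) > 1e-6 * spacing) {
    stop("'times' must be uniformly spaced (relative tolerance 1e-6)")
  }
  structure(
    list(times = times, flow = flow, site = as.character(site),
         spacing = spacing),
    class = "flow_waveform"
  )
}

#' @method print flow_waveform
#' @export
print.flow_waveform <- function(x, ...) {
  cat(sprintf(
    "<flow_waveform> site '%s': %d samples @ %.3g ms, flow %.1f to %.1f ml/s\n",
    x$site, length(x$times), x$spacing, min(x$flow), max(x$flow)
  ))
  invisible(x)
}

#' @export
plot.flow_waveform <- function(x, ...) {
  plot(x$times, x$flow, type = "l", xlab = "time (ms)",
       ylab = "flow (ml/s)", main = x$site, ...)
  invisible(x)
}
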