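#' Radar system parameters
#'
#' Operating parameters of the horizontally scanning S-band surveillance
#' radar. Defaults describe the marine-radar based avian tracking system the
#' package's methodology was developed for: 22.5 antenna scans per minute, a
#' pulse repetition frequency of 1,900 Hz, a 70 ns pulse, a 1.9 degree
#' horizontal 3 dB beam width, a 3,050 MHz carrier, and an instrumented range
#' of two nautical miles.
#'
#' @param scan_rate Antenna scans per minute.
#' @param prf Pulse repetition frequency in Hz.
#' @param pulse_width Pulse width in seconds.
#' @param h_beamwidth Horizontal 3 dB beam width in degrees.
#' @param frequency Carrier frequency in Hz.
#' @param instrumented_range Maximum recorded range in metres.
#' @return An object of class `radar_parameters`.
#' @examples
#' p <- radar_parameters()
#' scan_interval(p)   # ~2.67 s between scans
#' range_resolution(p) # ~10.5 m
#' @export
radar_parameters <- function(scan_rate = 22.5, prf = 1900,
                             pulse_width = 70e-9, h_beamwidth = 1.9,
                             frequency = 3.05e9,
                             instrumented_range = 2 * 1852) {
  vals <- c(scan_rate, prf, pulse_width, h_beamwidth, frequency,
            instrumented_range)
  stopifnot(all(is.finite(vals)), all(vals > 0))
  structure(list(scan_rate = scan_rate, prf = prf, pulse_width = pulse_width,
                 h_beamwidth = h_beamwidth, frequency = frequency,
                 instrumented_range = instrumented_range),
            class = "radar_parameters")
}

#' @rdname radar_parameters
#' @param params A `radar_parameters` object.
#' @return `scan_interval()`: seconds between successive scans (60/scan_rate).
#' @export
scan_interval <- function(params) 60 / params$scan_rate

#' @rdname radar_parameters
#' @return `range_resolution()`: best-case range resolution `c * tau / 2` in
#'   metres for pulse width `tau`.
#' @export
range_resolution <- function(params) .C0 * params$pulse_width / 2

#' @export
print.radar_parameters <- function(x, ...) {
  cat("Radar parameters:\n")
  cat(sprintf("  scan rate          %.1f scans/min (interval %.2f s)\n",
              x$scan_rate, scan_interval(x)))
  cat(sprintf("  PRF                %.0f Hz\n", x$prf))
  cat(sprintf("  pulse width        %.0f ns (range resolution %.1f m)\n",
              x$pulse_width * 1e9, range_resolution(x)))
  cat(sprintf("  horiz. beam width  %.1f deg\n", x$h_beamwidth))
  cat(sprintf("  frequency          %.0f MHz\n", x$frequency / 1e6))
  cat(sprintf("  instrumented range %.0f m\n", x$instrumented_range))
  invisible(x)
}
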