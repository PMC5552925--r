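#' Radar origin
#'
#' Location of the radar antenna in the projected planar coordinate system,
#' plus the antenna height above local ground. All geometry in this package is
#' two-dimensional: coordinates are projected metres (e.g. UTM), bearings are
#' degrees clockwise from grid north, and ranges are horizontal ranges --
#' altitude is carried along but never enters range or bearing.
#'
#' @param x,y Planar coordinates of the radar in metres.
#' @param antenna_height Height of the antenna above local ground in metres
#'   (used only by the line-of-sight clutter computation).
#' @return An object of class `radar_origin`.
#' @examples
#' radar_origin(0, 0, antenna_height = 5)
#' @export
radar_origin <- function(x, y, antenna_height = 0) {
  stopifnot(is.finite(x), is.finite(y), is.finite(antenna_height),
            antenna_height >= 0)
  structure(list(x = x, y = y, antenna_height = antenna_height),
            class = "radar_origin")
}

#' Range and bearing from the radar
#'
#' Horizontal range (m) and bearing (degrees clockwise from grid north, in
#' `[0, 360)`) of points relative to the radar origin. A point coincident with
#' the origin has range 0 and, by convention, bearing 0.
#'
#' @param origin A [radar_origin()].
#' @param x,y Numeric vectors of planar coordinates in metres.
#' @return A data frame with columns `range` and `bearing`.
#' @examples
#' range_bearing(radar_origin(0, 0), c(0, 1000, -300), c(1000, 0, -400))
#' @export
range_bearing <- function(origin, x, y) {
  dx <- x - origin$x
  dy <- y - origin$y
  rng <- sqrt(dx^2 + dy^2)
  brg <- (atan2(dx, dy) * 180 / pi) %% 360
  brg[rng == 0] <- 0
  data.frame(range = rng, bearing = brg)
}

#' Reconstruct planar coordinates from range and bearing
#'
#' Inverse of [range_bearing()].
#'
#' @inheritParams range_bearing
#' @param range Range in metres.
#' @param bearing Bearing in degrees clockwise from grid north.
#' @return A data frame with columns `x` and `y`.
#' @export
polar_to_xy <- function(origin, range, bearing) {
  b <- bearing * pi / 180
  data.frame(x = origin$x + range * sin(b),
             y = origin$y + range * cos(b))
}

#' Course over ground along a track
#'
#' Course (degrees clockwise from grid north, `[0, 360)`) of the segment
#' entering each point, i.e. from point `i - 1` to point `i`. The first
#' element is `NA`; coincident consecutive points yield `NA` (undefined
#' course).
#'
#' @param x,y Numeric vectors of planar coordinates (metres), time ordered.
#' @return Numeric vector of courses, same length as `x`.
#' @export
track_course <- function(x, y) {
  n <- length(x)
  out <- rep(NA_real_, n)
  if (n < 2) return(out)
  dx <- diff(x)
  dy <- diff(y)
  crs <- (atan2(dx, dy) * 180 / pi) %% 360
  crs[dx == 0 & dy == 0] <- NA_real_
  out[-1] <- crs
  out
}

# wrap an angle difference (degrees) into (-180, 180]
wrap_angle <- function(a) {
  w <- ((a + 180) %% 360) - 180
  w[!is.na(w) & w == -180] <- 180
  w
}

#' Turning angle between successive courses
#'
#' Change in heading at each point, computed from the courses of the entering
#' and leaving segments and wrapped to `(-180, 180]` degrees. Endpoints (and
#' points adjacent to degenerate zero-length segments) are `NA`.
#'
#' @inheritParams track_course
#' @return Numeric vector of turning angles in degrees.
#' @export
turning_angle <- function(x, y) {
  crs <- track_course(x, y)
  n <- length(crs)
  out <- rep(NA_real_, n)
  if (n >= 3) {
    out[2:(n - 1)] <- wrap_angle(crs[3:n] - crs[2:(n - 1)])
  }
  out
}

#' Tortuosity: normalized cosine of the turning angle
#'
#' The per-point tortuosity statistic `S = 1 - ((cos(dH) + 1) / 2)`, where
#' `dH` is the turning angle in degrees. `S` is 0 for straight flight, 1 for a
#' full reversal, and symmetric in turn direction. At a turning angle of 70
#' degrees, `S` is 0.329 (rounding to 0.33).
#'
#' @param dh Turning angle(s) in degrees.
#' @return Tortuosity value(s) in `[0, 1]`.
#' @examples
#' tortuosity(c(0, 70, 180))
#' @export
tortuosity <- function(dh) {
  1 - ((cos(dh * pi / 180) + 1) / 2)
}

#' Per-point tortuosity along a track
#'
#' Applies [tortuosity()] to the turning angles of a track. `NA` where the
#' turning angle is undefined (track ends, zero-length segments).
#'
#' @inheritParams track_course
#' @return Numeric vector of tortuosity values in `[0, 1]` (with `NA`s).
#' @export
track_tortuosity <- function(x, y) {
  tortuosity(turning_angle(x, y))
}

#' Classify track orientation relative to the radar beam
#'
#' Labels a track segment as moving "along" or "across" the radar beam from
#' the angular difference `alpha` between the course over ground and the
#' radial direction from the radar. With the default (radial) reference, a
#' segment is "along" when `|cos(alpha)| > cos(boundary)`; motion directly
#' toward or away from the radar is "along" either way. The boundary case
#' `|cos(alpha)| == cos(boundary)` is classified "across".
#'
#' The published inequality is ambiguous about whether `alpha` is measured
#' against the radial direction or the beam tangent; both readings are
#' available via `reference`. Under `reference = "tangent"` the same
#' inequality, applied to the course-vs-tangent angle, defines "across".
#'
#' @param course Course over ground, degrees.
#' @param radial_bearing Bearing of the point from the radar, degrees.
#' @param boundary Half-width of the "along" sector, degrees (default 45).
#' @param reference Angular reference for `alpha`: `"radial"` (default) or
#'   `"tangent"`.
#' @return Character vector with values `"along"` / `"across"` (`NA` where the
#'   course is `NA`).
#' @examples
#' orientation_class(c(0, 90, 45), 0)
#' @export
orientation_class <- function(course, radial_bearing, boundary = 45,
                              reference = c("radial", "tangent")) {
  reference <- match.arg(reference)
  alpha <- wrap_angle(course - radial_bearing)
  a <- abs(cos(alpha * pi / 180))
  thr <- cos(boundary * pi / 180)
  if (reference == "radial") {
    lab <- ifelse(a > thr, "along", "across")
  } else {
    # angle vs the beam tangent: |cos| large means tangential motion
    at <- abs(sin(alpha * pi / 180))
    lab <- ifelse(at > thr, "across", "along")
  }
  lab[is.na(course) | is.na(radial_bearing)] <- NA_character_
  lab
}
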