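#' Interpolate a GPS track in time
#'
#' Linear interpolation of the planar position (and altitude) of a GPS track
#' at arbitrary times. Times outside the track's span give `NA`.
#'
#' @param gps Data frame with columns `t` (seconds), `x`, `y` (metres) and
#'   optionally `alt` (metres AGL), strictly increasing in `t`.
#' @param t Times at which to interpolate.
#' @return Data frame with columns `t`, `x`, `y`, `alt`.
#' @export
gps_interpolate <- function(gps, t) {
  stopifnot(all(diff(gps$t) > 0))
  out <- data.frame(
    t = t,
    x = approx(gps$t, gps$x, xout = t, rule = 1)$y,
    y = approx(gps$t, gps$y, xout = t, rule = 1)$y
  )
  out$alt <- if ("alt" %in% names(gps))
    approx(gps$t, gps$alt, xout = t, rule = 1)$y else NA_real_
  out
}

#' Clock-offset objective for one candidate offset
#'
#' Evaluates the alignment quality of a candidate clock offset `T` between a
#' GPS track and its radar plots. Radar timestamps are shifted by `-T` into
#' the GPS frame, the GPS truth position is linearly interpolated at each
#' shifted time, and the squared pair distance `D^2` is regressed (ordinary
#' least squares, Gaussian likelihood) on the squared range difference
#' `dR^2 = (R_radar - R_gps)^2` and the squared bearing-difference distance
#' `dB^2 = (sin(alpha/2) * (R_radar + R_gps))^2`, where `alpha` is the
#' absolute bearing difference. The returned Gaussian log-likelihood is
#' maximal when the two streams are aligned: misalignment inflates the
#' residual variance of this near-identity.
#'
#' Maximizing the Gaussian log-likelihood over `T` is equivalent to
#' minimizing the residual variance of the fit; the likelihood form is kept
#' so that values are comparable across candidate offsets.
#'
#' @param gps GPS track data frame (`t`, `x`, `y`).
#' @param radar Radar plots data frame (`t`, `x`, `y`) for the same test.
#' @param T Candidate offset in seconds (radar clock minus GPS clock).
#' @param origin A [radar_origin()].
#' @return An object of class `offset_model`: list with `T`, `beta`
#'   (intercept, dR2, dB2), `loglik`, `n_pairs`, `sigma2`, `rank_deficient`.
#' @export
offset_objective <- function(gps, radar, T, origin) {
  ts <- radar$t - T
  keep <- ts >= min(gps$t) & ts <= max(gps$t)
  if (sum(keep) < 3) stop("fewer than 3 radar plots fall inside the GPS span")
  ts <- ts[keep]
  g <- gps_interpolate(gps, ts)
  rb_g <- range_bearing(origin, g$x, g$y)
  rb_r <- range_bearing(origin, radar$x[keep], radar$y[keep])
  d2 <- (radar$x[keep] - g$x)^2 + (radar$y[keep] - g$y)^2
  dr <- rb_r$range - rb_g$range
  alpha <- abs(wrap_angle(rb_r$bearing - rb_g$bearing))
  db <- sin(alpha / 2 * pi / 180) * (rb_r$range + rb_g$range)
  X <- cbind(1, dr^2, db^2)
  fit <- lm.fit(X, d2)
  rank_deficient <- fit$rank < 3
  if (rank_deficient) {
    # degenerate design (constant regressors): intercept-only fallback
    fit <- lm.fit(X[, 1, drop = FALSE], d2)
  }
  n <- length(d2)
  rss <- sum(fit$residuals^2)
  sigma2 <- max(rss / n, 1e-12)  # floor keeps the likelihood finite
  loglik <- -n / 2 * (log(2 * pi * sigma2) + 1)
  beta <- rep(NA_real_, 3)
  beta[seq_along(fit$coefficients)] <- fit$coefficients
  structure(list(T = T, beta = setNames(beta, c("intercept", "dR2", "dB2")),
                 loglik = loglik, n_pairs = n, sigma2 = sigma2,
                 rank_deficient = rank_deficient),
            class = "offset_model")
}

#' @export
print.offset_model <- function(x, ...) {
  cat(sprintf("Offset model at T = %.3f s: logLik %.2f over %d pairs (sigma %.2f m)\n",
              x$T, x$loglik, x$n_pairs, sqrt(x$sigma2)))
  invisible(x)
}

#' Estimate the GPS-radar clock offset
#'
#' Finds the clock offset maximizing [offset_objective()] over a search
#' window (default 0 to 120 s): a 1 s grid search followed by golden-section
#' refinement to 1e-3 s on the bracket around the best grid point. Grid ties
#' are broken toward the smaller offset. Offsets are estimated per flight
#' test; radar clocks typically run ahead of or behind GPS time by a constant
#' amount within one test.
#'
#' @inheritParams offset_objective
#' @param window Numeric length-2 search window in seconds.
#' @param grid_step Grid spacing for the coarse search, seconds.
#' @param tol Bracket width at which golden-section refinement stops.
#' @return An object of class `offset_estimate`: list with `offset` (s),
#'   `loglik`, `model` (the [offset_objective()] fit at the optimum) and
#'   `grid` (data frame of the coarse search).
#' @export
estimate_offset <- function(gps, radar, origin, window = c(0, 120),
                            grid_step = 1, tol = 1e-3) {
  stopifnot(length(window) == 2, window[2] >= window[1])
  Ts <- seq(window[1], window[2], by = grid_step)
  ll <- vapply(Ts, function(T) {
    tryCatch(offset_objective(gps, radar, T, origin)$loglik,
             error = function(e) -Inf)
  }, 0)
  if (!any(is.finite(ll)))
    stop("no candidate offset yields at least 3 position pairs")
  if (diff(range(ll[is.finite(ll)])) < 1e-9)
    stop("flat offset objective: no synchronization signal in the data")
  best <- which.max(ll)  # which.max takes the first (smallest T) on ties
  lo <- max(window[1], Ts[best] - grid_step)
  hi <- min(window[2], Ts[best] + grid_step)
  # golden-section maximization on [lo, hi]
  gr <- (sqrt(5) - 1) / 2
  f <- function(T) tryCatch(offset_objective(gps, radar, T, origin)$loglik,
                            error = function(e) -Inf)
  a <- lo; b <- hi
  c1 <- b - gr * (b - a); c2 <- a + gr * (b - a)
  f1 <- f(c1); f2 <- f(c2)
  while (b - a > tol) {
    if (f1 >= f2) {           # ties move toward smaller T
      b <- c2; c2 <- c1; f2 <- f1
      c1 <- b - gr * (b - a); f1 <- f(c1)
    } else {
      a <- c1; c1 <- c2; f1 <- f2
      c2 <- a + gr * (b - a); f2 <- f(c2)
    }
  }
  opt <- (a + b) / 2
  mod <- offset_objective(gps, radar, opt, origin)
  structure(list(offset = opt, loglik = mod$loglik, model = mod,
                 grid = data.frame(T = Ts, loglik = ll)),
            class = "offset_estimate")
}

#' @export
print.offset_estimate <- function(x, ...) {
  cat(sprintf("Estimated clock offset: %.3f s (logLik %.2f, %d pairs)\n",
              x$offset, x$loglik, x$model$n_pairs))
  invisible(x)
}

#' Pair radar plots with GPS truth positions by timestamp
#'
#' Shifts radar plot times by the estimated offset into the GPS frame and
#' matches each plot to the linearly interpolated GPS position at its shifted
#' time. Plots falling outside the GPS track's time span are dropped and
#' counted.
#'
#' @inheritParams offset_objective
#' @param offset Estimated clock offset in seconds.
#' @return Data frame with columns `t` (shifted, GPS frame), `t_radar`
#'   (original radar time), `x`, `y` (radar plot), `gps_x`, `gps_y`,
#'   `gps_alt`, plus attribute `n_dropped`.
#' @export
pair_by_timestamp <- function(gps, radar, offset) {
  ts <- radar$t - offset
  keep <- ts >= min(gps$t) & ts <= max(gps$t)
  g <- gps_interpolate(gps, ts[keep])
  out <- data.frame(t = ts[keep], t_radar = radar$t[keep],
                    x = radar$x[keep], y = radar$y[keep],
                    gps_x = g$x, gps_y = g$y, gps_alt = g$alt)
  attr(out, "n_dropped") <- sum(!keep)
  out
}

#' Lay out scan opportunities and derive nondetections
#'
#' Expands timestamp-paired detections of one flight test into the full set
#' of radar scan opportunities. Opportunities are spaced every
#' `60 / scan_rate` seconds (about 2.67 s at 22.5 scans per minute) from the
#' first to the last detection. An opportunity with a paired detection within
#' half a scan interval is a detection; every other opportunity is a
#' nondetection. The truth position of every opportunity is the GPS
#' interpolant at the opportunity time (`truth = "gps"`, default) or, for
#' sensitivity analysis, the interpolant between the bracketing radar
#' detections (`truth = "radar"`).
#'
#' Range, bearing, course, tortuosity and orientation class are computed
#' from the opportunity truth positions; tortuosity is undefined (`NA`) at
#' the first and last opportunity.
#'
#' @param gps GPS track data frame (`t`, `x`, `y`, `alt`).
#' @param pairs Output of [pair_by_timestamp()] for the same flight.
#' @param origin A [radar_origin()].
#' @param params A [radar_parameters()].
#' @param track_id Identifier stored with the observations.
#' @param truth Source of nondetection truth positions.
#' @param orientation_reference Passed to [orientation_class()].
#' @return Data frame of paired observations: `track_id`, `t`, `x`, `y`,
#'   `alt`, `detected`, `range`, `bearing`, `course`, `tortuosity`,
#'   `orientation`, `in_clutter` (`NA`, filled by the clutter stage).
#' @export
interpolate_nondetections <- function(gps, pairs, origin,
                                      params = radar_parameters(),
                                      track_id = 1L,
                                      truth = c("gps", "radar"),
                                      orientation_reference = "radial") {
  truth <- match.arg(truth)
  if (nrow(pairs) == 0) {
    return(data.frame(track_id = integer(), t = numeric(), x = numeric(),
                      y = numeric(), alt = numeric(), detected = logical(),
                      range = numeric(), bearing = numeric(),
                      course = numeric(), tortuosity = numeric(),
                      orientation = character(), in_clutter = logical()))
  }
  dt <- scan_interval(params)
  pt <- sort(pairs$t)
  times <- seq(pt[1], pt[length(pt)] + dt / 4, by = dt)
  # an opportunity is a detection when a paired plot lies within half a scan
  # interval of its nominal time
  detected <- vapply(times, function(tt) any(abs(pt - tt) <= dt / 2), TRUE)
  if (truth == "gps") {
    pos <- gps_interpolate(gps, times)
  } else {
    ord <- order(pairs$t)
    pos <- data.frame(
      t = times,
      x = approx(pairs$t[ord], pairs$x[ord], xout = times, rule = 2)$y,
      y = approx(pairs$t[ord], pairs$y[ord], xout = times, rule = 2)$y,
      alt = NA_real_
    )
  }
  rb <- range_bearing(origin, pos$x, pos$y)
  crs <- track_course(pos$x, pos$y)
  tor <- track_tortuosity(pos$x, pos$y)
  ori <- orientation_class(crs, rb$bearing, reference = orientation_reference)
  data.frame(track_id = track_id, t = times, x = pos$x, y = pos$y,
             alt = pos$alt, detected = detected, range = rb$range,
             bearing = rb$bearing, course = crs, tortuosity = tor,
             orientation = ori, in_clutter = NA)
}
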