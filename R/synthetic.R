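#' Configure a synthetic calibration-flight scenario
#'
#' Defines a UAV radar-calibration campaign with known ground truth: waypoint
#' flights at cruise altitude sampled at the GPS rate, a scanning radar that
#' detects the target with logistic probability in range and covariates, an
#' unknown clock offset per flight, per-track random detectability, and
#' planar position noise on radar plots. The generative model is exactly the
#' analysis model, so parameter recovery is well posed; optional toggles
#' introduce controlled model violations for robustness checks.
#'
#' The default scenario mirrors a realistic campaign at a coastal wind-power
#' plant: seven range-calibration flights flown radially out to 3,100 m and
#' back at 70 m above ground (around wind-turbine hub height), six clutter
#' flights repeatedly crossing terrain patches in line-of-sight of the radar
#' at 400-2,400 m, a 22.5 scans/min radar, 1 Hz GPS sampling, 20 m/s cruise
#' speed, clock offsets drawn uniformly from 0-120 s, 5 m isotropic radar
#' position noise, and detection truth `logit(Pd) = 3.136 - 0.00134 * range`
#' (true Pd = 0.5 at 2,340 m) with a clutter effect of -0.615 (a drop from
#' 0.51 to about 0.36 at the range where Pd is 0.51), an across-beam effect
#' of -0.3, a tortuosity effect of -1, and a track random-intercept SD
#' of 0.3.
#'
#' @param seed Integer seed; mandatory, every stochastic draw derives from it.
#' @param origin A [radar_origin()].
#' @param params A [radar_parameters()].
#' @param flights Optional list of flight definitions, each a list with
#'   `waypoints` (two-column matrix of planar metres) and `type`
#'   (`"DR"` range test or `"DC"` clutter test). `NULL` builds the default
#'   campaign.
#' @param speed Cruise speed in m/s.
#' @param alt_cruise Cruise altitude AGL in metres.
#' @param climb_rate Climb/descent rate for the take-off and landing ramps,
#'   m/s (the ramps exercise low-altitude screening).
#' @param gps_interval GPS sampling interval in seconds.
#' @param offsets Per-flight true clock offsets in seconds, or `NULL` to draw
#'   them uniformly from `offset_window`.
#' @param offset_window Range from which offsets are drawn.
#' @param beta0,beta_range,beta_clutter,beta_orientation,beta_tortuosity
#'   Detection-truth coefficients on the logit scale (`beta_range` per
#'   metre; `beta_orientation` applies to across-beam segments).
#' @param sigma_track SD of the per-track Gaussian random intercept.
#' @param noise_sd SD of the isotropic Gaussian radar position noise, metres.
#' @param terrain A [terrain_grid()], or `NULL` for the built-in rolling
#'   terrain.
#' @param clutter_mask Optional pre-computed `clutter_mask` (saves the
#'   viewshed computation when generating many replicates over the same
#'   terrain).
#' @param heavy_tail_noise If `TRUE`, radar position noise is t(3)-scaled
#'   instead of Gaussian (model-violation toggle).
#' @param range_power Power of range in the detection truth (1, or 4 for a
#'   radar-equation-scale violation with Pd still 0.5 at the same range).
#' @param beta_lowalt Additional logit penalty applied below
#'   `lowalt_threshold` m AGL (default 0 = off; model-violation toggle that
#'   makes the altitude screen recoverable).
#' @param lowalt_threshold Altitude below which `beta_lowalt` applies.
#' @param meander_amp Amplitude (m) of the deterministic cross-track meander
#'   superimposed on the planned flight line (0 disables); real UAV paths
#'   wander about the plan, which is what gives the tortuosity and beam
#'   orientation covariates their variation.
#' @param meander_wavelength Along-track wavelength of the meander, metres.
#' @return An object of class `scenario_config`.
#' @export
scenario_config <- function(seed,
                            origin = radar_origin(0, 0, antenna_height = 5),
                            params = radar_parameters(),
                            flights = NULL,
                            speed = 20, alt_cruise = 70, climb_rate = 5,
                            gps_interval = 1,
                            offsets = NULL, offset_window = c(0, 120),
                            beta0 = 3.136, beta_range = -0.00134,
                            beta_clutter = -0.615, beta_orientation = -0.3,
                            beta_tortuosity = -1, sigma_track = 0.3,
                            noise_sd = 5,
                            terrain = NULL, clutter_mask = NULL,
                            heavy_tail_noise = FALSE, range_power = 1,
                            beta_lowalt = 0, lowalt_threshold = 27,
                            meander_amp = 80, meander_wavelength = 500) {
  if (missing(seed)) stop("a seed is mandatory for scenario generation")
  stopifnot(speed > 0, gps_interval > 0, sigma_track >= 0, noise_sd >= 0,
            range_power %in% c(1, 4))
  structure(list(seed = as.integer(seed), origin = origin, params = params,
                 flights = flights, speed = speed, alt_cruise = alt_cruise,
                 climb_rate = climb_rate, gps_interval = gps_interval,
                 offsets = offsets, offset_window = offset_window,
                 beta0 = beta0, beta_range = beta_range,
                 beta_clutter = beta_clutter,
                 beta_orientation = beta_orientation,
                 beta_tortuosity = beta_tortuosity,
                 sigma_track = sigma_track, noise_sd = noise_sd,
                 terrain = terrain, clutter_mask = clutter_mask,
                 heavy_tail_noise = heavy_tail_noise,
                 range_power = range_power, beta_lowalt = beta_lowalt,
                 lowalt_threshold = lowalt_threshold,
                 meander_amp = meander_amp,
                 meander_wavelength = meander_wavelength),
            class = "scenario_config")
}

# default campaign: 7 radial range flights + 6 clutter flights. When a
# clutter mask is supplied, each clutter flight's bearing is chosen
# (deterministically) so its radial span crosses as much clutter as
# possible -- clutter tests are flown over known clutter areas on purpose.
default_flights <- function(mask = NULL, origin = NULL) {
  fl <- list()
  # range flights: out to 3,100 m and back along spread bearings
  bearings <- c(10, 60, 110, 160, 210, 260, 310)
  for (b in bearings * pi / 180) {
    u <- c(sin(b), cos(b))
    fl[[length(fl) + 1]] <- list(
      waypoints = rbind(150 * u, 3100 * u, 150 * u), type = "DR")
  }
  # clutter flights: repeated passes (3 out-and-backs) over mid-range spans
  spans <- list(c(400, 1100, 35), c(600, 1500, 85), c(900, 1800, 135),
                c(500, 1300, 185), c(800, 2000, 235), c(1200, 2400, 300))
  used <- numeric()
  for (s in spans) {
    b <- if (is.null(mask)) s[3] else
      best_clutter_bearing(mask, origin, s[1], s[2], exclude = used)
    used <- c(used, b)
    u <- c(sin(b * pi / 180), cos(b * pi / 180))
    leg <- rbind(s[1] * u, s[2] * u)
    fl[[length(fl) + 1]] <- list(
      waypoints = rbind(leg, leg[1, ], leg[2, ], leg[1, ]), type = "DC")
  }
  fl
}

# bearing (whole degrees, 5 deg grid) whose radial span r1..r2 crosses a
# clutter fraction nearest `target` -- the flight should sample both sides
# of the clutter boundary; deterministic given the mask
best_clutter_bearing <- function(mask, origin, r1, r2, exclude = numeric(),
                                 target = 0.45) {
  cand <- setdiff(seq(0, 355, by = 5), exclude)
  rr <- seq(r1, r2, by = mask$cell_size / 2)
  frac <- vapply(cand, function(b) {
    x <- origin$x + rr * sin(b * pi / 180)
    y <- origin$y + rr * cos(b * pi / 180)
    inside <- grid_inside(mask, x, y)
    if (!any(inside)) return(0)
    mean(in_clutter(mask, x[inside], y[inside]))
  }, 0)
  cand[which.min(abs(frac - target))]
}

#' Built-in rolling terrain for synthetic scenarios
#'
#' A smooth two-scale sinusoidal terrain over a square window centred on the
#' radar, producing a patchy viewshed: with the antenna a few metres above
#' local ground, hill faces toward the radar are in line-of-sight (clutter)
#' while lee sides and hollows are shadowed. Deterministic (no seed).
#'
#' @param half_extent Half-width of the square window in metres.
#' @param cell_size Raster cell size in metres.
#' @return A [terrain_grid()].
#' @export
default_terrain <- function(half_extent = 3500, cell_size = 100) {
  n <- ceiling(2 * half_extent / cell_size)
  cx <- -half_extent + (seq_len(n) - 0.5) * cell_size
  cy_north_first <- rev(cx)
  z <- outer(cy_north_first, cx, function(y, x)
    12 * sin(2 * pi * x / 1700) * cos(2 * pi * y / 1300) +
      7 * sin(2 * pi * (x + 400) / 900) * sin(2 * pi * (y - 250) / 1100) +
      3 * cos(2 * pi * (x - y) / 2300))
  terrain_grid(-half_extent, -half_extent, cell_size, z)
}

#' Simulate one UAV calibration flight
#'
#' Constant-speed piecewise-linear trajectory through the flight's waypoints,
#' sampled at the GPS interval, with linear altitude ramps at take-off and
#' landing (climb at `climb_rate` until cruise altitude).
#'
#' @param config A [scenario_config()].
#' @param flight_index Which flight of `config$flights` to generate.
#' @param t0 Start time (epoch seconds) of the flight.
#' @return A GPS track data frame: `track_id`, `t`, `x`, `y`, `alt`.
#' @export
simulate_flight <- function(config, flight_index, t0 = 0) {
  if (is.null(config$flights)) config$flights <- default_flights()
  fl <- config$flights[[flight_index]]
  wp <- fl$waypoints
  stopifnot(nrow(wp) >= 2)
  seg <- sqrt(rowSums((wp[-1, , drop = FALSE] - wp[-nrow(wp), , drop = FALSE])^2))
  if (any(seg == 0)) stop("coincident consecutive waypoints")
  cum <- c(0, cumsum(seg))
  total_t <- cum[length(cum)] / config$speed
  tt <- seq(0, total_t, by = config$gps_interval)
  if (total_t - tt[length(tt)] > 1e-6) tt <- c(tt, total_t)
  dist <- tt * config$speed
  x <- approx(cum, wp[, 1], xout = dist)$y
  y <- approx(cum, wp[, 2], xout = dist)$y
  # deterministic cross-track meander: real UAV paths wander about the
  # planned line, which is what makes tortuosity and beam orientation vary
  A <- config$meander_amp %||% 0
  if (A > 0) {
    L <- config$meander_wavelength
    n <- length(x)
    txv <- c(x[2] - x[1], x[3:n] - x[1:(n - 2)], x[n] - x[n - 1])
    tyv <- c(y[2] - y[1], y[3:n] - y[1:(n - 2)], y[n] - y[n - 1])
    nrm <- sqrt(txv^2 + tyv^2)
    nrm[nrm == 0] <- 1
    # taper to zero near the endpoints so take-off/landing stay on plan
    off <- A * sin(2 * pi * dist / L) *
      pmin(1, dist / L, (dist[length(dist)] - dist) / L)
    x <- x + off * (-tyv / nrm)
    y <- y + off * (txv / nrm)
  }
  alt <- pmin(config$alt_cruise,
              pmin(tt, total_t - tt) * config$climb_rate)
  alt <- pmax(alt, 0)
  data.frame(track_id = flight_index, t = t0 + tt, x = x, y = y, alt = alt)
}

#' Simulate the radar's view of one flight
#'
#' Lays out scan opportunities at the radar scan interval over the flight,
#' evaluates the true detection probability at each opportunity from the
#' configured logistic truth (range, clutter membership at the
#' ground-projected position, beam orientation, tortuosity, the track's
#' random intercept, and any low-altitude penalty), draws Bernoulli
#' detections, and emits detected plots with isotropic position noise and
#' timestamps shifted by the flight's true clock offset. Called by
#' [generate_scenario()]; draws from the current RNG state.
#'
#' @param config A [scenario_config()].
#' @param gps A track from [simulate_flight()].
#' @param u Random intercept of this track (logit scale).
#' @param offset True clock offset of this flight in seconds.
#' @param mask A `clutter_mask` (or `NULL` for no clutter anywhere).
#' @return List with `radar` (detected plots: `track_id`, `t`, `x`, `y`) and
#'   `truth` (every opportunity with covariates, true `pd` and the draw).
#' @export
simulate_radar <- function(config, gps, u, offset, mask = NULL) {
  dt <- scan_interval(config$params)
  if (diff(range(gps$t)) <= dt) stop("flight shorter than one scan interval")
  times <- seq(min(gps$t), max(gps$t), by = dt)
  pos <- gps_interpolate(gps, times)
  rb <- range_bearing(config$origin, pos$x, pos$y)
  crs <- track_course(pos$x, pos$y)
  tor <- track_tortuosity(pos$x, pos$y)
  tor_eff <- ifelse(is.na(tor), 0, tor)   # straight-flight assumption at ends
  ori <- orientation_class(crs, rb$bearing)
  across <- as.numeric(!is.na(ori) & ori == "across")
  clut <- if (is.null(mask)) rep(FALSE, length(times)) else {
    inside <- grid_inside(mask, pos$x, pos$y)
    cl <- rep(FALSE, length(times))
    cl[inside] <- in_clutter(mask, pos$x[inside], pos$y[inside])
    cl
  }
  r_term <- if (config$range_power == 1) config$beta_range * rb$range
            else config$beta_range * rb$range^4
  eta <- config$beta0 + r_term + config$beta_clutter * clut +
    config$beta_orientation * across + config$beta_tortuosity * tor_eff + u
  if (config$beta_lowalt != 0)
    eta <- eta + config$beta_lowalt * (pos$alt < config$lowalt_threshold)
  pd <- plogis(eta)
  det <- rbinom(length(pd), 1, pd) == 1
  nd <- sum(det)
  noise <- if (config$heavy_tail_noise)
    matrix(rt(2 * nd, df = 3) / sqrt(3), ncol = 2) * config$noise_sd
  else matrix(rnorm(2 * nd, sd = config$noise_sd), ncol = 2)
  radar <- data.frame(track_id = rep(gps$track_id[1], nd),
                      t = times[det] + offset,
                      x = pos$x[det] + noise[, 1],
                      y = pos$y[det] + noise[, 2])
  truth <- data.frame(track_id = gps$track_id[1], t = times,
                      x = pos$x, y = pos$y, alt = pos$alt,
                      range = rb$range, bearing = rb$bearing,
                      course = crs, tortuosity = tor,
                      orientation = ori, in_clutter = clut,
                      pd = pd, detected = det)
  list(radar = radar, truth = truth)
}

#' Generate a full synthetic calibration scenario
#'
#' Deterministic function of `(config, config$seed)`: draws per-track random
#' intercepts and clock offsets, simulates every flight and its radar view,
#' and returns the GPS tracks, radar plots and complete ground truth. The
#' caller's RNG state is restored afterwards.
#'
#' @param config A [scenario_config()].
#' @return List of class `scenario`: `gps` (all GPS fixes), `radar` (all
#'   detected plots), `mask` (the clutter mask used, possibly `NULL`),
#'   `terrain`, and `truth` (list: `observations` per-opportunity truth,
#'   `offsets`, `intercepts`, `config`).
#' @examples
#' scn <- generate_scenario(scenario_config(seed = 42))
#' head(scn$truth$observations)
#' @export
generate_scenario <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(config$seed)
  terrain <- config$terrain
  mask <- config$clutter_mask
  if (is.null(mask)) {
    if (is.null(terrain)) terrain <- default_terrain()
    mask <- build_clutter_mask(terrain, config$origin)
  }
  if (is.null(config$flights))
    config$flights <- default_flights(mask, config$origin)
  nf <- length(config$flights)
  u <- rnorm(nf, 0, config$sigma_track)
  offsets <- config$offsets
  if (is.null(offsets))
    offsets <- runif(nf, config$offset_window[1], config$offset_window[2])
  stopifnot(length(offsets) == nf)
  gps_all <- list(); radar_all <- list(); truth_all <- list()
  t0 <- 1000
  for (i in seq_len(nf)) {
    gps <- simulate_flight(config, i, t0 = t0)
    sim <- simulate_radar(config, gps, u[i], offsets[i], mask)
    gps_all[[i]] <- gps
    radar_all[[i]] <- sim$radar
    truth_all[[i]] <- sim$truth
    t0 <- max(gps$t) + 600   # flights well separated in time
  }
  structure(list(
    gps = do.call(rbind, gps_all),
    radar = do.call(rbind, radar_all),
    mask = mask, terrain = terrain,
    truth = list(observations = do.call(rbind, truth_all),
                 offsets = offsets, intercepts = u,
                 types = vapply(config$flights, `[[`, "", "type"),
                 config = config)),
    class = "scenario")
}

#' @export
print.scenario <- function(x, ...) {
  tt <- table(x$truth$types)
  cat(sprintf("Synthetic scenario: %d flights (%s); %d GPS fixes, %d radar plots\n",
              length(x$truth$offsets),
              paste(names(tt), tt, sep = "=", collapse = ", "),
              nrow(x$gps), nrow(x$radar)))
  cat(sprintf("  overall detection rate %.2f; offsets %.1f-%.1f s\n",
              mean(x$truth$observations$detected),
              min(x$truth$offsets), max(x$truth$offsets)))
  invisible(x)
}

#' Write a scenario to the package's standard file formats
#'
#' Emits `gps.csv`, `radar.csv`, `truth.json` and (when present)
#' `terrain.asc` / `clutter_mask.asc` under `dir`, using the same schemas the
#' pipeline readers consume, so synthetic and real data follow the same path.
#'
#' @param scenario A [generate_scenario()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_scenario <- function(scenario, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  gps <- scenario$gps
  write.csv(data.frame(test_id = gps$track_id, timestamp = gps$t,
                       x = gps$x, y = gps$y, alt_agl_m = gps$alt),
            file.path(dir, "gps.csv"), row.names = FALSE)
  rad <- scenario$radar
  write.csv(data.frame(track_id = rad$track_id, timestamp = rad$t,
                       x = rad$x, y = rad$y),
            file.path(dir, "radar.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(offsets = scenario$truth$offsets,
         intercepts = scenario$truth$intercepts,
         types = scenario$truth$types,
         seed = scenario$truth$config$seed),
    file.path(dir, "truth.json"), digits = NA, auto_unbox = FALSE)
  if (!is.null(scenario$terrain))
    write_asc(scenario$terrain, file.path(dir, "terrain.asc"))
  if (!is.null(scenario$mask))
    write_asc(scenario$mask, file.path(dir, "clutter_mask.asc"))
  invisible(dir)
}
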