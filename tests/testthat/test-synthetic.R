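test_that("flight simulation samples the planned line at the GPS rate", {
  cfg <- scenario_config(
    seed = 1, flights = list(list(waypoints = rbind(c(0, 0), c(0, 1000)),
                                  type = "DR")),
    speed = 20, gps_interval = 1, meander_amp = 0)
  g <- simulate_flight(cfg, 1)
  expect_equal(nrow(g), 51)               # 1000 m / 20 m/s = 50 s + endpoint
  expect_equal(g$x, rep(0, 51))
  expect_equal(g$y, seq(0, 1000, by = 20))
  # single-segment track: every course equal
  crs <- track_course(g$x, g$y)
  expect_true(all(crs[-1] == 0))
  # altitude ramps at 5 m/s to the 70 m cruise and back down
  expect_equal(g$alt[1], 0)
  expect_equal(g$alt[15], 70)
  expect_lt(g$alt[50], 70)
  expect_error(simulate_flight(
    scenario_config(seed = 1, flights = list(list(
      waypoints = rbind(c(0, 0), c(0, 0)), type = "DR"))), 1),
    "coincident")
})

test_that("an out-and-back flight reverses with tortuosity 1 at the turn", {
  cfg <- scenario_config(
    seed = 1, flights = list(list(
      waypoints = rbind(c(0, 100), c(0, 800), c(0, 100)), type = "DR")),
    meander_amp = 0)
  g <- simulate_flight(cfg, 1)
  s <- track_tortuosity(g$x, g$y)
  expect_equal(max(s, na.rm = TRUE), 1)
})

test_that("the meander makes tortuosity and orientation vary without leaving the plan", {
  cfg <- scenario_config(
    seed = 1, flights = list(list(
      waypoints = rbind(c(0, 150), c(0, 3000)), type = "DR")))
  g <- simulate_flight(cfg, 1)
  s <- track_tortuosity(g$x, g$y)
  expect_gt(stats::var(s, na.rm = TRUE), 0)
  expect_lt(max(abs(g$x)), cfg$meander_amp + 1)  # bounded cross-track offset
  expect_equal(g$x[1], 0)                         # endpoints stay on plan
  expect_equal(g$x[nrow(g)], 0, tolerance = 1e-9)
})

test_that("radar plots coincide with GPS truth when noise and offset are zero", {
  cfg <- tiny_config(seed = 9, offsets = c(0, 0, 0), noise_sd = 0)
  scn <- generate_scenario(cfg)
  g1 <- scn$gps[scn$gps$track_id == 1, ]
  r1 <- scn$radar[scn$radar$track_id == 1, ]
  truth <- gps_interpolate(g1, r1$t)
  expect_equal(r1$x, truth$x, tolerance = 1e-9)
  expect_equal(r1$y, truth$y, tolerance = 1e-9)
})

test_that("a hard range cut-off in the truth silences far detections", {
  cfg <- tiny_config(seed = 10, beta0 = 60, beta_range = -0.3)
  # Pd = 0.5 at 200 m, essentially 0 beyond ~250 m
  scn <- generate_scenario(cfg)
  obs <- scn$truth$observations
  expect_gt(sum(obs$detected), 0)
  expect_true(all(obs$range[obs$detected] < 280))
})

test_that("scenario generation is bit-reproducible from (config, seed)", {
  cfg <- tiny_config(seed = 77)
  s1 <- generate_scenario(cfg)
  s2 <- generate_scenario(cfg)
  expect_identical(s1$gps, s2$gps)
  expect_identical(s1$radar, s2$radar)
  expect_identical(s1$truth$offsets, s2$truth$offsets)
  s3 <- generate_scenario(tiny_config(seed = 78))
  expect_false(identical(s1$radar, s3$radar))
  # and the caller's RNG stream is left untouched
  set.seed(123); before <- runif(1)
  set.seed(123); invisible(generate_scenario(cfg)); after <- runif(1)
  expect_identical(before, after)
})

test_that("empirical detection rates match the configured truth (conservation)", {
  # long straight flight at constant range: fixed covariates, many scans
  r0 <- 1500
  fl <- list(list(waypoints = rbind(c(-4000, r0), c(4000, r0)), type = "DR"))
  cfg <- scenario_config(seed = 12, flights = fl, terrain = flat_grid(half = 4500),
                         clutter_mask = NULL, meander_amp = 0, sigma_track = 0,
                         offsets = 0, speed = 2, gps_interval = 4)
  cfg$clutter_mask <- build_clutter_mask(flat_grid(half = 4500, cell = 500),
                                         cfg$origin)
  scn <- generate_scenario(cfg)
  obs <- scn$truth$observations
  n <- nrow(obs)
  expect_gt(n, 1000)
  p_mean <- mean(obs$pd)
  expect_lt(abs(mean(obs$detected) - p_mean),
            3 * sqrt(p_mean * (1 - p_mean) / n))
})

test_that("per-track random intercepts shift detectability as configured", {
  cfg <- tiny_config(seed = 13, sigma_track = 2)
  scn <- generate_scenario(cfg)
  u <- scn$truth$intercepts
  obs <- scn$truth$observations
  # the generated pd is exactly the configured linear predictor plus u
  i <- which(obs$track_id == 2 & !is.na(obs$tortuosity) &
               !is.na(obs$orientation))[1]
  eta <- cfg$beta0 + cfg$beta_range * obs$range[i] +
    cfg$beta_clutter * obs$in_clutter[i] +
    cfg$beta_orientation * (obs$orientation[i] == "across") +
    cfg$beta_tortuosity * obs$tortuosity[i] + u[2]
  expect_equal(qlogis(obs$pd[i]), eta, tolerance = 1e-9)
})

test_that("scenario files round-trip through the standard formats", {
  cfg <- tiny_config(seed = 14)
  scn <- generate_scenario(cfg)
  dir <- tempfile("scn")
  write_scenario(scn, dir)
  gps <- read_gps(file.path(dir, "gps.csv"))
  rad <- read_radar(file.path(dir, "radar.csv"))
  expect_equal(nrow(gps), nrow(scn$gps))
  expect_equal(gps$x, scn$gps$x)
  expect_equal(rad$t, scn$radar$t)
  truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                               simplifyVector = TRUE)
  expect_equal(truth$offsets, scn$truth$offsets)
  m <- as_clutter_mask(read_asc(file.path(dir, "clutter_mask.asc")))
  expect_identical(m$z, scn$mask$z)
})
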