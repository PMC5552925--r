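origin <- radar_origin(0, 0, 5)

# a meandering flight with known radar view; returns gps, radar, truth offset
sync_fixture <- function(seed, offset, noise_sd = 5) {
  cfg <- tiny_config(seed, offsets = rep(offset, 3), noise_sd = noise_sd)
  scn <- generate_scenario(cfg)
  list(gps = scn$gps[scn$gps$track_id == 1, ],
       radar = scn$radar[scn$radar$track_id == 1, ],
       scn = scn, cfg = cfg)
}

test_that("offset objective is maximal at zero lag for coincident streams", {
  fx <- sync_fixture(seed = 3, offset = 0, noise_sd = 0)
  # with zero noise and zero offset the radar plots sit on the GPS track
  ll0 <- offset_objective(fx$gps, fx$radar, 0, origin)$loglik
  for (T in c(5, 20, 60, 110)) {
    expect_gt(ll0, offset_objective(fx$gps, fx$radar, T, origin)$loglik)
  }
})

test_that("offset objective prefers the injected offset over zero", {
  fx <- sync_fixture(seed = 4, offset = 46.2, noise_sd = 5)
  ll_true <- offset_objective(fx$gps, fx$radar, 46.2, origin)$loglik
  ll_zero <- offset_objective(fx$gps, fx$radar, 0, origin)$loglik
  expect_gt(ll_true, ll_zero)
})

test_that("offset estimation recovers an injected offset to half a second", {
  fx <- sync_fixture(seed = 5, offset = 46.2, noise_sd = 5)
  est <- estimate_offset(fx$gps, fx$radar, origin)
  expect_lt(abs(est$offset - 46.2), 0.5)
})

test_that("the objective's likelihood peak is within 10 s of truth across seeds", {
  hits <- vapply(1:12, function(s) {
    fx <- sync_fixture(seed = 100 + s, offset = 37.7, noise_sd = 5)
    ll <- function(T) offset_objective(fx$gps, fx$radar, T, origin)$loglik
    ll(37.7) >= max(ll(27.7), ll(47.7))
  }, TRUE)
  expect_gte(mean(hits), 0.95)
})

test_that("offset estimation signals degenerate inputs", {
  gps <- data.frame(t = 0:10, x = 0:10, y = 0, alt = 70)
  expect_error(offset_objective(gps, data.frame(t = c(1, 2), x = 1:2, y = 0),
                                0, origin),
               "fewer than 3")
  # a hovering target gives no synchronization signal at all: identical
  # positions fit perfectly at every candidate offset
  gps_hover <- data.frame(t = -200:300, x = 500, y = 500, alt = 70)
  radar_hover <- data.frame(t = seq(10, 150, by = 2.7), x = 500, y = 500)
  expect_error(estimate_offset(gps_hover, radar_hover, origin), "flat")
})

test_that("rank-deficient alignment designs fall back to intercept-only", {
  # stationary target seen at a constant offset position: the squared range
  # and bearing differences are constant columns, collinear with the
  # intercept
  gps <- data.frame(t = 0:100, x = 500, y = 500, alt = 70)
  radar <- data.frame(t = seq(5, 95, by = 3), x = 510, y = 500)
  m <- offset_objective(gps, radar, 0, origin)
  expect_true(m$rank_deficient)
  expect_true(is.finite(m$loglik))
})

test_that("timestamp pairing drops plots outside the GPS span and counts them", {
  gps <- data.frame(t = 100:200, x = (0:100) * 10, y = 0, alt = 70)
  radar <- data.frame(t = c(99.9, 100, 150.5, 200, 200.1),
                      x = c(0, 0, 505, 1000, 1000), y = 0)
  p <- pair_by_timestamp(gps, radar, offset = 0)
  expect_equal(nrow(p), 3)
  expect_equal(attr(p, "n_dropped"), 2)
  expect_equal(p$gps_x, c(0, 505, 1000))
})

test_that("pairing after offset estimation matches the simulator's bookkeeping", {
  fx <- sync_fixture(seed = 6, offset = 31.25, noise_sd = 3)
  est <- estimate_offset(fx$gps, fx$radar, origin)
  p <- pair_by_timestamp(fx$gps, fx$radar, est$offset)
  # every surviving pair's radar plot is within noise of its GPS truth
  d <- sqrt((p$x - p$gps_x)^2 + (p$y - p$gps_y)^2)
  expect_lt(stats::median(d), 5 * 3)
})

test_that("nondetection interpolation lays out the scan grid correctly", {
  params <- radar_parameters()         # 2.667 s interval
  dt <- scan_interval(params)
  gps <- data.frame(t = 0:60, x = (0:60) * 20, y = 1000, alt = 70)
  # detections at every scan time -> no nondetections
  full <- data.frame(t = seq(0, 32, by = dt))
  full$x <- full$t * 20; full$y <- 1000
  pairs <- pair_by_timestamp(gps, full, 0)
  obs <- interpolate_nondetections(gps, pairs, origin, params)
  expect_true(all(obs$detected))
  # two detections 8 s apart -> floor(8/dt) - 1 = 2 interior nondetections
  two <- data.frame(t = c(10, 18), x = c(200, 360), y = 1000)
  obs2 <- interpolate_nondetections(gps, pair_by_timestamp(gps, two, 0),
                                    origin, params)
  expect_equal(nrow(obs2), 4)
  expect_equal(sum(!obs2$detected), 2)
  expect_false(any(obs2$detected[2:3]))
  # opportunities are never closer than half the scan interval
  expect_true(all(diff(obs2$t) >= dt / 2))
  # truth positions are the GPS interpolants
  expect_equal(obs2$x, obs2$t * 20)
  # empty input -> empty output
  empty <- interpolate_nondetections(gps, pair_by_timestamp(
    gps, data.frame(t = numeric(), x = numeric(), y = numeric()), 0),
    origin, params)
  expect_equal(nrow(empty), 0)
})

test_that("detected plus nondetected equals the opportunity count", {
  fx <- sync_fixture(seed = 7, offset = 12.5)
  est <- estimate_offset(fx$gps, fx$radar, origin)
  p <- pair_by_timestamp(fx$gps, fx$radar, est$offset)
  obs <- interpolate_nondetections(fx$gps, p, origin)
  expect_equal(sum(obs$detected) + sum(!obs$detected), nrow(obs))
  expect_gt(sum(!obs$detected), 0)
})
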