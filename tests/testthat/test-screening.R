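test_that("segmented regression finds a constructed detection-rate step", {
  set.seed(41)
  n <- 2000
  alt <- runif(n, 0, 100)
  det <- rbinom(n, 1, ifelse(alt < 30, 0.1, 0.6))
  fit <- segmented_threshold(alt, det, side = "lower")
  expect_gt(fit$breakpoint, 28)
  expect_lt(fit$breakpoint, 32)
  expect_false(fit$degenerate)
  # and on the mirrored problem (high covariate = poor detection)
  tor <- 1 - alt / 100
  fit_u <- segmented_threshold(tor, det, side = "upper")
  expect_gt(fit_u$breakpoint, 0.68)
  expect_lt(fit_u$breakpoint, 0.72)
})

test_that("segmented regression equals an independent brute-force SSR scan", {
  set.seed(42)
  for (rep in 1:5) {
    n <- 800
    x <- runif(n, 0, 50)
    det <- rbinom(n, 1, plogis(-2 + 0.12 * x))
    nb <- sample(c(20, 50, 80), 1)
    fit <- segmented_threshold(x, det, side = "lower", bins = nb)
    # oracle: recompute the equal-count binning and scan every interior edge
    edges <- unique(quantile(x, seq(0, 1, length.out = nb + 1), names = FALSE))
    b <- findInterval(x, edges, rightmost.closed = TRUE, all.inside = TRUE)
    rate <- as.numeric(tapply(det, b, mean))
    ssr <- sapply(seq_len(length(rate) - 1), function(k) {
      lo <- rate[1:k]; hi <- rate[-(1:k)]
      sum((lo - mean(lo))^2) + sum((hi - mean(hi))^2)
    })
    expect_equal(fit$ssr_total, min(ssr), tolerance = 1e-12)
    expect_equal(fit$breakpoint, edges[which.min(ssr) + 1], tolerance = 1e-12)
  }
})

test_that("a constant detection rate is flagged degenerate", {
  set.seed(43)
  x <- runif(500)
  fit <- segmented_threshold(x, rep(1, 500), side = "lower")
  expect_true(fit$degenerate)
  expect_equal(fit$breakpoint, min(x))  # boundary: nothing screened out
  fit_u <- segmented_threshold(x, rep(0, 500), side = "upper")
  expect_true(fit_u$degenerate)
  expect_equal(fit_u$breakpoint, max(x))
})

test_that("segmented regression validates its inputs", {
  expect_error(segmented_threshold(1:10, rep(0:1, 5)), "at least")
  expect_error(segmented_threshold(rep(1, 100), rbinom(100, 1, 0.5)),
               "constant")
})

test_that("the deviance criterion agrees with SSR on clean step data", {
  set.seed(44)
  n <- 3000
  x <- runif(n, 0, 100)
  det <- rbinom(n, 1, ifelse(x < 40, 0.05, 0.7))
  f1 <- segmented_threshold(x, det, side = "lower", criterion = "ssr")
  f2 <- segmented_threshold(x, det, side = "lower", criterion = "deviance")
  expect_lt(abs(f1$breakpoint - f2$breakpoint), 5)
})

test_that("cumulative-SD diagnostics are emitted for inspection", {
  set.seed(45)
  x <- runif(1000, 0, 100)
  det <- rbinom(1000, 1, plogis((x - 30) / 10))
  fit <- segmented_threshold(x, det, side = "lower")
  d <- fit$diagnostics
  expect_true(all(c("mid", "n", "rate", "cum_sd") %in% names(d)))
  expect_equal(sum(d$n), 1000)
  expect_true(all(diff(d$mid) > 0))
})

test_that("exclusion rules count and drop exactly the flagged rows", {
  obs <- data.frame(alt = c(rep(10, 3), rep(70, 97)),
                    tortuosity = c(rep(0, 98), 0.9, 0.8))
  out <- apply_exclusions(obs, alt_min = 27, tort_max = 0.33)
  expect_equal(out$report$n_below_alt, 3)
  expect_equal(out$report$n_above_tort, 2)
  expect_equal(out$report$fraction, 0.05)  # disjoint rules: 5 of 100
  expect_equal(nrow(out$retained), 95)
  # disabled thresholds exclude nothing
  none <- apply_exclusions(obs, alt_min = -Inf, tort_max = 1)
  expect_equal(none$report$n_excluded, 0)
  # undefined tortuosity (track ends) and unknown altitude are retained
  obs2 <- data.frame(alt = c(NA, 70), tortuosity = c(0.1, NA))
  expect_equal(nrow(apply_exclusions(obs2, 27, 0.33)$retained), 2)
})

test_that("excluded fraction is monotone in both thresholds", {
  set.seed(46)
  obs <- data.frame(alt = runif(500, 0, 100), tortuosity = runif(500))
  fr_alt <- sapply(c(0, 20, 40, 60), function(a)
    apply_exclusions(obs, a, 1)$report$fraction)
  expect_true(all(diff(fr_alt) >= 0))
  fr_tort <- sapply(c(0.2, 0.4, 0.6, 0.8), function(tm)
    apply_exclusions(obs, -Inf, tm)$report$fraction)
  expect_true(all(diff(fr_tort) <= 0))
})
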