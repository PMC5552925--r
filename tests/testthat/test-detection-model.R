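# handcrafted fit objects let the derived quantities be tested closed-form
mock_fit <- function(beta0, beta_range, v = c(0.01, 1e-9),
                     extra = NULL, vextra = NULL) {
  cf <- c("(Intercept)" = beta0, range = beta_range, extra)
  V <- diag(c(v, vextra), length(cf))
  dimnames(V) <- list(names(cf), names(cf))
  covs <- c("range", if (!is.null(extra)) sub("across$", "", names(extra)))
  covs <- sub("^orientation$", "orientation", covs)
  structure(list(coefficients = cf, vcov = V, covariates = covs,
                 range_power = 1, sigma_track = 0,
                 reference = list(orientation = "along", tortuosity = 0,
                                  in_clutter = 0, range = 1000)),
            class = "detection_fit")
}

test_that("GLMM likelihood matches brute-force numerical integration", {
  # seeds cover both a positive fitted variance and a boundary (zero) fit
  for (s in 1:4) {
    d <- toy_glmm_data(s)
    fit <- fit_detection(d, covariates = "range", nAGQ = 25)
    expect_equal(as.numeric(logLik(fit)), glmm_loglik_oracle(fit, d),
                 tolerance = 1e-4)
  }
})

test_that("fitting recovers the generating coefficients on synthetic tracks", {
  set.seed(55)
  d <- do.call(rbind, lapply(1:7, function(i) {
    n <- 400
    r <- runif(n, 100, 3100)
    u <- rnorm(1, 0, 0.3)
    data.frame(track_id = i, range = r,
               detected = rbinom(n, 1, plogis(3.14 - 0.00134 * r + u)))
  }))
  fit <- fit_detection(d, covariates = "range")
  se <- sqrt(diag(fit$vcov))
  expect_lt(abs(coef(fit)[["range"]] - (-0.00134)), 3 * se[["range"]])
  expect_lt(abs(coef(fit)[["(Intercept)"]] - 3.14), 3 * se[["(Intercept)"]])
  expect_true(fit$converged)
  dr <- detection_range(fit)
  expect_lt(abs(dr$range_at_pd - 2340) / 2340, 0.1)
  expect_true(dr$ci_low <= dr$range_at_pd & dr$range_at_pd <= dr$ci_high)
})

test_that("detection range solves the logistic closed form", {
  fit <- mock_fit(2.34, -0.001)
  dr <- detection_range(fit, pd = 0.5)
  expect_equal(dr$range_at_pd, 2340)      # logit(0.5) = 0 -> -b0/b_range
  expect_equal(detection_range(mock_fit(0, -0.001))$range_at_pd, 0)
  # the delta-method SE matches the hand formula for the two-parameter case
  g <- c(-1 / -0.001, -2340 / -0.001)
  expect_equal(dr$se, sqrt(sum(g^2 * c(0.01, 1e-9))), tolerance = 1e-6)
  expect_error(detection_range(mock_fit(2, 0.001)), "non-negative")
})

test_that("detection range is equivariant under a change of range units", {
  fit_m <- mock_fit(2.34, -0.001, v = c(0.01, 1e-9))
  # same model with range measured in double-metres: slope halves, and the
  # returned range (in those units) must double when converted back
  fit_2m <- mock_fit(2.34, -0.0005, v = c(0.01, 1e-9 / 4))
  dr_m <- detection_range(fit_m)
  dr_2m <- detection_range(fit_2m)
  expect_equal(dr_2m$range_at_pd, 2 * dr_m$range_at_pd)
  expect_equal(dr_2m$se, 2 * dr_m$se, tolerance = 1e-12)
})

test_that("bootstrap and delta intervals agree to first order", {
  fit <- mock_fit(2.34, -0.001, v = c(0.04, 4e-9))
  d1 <- detection_range(fit, ci_method = "delta")
  d2 <- detection_range(fit, ci_method = "boot", nboot = 4000, seed = 9)
  expect_lt(abs(d1$ci_low - d2$ci_low) / d1$range_at_pd, 0.05)
  expect_lt(abs(d1$ci_high - d2$ci_high) / d1$range_at_pd, 0.05)
})

test_that("a zero clutter coefficient means zero reduction", {
  fit <- mock_fit(1.5, -0.001, extra = c(in_clutter = 0),
                  vextra = 1e-4)
  cc <- clutter_contrast(fit)
  expect_equal(cc$reduction, 0)
  expect_equal(cc$pd_inside, cc$pd_outside)
  expect_true(cc$reduction_ci[1] < 0 & cc$reduction_ci[2] > 0)
})

test_that("clutter contrast recovers a known probability drop", {
  # choose coefficients so Pd goes 0.51 -> 0.36 at the reference range
  b0 <- qlogis(0.51) + 0.001 * 1000
  bc <- qlogis(0.36) - qlogis(0.51)
  fit <- mock_fit(b0, -0.001, extra = c(in_clutter = bc), vextra = 1e-4)
  cc <- clutter_contrast(fit, at_range = 1000)
  expect_equal(cc$pd_outside, 0.51, tolerance = 1e-9)
  expect_equal(cc$pd_inside, 0.36, tolerance = 1e-9)
  expect_equal(cc$reduction, 1 - 0.36 / 0.51, tolerance = 1e-9)
})

test_that("blip/scan ratios count detections per 25-m bin", {
  obs <- data.frame(range = c(110, 115, 120, 124, 300),
                    detected = c(TRUE, TRUE, TRUE, FALSE, TRUE))
  bs <- blip_scan_ratio(obs)
  expect_equal(bs$pd[bs$bin_left == 100], 0.75)  # 3 of 4 in [100, 125)
  expect_equal(bs$pd[bs$bin_left == 300], 1)
  expect_equal(nrow(bs), 2)                      # empty bins omitted
  # all-detected input has pd 1 in every occupied bin
  all_det <- data.frame(range = runif(50, 0, 500), detected = TRUE)
  expect_true(all(blip_scan_ratio(all_det)$pd == 1))
})

test_that("pooled blip/scan ratio conserves total counts", {
  set.seed(66)
  obs <- data.frame(range = runif(2000, 0, 3000),
                    detected = rbinom(2000, 1, 0.6) == 1)
  bs <- blip_scan_ratio(obs)
  expect_equal(sum(bs$n_detections), sum(obs$detected))
  expect_equal(sum(bs$n_opportunities), nrow(obs))
  expect_equal(sum(bs$pd * bs$n_opportunities) / sum(bs$n_opportunities),
               mean(obs$detected))
})

test_that("crossing range reads the blip/scan curve like an analyst", {
  # never crosses -> beyond-data sentinel
  bs1 <- data.frame(bin_left = (0:9) * 25, bin_width = 25,
                    n_opportunities = 10, n_detections = 10, pd = 1)
  expect_identical(crossing_range(bs1), Inf)
  # monotone step 1 -> 0 at bin k: midpoint of bin k
  pd <- c(rep(1, 12), rep(0, 8))
  bs2 <- data.frame(bin_left = (0:19) * 25, bin_width = 25,
                    n_opportunities = 10, n_detections = 10 * pd, pd = pd)
  expect_equal(crossing_range(bs2), 12 * 25 + 12.5)
  # noisy logistic decay crossing 0.5 at 2,000 m: within 2 bins
  set.seed(67)
  r <- seq(12.5, 4000, by = 25)
  pdtrue <- plogis((2000 - r) / 300)
  k <- rbinom(length(r), 40, pdtrue)
  bs3 <- data.frame(bin_left = r - 12.5, bin_width = 25,
                    n_opportunities = 40, n_detections = k, pd = k / 40)
  expect_lte(abs(crossing_range(bs3) - 2000), 2 * 25 + 12.5)
})

test_that("crossing range and model range agree on large synthetic samples", {
  set.seed(68)
  n <- 12000
  d <- data.frame(track_id = rep(1:8, each = n / 8),
                  range = runif(n, 100, 3500))
  u <- rnorm(8, 0, 0.2)[d$track_id]
  d$detected <- rbinom(n, 1, plogis(3.136 - 0.00134 * d$range + u)) == 1
  fit <- fit_detection(d, covariates = "range")
  dr <- detection_range(fit)
  cr <- crossing_range(blip_scan_ratio(d))
  expect_lte(abs(cr - dr$range_at_pd), 2 * 25)
})

test_that("model object methods behave like standard fitted models", {
  d <- toy_glmm_data(70, sig_true = 0.5, n = 60, k = 4)
  fit <- fit_detection(d, covariates = "range")
  expect_s3_class(fit, "detection_fit")
  expect_named(coef(fit), c("(Intercept)", "range"))
  expect_equal(dim(vcov(fit)), c(2, 2))
  expect_output(print(fit), "random-intercept")
  expect_output(print(summary(fit)), "Std. Error")
  p <- predict(fit, data.frame(range = c(0, 2000)))
  expect_true(all(p >= 0 & p <= 1) && p[1] > p[2])
  pl <- predict(fit, data.frame(range = 1000), type = "link", se.fit = TRUE)
  expect_equal(plogis(pl$fit), predict(fit, data.frame(range = 1000)))
  expect_length(residuals(fit), fit$n_obs)
  sim <- simulate(fit, nsim = 2, seed = 1)
  expect_equal(dim(sim), c(fit$n_obs, 2))
})

test_that("degenerate model inputs are signalled honestly", {
  d <- toy_glmm_data(71, n = 40, k = 3)
  d$detected <- 1
  expect_error(fit_detection(d, covariates = "range"), "nondetection")
  d2 <- toy_glmm_data(72, n = 40, k = 1)
  expect_warning(fit1 <- fit_detection(d2, covariates = "range"),
                 "single track")
  expect_equal(fit1$sigma_track, 0)
  d3 <- toy_glmm_data(73, n = 40, k = 3)
  d3$range <- 1000
  expect_warning(expect_error(fit_detection(d3, covariates = "range"),
                              "no non-constant"),
                 "constant covariate")
})
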