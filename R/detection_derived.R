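#' Detection range at a threshold probability
#'
#' Solves the fitted logistic detection curve for the range at which the
#' population-level detection probability equals `pd`, at reference covariate
#' levels (orientation `"along"`, tortuosity 0, outside clutter unless
#' overridden via `at`): `R = (logit(pd) - beta0 - c) / beta_range`, where
#' `c` collects the non-range covariate contributions. The default threshold
#' of 0.5 reflects a track-while-scan tracker's tolerance: a track can be
#' maintained when every other detection is lost, so the Pd = 0.5 range acts
#' as the maximum range at which tracking remains reliable.
#'
#' Confidence intervals use the delta method on `R` with the fixed-effect
#' Wald covariance, or a seeded parametric bootstrap on the fixed effects
#' (`ci_method = "boot"`, 1,000 multivariate-normal draws).
#'
#' @param fit A [fit_detection()] object whose range coefficient is negative.
#' @param pd Threshold detection probability (default 0.5).
#' @param level Confidence level (default 0.95).
#' @param at Named list overriding reference covariate values (e.g.
#'   `list(orientation = "across")`).
#' @param ci_method `"delta"` or `"boot"`.
#' @param nboot,seed Bootstrap draws and seed (`ci_method = "boot"`).
#' @return An object of class `detection_range`: list with `range_at_pd`,
#'   `ci_low`, `ci_high`, `se`, `pd_threshold`.
#' @examples
#' fit <- structure(list(
#'   coefficients = c("(Intercept)" = 2.34, range = -0.001),
#'   vcov = diag(c(0.01, 1e-9)), covariates = "range", range_power = 1,
#'   reference = list(orientation = "along", tortuosity = 0, in_clutter = 0)),
#'   class = "detection_fit")
#' detection_range(fit)  # 2,340 m
#' @export
detection_range <- function(fit, pd = 0.5, level = 0.95, at = list(),
                            ci_method = c("delta", "boot"), nboot = 1000,
                            seed = 1) {
  ci_method <- match.arg(ci_method)
  stopifnot(inherits(fit, "detection_fit"), pd > 0, pd < 1)
  if (fit$range_power != 1)
    stop("detection_range requires a linear-range fit (range_power = 1)")
  beta <- fit$coefficients
  if (!"range" %in% names(beta)) stop("fit has no range coefficient")
  if (beta[["range"]] >= 0)
    stop("range coefficient is non-negative: no finite detection range")
  ref <- fit$reference
  ref[names(at)] <- at
  ref$range <- 0
  refdf <- as.data.frame(ref, stringsAsFactors = FALSE)
  solve_range <- function(b) {
    lp0 <- fit_linpred(fit, refdf, beta = b)$eta
    (qlogis(pd) - lp0) / b[["range"]]
  }
  R <- solve_range(beta)
  z <- qnorm(1 - (1 - level) / 2)
  if (ci_method == "delta") {
    # exact gradient: R = (logit(pd) - x'b_-r)/b_r, so dR/db_k = -x_k/b_r
    # for non-range terms and dR/db_r = -R/b_r
    X0 <- fit_linpred(fit, refdf, beta = beta)$X
    g <- -drop(X0) / beta[["range"]]
    g[names(beta) == "range"] <- -R / beta[["range"]]
    se <- sqrt(drop(t(g) %*% fit$vcov %*% g))
    lo <- R - z * se; hi <- R + z * se
  } else {
    draws <- mvn_draws(nboot, beta, fit$vcov, seed)
    Rb <- apply(draws, 1, function(b) {
      names(b) <- names(beta)
      if (b[["range"]] >= 0) NA_real_ else solve_range(b)
    })
    qs <- quantile(Rb, c((1 - level) / 2, 1 - (1 - level) / 2), na.rm = TRUE)
    se <- sd(Rb, na.rm = TRUE)
    lo <- qs[[1]]; hi <- qs[[2]]
  }
  structure(list(range_at_pd = unname(R), ci_low = max(0, lo),
                 ci_high = max(0, hi), se = unname(se), pd_threshold = pd,
                 level = level, ci_method = ci_method),
            class = "detection_range")
}

#' @export
print.detection_range <- function(x, ...) {
  cat(sprintf("Detection range at Pd = %.2f: %.0f m (%.0f - %.0f m, %d%% CI, %s)\n",
              x$pd_threshold, x$range_at_pd, x$ci_low, x$ci_high,
              round(100 * x$level), x$ci_method))
  invisible(x)
}

# central finite-difference gradient of f at named vector b
num_gradient <- function(f, b) {
  g <- numeric(length(b))
  for (i in seq_along(b)) {
    h <- max(1e-6, abs(b[i]) * 1e-6)
    bp <- b; bp[i] <- b[i] + h
    bm <- b; bm[i] <- b[i] - h
    g[i] <- (f(bp) - f(bm)) / (2 * h)
  }
  g
}

# multivariate normal draws via Cholesky (no external dependency)
mvn_draws <- function(n, mu, Sigma, seed) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  L <- chol(Sigma + diag(1e-12, nrow(Sigma)))
  Z <- matrix(rnorm(n * length(mu)), n)
  sweep(Z %*% L, 2, mu, `+`)
}

#' Clutter effect on detection probability
#'
#' Detection probability inside versus outside ground-clutter areas at
#' reference covariate levels and a reference range (default: the mean
#' observed range of the fitted data), and the proportional reduction
#' `1 - pd_inside / pd_outside`. Point-estimate intervals are delta-method
#' intervals on the logit scale (back-transformed); the reduction interval is
#' a delta-method interval on the log detection-probability ratio.
#'
#' @param fit A [fit_detection()] object including an `in_clutter` covariate.
#' @param at_range Reference range in metres (default: mean observed range).
#' @param level Confidence level.
#' @return An object of class `clutter_contrast`: list with `pd_outside`,
#'   `pd_inside` (each with CI), `reduction`, `reduction_ci`.
#' @export
clutter_contrast <- function(fit, at_range = NULL, level = 0.95) {
  stopifnot(inherits(fit, "detection_fit"))
  beta <- fit$coefficients
  if (!"in_clutter" %in% fit$covariates)
    stop("fit does not include an in_clutter covariate")
  if (is.null(at_range)) at_range <- fit$reference$range
  nd <- function(clut) {
    d <- list(in_clutter = clut)
    if ("range" %in% fit$covariates) d$range <- at_range
    d
  }
  z <- qnorm(1 - (1 - level) / 2)
  eta_ci <- function(clut) {
    lp <- fit_linpred(fit, nd(clut))
    se <- sqrt(drop(lp$X %*% fit$vcov %*% t(lp$X)))
    c(est = plogis(lp$eta), lo = plogis(lp$eta - z * se),
      hi = plogis(lp$eta + z * se))
  }
  out <- eta_ci(0)
  inn <- eta_ci(1)
  log_ratio <- function(b) {
    e_in <- fit_linpred(fit, nd(1), beta = b)$eta
    e_out <- fit_linpred(fit, nd(0), beta = b)$eta
    log(plogis(e_in)) - log(plogis(e_out))
  }
  theta <- log_ratio(beta)
  g <- num_gradient(log_ratio, beta)
  se_t <- sqrt(drop(t(g) %*% fit$vcov %*% g))
  red_ci <- sort(1 - exp(theta + c(-1, 1) * z * se_t))
  structure(list(pd_outside = out[["est"]], pd_outside_ci = unname(out[2:3]),
                 pd_inside = inn[["est"]], pd_inside_ci = unname(inn[2:3]),
                 reduction = 1 - exp(theta), reduction_ci = red_ci,
                 at_range = at_range, level = level),
            class = "clutter_contrast")
}

#' @export
print.clutter_contrast <- function(x, ...) {
  cat(sprintf("Detection probability at %.0f m: %.2f (%.2f-%.2f) outside vs %.2f (%.2f-%.2f) inside clutter\n",
              x$at_range, x$pd_outside, x$pd_outside_ci[1], x$pd_outside_ci[2],
              x$pd_inside, x$pd_inside_ci[1], x$pd_inside_ci[2]))
  cat(sprintf("Reduction inside clutter: %.0f%% (%.0f-%.0f%% CI)\n",
              100 * x$reduction, 100 * x$reduction_ci[1],
              100 * x$reduction_ci[2]))
  invisible(x)
}

#' Blip/scan ratio in range bins
#'
#' The traditional empirical detection-probability estimate: detections
#' divided by detection opportunities, counted in left-closed right-open
#' range bins of `bin_width` metres from zero. Empty bins are omitted.
#'
#' @param observations Data frame with columns `range` (m) and `detected`.
#' @param bin_width Bin width in metres (default 25).
#' @return A data frame of class `blip_scan` with columns `bin_left`,
#'   `bin_width`, `n_opportunities`, `n_detections`, `pd`.
#' @export
blip_scan_ratio <- function(observations, bin_width = 25) {
  stopifnot(bin_width > 0)
  r <- observations$range
  det <- as.numeric(observations$detected)
  ok <- is.finite(r)
  r <- r[ok]; det <- det[ok]
  bin <- floor(r / bin_width)
  n <- tapply(det, bin, length)
  k <- tapply(det, bin, sum)
  lev <- as.numeric(names(n))
  ord <- order(lev)
  out <- data.frame(bin_left = lev[ord] * bin_width, bin_width = bin_width,
                    n_opportunities = as.numeric(n[ord]),
                    n_detections = as.numeric(k[ord]),
                    pd = as.numeric(k[ord] / n[ord]))
  class(out) <- c("blip_scan", "data.frame")
  out
}

#' Detection-range crossing of a blip/scan curve
#'
#' Automated stand-in for reading the detection range off a plotted
#' blip/scan curve: the range at which a centred moving average (default 5
#' occupied bins) of the per-bin detection ratio first falls below the
#' threshold and stays below it for `persist` consecutive bins. Returns the
#' midpoint of that first bin, or `Inf` when the curve never crosses within
#' the data ("beyond data").
#'
#' @param table A [blip_scan_ratio()] table.
#' @param pd Threshold detection probability.
#' @param window Moving-average window in occupied bins (odd).
#' @param persist Number of consecutive below-threshold bins required.
#' @return Range in metres (midpoint of the crossing bin), or `Inf`.
#' @export
crossing_range <- function(table, pd = 0.5, window = 5, persist = 3) {
  stopifnot(nrow(table) > 0, window %% 2 == 1)
  p <- table$pd
  nb <- length(p)
  half <- (window - 1) / 2
  ma <- vapply(seq_len(nb), function(i) {
    idx <- max(1, i - half):min(nb, i + half)
    mean(p[idx])
  }, 0)
  below <- ma < pd
  run <- rle(below)
  ends <- cumsum(run$lengths)
  starts <- ends - run$lengths + 1
  hit <- which(run$values & (run$lengths >= persist | ends == nb))
  if (length(hit) == 0) return(Inf)
  i <- starts[hit[1]]
  table$bin_left[i] + table$bin_width[i] / 2
}
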