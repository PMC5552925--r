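#' Fit a binomial random-intercept detection model
#'
#' Models per-scan detection (detections versus derived nondetections) as a
#' logistic function of covariates, with a Gaussian random intercept over
#' tracks to absorb inter-track differences in detectability:
#' `logit(Pd) = beta0 + X beta + u_track`, `u_track ~ N(0, sigma_track^2)`.
#' Fitting is by maximum likelihood with adaptive Gauss-Hermite quadrature
#' (default 15 nodes) via [lme4::glmer()]; fixed-effect covariances are Wald
#' covariances from the observed information.
#'
#' The range covariate enters linearly on the logit scale, in metres
#' (internally rescaled to kilometres for numerical stability and converted
#' back, so reported coefficients are per metre). `range_power = 4` replaces
#' range by `range^4` (rescaled likewise) for a radar-equation-scale
#' sensitivity analysis. Orientation is a factor with reference level
#' `"along"`; `in_clutter` is 0/1; tortuosity is the per-observation turn
#' statistic in `[0, 1]`. Rows with missing values in the used covariates are
#' dropped.
#'
#' @param data Data frame of paired observations with columns `detected`,
#'   `track_id`, and the requested covariates (`range`, `in_clutter`,
#'   `orientation`, `tortuosity`).
#' @param covariates Character vector naming the fixed-effect covariates.
#' @param nAGQ Number of adaptive Gauss-Hermite quadrature nodes.
#' @param range_power 1 (default, linear range) or 4.
#' @param control Optional [lme4::glmerControl()].
#' @return An object of class `detection_fit` with components
#'   `coefficients` (logit scale; range per metre), `vcov`, `sigma_track`,
#'   `n_obs`, `n_tracks`, `converged`, `reference` (covariate reference
#'   levels used for derived quantities), `data` (the model frame used) and
#'   `model` (the underlying [lme4::glmer()] fit, or a [stats::glm()] fit
#'   when only one track is supplied).
#' @seealso [detection_range()], [clutter_contrast()], [blip_scan_ratio()]
#' @examples
#' \donttest{
#' scn <- generate_scenario(scenario_config(seed = 1))
#' obs <- scn$truth$observations
#' fit <- fit_detection(obs[!obs$in_clutter, ],
#'                      covariates = c("range", "orientation", "tortuosity"))
#' summary(fit)
#' detection_range(fit, pd = 0.5)
#' }
#' @export
fit_detection <- function(data,
                          covariates = c("range", "orientation", "tortuosity"),
                          nAGQ = 15, range_power = 1, control = NULL) {
  stopifnot(all(c("detected", "track_id") %in% names(data)),
            all(covariates %in% names(data)),
            range_power %in% c(1, 4))
  df <- data.frame(detected = as.integer(data$detected),
                   track_id = factor(data$track_id))
  scale_div <- 1
  for (cv in covariates) {
    v <- data[[cv]]
    if (cv == "range") {
      # rescale so the optimizer sees O(1) covariates; report per metre
      scale_div <- 1000^range_power
      df$range <- v^range_power / scale_div
    } else if (cv == "orientation") {
      df$orientation <- factor(v, levels = c("along", "across"))
    } else if (cv == "in_clutter") {
      df$in_clutter <- as.numeric(v)
    } else {
      df[[cv]] <- as.numeric(v)
    }
  }
  df <- df[stats::complete.cases(df), , drop = FALSE]
  if (nrow(df) == 0) stop("no complete observations to fit")
  # covariates without variation cannot enter the model
  constant <- vapply(covariates, function(cv) {
    v <- df[[cv]]
    length(unique(if (is.factor(v)) droplevels(v) else v)) < 2
  }, TRUE)
  if (any(constant)) {
    warning("dropping constant covariate(s): ",
            paste(covariates[constant], collapse = ", "))
    covariates <- covariates[!constant]
    if (length(covariates) == 0) stop("no non-constant covariates left")
  }
  if (sum(df$detected) == 0 || sum(df$detected) == nrow(df))
    stop("need at least one detection and one nondetection")
  n_tracks <- nlevels(droplevels(df$track_id))
  rhs <- paste(covariates, collapse = " + ")

  if (n_tracks < 2) {
    warning("single track: random intercept pinned to 0 (plain GLM fit)")
    model <- stats::glm(stats::as.formula(paste("detected ~", rhs)),
                        family = stats::binomial(), data = df)
    beta <- coef(model)
    V <- vcov(model)
    sigma_track <- 0
    converged <- model$converged
  } else {
    fml <- stats::as.formula(paste("detected ~", rhs, "+ (1 | track_id)"))
    if (is.null(control))
      control <- lme4::glmerControl(check.conv.singular = "ignore")
    model <- lme4::glmer(fml, data = df, family = stats::binomial(),
                         nAGQ = nAGQ, control = control)
    beta <- lme4::fixef(model)
    V <- as.matrix(vcov(model))
    sigma_track <- sqrt(unname(lme4::VarCorr(model)$track_id[1]))
    msgs <- model@optinfo$conv$lme4$messages
    converged <- model@optinfo$conv$opt == 0 && is.null(msgs)
    if (!is.null(msgs)) warning("glmer convergence: ",
                                paste(msgs, collapse = "; "))
  }
  # undo the internal range rescaling (exact linear reparametrization)
  if ("range" %in% covariates) {
    k <- grep("^range$", names(beta))
    beta[k] <- beta[k] / scale_div
    V[k, ] <- V[k, ] / scale_div
    V[, k] <- V[, k] / scale_div
  }
  dimnames(V) <- list(names(beta), names(beta))
  # complete-separation heuristic: absurd logit-scale magnitudes
  if (any(abs(beta) > 1e3) || any(!is.finite(diag(V)))) {
    warning("possible complete separation: coefficients or SEs degenerate")
    converged <- FALSE
  }
  reference <- list(orientation = "along", tortuosity = 0, in_clutter = 0,
                    range = if ("range" %in% names(data))
                      mean(data$range, na.rm = TRUE) else NA_real_)
  structure(list(coefficients = beta, vcov = V, sigma_track = sigma_track,
                 n_obs = nrow(df), n_tracks = n_tracks, converged = converged,
                 covariates = covariates, range_power = range_power,
                 reference = reference, data = df, model = model,
                 call = match.call()),
            class = "detection_fit")
}

# linear predictor at new covariate values, using reference levels for
# anything not supplied
fit_linpred <- function(object, newdata, beta = object$coefficients) {
  n <- if (is.data.frame(newdata)) max(1L, nrow(newdata))
       else if (length(newdata)) max(lengths(newdata)) else 1L
  X <- matrix(0, n, length(beta), dimnames = list(NULL, names(beta)))
  X[, "(Intercept)"] <- 1
  ref <- object$reference
  getv <- function(name, default) {
    v <- if (!is.null(newdata[[name]])) newdata[[name]] else default
    rep_len(v, n)
  }
  for (cv in object$covariates) {
    if (cv == "range") {
      X[, "range"] <- getv("range", ref$range)^object$range_power
    } else if (cv == "orientation") {
      o <- getv("orientation", ref$orientation)
      X[, "orientationacross"] <- as.numeric(o == "across")
    } else if (cv == "in_clutter") {
      X[, "in_clutter"] <- as.numeric(getv("in_clutter", ref$in_clutter))
    } else {
      X[, cv] <- getv(cv, ref[[cv]] %||% 0)
    }
  }
  list(X = X, eta = drop(X %*% beta))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.detection_fit <- function(x, ...) {
  cat("Binomial random-intercept detection model\n")
  cat(sprintf("  %d observations, %d tracks (%d detections)\n",
              x$n_obs, x$n_tracks, sum(x$data$detected)))
  cat("  Fixed effects (logit scale):\n")
  print(round(x$coefficients, 6))
  cat(sprintf("  Track random-intercept SD: %.3f\n", x$sigma_track))
  if (!x$converged) cat("  WARNING: fit did not converge cleanly\n")
  invisible(x)
}

#' @export
coef.detection_fit <- function(object, ...) object$coefficients

#' @export
vcov.detection_fit <- function(object, ...) object$vcov

#' @export
logLik.detection_fit <- function(object, ...) logLik(object$model)

#' @export
summary.detection_fit <- function(object, ...) {
  se <- sqrt(diag(object$vcov))
  z <- object$coefficients / se
  tab <- cbind(Estimate = object$coefficients, `Std. Error` = se,
               `z value` = z, `Pr(>|z|)` = 2 * pnorm(-abs(z)))
  structure(list(coefficients = tab, sigma_track = object$sigma_track,
                 n_obs = object$n_obs, n_tracks = object$n_tracks,
                 converged = object$converged, logLik = logLik(object),
                 call = object$call),
            class = "summary.detection_fit")
}

#' @export
print.summary.detection_fit <- function(x, ...) {
  cat("Binomial random-intercept detection model\n\n")
  stats::printCoefmat(x$coefficients, digits = 4)
  cat(sprintf("\nTrack random-intercept SD: %.3f\n", x$sigma_track))
  cat(sprintf("Observations: %d over %d tracks; logLik %.2f\n",
              x$n_obs, x$n_tracks, as.numeric(x$logLik)))
  if (!x$converged) cat("WARNING: fit did not converge cleanly\n")
  invisible(x)
}

#' Predicted detection probability
#'
#' Population-level predictions (random intercept set to 0). Covariates not
#' present in `newdata` are held at the fit's reference levels (orientation
#' `"along"`, tortuosity 0, outside clutter, mean observed range).
#'
#' @param object A `detection_fit`.
#' @param newdata Data frame or list of covariate values.
#' @param type `"response"` (probability) or `"link"` (logit).
#' @param se.fit Also return delta-method standard errors (on the chosen
#'   scale).
#' @param ... Unused.
#' @return Vector of predictions, or list with `fit` and `se.fit`.
#' @export
predict.detection_fit <- function(object, newdata = list(),
                                  type = c("response", "link"),
                                  se.fit = FALSE, ...) {
  type <- match.arg(type)
  lp <- fit_linpred(object, newdata)
  eta <- lp$eta
  out <- if (type == "response") plogis(eta) else eta
  if (!se.fit) return(out)
  se_eta <- sqrt(rowSums((lp$X %*% object$vcov) * lp$X))
  se <- if (type == "response") se_eta * stats::dlogis(eta) else se_eta
  list(fit = out, se.fit = se)
}

#' @export
residuals.detection_fit <- function(object, type = "deviance", ...) {
  residuals(object$model, type = type, ...)
}

#' @export
simulate.detection_fit <- function(object, nsim = 1, seed = NULL, ...) {
  simulate(object$model, nsim = nsim, seed = seed, ...)
}

#' Plot a detection fit
#'
#' Blip/scan detection ratios in range bins (bars) overlaid with the modelled
#' population-level detection curve at reference covariates, and the derived
#' detection range at the chosen threshold.
#'
#' @param x A `detection_fit` containing a `range` covariate.
#' @param bin_width Width of the blip/scan bins in metres.
#' @param pd_threshold Detection probability threshold to mark.
#' @param ... Passed to [plot()].
#' @export
plot.detection_fit <- function(x, bin_width = 25, pd_threshold = 0.5, ...) {
  if (!"range" %in% x$covariates) stop("fit has no range covariate")
  obs <- data.frame(range = x$data$range * 1000^x$range_power,
                    detected = x$data$detected)
  if (x$range_power == 4) obs$range <- obs$range^(1 / 4)
  bs <- blip_scan_ratio(obs, bin_width = bin_width)
  plot(NA, xlim = c(0, max(bs$bin_left + bs$bin_width)), ylim = c(0, 1),
       xlab = "Range from radar [m]", ylab = "Detection probability", ...)
  rect(bs$bin_left, 0, bs$bin_left + bs$bin_width, bs$pd,
       col = "grey80", border = "grey60")
  r <- seq(0, max(obs$range), length.out = 200)
  pr <- predict(x, data.frame(range = r), se.fit = TRUE)
  lines(r, pr$fit, lwd = 2)
  lines(r, pmin(1, pr$fit + pr$se.fit), lty = 3)
  lines(r, pmax(0, pr$fit - pr$se.fit), lty = 3)
  abline(h = pd_threshold, col = "red", lty = 2)
  dr <- tryCatch(detection_range(x, pd = pd_threshold), error = function(e) NULL)
  if (!is.null(dr)) abline(v = dr$range_at_pd, col = "red")
  invisible(x)
}
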