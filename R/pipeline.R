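#' Run the radar detection verification pipeline end to end
#'
#' Executes the full analysis on GPS tracks and radar plots from a
#' calibration campaign: per-test clock-offset estimation, timestamp
#' pairing, nondetection interpolation at the scan cadence, clutter
#' flagging, altitude/tortuosity screening, binomial random-intercept
#' detection models over clutter (clutter-test tracks) and over range
#' (range-test tracks, positions outside clutter only), the detection range
#' at the chosen probability threshold with CI, the empirical blip/scan
#' curve, and the extrapolation of the calibrated range to other target
#' sizes.
#'
#' @param gps GPS fixes data frame (`track_id`, `t`, `x`, `y`, `alt`), e.g.
#'   from [read_gps()] or [generate_scenario()].
#' @param radar Radar plots data frame (`track_id`, `t`, `x`, `y`).
#' @param origin A [radar_origin()].
#' @param params A [radar_parameters()].
#' @param mask Optional `clutter_mask`. Without it the clutter flag is
#'   `FALSE` everywhere and the clutter model is skipped.
#' @param track_types Optional named vector mapping track ids to `"DR"`
#'   (range test) or `"DC"` (clutter test); unnamed tracks (or `NULL`) are
#'   used in both models.
#' @param alt_min,tort_max Screening thresholds; `NULL` estimates them from
#'   the data with [segmented_threshold()].
#' @param pd_threshold Detection probability defining the detection range.
#' @param bin_width Blip/scan bin width in metres.
#' @param offset_window Clock-offset search window in seconds.
#' @param species Optional data frame with `species` and `rcs_db` (or
#'   `weight_g`, converted via [rcs_water_sphere()]) for extrapolation;
#'   defaults to [species_rcs()].
#' @param rcs_ref,rcs_quartiles Reference-target RCS calibration (median and
#'   quartiles, dBm2) used for extrapolation.
#' @param nAGQ Quadrature nodes for the detection models.
#' @param out_dir Optional directory; when given, every stage's output is
#'   persisted (CSV/JSON).
#' @return An object of class `radar_verification`: list with `offsets`,
#'   `observations` (screened), `screening`, `fit_clutter`, `fit_range`,
#'   `detection_range`, `clutter_contrast`, `blip_scan`, `crossing_range`,
#'   `extrapolation`, and a stage `log` data frame of observation counts.
#' @export
run_pipeline <- function(gps, radar, origin, params = radar_parameters(),
                         mask = NULL, track_types = NULL,
                         alt_min = NULL, tort_max = NULL,
                         pd_threshold = 0.5, bin_width = 25,
                         offset_window = c(0, 120),
                         species = species_rcs(),
                         rcs_ref = -11.0, rcs_quartiles = c(-14.6, -7.5),
                         nAGQ = 15, out_dir = NULL) {
  log <- list()
  note <- function(stage, n, detail = "") {
    log[[length(log) + 1]] <<- data.frame(stage = stage, n = n,
                                          detail = detail)
  }
  ids <- sort(unique(gps$track_id))
  note("input", nrow(gps), sprintf("%d GPS fixes, %d radar plots, %d tracks",
                                   nrow(gps), nrow(radar), length(ids)))

  # stage 1-3: sync, pair, interpolate per track -------------------------
  offsets <- data.frame(track_id = ids, offset = NA_real_,
                        loglik = NA_real_, n_pairs = NA_integer_)
  obs_list <- list()
  for (k in seq_along(ids)) {
    id <- ids[k]
    g <- gps[gps$track_id == id, , drop = FALSE]
    r <- radar[radar$track_id == id, , drop = FALSE]
    if (nrow(r) < 3) {
      warning("track ", id, ": too few radar plots, skipped")
      next
    }
    est <- tryCatch(
      estimate_offset(g, r, origin, window = offset_window),
      error = function(e) stop("offset estimation failed for track ", id,
                               ": ", conditionMessage(e)))
    offsets$offset[k] <- est$offset
    offsets$loglik[k] <- est$loglik
    offsets$n_pairs[k] <- est$model$n_pairs
    pairs <- pair_by_timestamp(g, r, est$offset)
    obs_list[[k]] <- interpolate_nondetections(g, pairs, origin, params,
                                               track_id = id)
  }
  observations <- do.call(rbind, obs_list)
  if (is.null(observations) || nrow(observations) == 0)
    stop("synchronization produced no observations")
  note("sync+interpolate", nrow(observations),
       sprintf("%d detections / %d opportunities",
               sum(observations$detected), nrow(observations)))

  # stage 4: clutter flag -------------------------------------------------
  if (!is.null(mask)) {
    inside <- grid_inside(mask, observations$x, observations$y)
    observations$in_clutter <- FALSE
    observations$in_clutter[inside] <-
      in_clutter(mask, observations$x[inside], observations$y[inside])
  } else {
    observations$in_clutter <- FALSE
  }
  note("clutter_flag", sum(observations$in_clutter), "opportunities in clutter")

  # stage 5: screening ----------------------------------------------------
  thr_alt <- thr_tort <- NULL
  if (is.null(alt_min)) {
    thr_alt <- tryCatch(
      segmented_threshold(observations$alt, observations$detected,
                          side = "lower"),
      error = function(e) NULL)
    alt_min <- if (!is.null(thr_alt) && !thr_alt$degenerate)
      thr_alt$breakpoint else -Inf
  }
  if (is.null(tort_max)) {
    thr_tort <- tryCatch(
      segmented_threshold(observations$tortuosity, observations$detected,
                          side = "upper"),
      error = function(e) NULL)
    tort_max <- if (!is.null(thr_tort) && !thr_tort$degenerate)
      thr_tort$breakpoint else 1
  }
  scr <- apply_exclusions(observations, alt_min, tort_max)
  screened <- scr$retained
  note("screening", nrow(screened),
       sprintf("excluded %.1f%% (alt_min=%.3g, tort_max=%.3g)",
               100 * scr$report$fraction, alt_min, tort_max))

  # stage 6: clutter model (clutter-test tracks) --------------------------
  types <- rep("both", length(ids))
  names(types) <- ids
  if (!is.null(track_types)) types[names(track_types)] <- track_types
  dc_ids <- ids[types[as.character(ids)] %in% c("DC", "both")]
  dr_ids <- ids[types[as.character(ids)] %in% c("DR", "both")]

  fit_clutter <- contrast <- NULL
  dc <- screened[screened$track_id %in% dc_ids, , drop = FALSE]
  if (!is.null(mask) && nrow(dc) > 0 && length(unique(dc$in_clutter)) > 1) {
    fit_clutter <- fit_detection(
      dc, covariates = c("range", "in_clutter", "orientation", "tortuosity"),
      nAGQ = nAGQ)
    contrast <- clutter_contrast(fit_clutter)
    note("fit_clutter", nrow(fit_clutter$data),
         sprintf("%d clutter-test tracks", length(unique(dc$track_id))))
  } else {
    note("fit_clutter", 0, "skipped: no clutter variation or no mask")
  }

  # stage 7: range model (range-test tracks outside clutter) --------------
  dr <- screened[screened$track_id %in% dr_ids & !screened$in_clutter, ,
                 drop = FALSE]
  fit_range <- fit_detection(
    dr, covariates = c("range", "orientation", "tortuosity"), nAGQ = nAGQ)
  note("fit_range", nrow(fit_range$data),
       sprintf("%d range-test tracks, outside clutter",
               length(unique(dr$track_id))))

  drange <- detection_range(fit_range, pd = pd_threshold)
  bs <- blip_scan_ratio(dr, bin_width = bin_width)
  cross <- crossing_range(bs, pd = pd_threshold)
  note("detection_range", round(drange$range_at_pd),
       sprintf("CI %.0f-%.0f m; blip/scan crossing %.0f m",
               drange$ci_low, drange$ci_high, cross))

  # stage 8: extrapolation -------------------------------------------------
  extrap <- NULL
  if (!is.null(species)) {
    if (!"rcs_db" %in% names(species)) {
      species$rcs_db <- rcs_water_sphere(species$weight_g)
    }
    extrap <- cbind(species["species"],
                    extrapolation_bounds(species$rcs_db, rcs_ref_db = rcs_ref,
                                         rcs_ref_quartiles = rcs_quartiles,
                                         r_ref_m = drange$range_at_pd))
    note("extrapolation", nrow(extrap),
         sprintf("reference range %.0f m, reference RCS %.1f dBm2",
                 drange$range_at_pd, rcs_ref))
  }

  res <- structure(list(
    offsets = offsets, observations = screened,
    observations_unscreened = observations,
    screening = list(report = scr$report, alt_fit = thr_alt,
                     tort_fit = thr_tort),
    fit_clutter = fit_clutter, clutter_contrast = contrast,
    fit_range = fit_range, detection_range = drange,
    blip_scan = bs, crossing_range = cross,
    extrapolation = extrap,
    log = do.call(rbind, log)),
    class = "radar_verification")

  if (!is.null(out_dir)) persist_results(res, out_dir)
  res
}

#' @export
print.radar_verification <- function(x, ...) {
  cat("Radar detection verification\n")
  cat(sprintf("  %d tracks; offsets %.1f-%.1f s\n",
              nrow(x$offsets), min(x$offsets$offset, na.rm = TRUE),
              max(x$offsets$offset, na.rm = TRUE)))
  cat(sprintf("  screening: excluded %.1f%% (alt < %.3g m, tortuosity > %.3g)\n",
              100 * x$screening$report$fraction, x$screening$report$alt_min,
              x$screening$report$tort_max))
  if (!is.null(x$clutter_contrast)) {
    cc <- x$clutter_contrast
    cat(sprintf("  clutter: Pd %.2f -> %.2f inside clutter (%.0f%% reduction, %.0f-%.0f%% CI)\n",
                cc$pd_outside, cc$pd_inside, 100 * cc$reduction,
                100 * cc$reduction_ci[1], 100 * cc$reduction_ci[2]))
  }
  dr <- x$detection_range
  cat(sprintf("  detection range at Pd=%.2f: %.0f m (%.0f-%.0f m CI); blip/scan crossing %.0f m\n",
              dr$pd_threshold, dr$range_at_pd, dr$ci_low, dr$ci_high,
              x$crossing_range))
  if (!is.null(x$extrapolation)) {
    cat("  extrapolated ranges (m):\n")
    e <- x$extrapolation
    for (i in seq_len(nrow(e)))
      cat(sprintf("    %-20s %5.0f (%.0f-%.0f)\n", e$species[i],
                  e$range_m[i], e$lower_m[i], e$upper_m[i]))
  }
  invisible(x)
}

persist_results <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(res$offsets, file.path(out_dir, "offsets.csv"), row.names = FALSE)
  write_observations(res$observations,
                     file.path(out_dir, "observations.csv"))
  write.csv(res$blip_scan, file.path(out_dir, "blip_scan.csv"),
            row.names = FALSE)
  if (!is.null(res$extrapolation))
    write.csv(res$extrapolation, file.path(out_dir, "extrapolation.csv"),
              row.names = FALSE)
  report <- list(
    screening = res$screening$report,
    detection_range = res$detection_range[c("range_at_pd", "ci_low",
                                            "ci_high", "pd_threshold")],
    crossing_range = res$crossing_range,
    range_model = list(coefficients = as.list(res$fit_range$coefficients),
                       sigma_track = res$fit_range$sigma_track,
                       n_obs = res$fit_range$n_obs,
                       converged = res$fit_range$converged),
    log = res$log
  )
  if (!is.null(res$clutter_contrast))
    report$clutter <- res$clutter_contrast[c("pd_outside", "pd_inside",
                                             "reduction", "reduction_ci",
                                             "at_range")]
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       digits = NA, auto_unbox = TRUE, force = TRUE)
  invisible(out_dir)
}
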