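#' Read GPS flight tracks
#'
#' Reads a CSV of GPS fixes with header columns `test_id`, `timestamp`
#' (ISO-8601 or epoch seconds) and either projected planar coordinates
#' `x`, `y` (metres) or geographic `lat`, `lon` (degrees), plus optional
#' `alt_agl_m`. Tracks are grouped by `test_id` and time-sorted; duplicate
#' timestamps within a track are rejected.
#'
#' Geographic coordinates are converted with a local tangent-plane
#' (equirectangular) projection about `projection_origin = c(lon0, lat0)`,
#' which the caller must declare; over the few-kilometre extents of a
#' calibration campaign the planar error of this projection is negligible
#' (centimetres).
#'
#' @param path CSV file path.
#' @param projection_origin Numeric `c(lon0, lat0)`, required when the file
#'   carries `lat`/`lon`.
#' @return Data frame with columns `track_id`, `t`, `x`, `y`, `alt`, sorted
#'   by track then time.
#' @export
read_gps <- function(path, projection_origin = NULL) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("test_id", "timestamp")
  if (!all(need %in% names(d)))
    stop("missing required columns: ",
         paste(setdiff(need, names(d)), collapse = ", "))
  t <- parse_timestamp(d$timestamp)
  if (all(c("x", "y") %in% names(d))) {
    x <- d$x; y <- d$y
  } else if (all(c("lat", "lon") %in% names(d))) {
    if (is.null(projection_origin))
      stop("lat/lon input requires a declared projection_origin = c(lon0, lat0)")
    xy <- latlon_to_local(d$lat, d$lon, projection_origin)
    x <- xy$x; y <- xy$y
  } else stop("need either x/y or lat/lon columns")
  alt <- if ("alt_agl_m" %in% names(d)) d$alt_agl_m else NA_real_
  out <- data.frame(track_id = d$test_id, t = t, x = x, y = y, alt = alt)
  out <- out[order(out$track_id, out$t), , drop = FALSE]
  dup <- unlist(tapply(out$t, out$track_id, function(v) duplicated(v)))
  if (any(dup)) stop("duplicate timestamps within a track")
  rownames(out) <- NULL
  out
}

parse_timestamp <- function(ts) {
  if (is.numeric(ts)) return(as.numeric(ts))
  suppressWarnings(num <- as.numeric(ts))
  if (!anyNA(num)) return(num)
  p <- as.POSIXct(ts, tz = "UTC",
                  tryFormats = c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS"))
  if (anyNA(p)) stop("unparseable timestamps")
  as.numeric(p)
}

# local tangent-plane projection, adequate for <= ~10 km extents
latlon_to_local <- function(lat, lon, origin) {
  R <- 6378137
  x <- R * cos(origin[2] * pi / 180) * (lon - origin[1]) * pi / 180
  y <- R * (lat - origin[2]) * pi / 180
  data.frame(x = x, y = y)
}

#' Read a GPX track file
#'
#' Minimal GPX reader: extracts all `trkpt` elements (lat, lon, ele, time)
#' of the first track and converts them with the declared local projection.
#'
#' @inheritParams read_gps
#' @param track_id Identifier to assign to the track.
#' @return Data frame with columns `track_id`, `t`, `x`, `y`, `alt`.
#' @export
read_gpx <- function(path, projection_origin, track_id = 1L) {
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  pts <- xml2::xml_find_all(doc, ".//trkpt")
  if (length(pts) == 0) stop("no track points in ", path)
  lat <- as.numeric(xml2::xml_attr(pts, "lat"))
  lon <- as.numeric(xml2::xml_attr(pts, "lon"))
  ele <- as.numeric(xml2::xml_text(xml2::xml_find_first(pts, "./ele")))
  tim <- xml2::xml_text(xml2::xml_find_first(pts, "./time"))
  xy <- latlon_to_local(lat, lon, projection_origin)
  data.frame(track_id = track_id, t = parse_timestamp(tim),
             x = xy$x, y = xy$y, alt = ele)
}

#' Read radar plot/track exports
#'
#' Reads a CSV of radar plots with header columns `track_id`, `timestamp`
#' and either planar `x`, `y` (metres) or polar `range_m`, `bearing_deg`
#' (converted about the radar origin). Plots are grouped by track and
#' time-sorted. An empty file yields an empty data frame with a warning.
#'
#' @param path CSV file path.
#' @param origin A [radar_origin()], required for polar input.
#' @return Data frame with columns `track_id`, `t`, `x`, `y`.
#' @export
read_radar <- function(path, origin = NULL) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  if (nrow(d) == 0) {
    warning("empty radar file: ", path)
    return(data.frame(track_id = integer(), t = numeric(),
                      x = numeric(), y = numeric()))
  }
  need <- c("track_id", "timestamp")
  if (!all(need %in% names(d)))
    stop("missing required columns: ",
         paste(setdiff(need, names(d)), collapse = ", "))
  t <- parse_timestamp(d$timestamp)
  if (all(c("x", "y") %in% names(d))) {
    x <- d$x; y <- d$y
  } else if (all(c("range_m", "bearing_deg") %in% names(d))) {
    if (is.null(origin)) stop("polar radar input requires the radar origin")
    xy <- polar_to_xy(origin, d$range_m, d$bearing_deg)
    x <- xy$x; y <- xy$y
  } else stop("need either x/y or range_m/bearing_deg columns")
  out <- data.frame(track_id = d$track_id, t = t, x = x, y = y)
  out <- out[order(out$track_id, out$t), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read and write paired-observation tables
#'
#' CSV round trip for the paired-observation schema produced by
#' [interpolate_nondetections()]: columns `track_id`, `t`, `x`, `y`, `alt`,
#' `detected`, `range`, `bearing`, `course`, `tortuosity`, `orientation`,
#' `in_clutter`.
#'
#' @param observations Paired-observation data frame.
#' @param path CSV file path.
#' @return `write_observations()` returns `path` invisibly;
#'   `read_observations()` the data frame.
#' @export
write_observations <- function(observations, path) {
  write.csv(observations, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_observations
#' @export
read_observations <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  d$detected <- as.logical(d$detected)
  d$in_clutter <- as.logical(d$in_clutter)
  d
}
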