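#' Terrain grid
#'
#' A regular elevation raster in the projected planar frame. `z` is a matrix
#' with rows running north to south (row 1 = northernmost), the ESRI ASCII
#' grid convention; `x0`, `y0` are the coordinates of the lower-left corner
#' of the lower-left cell. Cells are half-open: a point belongs to cell
#' `[x0 + (j-1)*cell, x0 + j*cell) x [y0 + (i-1)*cell, y0 + i*cell)`.
#'
#' @param x0,y0 Lower-left corner coordinates in metres.
#' @param cell_size Cell edge length in metres (positive).
#' @param z Elevation matrix in metres, rows north to south.
#' @param nodata Value marking missing cells (converted to `NA` internally).
#' @return An object of class `terrain_grid`.
#' @export
terrain_grid <- function(x0, y0, cell_size, z, nodata = -9999) {
  stopifnot(is.matrix(z), cell_size > 0)
  z[z == nodata] <- NA_real_
  structure(list(x0 = x0, y0 = y0, cell_size = cell_size,
                 n_rows = nrow(z), n_cols = ncol(z), z = z, nodata = nodata),
            class = "terrain_grid")
}

#' @export
print.terrain_grid <- function(x, ...) {
  cat(sprintf("Terrain grid: %d x %d cells of %g m, origin (%g, %g)\n",
              x$n_rows, x$n_cols, x$cell_size, x$x0, x$y0))
  cat(sprintf("  elevation %g - %g m; %d nodata cells\n",
              min(x$z, na.rm = TRUE), max(x$z, na.rm = TRUE), sum(is.na(x$z))))
  invisible(x)
}

# grid frame helpers -------------------------------------------------------

grid_extent <- function(g) {
  c(xmin = g$x0, xmax = g$x0 + g$n_cols * g$cell_size,
    ymin = g$y0, ymax = g$y0 + g$n_rows * g$cell_size)
}

# row/col of the cell containing (x, y); half-open convention
grid_cell <- function(g, x, y) {
  j <- floor((x - g$x0) / g$cell_size) + 1
  i_south <- floor((y - g$y0) / g$cell_size) + 1
  i <- g$n_rows - i_south + 1
  cbind(row = i, col = j)
}

grid_inside <- function(g, x, y) {
  e <- grid_extent(g)
  x >= e["xmin"] & x < e["xmax"] & y >= e["ymin"] & y < e["ymax"]
}

# cell-centre coordinates for all cells (matching z layout)
grid_centres <- function(g) {
  cx <- g$x0 + (seq_len(g$n_cols) - 0.5) * g$cell_size
  cy <- g$y0 + (g$n_rows - seq_len(g$n_rows) + 0.5) * g$cell_size  # row 1 = north
  list(x = cx, y = cy)
}

# bilinear elevation at arbitrary points, clamped to the cell-centre lattice
# edges; NA where any contributing node is nodata
grid_elevation <- function(g, x, y) {
  ctr <- grid_centres(g)
  cx <- ctr$x
  cy_desc <- ctr$y                 # descending (north to south)
  cy <- rev(cy_desc)               # ascending for interpolation math
  # fractional index in the ascending-y frame
  fx <- (x - cx[1]) / g$cell_size
  fy <- (y - cy[1]) / g$cell_size
  fx <- pmin(pmax(fx, 0), g$n_cols - 1)
  fy <- pmin(pmax(fy, 0), g$n_rows - 1)
  j0 <- pmin(floor(fx) + 1, g$n_cols - 1)
  i0 <- pmin(floor(fy) + 1, g$n_rows - 1)
  tx <- fx - (j0 - 1)
  ty <- fy - (i0 - 1)
  # translate ascending-y index to matrix row (row 1 = north)
  r0 <- g$n_rows - i0 + 1          # southern node
  r1 <- r0 - 1                     # northern node
  idx <- function(r, c) (c - 1) * g$n_rows + r
  z <- g$z
  z00 <- z[idx(r0, j0)]
  z10 <- z[idx(r0, j0 + 1)]
  z01 <- z[idx(r1, j0)]
  z11 <- z[idx(r1, j0 + 1)]
  (1 - ty) * ((1 - tx) * z00 + tx * z10) + ty * ((1 - tx) * z01 + tx * z11)
}

#' Read and write ESRI ASCII grids
#'
#' Plain-text raster I/O for terrain grids and clutter masks in the ESRI
#' ASCII (`.asc`) format. Both `xllcorner`/`yllcorner` and
#' `xllcenter`/`yllcenter` headers are accepted on read; files are written
#' with corner registration. Masks are written as 0/1 integers.
#'
#' @param path File path.
#' @return `read_asc()`: a [terrain_grid()] (logical content is preserved as
#'   0/1 and can be converted with [as_clutter_mask()]).
#' @export
read_asc <- function(path) {
  lines <- readLines(path, n = 6)
  kv <- lapply(strsplit(trimws(lines), "\\s+"), function(p)
    list(key = tolower(p[1]), val = as.numeric(p[2])))
  hdr <- setNames(vapply(kv, `[[`, 0, "val"), vapply(kv, `[[`, "", "key"))
  need <- c("ncols", "nrows", "cellsize")
  if (!all(need %in% names(hdr))) stop("malformed ESRI ASCII header in ", path)
  cell <- hdr[["cellsize"]]
  if ("xllcorner" %in% names(hdr)) {
    x0 <- hdr[["xllcorner"]]; y0 <- hdr[["yllcorner"]]
  } else {
    x0 <- hdr[["xllcenter"]] - cell / 2
    y0 <- hdr[["yllcenter"]] - cell / 2
  }
  nodata <- if ("nodata_value" %in% names(hdr)) hdr[["nodata_value"]] else -9999
  n_header <- if ("nodata_value" %in% names(hdr)) 6 else 5
  vals <- scan(path, skip = n_header, quiet = TRUE)
  nr <- hdr[["nrows"]]; nc <- hdr[["ncols"]]
  if (length(vals) != nr * nc) stop("grid body size mismatch in ", path)
  z <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  terrain_grid(x0, y0, cell, z, nodata = nodata)
}

#' @rdname read_asc
#' @param grid A [terrain_grid()] or `clutter_mask`.
#' @param digits Number formatting precision for elevations.
#' @export
write_asc <- function(grid, path, digits = 6) {
  z <- grid$z
  if (is.logical(z)) z <- z * 1L
  zo <- z
  zo[is.na(zo)] <- grid$nodata
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("ncols %d", grid$n_cols),
    sprintf("nrows %d", grid$n_rows),
    sprintf("xllcorner %.10g", grid$x0),
    sprintf("yllcorner %.10g", grid$y0),
    sprintf("cellsize %.10g", grid$cell_size),
    sprintf("NODATA_value %.10g", grid$nodata)
  ), con)
  apply(zo, 1, function(row)
    writeLines(paste(format(row, trim = TRUE, digits = digits),
                     collapse = " "), con))
  invisible(path)
}

#' Line-of-sight test over terrain
#'
#' Tests whether the sightline from the radar antenna (ground elevation at
#' the origin plus `antenna_height`) to a target point (ground elevation plus
#' `target_height`) clears the terrain. The terrain profile is sampled at
#' steps of half the cell size with bilinear interpolation; any intermediate
#' sample strictly above the sightline blocks it. Missing elevations along
#' the profile are treated as blocking, with a warning.
#'
#' Earth curvature and refraction are ignored by default (for ranges up to a
#' few kilometres the curvature drop is under a metre); `effective_earth =
#' 4/3` applies the standard effective-Earth-radius correction.
#'
#' @param grid A [terrain_grid()].
#' @param origin A [radar_origin()]; must lie inside the grid.
#' @param target_x,target_y Target coordinates in metres (inside the grid).
#' @param target_height Target height above ground in metres.
#' @param effective_earth `NULL` (no curvature) or a multiplier of the Earth
#'   radius, e.g. `4/3`.
#' @return Logical: `TRUE` if the target is visible from the antenna.
#' @export
line_of_sight <- function(grid, origin, target_x, target_y,
                          target_height = 0, effective_earth = NULL) {
  if (!grid_inside(grid, origin$x, origin$y))
    stop("radar origin lies outside the terrain grid")
  if (!grid_inside(grid, target_x, target_y))
    stop("target lies outside the terrain grid")
  z0 <- grid_elevation(grid, origin$x, origin$y) + origin$antenna_height
  z1 <- grid_elevation(grid, target_x, target_y) + target_height
  if (is.na(z0) || is.na(z1)) {
    warning("nodata at sightline endpoint; treated as not visible")
    return(FALSE)
  }
  d <- sqrt((target_x - origin$x)^2 + (target_y - origin$y)^2)
  if (d == 0) return(TRUE)
  n <- max(2L, ceiling(d / (grid$cell_size / 2)))
  f <- seq_len(n - 1) / n                     # interior samples only
  px <- origin$x + f * (target_x - origin$x)
  py <- origin$y + f * (target_y - origin$y)
  zt <- grid_elevation(grid, px, py)
  if (!is.null(effective_earth)) {
    # bulge of the terrain toward the chord between endpoints
    re <- effective_earth * 6371000
    zt <- zt + (f * d) * ((1 - f) * d) / (2 * re)
  }
  zline <- z0 + f * (z1 - z0)
  if (anyNA(zt)) {
    warning("nodata along sightline profile; treated as blocking")
    return(FALSE)
  }
  all(zt <= zline + 1e-9)
}

#' Build the ground-clutter mask as the radar's viewshed
#'
#' Ground clutter is modelled as the area in line-of-sight of the radar:
#' every grid cell whose centre (at `target_height` above ground) is visible
#' from the antenna is a clutter cell. The mask preserves the terrain grid's
#' frame exactly.
#'
#' @inheritParams line_of_sight
#' @return An object of class `clutter_mask` (a [terrain_grid()]-framed
#'   logical raster).
#' @export
build_clutter_mask <- function(grid, origin, target_height = 0,
                               effective_earth = NULL) {
  ctr <- grid_centres(grid)
  vis <- matrix(FALSE, grid$n_rows, grid$n_cols)
  for (i in seq_len(grid$n_rows)) {
    for (j in seq_len(grid$n_cols)) {
      vis[i, j] <- suppressWarnings(
        line_of_sight(grid, origin, ctr$x[j], ctr$y[i],
                      target_height = target_height,
                      effective_earth = effective_earth))
    }
  }
  structure(list(x0 = grid$x0, y0 = grid$y0, cell_size = grid$cell_size,
                 n_rows = grid$n_rows, n_cols = grid$n_cols, z = vis,
                 nodata = -9999),
            class = c("clutter_mask", "terrain_grid"))
}

#' Coerce a 0/1 terrain grid to a clutter mask
#'
#' Used after reading a pre-computed mask (e.g. exported from external GIS)
#' from an ESRI ASCII grid.
#'
#' @param grid A [terrain_grid()] whose values are 0/1 (NA allowed, treated
#'   as 0).
#' @return A `clutter_mask`.
#' @export
as_clutter_mask <- function(grid) {
  z <- grid$z
  z[is.na(z)] <- 0
  if (!all(z %in% c(0, 1))) stop("grid is not a 0/1 mask")
  grid$z <- z == 1
  class(grid) <- c("clutter_mask", "terrain_grid")
  grid
}

#' @export
print.clutter_mask <- function(x, ...) {
  cat(sprintf("Clutter mask: %d x %d cells of %g m; %.1f%% in line-of-sight\n",
              x$n_rows, x$n_cols, x$cell_size, 100 * mean(x$z)))
  invisible(x)
}

#' Point-in-clutter lookup
#'
#' Whether points fall in a clutter (line-of-sight) cell. Cells are half-open
#' (`[x, x + cell)`, `[y, y + cell)`), so a point on a shared edge belongs to
#' the cell to its north-east. Points outside the mask frame raise an error.
#'
#' @param mask A `clutter_mask` from [build_clutter_mask()] or
#'   [as_clutter_mask()].
#' @param x,y Point coordinates in metres (vectorized).
#' @return Logical vector.
#' @export
in_clutter <- function(mask, x, y) {
  ok <- grid_inside(mask, x, y)
  if (!all(ok)) stop(sum(!ok), " point(s) outside the clutter mask frame")
  rc <- grid_cell(mask, x, y)
  mask$z[cbind(rc[, "row"], rc[, "col"])]
}
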