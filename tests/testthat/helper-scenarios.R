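# shared fixtures, all built in code

# flat terrain over a small square window
flat_grid <- function(half = 2000, cell = 100, elev = 0) {
  n <- ceiling(2 * half / cell)
  terrain_grid(-half, -half, cell, matrix(elev, n, n))
}

# flat terrain with a north-south ridge of given height at x in [x_from, x_to]
ridge_grid <- function(half = 2000, cell = 100, height = 20,
                       x_from = 400, x_to = 600) {
  g <- flat_grid(half, cell)
  cx <- g$x0 + (seq_len(g$n_cols) - 0.5) * cell
  g$z[, cx >= x_from & cx <= x_to] <- height
  g
}

# terrain for the small scenario: a 25 m ridge east of the radar shadows
# part of the window, so the mask has both clutter and clear areas
tiny_terrain <- function() ridge_grid(half = 2000, cell = 100, height = 25,
                                      x_from = 300, x_to = 500)

tiny_mask <- local({
  m <- NULL
  function() {
    if (is.null(m))
      m <<- build_clutter_mask(tiny_terrain(), radar_origin(0, 0, 5))
    m
  }
})

# small fast scenario: 2 range flights + 1 clutter flight; the eastbound
# flight and the diagonal clutter flight cross the ridge shadow
tiny_config <- function(seed, ...) {
  fl <- list(
    list(waypoints = rbind(c(0, 150), c(0, 1800), c(0, 150)), type = "DR"),
    list(waypoints = rbind(c(150, 0), c(1800, 0), c(150, 0)), type = "DR"),
    list(waypoints = rbind(c(300, 300), c(1200, 1200), c(300, 300),
                           c(1200, 1200), c(300, 300)), type = "DC")
  )
  scenario_config(seed = seed, flights = fl, terrain = tiny_terrain(),
                  clutter_mask = tiny_mask(), ...)
}

# the default ("campaign") terrain viewshed is deterministic and expensive;
# compute it once per test run
campaign_mask <- local({
  mask <- NULL
  function() {
    if (is.null(mask)) {
      mask <<- build_clutter_mask(default_terrain(), radar_origin(0, 0, 5))
    }
    mask
  }
})

# truth-typed track map for a generated scenario
scenario_types <- function(scn) {
  stats::setNames(scn$truth$types, sort(unique(scn$gps$track_id)))
}
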