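# Shared fixture builders and the independent brute-force annotation
# oracle used in the engine equivalence tests.

# a grid whose cells are `cell_m` meters on a side near the equator
equator_grid <- function(n_rows = 20L, n_cols = 20L, cell_m = 250,
                         origin_lon = 0, origin_lat = 1) {
  grid_geometry(origin_lon, origin_lat, cell_m / 111320, n_rows, n_cols)
}

# a daily series over June 2015 on a small equatorial grid
daily_series <- function(..., n_rows = 20L, n_cols = 20L, cell_m = 250,
                         dates = c("2015-06-01", "2015-06-30"), seed = 1L) {
  make_layer_series(synth_layer_params(
    geometry = equator_grid(n_rows, n_cols, cell_m),
    temporal_grain = "daily", date_range = as.Date(dates), seed = seed, ...))
}

# interior extent of a grid with `margin_cells` cells kept clear of the edge
grid_extent <- function(geom, margin_cells = 0) {
  s <- geom$cell_size_deg
  c(geom$origin_lon + margin_cells * s,
    geom$origin_lon + (geom$n_cols - margin_cells) * s,
    geom$origin_lat - (geom$n_rows - margin_cells) * s,
    geom$origin_lat - margin_cells * s)
}

# Brute-force annotation oracle: enumerates all cells and days directly
# from interval logic and plain distance tests, independent of the engine's
# floor arithmetic, mask construction, and accumulation code.
oracle_annotate <- function(record, series, radius_m, buffer_days) {
  scenes <- series$scenes
  geom <- scenes[[1L]]$geometry
  s <- geom$cell_size_deg
  lon <- record$longitude; lat <- record$latitude
  anchor <- as.Date(record$event_date)
  days <- anchor - rev(seq_len(buffer_days) - 1L)

  # containing cell by explicit interval membership
  contain <- NULL
  for (i in seq_len(geom$n_rows)) {
    north <- geom$origin_lat - (i - 1L) * s
    south <- north - s
    if (!(lat > south && lat <= north)) next
    for (j in seq_len(geom$n_cols)) {
      west <- geom$origin_lon + (j - 1L) * s
      east <- west + s
      if (lon >= west && lon < east) { contain <- c(i, j); break }
    }
  }
  if (is.null(contain)) return(list(status = "out_of_extent"))

  # included cells: center within radius, else the containing cell
  coslat <- cos(lat * pi / 180)
  cells <- list()
  for (i in seq_len(geom$n_rows)) for (j in seq_len(geom$n_cols)) {
    clon <- geom$origin_lon + (j - 0.5) * s
    clat <- geom$origin_lat - (i - 0.5) * s
    dx <- (clon - lon) * 111320 * coslat
    dy <- (clat - lat) * 111320
    if (sqrt(dx^2 + dy^2) <= radius_m) cells[[length(cells) + 1L]] <- c(i, j)
  }
  if (!length(cells)) cells <- list(contain)

  vals <- numeric(0)
  scenes_used <- 0L
  any_scene <- FALSE
  vr <- series$layer$valid_range
  for (d in as.list(days)) {
    sc <- scenes[[scene_key(series$layer$name, d)]]
    if (is.null(sc)) next
    any_scene <- TRUE
    day_vals <- numeric(0)
    for (cl in cells) {
      v <- sc$values[cl[1L], cl[2L]]
      if (is.na(v)) next
      if (!is.null(vr) && (v < vr[1L] || v > vr[2L])) next
      day_vals <- c(day_vals, v)
    }
    if (length(day_vals)) scenes_used <- scenes_used + 1L
    vals <- c(vals, day_vals)
  }
  if (!any_scene) return(list(status = "out_of_coverage"))
  if (!length(vals)) return(list(status = "no_valid_data"))
  list(status = "ok", mean = mean(vals),
       sd = if (length(vals) >= 2L) sd(vals) else NA_real_,
       n = length(vals), scenes_used = scenes_used,
       min = min(vals), max = max(vals))
}

expect_results_equal <- function(a, b, tol = 1e-10) {
  expect_equal(a$record_id, b$record_id)
  expect_equal(a$layer, b$layer)
  expect_equal(a$status, b$status)
  expect_equal(a$valid_sample_count, b$valid_sample_count)
  expect_equal(a$scenes_used, b$scenes_used)
  expect_equal(a$value_mean, b$value_mean, tolerance = tol)
  expect_equal(a$value_stdev, b$value_stdev, tolerance = tol)
}
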