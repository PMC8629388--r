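# Spatial and temporal buffers: turn a requested radius and day count into
# an explicit pixel set and day window.

# meters per degree of latitude (and of longitude at the equator)
M_PER_DEG <- 111320

#' Pixel set implied by a spatial buffer
#'
#' A cell belongs to the mask iff the planar distance from its center to the
#' buffer center is at most `radius_m`, using a local equirectangular metric:
#' `dy = dlat * 111320` m and `dx = dlon * 111320 * cos(lat)` m with `lat`
#' the buffer center's latitude. For the radii this tool targets (up to a
#' few km) the approximation error is negligible relative to pixel size.
#' When the radius is smaller than the distance to the nearest cell center,
#' the mask degrades to the single containing cell, so radius 0 is exactly
#' the grid-cell-intersection mode. Cells are clipped to the grid extent.
#'
#' @param geometry A [grid_geometry()].
#' @param lon,lat Buffer center in degrees; must be inside the extent.
#' @param radius_m Buffer radius in meters, `>= 0`.
#' @return An object of class `"spatial_buffer_mask"`: list with `center`,
#'   `radius_m`, `cells` (two-column integer matrix of row, col) and
#'   `n_cells`.
#' @export
spatial_buffer_mask <- function(geometry, lon, lat, radius_m) {
  if (!is.numeric(radius_m) || length(radius_m) != 1L || is.na(radius_m) || radius_m < 0)
    stop_validation("radius_m must be a non-negative number")
  cc <- containing_cell(geometry, lon, lat)
  if (is.na(cc[1L]))
    stop_out_of_extent(sprintf("buffer center (%g, %g) lies outside the grid extent", lon, lat))
  s <- geometry$cell_size_deg
  coslat <- cos(lat * pi / 180)
  # candidate index window from the radius expressed in degrees
  dlat_deg <- radius_m / M_PER_DEG
  dlon_deg <- if (coslat > 1e-12) radius_m / (M_PER_DEG * coslat) else 360
  row_rng <- max(1L, cc[1L] - ceiling(dlat_deg / s) - 1L):
             min(geometry$n_rows, cc[1L] + ceiling(dlat_deg / s) + 1L)
  col_rng <- max(1L, cc[2L] - ceiling(dlon_deg / s) - 1L):
             min(geometry$n_cols, cc[2L] + ceiling(dlon_deg / s) + 1L)
  cand <- expand.grid(row = row_rng, col = col_rng, KEEP.OUT.ATTRS = FALSE)
  ctr <- cell_center(geometry, cand$row, cand$col)
  dx <- (ctr$lon - lon) * M_PER_DEG * coslat
  dy <- (ctr$lat - lat) * M_PER_DEG
  keep <- sqrt(dx * dx + dy * dy) <= radius_m
  cells <- cbind(row = as.integer(cand$row[keep]), col = as.integer(cand$col[keep]))
  if (nrow(cells) == 0L)
    cells <- cbind(row = cc[1L], col = cc[2L])
  # deterministic order: row-major
  cells <- cells[order(cells[, 1L], cells[, 2L]), , drop = FALSE]
  structure(list(center = c(lon = lon, lat = lat), radius_m = radius_m,
                 cells = cells, n_cells = nrow(cells)),
            class = "spatial_buffer_mask")
}

#' Trailing day window of a temporal buffer
#'
#' The window covers the observation day and the `buffer_days - 1` days
#' before it (never after): buffer 7 anchored on 2015-06-10 spans
#' 2015-06-04 .. 2015-06-10. The minimum buffer is 1 (the day itself).
#'
#' @param anchor `Date` (or ISO-8601 string): the observation date.
#' @param buffer_days Integer `>= 1`.
#' @return An object of class `"temporal_window"`: list with `anchor_date`,
#'   `buffer_days` and the ordered `days` vector.
#' @export
temporal_window <- function(anchor, buffer_days) {
  anchor <- as.Date(anchor)
  if (length(anchor) != 1L || is.na(anchor))
    stop_validation("anchor must be a single parseable date")
  buffer_days <- as.integer(buffer_days)
  if (is.na(buffer_days) || buffer_days < 1L)
    stop_validation("temporal buffer minimum is 1 (the day of observation counts)")
  structure(list(anchor_date = anchor, buffer_days = buffer_days,
                 days = seq(anchor - (buffer_days - 1L), anchor, by = "1 day")),
            class = "temporal_window")
}
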