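# Layer catalog: which gridded products exist, on what grids, at what
# spatial/temporal grains, and which raster file holds a given timestamp.

TEMPORAL_GRAINS <- c("static", "annual", "monthly", "sixteen_day", "daily")

#' Describe one environmental layer
#'
#' A layer spec records everything the annotation engine needs to know about
#' a gridded environmental product: its grain in space (pixel size in meters)
#' and time (how often scenes are sampled), the sentinel used for missing
#' pixels, the physically plausible value range used for quality screening,
#' and a strftime-style path template locating the raster file for a
#' timestamp.
#'
#' @param name Unique layer identifier (used in results and scene keys).
#' @param variable What the layer measures, free text (e.g. "EVI", "LST Day").
#' @param spatial_grain_m Pixel size in meters; positive.
#' @param temporal_grain One of `"static"`, `"annual"`, `"monthly"`,
#'   `"sixteen_day"`, `"daily"`. Static products have a single undated scene.
#' @param units Measurement units, free text.
#' @param nodata_value Sentinel marking missing pixels in raster files, or
#'   `NULL` if files never contain one.
#' @param valid_range Length-2 numeric `c(min, max)` outside which values are
#'   discarded as bad quality, or `NULL` for no screening.
#' @param scale_factor Multiplier applied to raw file values at read time so
#'   all downstream statistics are on the physical scale. Default 1.
#' @param date_coverage Length-2 `Date` (or ISO-8601 strings) giving the
#'   first and last available timestamp. Must be `NULL` for static layers.
#' @param path_template Path, relative to the catalog root, of the raster
#'   file for a timestamp; strftime tokens (`%Y`, `%m`, `%d`) are expanded.
#'   Static layers use a plain path.
#' @param citation Citation string carried into results bundle metadata.
#' @return An object of class `"layer_spec"`.
#' @export
layer_spec <- function(name, variable = name, spatial_grain_m, temporal_grain,
                       units = "", nodata_value = NULL, valid_range = NULL,
                       scale_factor = 1, date_coverage = NULL,
                       path_template = NULL, citation = "") {
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    stop_validation("layer name must be a non-empty string")
  if (!is.numeric(spatial_grain_m) || length(spatial_grain_m) != 1L ||
      !is.finite(spatial_grain_m) || spatial_grain_m <= 0)
    stop_validation(sprintf("layer '%s': spatial_grain_m must be a positive number", name))
  if (!is.character(temporal_grain) || length(temporal_grain) != 1L ||
      !temporal_grain %in% TEMPORAL_GRAINS)
    stop_validation(sprintf(
      "layer '%s': unknown temporal_grain '%s' (expected one of %s)",
      name, as.character(temporal_grain)[1L], paste(TEMPORAL_GRAINS, collapse = ", ")))
  if (!is.null(valid_range)) {
    valid_range <- as.numeric(valid_range)
    if (length(valid_range) != 2L || anyNA(valid_range) || valid_range[1L] > valid_range[2L])
      stop_validation(sprintf("layer '%s': valid_range must satisfy min <= max", name))
  }
  if (temporal_grain == "static") {
    if (!is.null(date_coverage))
      stop_validation(sprintf("layer '%s': static layers carry no date_coverage", name))
  } else {
    if (is.null(date_coverage))
      stop_validation(sprintf("layer '%s': %s layers need date_coverage", name, temporal_grain))
    date_coverage <- as.Date(date_coverage)
    if (length(date_coverage) != 2L || anyNA(date_coverage) ||
        date_coverage[1L] > date_coverage[2L])
      stop_validation(sprintf("layer '%s': date_coverage must be [first, last]", name))
  }
  structure(list(
    name = name, variable = variable, spatial_grain_m = spatial_grain_m,
    temporal_grain = temporal_grain, units = units,
    nodata_value = if (is.null(nodata_value)) NULL else as.numeric(nodata_value),
    valid_range = valid_range, scale_factor = as.numeric(scale_factor),
    date_coverage = date_coverage, path_template = path_template,
    citation = citation
  ), class = "layer_spec")
}

#' @export
print.layer_spec <- function(x, ...) {
  cov <- if (is.null(x$date_coverage)) "static" else
    paste(format(x$date_coverage), collapse = " .. ")
  cat(sprintf("<layer_spec> %s (%s), %g m, %s, %s\n",
              x$name, x$variable, x$spatial_grain_m, x$temporal_grain, cov))
  invisible(x)
}

#' Define a north-up geographic grid
#'
#' Grids are in WGS84 geographic coordinates with square cells in degrees,
#' row 1 at the north edge, column 1 at the west edge. Cell `(i, j)` covers
#' the half-open box `[origin_lon + (j-1)s, origin_lon + j*s)` in longitude
#' and `(origin_lat - i*s, origin_lat - (i-1)s]` in latitude, so every point
#' in the extent maps to exactly one cell and boundary points are assigned
#' east/south.
#'
#' @param origin_lon,origin_lat Top-left (north-west) corner in degrees.
#' @param cell_size_deg Cell edge in degrees; positive.
#' @param n_rows,n_cols Grid dimensions; positive integers.
#' @return An object of class `"grid_geometry"`.
#' @export
grid_geometry <- function(origin_lon, origin_lat, cell_size_deg, n_rows, n_cols) {
  if (!is.numeric(cell_size_deg) || cell_size_deg <= 0)
    stop_validation("cell_size_deg must be positive")
  n_rows <- as.integer(n_rows); n_cols <- as.integer(n_cols)
  if (is.na(n_rows) || is.na(n_cols) || n_rows < 1L || n_cols < 1L)
    stop_validation("grid must have at least one row and one column")
  structure(list(origin_lon = as.numeric(origin_lon),
                 origin_lat = as.numeric(origin_lat),
                 cell_size_deg = as.numeric(cell_size_deg),
                 n_rows = n_rows, n_cols = n_cols),
            class = "grid_geometry")
}

#' @export
print.grid_geometry <- function(x, ...) {
  cat(sprintf("<grid_geometry> %d x %d cells of %g deg, NW corner (%g, %g)\n",
              x$n_rows, x$n_cols, x$cell_size_deg, x$origin_lon, x$origin_lat))
  invisible(x)
}

#' One layer's grid of values at one timestamp
#'
#' @param layer A [layer_spec()].
#' @param timestamp A `Date`, or `NA` for a static scene.
#' @param geometry A [grid_geometry()].
#' @param values Numeric matrix `n_rows x n_cols`; `NA` marks nodata. Values
#'   are on the physical scale (scale factor already applied).
#' @return An object of class `"raster_scene"`.
#' @export
raster_scene <- function(layer, timestamp, geometry, values) {
  stopifnot(inherits(layer, "layer_spec"), inherits(geometry, "grid_geometry"))
  values <- as.matrix(values)
  if (nrow(values) != geometry$n_rows || ncol(values) != geometry$n_cols)
    stop_validation(sprintf(
      "scene values are %d x %d but geometry declares %d x %d",
      nrow(values), ncol(values), geometry$n_rows, geometry$n_cols))
  structure(list(layer = layer,
                 timestamp = if (is.na(timestamp)) as.Date(NA) else as.Date(timestamp),
                 geometry = geometry, values = values),
            class = "raster_scene")
}

#' Canonical identity of one retrievable scene
#'
#' Retrieval accounting counts distinct keys; two keys are equal iff layer
#' name, timestamp (or the static marker) and tile identifier all match.
#'
#' @param layer_name Layer identifier.
#' @param timestamp `Date` or `NA` (static).
#' @param tile Optional tile identifier (a geohash cell); `NA` for the whole
#'   scene.
#' @return Character key(s), one per timestamp.
#' @export
scene_key <- function(layer_name, timestamp, tile = NA_character_) {
  ts <- ifelse(is.na(timestamp), "static", format(as.Date(timestamp), "%Y-%m-%d"))
  tl <- ifelse(is.na(tile), "-", as.character(tile))
  paste(layer_name, ts, tl, sep = "|")
}

#' All catalog timestamps of a layer
#'
#' Derived from `date_coverage` and the temporal grain: daily layers have one
#' scene per day; sixteen-day layers one per 16 days from the first date;
#' monthly layers one on the first of each month; annual layers one on
#' January 1 of each covered year; static layers a single `NA` marker.
#'
#' @param layer A [layer_spec()].
#' @return A `Date` vector (length 1 `NA` for static layers).
#' @export
layer_timestamps <- function(layer) {
  stopifnot(inherits(layer, "layer_spec"))
  if (layer$temporal_grain == "static") return(as.Date(NA))
  first <- layer$date_coverage[1L]; last <- layer$date_coverage[2L]
  switch(layer$temporal_grain,
    daily = seq(first, last, by = "1 day"),
    sixteen_day = seq(first, last, by = "16 days"),
    monthly = {
      ts <- seq(as.Date(format(first, "%Y-%m-01")), last, by = "1 month")
      ts[ts >= first & ts <= last]
    },
    annual = {
      yrs <- seq(as.integer(format(first, "%Y")), as.integer(format(last, "%Y")))
      as.Date(sprintf("%d-01-01", yrs))
    })
}

#' Which scene timestamps serve a temporal window
#'
#' Daily layers return every window day inside the layer's coverage;
#' sixteen-day and monthly layers return the catalog timestamps that fall
#' inside the window (which may be none: a 7-day window can miss a 16-day
#' sampling interval entirely); annual layers return the single scene whose
#' calendar year contains the window's anchor date, ignoring the buffer;
#' static layers return their single marker regardless of window.
#'
#' @param layer A [layer_spec()].
#' @param window A [temporal_window()].
#' @return `Date` vector, possibly empty; `NA` marker for static. An empty
#'   result is not an error — it signals a missing value downstream.
#' @export
resolve_scene_dates <- function(layer, window) {
  stopifnot(inherits(layer, "layer_spec"), inherits(window, "temporal_window"))
  if (layer$temporal_grain == "static") return(as.Date(NA))
  ts <- layer_timestamps(layer)
  switch(layer$temporal_grain,
    daily = window$days[window$days %in% ts],
    sixteen_day = ,
    monthly = ts[ts >= window$days[1L] & ts <= window$days[length(window$days)]],
    annual = ts[format(ts, "%Y") == format(window$anchor_date, "%Y")])
}

#' Map a coordinate to its grid cell
#'
#' Uses the half-open cell convention of [grid_geometry()]: a point on a
#' shared cell edge belongs to the cell to its east/south, so every point
#' maps to exactly one cell. The grid's own north and west outer edges are
#' part of the extent; the south and east outer edges are not. Returns
#' 1-based `(row, col)`.
#'
#' @param geometry A [grid_geometry()].
#' @param lon,lat Coordinate in degrees.
#' @return Integer `c(row, col)`, or `c(NA, NA)` when outside the extent.
#' @export
containing_cell <- function(geometry, lon, lat) {
  s <- geometry$cell_size_deg
  col <- floor((lon - geometry$origin_lon) / s) + 1
  row <- floor((geometry$origin_lat - lat) / s) + 1
  # lat exactly on the north edge of a cell belongs to that cell (closed top):
  # (origin_lat - lat)/s integral means floor() already lands one row south,
  # which is correct for interior edges; the grid's own north edge (lat ==
  # origin_lat) gives row 1 as required.
  if (is.na(row) || is.na(col) || row < 1 || col < 1 ||
      row > geometry$n_rows || col > geometry$n_cols)
    return(c(NA_integer_, NA_integer_))
  c(as.integer(row), as.integer(col))
}

#' Center coordinate of a grid cell
#'
#' @param geometry A [grid_geometry()].
#' @param row,col 1-based cell indices (vectors allowed).
#' @return List with numeric `lon` and `lat` vectors.
#' @export
cell_center <- function(geometry, row, col) {
  s <- geometry$cell_size_deg
  list(lon = geometry$origin_lon + (col - 0.5) * s,
       lat = geometry$origin_lat - (row - 0.5) * s)
}

#' Load a layer catalog from a config file
#'
#' The config is YAML (or JSON, by file extension) with a top-level `layers`
#' list; each entry carries the [layer_spec()] fields (`nodata`,
#' `valid_range`, `scale_factor`, `date_coverage`, `path_template`,
#' `citation` optional). Order is preserved.
#'
#' @param config_path Path to the catalog config.
#' @return Named list of [layer_spec()] objects, in config order.
#' @export
load_catalog <- function(config_path) {
  if (!file.exists(config_path))
    stop_config(sprintf("catalog config not found: %s", config_path))
  cfg <- if (grepl("\\.json$", config_path, ignore.case = TRUE))
    jsonlite::read_json(config_path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  else yaml::read_yaml(config_path)
  if (is.null(cfg$layers) || !length(cfg$layers))
    stop_config(sprintf("catalog config has no 'layers' entry: %s", config_path))
  specs <- lapply(cfg$layers, function(l) {
    layer_spec(name = l$name,
               variable = if (is.null(l$variable)) l$name else l$variable,
               spatial_grain_m = l$spatial_grain_m,
               temporal_grain = l$temporal_grain,
               units = if (is.null(l$units)) "" else l$units,
               nodata_value = l$nodata,
               valid_range = if (is.null(l$valid_range)) NULL else unlist(l$valid_range),
               scale_factor = if (is.null(l$scale_factor)) 1 else l$scale_factor,
               date_coverage = if (is.null(l$date_coverage)) NULL else unlist(l$date_coverage),
               path_template = l$path_template,
               citation = if (is.null(l$citation)) "" else l$citation)
  })
  names(specs) <- vapply(specs, `[[`, "", "name")
  specs
}

# ---- condition helpers -----------------------------------------------------

stop_validation <- function(msg) {
  stop(structure(class = c("spatannot_validation_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1L))))
}

stop_config <- function(msg) {
  stop(structure(class = c("spatannot_config_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1L))))
}

stop_out_of_extent <- function(msg) {
  stop(structure(class = c("spatannot_out_of_extent", "error", "condition"),
                 list(message = msg, call = sys.call(-1L))))
}
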