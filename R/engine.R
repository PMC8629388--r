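# Core annotation engine: scene stores with retrieval accounting, zonal
# statistics under a buffer mask, and the per-record / whole-dataset
# (naive) annotation drivers.

#' Validate an annotation request
#'
#' @param layers Character vector of layer names, at least one.
#' @param spatial_buffer_m Spatial buffer radius in meters, `>= 0`.
#' @param temporal_buffer_days Temporal buffer in days, `>= 1` (the day of
#'   observation counts, so the minimum is 1).
#' @param max_spatial_buffer_m,max_temporal_buffer_days Configurable caps
#'   guarding against accidentally enormous jobs (the pixel count grows with
#'   the square of the spatial radius).
#' @return An object of class `"annotation_request"`.
#' @export
annotation_request <- function(layers, spatial_buffer_m = 0,
                               temporal_buffer_days = 1L,
                               max_spatial_buffer_m = 10000,
                               max_temporal_buffer_days = 365L) {
  if (!is.character(layers) || length(layers) < 1L)
    stop_validation("request needs at least one layer name")
  if (!is.numeric(spatial_buffer_m) || is.na(spatial_buffer_m) || spatial_buffer_m < 0)
    stop_validation("spatial buffer must be a non-negative number of meters")
  temporal_buffer_days <- suppressWarnings(as.integer(temporal_buffer_days))
  if (is.na(temporal_buffer_days) || temporal_buffer_days < 1L)
    stop_validation("temporal buffer must be at least 1 day (minimum is 1)")
  if (spatial_buffer_m > max_spatial_buffer_m)
    stop_validation(sprintf("spatial buffer %g m exceeds the configured maximum %g m",
                            spatial_buffer_m, max_spatial_buffer_m))
  if (temporal_buffer_days > max_temporal_buffer_days)
    stop_validation(sprintf("temporal buffer %d days exceeds the configured maximum %d days",
                            temporal_buffer_days, max_temporal_buffer_days))
  structure(list(layers = layers, spatial_buffer_m = spatial_buffer_m,
                 temporal_buffer_days = temporal_buffer_days),
            class = "annotation_request")
}

# ---- scene stores ----------------------------------------------------------

#' In-memory scene store
#'
#' A scene store answers scene (or scene-tile) fetch requests and counts
#' them; the count is the unit of retrieval cost that the clustering planner
#' minimizes. The memory store serves scenes generated by
#' [make_layer_series()].
#'
#' @param series One result of [make_layer_series()], or a list of them.
#' @return An object of class `c("memory_scene_store", "scene_store")`.
#' @export
memory_scene_store <- function(series) {
  if (!is.null(series$layer)) series <- list(series)
  env <- new.env(parent = emptyenv())
  env$scenes <- list()
  env$layers <- list()
  for (s in series) {
    env$layers[[s$layer$name]] <- s$layer
    env$scenes[names(s$scenes)] <- s$scenes
  }
  env$count <- 0L
  structure(env, class = c("memory_scene_store", "scene_store"))
}

#' Disk-backed scene store
#'
#' Reads ASCII-grid rasters on demand, locating each scene through the
#' layer's strftime path template relative to `root`. Every file read is one
#' counted retrieval.
#'
#' @param catalog Named list of [layer_spec()] (from [load_catalog()]).
#' @param root Directory the path templates are relative to.
#' @return An object of class `c("disk_scene_store", "scene_store")`.
#' @export
disk_scene_store <- function(catalog, root = ".") {
  env <- new.env(parent = emptyenv())
  env$layers <- catalog
  env$root <- root
  env$geom_cache <- list()
  env$count <- 0L
  structure(env, class = c("disk_scene_store", "scene_store"))
}

store_layer <- function(store, layer_name) {
  sp <- store$layers[[layer_name]]
  if (is.null(sp)) stop_config(sprintf("layer '%s' is not in the store's catalog", layer_name))
  sp
}

scene_path <- function(store, layer, timestamp) {
  rel <- if (is.na(timestamp)) layer$path_template else format(timestamp, layer$path_template)
  file.path(store$root, rel)
}

#' Number of retrievals a store has served
#' @param store A scene store.
#' @return Integer count.
#' @export
store_fetch_count <- function(store) store$count

#' Reset a store's retrieval counter
#' @param store A scene store.
#' @return Invisibly, the store.
#' @export
reset_fetch_count <- function(store) { store$count <- 0L; invisible(store) }

#' Grid geometry of a layer in a store
#'
#' Metadata lookup; does not count as a scene retrieval.
#' @param store A scene store.
#' @param layer_name Layer identifier.
#' @return A [grid_geometry()].
#' @export
store_geometry <- function(store, layer_name) {
  layer <- store_layer(store, layer_name)
  if (inherits(store, "memory_scene_store")) {
    k <- scene_key(layer_name, layer_timestamps(layer)[1L])
    return(store$scenes[[k]]$geometry)
  }
  if (!is.null(store$geom_cache[[layer_name]]))
    return(store$geom_cache[[layer_name]])
  ts <- layer_timestamps(layer)[1L]
  sc <- read_ascii_grid(scene_path(store, layer, ts), layer, ts)
  store$geom_cache[[layer_name]] <- sc$geometry
  sc$geometry
}

#' Fetch one whole scene (counted)
#'
#' @param store A scene store.
#' @param layer_name Layer identifier.
#' @param timestamp `Date`, or `NA` for a static layer's single scene.
#' @return A [raster_scene()], or `NULL` if the scene does not exist.
#' @export
fetch_scene <- function(store, layer_name, timestamp) {
  store$count <- store$count + 1L
  layer <- store_layer(store, layer_name)
  if (inherits(store, "memory_scene_store")) {
    store$scenes[[scene_key(layer_name, timestamp)]]
  } else {
    p <- scene_path(store, layer, timestamp)
    if (!file.exists(p)) return(NULL)
    read_ascii_grid(p, layer, timestamp)
  }
}

#' Fetch one scene tile (counted)
#'
#' Retrieves the sub-grid of a scene covering a bounding box (clipped to the
#' scene extent). The clustered driver fetches buffer-padded geohash tiles
#' through this call, so each counted retrieval is one (layer, timestamp,
#' tile) unit.
#'
#' @param store A scene store.
#' @param layer_name Layer identifier.
#' @param timestamp `Date` or `NA`.
#' @param bbox Numeric `c(lon_min, lon_max, lat_min, lat_max)`.
#' @return A cropped [raster_scene()] with shifted origin, or `NULL`.
#' @export
fetch_scene_tile <- function(store, layer_name, timestamp, bbox) {
  sc <- fetch_scene(store, layer_name, timestamp)
  if (is.null(sc)) return(NULL)
  crop_scene(sc, bbox)
}

crop_scene <- function(scene, bbox) {
  g <- scene$geometry
  s <- g$cell_size_deg
  c1 <- max(1L, as.integer(floor((bbox[1L] - g$origin_lon) / s)) + 1L)
  c2 <- min(g$n_cols, as.integer(ceiling((bbox[2L] - g$origin_lon) / s)))
  r1 <- max(1L, as.integer(floor((g$origin_lat - bbox[4L]) / s)) + 1L)
  r2 <- min(g$n_rows, as.integer(ceiling((g$origin_lat - bbox[3L]) / s)))
  if (c1 > c2 || r1 > r2) return(NULL)
  sub <- grid_geometry(origin_lon = g$origin_lon + (c1 - 1L) * s,
                       origin_lat = g$origin_lat - (r1 - 1L) * s,
                       cell_size_deg = s,
                       n_rows = r2 - r1 + 1L, n_cols = c2 - c1 + 1L)
  raster_scene(scene$layer, scene$timestamp, sub,
               scene$values[r1:r2, c1:c2, drop = FALSE])
}

# ---- zonal statistics ------------------------------------------------------

# valid values of a scene under a mask: not nodata, inside valid_range
scene_mask_values <- function(scene, mask) {
  v <- scene$values[mask$cells]
  v <- v[!is.na(v)]
  vr <- scene$layer$valid_range
  if (!is.null(vr)) v <- v[v >= vr[1L] & v <= vr[2L]]
  v
}

#' Zonal accumulators of one scene under a buffer mask
#'
#' Accumulates over mask cells whose value is present (not nodata) and
#' inside the layer's valid range — range screening doubles as the quality
#' control step of the annotation workflow.
#'
#' @param scene A [raster_scene()].
#' @param mask A [spatial_buffer_mask()] in the scene's geometry.
#' @return List with `sum`, `sum_sq`, `n_valid`. An all-nodata mask returns
#'   `(0, 0, 0)`.
#' @export
zonal_stats <- function(scene, mask) {
  v <- scene_mask_values(scene, mask)
  list(sum = sum(v), sum_sq = sum(v * v), n_valid = length(v))
}

# ---- per-record annotation -------------------------------------------------

empty_results <- function() {
  data.frame(record_id = character(0), layer = character(0),
             spatial_buffer_m = numeric(0), temporal_buffer_days = integer(0),
             value_mean = numeric(0), value_stdev = numeric(0),
             valid_sample_count = integer(0), scenes_used = integer(0),
             status = character(0), stringsAsFactors = FALSE)
}

result_row <- function(id, layer_name, request, mean = NA_real_, sd = NA_real_,
                       n = 0L, scenes = 0L, status) {
  data.frame(record_id = id, layer = layer_name,
             spatial_buffer_m = request$spatial_buffer_m,
             temporal_buffer_days = request$temporal_buffer_days,
             value_mean = mean, value_stdev = sd,
             valid_sample_count = as.integer(n), scenes_used = as.integer(scenes),
             status = status, stringsAsFactors = FALSE)
}

summarize_samples <- function(id, layer_name, request, values, scenes_used,
                              had_scenes) {
  n <- length(values)
  if (n == 0L) {
    status <- if (had_scenes) "no_valid_data" else "out_of_coverage"
    return(result_row(id, layer_name, request, status = status))
  }
  result_row(id, layer_name, request,
             mean = mean(values),
             sd = if (n >= 2L) stats::sd(values) else NA_real_,
             n = n, scenes = scenes_used, status = "ok")
}

#' Annotate one record against one layer
#'
#' Resolves the scene timestamps serving the record's temporal window,
#' applies the spatial buffer mask to each scene, pools all valid pixel-day
#' samples across scenes, and reports the pooled mean, sample (n-1)
#' standard deviation, valid sample count and number of contributing
#' scenes. Statuses: `ok` (at least one valid sample), `no_valid_data`
#' (scenes existed but every masked pixel was nodata or out of range),
#' `out_of_coverage` (no scene timestamp falls in the window — e.g. a short
#' window missing a 16-day sampling interval), `out_of_extent` (coordinates
#' outside the layer grid; never an exception on the dataset path).
#'
#' @param record One-row data frame (or list) with `id`, `longitude`,
#'   `latitude`, `event_date`.
#' @param layer A [layer_spec()] (must be in the store's catalog).
#' @param request An [annotation_request()].
#' @param store A scene store.
#' @return One-row result data frame.
#' @export
annotate_record <- function(record, layer, request, store) {
  window <- temporal_window(record$event_date, request$temporal_buffer_days)
  dates <- resolve_scene_dates(layer, window)
  geom <- store_geometry(store, layer$name)
  cc <- containing_cell(geom, record$longitude, record$latitude)
  if (is.na(cc[1L]))
    return(result_row(record$id, layer$name, request, status = "out_of_extent"))
  if (length(dates) == 0L)
    return(result_row(record$id, layer$name, request, status = "out_of_coverage"))
  mask <- spatial_buffer_mask(geom, record$longitude, record$latitude,
                              request$spatial_buffer_m)
  values <- numeric(0)
  scenes_used <- 0L
  had_scenes <- FALSE
  for (d in as.list(dates)) {
    sc <- fetch_scene(store, layer$name, d)
    if (is.null(sc)) next
    had_scenes <- TRUE
    v <- scene_mask_values(sc, mask)
    if (length(v)) {
      values <- c(values, v)
      scenes_used <- scenes_used + 1L
    }
  }
  summarize_samples(record$id, layer$name, request, values, scenes_used, had_scenes)
}

#' Naive whole-dataset annotation
#'
#' Iterates record by record, fetching one scene per (record, layer,
#' resolved timestamp) — the simple iterative baseline whose retrieval count
#' the clustering planner improves on. Statistics are exactly those of
#' [annotate_record()] applied independently.
#'
#' @param records Occurrence data frame (`id`, `longitude`, `latitude`,
#'   `event_date`).
#' @param layers List of [layer_spec()] (or a single spec).
#' @param request An [annotation_request()].
#' @param store A scene store.
#' @return List with `results` (one row per record x layer, input order,
#'   record-major) and `account` (list with `naive_count`, the number of
#'   scene retrievals performed).
#' @export
annotate_naive <- function(records, layers, request, store) {
  if (inherits(layers, "layer_spec")) layers <- list(layers)
  if (nrow(records) == 0L)
    return(list(results = empty_results(), account = list(naive_count = 0L,
                                                          clustered_count = NA_integer_)))
  before <- store_fetch_count(store)
  rows <- vector("list", nrow(records) * length(layers))
  k <- 0L
  for (i in seq_len(nrow(records))) {
    for (layer in layers) {
      k <- k + 1L
      rows[[k]] <- annotate_record(records[i, ], layer, request, store)
    }
  }
  list(results = do.call(rbind, rows),
       account = list(naive_count = store_fetch_count(store) - before,
                      clustered_count = NA_integer_))
}
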