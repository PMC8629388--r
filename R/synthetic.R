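# Synthetic landscapes and occurrence sets with known generating structure,
# so the annotation engine can be tested against closed forms.

#' Parameters of a synthetic layer series
#'
#' The noise-free generating surface is
#' `g(cell, day) = base_level + seasonal_amplitude * cos(2*pi*(doy - seasonal_peak_day)/365)
#'  + spatial_gradient * (col - 1) + heterogeneity(cell)`
#' where `doy` is the day of year (leap day 366 reuses 365) and
#' `heterogeneity` is a static per-cell Gaussian field with standard
#' deviation `heterogeneity_sd`. Each scene adds i.i.d. Gaussian noise with
#' sd `noise_sd` and masks each pixel to nodata independently with
#' probability `cloud_fraction` (emulating cloud-mask missingness).
#'
#' @param geometry A [grid_geometry()].
#' @param temporal_grain Temporal grain of the series (see [layer_spec()]).
#' @param date_range Length-2 dates; ignored (`NULL`) for static.
#' @param base_level Baseline value, layer units.
#' @param seasonal_amplitude Amplitude of the annual cosine cycle.
#' @param seasonal_peak_day Day of year (1..366) where the cycle peaks.
#' @param spatial_gradient Value increase per column moving east.
#' @param heterogeneity_sd Sd of the static per-cell Gaussian field; `>= 0`.
#' @param noise_sd Sd of per-scene pixel noise; `>= 0`.
#' @param cloud_fraction Probability a pixel is cloud-masked, in `[0, 1]`.
#' @param name Layer name for the generated [layer_spec()].
#' @param spatial_grain_m Nominal pixel size in meters for the spec.
#' @param valid_range Optional valid range recorded on the spec.
#' @param seed Integer seed; identical seeds give identical output.
#' @return An object of class `"synth_layer_params"`.
#' @export
synth_layer_params <- function(geometry, temporal_grain = "daily",
                               date_range = NULL, base_level = 0.4,
                               seasonal_amplitude = 0.2, seasonal_peak_day = 182L,
                               spatial_gradient = 0, heterogeneity_sd = 0,
                               noise_sd = 0, cloud_fraction = 0,
                               name = "synth", spatial_grain_m = 250,
                               valid_range = NULL, seed = 1L) {
  stopifnot(inherits(geometry, "grid_geometry"))
  if (geometry$n_rows < 1L || geometry$n_cols < 1L)
    stop_validation("degenerate geometry: need at least one row and column")
  if (!is.numeric(cloud_fraction) || cloud_fraction < 0 || cloud_fraction > 1)
    stop_validation("cloud_fraction must lie in [0, 1]")
  if (heterogeneity_sd < 0 || noise_sd < 0)
    stop_validation("heterogeneity_sd and noise_sd must be non-negative")
  if (!seasonal_peak_day %in% 1:366)
    stop_validation("seasonal_peak_day must be in 1..366")
  if (temporal_grain != "static") {
    if (is.null(date_range)) stop_validation("date_range required for dynamic series")
    date_range <- as.Date(date_range)
  } else date_range <- NULL
  structure(list(geometry = geometry, temporal_grain = temporal_grain,
                 date_range = date_range, base_level = base_level,
                 seasonal_amplitude = seasonal_amplitude,
                 seasonal_peak_day = as.integer(seasonal_peak_day),
                 spatial_gradient = spatial_gradient,
                 heterogeneity_sd = heterogeneity_sd, noise_sd = noise_sd,
                 cloud_fraction = cloud_fraction, name = name,
                 spatial_grain_m = spatial_grain_m, valid_range = valid_range,
                 seed = as.integer(seed)),
            class = "synth_layer_params")
}

# day of year with the 365-day cosine convention: day 366 reuses 365
day_of_year365 <- function(date) pmin(as.integer(format(as.Date(date), "%j")), 365L)

#' Generate a synthetic layer series
#'
#' Produces one [raster_scene()] per catalog timestamp of the implied layer
#' spec, plus the noise-free generating function `g(row, col, date)` for
#' closed-form checks. Fully reproducible under the seed.
#'
#' @param params A [synth_layer_params()].
#' @return List with `layer` (the [layer_spec()]), `scenes` (list of scenes
#'   keyed by [scene_key()] without tile), `g` (function `(row, col, date)`),
#'   and `heterogeneity` (the static field matrix).
#' @export
make_layer_series <- function(params) {
  stopifnot(inherits(params, "synth_layer_params"))
  geom <- params$geometry
  spec <- layer_spec(name = params$name, variable = params$name,
                     spatial_grain_m = params$spatial_grain_m,
                     temporal_grain = params$temporal_grain,
                     valid_range = params$valid_range,
                     date_coverage = params$date_range,
                     path_template = if (params$temporal_grain == "static")
                       paste0(params$name, ".asc")
                     else file.path(params$name, "%Y-%m-%d.asc"),
                     citation = "synthetic layer series (spatannot generator)")
  ts <- layer_timestamps(spec)
  nr <- geom$n_rows; nc <- geom$n_cols
  out <- withr::with_seed(params$seed, {
    het <- if (params$heterogeneity_sd > 0)
      matrix(stats::rnorm(nr * nc, 0, params$heterogeneity_sd), nr, nc)
    else matrix(0, nr, nc)
    grad <- matrix(rep(params$spatial_gradient * (seq_len(nc) - 1), each = nr), nr, nc)
    seasonal <- function(date) {
      if (is.na(date)) 0
      else params$seasonal_amplitude *
        cos(2 * pi * (day_of_year365(date) - params$seasonal_peak_day) / 365)
    }
    scenes <- lapply(ts, function(d) {
      vals <- params$base_level + seasonal(d) + grad + het
      if (params$noise_sd > 0)
        vals <- vals + matrix(stats::rnorm(nr * nc, 0, params$noise_sd), nr, nc)
      if (params$cloud_fraction > 0) {
        cloud <- matrix(stats::runif(nr * nc) < params$cloud_fraction, nr, nc)
        vals[cloud] <- NA_real_
      }
      raster_scene(spec, d, geom, vals)
    })
    names(scenes) <- scene_key(spec$name, ts)
    list(scenes = scenes, het = het)
  })
  g <- local({
    base <- params$base_level; amp <- params$seasonal_amplitude
    peak <- params$seasonal_peak_day; gradient <- params$spatial_gradient
    het <- out$het; static <- params$temporal_grain == "static"
    function(row, col, date) {
      seas <- if (static || is.na(as.Date(date))) 0
      else amp * cos(2 * pi * (day_of_year365(date) - peak) / 365)
      base + seas + gradient * (col - 1) + het[cbind(row, col)]
    }
  })
  list(layer = spec, scenes = out$scenes, g = g, heterogeneity = out$het)
}

#' Parameters of a synthetic occurrence set
#'
#' @param n_records Positive integer.
#' @param extent Numeric `c(lon_min, lon_max, lat_min, lat_max)`.
#' @param date_range Length-2 dates.
#' @param clustering `"uniform"` (i.i.d. uniform positions and dates) or
#'   `"colocated"` (all records share one position and one date — the shape
#'   of a dense citizen-science hotspot on a single day).
#' @param seed Integer seed.
#' @return An object of class `"synth_occurrence_params"`.
#' @export
synth_occurrence_params <- function(n_records, extent, date_range,
                                    clustering = c("uniform", "colocated"),
                                    seed = 1L) {
  n_records <- as.integer(n_records)
  if (is.na(n_records) || n_records < 1L)
    stop_validation("n_records must be a positive integer")
  extent <- as.numeric(extent)
  if (length(extent) != 4L || extent[1L] >= extent[2L] || extent[3L] >= extent[4L])
    stop_validation("extent must be c(lon_min, lon_max, lat_min, lat_max) with min < max")
  structure(list(n_records = n_records, extent = extent,
                 date_range = as.Date(date_range),
                 clustering = match.arg(clustering), seed = as.integer(seed)),
            class = "synth_occurrence_params")
}

#' Generate a synthetic occurrence set
#'
#' @param params A [synth_occurrence_params()].
#' @return A data frame with columns `id`, `longitude`, `latitude`,
#'   `event_date` (class `Date`).
#' @export
make_occurrences <- function(params) {
  stopifnot(inherits(params, "synth_occurrence_params"))
  n <- params$n_records; e <- params$extent
  d0 <- params$date_range[1L]; d1 <- params$date_range[2L]
  withr::with_seed(params$seed, {
    if (params$clustering == "colocated") {
      lon <- rep(stats::runif(1L, e[1L], e[2L]), n)
      lat <- rep(stats::runif(1L, e[3L], e[4L]), n)
      dates <- rep(d0 + sample.int(as.integer(d1 - d0) + 1L, 1L) - 1L, n)
    } else {
      lon <- stats::runif(n, e[1L], e[2L])
      lat <- stats::runif(n, e[3L], e[4L])
      dates <- d0 + sample.int(as.integer(d1 - d0) + 1L, n, replace = TRUE) - 1L
    }
    data.frame(id = sprintf("occ%05d", seq_len(n)),
               longitude = lon, latitude = lat, event_date = dates,
               stringsAsFactors = FALSE)
  })
}

#' Write a synthetic series to disk as a catalog + ASCII-grid rasters
#'
#' Writes one `.asc` file per scene under `dir` following the layer's path
#' template, plus a `catalog.yaml` describing the series, so the disk-backed
#' scene store and the CLI can operate on it.
#'
#' @param series Result of [make_layer_series()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the catalog config path.
#' @export
write_layer_series <- function(series, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  spec <- series$layer
  for (sc in series$scenes) {
    rel <- if (is.na(sc$timestamp)) spec$path_template
    else format(sc$timestamp, spec$path_template)
    path <- file.path(dir, rel)
    dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
    write_ascii_grid(sc, path)
  }
  cfg <- list(layers = list(list(
    name = spec$name, variable = spec$variable,
    spatial_grain_m = spec$spatial_grain_m,
    temporal_grain = spec$temporal_grain, units = spec$units,
    nodata = -9999,
    valid_range = if (is.null(spec$valid_range)) NULL else as.list(spec$valid_range),
    scale_factor = 1,
    date_coverage = if (is.null(spec$date_coverage)) NULL
    else as.list(format(spec$date_coverage)),
    path_template = spec$path_template, citation = spec$citation)))
  cfg_path <- file.path(dir, "catalog.yaml")
  yaml::write_yaml(cfg, cfg_path)
  invisible(cfg_path)
}

#' Write an occurrence set as CSV
#'
#' @param occurrences Data frame from [make_occurrences()] (or compatible).
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_occurrences <- function(occurrences, path) {
  df <- data.frame(id = occurrences$id,
                   longitude = occurrences$longitude,
                   latitude = occurrences$latitude,
                   date = format(as.Date(occurrences$event_date)),
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
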