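# Spatial coarsening, temporal compositing, grain-agnostic annotation, and
# the cross-grain delta metrics used to diagnose scale dependence.

#' Coarsen scenes by integer block aggregation
#'
#' Each output cell is the mean of its `factor x factor` input block,
#' ignoring nodata; the output cell is nodata only when the whole block is.
#' Grids whose dimensions are not multiples of `factor` are trimmed at the
#' south and east edges (trimming is deterministic; padding would fabricate
#' data). The output layer's spatial grain is `factor` times the input's.
#'
#' @param scenes A list of [raster_scene()] (or a single scene).
#' @param factor Integer `>= 2`.
#' @return List of coarsened scenes (same order).
#' @export
coarsen_spatial <- function(scenes, factor) {
  factor <- as.integer(factor)
  if (is.na(factor) || factor < 2L)
    stop_validation("coarsening factor must be an integer >= 2")
  if (inherits(scenes, "raster_scene")) scenes <- list(scenes)
  lapply(scenes, function(sc) {
    g <- sc$geometry
    nr2 <- g$n_rows %/% factor
    nc2 <- g$n_cols %/% factor
    if (nr2 < 1L || nc2 < 1L)
      stop_validation("grid smaller than one coarse cell")
    m <- sc$values[seq_len(nr2 * factor), seq_len(nc2 * factor), drop = FALSE]
    a <- array(m, dim = c(factor, nr2, factor, nc2))
    sums <- apply(a, c(2L, 4L), function(b) sum(b, na.rm = TRUE))
    cnts <- apply(a, c(2L, 4L), function(b) sum(!is.na(b)))
    out <- sums / cnts
    out[cnts == 0L] <- NA_real_
    spec <- sc$layer
    spec$name <- paste0(spec$name, "_x", factor)
    spec$spatial_grain_m <- spec$spatial_grain_m * factor
    geom2 <- grid_geometry(g$origin_lon, g$origin_lat,
                           g$cell_size_deg * factor, nr2, nc2)
    raster_scene(spec, sc$timestamp, geom2, out)
  })
}

#' Specify a temporal composite
#'
#' @param mode `"long_term"` (one static layer averaging every source scene)
#'   or `"monthly_climatology"` (12 static layers, one per calendar month
#'   across all years; months with no source scenes are marked empty).
#' @param date_range Optional length-2 dates restricting the source scenes.
#' @return An object of class `"composite_spec"`.
#' @export
composite_spec <- function(mode = c("long_term", "monthly_climatology"),
                           date_range = NULL) {
  mode <- match.arg(mode)
  if (!is.null(date_range)) {
    date_range <- as.Date(date_range)
    if (length(date_range) != 2L || anyNA(date_range) || date_range[1L] > date_range[2L])
      stop_validation("composite date_range must be [first, last]")
  }
  structure(list(mode = mode, date_range = date_range), class = "composite_spec")
}

cellwise_mean <- function(scene_list) {
  sums <- NULL; cnts <- NULL
  for (sc in scene_list) {
    v <- sc$values
    ok <- !is.na(v)
    v[!ok] <- 0
    if (is.null(sums)) { sums <- v; cnts <- ok + 0 }
    else { sums <- sums + v; cnts <- cnts + ok }
  }
  out <- sums / cnts
  out[cnts == 0] <- NA_real_
  out
}

#' Composite a scene series into static layer(s)
#'
#' Per-cell mean across contributing scenes, nodata-excluded. Long-term
#' composites use every scene in range; monthly climatologies group scenes
#' by calendar month across years.
#'
#' @param scenes List of dated [raster_scene()] from one layer.
#' @param spec A [composite_spec()].
#' @return For `long_term`, a list with one static scene (named `"all"`);
#'   for `monthly_climatology`, a list of 12 entries named `"01"`..`"12"`,
#'   `NULL` for months with no source scenes.
#' @export
composite_layers <- function(scenes, spec) {
  stopifnot(inherits(spec, "composite_spec"))
  if (inherits(scenes, "raster_scene")) scenes <- list(scenes)
  if (!length(scenes)) stop_validation("no source scenes to composite")
  if (!is.null(spec$date_range)) {
    ts <- as.Date(vapply(scenes, function(s) format(s$timestamp), ""))
    scenes <- scenes[ts >= spec$date_range[1L] & ts <= spec$date_range[2L]]
    if (!length(scenes)) stop_validation("no source scenes inside composite date_range")
  }
  src <- scenes[[1L]]$layer
  make_static <- function(name_suffix, scene_subset) {
    sp <- src
    sp$name <- paste0(src$name, name_suffix)
    sp$temporal_grain <- "static"
    sp$date_coverage <- NULL
    sp$path_template <- paste0(sp$name, ".asc")
    raster_scene(sp, as.Date(NA), scene_subset[[1L]]$geometry,
                 cellwise_mean(scene_subset))
  }
  if (spec$mode == "long_term")
    return(list(all = make_static("_longterm", scenes)))
  months <- vapply(scenes, function(s) format(s$timestamp, "%m"), "")
  out <- stats::setNames(vector("list", 12L), sprintf("%02d", 1:12))
  for (m in sprintf("%02d", 1:12)) {
    sub <- scenes[months == m]
    if (length(sub)) out[[m]] <- make_static(paste0("_m", m), sub)
  }
  out
}

#' Grain-agnostic annotation against composite layer(s)
#'
#' The status-quo annotation the cross-grain diagnostics compare against:
#' each record is intersected with the grid cell containing it (no spatial
#' buffer) on a single composite layer. With `date_mode = "ignore_date"` the
#' long-term composite is used for every record; with `"match_month"` the
#' record's observation date is coarsened to its month and the monthly
#' climatology layer for that month is used.
#'
#' @param records Occurrence data frame.
#' @param composites Result of [composite_layers()].
#' @param date_mode `"ignore_date"` or `"match_month"`.
#' @return Data frame with `record_id`, `value`, `status` (`ok`,
#'   `no_valid_data` for a nodata cell or empty month layer,
#'   `out_of_extent`).
#' @export
annotate_grain_agnostic <- function(records, composites,
                                    date_mode = c("ignore_date", "match_month")) {
  date_mode <- match.arg(date_mode)
  if (date_mode == "ignore_date" && is.null(composites$all))
    stop_validation("ignore_date mode needs a long_term composite (entry 'all')")
  n <- nrow(records)
  value <- rep(NA_real_, n)
  status <- character(n)
  for (i in seq_len(n)) {
    sc <- if (date_mode == "ignore_date") composites$all
    else composites[[format(as.Date(records$event_date[i]), "%m")]]
    if (is.null(sc)) { status[i] <- "no_valid_data"; next }
    cc <- containing_cell(sc$geometry, records$longitude[i], records$latitude[i])
    if (is.na(cc[1L])) { status[i] <- "out_of_extent"; next }
    v <- sc$values[cc[1L], cc[2L]]
    vr <- sc$layer$valid_range
    if (!is.na(v) && !is.null(vr) && (v < vr[1L] || v > vr[2L])) v <- NA_real_
    if (is.na(v)) { status[i] <- "no_valid_data"; next }
    value[i] <- v
    status[i] <- "ok"
  }
  data.frame(record_id = records$id, value = value, status = status,
             stringsAsFactors = FALSE)
}

#' Cross-grain difference per record
#'
#' Inner-joins two per-record annotations on record id, keeping only
#' records valid under both (the standard practice for cross-buffer
#' comparisons, since larger buffers retrieve valid data more often), and
#' computes `delta = value_a - value_b` and its absolute value.
#'
#' @param results_a,results_b Data frames keyed by `record_id` with a value
#'   column (`value_mean` from the engine, or `value` from
#'   [annotate_grain_agnostic()]).
#' @param covariate Optional named numeric vector (names = record ids)
#'   carried into the output, e.g. habitat heterogeneity or day of year.
#' @return Data frame with `record_id`, `value_a`, `value_b`, `delta`,
#'   `abs_delta`, and `covariate` when supplied. Empty (with a warning)
#'   when the valid id sets are disjoint.
#' @export
cross_grain_delta <- function(results_a, results_b, covariate = NULL) {
  pick <- function(df) {
    vcol <- if ("value_mean" %in% names(df)) "value_mean" else "value"
    data.frame(record_id = df$record_id, value = df[[vcol]],
               stringsAsFactors = FALSE)
  }
  a <- pick(results_a); b <- pick(results_b)
  a <- a[!is.na(a$value), ]; b <- b[!is.na(b$value), ]
  m <- merge(a, b, by = "record_id", suffixes = c("_a", "_b"), sort = FALSE)
  if (nrow(m) == 0L) {
    warning("no records valid under both annotations; empty comparison")
    return(data.frame(record_id = character(0), value_a = numeric(0),
                      value_b = numeric(0), delta = numeric(0),
                      abs_delta = numeric(0), stringsAsFactors = FALSE))
  }
  out <- data.frame(record_id = m$record_id, value_a = m$value_a,
                    value_b = m$value_b, delta = m$value_a - m$value_b,
                    abs_delta = abs(m$value_a - m$value_b),
                    stringsAsFactors = FALSE)
  if (!is.null(covariate)) out$covariate <- unname(covariate[out$record_id])
  out[order(match(out$record_id, results_a$record_id)), , drop = FALSE]
}

#' Summarize cross-grain deltas
#'
#' The two summary forms used for scale-dependence diagnostics: the median
#' absolute delta and the fraction of records whose absolute delta exceeds
#' a stated threshold.
#'
#' @param comparison Result of [cross_grain_delta()].
#' @param threshold Exceedance threshold on `abs_delta`.
#' @return List with `n`, `median_abs_delta`, `exceedance_fraction`.
#' @export
delta_summary <- function(comparison, threshold = 0.2) {
  list(n = nrow(comparison),
       median_abs_delta = stats::median(comparison$abs_delta),
       exceedance_fraction = mean(comparison$abs_delta > threshold))
}

#' Write a comparison table as CSV
#'
#' @param comparison Result of [cross_grain_delta()].
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_comparison <- function(comparison, path) {
  utils::write.csv(comparison, path, row.names = FALSE, na = "")
  invisible(path)
}
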