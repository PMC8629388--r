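# Arc/Info ASCII Grid reader/writer: the plain-text raster interchange
# format used by the catalog (single band, north-up, square cells, WGS84).

#' Read an ASCII-grid raster as a scene
#'
#' Parses the six-line ESRI ASCII grid header (`ncols`, `nrows`,
#' `xllcorner`, `yllcorner`, `cellsize`, `NODATA_value`) followed by
#' row-major values, north row first. Nodata pixels become `NA`; the layer's
#' `scale_factor` is applied so the scene holds physical values.
#'
#' @param path Raster file path.
#' @param layer A [layer_spec()] the scene belongs to.
#' @param timestamp `Date` or `NA` (static).
#' @return A [raster_scene()].
#' @export
read_ascii_grid <- function(path, layer, timestamp = as.Date(NA)) {
  if (!file.exists(path)) stop_config(sprintf("raster file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  hdr <- list()
  i <- 1L
  while (i <= length(lines) && grepl("^[A-Za-z]", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "[[:space:]]+")[[1L]]
    hdr[[tolower(kv[1L])]] <- as.numeric(kv[2L])
    i <- i + 1L
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  if (!all(need %in% names(hdr)))
    stop_config(sprintf("malformed ASCII grid header in %s", path))
  nr <- as.integer(hdr$nrows); nc <- as.integer(hdr$ncols)
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  if (length(vals) != nr * nc)
    stop_config(sprintf("expected %d values in %s, found %d", nr * nc, path, length(vals)))
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  nodata <- if (!is.null(hdr$nodata_value)) hdr$nodata_value else layer$nodata_value
  if (!is.null(nodata)) m[m == nodata] <- NA_real_
  if (!is.null(layer$scale_factor) && layer$scale_factor != 1)
    m <- m * layer$scale_factor
  geom <- grid_geometry(origin_lon = hdr$xllcorner,
                        origin_lat = hdr$yllcorner + nr * hdr$cellsize,
                        cell_size_deg = hdr$cellsize, n_rows = nr, n_cols = nc)
  raster_scene(layer, timestamp, geom, m)
}

#' Write a scene as an ASCII-grid raster
#'
#' `NA` pixels are written as the nodata sentinel (-9999). Values are
#' written at full precision (`%.10g`) so write/read round-trips preserve
#' them to within formatting precision.
#'
#' @param scene A [raster_scene()].
#' @param path Output file path.
#' @param nodata Sentinel written for `NA` pixels.
#' @return Invisibly, `path`.
#' @export
write_ascii_grid <- function(scene, path, nodata = -9999) {
  g <- scene$geometry
  m <- scene$values
  m[is.na(m)] <- nodata
  hdr <- c(sprintf("ncols %d", g$n_cols),
           sprintf("nrows %d", g$n_rows),
           sprintf("xllcorner %.15g", g$origin_lon),
           sprintf("yllcorner %.15g", g$origin_lat - g$n_rows * g$cell_size_deg),
           sprintf("cellsize %.15g", g$cell_size_deg),
           sprintf("NODATA_value %g", nodata))
  rows <- apply(m, 1L, function(r) paste(sprintf("%.10g", r), collapse = " "))
  writeLines(c(hdr, rows), path)
  invisible(path)
}
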