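# Occurrence CSV reading/validation and the results bundle writer.

#' Read and validate an occurrence CSV
#'
#' Required columns (case-insensitive): `id`, `longitude`, `latitude`,
#' `date` (ISO-8601). Extra columns are preserved as passthrough so upstream
#' attributes survive to the comparison stage. Invalid rows — coordinates
#' out of range, unparseable dates, duplicate ids (the second and later
#' occurrences) — are collected into a rejection report with row numbers and
#' reasons rather than aborting the run; `strict = TRUE` turns any
#' rejection into an error.
#'
#' @param path CSV file path.
#' @param strict Error on any rejected row?
#' @return List with `records` (data frame: `id`, `longitude`, `latitude`,
#'   `event_date`, plus passthrough columns) and `rejected` (data frame:
#'   `row`, `id`, `reason`).
#' @export
read_occurrences <- function(path, strict = FALSE) {
  if (!file.exists(path)) stop_config(sprintf("occurrence file not found: %s", path))
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character",
                         check.names = FALSE)
  lname <- tolower(names(raw))
  need <- c("id", "longitude", "latitude", "date")
  missing_cols <- setdiff(need, lname)
  if (length(missing_cols))
    stop_config(sprintf("occurrence CSV is missing required column(s): %s",
                        paste(missing_cols, collapse = ", ")))
  col <- function(nm) raw[[which(lname == nm)[1L]]]
  id <- col("id")
  lon <- suppressWarnings(as.numeric(col("longitude")))
  lat <- suppressWarnings(as.numeric(col("latitude")))
  date <- suppressWarnings(as.Date(col("date"), format = "%Y-%m-%d"))
  n <- nrow(raw)
  reason <- character(n)
  bad <- function(cond, why) {
    hit <- cond & !nzchar(reason)
    reason[hit] <<- why
  }
  bad(is.na(id) | !nzchar(id), "missing id")
  bad(is.na(lon) | lon < -180 | lon > 180, "longitude out of range")
  bad(is.na(lat) | lat < -90 | lat > 90, "latitude out of range")
  bad(is.na(date), "unparseable date (expected ISO-8601)")
  bad(duplicated(id), "duplicate id")
  keep <- !nzchar(reason)
  rejected <- data.frame(row = which(!keep), id = id[!keep],
                         reason = reason[!keep], stringsAsFactors = FALSE)
  if (strict && nrow(rejected))
    stop_validation(sprintf("strict mode: %d invalid occurrence row(s), first: row %d (%s)",
                            nrow(rejected), rejected$row[1L], rejected$reason[1L]))
  records <- data.frame(id = id[keep], longitude = lon[keep], latitude = lat[keep],
                        event_date = date[keep], stringsAsFactors = FALSE)
  extra <- which(!lname %in% need)
  for (j in extra) records[[names(raw)[j]]] <- raw[[j]][keep]
  list(records = records, rejected = rejected)
}

format_csv <- function(df) {
  tc <- textConnection("out", "w", local = TRUE)
  utils::write.csv(df, tc, row.names = FALSE, na = "")
  close(tc)
  out
}

#' Write an annotation results bundle
#'
#' Produces a ZIP archive containing `values.csv` (one row per record x
#' layer, input order, failed records retained with empty value fields and
#' their status flag), `parameters.txt` (the annotation request and dataset
#' summary), and `metadata.txt` (per-layer citations from the catalog).
#' Output is deterministic: identical inputs give byte-identical archives.
#'
#' @param results Results data frame from [annotate_naive()] /
#'   [annotate_clustered()].
#' @param request The [annotation_request()] that produced them.
#' @param catalog Named list of [layer_spec()].
#' @param out_path Output `.zip` path.
#' @return Invisibly, `out_path`.
#' @export
write_results_bundle <- function(results, request, catalog, out_path) {
  vals <- results[, c("record_id", "layer", "spatial_buffer_m",
                      "temporal_buffer_days", "value_mean", "value_stdev",
                      "valid_sample_count", "scenes_used", "status")]
  params <- c("annotation parameters",
              "---------------------",
              sprintf("layers: %s", paste(request$layers, collapse = ", ")),
              sprintf("spatial_buffer_m: %g", request$spatial_buffer_m),
              sprintf("temporal_buffer_days: %d", request$temporal_buffer_days),
              sprintf("n_records: %d", length(unique(vals$record_id))),
              sprintf("n_result_rows: %d", nrow(vals)),
              sprintf("status counts: %s",
                      paste(sprintf("%s=%d", names(table(vals$status)),
                                    as.integer(table(vals$status))), collapse = ", ")))
  meta <- unlist(lapply(request$layers, function(nm) {
    sp <- catalog[[nm]]
    if (is.null(sp)) return(sprintf("%s: (not in catalog)", nm))
    c(sprintf("layer: %s", sp$name),
      sprintf("  variable: %s", sp$variable),
      sprintf("  spatial_grain_m: %g", sp$spatial_grain_m),
      sprintf("  temporal_grain: %s", sp$temporal_grain),
      sprintf("  citation: %s", sp$citation))
  }))
  write_zip(out_path, list("values.csv" = format_csv(vals),
                           "parameters.txt" = params,
                           "metadata.txt" = meta))
  invisible(out_path)
}
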