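static_scene <- function(values, cell_m = 100, grain_m = 100, name = "s",
                         valid_range = NULL) {
  g <- equator_grid(nrow(values), ncol(values), cell_m)
  spec <- layer_spec(name, spatial_grain_m = grain_m, temporal_grain = "static",
                     valid_range = valid_range)
  raster_scene(spec, as.Date(NA), g, values)
}

test_that("block coarsening averages blocks and excludes nodata", {
  m <- matrix(c(1, 3, 2, 4), 2, 2)  # one 2x2 block: 1..4
  out <- coarsen_spatial(static_scene(m), 2L)[[1L]]
  expect_equal(dim(out$values), c(1L, 1L))
  expect_equal(out$values[1L, 1L], 2.5)
  expect_equal(out$layer$spatial_grain_m, 200)
  expect_equal(out$geometry$cell_size_deg, 2 * 100 / 111320)

  m2 <- matrix(c(1, 3, 2, NA), 2, 2)
  expect_equal(coarsen_spatial(static_scene(m2), 2L)[[1L]]$values[1L, 1L], 2)

  all_na <- matrix(NA_real_, 2, 2)
  expect_true(is.na(coarsen_spatial(static_scene(all_na), 2L)[[1L]]$values[1L, 1L]))

  const <- matrix(7, 6, 6)
  outc <- coarsen_spatial(static_scene(const), 3L)[[1L]]
  expect_true(all(outc$values == 7))
  expect_error(coarsen_spatial(static_scene(const), 1L), ">= 2",
               class = "spatannot_validation_error")
})

test_that("coarsening trims non-divisible grids and conserves complete means", {
  withr::with_seed(41, {
    m <- matrix(rnorm(7 * 9), 7, 9)
  })
  out <- coarsen_spatial(static_scene(m), 3L)[[1L]]
  expect_equal(dim(out$values), c(2L, 3L))
  # conservation on the trimmed complete sub-grid
  expect_equal(mean(out$values), mean(m[1:6, 1:9]), tolerance = 1e-12)
})

test_that("composites are per-cell nodata-excluded means with correct grouping", {
  series <- daily_series(base_level = 0.4, seasonal_amplitude = 0.3,
                         seasonal_peak_day = 182L, spatial_gradient = 0.01,
                         heterogeneity_sd = 0.1, noise_sd = 0, cloud_fraction = 0,
                         n_rows = 5L, n_cols = 5L,
                         dates = c("2015-01-01", "2015-12-31"), seed = 2)
  lt <- composite_layers(series$scenes, composite_spec("long_term"))
  expect_named(lt, "all")
  expect_equal(lt$all$layer$temporal_grain, "static")
  # full-cycle cosine integrates out: composite = de-seasonalized field
  expected <- 0.4 + 0.01 * matrix(rep(0:4, each = 5), 5, 5) + series$heterogeneity
  expect_equal(lt$all$values, expected, tolerance = 1e-6)

  mc <- composite_layers(series$scenes, composite_spec("monthly_climatology"))
  expect_named(mc, sprintf("%02d", 1:12))
  # month layer = mean of the cosine over that month's days, per cell
  june_days <- seq(as.Date("2015-06-01"), as.Date("2015-06-30"), by = "1 day")
  doy <- as.integer(format(june_days, "%j"))
  seas <- mean(0.3 * cos(2 * pi * (doy - 182) / 365))
  expect_equal(mc[["06"]]$values, expected + seas, tolerance = 1e-10)

  single <- composite_layers(series$scenes[5], composite_spec("long_term"))
  expect_equal(single$all$values, series$scenes[[5]]$values, tolerance = 0)

  expect_error(composite_layers(series$scenes,
                                composite_spec("long_term",
                                               c("2020-01-01", "2020-12-31"))),
               "no source scenes", class = "spatannot_validation_error")
})

test_that("composite cells stay within the range of contributing scenes", {
  series <- daily_series(noise_sd = 0.1, cloud_fraction = 0.3,
                         heterogeneity_sd = 0.1, n_rows = 8L, n_cols = 8L,
                         dates = c("2015-06-01", "2015-06-20"), seed = 19)
  lt <- composite_layers(series$scenes, composite_spec("long_term"))$all
  stack <- sapply(series$scenes, function(s) as.vector(s$values))
  lo <- apply(stack, 1L, min, na.rm = TRUE)
  hi <- apply(stack, 1L, max, na.rm = TRUE)
  v <- as.vector(lt$values)
  ok <- !is.na(v)
  expect_true(all(v[ok] >= lo[ok] - 1e-12 & v[ok] <= hi[ok] + 1e-12))
})

test_that("grain-agnostic annotation intersects the containing composite cell", {
  series <- daily_series(base_level = 0.5, seasonal_amplitude = 0.2,
                         heterogeneity_sd = 0.1, n_rows = 6L, n_cols = 6L,
                         dates = c("2015-01-01", "2015-12-31"), seed = 22)
  comps <- c(composite_layers(series$scenes, composite_spec("long_term")),
             composite_layers(series$scenes, composite_spec("monthly_climatology")))
  geom <- equator_grid(6L, 6L)
  ctr <- cell_center(geom, 2L, 5L)
  recs <- data.frame(id = c("a", "off"),
                     longitude = c(ctr$lon, 10), latitude = c(ctr$lat, 10),
                     event_date = as.Date("2015-06-15"))
  lt <- annotate_grain_agnostic(recs, comps, "ignore_date")
  expect_equal(lt$value[1L], comps$all$values[2L, 5L])
  expect_equal(lt$status, c("ok", "out_of_extent"))
  mm <- annotate_grain_agnostic(recs, comps, "match_month")
  expect_equal(mm$value[1L], comps[["06"]]$values[2L, 5L])

  # nodata composite cell flags the record
  holed <- comps
  holed$all$values[2L, 5L] <- NA_real_
  lt2 <- annotate_grain_agnostic(recs, holed, "ignore_date")
  expect_equal(lt2$status[1L], "no_valid_data")
  expect_true(is.na(lt2$value[1L]))
})

test_that("cross-grain deltas join on ids and summarize as stated", {
  a <- data.frame(record_id = c("r1", "r2", "r3"),
                  value_mean = c(0.5, 0.8, NA), stringsAsFactors = FALSE)
  b <- data.frame(record_id = c("r1", "r2", "r3"),
                  value = c(0.3, 0.8, 0.1), stringsAsFactors = FALSE)
  cmp <- cross_grain_delta(a, b)
  expect_equal(nrow(cmp), 2L)  # r3 invalid under a
  expect_equal(cmp$delta[cmp$record_id == "r1"], 0.2)
  expect_equal(cmp$abs_delta[cmp$record_id == "r1"], 0.2)
  s <- delta_summary(cmp, threshold = 0.1)
  expect_equal(s$median_abs_delta, 0.1)
  expect_equal(s$exceedance_fraction, 0.5)

  ident <- cross_grain_delta(a, a)
  expect_true(all(ident$abs_delta == 0))
  expect_equal(delta_summary(ident, 0.2)$exceedance_fraction, 0)

  disjoint <- data.frame(record_id = "zz", value = 1, stringsAsFactors = FALSE)
  expect_warning(empty <- cross_grain_delta(a, disjoint), "no records")
  expect_equal(nrow(empty), 0L)
})

test_that("spatial cross-grain deltas vanish on homogeneous noise-free landscapes", {
  series <- daily_series(base_level = 0.4, heterogeneity_sd = 0, noise_sd = 0,
                         spatial_gradient = 0, cloud_fraction = 0,
                         n_rows = 30L, n_cols = 30L, cell_m = 100,
                         dates = c("2015-06-10", "2015-06-10"), seed = 31)
  store <- memory_scene_store(series)
  withr::with_seed(53, {
    recs <- data.frame(id = sprintf("r%02d", 1:12),
                       longitude = runif(12, 0.012, 0.015),
                       latitude = runif(12, 0.985, 0.988),
                       event_date = as.Date("2015-06-10"))
  })
  fine <- annotate_naive(recs, series$layer, annotation_request("synth", 120, 1L), store)
  coarse <- annotate_naive(recs, series$layer, annotation_request("synth", 990, 1L), store)
  cmp <- cross_grain_delta(fine$results, coarse$results)
  expect_equal(max(cmp$abs_delta), 0, tolerance = 1e-12)
})
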