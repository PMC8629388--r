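make_request <- function(...) annotation_request("synth", ...)

test_that("zonal statistics accumulate valid pixels under the mask", {
  g <- equator_grid(n_rows = 3L, n_cols = 3L, cell_m = 100)
  spec <- layer_spec("z", spatial_grain_m = 100, temporal_grain = "static")
  sc <- raster_scene(spec, as.Date(NA), g, matrix(1:9, 3, 3))
  ctr <- cell_center(g, 2L, 2L)
  full <- spatial_buffer_mask(g, ctr$lon, ctr$lat, 150)
  zs <- zonal_stats(sc, full)
  expect_equal(zs$n_valid, 9L)
  expect_equal(zs$sum, 45)
  m <- zs$sum / zs$n_valid
  expect_equal(m, 5)
  expect_equal(sqrt((zs$sum_sq - zs$n_valid * m^2) / (zs$n_valid - 1)),
               sd(1:9), tolerance = 1e-12)

  const <- raster_scene(spec, as.Date(NA), g, matrix(2.5, 3, 3))
  zc <- zonal_stats(const, full)
  expect_equal(zc$sum / zc$n_valid, 2.5)
  expect_equal(zc$sum_sq - zc$n_valid * 2.5^2, 0, tolerance = 1e-12)

  empty <- raster_scene(spec, as.Date(NA), g, matrix(NA_real_, 3, 3))
  expect_equal(zonal_stats(empty, full), list(sum = 0, sum_sq = 0, n_valid = 0L))
})

test_that("values outside the layer's valid range are screened out", {
  g <- equator_grid(n_rows = 2L, n_cols = 2L, cell_m = 100)
  spec <- layer_spec("q", spatial_grain_m = 100, temporal_grain = "static",
                     valid_range = c(0, 1))
  sc <- raster_scene(spec, as.Date(NA), g, matrix(c(0.2, 5, -3, 0.6), 2, 2))
  ctr <- cell_center(g, 1L, 1L)
  mask <- spatial_buffer_mask(g, ctr$lon, ctr$lat, 250)
  zs <- zonal_stats(sc, mask)
  expect_equal(zs$n_valid, 2L)
  expect_equal(zs$sum, 0.8)
})

test_that("noise-free single-cell single-day annotation recovers the generator", {
  series <- daily_series(base_level = 0.5, seasonal_amplitude = 0.2,
                         spatial_gradient = 0.01, heterogeneity_sd = 0.08,
                         noise_sd = 0, cloud_fraction = 0,
                         n_rows = 10L, n_cols = 10L, seed = 4)
  store <- memory_scene_store(series)
  geom <- equator_grid(10L, 10L)
  req <- make_request(spatial_buffer_m = 0, temporal_buffer_days = 1L)
  for (cell in list(c(2L, 3L), c(7L, 9L))) {
    ctr <- cell_center(geom, cell[1L], cell[2L])
    rec <- list(id = "r", longitude = ctr$lon, latitude = ctr$lat,
                event_date = as.Date("2015-06-12"))
    res <- annotate_record(rec, series$layer, req, store)
    expect_equal(res$status, "ok")
    expect_equal(res$value_mean, series$g(cell[1L], cell[2L], rec$event_date),
                 tolerance = 0)
    expect_equal(res$valid_sample_count, 1L)
    expect_true(is.na(res$value_stdev))  # sample sd undefined at n = 1
  }
})

test_that("statuses distinguish coverage gaps, cloud, and extent misses", {
  # 16-day sampling with a window that misses every timestamp
  g <- equator_grid(6L, 6L, cell_m = 30)
  l16 <- make_layer_series(synth_layer_params(
    g, "sixteen_day", date_range = c("2015-06-01", "2015-06-17"),
    name = "l8", spatial_grain_m = 30, seed = 2))
  store16 <- memory_scene_store(l16)
  ctr <- cell_center(g, 3L, 3L)
  rec <- list(id = "r1", longitude = ctr$lon, latitude = ctr$lat,
              event_date = as.Date("2015-06-10"))
  res <- annotate_record(rec, l16$layer, annotation_request("l8", 0, 7L), store16)
  expect_equal(res$status, "out_of_coverage")
  expect_equal(res$valid_sample_count, 0L)
  expect_true(is.na(res$value_mean))

  # full cloud on every window day
  cloudy <- daily_series(cloud_fraction = 1, n_rows = 6L, n_cols = 6L, seed = 5)
  store_c <- memory_scene_store(cloudy)
  gctr <- cell_center(equator_grid(6L, 6L), 3L, 3L)
  rec2 <- list(id = "r2", longitude = gctr$lon, latitude = gctr$lat,
               event_date = as.Date("2015-06-10"))
  res2 <- annotate_record(rec2, cloudy$layer, make_request(0, 7L), store_c)
  expect_equal(res2$status, "no_valid_data")

  # coordinates off the grid: a flagged result, not an exception
  rec3 <- list(id = "r3", longitude = 50, latitude = 50,
               event_date = as.Date("2015-06-10"))
  res3 <- annotate_record(rec3, cloudy$layer, make_request(0, 7L), store_c)
  expect_equal(res3$status, "out_of_extent")
})

test_that("naive retrieval counts are one fetch per record per resolved day", {
  series <- daily_series(n_rows = 8L, n_cols = 8L, seed = 6)
  store <- memory_scene_store(series)
  geom <- equator_grid(8L, 8L)
  ctr <- cell_center(geom, 4L, 4L)
  one <- data.frame(id = "a", longitude = ctr$lon, latitude = ctr$lat,
                    event_date = as.Date("2015-06-10"))
  reset_fetch_count(store)
  ans <- annotate_naive(one, series$layer, make_request(0, 1L), store)
  expect_equal(ans$account$naive_count, 1L)

  two <- data.frame(id = c("a", "b"), longitude = ctr$lon, latitude = ctr$lat,
                    event_date = as.Date(c("2015-06-10", "2015-06-20")))
  reset_fetch_count(store)
  ans2 <- annotate_naive(two, series$layer, make_request(0, 2L), store)
  expect_equal(ans2$account$naive_count, 4L)  # 2 records x 2 window days
})

test_that("pooled means stay inside the pooled sample range", {
  series <- daily_series(noise_sd = 0.1, cloud_fraction = 0.2,
                         heterogeneity_sd = 0.1, spatial_gradient = 0.005,
                         n_rows = 12L, n_cols = 12L, seed = 8)
  store <- memory_scene_store(series)
  geom <- equator_grid(12L, 12L)
  withr::with_seed(31, {
    for (k in 1:30) {
      rec <- list(id = "r", longitude = runif(1, 0.001, 0.025),
                  latitude = runif(1, 0.975, 0.999),
                  event_date = as.Date("2015-06-01") + sample(0:29, 1))
      req <- make_request(runif(1, 0, 800), sample(1:6, 1))
      res <- annotate_record(rec, series$layer, req, store)
      if (res$status != "ok") next
      orc <- oracle_annotate(rec, series, req$spatial_buffer_m,
                             req$temporal_buffer_days)
      # mean bounded by the min/max of the independently enumerated samples
      expect_gte(res$value_mean, orc$min - 1e-12)
      expect_lte(res$value_mean, orc$max + 1e-12)
      expect_equal(res$value_mean, orc$mean, tolerance = 1e-12)
    }
  })
})

test_that("enlarging a buffer never turns an ok annotation into no_valid_data", {
  series <- daily_series(cloud_fraction = 0.85, noise_sd = 0.05,
                         n_rows = 12L, n_cols = 12L, seed = 9)
  store <- memory_scene_store(series)
  withr::with_seed(17, {
    recs <- data.frame(id = sprintf("r%02d", 1:15),
                       longitude = runif(15, 0.005, 0.022),
                       latitude = runif(15, 0.978, 0.995),
                       event_date = as.Date("2015-06-05") + sample(0:20, 15, TRUE))
  })
  grid_cfg <- expand.grid(r = c(0, 300, 700), b = c(1L, 3L, 7L))
  status_tab <- lapply(seq_len(nrow(grid_cfg)), function(i) {
    ans <- annotate_naive(recs, series$layer,
                          make_request(grid_cfg$r[i], grid_cfg$b[i]), store)
    ans$results$status
  })
  for (i in seq_len(nrow(grid_cfg))) for (j in seq_len(nrow(grid_cfg))) {
    if (grid_cfg$r[j] >= grid_cfg$r[i] && grid_cfg$b[j] >= grid_cfg$b[i]) {
      was_ok <- status_tab[[i]] == "ok"
      expect_false(any(status_tab[[j]][was_ok] == "no_valid_data"))
    }
  }
})

test_that("buffer caps are enforced at request validation", {
  expect_error(annotation_request("x", spatial_buffer_m = 20000),
               "maximum", class = "spatannot_validation_error")
  expect_error(annotation_request("x", temporal_buffer_days = 400),
               "maximum", class = "spatannot_validation_error")
  expect_error(annotation_request(character(0)), "layer")
  expect_error(annotation_request("x", temporal_buffer_days = 0), "minimum is 1")
})
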