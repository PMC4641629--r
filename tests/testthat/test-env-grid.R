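make_records <- function(x, y, date, value, variable = "SAL") {
  d <- data.frame(station_id = "s1", x_km = x, y_km = y,
                  date = as.Date(date), stringsAsFactors = FALSE)
  d[[variable]] <- value
  d
}

test_that("surface/bottom split honors the 5 m bottom rule", {
  cast <- data.frame(depth_m = c(0.5, 4.0), SAL = c(30, 31))
  sb <- extract_surface_bottom(cast)
  expect_equal(sb$surface$depth_m, 0.5)
  expect_null(sb$bottom)

  cast2 <- data.frame(depth_m = c(6, 0.5, 18), SAL = 1:3)
  sb2 <- extract_surface_bottom(cast2)
  expect_equal(sb2$surface$depth_m, 0.5)
  expect_equal(sb2$bottom$depth_m, 18)

  cast3 <- data.frame(depth_m = 6, SAL = 7)
  sb3 <- extract_surface_bottom(cast3)
  expect_equal(sb3$surface$depth_m, 6)
  expect_equal(sb3$bottom$depth_m, 6)

  empty <- extract_surface_bottom(data.frame(depth_m = numeric(0)))
  expect_null(empty$surface)
  expect_null(empty$bottom)
})

test_that("season assignment partitions the twelve months", {
  expect_equal(as.character(assign_season(as.Date("2019-03-31"))), "winter")
  expect_equal(as.character(assign_season(as.Date("2019-10-01"))), "autumn")
  months <- as.Date(sprintf("2019-%02d-10", 1:12))
  s <- assign_season(months)
  expect_equal(as.integer(table(s)), rep(3L, 4))
  expect_equal(as.character(s[c(1, 4, 7, 10)]),
               c("winter", "spring", "summer", "autumn"))
})

test_that("yearly medians require all four seasons and equal the median of seasonal medians", {
  spec <- grid_spec(n_rows = 2, n_cols = 2)
  # one record per season in cell (1,1), seasonal medians 10/12/14/20
  recs <- make_records(
    x = rep(1, 4), y = rep(1, 4),
    date = c("2019-02-01", "2019-05-01", "2019-08-01", "2019-11-01"),
    value = c(10, 12, 14, 20)
  )
  out <- seasonal_and_yearly_medians(recs, spec, "SAL")
  expect_equal(out$yearly$values[1, 1], 13)  # median(c(10,12,14,20))
  expect_equal(out$winter$values[1, 1], 10)
  # winter-only cell: seasonal layer populated, yearly missing
  w <- make_records(4, 1, "2019-01-15", 5)
  out_w <- seasonal_and_yearly_medians(w, spec, "SAL")
  expect_equal(out_w$winter$values[1, 2], 5)
  expect_true(is.na(out_w$yearly$values[1, 2]))
  # constant value across seasons: yearly equals it
  const <- make_records(rep(1, 4), rep(1, 4),
                        c("2019-02-01", "2019-05-01", "2019-08-01", "2019-11-01"),
                        rep(7, 4))
  expect_equal(seasonal_and_yearly_medians(const, spec, "SAL")$yearly$values[1, 1], 7)
})

test_that("median layers are invariant to record order and median-duplication", {
  spec <- grid_spec(n_rows = 1, n_cols = 1, cell_size = 10)
  vals <- c(3, 1, 4, 1, 5)
  dates <- rep("2019-02-01", 5)
  base <- seasonal_and_yearly_medians(
    make_records(rep(1, 5), rep(1, 5), dates, vals), spec, "SAL")
  perm <- seasonal_and_yearly_medians(
    make_records(rep(1, 5), rep(1, 5), dates, vals[c(4, 2, 5, 1, 3)]),
    spec, "SAL")
  expect_identical(base$winter$values, perm$winter$values)
  dup <- seasonal_and_yearly_medians(
    make_records(rep(1, 6), rep(1, 6), rep(dates[1], 6), c(vals, 3)),
    spec, "SAL")
  expect_equal(dup$winter$values[1, 1], base$winter$values[1, 1])
})

test_that("percentile ranges match the interpolation rule and degenerate limits", {
  spec <- grid_spec(n_rows = 1, n_cols = 1, cell_size = 10)
  # 100 values spread over the four seasons
  dates <- rep(c("2019-02-01", "2019-05-01", "2019-08-01", "2019-11-01"), 25)
  recs <- make_records(rep(1, 100), rep(1, 100), dates, 1:100)
  rng <- percentile_range(recs, spec, "SAL")
  expect_equal(rng$values[1, 1], 95.05 - 5.95, tolerance = 1e-12)
  expect_equal(rng$values[1, 1],
               oracle_percentile(1:100, 0.95) - oracle_percentile(1:100, 0.05))
  # constant records: range 0
  const <- make_records(rep(1, 8), rep(1, 8), dates[1:8], rep(4.2, 8))
  expect_equal(percentile_range(const, spec, "SAL")$values[1, 1], 0)
  # single record: range 0 once the seasonal gate is lifted
  single <- make_records(1, 1, "2019-02-01", 9)
  expect_true(is.na(percentile_range(single, spec, "SAL")$values[1, 1]))
  expect_equal(percentile_range(single, spec, "SAL",
                                require_all_seasons = FALSE)$values[1, 1], 0)
})

test_that("cell medians and percentiles agree with a sort-based oracle", {
  spec <- grid_spec(n_rows = 1, n_cols = 1, cell_size = 10)
  set.seed(99)
  for (rep_i in 1:20) {
    n <- sample(1:50, 1)
    vals <- rnorm(n)
    recs <- make_records(rep(1, n), rep(1, n), rep("2019-02-01", n), vals)
    out <- seasonal_and_yearly_medians(recs, spec, "SAL")
    s <- sort(vals)
    med_oracle <- if (n %% 2 == 1) s[(n + 1) / 2] else (s[n / 2] + s[n / 2 + 1]) / 2
    expect_equal(out$winter$values[1, 1], med_oracle)
    rng <- percentile_range(recs, spec, "SAL", require_all_seasons = FALSE)
    expect_equal(rng$values[1, 1],
                 oracle_percentile(vals, 0.95) - oracle_percentile(vals, 0.05),
                 tolerance = 1e-12)
  }
})

test_that("moving-window fill honors the point threshold and never edits data cells", {
  # 1-D toy grid: 1 row, 10 columns of 2.5 km
  spec <- grid_spec(n_rows = 1, n_cols = 10)
  vals <- matrix(NA_real_, 1, 10)
  vals[1, 1] <- 42  # populated cell
  layer <- grid_layer(spec, vals, variable = "SAL")
  # 6 points in cells within 30 km of target cell 8
  pts <- data.frame(x_km = c(2, 5, 7, 10, 12, 15), y_km = rep(1, 6),
                    SAL = c(1, 2, 3, 4, 100, 101))
  filled <- moving_window_fill(layer, pts, radius_km = 30, min_points = 6)
  expect_equal(filled$values[1, 8], 3.5)   # median(c(1,2,3,4,100,101))
  expect_equal(filled$values[1, 1], 42)    # populated cell untouched
  # with min_points - 1 available the cell stays missing
  strict <- moving_window_fill(layer, pts[1:5, ], radius_km = 30, min_points = 6)
  expect_true(is.na(strict$values[1, 8]))
  # no missing cells: returned unchanged
  full <- grid_layer(spec, matrix(1, 1, 10), variable = "SAL")
  expect_identical(moving_window_fill(full, pts, 30, 6)$values, full$values)
  expect_error(moving_window_fill(layer, pts, radius_km = -1, min_points = 6),
               "radius_km")
})

test_that("moving-window fill is idempotent and monotone in coverage", {
  spec <- grid_spec(n_rows = 5, n_cols = 8)
  set.seed(7)
  pts <- data.frame(x_km = runif(25, 0, 20), y_km = runif(25, 0, 12.5),
                    SAL = rnorm(25, 35))
  empty <- grid_layer(spec, matrix(NA_real_, 5, 8), variable = "SAL")
  once <- moving_window_fill(empty, pts, radius_km = 8, min_points = 4)
  twice <- moving_window_fill(once, pts, radius_km = 8, min_points = 4)
  expect_identical(once$values, twice$values)
  expect_true(all(which(!is.na(empty$values)) %in% which(!is.na(once$values))))
  expect_gt(sum(!is.na(once$values)), 0)
})

test_that("site extraction returns containing-cell values and flags outsiders", {
  spec <- grid_spec(n_rows = 2, n_cols = 2)
  layer <- grid_layer(spec, matrix(1:4, 2, 2), variable = "SAL")
  centers <- grid_cell_centers(spec)
  at_center <- extract_at_sites(layer, centers[1, ])
  expect_equal(at_center, layer$values[1, 1])
  two <- data.frame(x_km = c(0.4, 2.0), y_km = c(0.4, 2.0))  # same cell
  expect_equal(diff(extract_at_sites(layer, two)), 0)
  expect_warning(
    out <- extract_at_sites(layer, data.frame(x_km = 99, y_km = 99)),
    "outside"
  )
  expect_true(is.na(out))
})

test_that("ESRI ASCII rasters round-trip", {
  spec <- grid_spec(origin = c(10, 20), cell_size = 2.5, n_rows = 3, n_cols = 4)
  vals <- matrix(rnorm(12), 3, 4)
  vals[2, 3] <- NA
  layer <- grid_layer(spec, vals, variable = "PHOS", layer = "bottom")
  path <- withr::local_tempfile(fileext = ".asc")
  write_esri_ascii(layer, path)
  back <- read_esri_ascii(path, variable = "PHOS", layer = "bottom")
  expect_equal(back$values, layer$values, tolerance = 1e-8)
  expect_equal(back$spec, layer$spec)
})
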