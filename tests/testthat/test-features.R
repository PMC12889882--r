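# Feature pipeline: encodings, NDVI assignment, scaler, imputation,
# sequence construction.

test_that("temporal encodings follow the 365-day zero-angle convention", {
  jan1 <- encode_time(as.Date("2021-01-01"))
  expect_equal(jan1$cos_doy, 1)
  expect_equal(jan1$sin_doy, 0)
  expect_equal(jan1$cos_month, 1)
  expect_equal(jan1$sin_month, 0)
  expect_equal(jan1$year, 2021)

  # Independent trigonometric oracle at doy = 100.
  d100 <- encode_time(as.Date("2021-04-10"))
  expect_equal(as.POSIXlt(as.Date("2021-04-10"))$yday + 1, 100)
  expect_equal(d100$cos_doy, cos(2 * pi * 99 / 365), tolerance = 1e-12)
  expect_equal(d100$sin_doy, sin(2 * pi * 99 / 365), tolerance = 1e-12)

  # Circular continuity: Dec 31 and Jan 1 nearly coincide on the circle.
  gap <- function(a, b) {
    ea <- encode_time(a); eb <- encode_time(b)
    sqrt((ea$cos_doy - eb$cos_doy)^2 + (ea$sin_doy - eb$sin_doy)^2)
  }
  expect_lt(gap(as.Date("2021-12-31"), as.Date("2022-01-01")),
            gap(as.Date("2021-01-01"), as.Date("2021-07-01")))
  # All encodings bounded.
  dates <- as.Date("2020-01-01") + 0:730
  enc <- encode_time(dates)
  for (col in c("cos_doy", "sin_doy", "cos_month", "sin_month")) {
    expect_true(all(abs(enc[[col]]) <= 1))
  }
})

test_that("NDVI layer assignment picks the nearest date, earlier on ties", {
  layers <- as.Date("2020-06-01") + c(0, 16, 32)
  expect_equal(assign_ndvi(as.Date("2020-06-01"), layers), 1L)
  expect_equal(assign_ndvi(as.Date("2020-06-08"), layers), 1L)  # 7 vs 9 days
  expect_equal(assign_ndvi(as.Date("2020-06-09"), layers), 1L)  # tie 8 vs 8
  expect_equal(assign_ndvi(as.Date("2020-06-24"), layers), 2L)  # 7 vs 9 days
})

test_that("MinMax scaler maps the training range onto [-1, 1] exactly", {
  df <- tibble::tibble(tmax = c(0, 5, 10), prcp = c(3, 3, 3), y = c(1, 2, 4))
  sc <- fit_scaler(df, features = c("tmax", "prcp"))
  out <- apply_scaler(tibble::tibble(tmax = c(0, 5, 10, 20),
                                     prcp = c(3, 3, 3, 3)), sc)
  expect_equal(out$tmax, c(-1, 0, 1, 3))  # out-of-range maps outside, unclipped
  expect_equal(out$prcp, c(0, 0, 0, 0))   # constant feature, no blow-up
  # Round trip on the target to 1e-9.
  ys <- apply_scaler_target(c(1, 2.7, 4), sc)
  expect_equal(invert_scaler_target(ys, sc), c(1, 2.7, 4), tolerance = 1e-9)
})

test_that("refitting the scaler with test data changes it (leakage tripwire)", {
  w <- tiny_world()
  ft <- build_feature_table(w)
  tg <- pm25seq:::eligible_targets(ft)
  sc_train <- fit_scaler(tg[1:60, ])
  sc_all <- fit_scaler(tg)
  expect_false(isTRUE(all.equal(sc_train$params$max, sc_all$params$max)))
})

test_that("AOD imputation passes observed cells through and fills every gap", {
  w0 <- tiny_world(aod_missing_rate = 0)
  expect_identical(impute_aod(w0), w0)  # no gaps: untouched

  w <- tiny_world(aod_missing_rate = 0.35)
  wi <- impute_aod(w)
  expect_equal(sum(is.na(wi$covariates$aod_047)), 0)
  expect_equal(sum(is.na(wi$covariates$aod_055)), 0)
  obs <- !w$aod_mask
  expect_identical(wi$covariates$aod_047[obs], w$covariates$aod_047[obs])
})

test_that("imputation recovers a noiseless linear AOD field well", {
  # Oracle world: AOD is an exact linear function of PM2.5 and the field is
  # a smooth, persistent regional surface (the regime in which daily
  # satellite AOD actually varies), so held-back truth is recoverable.
  w <- generate_world(world_config(
    grid_nx = 15, grid_ny = 15, n_days = 45, n_stations = 12,
    spatial_range_km = 200, ar1_rho = 0.95, noise_sd = 0,
    aod_noise_sd = 0, aod_missing_rate = 0.4, seed = 19))
  wi <- impute_aod(w, nrounds = 250)
  miss <- w$aod_mask
  truth <- w$aod_true_047[miss]
  imputed <- wi$covariates$aod_047[miss]
  rmse <- sqrt(mean((imputed - truth)^2))
  expect_lt(rmse, 0.2 * sd(w$aod_true_047))
})

test_that("all-missing AOD stack refuses to train", {
  w <- tiny_world()
  w$aod_mask[] <- TRUE
  w <- pm25seq:::rederive_world(w)
  expect_error(impute_aod(w), "nothing to train")
})

test_that("sequences have exact windows, oldest-first rows and aligned targets", {
  w <- tiny_world(aod_missing_rate = 0)
  ft <- build_feature_table(w)
  tg <- pm25seq:::eligible_targets(ft)
  sc <- fit_scaler(tg)
  ss <- build_sequences(ft, tg, sc)
  expect_equal(dim(ss$X)[2], 21)
  expect_equal(dim(ss$X)[3], length(ss$features))
  expect_false(any(ss$mask))  # continuous daily features
  # The last row of each sample is the target day's feature vector.
  i <- 5
  row_t <- apply_scaler(tg[i, ], sc)
  expect_equal(as.numeric(ss$X[i, 21, ]),
               as.numeric(row_t[, ss$features]))
  expect_equal(ss$meta$date[i], tg$date[i])
})

test_that("targets without a full window are skipped with a warning", {
  w <- tiny_world()
  ft <- build_feature_table(w)
  early <- ft[!is.na(ft$y), ][1:5, ]
  sc <- fit_scaler(ft[!is.na(ft$y), ])
  expect_warning(ss <- build_sequences(ft, early, sc), "skipping")
  expect_equal(dim(ss$X)[1], 0)
})

test_that("an idw gap alone is median-filled and flagged, not masked", {
  w <- tiny_world(station_reporting_period = 3, aod_missing_rate = 0)
  ft <- build_feature_table(w)
  tg <- pm25seq:::eligible_targets(ft)
  sc <- fit_scaler(tg)
  # With irregular reporting the grid covariates persist daily: no masks.
  ss <- build_sequences(ft, tg, sc)
  expect_false(any(ss$mask))
  # Remove every record on one in-window day: idw becomes missing there,
  # but AOD persists, so the timestep stays unmasked and is median-filled.
  d <- tg$date[1] - 4
  ft2 <- ft
  ft2$idw_pm25[ft2$date == d] <- NA
  ss2 <- build_sequences(ft2, tg[1, ], sc)
  expect_false(any(ss2$mask[1, ]))
  expect_gt(ss2$meta$n_filled[1], 0)
  j <- match("idw_pm25", ss2$features)
  med <- sc$params$median_scaled[match("idw_pm25", sc$params$feature)]
  expect_equal(ss2$X[1, 17, j], med)  # row 17 is day t-4
})

test_that("a day missing both the fused feature and AOD is a masked timestep", {
  w <- tiny_world(aod_missing_rate = 0)
  ft <- build_feature_table(w)
  tg <- pm25seq:::eligible_targets(ft)
  sc <- fit_scaler(tg)
  # Knock out day t-5 entirely for one station: idw and aod both missing.
  st <- tg$station_id[1]
  d <- tg$date[1] - 5
  hit <- ft$station_id == st & ft$date == d
  ft$idw_pm25[hit] <- NA
  ft$aod_047[hit] <- NA
  ft$aod_055[hit] <- NA
  ss <- build_sequences(ft, tg[1, ], sc)
  expect_true(ss$mask[1, 16])      # row 16 is day t-5
  expect_equal(sum(ss$mask[1, ]), 1)
  expect_true(all(ss$X[1, 16, ] == ss$sentinel))
})
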