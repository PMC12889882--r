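# Synthetic world generator: determinism, generative structure, reporting.

test_that("identical config and seed give bit-identical worlds", {
  w1 <- tiny_world()
  w2 <- tiny_world()
  expect_identical(w1$true_pm25, w2$true_pm25)
  expect_identical(w1$observations, w2$observations)
  expect_identical(w1$covariates$aod_047, w2$covariates$aod_047)
  w3 <- tiny_world(seed = 102)
  expect_false(identical(w1$true_pm25, w3$true_pm25))
})

test_that("degenerate generative model collapses to the baseline constant", {
  w <- tiny_world(smoke_beta = 0, seasonal_amp = 0, noise_sd = 0,
                  field_sd = 0, baseline_mu = 9)
  expect_true(all(w$true_pm25 == 9))
})

test_that("invalid configuration names the offending field", {
  expect_error(tiny_world_config(ar1_rho = 1), "ar1_rho")
  expect_error(tiny_world_config(n_stations = 5), "n_stations")
  expect_error(tiny_world_config(n_days = 10), "n_days")
  expect_error(tiny_world_config(aod_missing_rate = 1), "aod_missing_rate")
})

test_that("smoke term elevates heavy-smoke cells by about 3 * smoke_beta", {
  # Sample-mean oracle over >= 1e4 cell-days of a large smoky world.
  w <- generate_world(world_config(
    grid_nx = 25, grid_ny = 25, n_days = 40, n_stations = 10,
    smoke_beta = 10, n_smoke_events = 6, smoke_radius_km = 60,
    smoke_duration_days = 12, noise_sd = 0.5, seed = 7))
  expect_gte(length(w$true_pm25), 1e4)
  d3 <- mean(w$true_pm25[w$smoke_density == 3])
  d0 <- mean(w$true_pm25[w$smoke_density == 0])
  # The Gaussian field contributes sampling noise; allow a few ug/m3.
  expect_lt(abs((d3 - d0) - 30), 4)
})

test_that("increasing smoke_beta strictly increases smoky-cell means", {
  w5 <- tiny_world(smoke_beta = 5)
  w15 <- tiny_world(smoke_beta = 15)
  sm <- w5$smoke_density > 0
  expect_identical(sm, w15$smoke_density > 0)  # same events, same seed
  expect_gt(mean(w15$true_pm25[sm]), mean(w5$true_pm25[sm]))
})

test_that("station reporting period controls the record count per station", {
  w1 <- tiny_world(station_reporting_period = 1)
  counts <- table(w1$observations$station_id)
  expect_true(all(counts == w1$config$n_days))

  w3 <- tiny_world(station_reporting_period = 3)
  counts3 <- table(w3$observations$station_id)
  expect_true(all(counts3 %in% c(10, 10, 10) | counts3 == 10))
  expect_true(all(counts3 == ceiling(w3$config$n_days / 3)))
})

test_that("noiseless observations equal the true field at the station cell", {
  w <- tiny_world(obs_noise_sd = 0)
  st <- w$stations
  obs <- w$observations
  for (i in sample(nrow(obs), 20)) {
    row <- obs[i, ]
    s <- st[st$station_id == row$station_id, ]
    t <- match(row$date, w$dates)
    expect_equal(row$pm25, max(w$true_pm25[s$ix, s$iy, t], 0))
  }
})

test_that("smoke events produce ordinal disks and nothing outside them", {
  w <- tiny_world(n_smoke_events = 0)
  expect_true(all(w$smoke_density == 0))

  w2 <- inject_smoke_events(tiny_world(), n_events = 2, event_radius_km = 30,
                            event_duration_days = 5, seed = 9)
  expect_true(all(w2$smoke_density %in% 0:3))
  # Brute-force oracle: recompute the union of event disks independently.
  ev <- w2$smoke_events
  cfg <- w2$config
  expected <- array(FALSE, dim = dim(w2$smoke_density))
  for (e in seq_len(nrow(ev))) {
    for (ix in seq_len(cfg$grid_nx)) for (iy in seq_len(cfg$grid_ny)) {
      d <- sqrt((ix - ev$cx[e])^2 + (iy - ev$cy[e])^2) * cfg$cell_km
      if (d <= ev$radius_km[e]) {
        expected[ix, iy, ev$day_start[e]:ev$day_end[e]] <- TRUE
      }
    }
  }
  expect_identical(w2$smoke_density > 0, expected)
})

test_that("smoke injection re-derives the true field and observations", {
  w <- tiny_world(obs_noise_sd = 0)
  w2 <- inject_smoke_events(w, n_events = 3, event_radius_km = 40,
                            event_duration_days = 8, seed = 5)
  delta <- w2$true_pm25 - pmax(w$base_pm25 +
                                 w$config$smoke_beta * w2$smoke_density, 0)
  expect_lt(max(abs(delta)), 1e-12)
  # Observations move with the field.
  joined <- dplyr::inner_join(
    w$observations, w2$observations,
    by = c("station_id", "date"), suffix = c("_old", "_new"))
  expect_gt(sum(joined$pm25_new != joined$pm25_old), 0)
})

test_that("AOD missingness matches the binomial rate and masks cleanly", {
  w0 <- tiny_world(aod_missing_rate = 0)
  expect_identical(sum(is.na(w0$covariates$aod_047)), 0L)

  w <- generate_world(world_config(grid_nx = 50, grid_ny = 50, n_days = 40,
                                   n_stations = 10, aod_missing_rate = 0.4,
                                   seed = 11))
  n <- length(w$aod_mask)
  expect_gte(n, 1e5)
  frac <- mean(w$aod_mask)
  tol <- 3 * sqrt(0.4 * 0.6 / n)
  expect_lt(abs(frac - 0.4), tol)
  expect_true(all(is.na(w$covariates$aod_047[w$aod_mask])))
  expect_true(all(is.na(w$covariates$aod_055[w$aod_mask])))
  expect_true(all(is.finite(w$covariates$aod_047[!w$aod_mask])))
  # Other covariates untouched by masking.
  expect_true(all(is.finite(w$covariates$tmax)))
})

test_that("the latent field is stationary with the configured range", {
  # Empirical correlation at lag = spatial_range_km within [0.7, 1.3] * 1/e.
  nx <- 100
  g <- pm25seq:::sim_grf_stack(nx, nx, cell_km = 10, range_km = 60,
                               field_sd = 1, rho = 0, n_days = 6, seed = 13)
  lag <- 6  # cells: 60 km at 10 km spacing
  cors <- vapply(1:6, function(t) {
    x <- g[, , t]
    cor(as.vector(x[1:(nx - lag), ]), as.vector(x[(1 + lag):nx, ]))
  }, numeric(1))
  expect_gt(mean(cors), 0.7 * exp(-1))
  expect_lt(mean(cors), 1.3 * exp(-1))
})

test_that("regressing observed AOD on true PM2.5 recovers the slope", {
  w <- tiny_world(grid_nx = 20, grid_ny = 20, n_days = 40,
                  aod_missing_rate = 0.3, aod_noise_sd = 0.02)
  obs <- !w$aod_mask
  fit <- lm(w$covariates$aod_047[obs] ~ w$true_pm25[obs])
  slope <- coef(fit)[2]
  se <- sqrt(diag(vcov(fit)))[2]
  expect_lt(abs(slope - w$config$aod_slope), 3 * se)
})

test_that("stations CSV round-trips with ISO dates and a manifest", {
  w <- tiny_world()
  path <- file.path(withr::local_tempdir(), "stations.csv")
  write_stations_csv(w, path)
  back <- read_stations_csv(path)
  expect_equal(nrow(back), nrow(w$observations))
  expect_s3_class(back$date, "Date")
  expect_true(file.exists(sub("\\.csv$", ".manifest.json", path)))
  man <- jsonlite::read_json(sub("\\.csv$", ".manifest.json", path))
  expect_equal(man$config$seed, w$config$seed)
})
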