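# KNN-IDW fusion: neighbour selection, weighting, leakage control.

test_that("neighbour sets match brute-force search on many random days", {
  set.seed(21)
  for (rep in 1:5) {
    n <- 50
    obs <- tibble::tibble(
      station_id = sprintf("S%02d", 1:n),
      lon = runif(n, -110, -100), lat = runif(n, 35, 42),
      date = as.Date("2020-07-01"), pm25 = runif(n, 2, 40))
    cfg <- fusion_config(k = 9)
    tlon <- runif(1, -110, -100); tlat <- runif(1, 35, 42)
    ns <- find_neighbors(tlon, tlat, obs, cfg)
    # Exhaustive all-pairs oracle.
    d <- pm25seq:::haversine_km(tlon, tlat, obs$lon, obs$lat)
    ord <- order(d, obs$station_id)[1:9]
    expect_identical(ns$station_id, obs$station_id[ord])
    expect_equal(ns$distance_km, d[ord])
    expect_false(is.unsorted(ns$distance_km))
    expect_equal(sum(ns$weight), 1, tolerance = 1e-12)
    # IDW value against an explicit computation.
    w <- d[ord]^(-1) / sum(d[ord]^(-1))
    expect_equal(idw_estimate(ns), sum(w * obs$pm25[ord]), tolerance = 1e-12)
  }
})

test_that("k caps at the available station count and flags underfill", {
  obs <- line_observations(c(10, 20, 30, 40, 50))
  ns <- find_neighbors(0, 0, obs, fusion_config(k = 9))
  expect_equal(ns$n, 5L)
  expect_true(ns$underfilled)
  ns12 <- find_neighbors(0, 0, dplyr::bind_rows(obs, dplyr::mutate(
    obs, station_id = paste0(station_id, "b"), lon = lon + 0.1)),
    fusion_config(k = 9))
  expect_equal(ns12$n, 9L)
  expect_false(ns12$underfilled)
})

test_that("leave-target-out excludes only the target station identity", {
  obs <- line_observations(c(10, 20, 30))
  # Co-located distinct station at the target point stays eligible.
  obs <- dplyr::bind_rows(obs, tibble::tibble(
    station_id = "TWIN", lon = 0, lat = 0, date = obs$date[1], pm25 = 99))
  ns <- find_neighbors(0, 0, obs, fusion_config(), exclude_station_id = "L01")
  expect_false("L01" %in% ns$station_id)
  expect_true("TWIN" %in% ns$station_id)
  # Zero-distance twin short-circuits the estimate.
  expect_equal(idw_estimate(ns), 99)
})

test_that("IDW closed forms: equidistant mean, power weighting, zero distance", {
  mk <- function(d, v) {
    structure(list(station_id = sprintf("S%d", seq_along(d)),
                   distance_km = d, value = v,
                   weight = pm25seq:::idw_weights(d, 1),
                   n = length(d), underfilled = FALSE),
              class = "neighbor_set")
  }
  expect_equal(idw_estimate(mk(c(5, 5, 5), c(10, 20, 30))), 20)
  expect_equal(idw_estimate(mk(c(1, 2), c(10, 40))), 20)
  expect_equal(idw_estimate(mk(c(0, 3), c(7.3, 100))), 7.3)
  # Interpolation bound holds for random sets.
  set.seed(4)
  for (i in 1:20) {
    d <- runif(9, 0.1, 50); v <- runif(9, 0, 80)
    est <- idw_estimate(mk(d, v))
    expect_gte(est, min(v)); expect_lte(est, max(v))
  }
})

test_that("empty candidate set yields a missing feature, not an error", {
  obs <- line_observations(5)[0, ]
  ns <- find_neighbors(0, 0, obs, fusion_config())
  expect_equal(ns$n, 0L)
  expect_true(is.na(idw_estimate(ns)))
  one <- line_observations(12)
  single <- build_idw_feature(
    one, tibble::tibble(station_id = "L01", lon = 0, lat = 0,
                        date = one$date[1]),
    fusion_config(mode = "leave_target_out"))
  expect_true(is.na(single$idw_pm25))
})

test_that("fused feature is invariant to the target's own record only in leave-target-out mode", {
  w <- tiny_world(n_stations = 50, grid_nx = 12, grid_ny = 12, n_days = 25)
  obs <- w$observations
  st <- w$stations[3, ]
  day <- w$dates[10]
  target <- tibble::tibble(station_id = st$station_id, lon = st$lon,
                           lat = st$lat, date = day)
  perturbed <- obs
  hit <- perturbed$station_id == st$station_id & perturbed$date == day
  expect_equal(sum(hit), 1)
  perturbed$pm25[hit] <- perturbed$pm25[hit] + 50

  lto <- fusion_config(mode = "leave_target_out")
  full <- fusion_config(mode = "full")
  f_lto_a <- build_idw_feature(obs, target, lto)$idw_pm25
  f_lto_b <- build_idw_feature(perturbed, target, lto)$idw_pm25
  expect_identical(f_lto_a, f_lto_b)
  f_full_a <- build_idw_feature(obs, target, full)$idw_pm25
  f_full_b <- build_idw_feature(perturbed, target, full)$idw_pm25
  expect_false(isTRUE(all.equal(f_full_a, f_full_b)))
})

test_that("every station-day feature in a feature table is leakage-free", {
  w <- tiny_world(n_days = 25)
  ft <- build_feature_table(w)
  # Perturb every observation at one date; features on that date must not
  # change for the perturbed station itself.
  day <- w$dates[12]
  obs2 <- w$observations
  sel <- obs2$date == day
  obs2$pm25[sel] <- obs2$pm25[sel] + 100
  w2 <- w; w2$observations <- obs2
  ft2 <- build_feature_table(w2)
  same_day <- ft$date == day
  expect_equal(ft$idw_pm25[!same_day], ft2$idw_pm25[!same_day])
  # On the perturbed day, each station's own feature uses only the others:
  # it changes because its neighbours changed, but removing neighbours'
  # influence entirely (perturb only station S) leaves S's feature fixed.
  s <- w$stations$station_id[1]
  obs3 <- w$observations
  sel3 <- obs3$station_id == s & obs3$date == day
  obs3$pm25[sel3] <- obs3$pm25[sel3] + 100
  w3 <- w; w3$observations <- obs3
  ft3 <- build_feature_table(w3)
  own <- ft$station_id == s & ft$date == day
  expect_equal(ft$idw_pm25[own], ft3$idw_pm25[own])
  others <- ft$station_id != s & ft$date == day
  expect_false(isTRUE(all.equal(ft$idw_pm25[others], ft3$idw_pm25[others])))
})
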