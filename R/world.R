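#' Configuration for a synthetic PM2.5 world
#'
#' Defines the generative model for a seeded synthetic spatiotemporal world: a
#' regular grid carrying a daily true PM2.5 field with seasonal cycle, spatial
#' and temporal autocorrelation, episodic wildfire smoke, satellite-style
#' covariates (two gappy AOD bands, meteorology, wind, elevation, 16-day NDVI)
#' and a sparse, possibly irregularly reporting station network. Everything
#' downstream of this object is a pure function of `(config, seed)`.
#'
#' The true field is
#' `PM2.5(s,t) = baseline_mu + seasonal_amp * cos(2*pi*(doy-1)/365) + G(s,t) +
#'  smoke_beta * density(s,t) + eps`, clamped at 0, where `G` is a Gaussian
#' field with exponential spatial covariance (correlation length
#' `spatial_range_km`, marginal sd `field_sd`) evolving as an AR(1) process in
#' time with coefficient `ar1_rho`, and `eps` is iid cell-day noise with sd
#' `noise_sd`. Station observations add independent measurement noise with sd
#' `obs_noise_sd`.
#'
#' @param grid_nx,grid_ny Grid cell counts in x and y.
#' @param cell_km Grid spacing in km.
#' @param n_stations Number of monitoring stations (>= 10).
#' @param n_days Number of days (>= 21, one full sequence window).
#' @param start_date First calendar date (anything `as.Date()` accepts).
#' @param baseline_mu Mean PM2.5 in ug/m3.
#' @param seasonal_amp Seasonal amplitude in ug/m3 (peak at Jan 1).
#' @param field_sd Marginal sd of the spatiotemporal Gaussian field, ug/m3.
#' @param spatial_range_km Correlation length of the exponential covariance.
#' @param ar1_rho Daily temporal autocorrelation in `[0, 1)`.
#' @param noise_sd Cell-day micro-variability sd, ug/m3.
#' @param smoke_beta PM2.5 added per smoke-density level, ug/m3.
#' @param n_smoke_events,smoke_radius_km,smoke_duration_days Smoke event
#'   count, disk radius and duration used by [generate_world()].
#' @param aod_slope,aod_intercept,aod_noise_sd Linear AOD given PM2.5 model.
#' @param aod_missing_rate Fraction of AOD cell-days masked, in `[0, 1)`.
#' @param station_reporting_period Days between station reports (1 = daily,
#'   3 = one-in-three-day reporting).
#' @param obs_noise_sd Station measurement noise sd, ug/m3.
#' @param station_placement `"uniform"` (default) or `"clustered"`.
#' @param origin_lon,origin_lat Geographic coordinates of the grid origin
#'   (south-west corner), degrees WGS84.
#' @param seed Integer seed; the single source of randomness.
#'
#' @return An object of class `world_config` (a named list).
#' @export
#' @examples
#' cfg <- world_config(grid_nx = 12, grid_ny = 12, n_stations = 12,
#'                     n_days = 30, seed = 1)
#' w <- generate_world(cfg)
#' dim(w$true_pm25)
world_config <- function(grid_nx = 20, grid_ny = 20, cell_km = 10,
                         n_stations = 25, n_days = 90,
                         start_date = "2020-06-01",
                         baseline_mu = 8, seasonal_amp = 3, field_sd = 5,
                         spatial_range_km = 60, ar1_rho = 0.8, noise_sd = 0.5,
                         smoke_beta = 10, n_smoke_events = 3,
                         smoke_radius_km = 40, smoke_duration_days = 7,
                         aod_slope = 0.02, aod_intercept = 0.05,
                         aod_noise_sd = 0.02, aod_missing_rate = 0.35,
                         station_reporting_period = 1, obs_noise_sd = 1,
                         station_placement = c("uniform", "clustered"),
                         origin_lon = -108, origin_lat = 38, seed = 1) {
  cfg <- list(
    grid_nx = as.integer(grid_nx), grid_ny = as.integer(grid_ny),
    cell_km = cell_km, n_stations = as.integer(n_stations),
    n_days = as.integer(n_days), start_date = as.Date(start_date),
    baseline_mu = baseline_mu, seasonal_amp = seasonal_amp,
    field_sd = field_sd, spatial_range_km = spatial_range_km,
    ar1_rho = ar1_rho, noise_sd = noise_sd, smoke_beta = smoke_beta,
    n_smoke_events = as.integer(n_smoke_events),
    smoke_radius_km = smoke_radius_km,
    smoke_duration_days = as.integer(smoke_duration_days),
    aod_slope = aod_slope, aod_intercept = aod_intercept,
    aod_noise_sd = aod_noise_sd, aod_missing_rate = aod_missing_rate,
    station_reporting_period = as.integer(station_reporting_period),
    obs_noise_sd = obs_noise_sd,
    station_placement = match.arg(station_placement),
    origin_lon = origin_lon, origin_lat = origin_lat,
    seed = as.integer(seed)
  )
  validate_world_config(cfg)
  structure(cfg, class = "world_config")
}

validate_world_config <- function(cfg) {
  assert_field(cfg$grid_nx >= 2 && cfg$grid_ny >= 2, "grid_nx/grid_ny",
               "must be at least 2")
  assert_field(cfg$cell_km > 0, "cell_km", "must be positive")
  assert_field(cfg$n_stations >= 10, "n_stations",
               "must be >= 10 (KNN-IDW needs nine neighbours plus the target)")
  assert_field(cfg$n_stations <= cfg$grid_nx * cfg$grid_ny, "n_stations",
               "cannot exceed the number of grid cells")
  assert_field(cfg$n_days >= 21, "n_days",
               "must be >= 21 (one full sequence window)")
  assert_field(!is.na(cfg$start_date), "start_date", "must be a valid date")
  assert_field(cfg$field_sd >= 0, "field_sd", "must be non-negative")
  assert_field(cfg$spatial_range_km > 0, "spatial_range_km",
               "must be positive")
  assert_field(cfg$ar1_rho >= 0 && cfg$ar1_rho < 1, "ar1_rho",
               "must be in [0, 1)")
  assert_field(cfg$noise_sd >= 0, "noise_sd", "must be non-negative")
  assert_field(cfg$aod_noise_sd >= 0, "aod_noise_sd", "must be non-negative")
  assert_field(cfg$aod_missing_rate >= 0 && cfg$aod_missing_rate < 1,
               "aod_missing_rate", "must be in [0, 1)")
  assert_field(cfg$station_reporting_period >= 1, "station_reporting_period",
               "must be >= 1")
  assert_field(cfg$obs_noise_sd >= 0, "obs_noise_sd", "must be non-negative")
  assert_field(cfg$n_smoke_events >= 0, "n_smoke_events",
               "must be non-negative")
  invisible(cfg)
}

# --- Gaussian random field -------------------------------------------------

# One standard-normal-marginal spatial innovation with exponential covariance
# exp(-d / range_km), sampled by circulant embedding on a padded torus.
# Negative embedding eigenvalues (a known small defect of the plain embedding
# for the exponential model) are clamped to zero; the stationarity property
# tests define adequacy of the approximation.
grf_spectrum <- function(nx, ny, cell_km, range_km) {
  mx <- stats::nextn(4L * nx, c(2, 3, 5))
  my <- stats::nextn(4L * ny, c(2, 3, 5))
  dx <- pmin(0:(mx - 1), mx - 0:(mx - 1)) * cell_km
  dy <- pmin(0:(my - 1), my - 0:(my - 1)) * cell_km
  d <- sqrt(outer(dx^2, dy^2, `+`))
  lam <- Re(stats::fft(exp(-d / range_km)))
  lam[lam < 0] <- 0
  list(mx = mx, my = my, lam = lam)
}

grf_draw <- function(spec, nx, ny) {
  m <- spec$mx * spec$my
  z <- matrix(stats::rnorm(m), spec$mx, spec$my) +
    1i * matrix(stats::rnorm(m), spec$mx, spec$my)
  x <- stats::fft(sqrt(spec$lam) * z)
  Re(x[seq_len(nx), seq_len(ny)]) / sqrt(m)
}

# Stack of n_days fields with AR(1) temporal evolution and constant marginal
# variance field_sd^2.
sim_grf_stack <- function(nx, ny, cell_km, range_km, field_sd, rho, n_days,
                          seed) {
  g <- array(0, dim = c(nx, ny, n_days))
  if (field_sd == 0) return(g)
  with_seed(seed, {
    spec <- grf_spectrum(nx, ny, cell_km, range_km)
    g[, , 1] <- grf_draw(spec, nx, ny)
    if (n_days > 1) {
      innov_scale <- sqrt(1 - rho^2)
      for (t in 2:n_days) {
        g[, , t] <- rho * g[, , t - 1] + innov_scale * grf_draw(spec, nx, ny)
      }
    }
  })
  g * field_sd
}

# --- World assembly --------------------------------------------------------

world_grid <- function(cfg) {
  # Cell centres; km offsets converted to degrees at the grid origin latitude.
  dlat <- cfg$cell_km / 111.32
  dlon <- cfg$cell_km / (111.32 * cos(cfg$origin_lat * pi / 180))
  ix <- rep(seq_len(cfg$grid_nx), times = cfg$grid_ny)
  iy <- rep(seq_len(cfg$grid_ny), each = cfg$grid_nx)
  tibble::tibble(
    cell = seq_along(ix), ix = ix, iy = iy,
    lon = cfg$origin_lon + (ix - 0.5) * dlon,
    lat = cfg$origin_lat + (iy - 0.5) * dlat
  )
}

seasonal_term <- function(cfg, dates) {
  cfg$seasonal_amp * cos(2 * pi * (date_doy(dates) - 1) / 365)
}

place_stations <- function(cfg) {
  with_seed(child_seed(cfg$seed, "stations"), {
    n_cells <- cfg$grid_nx * cfg$grid_ny
    if (cfg$station_placement == "uniform") {
      cells <- sample.int(n_cells, cfg$n_stations)
    } else {
      # A few cluster centres with geometric scatter, emulating the uneven
      # density of real monitoring networks.
      n_clusters <- max(2L, cfg$n_stations %/% 8L)
      cx <- sample.int(cfg$grid_nx, n_clusters, replace = TRUE)
      cy <- sample.int(cfg$grid_ny, n_clusters, replace = TRUE)
      cells <- integer(0)
      while (length(cells) < cfg$n_stations) {
        k <- sample.int(n_clusters, 1)
        ix <- pmin(pmax(cx[k] + round(stats::rnorm(1, 0, cfg$grid_nx / 8)), 1),
                   cfg$grid_nx)
        iy <- pmin(pmax(cy[k] + round(stats::rnorm(1, 0, cfg$grid_ny / 8)), 1),
                   cfg$grid_ny)
        cell <- (iy - 1L) * cfg$grid_nx + ix
        cells <- unique(c(cells, cell))
      }
      cells <- cells[seq_len(cfg$n_stations)]
    }
    grid <- world_grid(cfg)
    st <- grid[match(cells, grid$cell), ]
    tibble::tibble(
      station_id = sprintf("S%03d", seq_len(cfg$n_stations)),
      cell = st$cell, ix = st$ix, iy = st$iy, lon = st$lon, lat = st$lat
    )
  })
}

make_smoke_events <- function(cfg, n_events, radius_km, duration_days, seed) {
  if (n_events == 0) {
    return(tibble::tibble(event = integer(0), cx = integer(0), cy = integer(0),
                          radius_km = numeric(0), day_start = integer(0),
                          day_end = integer(0)))
  }
  with_seed(seed, {
    tibble::tibble(
      event = seq_len(n_events),
      cx = sample.int(cfg$grid_nx, n_events, replace = TRUE),
      cy = sample.int(cfg$grid_ny, n_events, replace = TRUE),
      radius_km = radius_km,
      day_start = sample.int(max(1L, cfg$n_days - duration_days + 1L),
                             n_events, replace = TRUE)
    ) |>
      dplyr::mutate(day_end = pmin(.data$day_start + duration_days - 1L,
                                   cfg$n_days))
  })
}

# Ordinal density raster from event disks: 3 in the core third of the radius,
# 2 in the middle third, 1 in the fringe; overlapping events take the maximum.
smoke_density_field <- function(cfg, events) {
  dens <- array(0L, dim = c(cfg$grid_nx, cfg$grid_ny, cfg$n_days))
  if (nrow(events) == 0) return(dens)
  ix <- matrix(seq_len(cfg$grid_nx), cfg$grid_nx, cfg$grid_ny)
  iy <- matrix(seq_len(cfg$grid_ny), cfg$grid_nx, cfg$grid_ny, byrow = TRUE)
  for (e in seq_len(nrow(events))) {
    d_km <- sqrt((ix - events$cx[e])^2 + (iy - events$cy[e])^2) * cfg$cell_km
    r <- events$radius_km[e]
    lev <- matrix(0L, cfg$grid_nx, cfg$grid_ny)
    lev[d_km <= r] <- 1L
    lev[d_km <= 2 * r / 3] <- 2L
    lev[d_km <= r / 3] <- 3L
    for (t in events$day_start[e]:events$day_end[e]) {
      dens[, , t] <- pmax(dens[, , t], lev)
    }
  }
  dens
}

met_covariates <- function(cfg, dates, g_field) {
  nx <- cfg$grid_nx; ny <- cfg$grid_ny; nt <- cfg$n_days
  ang <- 2 * pi * (date_doy(dates) - 1) / 365
  day_layer <- function(vals) {
    array(rep(vals, each = nx * ny), dim = c(nx, ny, nt))
  }
  with_seed(child_seed(cfg$seed, "met"), {
    lat_grad <- array(rep((seq_len(ny) - ny / 2) / ny, each = nx),
                      dim = c(nx, ny, nt))
    n <- nx * ny * nt
    # Temperatures carry a weak imprint of the pollution-driving field so the
    # meteorology is weakly informative, as in real data (the imprint is kept
    # well below the noise so meteorology alone cannot reconstruct the field).
    tmax <- day_layer(22 + 9 * cos(ang + pi)) - 4 * lat_grad +
      0.15 * g_field + array(stats::rnorm(n, 0, 1.5), dim = dim(g_field))
    tmin <- tmax - 8 - array(abs(stats::rnorm(n, 0, 1.5)), dim = dim(g_field))
    list(
      dayl = day_layer(43200 + 7200 * cos(ang)) - 600 * lat_grad,
      prcp = array(stats::rbinom(n, 1, 0.15) *
                     stats::rgamma(n, shape = 0.7, scale = 6),
                   dim = dim(g_field)),
      srad = day_layer(260 + 110 * cos(ang)) +
        array(stats::rnorm(n, 0, 25), dim = dim(g_field)),
      tmax = tmax,
      tmin = tmin,
      vp = day_layer(900 + 350 * cos(ang + pi)) +
        array(stats::rnorm(n, 0, 60), dim = dim(g_field)),
      wind_th = (day_layer(180 + 80 * sin(2 * pi * seq_len(nt) / 30)) +
                   array(stats::rnorm(n, 0, 20), dim = dim(g_field))) %% 360,
      wind_vs = pmax(3 + array(stats::rnorm(n, 0, 1), dim = dim(g_field)),
                     0.1)
    )
  })
}

ndvi_layers <- function(cfg, dates) {
  with_seed(child_seed(cfg$seed, "ndvi"), {
    layer_dates <- seq(min(dates) - 16, max(dates) + 16, by = 16)
    ang <- 2 * pi * (date_doy(layer_dates) - 1) / 365
    layers <- lapply(seq_along(layer_dates), function(i) {
      base <- 0.35 + 0.25 * cos(ang[i] + pi)
      pmin(pmax(base + matrix(stats::rnorm(cfg$grid_nx * cfg$grid_ny, 0, 0.05),
                              cfg$grid_nx, cfg$grid_ny), -1), 1)
    })
    list(dates = layer_dates, layers = layers)
  })
}

elevation_field <- function(cfg) {
  with_seed(child_seed(cfg$seed, "elev"), {
    ix <- matrix(seq_len(cfg$grid_nx), cfg$grid_nx, cfg$grid_ny)
    iy <- matrix(seq_len(cfg$grid_ny), cfg$grid_nx, cfg$grid_ny, byrow = TRUE)
    700 + 25 * ix + 15 * iy +
      matrix(stats::rnorm(cfg$grid_nx * cfg$grid_ny, 0, 60),
             cfg$grid_nx, cfg$grid_ny)
  })
}

# Recompute everything downstream of (base field, smoke density): the true
# field, the AOD bands (reusing the stored retrieval-noise draws and mask) and
# the station observations (reusing stored measurement-noise draws). Keeps
# inject_smoke_events() and apply_aod_missingness() pure and consistent.
rederive_world <- function(world) {
  cfg <- world$config
  world$true_pm25 <- pmax(world$base_pm25 +
                            cfg$smoke_beta * world$smoke_density, 0)
  aod_clean_047 <- cfg$aod_intercept + cfg$aod_slope * world$true_pm25
  world$aod_true_047 <- aod_clean_047 + world$aod_noise_047
  world$aod_true_055 <- 0.85 * aod_clean_047 + world$aod_noise_055
  a047 <- world$aod_true_047; a055 <- world$aod_true_055
  a047[world$aod_mask] <- NA_real_
  a055[world$aod_mask] <- NA_real_
  world$covariates$aod_047 <- a047
  world$covariates$aod_055 <- a055
  world$observations <- sample_station_observations(world, cfg)
  world
}

#' Generate a seeded synthetic world
#'
#' Builds the full synthetic world defined by a [world_config()]: true PM2.5
#' field, smoke-density raster, covariate stacks, station network and
#' observation table. Bit-identical output for identical `(config, seed)`.
#'
#' @param config A [world_config()].
#' @return An object of class `pm25_world`: a list with elements `config`,
#'   `dates`, `grid`, `stations`, `observations` (a tibble of
#'   station-day PM2.5 records), `true_pm25`, `base_pm25`, `smoke_density`
#'   (`grid_nx x grid_ny x n_days` arrays), `smoke_events`, `covariates`
#'   (named list of arrays), `elevation`, `ndvi` and AOD truth/mask arrays.
#' @export
generate_world <- function(config) {
  stopifnot(inherits(config, "world_config"))
  validate_world_config(config)
  cfg <- config
  dates <- cfg$start_date + 0:(cfg$n_days - 1)
  g <- sim_grf_stack(cfg$grid_nx, cfg$grid_ny, cfg$cell_km,
                     cfg$spatial_range_km, cfg$field_sd, cfg$ar1_rho,
                     cfg$n_days, child_seed(cfg$seed, "field"))
  eps <- if (cfg$noise_sd > 0) {
    with_seed(child_seed(cfg$seed, "micro"),
              array(stats::rnorm(length(g), 0, cfg$noise_sd), dim = dim(g)))
  } else {
    array(0, dim = dim(g))
  }
  seas <- array(rep(seasonal_term(cfg, dates),
                    each = cfg$grid_nx * cfg$grid_ny), dim = dim(g))
  base <- cfg$baseline_mu + seas + g + eps

  events <- make_smoke_events(cfg, cfg$n_smoke_events, cfg$smoke_radius_km,
                              cfg$smoke_duration_days,
                              child_seed(cfg$seed, "smoke"))
  dens <- smoke_density_field(cfg, events)

  world <- list(config = cfg, dates = dates, grid = world_grid(cfg),
                base_pm25 = base, smoke_density = dens, smoke_events = events,
                g_field = g)
  world$stations <- place_stations(cfg)
  world$covariates <- met_covariates(cfg, dates, g)
  world$elevation <- elevation_field(cfg)
  world$ndvi <- ndvi_layers(cfg, dates)
  world$aod_noise_047 <- with_seed(child_seed(cfg$seed, "aod1"),
    array(stats::rnorm(length(g), 0, cfg$aod_noise_sd), dim = dim(g)))
  world$aod_noise_055 <- with_seed(child_seed(cfg$seed, "aod2"),
    array(stats::rnorm(length(g), 0, 0.8 * cfg$aod_noise_sd), dim = dim(g)))
  world$obs_noise <- with_seed(child_seed(cfg$seed, "obs"),
    matrix(stats::rnorm(cfg$n_stations * cfg$n_days, 0, cfg$obs_noise_sd),
           cfg$n_stations, cfg$n_days))
  world$report_phase <- with_seed(child_seed(cfg$seed, "phase"),
    sample.int(cfg$station_reporting_period, cfg$n_stations, replace = TRUE))
  world$aod_mask <- if (cfg$aod_missing_rate > 0) {
    with_seed(child_seed(cfg$seed, "aodmask"),
      array(stats::runif(length(g)) < cfg$aod_missing_rate, dim = dim(g)))
  } else {
    array(FALSE, dim = dim(g))
  }
  world <- rederive_world(world)
  class(world) <- "pm25_world"
  world
}

#' Sample station observations from a world
#'
#' Each station reports every `station_reporting_period` days with a
#' per-station phase offset; reported values are the true field at the
#' station's cell plus Gaussian measurement noise (sd `obs_noise_sd`),
#' clamped at zero.
#'
#' @param world A `pm25_world`.
#' @param config The [world_config()] governing reporting (defaults to the
#'   world's own config).
#' @return A tibble with columns `station_id`, `lon`, `lat`, `date`, `pm25`.
#' @export
sample_station_observations <- function(world, config = world$config) {
  cfg <- config
  st <- world$stations
  period <- cfg$station_reporting_period
  rows <- lapply(seq_len(nrow(st)), function(i) {
    phase <- if (period > 1) world$report_phase[i] else 1L
    days <- seq.int(((phase - 1L) %% period) + 1L, cfg$n_days, by = period)
    truth <- world$true_pm25[st$ix[i], st$iy[i], days]
    tibble::tibble(
      station_id = st$station_id[i], lon = st$lon[i], lat = st$lat[i],
      date = world$dates[days],
      pm25 = pmax(truth + world$obs_noise[i, days], 0)
    )
  })
  dplyr::bind_rows(rows)
}

#' Replace the smoke-event set of a world
#'
#' Draws `n_events` spatiotemporal disks (density 3 in the core third of the
#' radius, 2 in the middle, 1 in the fringe) and re-derives the true PM2.5
#' field, AOD stacks and station observations so the smoke term reflects the
#' new density field.
#'
#' @param world A `pm25_world`.
#' @param n_events Number of events (0 clears all smoke).
#' @param event_radius_km Disk radius in km.
#' @param event_duration_days Event duration in days.
#' @param seed Seed for event placement.
#' @return The modified `pm25_world`.
#' @export
inject_smoke_events <- function(world, n_events, event_radius_km,
                                event_duration_days, seed = world$config$seed) {
  stopifnot(n_events >= 0, event_radius_km > 0, event_duration_days > 0)
  cfg <- world$config
  events <- make_smoke_events(cfg, as.integer(n_events), event_radius_km,
                              as.integer(event_duration_days),
                              child_seed(seed, "smoke"))
  world$smoke_events <- events
  world$smoke_density <- smoke_density_field(cfg, events)
  rederive_world(world)
}

#' Mask AOD cell-days at random
#'
#' Independently masks each AOD cell-day with probability `rate` (both bands
#' share the mask, as in a shared retrieval failure); other covariates are
#' untouched. Masked cells carry `NA`; the gap-free truth is retained in the
#' world for held-back evaluation of imputation.
#'
#' @param world A `pm25_world`.
#' @param rate Missingness probability in `[0, 1)`.
#' @param seed Seed for the mask draw.
#' @return The modified `pm25_world`.
#' @export
apply_aod_missingness <- function(world, rate, seed = world$config$seed) {
  stopifnot(rate >= 0, rate < 1)
  dims <- dim(world$true_pm25)
  world$aod_mask <- if (rate > 0) {
    with_seed(child_seed(seed, "aodmask"),
              array(stats::runif(prod(dims)) < rate, dim = dims))
  } else {
    array(FALSE, dim = dims)
  }
  world$config$aod_missing_rate <- rate
  rederive_world(world)
}

#' Write the station observation table as CSV
#'
#' Writes `station_id,lon,lat,date,pm25` with ISO-8601 dates, plus a JSON
#' manifest of the generating config and seed alongside.
#'
#' @param world A `pm25_world`.
#' @param path Output CSV path.
#' @param manifest Write the JSON manifest next to the CSV? Default `TRUE`.
#' @return `path`, invisibly.
#' @export
write_stations_csv <- function(world, path, manifest = TRUE) {
  obs <- world$observations
  obs$date <- format(obs$date, "%Y-%m-%d")
  utils::write.csv(obs, path, row.names = FALSE, quote = FALSE)
  if (manifest) {
    cfg <- world$config
    cfg$start_date <- format(cfg$start_date, "%Y-%m-%d")
    jsonlite::write_json(list(config = unclass(cfg)),
                         sub("\\.csv$", ".manifest.json", path),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(path)
}

#' Read a station observation table from CSV
#'
#' @param path CSV path with columns `station_id,lon,lat,date,pm25`.
#' @return A tibble with `date` parsed to `Date`.
#' @export
read_stations_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$date <- as.Date(df$date)
  tibble::as_tibble(df)
}

#' @export
print.pm25_world <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "<pm25_world> %d x %d grid (%g km cells), %d days from %s, %d stations\n",
    cfg$grid_nx, cfg$grid_ny, cfg$cell_km, cfg$n_days,
    format(cfg$start_date), cfg$n_stations))
  cat(sprintf("  true PM2.5: mean %.2f, max %.2f ug/m3; smoke cell-days: %d\n",
              mean(x$true_pm25), max(x$true_pm25),
              sum(x$smoke_density > 0)))
  invisible(x)
}
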