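# Shared fixture factories; everything is generated in code, seeded.

tiny_world_config <- function(...) {
  args <- list(grid_nx = 10, grid_ny = 10, cell_km = 10, n_stations = 12,
               n_days = 30, n_smoke_events = 1, smoke_radius_km = 30,
               smoke_duration_days = 5, aod_missing_rate = 0.2, seed = 101)
  override <- list(...)
  args[names(override)] <- override
  do.call(world_config, args)
}

tiny_world <- function(...) generate_world(tiny_world_config(...))

# A small synthetic sequence set with known structure (not from a world),
# for model-level tests.
random_seq_set <- function(n = 8, window = 21, f = 6, seed = 1,
                           mask_frac = 0) {
  set.seed(seed)
  X <- array(rnorm(n * window * f), dim = c(n, window, f))
  mask <- matrix(FALSE, n, window)
  if (mask_frac > 0) {
    mask <- matrix(runif(n * window) < mask_frac, n, window)
    mask[, window] <- FALSE  # keep the query step unmasked at least once
    mask[cbind(1:n, sample(window, n, replace = TRUE))] <- FALSE
  }
  y <- rnorm(n, 0, 0.5)
  structure(list(
    X = X, mask = mask, y = y, y_raw = y,
    meta = tibble::tibble(cell = seq_len(n),
                          date = as.Date("2020-07-01") + seq_len(n)),
    features = paste0("f", seq_len(f)), window = window, sentinel = -2,
    scaler = structure(list(
      params = tibble::tibble(feature = paste0("f", seq_len(f)),
                              min = 0, max = 1, median_scaled = 0),
      target_min = 0, target_max = 1), class = "scaler_params")
  ), class = "sequence_set")
}

tiny_model <- function(f = 6, widths = c(8, 4, 4), window = 21,
                       dropout = 0, bidirectional = TRUE, seed = 3) {
  cfg <- model_config(n_features = f, widths = widths, dropout = dropout,
                      bidirectional = bidirectional,
                      width_mode = "per_direction", window = window,
                      seed = seed)
  list(cfg = cfg, params = pm25seq:::init_params(cfg))
}

# Observation table on a line of stations, one day, for fusion tests.
line_observations <- function(values, spacing_km = 10,
                              date = as.Date("2020-07-01")) {
  n <- length(values)
  dlat <- spacing_km / 111.32
  tibble::tibble(
    station_id = sprintf("L%02d", seq_len(n)),
    lon = 0, lat = (seq_len(n) - 1) * dlat,
    date = date, pm25 = values)
}
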