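#' Canonical predictor roster
#'
#' The fixed, versioned feature order used by sequence building, the model
#' checkpoint schema and the gridded-inference path: two AOD bands, six
#' meteorological surfaces, wind direction/velocity, wildfire smoke density,
#' elevation, 16-day NDVI, the fused IDW PM2.5 feature, latitude/longitude
#' and five temporal encodings — 21 predictors in all.
#'
#' @return Character vector of feature names, in order.
#' @export
feature_names <- function() {
  c("aod_047", "aod_055",
    "dayl", "prcp", "srad", "tmax", "tmin", "vp",
    "wind_th", "wind_vs",
    "wsd", "elevation", "ndvi", "idw_pm25",
    "lat", "lon",
    "cos_doy", "sin_doy", "cos_month", "sin_month", "year")
}

#' Cyclic temporal encodings for a date
#'
#' Cos/sin of `2*pi*(doy - 1)/365` and `2*pi*(month - 1)/12` (zero angle at
#' Jan 1 / January; a 365-day year is assumed throughout the simulator), plus
#' the calendar year as a numeric feature scaled later like any other.
#'
#' @param date A `Date` vector.
#' @return A tibble with columns `cos_doy`, `sin_doy`, `cos_month`,
#'   `sin_month`, `year`.
#' @export
encode_time <- function(date) {
  a_doy <- 2 * pi * (date_doy(date) - 1) / 365
  a_mon <- 2 * pi * (date_month(date) - 1) / 12
  tibble::tibble(cos_doy = cos(a_doy), sin_doy = sin(a_doy),
                 cos_month = cos(a_mon), sin_month = sin(a_mon),
                 year = as.numeric(date_year(date)))
}

#' Index of the closest dated layer
#'
#' For each query date, the layer whose date minimizes `|delta days|`; exact
#' ties go to the earlier layer. Used to assign 16-day NDVI composites to
#' daily estimation dates.
#'
#' @param date Query `Date` vector.
#' @param layer_dates Sorted `Date` vector of available layers.
#' @return Integer vector of layer indices.
#' @export
assign_ndvi <- function(date, layer_dates) {
  stopifnot(length(layer_dates) > 0)
  vapply(as.numeric(date), function(d) {
    dd <- abs(as.numeric(layer_dates) - d)
    which.min(dd)  # which.min takes the first (earlier) index on ties
  }, integer(1))
}

# --- Feature-table assembly ------------------------------------------------

# Long feature table for a set of (location, day) targets on the world grid.
# `cells` is an integer vector of grid cell ids; one row per cell per day.
grid_feature_rows <- function(world, cells, days = seq_along(world$dates)) {
  cfg <- world$config
  grid <- world$grid[match(cells, world$grid$cell), ]
  n_c <- length(cells); n_d <- length(days)
  idx_cell <- rep(seq_len(n_c), times = n_d)
  idx_day <- rep(days, each = n_c)
  flat <- function(a) a[cbind(grid$ix[idx_cell], grid$iy[idx_cell], idx_day)]
  dates <- world$dates[idx_day]
  ndvi_idx <- assign_ndvi(world$dates[days], world$ndvi$dates)[
    rep(seq_len(n_d), each = n_c)]
  ndvi_val <- vapply(seq_along(idx_cell), function(i) {
    world$ndvi$layers[[ndvi_idx[i]]][grid$ix[idx_cell[i]],
                                     grid$iy[idx_cell[i]]]
  }, numeric(1))
  out <- tibble::tibble(
    cell = grid$cell[idx_cell],
    lon = grid$lon[idx_cell], lat = grid$lat[idx_cell], date = dates,
    aod_047 = flat(world$covariates$aod_047),
    aod_055 = flat(world$covariates$aod_055),
    dayl = flat(world$covariates$dayl),
    prcp = flat(world$covariates$prcp),
    srad = flat(world$covariates$srad),
    tmax = flat(world$covariates$tmax),
    tmin = flat(world$covariates$tmin),
    vp = flat(world$covariates$vp),
    wind_th = flat(world$covariates$wind_th),
    wind_vs = flat(world$covariates$wind_vs),
    wsd = as.numeric(flat(world$smoke_density)),
    elevation = world$elevation[cbind(grid$ix[idx_cell], grid$iy[idx_cell])],
    ndvi = ndvi_val
  )
  dplyr::bind_cols(out, encode_time(dates))
}

#' Assemble the per-(station, day) feature table for a world
#'
#' One row per station per day, carrying the full predictor roster: grid
#' covariates at the station's cell, the NDVI layer nearest in time, temporal
#' encodings, and the fused KNN-IDW PM2.5 feature (leave-target-out by
#' default, so a station's own same-day measurement never enters its own
#' feature). The observed station PM2.5 (`y`) is attached on reporting days
#' and `NA` elsewhere.
#'
#' @param world A `pm25_world`.
#' @param fusion A [fusion_config()].
#' @param include_wsd Keep the wildfire smoke density column? Setting `FALSE`
#'   supports the ablation study.
#' @return A tibble with metadata columns (`station_id`, `cell`, `lon`,
#'   `lat`, `date`), the predictors of [feature_names()] and the target `y`.
#' @export
build_feature_table <- function(world, fusion = fusion_config(),
                                include_wsd = TRUE) {
  st <- world$stations
  ft <- grid_feature_rows(world, st$cell)
  ft$station_id <- st$station_id[match(ft$cell, st$cell)]
  ft <- build_idw_feature(world$observations, ft, fusion)
  obs <- world$observations
  key <- paste(obs$station_id, obs$date)
  ft$y <- obs$pm25[match(paste(ft$station_id, ft$date), key)]
  if (!include_wsd) ft$wsd <- NULL
  dplyr::relocate(ft, "station_id", "cell", "lon", "lat", "date")
}

# --- AOD gap filling -------------------------------------------------------

aod_imputer_predictors <- function() {
  c("dayl", "prcp", "srad", "tmax", "tmin", "vp", "wind_th", "wind_vs",
    "elevation", "ndvi", "wsd", "lat", "lon",
    "cos_doy", "sin_doy", "cos_month", "sin_month", "year")
}

# Per-day box sums and observation counts over a (2r+1)^2 neighbourhood.
box_sums <- function(stack, r) {
  d <- dim(stack)
  s <- array(0, dim = d); n <- array(0, dim = d)
  for (t in seq_len(d[3])) {
    x <- stack[, , t]
    obs <- !is.na(x)
    xz <- x; xz[!obs] <- 0
    st <- matrix(0, d[1], d[2]); nt <- matrix(0, d[1], d[2])
    for (di in -r:r) for (dj in -r:r) {
      si <- max(1, 1 - di):min(d[1], d[1] - di)
      sj <- max(1, 1 - dj):min(d[2], d[2] - dj)
      st[si, sj] <- st[si, sj] + xz[si + di, sj + dj]
      nt[si, sj] <- nt[si, sj] + obs[si + di, sj + dj]
    }
    s[, , t] <- st; n[, , t] <- nt
  }
  list(s = s, n = n)
}

# Mean of observed values in a (2r+1)^2 x (2rt+1)-day spatiotemporal box;
# cells with no observed neighbour fall back to the stack mean.
box_mean_stack <- function(stack, r, rt = 0) {
  d <- dim(stack)
  bs <- box_sums(stack, r)
  s <- bs$s; n <- bs$n
  if (rt > 0) {
    s2 <- s; n2 <- n
    for (dt in setdiff(-rt:rt, 0)) {
      tt <- seq_len(d[3])
      src <- pmin(pmax(tt + dt, 1), d[3])
      s2 <- s2 + bs$s[, , src, drop = FALSE]
      n2 <- n2 + bs$n[, , src, drop = FALSE]
    }
    s <- s2; n <- n2
  }
  m <- s / n
  m[n == 0] <- mean(stack, na.rm = TRUE)
  m
}

# Neighbour composites of the observed (gappy) stack, used as imputer
# predictors: per-cell linear interpolation of observed values through time,
# the same-day local box mean of observed cells, and the per-day spatial
# mean. All derive only from observed retrievals, never from held-back truth.
aod_neighbor_predictors <- function(stack) {
  d <- dim(stack)
  flat <- matrix(stack, d[1] * d[2], d[3])  # cells x days
  overall <- mean(flat, na.rm = TRUE)
  tinterp <- t(apply(flat, 1, function(v) {
    obs <- which(!is.na(v))
    if (length(obs) == 0) return(rep(overall, length(v)))
    if (length(obs) == 1) return(rep(v[obs], length(v)))
    stats::approx(obs, v[obs], xout = seq_along(v), rule = 2)$y
  }))
  dmean <- colMeans(flat, na.rm = TRUE)
  dmean[is.nan(dmean)] <- overall
  list(time_interp = as.vector(tinterp),
       local_mean1 = as.vector(box_mean_stack(stack, 1)),
       local_mean = as.vector(box_mean_stack(stack, 2)),
       st_mean = as.vector(box_mean_stack(stack, 2, rt = 1)),
       day_mean = rep(dmean, each = d[1] * d[2]))
}

#' Gap-fill the AOD stacks with gradient boosting
#'
#' Trains one gradient-boosted regressor per AOD band on the observed
#' cell-days and predicts the masked cells. Predictors: meteorology, wind,
#' elevation, NDVI, smoke density, latitude/longitude, temporal encodings,
#' and two neighbour composites of the observed retrievals themselves (the
#' cell's temporally interpolated observed series and the day's spatial mean
#' of observed cells) — the standard ingredients of satellite gap-filling.
#' Observed cells pass through unchanged; the returned world has gap-free
#' AOD stacks.
#'
#' @param world A `pm25_world` whose AOD stacks may contain `NA`.
#' @param nrounds Boosting rounds per band.
#' @param max_train_rows Cap on training cell-days (sampled, seeded) to bound
#'   fitting cost on large worlds.
#' @param seed Seed for row subsampling.
#' @return The world with imputed `covariates$aod_047` / `aod_055`; the
#'   per-band training RMSE is attached as attribute `aod_imputation_rmse`.
#' @export
impute_aod <- function(world, nrounds = 150, max_train_rows = 50000,
                       seed = world$config$seed) {
  mask <- world$aod_mask
  if (!any(mask)) return(world)
  if (all(mask)) stop("all AOD cell-days are missing; nothing to train on",
                      call. = FALSE)
  ft <- grid_feature_rows(world, world$grid$cell)
  pred_cols <- aod_imputer_predictors()
  xmat <- as.matrix(ft[, pred_cols])
  miss <- as.vector(mask)
  rmse <- c(aod_047 = NA_real_, aod_055 = NA_real_)
  for (band in c("aod_047", "aod_055")) {
    y_obs <- as.vector(world$covariates[[band]])
    obs_idx <- which(!miss)
    # Train on rotating pseudo-gaps: hold an eighth of the observed cells
    # out at a time, rebuild the neighbour composites without them, and
    # learn to predict the held-out retrievals. The target never contributes
    # to its own composites, and because each holdout is small, the
    # composite availability during training matches the real gaps.
    add_nb <- function(nb) cbind(
      xmat, aod_time_interp = nb$time_interp,
      aod_local_mean1 = nb$local_mean1, aod_local_mean = nb$local_mean,
      aod_st_mean = nb$st_mean, aod_day_mean = nb$day_mean)
    rotations <- with_seed(child_seed(seed, paste0("aodimp_", band)), {
      shuffled <- sample(obs_idx)
      split(shuffled, rep_len(seq_len(8L), length(shuffled)))[1:4]
    })
    xmat_tr <- NULL; y_tr <- NULL
    for (rot in rotations) {
      pseudo <- world$covariates[[band]]
      pseudo[rot] <- NA_real_
      xmat_tr <- rbind(xmat_tr,
                       add_nb(aod_neighbor_predictors(pseudo))[rot, ,
                                                               drop = FALSE])
      y_tr <- c(y_tr, y_obs[rot])
    }
    if (length(y_tr) > max_train_rows) {
      keep <- seq_len(max_train_rows)
      xmat_tr <- xmat_tr[keep, , drop = FALSE]
      y_tr <- y_tr[keep]
    }
    booster <- xgboost::xgboost(
      x = xmat_tr, y = y_tr,
      objective = "reg:squarederror", nrounds = nrounds, max_depth = 6,
      learning_rate = 0.1, subsample = 0.8, nthreads = 1, seed = 0L
    )
    # Predict the real gaps with composites built from all observed cells.
    xmat_b <- add_nb(aod_neighbor_predictors(world$covariates[[band]]))
    filled <- y_obs
    filled[miss] <- stats::predict(booster, xmat_b[miss, , drop = FALSE])
    world$covariates[[band]] <- array(filled, dim = dim(mask))
    rmse[band] <- sqrt(mean((stats::predict(booster, xmat_tr) - y_tr)^2))
  }
  attr(world, "aod_imputation_rmse") <- rmse
  world
}

# --- MinMax scaling --------------------------------------------------------

#' Fit a feature-wise MinMax scaler on the training split
#'
#' Records, for every predictor and for the target, the observed training
#' minimum and maximum (and the scaled-space median used for partial-day gap
#' filling). [apply_scaler()] maps `x` to `2*(x - min)/(max - min) - 1`, i.e.
#' the training range maps onto `[-1, 1]`; values outside the training range
#' map outside `[-1, 1]` and are deliberately not clipped. A constant feature
#' maps to 0.
#'
#' @param train_df Training-split feature table.
#' @param features Predictor columns (default [feature_names()], intersected
#'   with the table).
#' @param target Target column name, or `NULL` to skip target scaling.
#' @return A `scaler_params` object.
#' @export
fit_scaler <- function(train_df, features = feature_names(), target = "y") {
  features <- intersect(features, names(train_df))
  rng <- lapply(features, function(f) {
    x <- train_df[[f]]
    x <- x[is.finite(x)]
    if (length(x) == 0) return(c(0, 0, 0))
    c(min(x), max(x), stats::median(x))
  })
  params <- tibble::tibble(
    feature = features,
    min = vapply(rng, `[`, numeric(1), 1),
    max = vapply(rng, `[`, numeric(1), 2)
  )
  params$median_scaled <- minmax_scale(vapply(rng, `[`, numeric(1), 3),
                                       params$min, params$max)
  out <- list(params = params)
  if (!is.null(target) && target %in% names(train_df)) {
    yt <- train_df[[target]]
    yt <- yt[is.finite(yt)]
    out$target_min <- min(yt)
    out$target_max <- max(yt)
  }
  structure(out, class = "scaler_params")
}

# `mn`/`mx` may be scalars or per-element vectors; a degenerate (constant)
# feature maps to 0 rather than dividing by zero.
minmax_scale <- function(x, mn, mx) {
  z <- 2 * (x - mn) / (mx - mn) - 1
  deg <- rep_len(mx <= mn, length(x))
  z[deg & !is.na(x)] <- 0
  z
}

minmax_invert <- function(s, mn, mx) {
  z <- (s + 1) / 2 * (mx - mn) + mn
  deg <- rep_len(mx <= mn, length(s))
  z[deg & !is.na(s)] <- rep_len(mn, length(s))[deg & !is.na(s)]
  z
}

#' Apply / invert a fitted MinMax scaler
#'
#' @param df Feature table (apply) or numeric vector in scaled target space
#'   (invert).
#' @param scaler A `scaler_params` from [fit_scaler()].
#' @return `apply_scaler()`: the table with scaled predictor columns;
#'   `invert_scaler_target()` / `apply_scaler_target()`: numeric vectors.
#' @export
apply_scaler <- function(df, scaler) {
  for (i in seq_len(nrow(scaler$params))) {
    f <- scaler$params$feature[i]
    if (f %in% names(df)) {
      df[[f]] <- minmax_scale(df[[f]], scaler$params$min[i],
                              scaler$params$max[i])
    }
  }
  df
}

#' @rdname apply_scaler
#' @export
apply_scaler_target <- function(df, scaler) {
  minmax_scale(df, scaler$target_min, scaler$target_max)
}

#' @rdname apply_scaler
#' @export
invert_scaler_target <- function(df, scaler) {
  minmax_invert(df, scaler$target_min, scaler$target_max)
}

# --- Sequence building -----------------------------------------------------

#' Build masked 21-day sequence samples
#'
#' For every target `(location, date)` with an observed target value, stacks
#' the scaled feature rows of days `t-20 ... t` (oldest first) into a
#' `21 x F` matrix. A day with no feature row, or whose fused IDW feature and
#' AOD are both missing, becomes a masked timestep: its row is filled with
#' the sentinel value and flagged in the timestep mask (the model consumes
#' the mask, never the sentinel). Remaining missing entries within an
#' unmasked day are filled with the training-split scaled median and counted
#' in `meta$n_filled`.
#'
#' @param features Feature table from [build_feature_table()] (unscaled),
#'   covering at least the window before each target.
#' @param targets Rows of `features` to use as targets; defaults to all rows
#'   with a non-missing `y`.
#' @param scaler A fitted [fit_scaler()]; supplies scaling and fill medians.
#' @param window Sequence length in days (default 21).
#' @param sentinel Fill value for masked rows (default -2, outside the scaled
#'   range).
#' @param location_col Column identifying a location's time series.
#' @return A `sequence_set`: list with `X` (`N x window x F` array), `mask`
#'   (`N x window`, `TRUE` = masked timestep), `y` (scaled targets), `y_raw`,
#'   `meta` tibble, `features` (column order) and the `scaler`. Targets with
#'   fewer than `window` days of record before them are skipped with a
#'   warning.
#' @export
build_sequences <- function(features, targets = NULL, scaler,
                            window = 21, sentinel = -2,
                            location_col = if ("station_id" %in%
                                               names(features)) "station_id"
                                           else "cell") {
  feats <- intersect(feature_names(), names(features))
  scaled <- apply_scaler(features, scaler)
  fmat <- as.matrix(scaled[, feats])
  med <- scaler$params$median_scaled[match(feats, scaler$params$feature)]
  key <- paste(features[[location_col]], features$date)
  if (is.null(targets)) {
    targets <- features[!is.na(features$y), ]
  }
  first_date <- min(features$date)
  ok <- targets$date - (window - 1) >= first_date
  if (any(!ok)) {
    warning(sprintf("skipping %d target(s) earlier than day %d of the record",
                    sum(!ok), window), call. = FALSE)
    targets <- targets[ok, , drop = FALSE]
  }
  n <- nrow(targets)
  f_n <- length(feats)
  X <- array(sentinel, dim = c(n, window, f_n))
  mask <- matrix(TRUE, n, window)
  n_filled <- integer(n)
  idw_j <- match("idw_pm25", feats)
  aod_j <- match(c("aod_047", "aod_055"), feats)
  for (i in seq_len(n)) {
    seq_dates <- targets$date[i] - (window - 1):0
    idx <- match(paste(targets[[location_col]][i], seq_dates), key)
    for (s in seq_len(window)) {
      if (is.na(idx[s])) next
      row <- fmat[idx[s], ]
      idw_missing <- !is.na(idw_j) && is.na(row[idw_j])
      aod_missing <- all(is.na(row[aod_j[!is.na(aod_j)]]))
      if (idw_missing && aod_missing) next  # fully masked timestep
      gaps <- is.na(row)
      if (any(gaps)) {
        row[gaps] <- med[gaps]
        n_filled[i] <- n_filled[i] + sum(gaps)
      }
      X[i, s, ] <- row
      mask[i, s] <- FALSE
    }
  }
  y_raw <- targets$y
  meta <- targets[, intersect(c("station_id", "cell", "lon", "lat", "date"),
                              names(targets))]
  meta$n_filled <- n_filled
  structure(list(
    X = X, mask = mask,
    y = if (!is.null(scaler$target_min)) apply_scaler_target(y_raw, scaler)
        else y_raw,
    y_raw = y_raw, meta = meta, features = feats, window = window,
    sentinel = sentinel, scaler = scaler
  ), class = "sequence_set")
}

#' @export
print.sequence_set <- function(x, ...) {
  cat(sprintf("<sequence_set> %d samples, window %d, %d features; %.1f%% masked timesteps\n",
              dim(x$X)[1], x$window, length(x$features), 100 * mean(x$mask)))
  invisible(x)
}

# Subset a sequence_set by sample index.
subset_sequences <- function(ss, idx) {
  ss$X <- ss$X[idx, , , drop = FALSE]
  ss$mask <- ss$mask[idx, , drop = FALSE]
  ss$y <- ss$y[idx]
  ss$y_raw <- ss$y_raw[idx]
  ss$meta <- ss$meta[idx, , drop = FALSE]
  ss
}
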