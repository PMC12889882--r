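#' Predict daily PM2.5 surfaces over the grid
#'
#' For every requested date and grid cell, assembles the 21-day covariate
#' sequence (fused feature in full mode: all station records incorporated,
#' as appropriate for a production surface after evaluation), runs inference
#' with the fitted model, inverse-scales and clamps at zero.
#'
#' @param fit A `pm25_fit` (or checkpoint loaded with [load_checkpoint()]).
#' @param world A `pm25_world` supplying covariates and observations.
#' @param dates Dates to predict (must have >= window - 1 days of covariates
#'   before them).
#' @param cells Grid cell ids (default: all).
#' @param fusion Fusion settings; mode is forced to `"full"`.
#' @param impute Gap-fill AOD first (default `TRUE`).
#' @return A `pm25_surface`: list with `dates`, `rasters` (list of
#'   `grid_nx x grid_ny` matrices, ug/m3), `grid`, `predictions` (long
#'   tibble) and the generating metadata.
#' @export
predict_grid <- function(fit, world, dates, cells = NULL,
                         fusion = fusion_config(mode = "full"),
                         impute = TRUE) {
  stopifnot(inherits(fit, "pm25_fit"))
  fusion$mode <- "full"
  dates <- as.Date(dates)
  window <- fit$model_config$window
  day_idx <- match(dates, world$dates)
  if (any(is.na(day_idx))) {
    stop("requested dates outside the world's record", call. = FALSE)
  }
  if (any(day_idx < window)) {
    stop(sprintf(
      "insufficient look-back: earliest predictable date is %s (%d covariate days required)",
      format(world$dates[window]), window), call. = FALSE)
  }
  if (impute && any(world$aod_mask)) world <- impute_aod(world)
  cells <- cells %||% world$grid$cell
  need_days <- seq.int(min(day_idx) - window + 1L, max(day_idx))
  ft <- grid_feature_rows(world, cells, need_days)
  ft <- build_idw_feature(world$observations, ft, fusion)
  if (!"wsd" %in% fit$features) ft$wsd <- NULL
  targets <- ft[ft$date %in% dates, , drop = FALSE]
  targets$y <- NA_real_
  ss <- build_sequences(ft, targets, fit$scaler, window = window,
                        location_col = "cell")
  pred <- stats::predict(fit, ss)
  pred$pred <- pmax(pred$pred, 0)
  cfg <- world$config
  rasters <- lapply(dates, function(d) {
    r <- matrix(NA_real_, cfg$grid_nx, cfg$grid_ny)
    sub <- pred[pred$date == d, ]
    g <- world$grid[match(sub$cell, world$grid$cell), ]
    r[cbind(g$ix, g$iy)] <- sub$pred
    r
  })
  names(rasters) <- format(dates)
  structure(list(dates = dates, rasters = rasters, grid = world$grid,
                 predictions = pred, config = cfg,
                 schema = schema_hash(fit$features)),
            class = "pm25_surface")
}

#' Write surfaces as ASCII grid rasters
#'
#' One ESRI ASCII grid (`.asc`, GDAL-readable text) per day, on the world's
#' local equidistant grid in metres (cell size `cell_km * 1000`), nodata
#' -9999, plus a JSON manifest carrying the WGS84 origin, cell size and
#' generation metadata so every raster is reproducible from config + seed.
#'
#' @param surface A `pm25_surface`.
#' @param dir Output directory (created if needed).
#' @return Character vector of the `.asc` paths, invisibly.
#' @export
write_surface_asc <- function(surface, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- surface$config
  cell_m <- cfg$cell_km * 1000
  paths <- vapply(seq_along(surface$dates), function(i) {
    path <- file.path(dir, sprintf("pm25_%s.asc",
                                   format(surface$dates[i], "%Y%m%d")))
    r <- surface$rasters[[i]]
    r[!is.finite(r)] <- -9999
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c(
      sprintf("ncols %d", nrow(r)),       # x dimension
      sprintf("nrows %d", ncol(r)),       # y dimension
      "xllcorner 0", "yllcorner 0",
      sprintf("cellsize %g", cell_m),
      "NODATA_value -9999"), con)
    # ASCII grids run north to south: top row = largest y index.
    for (iy in rev(seq_len(ncol(r)))) {
      writeLines(paste(sprintf("%.4f", r[, iy]), collapse = " "), con)
    }
    path
  }, character(1))
  jsonlite::write_json(
    list(crs = "local equidistant grid, metres; origin at WGS84 lon/lat below",
         origin_lon = cfg$origin_lon, origin_lat = cfg$origin_lat,
         cell_km = cfg$cell_km, nodata = -9999,
         dates = format(surface$dates), schema = surface$schema,
         units = "ug/m3"),
    file.path(dir, "surfaces.manifest.json"), auto_unbox = TRUE,
    pretty = TRUE)
  invisible(paths)
}

#' Read back an ASCII grid raster
#'
#' @param path A `.asc` file written by [write_surface_asc()].
#' @return A matrix in the package's `[ix, iy]` orientation, `NA` for
#'   nodata.
#' @export
read_surface_asc <- function(path) {
  hdr <- readLines(path, n = 6)
  val <- function(k) as.numeric(strsplit(hdr[grep(k, hdr)], " +")[[1]][2])
  ncols <- val("ncols"); nrows <- val("nrows"); nodata <- val("NODATA")
  dat <- scan(path, skip = 6, quiet = TRUE)
  m <- matrix(dat, nrow = ncols)  # columns of the file = one grid row (y)
  m <- m[, rev(seq_len(nrows)), drop = FALSE]
  m[m == nodata] <- NA_real_
  m
}

#' @export
print.pm25_surface <- function(x, ...) {
  cat(sprintf("<pm25_surface> %d day(s), %d x %d grid; range %.2f-%.2f ug/m3\n",
              length(x$dates), x$config$grid_nx, x$config$grid_ny,
              min(unlist(x$rasters), na.rm = TRUE),
              max(unlist(x$rasters), na.rm = TRUE)))
  invisible(x)
}
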