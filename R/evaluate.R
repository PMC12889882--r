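#' Core accuracy metrics
#'
#' `R2 = 1 - sum((y - pred)^2) / sum((y - mean(y))^2)`,
#' `RMSE = sqrt(mean((y - pred)^2))`, `MBE = mean(pred - y)` (positive =
#' systematic overestimation). With `log_space = TRUE` both vectors are
#' `log(1 + x)`-transformed first (the reporting convention for density
#' scatter comparisons dominated by high concentrations).
#'
#' @param data Data frame with columns `y` and `pred`, or a numeric vector
#'   of observations (then `pred` must be given).
#' @param pred Predictions when `data` is a vector.
#' @param log_space Compute metrics on `log1p` scale.
#' @return A tibble with `r2`, `rmse`, `mbe`, `n`. `r2` is `NA` (with a
#'   warning) when `y` is constant or `n < 2`.
#' @export
compute_metrics <- function(data, pred = NULL, log_space = FALSE) {
  if (is.data.frame(data)) {
    y <- data$y; yhat <- data$pred
  } else {
    y <- data; yhat <- pred
  }
  keep <- is.finite(y) & is.finite(yhat)
  y <- y[keep]; yhat <- yhat[keep]
  stopifnot(length(y) == length(yhat))
  if (log_space) {
    y <- log1p(y); yhat <- log1p(yhat)
  }
  n <- length(y)
  if (n == 0) {
    return(tibble::tibble(r2 = NA_real_, rmse = NA_real_, mbe = NA_real_,
                          n = 0L))
  }
  sse <- sum((y - yhat)^2)
  rmse <- sqrt(sse / n)
  mbe <- mean(yhat - y)
  sst <- sum((y - mean(y))^2)
  r2 <- if (n < 2 || sst == 0) {
    warning("R2 undefined for constant or single observation; reported NA",
            call. = FALSE)
    NA_real_
  } else {
    1 - sse / sst
  }
  tibble::tibble(r2 = r2, rmse = rmse, mbe = mbe, n = n)
}

#' Concentration category scheme
#'
#' The six air-quality concentration bins used for stratified evaluation,
#' with the conventional breakpoint gaps (12.0 vs 12.1 etc.) reconciled by
#' rounding values to one decimal before binning.
#'
#' @return A tibble with `category`, `lower`, `upper` (ug/m3).
#' @export
pm25_categories <- function() {
  tibble::tibble(
    category = c("Good", "Moderate", "Unhealthy for Sensitive Groups",
                 "Unhealthy", "Very Unhealthy", "Hazardous"),
    lower = c(0, 12.1, 35.5, 55.5, 150.5, 250.5),
    upper = c(12.0, 35.4, 55.4, 150.4, 250.4, Inf)
  )
}

#' Categorize PM2.5 concentrations
#'
#' Values are rounded to one decimal, then binned per [pm25_categories()].
#' Negative values are an error.
#'
#' @param pm25 Numeric vector, ug/m3.
#' @return An ordered factor of categories.
#' @export
categorize_pm25 <- function(pm25) {
  if (any(pm25 < 0, na.rm = TRUE)) {
    stop("PM2.5 concentrations must be non-negative", call. = FALSE)
  }
  sch <- pm25_categories()
  r <- round(pm25, 1)
  idx <- findInterval(r + 1e-9, c(sch$lower, Inf))
  # findInterval against lower bounds: value in [lower_i, lower_{i+1}) -> i
  factor(sch$category[idx], levels = sch$category, ordered = TRUE)
}

season_of <- function(date) {
  m <- date_month(date)
  factor(dplyr::case_when(
    m %in% 3:5 ~ "Spring", m %in% 6:8 ~ "Summer",
    m %in% 9:11 ~ "Autumn", TRUE ~ "Winter"),
    levels = c("Spring", "Summer", "Autumn", "Winter"))
}

#' Assign spatial regions by quadrant
#'
#' Default synthetic region partition: a 2x2 split of the domain at the
#' given (or median) longitude/latitude, labelled NW/NE/SW/SE. Real-data
#' runs can supply any precomputed `region` column instead.
#'
#' @param data Data frame with `lon`, `lat`.
#' @param lon_mid,lat_mid Split coordinates; default the data medians.
#' @return `data` with a `region` factor column added.
#' @export
assign_quadrant_region <- function(data, lon_mid = NULL, lat_mid = NULL) {
  lon_mid <- lon_mid %||% stats::median(data$lon)
  lat_mid <- lat_mid %||% stats::median(data$lat)
  ns <- ifelse(data$lat > lat_mid, "N", "S")
  ew <- ifelse(data$lon > lon_mid, "E", "W")
  data$region <- factor(paste0(ns, ew), levels = c("NW", "NE", "SW", "SE"))
  data
}

#' Season-by-region mean bias error table
#'
#' MBE per (season, region) cell with row and column averages. Samples with
#' a missing region are counted in an `"unassigned"` bucket with a warning.
#'
#' @param data Predictions with `y`, `pred`, `date` and a `region` column.
#' @return A wide tibble (one row per region, one column per season, plus
#'   `Avg`); the long per-cell table (`season`, `region`, `mbe`, `n`) is
#'   attached as attribute `"long"`.
#' @export
seasonal_regional_mbe <- function(data) {
  stopifnot(all(c("y", "pred", "date", "region") %in% names(data)))
  data$season <- season_of(data$date)
  if (any(is.na(data$region))) {
    warning(sprintf("%d sample(s) with no region; counted as 'unassigned'",
                    sum(is.na(data$region))), call. = FALSE)
    lv <- c(levels(data$region), "unassigned")
    data$region <- factor(ifelse(is.na(as.character(data$region)),
                                 "unassigned", as.character(data$region)),
                          levels = lv)
  }
  long <- data |>
    dplyr::group_by(.data$season, .data$region) |>
    dplyr::summarise(mbe = mean(.data$pred - .data$y), n = dplyr::n(),
                     .groups = "drop")
  wide <- long |>
    dplyr::select("season", "region", "mbe") |>
    tidyr::pivot_wider(names_from = "season", values_from = "mbe")
  season_cols <- intersect(levels(data$season), names(wide))
  wide$Avg <- rowMeans(wide[, season_cols], na.rm = TRUE)
  avg_row <- c(list(region = "Avg"),
               lapply(wide[, c(season_cols, "Avg")], mean, na.rm = TRUE))
  wide <- dplyr::bind_rows(wide, tibble::as_tibble(avg_row))
  attr(wide, "long") <- long
  wide
}

#' Full stratified metrics report
#'
#' Overall R2/RMSE/MBE plus the evaluation strata: concentration category,
#' season, region (quadrants unless a `region` column is present) and the
#' high-concentration subset (ground truth > 35 ug/m3).
#'
#' @param data Predictions with `y`, `pred` and optionally `date`, `lon`,
#'   `lat`, `region`.
#' @param high_threshold High-concentration cutoff, ug/m3 (default 35).
#' @return A `metrics_report`: list with `overall`, `by_category`,
#'   `by_season`, `by_region`, `high` tibbles and `n`.
#' @export
metrics_report <- function(data, high_threshold = 35) {
  stopifnot(all(c("y", "pred") %in% names(data)))
  overall <- compute_metrics(data)
  data$category <- categorize_pm25(pmax(data$y, 0))
  by_cat <- data |>
    dplyr::group_by(.data$category) |>
    dplyr::group_modify(~ suppressWarnings(compute_metrics(.x))) |>
    dplyr::ungroup()
  by_season <- NULL
  if ("date" %in% names(data)) {
    data$season <- season_of(data$date)
    by_season <- data |>
      dplyr::group_by(.data$season) |>
      dplyr::group_modify(~ suppressWarnings(compute_metrics(.x))) |>
      dplyr::ungroup()
  }
  by_region <- NULL
  if (!"region" %in% names(data) && all(c("lon", "lat") %in% names(data))) {
    data <- assign_quadrant_region(data)
  }
  if ("region" %in% names(data)) {
    by_region <- data |>
      dplyr::group_by(.data$region) |>
      dplyr::group_modify(~ suppressWarnings(compute_metrics(.x))) |>
      dplyr::ungroup()
  }
  high <- suppressWarnings(
    compute_metrics(data[data$y > high_threshold, , drop = FALSE]))
  structure(list(overall = overall, by_category = by_cat,
                 by_season = by_season, by_region = by_region, high = high,
                 high_threshold = high_threshold, n = overall$n),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  o <- x$overall
  cat(sprintf("<metrics_report> n = %d\n", x$n))
  cat(sprintf("  overall: R2 %.3f  RMSE %.3f  MBE %+.3f ug/m3\n",
              o$r2, o$rmse, o$mbe))
  if (is.finite(x$high$rmse)) {
    cat(sprintf("  > %g ug/m3 (n = %d): RMSE %.2f  MBE %+.2f\n",
                x$high_threshold, x$high$n, x$high$rmse, x$high$mbe))
  }
  invisible(x)
}

# --- Split protocol --------------------------------------------------------

#' Held-out test split plus k-fold partition
#'
#' Randomly holds out `test_frac` of the samples for final testing and
#' partitions the remainder into `k` disjoint, exhaustive folds. With
#' `blocks` (e.g. station ids), whole blocks are assigned to one side of
#' every split (station-blocked validation); the default is sample-random.
#'
#' @param n Number of samples.
#' @param seed Seed; identical seeds give identical assignments.
#' @param test_frac Held-out fraction (default 0.1).
#' @param k Fold count (default 10).
#' @param blocks Optional length-`n` blocking factor.
#' @return List with `test` (indices), `folds` (list of k index vectors) and
#'   `hash` (content hash of the assignment, for protocol identity checks).
#' @export
split_protocol <- function(n, seed = 1, test_frac = 0.1, k = 10,
                           blocks = NULL) {
  stopifnot(n >= 20)
  with_seed(child_seed(seed, "split"), {
    if (is.null(blocks)) {
      ord <- sample.int(n)
      n_test <- round(test_frac * n)
      test <- sort(ord[seq_len(n_test)])
      rest <- ord[(n_test + 1):n]
      fold_id <- rep_len(seq_len(k), length(rest))
      folds <- lapply(seq_len(k), function(f) sort(rest[fold_id == f]))
    } else {
      ub <- sample(unique(blocks))
      n_test_b <- max(1, round(test_frac * length(ub)))
      test_b <- ub[seq_len(n_test_b)]
      rest_b <- ub[-seq_len(n_test_b)]
      fold_b <- rep_len(seq_len(k), length(rest_b))
      test <- sort(which(blocks %in% test_b))
      folds <- lapply(seq_len(k), function(f)
        sort(which(blocks %in% rest_b[fold_b == f])))
    }
    list(test = test, folds = folds,
         hash = schema_hash(paste(c(test, 0, unlist(folds)),
                                  collapse = ",")))
  })
}

# --- Experiment orchestration ----------------------------------------------

# Targets eligible as sequence samples: observed y and a full window of
# record behind them.
eligible_targets <- function(ft, window = 21) {
  first_date <- min(ft$date)
  ft[!is.na(ft$y) & (ft$date - (window - 1) >= first_date), , drop = FALSE]
}

#' Run the training and evaluation protocol on a world
#'
#' End-to-end: AOD imputation, feature assembly (leave-target-out fusion),
#' target eligibility, the held-out/k-fold split, per-fold scaler fitting
#' (training rows only), sequence building, model training and stratified
#' evaluation. `folds_to_fit` controls how many of the `k` folds are
#' actually trained (averaged for the validation numbers); the test metrics
#' come from the best-validation fold's model applied to the held-out set.
#'
#' @param world A `pm25_world`.
#' @param fusion A [fusion_config()].
#' @param include_wsd Keep the smoke-density predictor?
#' @param widths,model_cfg Network size (see [train_bilstm()]).
#' @param train_cfg A [train_config()].
#' @param seed Protocol seed (split + training).
#' @param test_frac,k,folds_to_fit Split protocol settings.
#' @param impute Gap-fill AOD first?
#' @param window Sequence window.
#' @param n_restarts Seeded training restarts per fold (see
#'   [train_bilstm()]).
#' @param dropout Dropout rate used when `model_cfg` is `NULL` (desk-scale
#'   default 0.05; production-scale fits use 0.2).
#' @return A `pm25_experiment`: list with `fit` (best fold's model),
#'   `val_metrics` (per-fold tibble), `val_summary` (fold average),
#'   `test_report` (a [metrics_report()]), `test_predictions`, `split_hash`,
#'   `targets` and bookkeeping fields.
#' @export
run_experiment <- function(world, fusion = fusion_config(),
                           include_wsd = TRUE, widths = c(32, 16, 16),
                           model_cfg = NULL, train_cfg = NULL, seed = 1,
                           test_frac = 0.1, k = 10, folds_to_fit = 1,
                           impute = TRUE, window = 21, n_restarts = 1,
                           dropout = 0.05) {
  if (impute && any(world$aod_mask)) world <- impute_aod(world)
  train_cfg <- train_cfg %||% train_config(batch_size = 64, max_epochs = 40,
                                           patience = 8, seed = seed)
  ft <- build_feature_table(world, fusion, include_wsd = include_wsd)
  if (is.null(model_cfg)) {
    model_cfg <- model_config(
      n_features = length(intersect(feature_names(), names(ft))),
      widths = widths, dropout = dropout, window = window, seed = seed)
  }
  targets <- eligible_targets(ft, window)
  sp <- split_protocol(nrow(targets), seed = seed, test_frac = test_frac,
                       k = k)
  rest <- sort(unlist(sp$folds))
  folds_to_fit <- min(folds_to_fit, k)
  fold_fits <- vector("list", folds_to_fit)
  val_rows <- vector("list", folds_to_fit)
  for (f in seq_len(folds_to_fit)) {
    val_idx <- sp$folds[[f]]
    train_idx <- setdiff(rest, val_idx)
    scaler <- fit_scaler(targets[train_idx, , drop = FALSE])
    mk <- function(idx) build_sequences(ft, targets[idx, , drop = FALSE],
                                        scaler, window = window)
    train_set <- mk(train_idx)
    val_set <- mk(val_idx)
    fit <- train_bilstm(train_set, val_set, model_cfg = model_cfg,
                        train_cfg = train_cfg, widths = widths,
                        n_restarts = n_restarts)
    vp <- stats::predict(fit, val_set)
    vm <- compute_metrics(vp$y, vp$pred)
    fold_fits[[f]] <- fit
    val_rows[[f]] <- dplyr::mutate(vm, fold = f,
                                   val_rmse_scaled = fit$best_metric)
  }
  val_metrics <- dplyr::bind_rows(val_rows)
  best_f <- which.min(val_metrics$val_rmse_scaled)
  best_fit <- fold_fits[[best_f]]
  test_set <- build_sequences(ft, targets[sp$test, , drop = FALSE],
                              best_fit$scaler, window = window)
  tp <- stats::predict(best_fit, test_set)
  structure(list(
    fit = best_fit, fold_fits = fold_fits,
    val_metrics = val_metrics,
    val_summary = dplyr::summarise(val_metrics,
                                   r2 = mean(.data$r2),
                                   rmse = mean(.data$rmse),
                                   mbe = mean(.data$mbe)),
    test_report = metrics_report(tp),
    test_predictions = tp,
    split_hash = sp$hash, split = sp, targets = targets,
    feature_table = ft, include_wsd = include_wsd, seed = seed
  ), class = "pm25_experiment")
}

#' @export
print.pm25_experiment <- function(x, ...) {
  cat(sprintf("<pm25_experiment> %d targets, split %s, %d fold(s) fitted\n",
              nrow(x$targets), x$split_hash, nrow(x$val_metrics)))
  cat("  validation (fold avg): ")
  v <- x$val_summary
  cat(sprintf("R2 %.3f RMSE %.3f MBE %+.3f\n", v$r2, v$rmse, v$mbe))
  print(x$test_report)
  invisible(x)
}

# --- Baselines -------------------------------------------------------------

#' Random-forest point-to-point baseline
#'
#' Fits a random forest on day-t feature vectors only (no sequence
#' information), with a seeded random search over a small documented grid
#' (trees, mtry, minimum node size) selected on validation RMSE. Missing
#' predictor entries are filled with training-split medians.
#'
#' @param train_df,val_df,test_df Feature tables (rows = target samples)
#'   with predictors and `y`.
#' @param features Predictor columns.
#' @param seed Seed for the search.
#' @param n_draws Random-search budget.
#' @return List with `model`, `best` (chosen hyperparameters),
#'   `val_metrics`, `test_predictions` tibble.
#' @export
fit_rf_baseline <- function(train_df, val_df, test_df = NULL,
                            features = NULL, seed = 1, n_draws = 5) {
  features <- features %||% intersect(feature_names(), names(train_df))
  med <- vapply(train_df[features], function(x)
    stats::median(x, na.rm = TRUE), numeric(1))
  fill <- function(df) {
    for (f in features) {
      x <- df[[f]]
      x[!is.finite(x)] <- med[[f]]
      df[[f]] <- x
    }
    df
  }
  train_df <- fill(train_df); val_df <- fill(val_df)
  grid <- with_seed(child_seed(seed, "rfsearch"), tibble::tibble(
    ntree = sample(c(100L, 200L, 300L), n_draws, replace = TRUE),
    mtry = sample(seq(2L, max(3L, length(features) %/% 2)), n_draws,
                  replace = TRUE),
    nodesize = sample(c(1L, 5L, 10L), n_draws, replace = TRUE)
  ))
  xs <- as.matrix(train_df[features]); ys <- train_df$y
  xv <- as.matrix(val_df[features])
  best <- NULL
  for (i in seq_len(n_draws)) {
    m <- with_seed(child_seed(seed, paste0("rf", i)),
      randomForest::randomForest(x = xs, y = ys, ntree = grid$ntree[i],
                                 mtry = grid$mtry[i],
                                 nodesize = grid$nodesize[i]))
    rmse <- sqrt(mean((stats::predict(m, xv) - val_df$y)^2))
    if (is.null(best) || rmse < best$rmse) {
      best <- list(model = m, rmse = rmse, draw = grid[i, ])
    }
  }
  out <- list(model = best$model, best = best$draw,
              val_metrics = compute_metrics(val_df$y,
                                            stats::predict(best$model, xv)))
  if (!is.null(test_df)) {
    test_df <- fill(test_df)
    tp <- test_df[, intersect(c("station_id", "cell", "lon", "lat", "date"),
                              names(test_df))]
    tp$y <- test_df$y
    tp$pred <- stats::predict(best$model, as.matrix(test_df[features]))
    out$test_predictions <- tibble::as_tibble(tp)
  }
  out
}

#' Benchmark the Bi-LSTM against its baselines on one world
#'
#' Runs the bidirectional model, the unidirectional attention LSTM and the
#' point-to-point random forest on the identical split protocol (asserted
#' via the split hash) and reports validation and test metrics per model.
#'
#' @inheritParams run_experiment
#' @param models Subset of `c("bilstm", "lstm", "rf")`.
#' @return A `pm25_benchmark`: list with `metrics` (tibble: model, phase,
#'   r2, rmse, mbe), `experiments`, `split_hash`.
#' @export
run_benchmark <- function(world, fusion = fusion_config(),
                          widths = c(16, 8, 8), train_cfg = NULL, seed = 1,
                          test_frac = 0.1, k = 10,
                          models = c("bilstm", "lstm", "rf"),
                          impute = TRUE, window = 21, n_restarts = 1,
                          dropout = 0.05) {
  if (impute && any(world$aod_mask)) world <- impute_aod(world)
  rows <- list(); exps <- list(); hashes <- character(0)
  for (m in intersect(c("bilstm", "lstm"), models)) {
    mc <- NULL
    if (m == "lstm") {
      ftab <- build_feature_table(world, fusion)
      mc <- model_config(n_features = length(intersect(feature_names(),
                                                       names(ftab))),
                         widths = widths, width_mode = "per_direction",
                         bidirectional = FALSE, dropout = dropout,
                         window = window, seed = seed)
    }
    ex <- run_experiment(world, fusion, widths = widths, model_cfg = mc,
                         train_cfg = train_cfg, seed = seed,
                         test_frac = test_frac, k = k, impute = FALSE,
                         window = window, n_restarts = n_restarts,
                         dropout = dropout)
    exps[[m]] <- ex
    hashes[m] <- ex$split_hash
    rows[[length(rows) + 1]] <- dplyr::bind_rows(
      dplyr::mutate(ex$val_summary, model = m, phase = "validation"),
      dplyr::mutate(ex$test_report$overall[, c("r2", "rmse", "mbe")],
                    model = m, phase = "test"))
  }
  if ("rf" %in% models) {
    # Same targets and split as the sequence models.
    ref <- exps[[1]] %||% run_experiment(world, fusion, widths = widths,
                                         train_cfg = train_cfg, seed = seed,
                                         test_frac = test_frac, k = k,
                                         impute = FALSE, window = window)
    targets <- ref$targets; sp <- ref$split
    rest <- sort(unlist(sp$folds))
    val_idx <- sp$folds[[1]]
    train_idx <- setdiff(rest, val_idx)
    rf <- fit_rf_baseline(targets[train_idx, ], targets[val_idx, ],
                          targets[sp$test, ], seed = seed)
    exps$rf <- rf
    hashes["rf"] <- sp$hash
    rows[[length(rows) + 1]] <- dplyr::bind_rows(
      dplyr::mutate(rf$val_metrics[, c("r2", "rmse", "mbe")], model = "rf",
                    phase = "validation"),
      dplyr::mutate(compute_metrics(rf$test_predictions$y,
                                    rf$test_predictions$pred)[,
                      c("r2", "rmse", "mbe")],
                    model = "rf", phase = "test"))
  }
  stopifnot(length(unique(hashes)) == 1)  # protocol identity across models
  structure(list(metrics = dplyr::bind_rows(rows) |>
                   dplyr::relocate("model", "phase"),
                 experiments = exps, split_hash = hashes[[1]]),
            class = "pm25_benchmark")
}

#' @export
print.pm25_benchmark <- function(x, ...) {
  cat(sprintf("<pm25_benchmark> split %s\n", x$split_hash))
  print(as.data.frame(x$metrics), digits = 3)
  invisible(x)
}

#' Smoke-density ablation
#'
#' Trains two models under an identical pipeline, split and seed — one with
#' the wildfire smoke density (WSD) predictor, one without — and reports
#' overall and high-concentration metrics for both.
#'
#' @inheritParams run_experiment
#' @return A `wsd_ablation`: list with `with_wsd`, `without_wsd`
#'   (`pm25_experiment`s) and `summary` (tibble: model, subset, r2, rmse,
#'   mbe, n).
#' @export
ablate_wsd <- function(world, fusion = fusion_config(), widths = c(16, 8, 8),
                       train_cfg = NULL, seed = 1, test_frac = 0.1, k = 10,
                       impute = TRUE, window = 21, n_restarts = 1,
                       dropout = 0.05) {
  if (impute && any(world$aod_mask)) world <- impute_aod(world)
  runs <- list(
    with_wsd = run_experiment(world, fusion, include_wsd = TRUE,
                              widths = widths, train_cfg = train_cfg,
                              seed = seed, test_frac = test_frac, k = k,
                              impute = FALSE, window = window,
                              n_restarts = n_restarts, dropout = dropout),
    without_wsd = run_experiment(world, fusion, include_wsd = FALSE,
                                 widths = widths, train_cfg = train_cfg,
                                 seed = seed, test_frac = test_frac, k = k,
                                 impute = FALSE, window = window,
                                 n_restarts = n_restarts, dropout = dropout))
  stopifnot(runs$with_wsd$split_hash == runs$without_wsd$split_hash)
  summary <- dplyr::bind_rows(lapply(names(runs), function(nm) {
    rep_ <- runs[[nm]]$test_report
    dplyr::bind_rows(
      dplyr::mutate(rep_$overall, model = nm, subset = "overall"),
      dplyr::mutate(rep_$high, model = nm, subset = "high"))
  })) |> dplyr::relocate("model", "subset")
  structure(c(runs, list(summary = summary)), class = "wsd_ablation")
}

#' @export
print.wsd_ablation <- function(x, ...) {
  cat("<wsd_ablation>\n")
  print(as.data.frame(x$summary), digits = 3)
  invisible(x)
}
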