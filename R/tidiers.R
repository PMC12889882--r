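#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a fitted model's training history
#'
#' @param x A `pm25_fit`.
#' @param ... Unused.
#' @return The per-epoch history tibble (`epoch`, `lr`, `train_loss`,
#'   `val_loss`, `val_rmse`).
#' @method tidy pm25_fit
#' @export
tidy.pm25_fit <- function(x, ...) x$history

#' One-row model summary
#'
#' @param x A `pm25_fit`.
#' @param ... Unused.
#' @return A one-row tibble: architecture, parameter count, epochs trained,
#'   best epoch and best validation metric (scaled RMSE).
#' @method glance pm25_fit
#' @export
glance.pm25_fit <- function(x, ...) {
  tibble::tibble(
    model = if (x$model_config$bidirectional) "bilstm" else "lstm",
    widths = paste(x$model_config$widths, collapse = "/"),
    n_params = length(unlist(unclass(x$params))),
    epochs = nrow(x$history),
    best_epoch = x$best_epoch,
    best_val_metric = x$best_metric)
}

#' Tidy a stratified metrics report
#'
#' @param x A `metrics_report`.
#' @param ... Unused.
#' @return Long tibble with `stratum`, `level`, `r2`, `rmse`, `mbe`, `n`.
#' @method tidy metrics_report
#' @export
tidy.metrics_report <- function(x, ...) {
  rows <- list(dplyr::mutate(x$overall, stratum = "overall",
                             level = "overall"))
  if (!is.null(x$by_category)) {
    rows <- c(rows, list(dplyr::mutate(
      dplyr::rename(x$by_category, level = "category"),
      stratum = "category", level = as.character(.data$level))))
  }
  if (!is.null(x$by_season)) {
    rows <- c(rows, list(dplyr::mutate(
      dplyr::rename(x$by_season, level = "season"),
      stratum = "season", level = as.character(.data$level))))
  }
  if (!is.null(x$by_region)) {
    rows <- c(rows, list(dplyr::mutate(
      dplyr::rename(x$by_region, level = "region"),
      stratum = "region", level = as.character(.data$level))))
  }
  rows <- c(rows, list(dplyr::mutate(x$high, stratum = "high",
                                     level = sprintf(">%g", x$high_threshold))))
  dplyr::bind_rows(rows) |> dplyr::relocate("stratum", "level")
}

#' @rdname tidy.metrics_report
#' @method glance metrics_report
#' @export
glance.metrics_report <- function(x, ...) x$overall

#' Training-history plot
#'
#' @param object A `pm25_fit`.
#' @param ... Unused.
#' @return A ggplot of train/validation loss per epoch.
#' @method autoplot pm25_fit
#' @export
autoplot.pm25_fit <- function(object, ...) {
  h <- tidyr::pivot_longer(object$history, c("train_loss", "val_loss"),
                           names_to = "series", values_to = "loss")
  ggplot2::ggplot(h, ggplot2::aes(x = .data$epoch, y = .data$loss,
                                  colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "epoch", y = "Huber loss (scaled space)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Observed-versus-predicted plot for an experiment
#'
#' @param object A `pm25_experiment`.
#' @param ... Unused.
#' @return A ggplot of held-out test predictions against observations with
#'   the identity line.
#' @method autoplot pm25_experiment
#' @export
autoplot.pm25_experiment <- function(object, ...) {
  ggplot2::ggplot(object$test_predictions,
                  ggplot2::aes(x = .data$y, y = .data$pred)) +
    ggplot2::geom_point(alpha = 0.4) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
    ggplot2::labs(x = "observed PM2.5 (ug/m3)",
                  y = "predicted PM2.5 (ug/m3)") +
    ggplot2::theme_minimal()
}

#' Surface raster plot
#'
#' @param object A `pm25_surface`.
#' @param date Which date to draw (default the first).
#' @param ... Unused.
#' @return A ggplot tile map of the predicted surface.
#' @method autoplot pm25_surface
#' @export
autoplot.pm25_surface <- function(object, date = object$dates[1], ...) {
  d <- format(as.Date(date))
  r <- object$rasters[[d]]
  df <- object$grid
  df$pm25 <- r[cbind(df$ix, df$iy)]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$lon, y = .data$lat,
                                   fill = .data$pm25)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = "PM2.5\n(ug/m3)") +
    ggplot2::labs(title = d, x = "lon", y = "lat") +
    ggplot2::theme_minimal()
}

#' Attention-weight plot for one sample
#'
#' Shows where over the 21-day window the model allocated attention for a
#' single sequence sample; masked timesteps necessarily carry zero weight.
#'
#' @param fit A `pm25_fit`.
#' @param seq_set A `sequence_set`.
#' @param i Sample index.
#' @return A ggplot bar chart of attention weights by lag.
#' @export
plot_attention <- function(fit, seq_set, i = 1) {
  tr <- trace_sample(fit$params, fit$model_config, seq_set, i)
  w <- seq_set$window
  df <- tibble::tibble(lag = -(w - 1):0, alpha = tr$alpha,
                       masked = seq_set$mask[i, ])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$lag, y = .data$alpha,
                                   fill = .data$masked)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "day relative to target", y = "attention weight",
                  fill = "masked") +
    ggplot2::theme_minimal()
}
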