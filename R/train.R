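#' Training configuration
#'
#' Optimization settings: Huber loss, Adam, and an exponential learning-rate
#' schedule (initial rate 1e-3, decayed by a factor 0.8 every 30,000 steps,
#' continuously by default). Batch size defaults to 256. Early stopping on
#' validation RMSE is included with a patience default of 10 so desk-scale
#' runs are bounded; it can be disabled with `patience = Inf`.
#'
#' @param initial_lr Initial learning rate.
#' @param decay_rate Multiplicative decay per `decay_steps` (in `(0, 1)`).
#' @param decay_steps Step interval of the decay.
#' @param staircase Discrete (floor) decay instead of continuous.
#' @param batch_size Mini-batch size.
#' @param clip_norm Global gradient-norm clipping threshold (Inf disables);
#'   the standard stabilizer for recurrent backpropagation.
#' @param huber_delta Huber transition point, in scaled-target units.
#' @param max_epochs Maximum training epochs.
#' @param patience Early-stopping patience (epochs without val improvement).
#' @param seed Seed for shuffling and dropout.
#' @return A `train_config` list.
#' @export
train_config <- function(initial_lr = 1e-3, decay_rate = 0.8,
                         decay_steps = 30000, staircase = FALSE,
                         batch_size = 256, clip_norm = 5, huber_delta = 1,
                         max_epochs = 100, patience = 10, seed = 1) {
  stopifnot(decay_rate > 0, decay_rate < 1, batch_size >= 1, huber_delta > 0,
            initial_lr > 0, decay_steps >= 1)
  structure(list(initial_lr = initial_lr, decay_rate = decay_rate,
                 decay_steps = decay_steps, staircase = staircase,
                 batch_size = as.integer(batch_size),
                 clip_norm = clip_norm, huber_delta = huber_delta,
                 max_epochs = as.integer(max_epochs), patience = patience,
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Huber loss
#'
#' Per-residual `0.5 * r^2` for `|r| <= delta` and `delta * (|r| - 0.5 *
#' delta)` beyond, averaged over the batch. Quadratic near zero like squared
#' error, linear in the tails like absolute error, hence robust to the
#' outliers typical of wildfire-driven concentration spikes.
#'
#' @param y_true,y_pred Numeric vectors.
#' @param delta Transition point (> 0).
#' @return Mean loss (scalar).
#' @export
huber_loss <- function(y_true, y_pred, delta = 1) {
  stopifnot(delta > 0, length(y_true) == length(y_pred))
  huber_value_grad(y_pred, y_true, delta)$loss
}

#' Exponential learning-rate schedule
#'
#' `initial_lr * decay_rate^(step / decay_steps)`; with `staircase = TRUE`
#' the exponent is floored so the rate drops in discrete steps.
#'
#' @param step Global optimizer step (>= 0).
#' @param config A [train_config()].
#' @return Learning rate at `step`.
#' @export
lr_schedule <- function(step, config = train_config()) {
  stopifnot(all(step >= 0))
  e <- step / config$decay_steps
  if (config$staircase) e <- floor(e)
  config$initial_lr * config$decay_rate^e
}

# Adam over a flat parameter vector.
adam_step <- function(pv, gv, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1
  state$m <- beta1 * state$m + (1 - beta1) * gv
  state$v <- beta2 * state$v + (1 - beta2) * gv^2
  mhat <- state$m / (1 - beta1^state$t)
  vhat <- state$v / (1 - beta2^state$t)
  state$pv <- pv - lr * mhat / (sqrt(vhat) + eps)
  state
}

eval_rmse_scaled <- function(params, mcfg, ss) {
  pred <- forward_bilstm(params, mcfg, ss$X, ss$mask, training = FALSE)$pred
  sqrt(mean((pred - ss$y)^2))
}

#' Train the attention Bi-LSTM
#'
#' Seeded mini-batch optimization with Adam, the exponential learning-rate
#' schedule and Huber loss. Tracks per-epoch training loss and validation
#' loss/RMSE (scaled space), retains the best-validation parameters and
#' stops early after `patience` epochs without improvement. Aborts with a
#' diagnostic if the loss becomes non-finite.
#'
#' @param train_set,val_set `sequence_set`s (validation may be `NULL`, in
#'   which case training loss drives checkpointing).
#' @param model_cfg A [model_config()]; `NULL` derives one from the data with
#'   the given `widths`.
#' @param train_cfg A [train_config()].
#' @param widths Layer widths used when `model_cfg` is `NULL`.
#' @param n_restarts Independent seeded restarts (fresh initialization and
#'   shuffling); the restart with the best validation metric is returned.
#'   Restarts tame the optimization variance of small-sample training.
#' @param verbose Print per-epoch progress.
#' @return A `pm25_fit`: list with `params` (best), `model_config`,
#'   `train_config`, `history` tibble (epoch, lr, train_loss, val_loss,
#'   val_rmse), `best_epoch`, `features` and the training `scaler`.
#' @export
train_bilstm <- function(train_set, val_set = NULL, model_cfg = NULL,
                         train_cfg = train_config(), widths = c(32, 16, 16),
                         n_restarts = 1, verbose = FALSE) {
  stopifnot(inherits(train_set, "sequence_set"))
  n <- dim(train_set$X)[1]
  stopifnot(n >= 1)
  if (n_restarts > 1) {
    fits <- lapply(seq_len(n_restarts) - 1L, function(r) {
      mc <- model_cfg
      tc <- train_cfg
      tc$seed <- train_cfg$seed + 1000L * r
      if (!is.null(mc)) mc$seed <- mc$seed + 1000L * r
      train_bilstm(train_set, val_set, model_cfg = mc, train_cfg = tc,
                   widths = widths, n_restarts = 1, verbose = verbose)
    })
    return(fits[[which.min(vapply(fits, `[[`, numeric(1), "best_metric"))]])
  }
  if (is.null(model_cfg)) {
    model_cfg <- model_config(n_features = length(train_set$features),
                              widths = widths, window = train_set$window,
                              seed = train_cfg$seed)
  }
  params <- init_params(model_cfg)
  skel <- unclass(params)
  pv <- unlist(skel, use.names = FALSE)
  state <- list(m = numeric(length(pv)), v = numeric(length(pv)), t = 0,
                pv = pv)
  step <- 0L
  best <- list(metric = Inf, pv = pv, epoch = 0L)
  bad_epochs <- 0L
  hist <- list()
  for (epoch in seq_len(train_cfg$max_epochs)) {
    ord <- with_seed(child_seed(train_cfg$seed, paste0("shuffle", epoch)),
                     sample.int(n))
    batches <- split(ord, ceiling(seq_along(ord) / train_cfg$batch_size))
    epoch_loss <- 0
    for (b in seq_along(batches)) {
      idx <- batches[[b]]
      params <- utils::relist(state$pv, skel)
      lg <- bilstm_loss_grad(
        params, model_cfg,
        train_set$X[idx, , , drop = FALSE],
        train_set$mask[idx, , drop = FALSE],
        train_set$y[idx], delta = train_cfg$huber_delta, training = TRUE,
        dropout_seed = child_seed(train_cfg$seed,
                                  paste0("drop", epoch, "_", b)))
      if (!is.finite(lg$loss)) {
        stop(sprintf(
          "training diverged: non-finite loss at epoch %d, batch %d (lr %.3g)",
          epoch, b, lr_schedule(step, train_cfg)), call. = FALSE)
      }
      gv <- unlist(lg$grads, use.names = FALSE)
      gnorm <- sqrt(sum(gv^2))
      clip <- train_cfg$clip_norm %||% Inf
      if (is.finite(clip) && gnorm > clip) gv <- gv * (clip / gnorm)
      state <- adam_step(state$pv, gv, state, lr_schedule(step, train_cfg))
      step <- step + 1L
      epoch_loss <- epoch_loss + lg$loss * length(idx)
    }
    epoch_loss <- epoch_loss / n
    params <- utils::relist(state$pv, skel)
    val_loss <- NA_real_; val_rmse <- NA_real_
    if (!is.null(val_set) && dim(val_set$X)[1] > 0) {
      vp <- forward_bilstm(params, model_cfg, val_set$X, val_set$mask,
                           training = FALSE)$pred
      val_loss <- huber_value_grad(vp, val_set$y, train_cfg$huber_delta)$loss
      val_rmse <- sqrt(mean((vp - val_set$y)^2))
      metric <- val_rmse
    } else {
      metric <- epoch_loss
    }
    hist[[epoch]] <- tibble::tibble(
      epoch = epoch, lr = lr_schedule(step, train_cfg),
      train_loss = epoch_loss, val_loss = val_loss, val_rmse = val_rmse)
    if (verbose) {
      message(sprintf("epoch %3d  train %.5f  val_rmse %s", epoch, epoch_loss,
                      ifelse(is.na(val_rmse), "-", sprintf("%.5f", val_rmse))))
    }
    if (metric < best$metric - 1e-12) {
      best <- list(metric = metric, pv = state$pv, epoch = epoch)
      bad_epochs <- 0L
    } else {
      bad_epochs <- bad_epochs + 1L
      if (bad_epochs >= train_cfg$patience) break
    }
  }
  params <- utils::relist(best$pv, skel)
  class(params) <- "bilstm_params"
  structure(list(params = params, model_config = model_cfg,
                 train_config = train_cfg,
                 history = dplyr::bind_rows(hist), best_epoch = best$epoch,
                 best_metric = best$metric,
                 features = train_set$features,
                 scaler = train_set$scaler),
            class = "pm25_fit")
}

#' Predict PM2.5 for a sequence set
#'
#' Inference-mode forward pass; predictions are inverse-scaled back to
#' ug/m3 and never clamped here (surface writers clamp at 0).
#'
#' @param object A `pm25_fit`.
#' @param seq_set A `sequence_set` built with the fit's feature order.
#' @param ... Unused.
#' @return A tibble: the set's metadata plus `y` (observed, ug/m3, `NA` for
#'   prediction-only samples) and `pred` (ug/m3).
#' @export
predict.pm25_fit <- function(object, seq_set, ...) {
  stopifnot(identical(seq_set$features, object$features))
  pred_s <- forward_bilstm(object$params, object$model_config, seq_set$X,
                           seq_set$mask, training = FALSE)$pred
  out <- seq_set$meta
  out$y <- seq_set$y_raw
  out$pred <- invert_scaler_target(pred_s, object$scaler)
  tibble::as_tibble(out)
}

#' @export
print.pm25_fit <- function(x, ...) {
  mc <- x$model_config
  cat(sprintf(
    "<pm25_fit> %s, widths %s (%s), %d features, window %d\n",
    if (mc$bidirectional) "Bi-LSTM + attention" else "LSTM + attention",
    paste(mc$widths, collapse = "/"), mc$width_mode, mc$n_features,
    mc$window))
  cat(sprintf("  trained %d epochs, best epoch %d (val metric %.4f scaled)\n",
              nrow(x$history), x$best_epoch, x$best_metric))
  invisible(x)
}

# Tiny stable content hash for schema validation (djb2 over the bytes of the
# feature-order string, kept in 31-bit integer range).
schema_hash <- function(features) {
  h <- 5381
  for (b in utf8ToInt(paste(features, collapse = "|"))) {
    h <- (h * 33 + b) %% 2147483647
  }
  sprintf("%08x", h)
}

#' Save / load a model checkpoint
#'
#' The checkpoint archives parameters, model and training configuration,
#' scaler and the feature-order schema with a content hash; loading
#' validates the hash so a checkpoint can never silently be applied to a
#' feature table in a different order.
#'
#' @param fit A `pm25_fit`.
#' @param path Checkpoint path (`.rds`).
#' @return `save_checkpoint()`: `path` invisibly; `load_checkpoint()`: the
#'   `pm25_fit`.
#' @export
save_checkpoint <- function(fit, path) {
  obj <- unclass(fit)
  obj$schema <- list(features = fit$features,
                     hash = schema_hash(fit$features), version = 1L)
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$schema$hash, schema_hash(obj$schema$features))) {
    stop("checkpoint schema hash mismatch; refusing to load", call. = FALSE)
  }
  obj$features <- obj$schema$features
  obj$schema <- NULL
  class(obj$params) <- "bilstm_params"
  structure(obj, class = "pm25_fit")
}
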