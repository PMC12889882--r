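#' Model configuration
#'
#' Architecture of the sequence regressor: three stacked bidirectional LSTM
#' layers with layer normalization and dropout after each, Luong
#' multiplicative attention over the normalized hidden states of the final
#' layer (query = last timestep), and a linear head producing one PM2.5
#' estimate (in scaled target space) per 21-day sequence.
#'
#' The published layer widths are 256, 128 and 128 neurons. A bidirectional
#' layer's width can be read as the total across both directions
#' (`width_mode = "total"`, the default: 128 per direction in the first
#' layer) or as per-direction; the switch documents the ambiguity and the
#' rest of the package is width-agnostic.
#'
#' @param n_features Number of input features per timestep.
#' @param widths Hidden widths of the three recurrent layers.
#' @param width_mode `"total"` or `"per_direction"`.
#' @param bidirectional `FALSE` gives the unidirectional ablation (the
#'   standard attention-LSTM baseline).
#' @param dropout Dropout rate in `[0, 1)`, active only during training.
#' @param window Sequence length (default 21 days).
#' @param seed Seed for parameter initialization.
#' @return A `model_config` list.
#' @export
model_config <- function(n_features, widths = c(256, 128, 128),
                         width_mode = c("total", "per_direction"),
                         bidirectional = TRUE, dropout = 0.2, window = 21,
                         seed = 1) {
  width_mode <- match.arg(width_mode)
  stopifnot(all(widths >= 1), dropout >= 0, dropout < 1, n_features >= 1)
  h_dir <- if (bidirectional && width_mode == "total") {
    if (any(widths %% 2 != 0)) {
      stop("bidirectional widths in 'total' mode must be even", call. = FALSE)
    }
    as.integer(widths / 2)
  } else {
    as.integer(widths)
  }
  structure(list(n_features = as.integer(n_features),
                 widths = as.integer(widths), width_mode = width_mode,
                 h_dir = h_dir, bidirectional = bidirectional,
                 dropout = dropout, window = as.integer(window),
                 seed = as.integer(seed)),
            class = "model_config")
}

glorot <- function(n_in, n_out) {
  lim <- sqrt(6 / (n_in + n_out))
  matrix(stats::runif(n_in * n_out, -lim, lim), n_in, n_out)
}

#' Initialize model parameters
#'
#' Glorot-uniform weights, zero biases with the LSTM forget-gate bias set to
#' one (standard practice for gradient flow early in training).
#'
#' @param config A [model_config()].
#' @return Nested parameter list (class `bilstm_params`).
#' @export
init_params <- function(config) {
  with_seed(config$seed, {
    n_dir <- if (config$bidirectional) 2L else 1L
    d_in <- config$n_features
    layers <- vector("list", length(config$widths))
    for (l in seq_along(config$widths)) {
      h <- config$h_dir[l]
      dir_params <- function() {
        b <- numeric(4 * h)
        b[(h + 1):(2 * h)] <- 1  # forget gate bias
        list(W = glorot(d_in, 4 * h), U = glorot(h, 4 * h), b = b)
      }
      d_out <- n_dir * h
      layers[[l]] <- list(
        fwd = dir_params(),
        bwd = if (config$bidirectional) dir_params(),
        gamma = rep(1, d_out), beta = numeric(d_out)
      )
      d_in <- d_out
    }
    d <- d_in  # final hidden size
    structure(list(
      layers = layers,
      Wa = glorot(d, d),
      Wc = glorot(d, 2 * d),
      w_out = matrix(stats::rnorm(d, 0, 1 / sqrt(d)), d, 1),
      b_out = 0
    ), class = "bilstm_params")
  })
}

# --- Attention operators (single-sample, introspectable) -------------------

#' Luong multiplicative attention score
#'
#' `score(h_t, h_s) = t(h_t) %*% W %*% h_s` for every row `h_s` of
#' `h_hat_all`.
#'
#' @param h_hat_t Query state (numeric vector, length d).
#' @param h_hat_all Matrix of states, one row per timestep (`T x d`).
#' @param W Trainable bilinear score matrix (`d x d`).
#' @return Numeric vector of scores, one per timestep.
#' @export
attention_scores <- function(h_hat_t, h_hat_all, W) {
  if (length(h_hat_t) != ncol(W) || ncol(h_hat_all) != ncol(W)) {
    stop("attention score shape mismatch", call. = FALSE)
  }
  as.vector(h_hat_all %*% crossprod(W, h_hat_t))
}

#' Masked softmax attention weights
#'
#' Softmax over the unmasked scores, numerically stabilized by
#' max-subtraction; masked timesteps receive weight exactly 0, so the output
#' is invariant to their score values.
#'
#' @param scores Numeric score vector.
#' @param mask Logical vector, `TRUE` = masked; `NULL` for no masking.
#' @return Weights summing to 1 over unmasked timesteps.
#' @export
attention_weights <- function(scores, mask = NULL) {
  if (is.null(mask)) mask <- rep(FALSE, length(scores))
  if (all(mask)) stop("all timesteps are masked", call. = FALSE)
  a <- numeric(length(scores))
  s <- scores[!mask]
  e <- exp(s - max(s))
  a[!mask] <- e / sum(e)
  a
}

#' Attention context vector
#'
#' Weighted average of the hidden states: `c_t = sum_s alpha_s * h_s`.
#'
#' @param alpha Attention weights (length T).
#' @param h_hat_all `T x d` state matrix.
#' @return Numeric vector of length d.
#' @export
context_vector <- function(alpha, h_hat_all) {
  as.vector(crossprod(h_hat_all, alpha))
}

#' Attended output state
#'
#' `h_tilde = tanh(Wc %*% c(c_t, h_hat_t))`; components are bounded in
#' (-1, 1) by construction.
#'
#' @param c_t Context vector (length d).
#' @param h_hat_t Query state (length d).
#' @param Wc Combination matrix (`d x 2d`).
#' @return Numeric vector of length d.
#' @export
attended_output <- function(c_t, h_hat_t, Wc) {
  if (ncol(Wc) != length(c_t) + length(h_hat_t)) {
    stop("attended output shape mismatch", call. = FALSE)
  }
  as.vector(tanh(Wc %*% c(c_t, h_hat_t)))
}

# --- Batched forward pass --------------------------------------------------

slice_t <- function(A, t) {
  d <- dim(A)
  matrix(A[, t, ], d[1], d[3])
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# One LSTM direction over the window. `ord` is the timestep processing order
# (1:T forward, T:1 backward). Masked timesteps copy the previous hidden and
# cell state, so stored input values at masked steps never influence any
# state. Returns all-timestep hidden states plus caches for BPTT.
lstm_direction <- function(inp, mask, W, U, b, ord) {
  n <- dim(inp)[1]; tt <- dim(inp)[2]; h_n <- nrow(U)
  h4 <- ncol(W)
  stopifnot(h4 == 4 * h_n)
  H <- array(0, dim = c(n, tt, h_n))
  gi <- array(0, dim = c(n, tt, h_n)); gf <- gi; gg <- gi; go <- gi
  cc <- gi
  h <- matrix(0, n, h_n); cst <- matrix(0, n, h_n)
  idx_i <- 1:h_n; idx_f <- h_n + idx_i; idx_g <- 2 * h_n + idx_i
  idx_o <- 3 * h_n + idx_i
  for (t in ord) {
    a <- slice_t(inp, t) %*% W + h %*% U + rep(b, each = n)
    i_ <- sigmoid(a[, idx_i, drop = FALSE])
    f_ <- sigmoid(a[, idx_f, drop = FALSE])
    g_ <- tanh(a[, idx_g, drop = FALSE])
    o_ <- sigmoid(a[, idx_o, drop = FALSE])
    c_new <- f_ * cst + i_ * g_
    h_new <- o_ * tanh(c_new)
    m <- mask[, t]
    if (any(m)) {
      c_new[m, ] <- cst[m, ]
      h_new[m, ] <- h[m, ]
    }
    gi[, t, ] <- i_; gf[, t, ] <- f_; gg[, t, ] <- g_; go[, t, ] <- o_
    cc[, t, ] <- c_new
    h <- h_new; cst <- c_new
    H[, t, ] <- h
  }
  list(H = H, i = gi, f = gf, g = gg, o = go, c = cc, ord = ord)
}

ln_forward <- function(x3, gamma, beta, eps = 1e-5) {
  d <- dim(x3)
  x <- matrix(x3, d[1] * d[2], d[3])
  mu <- rowMeans(x)
  xc <- x - mu
  inv <- 1 / sqrt(rowMeans(xc^2) + eps)
  xhat <- xc * inv
  y <- xhat * rep(gamma, each = nrow(x)) + rep(beta, each = nrow(x))
  list(y = array(y, dim = d), xhat = xhat, inv = inv)
}

#' Forward pass of the attention Bi-LSTM
#'
#' Runs the masked network on a batch: three (bi)directional recurrent
#' layers, each followed by layer normalization and (training only)
#' per-timestep feature dropout; Luong attention with the last-timestep
#' normalized state as query and a masked softmax (weight exactly 0 on
#' masked timesteps); a linear head in scaled target space. With
#' `training = FALSE` the output is deterministic given the parameters.
#'
#' @param params A `bilstm_params` list.
#' @param config The matching [model_config()].
#' @param X `N x window x F` array of scaled features.
#' @param mask `N x window` logical matrix, `TRUE` = masked timestep. Every
#'   sample must have at least one unmasked timestep.
#' @param training Enable dropout and keep backprop caches?
#' @param dropout_seed Seed for the dropout draw (training only).
#' @return List with `pred` (length-N vector, scaled space), `alpha`
#'   (`N x window` attention weights) and, when `training = TRUE` or
#'   `keep_cache = TRUE`, the caches needed for backpropagation.
#' @param keep_cache Keep intermediate activations (forced `TRUE` when
#'   training).
#' @export
forward_bilstm <- function(params, config, X, mask, training = FALSE,
                           dropout_seed = 0, keep_cache = training) {
  n <- dim(X)[1]; tt <- dim(X)[2]
  if (any(rowSums(!mask) == 0)) {
    stop("sample with all timesteps masked", call. = FALSE)
  }
  keep_cache <- keep_cache || training
  inp <- X
  caches <- vector("list", length(params$layers))
  drop_masks <- vector("list", length(params$layers))
  for (l in seq_along(params$layers)) {
    lay <- params$layers[[l]]
    fwd <- lstm_direction(inp, mask, lay$fwd$W, lay$fwd$U, lay$fwd$b, 1:tt)
    if (config$bidirectional) {
      bwd <- lstm_direction(inp, mask, lay$bwd$W, lay$bwd$U, lay$bwd$b, tt:1)
      hcat <- array(0, dim = c(n, tt, 2 * config$h_dir[l]))
      hcat[, , seq_len(config$h_dir[l])] <- fwd$H
      hcat[, , config$h_dir[l] + seq_len(config$h_dir[l])] <- bwd$H
    } else {
      bwd <- NULL
      hcat <- fwd$H
    }
    ln <- ln_forward(hcat, lay$gamma, lay$beta)
    out <- ln$y
    if (training && config$dropout > 0) {
      keep <- 1 - config$dropout
      dm <- with_seed(child_seed(dropout_seed, paste0("drop", l)),
                      array((stats::runif(length(out)) < keep) / keep,
                            dim = dim(out)))
      out <- out * dm
      drop_masks[[l]] <- dm
    }
    if (keep_cache) {
      caches[[l]] <- list(inp = inp, fwd = fwd, bwd = bwd, ln = ln)
    }
    inp <- out
  }
  hhat <- inp  # N x T x D, normalized (and possibly dropped-out) states
  d_fin <- dim(hhat)[3]
  q <- slice_t(hhat, tt)
  qw <- q %*% params$Wa
  scores <- matrix(0, n, tt)
  for (t in seq_len(tt)) scores[, t] <- rowSums(qw * slice_t(hhat, t))
  s_shift <- scores
  s_shift[mask] <- -Inf
  mx <- apply(s_shift, 1, max)
  al <- exp(s_shift - mx)
  al[mask] <- 0
  alpha <- al / rowSums(al)
  ctx <- matrix(0, n, d_fin)
  for (t in seq_len(tt)) ctx <- ctx + alpha[, t] * slice_t(hhat, t)
  cq <- cbind(ctx, q)
  pre <- cq %*% t(params$Wc)
  htil <- tanh(pre)
  pred <- as.vector(htil %*% params$w_out) + params$b_out
  out <- list(pred = pred, alpha = alpha)
  if (keep_cache) {
    out$cache <- list(caches = caches, drop_masks = drop_masks, hhat = hhat,
                      q = q, qw = qw, scores = scores, alpha = alpha,
                      ctx = ctx, cq = cq, htil = htil, mask = mask,
                      training = training)
  }
  out
}

#' Attention trace for one sequence sample
#'
#' Exposes the introspectable attention quantities for a single sample:
#' normalized hidden states, raw scores, weights, context vector and
#' attended output.
#'
#' @param params,config Model parameters and configuration.
#' @param X,mask A single sample's `window x F` matrix and length-`window`
#'   logical mask (or a `sequence_set` plus index via [trace_sample()]).
#' @return List with `h_hat` (`window x d`), `scores`, `alpha`, `context`,
#'   `h_tilde` and `pred`.
#' @export
attention_trace <- function(params, config, X, mask) {
  Xa <- array(X, dim = c(1, nrow(X), ncol(X)))
  m <- matrix(mask, 1, length(mask))
  fw <- forward_bilstm(params, config, Xa, m, training = FALSE,
                       keep_cache = TRUE)
  tt <- nrow(X)
  hh <- matrix(fw$cache$hhat[1, , ], tt, dim(fw$cache$hhat)[3])
  list(h_hat = hh, scores = fw$cache$scores[1, ], alpha = fw$alpha[1, ],
       context = fw$cache$ctx[1, ], h_tilde = fw$cache$htil[1, ],
       pred = fw$pred[1])
}

#' @rdname attention_trace
#' @param seq_set A `sequence_set`.
#' @param i Sample index.
#' @export
trace_sample <- function(params, config, seq_set, i) {
  attention_trace(params, config,
                  matrix(seq_set$X[i, , ], seq_set$window,
                         length(seq_set$features)),
                  seq_set$mask[i, ])
}
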