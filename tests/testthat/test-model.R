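# Attention operators, masked forward pass, gradients.

test_that("attention scores match the brute-force bilinear oracle", {
  set.seed(31)
  for (rep in 1:5) {
    d <- 4; tt <- 21
    W <- matrix(rnorm(d * d), d, d)
    h_all <- matrix(rnorm(tt * d), tt, d)
    h_t <- rnorm(d)
    s <- attention_scores(h_t, h_all, W)
    oracle <- vapply(seq_len(tt), function(si) {
      acc <- 0
      for (i in 1:d) for (j in 1:d) {
        acc <- acc + h_t[i] * W[i, j] * h_all[si, j]
      }
      acc
    }, numeric(1))
    expect_equal(s, oracle, tolerance = 1e-8)
  }
  # Identity-W symmetries.
  d <- 4
  h <- rnorm(d)
  same <- matrix(h, 3, d, byrow = TRUE)
  expect_equal(attention_scores(h, same, diag(d)),
               rep(sum(h^2), 3))
  orth <- c(h[2], -h[1], h[4], -h[3])
  expect_equal(attention_scores(h, matrix(orth, 1), diag(d)), 0)
  expect_error(attention_scores(h, same, diag(3)), "shape")
})

test_that("softmax weights are normalized, masked and shift-invariant", {
  a <- attention_weights(rep(0.7, 21))
  expect_equal(a, rep(1 / 21, 21))
  expect_equal(attention_weights(c(log(2), 0)), c(2 / 3, 1 / 3),
               tolerance = 1e-12)
  s <- rnorm(21)
  expect_equal(attention_weights(s), attention_weights(s + 13.7),
               tolerance = 1e-12)
  m <- rep(FALSE, 21); m[c(3, 9)] <- TRUE
  am <- attention_weights(s, m)
  expect_equal(am[c(3, 9)], c(0, 0))
  expect_equal(sum(am), 1)
  expect_true(all(am >= 0))
  expect_error(attention_weights(s, rep(TRUE, 21)), "masked")
  # Extreme scores stay finite (max-subtraction stabilization).
  expect_true(all(is.finite(attention_weights(c(1e4, 1e4 - 2, 0)))))
})

test_that("context vector and attended output match explicit loops", {
  set.seed(33)
  d <- 4; tt <- 21
  h_all <- matrix(rnorm(tt * d), tt, d)
  alpha <- attention_weights(rnorm(tt))
  ctx <- context_vector(alpha, h_all)
  oracle <- numeric(d)
  for (s in seq_len(tt)) oracle <- oracle + alpha[s] * h_all[s, ]
  expect_equal(ctx, oracle, tolerance = 1e-12)
  # One-hot weights pick out a single state.
  one <- numeric(tt); one[7] <- 1
  expect_equal(context_vector(one, h_all), h_all[7, ])

  Wc <- matrix(rnorm(d * 2 * d), d, 2 * d)
  h_t <- rnorm(d)
  out <- attended_output(ctx, h_t, Wc)
  expect_equal(out, as.vector(tanh(Wc %*% c(ctx, h_t))), tolerance = 1e-12)
  expect_true(all(abs(out) < 1))
  expect_equal(attended_output(ctx, h_t, Wc * 0), rep(0, d))
})

test_that("inference is deterministic and the trace is internally consistent", {
  m <- tiny_model(f = 6, window = 10)
  ss <- random_seq_set(n = 4, window = 10, f = 6, mask_frac = 0.2)
  p1 <- forward_bilstm(m$params, m$cfg, ss$X, ss$mask)$pred
  p2 <- forward_bilstm(m$params, m$cfg, ss$X, ss$mask)$pred
  expect_identical(p1, p2)
  tr <- trace_sample(m$params, m$cfg, ss, 2)
  expect_equal(sum(tr$alpha), 1)
  expect_true(all(tr$alpha[ss$mask[2, ]] == 0))
  expect_equal(tr$alpha,
               attention_weights(tr$scores, ss$mask[2, ]), tolerance = 1e-12)
  expect_equal(tr$context, context_vector(tr$alpha, tr$h_hat),
               tolerance = 1e-12)
  expect_equal(tr$pred, p1[2], tolerance = 1e-12)
})

test_that("masked timesteps have exactly zero influence on the output", {
  m <- tiny_model(f = 5)
  for (seed in 1:6) {
    ss <- random_seq_set(n = 4, f = 5, seed = seed, mask_frac = 0.3)
    base <- forward_bilstm(m$params, m$cfg, ss$X, ss$mask)
    X2 <- ss$X
    for (i in 1:4) {
      for (t in which(ss$mask[i, ])) X2[i, t, ] <- rnorm(5, 0, 100)
    }
    pert <- forward_bilstm(m$params, m$cfg, X2, ss$mask)
    expect_identical(base$pred, pert$pred)
    expect_identical(base$alpha, pert$alpha)
  }
  expect_error(
    forward_bilstm(m$params, m$cfg, random_seq_set(n = 2, f = 5)$X,
                   matrix(TRUE, 2, 21)),
    "all timesteps masked")
})

test_that("the unidirectional flag removes the backward direction", {
  uni <- tiny_model(f = 5, bidirectional = FALSE)
  expect_null(uni$params$layers[[1]]$bwd)
  ss <- random_seq_set(n = 3, f = 5)
  p <- forward_bilstm(uni$params, uni$cfg, ss$X, ss$mask)$pred
  expect_true(all(is.finite(p)))
  # Unidirectional output is invariant to the future beyond attention: with
  # attention only over past states it still differs from bidirectional.
  bi <- tiny_model(f = 5, bidirectional = TRUE)
  pb <- forward_bilstm(bi$params, bi$cfg, ss$X, ss$mask)$pred
  expect_false(isTRUE(all.equal(p, pb)))
})

test_that("a weight-tied Bi-LSTM is symmetric under sequence reversal", {
  # Swapping direction weights and reversing the input sequence leaves the
  # concatenated-state multiset unchanged; with a symmetric attention head
  # built from the last layer, the reversed twin's states mirror exactly.
  cfg <- model_config(n_features = 4, widths = c(6, 6, 6),
                      width_mode = "per_direction", dropout = 0, window = 8,
                      seed = 5)
  p <- pm25seq:::init_params(cfg)
  swap <- p
  for (l in seq_along(p$layers)) {
    swap$layers[[l]]$fwd <- p$layers[[l]]$bwd
    swap$layers[[l]]$bwd <- p$layers[[l]]$fwd
    d <- length(p$layers[[l]]$gamma) / 2
    swap$layers[[l]]$gamma <- p$layers[[l]]$gamma[c(d + 1:d, 1:d)]
    swap$layers[[l]]$beta <- p$layers[[l]]$beta[c(d + 1:d, 1:d)]
    if (l > 1) {
      # Deeper layers consume the concatenated [fwd; bwd] states of the
      # layer below, whose halves the twin has swapped: permute the input
      # rows of the recurrent input weights to match.
      din <- nrow(p$layers[[l]]$fwd$W) / 2
      perm <- c(din + 1:din, 1:din)
      swap$layers[[l]]$fwd$W <- swap$layers[[l]]$fwd$W[perm, ]
      swap$layers[[l]]$bwd$W <- swap$layers[[l]]$bwd$W[perm, ]
    }
  }
  set.seed(6)
  X <- array(rnorm(2 * 8 * 4), dim = c(2, 8, 4))
  mask <- matrix(FALSE, 2, 8)
  fw <- forward_bilstm(p, cfg, X, mask, keep_cache = TRUE)
  Xr <- X[, 8:1, , drop = FALSE]
  fr <- forward_bilstm(swap, cfg, Xr, mask, keep_cache = TRUE)
  d <- dim(fw$cache$hhat)[3] / 2
  # State at time t of the original = swapped-half state at time T+1-t of
  # the reversed twin.
  for (t in c(1, 4, 8)) {
    expect_equal(fw$cache$hhat[, t, c(d + 1:d, 1:d)],
                 fr$cache$hhat[, 8 + 1 - t, ], tolerance = 1e-10)
  }
})

test_that("backpropagated gradients match finite differences on a toy model", {
  cfg <- model_config(n_features = 3, widths = c(4, 4, 4), dropout = 0.2,
                      window = 6, seed = 7)
  p <- pm25seq:::init_params(cfg)
  set.seed(8)
  X <- array(rnorm(3 * 6 * 3), dim = c(3, 6, 3))
  mask <- matrix(FALSE, 3, 6); mask[1, 2] <- TRUE; mask[2, c(1, 6)] <- TRUE
  y <- rnorm(3)
  lg <- pm25seq:::bilstm_loss_grad(p, cfg, X, mask, y, delta = 1,
                                   training = TRUE, dropout_seed = 11)
  obj <- function(pp) {
    fw <- forward_bilstm(pp, cfg, X, mask, training = TRUE,
                         dropout_seed = 11, keep_cache = FALSE)
    huber_loss(y, fw$pred, 1)
  }
  skel <- unclass(p)
  pv <- unlist(skel, use.names = FALSE)
  gv <- unlist(lg$grads, use.names = FALSE)
  set.seed(9)
  idx <- sample(length(pv), 80)
  eps <- 1e-5
  for (i in idx) {
    v1 <- pv; v1[i] <- v1[i] + eps
    v2 <- pv; v2[i] <- v2[i] - eps
    fd <- (obj(utils::relist(v1, skel)) - obj(utils::relist(v2, skel))) /
      (2 * eps)
    denom <- max(abs(fd) + abs(gv[i]), 1e-4)
    expect_lt(abs(fd - gv[i]) / denom, 1e-4)
  }
})

test_that("checkpoints round-trip and validate their schema", {
  ss <- random_seq_set(n = 12, window = 8, f = 4, seed = 12)
  tc <- train_config(batch_size = 8, max_epochs = 2, patience = 5, seed = 2)
  fit <- train_bilstm(ss, NULL, train_cfg = tc, widths = c(4, 4, 4))
  path <- file.path(withr::local_tempdir(), "ckpt.rds")
  save_checkpoint(fit, path)
  back <- load_checkpoint(path)
  expect_equal(back$features, fit$features)
  p1 <- forward_bilstm(fit$params, fit$model_config, ss$X, ss$mask)$pred
  p2 <- forward_bilstm(back$params, back$model_config, ss$X, ss$mask)$pred
  expect_identical(p1, p2)
  # Corrupt the schema: loading must refuse.
  obj <- readRDS(path)
  obj$schema$features <- c(obj$schema$features, "rogue")
  saveRDS(obj, path)
  expect_error(load_checkpoint(path), "schema")
})
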