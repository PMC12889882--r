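# Reverse-mode gradients for the attention Bi-LSTM. Mirrors forward_bilstm()
# exactly; correctness is pinned by a finite-difference gradient check in the
# test suite.

ln_backward <- function(dY3, ln, gamma) {
  d <- dim(dY3)
  m <- d[1] * d[2]
  dY <- matrix(dY3, m, d[3])
  dgamma <- colSums(dY * ln$xhat)
  dbeta <- colSums(dY)
  dxhat <- dY * rep(gamma, each = m)
  dx <- ln$inv * (dxhat - rowMeans(dxhat) - ln$xhat * rowMeans(dxhat * ln$xhat))
  list(dx = array(dx, dim = d), dgamma = dgamma, dbeta = dbeta)
}

lstm_direction_backward <- function(dH, dir, inp, mask, W, U) {
  n <- dim(dH)[1]; tt <- dim(dH)[2]; h_n <- dim(dH)[3]
  d_in <- dim(inp)[3]
  gW <- matrix(0, d_in, 4 * h_n); gU <- matrix(0, h_n, 4 * h_n)
  gb <- numeric(4 * h_n)
  dInp <- array(0, dim = c(n, tt, d_in))
  dh_next <- matrix(0, n, h_n); dc_next <- matrix(0, n, h_n)
  ord <- dir$ord
  for (p in rev(seq_along(ord))) {
    t <- ord[p]
    dh <- slice_t(dH, t) + dh_next
    dc_in <- dc_next
    i_ <- slice_t(dir$i, t); f_ <- slice_t(dir$f, t)
    g_ <- slice_t(dir$g, t); o_ <- slice_t(dir$o, t)
    c_t <- slice_t(dir$c, t)
    c_prev <- if (p == 1) matrix(0, n, h_n) else slice_t(dir$c, ord[p - 1])
    tc <- tanh(c_t)
    do_ <- dh * tc
    dct <- dc_in + dh * o_ * (1 - tc^2)
    di <- dct * g_; dg <- dct * i_; df <- dct * c_prev
    unm <- as.numeric(!mask[, t])
    dA <- cbind(di * i_ * (1 - i_), df * f_ * (1 - f_),
                dg * (1 - g_^2), do_ * o_ * (1 - o_)) * unm
    x_t <- slice_t(inp, t)
    h_prev <- if (p == 1) matrix(0, n, h_n) else
      matrix(dir$H[, ord[p - 1], ], n, h_n)
    gW <- gW + crossprod(x_t, dA)
    gU <- gU + crossprod(h_prev, dA)
    gb <- gb + colSums(dA)
    dInp[, t, ] <- dA %*% t(W)
    mrow <- 1 - unm
    dh_next <- dA %*% t(U) + dh * mrow
    dc_next <- dct * f_ * unm + dc_in * mrow
  }
  list(dInp = dInp, gW = gW, gU = gU, gb = gb)
}

backward_bilstm <- function(params, config, cache, dpred) {
  n <- length(dpred)
  hhat <- cache$hhat
  tt <- dim(hhat)[2]; d_fin <- dim(hhat)[3]
  alpha <- cache$alpha; mask <- cache$mask
  # Head
  dhtil <- matrix(dpred, n, 1) %*% t(params$w_out)
  g_wout <- matrix(colSums(cache$htil * dpred), ncol = 1)
  g_bout <- sum(dpred)
  # h_tilde = tanh(cq %*% t(Wc))
  dpre <- dhtil * (1 - cache$htil^2)
  g_Wc <- crossprod(dpre, cache$cq)
  dcq <- dpre %*% params$Wc
  dctx <- dcq[, seq_len(d_fin), drop = FALSE]
  dq <- dcq[, d_fin + seq_len(d_fin), drop = FALSE]
  # context and softmax
  dalpha <- matrix(0, n, tt)
  dhhat <- array(0, dim = dim(hhat))
  for (t in seq_len(tt)) {
    h_t <- slice_t(hhat, t)
    dalpha[, t] <- rowSums(dctx * h_t)
    dhhat[, t, ] <- dhhat[, t, ] + alpha[, t] * dctx
  }
  dS <- alpha * (dalpha - rowSums(alpha * dalpha))
  # scores: S[,t] = rowSums((q %*% Wa) * h_t)
  tsum <- matrix(0, n, d_fin)
  for (t in seq_len(tt)) {
    h_t <- slice_t(hhat, t)
    tsum <- tsum + dS[, t] * h_t
    dhhat[, t, ] <- dhhat[, t, ] + dS[, t] * cache$qw
  }
  g_Wa <- crossprod(cache$q, tsum)
  dq <- dq + tsum %*% t(params$Wa)
  dhhat[, tt, ] <- dhhat[, tt, ] + dq
  # layers, top down
  n_layers <- length(params$layers)
  g_layers <- vector("list", n_layers)
  dout <- dhhat
  for (l in rev(seq_len(n_layers))) {
    lay <- params$layers[[l]]
    lcache <- cache$caches[[l]]
    if (!is.null(cache$drop_masks[[l]])) {
      dout <- dout * cache$drop_masks[[l]]
    }
    lnb <- ln_backward(dout, lcache$ln, lay$gamma)
    dh_cat <- lnb$dx
    h_l <- dim(lcache$fwd$H)[3]
    fwd_b <- lstm_direction_backward(
      dh_cat[, , seq_len(h_l), drop = FALSE], lcache$fwd, lcache$inp, mask,
      lay$fwd$W, lay$fwd$U)
    dinp <- fwd_b$dInp
    g_bwd <- NULL
    if (config$bidirectional) {
      bwd_b <- lstm_direction_backward(
        dh_cat[, , h_l + seq_len(h_l), drop = FALSE], lcache$bwd,
        lcache$inp, mask, lay$bwd$W, lay$bwd$U)
      dinp <- dinp + bwd_b$dInp
      g_bwd <- list(W = bwd_b$gW, U = bwd_b$gU, b = bwd_b$gb)
    }
    g_layers[[l]] <- list(
      fwd = list(W = fwd_b$gW, U = fwd_b$gU, b = fwd_b$gb),
      bwd = g_bwd, gamma = lnb$dgamma, beta = lnb$dbeta)
    dout <- dinp
  }
  list(layers = g_layers, Wa = g_Wa, Wc = g_Wc, w_out = g_wout,
       b_out = g_bout)
}

# Huber loss (batch mean) and its gradient in the prediction.
huber_value_grad <- function(pred, y, delta) {
  r <- pred - y
  a <- abs(r)
  quad <- a <= delta
  loss <- mean(ifelse(quad, 0.5 * r^2, delta * (a - 0.5 * delta)))
  grad <- ifelse(quad, r, delta * sign(r)) / length(r)
  list(loss = loss, grad = grad)
}

# One training-step objective: forward, Huber loss, full gradient.
bilstm_loss_grad <- function(params, config, X, mask, y, delta = 1,
                             training = TRUE, dropout_seed = 0) {
  fw <- forward_bilstm(params, config, X, mask, training = training,
                       dropout_seed = dropout_seed, keep_cache = TRUE)
  hv <- huber_value_grad(fw$pred, y, delta)
  grads <- backward_bilstm(params, config, fw$cache, hv$grad)
  list(loss = hv$loss, grads = grads, pred = fw$pred)
}
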