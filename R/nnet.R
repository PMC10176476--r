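# Minimal dense/convolutional/recurrent layer kit with manual backprop.
# Everything operates on batched row-major matrices (one example per row)
# and plain R matrix algebra; Adam is the only optimizer. Internal.

.glorot <- function(nin, nout, n_row = nin, n_col = nout) {
  lim <- sqrt(6 / (nin + nout))
  matrix(stats::runif(n_row * n_col, -lim, lim), n_row, n_col)
}

.relu <- function(x) x * (x > 0)

.softmax_rows <- function(z) {
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

# ---- convolution via im2col ------------------------------------------------

# precompute geometry for one conv layer ('same' padding, square input)
.conv_geom <- function(npix, c_in, k = 3L, stride = 2L) {
  pad <- (k - 1L) %/% 2L
  pp <- npix + 2L * pad
  out <- as.integer(ceiling(npix / stride))
  # linear indices into the padded, flattened (pp, pp, c_in) volume for each
  # output position (rows) and kernel element (cols)
  ox <- rep(seq_len(out), times = out)
  oy <- rep(seq_len(out), each = out)
  x0 <- (ox - 1L) * stride      # top-left (0-based) in padded coords
  y0 <- (oy - 1L) * stride
  idx <- matrix(0L, out * out, k * k * c_in)
  col <- 1L
  for (c in seq_len(c_in)) {
    chan_off <- (c - 1L) * pp * pp
    for (ky in seq_len(k)) {
      for (kx in seq_len(k)) {
        idx[, col] <- chan_off + (y0 + ky - 1L) * pp + (x0 + kx)
        col <- col + 1L
      }
    }
  }
  # index map from unpadded to padded volume (for padding/unpadding)
  ux <- rep(seq_len(npix), times = npix)
  uy <- rep(seq_len(npix), each = npix)
  unpad1 <- (uy + pad - 1L) * pp + (ux + pad)   # one channel
  unpad <- as.vector(outer(unpad1, (seq_len(c_in) - 1L) * pp * pp, `+`))
  list(npix = npix, c_in = c_in, k = k, stride = stride, pad = pad,
       pp = pp, out = out, idx = idx, unpad = unpad)
}

.conv_pad <- function(X, g) {
  Xp <- matrix(0, nrow(X), g$pp * g$pp * g$c_in)
  Xp[, g$unpad] <- X
  Xp
}

# forward: X is N x (npix^2 * c_in); returns list(out: N x (out^2 * c_out),
# cache for backprop)
.conv_forward <- function(X, W, b, g) {
  n <- nrow(X)
  Xp <- .conv_pad(X, g)
  M <- Xp[, as.vector(g$idx), drop = FALSE]      # N x (outHW * kkC)
  colm <- matrix(M, n * nrow(g$idx), ncol(g$idx)) # (N*outHW) x kkC
  z <- sweep(colm %*% W, 2L, b, `+`)
  a <- .relu(z)
  list(out = matrix(a, n, nrow(g$idx) * ncol(W)),
       cache = list(colm = colm, z = z, n = n, g = g, W = W))
}

.conv_backward <- function(dout, cache) {
  g <- cache$g; n <- cache$n
  out_hw <- nrow(g$idx)
  dA <- matrix(dout, n * out_hw, ncol(cache$W))
  dZ <- dA * (cache$z > 0)
  dW <- crossprod(cache$colm, dZ)
  db <- colSums(dZ)
  dcol <- tcrossprod(dZ, cache$W)                 # (N*outHW) x kkC
  dXp <- matrix(0, n, g$pp * g$pp * g$c_in)
  for (j in seq_len(ncol(g$idx))) {
    slice <- matrix(dcol[, j], n, out_hw)
    cols <- g$idx[, j]
    dXp[, cols] <- dXp[, cols] + slice
  }
  list(dX = dXp[, g$unpad, drop = FALSE], dW = dW, db = db)
}

# ---- masked LSTM over ragged token sequences -------------------------------

# ids: N x Tmax integer matrix, dense tokens left-aligned, 0-padded at the
# end. emb has one row per vocabulary id (id 0 embeds to zeros and never
# occurs among the first len_i tokens). Returns the hidden state after each
# example's last token.
.lstm_forward <- function(ids, emb, W, U, b, keep_cache = TRUE) {
  n <- nrow(ids)
  H <- as.integer(ncol(W) / 4L)
  len <- rowSums(ids > 0L)
  tmax <- if (n > 0) max(len, 1L) else 0L
  h <- matrix(0, n, H); cst <- matrix(0, n, H)
  h_final <- matrix(0, n, H)
  cache <- if (keep_cache) vector("list", tmax) else NULL
  for (t in seq_len(tmax)) {
    act <- which(len >= t)
    if (length(act) == 0L) break
    x_t <- emb[ids[act, t], , drop = FALSE]
    hp <- h[act, , drop = FALSE]
    cp <- cst[act, , drop = FALSE]
    A <- x_t %*% W + hp %*% U
    A <- sweep(A, 2L, b, `+`)
    i_g <- 1 / (1 + exp(-A[, 1:H, drop = FALSE]))
    f_g <- 1 / (1 + exp(-A[, (H + 1):(2 * H), drop = FALSE]))
    g_g <- tanh(A[, (2 * H + 1):(3 * H), drop = FALSE])
    o_g <- 1 / (1 + exp(-A[, (3 * H + 1):(4 * H), drop = FALSE]))
    c_new <- f_g * cp + i_g * g_g
    tc <- tanh(c_new)
    h_new <- o_g * tc
    h[act, ] <- h_new
    cst[act, ] <- c_new
    done <- act[len[act] == t]
    if (length(done)) h_final[done, ] <- h[done, , drop = FALSE]
    if (keep_cache)
      cache[[t]] <- list(act = act, x_ids = ids[act, t], i = i_g, f = f_g,
                         g = g_g, o = o_g, c_prev = cp, c_new = c_new,
                         tc = tc, h_prev = hp)
  }
  list(h_final = h_final, len = len, tmax = tmax, cache = cache)
}

# dh_final: N x H gradient wrt each example's final hidden state
.lstm_backward <- function(dh_final, fwd, emb, W, U) {
  n <- nrow(dh_final)
  H <- ncol(dh_final)
  dW <- matrix(0, nrow(W), ncol(W))
  dU <- matrix(0, H, 4L * H)
  db <- numeric(4L * H)
  demb <- matrix(0, nrow(emb), ncol(emb))
  dh <- matrix(0, n, H)
  dc <- matrix(0, n, H)
  len <- fwd$len
  for (t in rev(seq_len(fwd$tmax))) {
    cc <- fwd$cache[[t]]
    if (is.null(cc)) next
    act <- cc$act
    inject <- act[len[act] == t]
    if (length(inject))
      dh[inject, ] <- dh[inject, , drop = FALSE] +
        dh_final[inject, , drop = FALSE]
    dha <- dh[act, , drop = FALSE]
    dca <- dc[act, , drop = FALSE]
    do_g <- dha * cc$tc
    dct <- dca + dha * cc$o * (1 - cc$tc^2)
    di <- dct * cc$g
    dg <- dct * cc$i
    df <- dct * cc$c_prev
    dcp <- dct * cc$f
    dA <- cbind(di * cc$i * (1 - cc$i),
                df * cc$f * (1 - cc$f),
                dg * (1 - cc$g^2),
                do_g * cc$o * (1 - cc$o))
    x_t <- emb[cc$x_ids, , drop = FALSE]
    dW <- dW + crossprod(x_t, dA)
    dU <- dU + crossprod(cc$h_prev, dA)
    db <- db + colSums(dA)
    dx <- tcrossprod(dA, W)
    agg <- rowsum(dx, group = cc$x_ids)
    rid <- as.integer(rownames(agg))
    demb[rid, ] <- demb[rid, , drop = FALSE] + agg
    dh[act, ] <- tcrossprod(dA, U)
    dc[act, ] <- dcp
  }
  list(dW = dW, dU = dU, db = db, demb = demb)
}

# ---- Adam ------------------------------------------------------------------

.adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

.adam_step <- function(params, grads, state, lr = 1e-3, beta1 = 0.9,
                       beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    gnm <- grads[[nm]]
    if (is.null(gnm)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * gnm
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * gnm^2
    mhat <- state$m[[nm]] / bc1
    vhat <- state$v[[nm]] / bc2
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}
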