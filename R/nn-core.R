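# Minimal neural-network engine: dense / 1-D convolution / max-pooling /
# vanilla-RNN / LSTM / GRU layers with analytic backpropagation, plus Adam.
# Sequences travel through recurrent layers as length-T lists of B x D
# matrices (batch-major); convolutional code uses B x C x W arrays.
# Everything here is internal; the model builders in models.R and
# baselines.R compose these primitives.

sigmoid <- function(x) 1 / (1 + exp(-x))

nn_leaky_relu <- function(x, slope = 0.2) {
  neg <- x < 0
  x[neg] <- x[neg] * slope
  x
}

nn_leaky_relu_grad <- function(d, x, slope = 0.2) {
  d[x < 0] <- d[x < 0] * slope
  d
}

# Glorot-uniform initialisation; draws come from the ambient RNG stream so a
# single set.seed() at model-build time makes initialisation reproducible.
nn_glorot <- function(nr, nc) {
  s <- sqrt(6 / (nr + nc))
  matrix(runif(nr * nc, -s, s), nr, nc)
}

add_bias <- function(A, b) A + rep(b, each = nrow(A))

## ---- dense -----------------------------------------------------------------

nn_dense_init <- function(d_in, d_out) {
  list(W = nn_glorot(d_in, d_out), b = numeric(d_out))
}

nn_dense_forward <- function(X, p) add_bias(X %*% p$W, p$b)

nn_dense_backward <- function(dY, X, p) {
  list(dX = dY %*% t(p$W),
       grads = list(W = crossprod(X, dY), b = colSums(dY)))
}

## ---- LSTM ------------------------------------------------------------------

# Gate layout in the 4H-wide blocks: input, forget, candidate, output.
nn_lstm_init <- function(d_in, h) {
  list(W = nn_glorot(d_in, 4L * h), U = nn_glorot(h, 4L * h), b = numeric(4L * h))
}

nn_lstm_forward <- function(xs, p) {
  T_len <- length(xs)
  B <- nrow(xs[[1L]])
  H <- nrow(p$U)
  i1 <- seq_len(H); i2 <- H + i1; i3 <- 2L * H + i1; i4 <- 3L * H + i1
  h <- matrix(0, B, H)
  cc <- matrix(0, B, H)
  hs <- vector("list", T_len)
  cache <- vector("list", T_len)
  for (t in seq_len(T_len)) {
    A <- add_bias(xs[[t]] %*% p$W + h %*% p$U, p$b)
    ig <- sigmoid(A[, i1, drop = FALSE])
    fg <- sigmoid(A[, i2, drop = FALSE])
    gg <- tanh(A[, i3, drop = FALSE])
    og <- sigmoid(A[, i4, drop = FALSE])
    c_new <- fg * cc + ig * gg
    tc <- tanh(c_new)
    h_new <- og * tc
    cache[[t]] <- list(x = xs[[t]], h_prev = h, c_prev = cc,
                       i = ig, f = fg, g = gg, o = og, tc = tc)
    h <- h_new; cc <- c_new
    hs[[t]] <- h_new
  }
  list(hs = hs, cache = cache)
}

# dhs: list of B x H gradients on the hidden outputs (NULL entries = zero).
nn_lstm_backward <- function(dhs, cache, p) {
  T_len <- length(cache)
  B <- nrow(cache[[1L]]$h_prev)
  H <- nrow(p$U)
  dW <- p$W * 0; dU <- p$U * 0; db <- p$b * 0
  dh_next <- matrix(0, B, H)
  dc_next <- matrix(0, B, H)
  dxs <- vector("list", T_len)
  for (t in rev(seq_len(T_len))) {
    cc <- cache[[t]]
    dh <- if (is.null(dhs[[t]])) dh_next else dhs[[t]] + dh_next
    dc <- dh * cc$o * (1 - cc$tc^2) + dc_next
    d_o <- dh * cc$tc * cc$o * (1 - cc$o)
    d_i <- dc * cc$g * cc$i * (1 - cc$i)
    d_f <- dc * cc$c_prev * cc$f * (1 - cc$f)
    d_g <- dc * cc$i * (1 - cc$g^2)
    dA <- cbind(d_i, d_f, d_g, d_o)
    dW <- dW + crossprod(cc$x, dA)
    dU <- dU + crossprod(cc$h_prev, dA)
    db <- db + colSums(dA)
    dxs[[t]] <- dA %*% t(p$W)
    dh_next <- dA %*% t(p$U)
    dc_next <- dc * cc$f
  }
  list(dxs = dxs, grads = list(W = dW, U = dU, b = db))
}

## ---- vanilla RNN -----------------------------------------------------------

nn_rnn_init <- function(d_in, h) {
  list(W = nn_glorot(d_in, h), U = nn_glorot(h, h), b = numeric(h))
}

nn_rnn_forward <- function(xs, p) {
  T_len <- length(xs)
  B <- nrow(xs[[1L]])
  H <- nrow(p$U)
  h <- matrix(0, B, H)
  hs <- vector("list", T_len)
  cache <- vector("list", T_len)
  for (t in seq_len(T_len)) {
    h_new <- tanh(add_bias(xs[[t]] %*% p$W + h %*% p$U, p$b))
    cache[[t]] <- list(x = xs[[t]], h_prev = h, h = h_new)
    h <- h_new
    hs[[t]] <- h_new
  }
  list(hs = hs, cache = cache)
}

nn_rnn_backward <- function(dhs, cache, p) {
  T_len <- length(cache)
  B <- nrow(cache[[1L]]$h_prev)
  H <- nrow(p$U)
  dW <- p$W * 0; dU <- p$U * 0; db <- p$b * 0
  dh_next <- matrix(0, B, H)
  dxs <- vector("list", T_len)
  for (t in rev(seq_len(T_len))) {
    cc <- cache[[t]]
    dh <- if (is.null(dhs[[t]])) dh_next else dhs[[t]] + dh_next
    dA <- dh * (1 - cc$h^2)
    dW <- dW + crossprod(cc$x, dA)
    dU <- dU + crossprod(cc$h_prev, dA)
    db <- db + colSums(dA)
    dxs[[t]] <- dA %*% t(p$W)
    dh_next <- dA %*% t(p$U)
  }
  list(dxs = dxs, grads = list(W = dW, U = dU, b = db))
}

## ---- GRU -------------------------------------------------------------------

# Block layout: update z, reset r, candidate g.  The candidate's recurrent
# term uses the reset-gated state r * h_prev.
nn_gru_init <- function(d_in, h) {
  list(W = nn_glorot(d_in, 3L * h), U = nn_glorot(h, 3L * h), b = numeric(3L * h))
}

nn_gru_forward <- function(xs, p) {
  T_len <- length(xs)
  B <- nrow(xs[[1L]])
  H <- nrow(p$U)
  iz <- seq_len(H); ir <- H + iz; ig <- 2L * H + iz
  h <- matrix(0, B, H)
  hs <- vector("list", T_len)
  cache <- vector("list", T_len)
  Uz <- p$U[, iz, drop = FALSE]; Ur <- p$U[, ir, drop = FALSE]; Ug <- p$U[, ig, drop = FALSE]
  for (t in seq_len(T_len)) {
    XW <- add_bias(xs[[t]] %*% p$W, p$b)
    z <- sigmoid(XW[, iz, drop = FALSE] + h %*% Uz)
    r <- sigmoid(XW[, ir, drop = FALSE] + h %*% Ur)
    rh <- r * h
    g <- tanh(XW[, ig, drop = FALSE] + rh %*% Ug)
    h_new <- (1 - z) * h + z * g
    cache[[t]] <- list(x = xs[[t]], h_prev = h, z = z, r = r, g = g, rh = rh)
    h <- h_new
    hs[[t]] <- h_new
  }
  list(hs = hs, cache = cache)
}

nn_gru_backward <- function(dhs, cache, p) {
  T_len <- length(cache)
  B <- nrow(cache[[1L]]$h_prev)
  H <- nrow(p$U)
  iz <- seq_len(H); ir <- H + iz; ig <- 2L * H + iz
  Uz <- p$U[, iz, drop = FALSE]; Ur <- p$U[, ir, drop = FALSE]; Ug <- p$U[, ig, drop = FALSE]
  dW <- p$W * 0; dU <- p$U * 0; db <- p$b * 0
  dh_next <- matrix(0, B, H)
  dxs <- vector("list", T_len)
  for (t in rev(seq_len(T_len))) {
    cc <- cache[[t]]
    dh <- if (is.null(dhs[[t]])) dh_next else dhs[[t]] + dh_next
    dz <- dh * (cc$g - cc$h_prev) * cc$z * (1 - cc$z)
    dg <- dh * cc$z * (1 - cc$g^2)
    dh_prev <- dh * (1 - cc$z)
    drh <- dg %*% t(Ug)
    dr <- drh * cc$h_prev * cc$r * (1 - cc$r)
    dh_prev <- dh_prev + drh * cc$r + dz %*% t(Uz) + dr %*% t(Ur)
    dA <- cbind(dz, dr, dg)
    dW <- dW + crossprod(cc$x, dA)
    db <- db + colSums(dA)
    dU[, iz] <- dU[, iz] + crossprod(cc$h_prev, dz)
    dU[, ir] <- dU[, ir] + crossprod(cc$h_prev, dr)
    dU[, ig] <- dU[, ig] + crossprod(cc$rh, dg)
    dxs[[t]] <- dA %*% t(p$W)
    dh_next <- dh_prev
  }
  list(dxs = dxs, grads = list(W = dW, U = dU, b = db))
}

nn_cell <- function(cell) {
  switch(cell,
         lstm = list(init = nn_lstm_init, forward = nn_lstm_forward, backward = nn_lstm_backward),
         gru  = list(init = nn_gru_init,  forward = nn_gru_forward,  backward = nn_gru_backward),
         rnn  = list(init = nn_rnn_init,  forward = nn_rnn_forward,  backward = nn_rnn_backward),
         stop_validation("unknown recurrent cell `%s`", cell))
}

## ---- 1-D convolution and max pooling ---------------------------------------

# X: B x C_in x W array.  Weights: (C_in * h) x M matrix whose rows follow the
# column-major layout of the B x C_in x h patch, so patch extraction is a
# single matrix() reshape.  Stride k, symmetric zero padding P on the W axis.
nn_conv1d_init <- function(c_in, h, m) {
  list(W = nn_glorot(c_in * h, m), b = numeric(m))
}

nn_pad_width <- function(X, P) {
  if (P == 0L) return(X)
  d <- dim(X)
  out <- array(0, c(d[1L], d[2L], d[3L] + 2L * P))
  out[, , P + seq_len(d[3L])] <- X
  out
}

nn_conv1d_forward <- function(X, p, stride, padding = 0L) {
  X <- nn_pad_width(X, padding)
  d <- dim(X)
  B <- d[1L]; W_in <- d[3L]
  h <- nrow(p$W) / d[2L]
  M <- ncol(p$W)
  L <- (W_in - h) %/% stride + 1L
  out <- array(0, c(B, M, L))
  patches <- vector("list", L)
  for (i in seq_len(L)) {
    l <- (i - 1L) * stride + 1L
    patch <- matrix(X[, , l:(l + h - 1L)], nrow = B)
    patches[[i]] <- patch
    out[, , i] <- add_bias(patch %*% p$W, p$b)
  }
  list(out = out, cache = list(patches = patches, dimX = d, h = h,
                               stride = stride, padding = padding))
}

nn_conv1d_backward <- function(dOut, cache, p) {
  d <- cache$dimX
  B <- d[1L]; C <- d[2L]
  h <- cache$h; stride <- cache$stride; P <- cache$padding
  L <- dim(dOut)[3L]
  dW <- p$W * 0; db <- p$b * 0
  dX <- array(0, d)
  for (i in seq_len(L)) {
    dOi <- matrix(dOut[, , i], nrow = B)
    dW <- dW + crossprod(cache$patches[[i]], dOi)
    db <- db + colSums(dOi)
    l <- (i - 1L) * stride + 1L
    dX[, , l:(l + h - 1L)] <- dX[, , l:(l + h - 1L), drop = FALSE] +
      array(dOi %*% t(p$W), c(B, C, h))
  }
  if (P > 0L) dX <- dX[, , P + seq_len(d[3L] - 2L * P), drop = FALSE]
  list(dX = dX, grads = list(W = dW, b = db))
}

# Max pooling along the W axis, window `a`, stride `b`; windows may overlap so
# the backward pass accumulates.
nn_maxpool_forward <- function(X, a, b) {
  d <- dim(X)
  B <- d[1L]; C <- d[2L]; W_in <- d[3L]
  L <- (W_in - a) %/% b + 1L
  out <- array(0, c(B, C, L))
  argmax <- array(0L, c(B, C, L))
  for (j in seq_len(L)) {
    s <- (j - 1L) * b + 1L
    best <- matrix(X[, , s], B, C)
    idx <- matrix(s, B, C)
    if (a > 1L) for (off in 1L:(a - 1L)) {
      v <- matrix(X[, , s + off], B, C)
      upd <- v > best
      best[upd] <- v[upd]
      idx[upd] <- s + off
    }
    out[, , j] <- best
    argmax[, , j] <- idx
  }
  list(out = out, cache = list(argmax = argmax, dimX = d))
}

nn_maxpool_backward <- function(dOut, cache) {
  d <- cache$dimX
  B <- d[1L]; C <- d[2L]
  dX <- array(0, d)
  L <- dim(dOut)[3L]
  bc <- cbind(rep(seq_len(B), C), rep(seq_len(C), each = B))
  for (j in seq_len(L)) {
    pos <- as.vector(cache$argmax[, , j])
    lin <- bc[, 1L] + (bc[, 2L] - 1L) * B + (pos - 1L) * B * C
    dX[lin] <- dX[lin] + as.vector(dOut[, , j])
  }
  list(dX = dX)
}

## ---- softmax ---------------------------------------------------------------

nn_softmax <- function(Z) {
  Z <- Z - apply(Z, 1L, max)
  E <- exp(Z)
  E / rowSums(E)
}

## ---- dropout ---------------------------------------------------------------

# Inverted dropout; mask drawn from the ambient RNG stream.
nn_dropout_mask <- function(dims, p_drop) {
  if (p_drop <= 0) return(NULL)
  array((runif(prod(dims)) >= p_drop) / (1 - p_drop), dims)
}

## ---- parameter trees and Adam ----------------------------------------------

tree_zeros <- function(p) if (is.list(p)) lapply(p, tree_zeros) else p * 0

tree_add <- function(a, b) {
  if (is.list(a)) Map(tree_add, a, b) else a + b
}

tree_count <- function(p) {
  if (is.list(p)) sum(vapply(p, tree_count, numeric(1))) else length(p)
}

nn_adam_init <- function(params) {
  list(t = 0L, m = tree_zeros(params), v = tree_zeros(params))
}

.adam_rec <- function(p, g, m, v, lr, b1, b2, eps, t) {
  if (is.list(p)) {
    if (!is.null(names(p)) && !is.null(names(g))) g <- g[names(p)]
    out <- mapply(.adam_rec, p, g, m, v, SIMPLIFY = FALSE,
                  MoreArgs = list(lr = lr, b1 = b1, b2 = b2, eps = eps, t = t))
    list(p = lapply(out, `[[`, "p"),
         m = lapply(out, `[[`, "m"),
         v = lapply(out, `[[`, "v"))
  } else {
    m2 <- b1 * m + (1 - b1) * g
    v2 <- b2 * v + (1 - b2) * g * g
    mh <- m2 / (1 - b1^t)
    vh <- v2 / (1 - b2^t)
    list(p = p - lr * mh / (sqrt(vh) + eps), m = m2, v = v2)
  }
}

nn_adam_step <- function(params, grads, state, lr, b1 = 0.9, b2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  out <- .adam_rec(params, grads, state$m, state$v, lr, b1, b2, eps, state$t)
  state$m <- out$m
  state$v <- out$v
  list(params = out$p, state = state)
}

## ---- array <-> list-of-timesteps helpers -----------------------------------

# B x T x D array to length-T list of B x D matrices.
array_to_steps <- function(X) {
  d <- dim(X)
  lapply(seq_len(d[2L]), function(t) matrix(X[, t, ], nrow = d[1L]))
}

steps_to_array <- function(xs) {
  B <- nrow(xs[[1L]]); D <- ncol(xs[[1L]]); T_len <- length(xs)
  out <- array(0, c(B, T_len, D))
  for (t in seq_len(T_len)) out[, t, ] <- xs[[t]]
  out
}

# Sequence matrix (B x T, one channel) to list of B x 1 inputs.
matrix_to_steps <- function(X) {
  lapply(seq_len(ncol(X)), function(t) X[, t, drop = FALSE])
}
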