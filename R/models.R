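#' Output length of a strided 1-D convolution
#'
#' Computes the number of valid filter placements along the time axis,
#' `floor((W - F + 2P) / S) + 1`, the standard shape rule for a strided
#' convolution with symmetric zero padding.
#'
#' @param W Input length (samples).
#' @param F Filter length (samples).
#' @param S Stride (samples).
#' @param P Amount of zero padding on each side (samples); default 0.
#' @return Integer output length.
#' @examples
#' conv_output_length(3120, 120, 5)  # 601
#' @export
conv_output_length <- function(W, F, S, P = 0L) {
  W <- check_count(W, "W"); F <- check_count(F, "F")
  S <- check_count(S, "S"); P <- check_count(P, "P", min = 0L)
  if (W + 2L * P < F) {
    stop_shape("convolution input length %d (+2*%d padding) is shorter than filter length %d",
               W, P, F)
  }
  as.integer((W - F + 2L * P) %/% S + 1L)
}

#' Output length of a strided max-pooling layer
#'
#' `floor((W - F) / S) + 1` for pooling window `F` and stride `S`.
#'
#' @param W Input length (samples).
#' @param F Pooling window (samples).
#' @param S Stride (samples).
#' @return Integer output length.
#' @examples
#' pool_output_length(601, 46, 3)  # 186
#' @export
pool_output_length <- function(W, F, S) {
  W <- check_count(W, "W"); F <- check_count(F, "F"); S <- check_count(S, "S")
  if (W < F) stop_shape("pooling input length %d is shorter than window %d", W, F)
  as.integer((W - F) %/% S + 1L)
}

#' Input window covered by the i-th convolution filter placement
#'
#' For a filter of length `h` moved with stride `k` over a length-`T`
#' sequence, the i-th placement (1-based) covers samples `l = k*i + 1 - k`
#' through `r = k*i - k + h`, inclusive.
#'
#' @param i 1-based placement index.
#' @param k Stride.
#' @param h Filter length.
#' @param T Input length.
#' @return Named integer vector `c(l = , r = )`.
#' @export
conv_window_bounds <- function(i, k, h, T) {
  i <- check_count(i, "i"); k <- check_count(k, "k")
  h <- check_count(h, "h"); T <- check_count(T, "T")
  n <- (T - h) %/% k + 1L
  if (i > n) stop_index("placement index %d out of range [1, %d]", i, n)
  l <- k * i + 1L - k
  r <- k * i - k + h
  c(l = as.integer(l), r = as.integer(r))
}

## ---- configuration objects -------------------------------------------------

#' Generator hyper-parameters
#'
#' Bundles the architecture of the bidirectional-LSTM generator: per-time-step
#' Gaussian noise of width `noise_dim` enters a stack of `n_bilstm_layers`
#' BiLSTM layers with `hidden_units` LSTM cells per direction; each layer's
#' two directional hidden states are combined through a tanh layer, and a
#' time-distributed affine head (after dropout) emits `output_dim` values per
#' step.  Output element 1 is the time-step channel, element 2 the lead
#' (amplitude) channel.
#'
#' @param noise_dim Width of the per-step noise vector (default 5).
#' @param seq_len Default sequence length; training uses 3120 samples, and
#'   generation may use any length since the weights are length-independent.
#' @param hidden_units LSTM cells per direction per layer (default 100).
#' @param n_bilstm_layers Number of BiLSTM layers (default 2).
#' @param dropout_p Dropout probability before the affine head (default 0.5).
#' @param output_dim Values emitted per time step (default 2).
#' @return A `generator_config` object.
#' @export
generator_config <- function(noise_dim = 5L, seq_len = 3120L, hidden_units = 100L,
                             n_bilstm_layers = 2L, dropout_p = 0.5, output_dim = 2L) {
  cfg <- list(
    noise_dim = check_count(noise_dim, "noise_dim"),
    seq_len = check_count(seq_len, "seq_len"),
    hidden_units = check_count(hidden_units, "hidden_units"),
    n_bilstm_layers = check_count(n_bilstm_layers, "n_bilstm_layers"),
    dropout_p = check_number(dropout_p, "dropout_p", min = 0, max = 1 - 1e-12),
    output_dim = check_count(output_dim, "output_dim")
  )
  structure(cfg, class = "generator_config")
}

#' Convolutional layer specification
#' @param n_filters Number of filters (feature maps).
#' @param filter_length Filter length in samples.
#' @param stride Stride in samples; must not exceed the filter length.
#' @param padding Zero padding per side (default 0).
#' @return A `conv_layer_spec` object.
#' @export
conv_layer_spec <- function(n_filters, filter_length, stride, padding = 0L) {
  n_filters <- check_count(n_filters, "n_filters")
  filter_length <- check_count(filter_length, "filter_length")
  stride <- check_count(stride, "stride")
  padding <- check_count(padding, "padding", min = 0L)
  if (stride > filter_length) {
    stop_validation("stride (%d) must not exceed filter length (%d)", stride, filter_length)
  }
  structure(list(type = "conv", n_filters = n_filters, filter_length = filter_length,
                 stride = stride, padding = padding),
            class = "conv_layer_spec")
}

#' Max-pooling layer specification
#' @param window Pooling window in samples.
#' @param stride Stride in samples.
#' @return A `pool_layer_spec` object.
#' @export
pool_layer_spec <- function(window, stride) {
  structure(list(type = "pool", window = check_count(window, "window"),
                 stride = check_count(stride, "stride")),
            class = "pool_layer_spec")
}

default_cnn_layers <- function() {
  list(conv_layer_spec(10L, 120L, 5L, 0L),
       pool_layer_spec(46L, 3L),
       conv_layer_spec(5L, 36L, 3L, 0L),
       pool_layer_spec(24L, 3L))
}

#' Discriminator specification
#'
#' Describes one of the four discriminator architectures.  The default CNN is
#' the published geometry for a 1 x 3120 x 1 input: conv(10 filters, length
#' 120, stride 5) -> maxpool(46, 3) -> conv(5, 36, 3) -> maxpool(24, 3) ->
#' fully connected 25 -> 2-way softmax, giving time-axis lengths
#' 601, 186, 51 and 10.  Shape consistency is checked at construction via
#' [conv_output_length()] and [pool_output_length()].
#'
#' @param kind One of `"cnn"`, `"mlp"`, `"lstm"`, `"gru"`.
#' @param input_length Length of the input sequence (default 3120).
#' @param layers For `kind = "cnn"`, an ordered list of [conv_layer_spec()] /
#'   [pool_layer_spec()] objects (default: the published geometry).
#' @param fc_units Width of the fully connected layer after the CNN stack
#'   (default 25).
#' @param hidden For `kind = "mlp"` the hidden widths (default `c(64, 16)`);
#'   for `"lstm"`/`"gru"` the recurrent width (default 32).
#' @param activation_slope Negative slope of the leaky-ReLU nonlinearity used
#'   after convolutions and the fully connected layer (default 0.2).
#' @return A `discriminator_spec` object with a `layer_lengths` element
#'   giving the computed time-axis length after each conv/pool layer.
#' @export
discriminator_spec <- function(kind = c("cnn", "mlp", "lstm", "gru"),
                               input_length = 3120L,
                               layers = NULL, fc_units = 25L,
                               hidden = NULL, activation_slope = 0.2) {
  kind <- match.arg(kind)
  input_length <- check_count(input_length, "input_length")
  spec <- list(kind = kind, input_length = input_length,
               activation_slope = check_number(activation_slope, "activation_slope", min = 0, max = 1))
  if (kind == "cnn") {
    layers <- layers %||% default_cnn_layers()
    len <- input_length
    channels <- 1L
    lens <- integer(0)
    chans <- integer(0)
    for (ly in layers) {
      if (inherits(ly, "conv_layer_spec")) {
        len <- conv_output_length(len, ly$filter_length, ly$stride, ly$padding)
        channels <- ly$n_filters
      } else if (inherits(ly, "pool_layer_spec")) {
        len <- pool_output_length(len, ly$window, ly$stride)
      } else {
        stop_validation("CNN layers must be conv_layer_spec or pool_layer_spec objects")
      }
      lens <- c(lens, len)
      chans <- c(chans, channels)
    }
    spec$layers <- layers
    spec$layer_lengths <- lens
    spec$layer_channels <- chans
    spec$flat_units <- len * channels
    spec$fc_units <- check_count(fc_units, "fc_units")
  } else if (kind == "mlp") {
    spec$hidden <- vapply(hidden %||% c(64L, 16L), check_count, integer(1), name = "hidden")
  } else {
    spec$hidden <- check_count(hidden %||% 32L, "hidden")
  }
  structure(spec, class = "discriminator_spec")
}

#' Proportionally scaled CNN discriminator geometry
#'
#' For desk-scale runs on sequences shorter than the published 3120-sample
#' input, returns a CNN spec whose filter and pooling windows shrink in
#' proportion to the input length (with small floors so every layer stays
#' well-formed), keeping the published two conv-pool pairs and a reduced
#' fully connected layer.  For `input_length = 3120` the published geometry
#' is returned unchanged.
#'
#' @param input_length Sequence length in samples.
#' @return A `discriminator_spec` of kind `"cnn"`.
#' @examples
#' discriminator_shapes(scaled_cnn_spec(312))
#' @export
scaled_cnn_spec <- function(input_length) {
  input_length <- check_count(input_length, "input_length")
  if (input_length == 3120L) return(discriminator_spec("cnn"))
  s <- input_length / 3120
  len <- input_length
  scaled <- function(full, floor_) min(max(floor_, as.integer(round(full * s))), len)
  h1 <- scaled(120, 4L); k1 <- min(5L, h1)
  len <- conv_output_length(len, h1, k1)
  a1 <- scaled(46, 2L); b1 <- min(3L, a1)
  len <- pool_output_length(len, a1, b1)
  h2 <- scaled(36, 2L); k2 <- min(3L, h2)
  len <- conv_output_length(len, h2, k2)
  a2 <- scaled(24, 2L); b2 <- min(2L, a2)
  layers <- list(conv_layer_spec(10L, h1, k1), pool_layer_spec(a1, b1),
                 conv_layer_spec(5L, h2, k2), pool_layer_spec(a2, b2))
  discriminator_spec("cnn", input_length = input_length, layers = layers,
                     fc_units = max(8L, as.integer(round(25 * s))))
}

#' Per-layer output shapes of a CNN discriminator
#'
#' @param spec A `discriminator_spec` of kind `"cnn"`.
#' @return A tibble with one row per layer: layer label, feature maps and
#'   time-axis output length, ending with the fully connected and softmax
#'   widths.
#' @export
discriminator_shapes <- function(spec) {
  stopifnot(inherits(spec, "discriminator_spec"))
  if (spec$kind != "cnn") stop_validation("layer shapes are defined for the CNN discriminator")
  n_cp <- length(spec$layers)
  lab <- character(n_cp)
  ci <- 0L; pi <- 0L
  for (j in seq_len(n_cp)) {
    if (spec$layers[[j]]$type == "conv") { ci <- ci + 1L; lab[j] <- paste0("C", ci) }
    else { pi <- pi + 1L; lab[j] <- paste0("P", pi) }
  }
  tibble::tibble(
    layer = c("input", lab, "FC", "softmax"),
    feature_maps = c(1L, spec$layer_channels, NA_integer_, NA_integer_),
    output_length = c(spec$input_length, spec$layer_lengths,
                      spec$fc_units, 2L)
  )
}

## ---- generator -------------------------------------------------------------

#' Build a BiLSTM generator
#'
#' Initialises all weights (Glorot-uniform, seeded) for the generator
#' described by `config`.  Each BiLSTM layer runs an LSTM forwards and an
#' independent LSTM backwards over the sequence and combines the two hidden
#' states per step through `tanh(h_fwd W_f + h_bwd W_b + b)`; initial hidden
#' and cell states are zero vectors.  The affine output head is shared across
#' time steps.
#'
#' @param config A [generator_config()].
#' @param seed Integer seed for weight initialisation.
#' @return An `ecg_generator` object.
#' @export
build_generator <- function(config = generator_config(), seed = 1L) {
  stopifnot(inherits(config, "generator_config"))
  seed <- check_count(seed, "seed", min = 0L)
  H <- config$hidden_units
  params <- with_seed(seed, {
    layers <- vector("list", config$n_bilstm_layers)
    d_in <- config$noise_dim
    for (l in seq_len(config$n_bilstm_layers)) {
      layers[[l]] <- list(
        fwd = nn_lstm_init(d_in, H),
        bwd = nn_lstm_init(d_in, H),
        Wf = nn_glorot(H, H),
        Wb = nn_glorot(H, H),
        bo = numeric(H)
      )
      d_in <- H
    }
    list(layers = layers, head = nn_dense_init(H, config$output_dim))
  })
  structure(list(config = config, params = params, seed = seed),
            class = "ecg_generator")
}

# Forward pass through one BiLSTM layer; xs is a list of B x D matrices.
bilstm_layer_forward <- function(xs, lp) {
  T_len <- length(xs)
  f <- nn_lstm_forward(xs, lp$fwd)
  b <- nn_lstm_forward(rev(xs), lp$bwd)
  hb <- rev(b$hs)                      # hb[[t]] is the backward state at time t
  ys <- vector("list", T_len)
  for (t in seq_len(T_len)) {
    ys[[t]] <- tanh(add_bias(f$hs[[t]] %*% lp$Wf + hb[[t]] %*% lp$Wb, lp$bo))
  }
  list(ys = ys, cache = list(f = f, b = b, hb = hb, ys = ys, xs = xs))
}

bilstm_layer_backward <- function(dys, cache, lp) {
  T_len <- length(dys)
  B <- nrow(dys[[1L]])
  H <- ncol(dys[[1L]])
  dWf <- lp$Wf * 0; dWb <- lp$Wb * 0; dbo <- lp$bo * 0
  dhf <- vector("list", T_len)
  dhb <- vector("list", T_len)
  for (t in seq_len(T_len)) {
    da <- dys[[t]] * (1 - cache$ys[[t]]^2)
    dWf <- dWf + crossprod(cache$f$hs[[t]], da)
    dWb <- dWb + crossprod(cache$hb[[t]], da)
    dbo <- dbo + colSums(da)
    dhf[[t]] <- da %*% t(lp$Wf)
    dhb[[t]] <- da %*% t(lp$Wb)
  }
  back_f <- nn_lstm_backward(dhf, cache$f$cache, lp$fwd)
  back_b <- nn_lstm_backward(rev(dhb), cache$b$cache, lp$bwd)
  dxs_b <- rev(back_b$dxs)
  dxs <- vector("list", T_len)
  for (t in seq_len(T_len)) dxs[[t]] <- back_f$dxs[[t]] + dxs_b[[t]]
  list(dxs = dxs,
       grads = list(fwd = back_f$grads, bwd = back_b$grads,
                    Wf = dWf, Wb = dWb, bo = dbo))
}

# Internal forward with cache.  Z: B x T x d array.  Dropout masks (training
# mode only) are drawn from the ambient RNG stream.
generator_forward_cache <- function(gen, Z, training = FALSE) {
  xs <- array_to_steps(Z)
  caches <- vector("list", length(gen$params$layers))
  for (l in seq_along(gen$params$layers)) {
    fw <- bilstm_layer_forward(xs, gen$params$layers[[l]])
    caches[[l]] <- fw$cache
    xs <- fw$ys
  }
  B <- nrow(xs[[1L]])
  T_len <- length(xs)
  H <- ncol(xs[[1L]])
  Hmat <- do.call(rbind, xs)           # (T*B) x H, time-major blocks
  mask <- NULL
  if (training && gen$config$dropout_p > 0) {
    mask <- nn_dropout_mask(dim(Hmat), gen$config$dropout_p)
    Hmat <- Hmat * mask
  }
  Ymat <- nn_dense_forward(Hmat, gen$params$head)
  out <- array(0, c(B, T_len, gen$config$output_dim))
  for (t in seq_len(T_len)) out[, t, ] <- Ymat[(t - 1L) * B + seq_len(B), , drop = FALSE]
  list(out = out,
       cache = list(layers = caches, Hmat = Hmat, mask = mask, B = B, T_len = T_len))
}

generator_backward <- function(gen, dOut, cache) {
  B <- cache$B; T_len <- cache$T_len
  dYmat <- matrix(0, B * T_len, gen$config$output_dim)
  for (t in seq_len(T_len)) dYmat[(t - 1L) * B + seq_len(B), ] <- matrix(dOut[, t, ], nrow = B)
  head_bk <- nn_dense_backward(dYmat, cache$Hmat, gen$params$head)
  dH <- head_bk$dX
  if (!is.null(cache$mask)) dH <- dH * cache$mask
  dys <- lapply(seq_len(T_len), function(t) dH[(t - 1L) * B + seq_len(B), , drop = FALSE])
  layer_grads <- vector("list", length(gen$params$layers))
  for (l in rev(seq_along(gen$params$layers))) {
    bk <- bilstm_layer_backward(dys, cache$layers[[l]], gen$params$layers[[l]])
    layer_grads[[l]] <- bk$grads
    dys <- bk$dxs
  }
  list(layers = layer_grads, head = head_bk$grads)
}

#' Run the generator forward
#'
#' @param gen An `ecg_generator`.
#' @param noise A `B x T x noise_dim` array (or `T x noise_dim` matrix for a
#'   single sequence), e.g. from [sample_noise()].
#' @param training If `TRUE`, dropout is active (stochastic); default `FALSE`
#'   (deterministic evaluation mode).
#' @return A `B x T x output_dim` array; `[ , , 1]` is the time-step channel,
#'   `[ , , 2]` the lead channel.
#' @export
generator_forward <- function(gen, noise, training = FALSE) {
  stopifnot(inherits(gen, "ecg_generator"))
  if (is.matrix(noise)) noise <- array(noise, c(1L, nrow(noise), ncol(noise)))
  if (length(dim(noise)) != 3L || dim(noise)[3L] != gen$config$noise_dim) {
    stop_shape("noise must be a B x T x %d array", gen$config$noise_dim)
  }
  generator_forward_cache(gen, noise, training = training)$out
}

#' Number of trainable parameters
#' @param model An `ecg_generator`, `ecg_discriminator` or `ecg_autoencoder`.
#' @return Integer count of scalar parameters.
#' @export
count_parameters <- function(model) {
  as.integer(tree_count(model$params))
}

## ---- discriminators --------------------------------------------------------

#' Build a discriminator
#'
#' Initialises weights (seeded) for the architecture in `spec`.  The CNN
#' discriminator computes, per filter placement, `c_i = f(w . x_{l:r} + b)`
#' with a leaky-ReLU `f`, max pooling `p_j = max` over each pooling window,
#' a fully connected layer, and a 2-class softmax whose first component is
#' the probability that the input is real.
#'
#' @param spec A [discriminator_spec()].
#' @param seed Integer seed for weight initialisation.
#' @return An `ecg_discriminator` object.
#' @export
build_discriminator <- function(spec = discriminator_spec(), seed = 1L) {
  stopifnot(inherits(spec, "discriminator_spec"))
  seed <- check_count(seed, "seed", min = 0L)
  params <- with_seed(seed, {
    if (spec$kind == "cnn") {
      convs <- list()
      c_in <- 1L
      for (ly in spec$layers) {
        if (ly$type == "conv") {
          convs[[length(convs) + 1L]] <- nn_conv1d_init(c_in, ly$filter_length, ly$n_filters)
          c_in <- ly$n_filters
        }
      }
      list(convs = convs,
           fc = nn_dense_init(spec$flat_units, spec$fc_units),
           out = nn_dense_init(spec$fc_units, 2L))
    } else if (spec$kind == "mlp") {
      widths <- c(spec$input_length, spec$hidden, 2L)
      dense <- lapply(seq_len(length(widths) - 1L),
                      function(i) nn_dense_init(widths[i], widths[i + 1L]))
      list(dense = dense)
    } else {
      list(cell = nn_cell(spec$kind)$init(1L, spec$hidden),
           out = nn_dense_init(spec$hidden, 2L))
    }
  })
  structure(list(spec = spec, params = params, seed = seed),
            class = "ecg_discriminator")
}

disc_forward_cache <- function(disc, X) {
  spec <- disc$spec
  p <- disc$params
  B <- nrow(X)
  slope <- spec$activation_slope
  if (spec$kind == "cnn") {
    A <- array(X, c(B, 1L, ncol(X)))
    stage <- list()
    ci <- 0L
    for (j in seq_along(spec$layers)) {
      ly <- spec$layers[[j]]
      if (ly$type == "conv") {
        ci <- ci + 1L
        fw <- nn_conv1d_forward(A, p$convs[[ci]], ly$stride, ly$padding)
        pre <- fw$out
        A <- nn_leaky_relu(pre, slope)
        stage[[j]] <- list(type = "conv", cache = fw$cache, pre = pre, ci = ci)
      } else {
        fw <- nn_maxpool_forward(A, ly$window, ly$stride)
        A <- fw$out
        stage[[j]] <- list(type = "pool", cache = fw$cache)
      }
    }
    flat <- matrix(A, nrow = B)          # column-major: channel fastest
    fc_pre <- nn_dense_forward(flat, p$fc)
    fc_act <- nn_leaky_relu(fc_pre, slope)
    logits <- nn_dense_forward(fc_act, p$out)
    probs <- nn_softmax(logits)
    list(probs = probs, logits = logits,
         cache = list(kind = "cnn", stage = stage, flat = flat,
                      fc_pre = fc_pre, fc_act = fc_act, dimA = dim(A), B = B))
  } else if (spec$kind == "mlp") {
    acts <- list(X)
    pres <- list()
    A <- X
    n <- length(p$dense)
    for (i in seq_len(n)) {
      pre <- nn_dense_forward(A, p$dense[[i]])
      pres[[i]] <- pre
      A <- if (i < n) nn_leaky_relu(pre, slope) else pre
      acts[[i + 1L]] <- A
    }
    probs <- nn_softmax(A)
    list(probs = probs, logits = A,
         cache = list(kind = "mlp", acts = acts, pres = pres))
  } else {
    xs <- matrix_to_steps(X)
    cell <- nn_cell(spec$kind)
    fw <- cell$forward(xs, p$cell)
    h_last <- fw$hs[[length(fw$hs)]]
    logits <- nn_dense_forward(h_last, p$out)
    probs <- nn_softmax(logits)
    list(probs = probs, logits = logits,
         cache = list(kind = spec$kind, rnn = fw, h_last = h_last, T_len = ncol(X)))
  }
}

# dLogits: B x 2 gradient on the logits.  Returns parameter grads and the
# gradient on the input sequences (B x T), needed for generator updates.
disc_backward <- function(disc, dLogits, cache) {
  spec <- disc$spec
  p <- disc$params
  slope <- spec$activation_slope
  if (cache$kind == "cnn") {
    out_bk <- nn_dense_backward(dLogits, cache$fc_act, p$out)
    d_fc_act <- nn_leaky_relu_grad(out_bk$dX, cache$fc_pre, slope)
    fc_bk <- nn_dense_backward(d_fc_act, cache$flat, p$fc)
    dA <- array(fc_bk$dX, cache$dimA)
    conv_grads <- vector("list", length(p$convs))
    for (j in rev(seq_along(spec$layers))) {
      st <- cache$stage[[j]]
      if (st$type == "pool") {
        dA <- nn_maxpool_backward(dA, st$cache)$dX
      } else {
        dPre <- nn_leaky_relu_grad(dA, st$pre, slope)
        bk <- nn_conv1d_backward(dPre, st$cache, p$convs[[st$ci]])
        conv_grads[[st$ci]] <- bk$grads
        dA <- bk$dX
      }
    }
    dX <- matrix(dA, nrow = cache$B)     # back to B x T (single channel)
    list(grads = list(convs = conv_grads, fc = fc_bk$grads, out = out_bk$grads),
         dX = dX)
  } else if (cache$kind == "mlp") {
    n <- length(p$dense)
    dA <- dLogits
    grads <- vector("list", n)
    for (i in rev(seq_len(n))) {
      if (i < n) dA <- nn_leaky_relu_grad(dA, cache$pres[[i]], slope)
      bk <- nn_dense_backward(dA, cache$acts[[i]], p$dense[[i]])
      grads[[i]] <- bk$grads
      dA <- bk$dX
    }
    list(grads = list(dense = grads), dX = dA)
  } else {
    out_bk <- nn_dense_backward(dLogits, cache$h_last, p$out)
    cell <- nn_cell(cache$kind)
    dhs <- vector("list", cache$T_len)
    dhs[[cache$T_len]] <- out_bk$dX
    cell_bk <- cell$backward(dhs, cache$rnn$cache, p$cell)
    dX <- do.call(cbind, lapply(cell_bk$dxs, function(m) m[, 1L]))
    if (is.null(dim(dX))) dX <- matrix(dX, nrow = 1L)
    list(grads = list(cell = cell_bk$grads, out = out_bk$grads), dX = dX)
  }
}

#' Discriminator forward pass
#'
#' @param disc An `ecg_discriminator`.
#' @param x A batch of sequences: `B x input_length` matrix or a single
#'   numeric vector.
#' @param decision If `TRUE`, additionally return the hard real/fake call
#'   (argmax of the softmax pair).
#' @return A tibble with one row per sequence: `p_real` (softmax component
#'   for the "real" class, in (0,1)) and, if requested, `is_real`.
#' @export
discriminator_forward <- function(disc, x, decision = FALSE) {
  stopifnot(inherits(disc, "ecg_discriminator"))
  if (is.numeric(x) && is.null(dim(x))) x <- matrix(x, nrow = 1L)
  x <- as_window_matrix(x)
  if (ncol(x) != disc$spec$input_length) {
    stop_shape("input length %d does not match discriminator input_length %d",
               ncol(x), disc$spec$input_length)
  }
  fw <- disc_forward_cache(disc, x)
  out <- tibble::tibble(p_real = fw$probs[, 1L])
  if (decision) out$is_real <- fw$probs[, 1L] >= fw$probs[, 2L]
  out
}

#' @export
print.ecg_generator <- function(x, ...) {
  cat(sprintf("BiLSTM generator: %d layer(s) x %d units/direction, noise dim %d, output dim %d, %d parameters\n",
              x$config$n_bilstm_layers, x$config$hidden_units,
              x$config$noise_dim, x$config$output_dim, count_parameters(x)))
  invisible(x)
}

#' @export
print.ecg_discriminator <- function(x, ...) {
  cat(sprintf("%s discriminator, input length %d, %d parameters\n",
              toupper(x$spec$kind), x$spec$input_length, count_parameters(x)))
  if (x$spec$kind == "cnn") {
    cat("  time-axis lengths:", paste(x$spec$layer_lengths, collapse = " -> "), "\n")
  }
  invisible(x)
}
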