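test_that("shape formulas reproduce the published discriminator geometry", {
  expect_identical(conv_output_length(3120, 120, 5, 0), 601L)
  expect_identical(pool_output_length(601, 46, 3), 186L)
  expect_identical(conv_output_length(186, 36, 3, 0), 51L)
  expect_identical(pool_output_length(51, 24, 3), 10L)
  expect_identical(conv_output_length(7, 7, 1, 0), 1L)   # filter spans input
  expect_identical(pool_output_length(9, 9, 4), 1L)
  expect_error(conv_output_length(10, 20, 1, 0), class = "ecggan_error_shape")
  expect_error(pool_output_length(5, 6, 1), class = "ecggan_error_shape")
  # padding enters as W + 2P
  expect_identical(conv_output_length(10, 12, 1, 1), 1L)
})

test_that("shape formulas agree with sliding-window enumeration on a grid", {
  for (W in seq(1L, 60L, by = 3L)) for (F in seq_len(W)) for (S in 1:6) {
    expect_identical(pool_output_length(W, F, S), enumerate_pool_positions(W, F, S))
    for (P in 0:2) {
      expect_identical(conv_output_length(W, F, S, P),
                       enumerate_conv_positions(W, F, S, P))
    }
  }
})

test_that("conv_window_bounds tiles the input with stride-spaced windows", {
  expect_equal(conv_window_bounds(1, 5, 120, 3120), c(l = 1L, r = 120L))
  expect_equal(conv_window_bounds(2, 5, 120, 3120), c(l = 6L, r = 125L))
  expect_equal(conv_window_bounds(601, 5, 120, 3120), c(l = 3001L, r = 3120L))
  expect_error(conv_window_bounds(602, 5, 120, 3120), class = "ecggan_error_index")
  # every window has width h; consecutive windows start k apart; when
  # (T - h) %% k == 0 the final window ends exactly at T
  for (case in list(c(k = 3, h = 7, T = 25), c(k = 2, h = 4, T = 20))) {
    n <- (case["T"] - case["h"]) %/% case["k"] + 1
    prev_l <- NULL
    for (i in seq_len(n)) {
      b <- conv_window_bounds(i, case["k"], case["h"], case["T"])
      expect_equal(b["r"] - b["l"] + 1L, case["h"], ignore_attr = TRUE)
      if (!is.null(prev_l)) expect_equal(b["l"] - prev_l, case["k"], ignore_attr = TRUE)
      prev_l <- b["l"]
    }
    expect_equal(conv_window_bounds(n, case["k"], case["h"], case["T"])["r"],
                 case["T"], ignore_attr = TRUE)
  }
})

test_that("the published CNN spec builds with the Table-1 layer shapes", {
  spec <- discriminator_spec("cnn")
  expect_equal(spec$layer_lengths, c(601L, 186L, 51L, 10L))
  expect_equal(spec$layer_channels, c(10L, 10L, 5L, 5L))
  expect_equal(spec$flat_units, 50L)
  expect_equal(spec$fc_units, 25L)
  shapes <- discriminator_shapes(spec)
  expect_equal(shapes$output_length, c(3120L, 601L, 186L, 51L, 10L, 25L, 2L))
  # shape-inconsistent specs fail at construction
  expect_error(discriminator_spec("cnn", input_length = 100),
               class = "ecggan_error_shape")
})

test_that("scaled CNN geometry stays well-formed across lengths", {
  for (L in c(64L, 200L, 312L, 1000L, 3120L)) {
    spec <- scaled_cnn_spec(L)
    expect_s3_class(spec, "discriminator_spec")
    expect_true(all(spec$layer_lengths >= 1L))
  }
  expect_equal(scaled_cnn_spec(3120L)$layer_lengths, c(601L, 186L, 51L, 10L))
})

test_that("generator emits (batch, T, 2) for every valid batch and length", {
  cfg <- generator_config(noise_dim = 3L, hidden_units = 5L, dropout_p = 0.5)
  gen <- build_generator(cfg, seed = 2L)
  for (dims in list(c(1L, 8L), c(3L, 20L), c(2L, 400L))) {
    Z <- sample_noise(dims[1], dims[2], 3L, seed = 7L)
    Y <- generator_forward(gen, Z)
    expect_equal(dim(Y), c(dims, 2L))
    expect_true(all(is.finite(Y)))
  }
  # evaluation mode is deterministic even though dropout_p > 0
  Z <- sample_noise(2L, 30L, 3L, seed = 1L)
  expect_identical(generator_forward(gen, Z), generator_forward(gen, Z))
  expect_error(generator_forward(gen, sample_noise(1L, 5L, 4L, seed = 1L)),
               class = "ecggan_error_shape")
})

test_that("generator parameter count matches the closed-form expression", {
  d <- 5L; H <- 7L; odim <- 2L
  gen <- build_generator(generator_config(noise_dim = d, hidden_units = H,
                                          output_dim = odim), seed = 1L)
  # per direction: LSTM with 4H(d_in + H + 1) weights; per layer: two
  # directions plus the tanh combination (2 H^2 + H); head: H*odim + odim
  lstm_n <- function(d_in) 4 * H * (d_in + H + 1)
  expected <- (2 * lstm_n(d) + 2 * H^2 + H) +       # layer 1 (input d)
    (2 * lstm_n(H) + 2 * H^2 + H) +                 # layer 2 (input H)
    (H * odim + odim)
  expect_identical(count_parameters(gen), as.integer(expected))
})

test_that("convolution values equal hand-computed windowed dot products", {
  # one filter of length 3, stride 2, constant weights, known bias
  p <- list(W = matrix(c(1, 2, 3), ncol = 1), b = 0.5)
  x <- c(1, 0, -1, 2, 4, 1, 0, 3, -2, 5)
  X <- array(x, c(1, 1, 10))
  out <- ecggan:::nn_conv1d_forward(X, p, stride = 2L)$out
  hand <- vapply(seq(1, 7, by = 2),
                 function(l) sum(x[l:(l + 2)] * c(1, 2, 3)) + 0.5, numeric(1))
  expect_equal(as.numeric(out[1, 1, ]), hand)
  expect_equal(dim(out)[3], conv_output_length(10, 3, 2, 0))
})

test_that("softmax output is a proper two-class distribution", {
  P <- ecggan:::nn_softmax(matrix(c(3, 3, -1, 2, 100, 100), ncol = 2, byrow = TRUE))
  expect_equal(rowSums(P), rep(1, 3))
  expect_true(all(P > 0 & P < 1))
  expect_equal(P[1, ], c(0.5, 0.5))      # equal logits
  expect_equal(P[3, ], c(0.5, 0.5))      # stable at large magnitude
})

test_that("discriminator outputs are probabilities and respect batch order", {
  set.seed(8)
  X <- matrix(rnorm(4 * 64), 4)
  for (kind in c("cnn", "mlp", "lstm", "gru")) {
    spec <- if (kind == "cnn") scaled_cnn_spec(64L)
            else discriminator_spec(kind, input_length = 64L,
                                    hidden = if (kind == "mlp") c(10L, 6L) else 6L)
    disc <- build_discriminator(spec, seed = 3L)
    out <- discriminator_forward(disc, X)
    expect_equal(nrow(out), 4L)
    expect_true(all(out$p_real > 0 & out$p_real < 1))
    # permuting inputs permutes outputs
    perm <- c(3L, 1L, 4L, 2L)
    expect_equal(discriminator_forward(disc, X[perm, ])$p_real, out$p_real[perm])
    # hard decision is the softmax argmax
    dec <- discriminator_forward(disc, X, decision = TRUE)
    expect_equal(dec$is_real, dec$p_real >= 0.5)
  }
  disc <- build_discriminator(scaled_cnn_spec(64L), seed = 3L)
  expect_error(discriminator_forward(disc, matrix(rnorm(65), 1)),
               class = "ecggan_error_shape")
})

test_that("analytic gradients match finite differences on tiny networks", {
  set.seed(42)
  # LSTM layer
  xs <- lapply(1:3, function(t) matrix(rnorm(4), 2))
  p <- ecggan:::nn_lstm_init(2L, 2L)
  tgt <- lapply(1:3, function(t) matrix(rnorm(4), 2))
  lstm_loss <- function(pp) {
    fw <- ecggan:::nn_lstm_forward(xs, pp)
    sum(vapply(1:3, function(t) sum((fw$hs[[t]] - tgt[[t]])^2), numeric(1)))
  }
  fw <- ecggan:::nn_lstm_forward(xs, p)
  bk <- ecggan:::nn_lstm_backward(lapply(1:3, function(t) 2 * (fw$hs[[t]] - tgt[[t]])),
                                  fw$cache, p)
  expect_lt(max_grad_error(lstm_loss, p, bk$grads), 1e-6)

  # generator end-to-end (dropout off)
  cfg <- generator_config(noise_dim = 2L, seq_len = 4L, hidden_units = 2L,
                          dropout_p = 0)
  gen <- build_generator(cfg, seed = 5L)
  Z <- sample_noise(2L, 4L, 2L, seed = 9L)
  tgt <- array(rnorm(16), c(2, 4, 2))
  gen_loss <- function(pp) {
    g2 <- gen; g2$params <- pp
    sum((ecggan:::generator_forward_cache(g2, Z)$out - tgt)^2)
  }
  gfw <- ecggan:::generator_forward_cache(gen, Z)
  grads <- ecggan:::generator_backward(gen, 2 * (gfw$out - tgt), gfw$cache)
  expect_lt(max_grad_error(gen_loss, gen$params, grads), 1e-6)

  # CNN discriminator end-to-end, parameters and input
  spec <- discriminator_spec("cnn", input_length = 20L,
                             layers = list(conv_layer_spec(3L, 5L, 2L),
                                           pool_layer_spec(3L, 2L),
                                           conv_layer_spec(2L, 2L, 1L),
                                           pool_layer_spec(2L, 1L)),
                             fc_units = 4L)
  disc <- build_discriminator(spec, seed = 3L)
  Xb <- matrix(rnorm(3 * 20), 3)
  lbl <- c(1L, 2L, 1L)
  disc_loss <- function(pp) {
    d2 <- disc; d2$params <- pp
    fwd <- ecggan:::disc_forward_cache(d2, Xb)
    -mean(log(fwd$probs[cbind(1:3, lbl)]))
  }
  dfw <- ecggan:::disc_forward_cache(disc, Xb)
  dbk <- ecggan:::disc_backward(disc, ecggan:::ce_logit_grad(dfw$probs, lbl), dfw$cache)
  expect_lt(max_grad_error(disc_loss, disc$params, dbk$grads), 1e-6)
  input_loss <- function(xx) {
    fwd <- ecggan:::disc_forward_cache(disc, xx$X)
    -mean(log(fwd$probs[cbind(1:3, lbl)]))
  }
  expect_lt(max_grad_error(input_loss, list(X = Xb), list(X = dbk$dX)), 1e-6)
})
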