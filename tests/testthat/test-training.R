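test_that("adversarial losses match direct scalar arithmetic", {
  # equilibrium: D == 0.5 everywhere gives d_loss = 2 log 2 exactly
  expect_equal(gan_losses(0.5, 0.5)$d_loss, 2 * log(2))
  expect_equal(gan_losses(0.5, 0.5)$g_loss, log(0.5))
  expect_equal(gan_losses(0.5, 0.5, g_mode = "non-saturating")$g_loss, -log(0.5))
  # perfect-discriminator limit: loss tends to 0
  expect_lt(gan_losses(1 - 1e-9, 1e-9)$d_loss, 1e-6)
  # independent scalar oracle on random batches
  set.seed(3)
  for (i in 1:10) {
    n <- sample(1:20, 1)
    dr <- runif(n, 0.01, 0.99); df <- runif(n, 0.01, 0.99)
    oracle_d <- -sum(log(dr) + log(1 - df)) / n
    oracle_g <- sum(log(1 - df)) / n
    got <- gan_losses(dr, df)
    expect_equal(got$d_loss, oracle_d, tolerance = 1e-12)
    expect_equal(got$g_loss, oracle_g, tolerance = 1e-12)
    expect_equal(gan_losses(dr, df, g_mode = "non-saturating")$g_loss,
                 -sum(log(df)) / n, tolerance = 1e-12)
  }
})

test_that("degenerate probabilities are clamped with a warning", {
  expect_warning(out <- gan_losses(c(1, 0.5), c(0, 0.5)), "clamped")
  expect_true(all(is.finite(unlist(out))))
  expect_error(gan_losses(0.5, 1.5), class = "ecggan_error_domain")
  expect_error(gan_losses(c(0.5, 0.5), 0.5), class = "ecggan_error_shape")
})

test_that("noise sampling is shaped, seeded and standard normal", {
  Z <- sample_noise(2L, 400L, 5L, seed = 7L)
  expect_equal(dim(Z), c(2L, 400L, 5L))
  expect_identical(Z, sample_noise(2L, 400L, 5L, seed = 7L))
  expect_equal(dim(sample_noise(1L, 3120L, 5L, seed = 1L)), c(1L, 3120L, 5L))
  big <- sample_noise(10L, 1000L, 100L, seed = 2L)   # 1e6 draws
  expect_lt(abs(mean(big)), 0.003)                   # CLT bound 3/sqrt(n)
  expect_equal(sd(big), 1, tolerance = 0.01)
})

test_that("GAN training completes, logs per-epoch losses and is reproducible", {
  w <- tiny_windows(n = 10L, len = 64L)
  gc <- generator_config(noise_dim = 3L, seq_len = 64L, hidden_units = 4L)
  tc <- gan_train_config(epochs = 3L, batch_size = 5L, learning_rate = 1e-3,
                         seq_len = 64L, seed = 4L)
  gan <- train_gan(w, gc, scaled_cnn_spec(64L), tc)
  expect_s3_class(gan, "ecg_gan")
  expect_equal(nrow(gan$history), 3L)
  expect_true(all(is.finite(gan$history$d_loss)))
  expect_true(all(is.finite(gan$history$g_loss)))
  gan2 <- train_gan(w, gc, scaled_cnn_spec(64L), tc)
  expect_identical(gan$history, gan2$history)
  # mismatched lengths are rejected up front
  expect_error(train_gan(w, gc, scaled_cnn_spec(128L), tc),
               class = "ecggan_error_validation")
  expect_error(train_gan(w[0, ], gc, scaled_cnn_spec(64L), tc),
               class = "ecggan_error_validation")
})

test_that("GAN training works with each discriminator variant", {
  w <- tiny_windows(n = 6L, len = 32L)
  gc <- generator_config(noise_dim = 2L, seq_len = 32L, hidden_units = 3L)
  tc <- gan_train_config(epochs = 2L, batch_size = 3L, learning_rate = 1e-3,
                         seq_len = 32L, seed = 6L)
  for (kind in c("mlp", "lstm", "gru")) {
    spec <- discriminator_spec(kind, input_length = 32L,
                               hidden = if (kind == "mlp") c(8L, 4L) else 4L)
    gan <- train_gan(w, gc, spec, tc)
    expect_equal(nrow(gan$history), 2L)
    expect_true(all(is.finite(unlist(gan$history[, c("d_loss", "g_loss")]))))
  }
})

test_that("a briefly trained discriminator separates real from untrained output", {
  # discriminator-dominant schedule: 25 D updates per G update keeps the
  # generator essentially at its untrained initialization while D learns
  w <- tiny_windows(n = 2L, len = 64L, seed = 2L)
  gc <- generator_config(noise_dim = 3L, seq_len = 64L, hidden_units = 4L)
  tc <- gan_train_config(epochs = 8L, batch_size = 2L, learning_rate = 3e-3,
                         seq_len = 64L, seed = 4L, d_steps_per_g_step = 25L)
  gan <- train_gan(w, gc, scaled_cnn_spec(64L), tc)
  fresh <- build_generator(gc, seed = 4L)             # the untrained initialization
  fake <- generate_ecgs(fresh, n = 10L, length = 64L, seed = 7L)
  p_real <- discriminator_forward(gan$discriminator, w)$p_real
  p_fake <- discriminator_forward(gan$discriminator, fake)$p_real
  acc <- (sum(p_real > 0.5) + sum(p_fake <= 0.5)) / (length(p_real) + length(p_fake))
  expect_gt(acc, 0.9)
})

test_that("generation honours the published settings and the seed", {
  gen <- build_generator(generator_config(noise_dim = 5L, hidden_units = 6L),
                         seed = 3L)
  out <- generate_ecgs(gen, n = 4L, length = 400L, seed = 1L)
  expect_equal(nrow(out), 4L)
  expect_true(all(lengths(out$values) == 400L))
  # length 250 (the reported optimum) works off the same weights
  out250 <- generate_ecgs(gen, n = 1L, length = 250L, seed = 1L)
  expect_equal(lengths(out250$values), 250L)
  expect_identical(generate_ecgs(gen, 2L, 100L, seed = 9L),
                   generate_ecgs(gen, 2L, 100L, seed = 9L))
})

test_that("training configuration defaults mirror the published protocol", {
  tc <- gan_train_config()
  expect_equal(tc$epochs, 500L)
  expect_equal(tc$batch_size, 100L)
  expect_equal(tc$learning_rate, 1e-5)
  expect_equal(tc$seq_len, 3120L)
  expect_equal(tc$g_loss_mode, "saturating")
  expect_error(gan_train_config(learning_rate = 0), class = "ecggan_error_validation")
})
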