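test_that("reparameterization reproduces the Gaussian it claims", {
  expect_equal(reparameterize(c(1, 2, 3), c(0, 0, 0)), c(1, 2, 3))
  eps <- c(0.3, -1.2)
  expect_equal(reparameterize(c(0, 0), c(1, 1), epsilon = eps), eps)
  expect_identical(reparameterize(c(0, 1), c(1, 2), seed = 5L),
                   reparameterize(c(0, 1), c(1, 2), seed = 5L))
  # Monte-Carlo: mean of draws matches mu within 3 sigma / sqrt(n)
  n <- 100000L
  draws <- matrix(reparameterize(rep(c(1, 2), each = n), rep(0.5, 2L * n),
                                 seed = 8L), ncol = 2L)
  expect_lt(abs(mean(draws[, 1]) - 1), 3 * 0.5 / sqrt(n))
  expect_lt(abs(mean(draws[, 2]) - 2), 3 * 0.5 / sqrt(n))
  expect_error(reparameterize(c(0, 0), c(1, -1)), class = "ecggan_error_domain")
  expect_error(reparameterize(c(0, 0), c(1, 1, 1)), class = "ecggan_error_shape")
})

test_that("reconstruction loss equals elementwise mean squared error", {
  x <- matrix(rnorm(12), 3)
  expect_equal(ae_loss(x, x), 0)
  expect_equal(ae_loss(matrix(0, 2, 5), matrix(1, 2, 5)), 1)
  set.seed(2)
  a <- matrix(rnorm(10), 2); b <- matrix(rnorm(10), 2)
  brute <- sum((as.numeric(a) - as.numeric(b))^2) / 10   # independent arithmetic
  expect_equal(ae_loss(a, b), brute)
  expect_error(ae_loss(matrix(0, 2, 3), matrix(0, 2, 4)),
               class = "ecggan_error_shape")
})

test_that("VAE loss carries the closed-form Gaussian KL term", {
  x <- c(1, 2, 3)
  expect_equal(vae_loss(x, x, mu = 0, sigma = 1), 0)      # both terms vanish
  expect_equal(vae_loss(x, x, mu = 1, sigma = 1), 0.5)    # KL = mu^2 / 2
  expect_equal(vae_loss(x, x, mu = 0, sigma = 2),
               0.5 * (4 - 1 - 2 * log(2)))
  expect_error(vae_loss(x, x, mu = 0, sigma = 0), class = "ecggan_error_domain")
  # KL >= 0 with equality iff mu = 0, sigma = 1
  set.seed(6)
  for (i in 1:20) {
    mu <- rnorm(4); sigma <- exp(rnorm(4) / 2)
    kl <- vae_loss(x, x, mu, sigma)
    expect_gte(kl, 0)
    if (kl < 1e-12) {
      expect_equal(mu, rep(0, 4)); expect_equal(sigma, rep(1, 4))
    }
  }
  expect_equal(vae_loss(x, x, rep(0, 4), rep(1, 4)), 0)
})

test_that("autoencoder training records finite losses and is reproducible", {
  w <- tiny_windows(n = 8L, len = 30L)
  cfg <- ae_config("rnn", hidden_units = 6L, latent_dim = 4L, seq_len = 30L)
  m1 <- train_autoencoder(w, cfg, epochs = 5L, batch_size = 4L,
                          learning_rate = 1e-3, seed = 2L)
  expect_equal(nrow(m1$history), 5L)
  expect_true(all(is.finite(m1$history$loss)))
  m2 <- train_autoencoder(w, cfg, epochs = 5L, batch_size = 4L,
                          learning_rate = 1e-3, seed = 2L)
  expect_identical(m1$history, m2$history)
  expect_error(train_autoencoder(matrix(nrow = 0, ncol = 30), cfg),
               class = "ecggan_error_validation")
})

test_that("training drives the loss to zero on a constant dataset", {
  X <- matrix(0.5, 4, 20)
  m <- train_autoencoder(X, ae_config("rnn", hidden_units = 8L, latent_dim = 4L,
                                      seq_len = 20L),
                         epochs = 200L, batch_size = 4L, learning_rate = 1e-2,
                         seed = 3L)
  expect_lt(tail(m$history$loss, 1), 1e-3)
})

test_that("an over-parameterized AE memorizes a two-example dataset", {
  # latent_dim == seq_len: ample capacity; threshold 1e-3 on final MSE
  set.seed(5)
  X <- matrix(rnorm(2 * 16), 2, 16)
  m <- train_autoencoder(X, ae_config("rnn", hidden_units = 24L, latent_dim = 16L,
                                      seq_len = 16L),
                         epochs = 400L, batch_size = 2L, learning_rate = 1e-2,
                         seed = 5L)
  expect_lt(tail(m$history$loss, 1), 1e-3)
  # teacher-forced reconstruction matches the training windows closely
  rec <- ae_reconstruct(m, X)
  expect_lt(ae_loss(X, rec), 1e-3)
})

test_that("LSTM and variational variants train and decode free-running", {
  w <- tiny_windows(n = 6L, len = 20L)
  for (cell in c("rnn", "lstm")) {
    cfg <- ae_config(cell, hidden_units = 5L, latent_dim = 3L, seq_len = 20L,
                     variational = TRUE)
    m <- train_autoencoder(w, cfg, epochs = 3L, batch_size = 3L,
                           learning_rate = 1e-3, seed = 4L)
    expect_equal(nrow(m$history), 3L)
    expect_true(all(is.finite(m$history$loss)))
    fr <- ae_reconstruct(m, w, free_running = TRUE, seed = 1L)
    expect_equal(dim(fr), c(6L, 20L))
    expect_true(all(is.finite(fr)))
  }
})

test_that("batch loss is invariant under a joint permutation of both batches", {
  set.seed(9)
  a <- matrix(rnorm(40), 8); b <- matrix(rnorm(40), 8)
  perm <- sample(8)
  expect_equal(ae_loss(a, b), ae_loss(a[perm, ], b[perm, ]))
})
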