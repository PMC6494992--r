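#' Adversarial (minimax) batch losses
#'
#' From discriminator outputs on a real batch and a generated batch, returns
#' the empirical two-player losses: the discriminator maximizes
#' `1/N sum(log D(x_i) + log(1 - D(G(z_i))))`, so its loss is the negation
#' of that mean; the generator is trained to minimize `log(1 - D(G(z)))`
#' (`g_mode = "saturating"`, the published scheme), with the standard
#' non-saturating alternative `-1/N sum(log D(G(z_i)))` available.
#'
#' Probabilities at exactly 0 or 1 are clamped to `[eps, 1 - eps]` with a
#' warning, so the logs stay finite.
#'
#' @param d_real Discriminator probabilities on real sequences, in (0,1).
#' @param d_fake Discriminator probabilities on generated sequences; same
#'   length as `d_real`.
#' @param g_mode `"saturating"` (default) or `"non-saturating"`.
#' @param eps Clamping epsilon (default 1e-7).
#' @return List with `d_loss` and `g_loss`.
#' @examples
#' gan_losses(0.5, 0.5)$d_loss  # 2 log 2
#' @export
gan_losses <- function(d_real, d_fake, g_mode = c("saturating", "non-saturating"),
                       eps = 1e-7) {
  g_mode <- match.arg(g_mode)
  if (length(d_real) != length(d_fake)) {
    stop_shape("d_real (%d) and d_fake (%d) batch sizes differ",
               length(d_real), length(d_fake))
  }
  if (length(d_real) == 0L) stop_validation("batches must be non-empty")
  if (any(d_real < 0 | d_real > 1 | d_fake < 0 | d_fake > 1)) {
    stop_domain("discriminator outputs must lie in [0, 1]")
  }
  if (any(d_real <= 0 | d_real >= 1 | d_fake <= 0 | d_fake >= 1)) {
    warn(sprintf("probabilities at 0 or 1 clamped to [%g, %g]", eps, 1 - eps))
  }
  dr <- pmin(pmax(d_real, eps), 1 - eps)
  df <- pmin(pmax(d_fake, eps), 1 - eps)
  d_loss <- -mean(log(dr) + log(1 - df))
  g_loss <- if (g_mode == "saturating") mean(log(1 - df)) else -mean(log(df))
  list(d_loss = d_loss, g_loss = g_loss)
}

#' Sample a Gaussian noise batch
#'
#' Standard-normal noise of shape `n x T x d`, the generator's input: one
#' `d`-dimensional noise vector per time step.
#'
#' @param n Batch size.
#' @param T Sequence length.
#' @param d Noise width per step (default 5).
#' @param seed Optional seed; a given seed always yields the same array.
#' @return Numeric array `n x T x d`.
#' @export
sample_noise <- function(n, T, d = 5L, seed = NULL) {
  n <- check_count(n, "n"); T <- check_count(T, "T"); d <- check_count(d, "d")
  with_seed(seed, array(rnorm(n * T * d), c(n, T, d)))
}

#' GAN training configuration
#'
#' Defaults follow the published protocol: 500 epochs, mini-batch 100,
#' learning rate 1e-5, sequence length 3120, strict alternation of one
#' discriminator update and one generator update per mini-batch, and the
#' saturating generator loss.
#'
#' @param epochs,batch_size,learning_rate,seq_len Training hyper-parameters.
#' @param d_steps_per_g_step Discriminator updates per generator update
#'   (default 1).
#' @param seed Seed covering initialisation, batching, noise and dropout.
#' @param g_loss_mode Passed to [gan_losses()].
#' @param optimizer Optimizer name; `"adam"` (default moments 0.9/0.999) is
#'   the only supported value.
#' @return A `gan_train_config` object.
#' @export
gan_train_config <- function(epochs = 500L, batch_size = 100L,
                             learning_rate = 1e-5, seq_len = 3120L,
                             d_steps_per_g_step = 1L, seed = 1L,
                             g_loss_mode = c("saturating", "non-saturating"),
                             optimizer = "adam") {
  g_loss_mode <- match.arg(g_loss_mode)
  if (!identical(optimizer, "adam")) stop_validation("only the adam optimizer is supported")
  structure(list(
    epochs = check_count(epochs, "epochs"),
    batch_size = check_count(batch_size, "batch_size"),
    learning_rate = check_number(learning_rate, "learning_rate", min = 0, strict_min = TRUE),
    seq_len = check_count(seq_len, "seq_len"),
    d_steps_per_g_step = check_count(d_steps_per_g_step, "d_steps_per_g_step"),
    seed = check_count(seed, "seed", min = 0L),
    g_loss_mode = g_loss_mode,
    optimizer = optimizer
  ), class = "gan_train_config")
}

# Cross-entropy gradient on logits for a batch labelled `real_class`
# (1 = real, 2 = fake), scaled by 1/B.
ce_logit_grad <- function(probs, class_idx) {
  B <- nrow(probs)
  g <- probs
  g[cbind(seq_len(B), class_idx)] <- g[cbind(seq_len(B), class_idx)] - 1
  g / B
}

#' Train the adversarial model
#'
#' Alternating minimax training: per mini-batch, `d_steps_per_g_step`
#' discriminator updates (cross-entropy on real-vs-generated labels, which
#' is the negated empirical minimax objective) followed by one generator
#' update through the frozen discriminator.  All randomness — weight
#' initialisation, batch order, noise, dropout — is governed by
#' `train_config$seed`, so equal seeds give identical loss traces.
#'
#' @param data Real windows (`sequence_windows` tibble, matrix, or list);
#'   window length must equal both `train_config$seq_len` and the
#'   discriminator's `input_length`.
#' @param gen_config A [generator_config()].
#' @param disc_spec A [discriminator_spec()].
#' @param train_config A [gan_train_config()].
#' @return An `ecg_gan`: `generator`, `discriminator`, `history` (tibble
#'   `epoch`, `d_loss`, `g_loss`: per-epoch means over mini-batches),
#'   `train_config`, `seed`.
#' @export
train_gan <- function(data, gen_config = generator_config(),
                      disc_spec = discriminator_spec(),
                      train_config = gan_train_config()) {
  stopifnot(inherits(gen_config, "generator_config"),
            inherits(disc_spec, "discriminator_spec"),
            inherits(train_config, "gan_train_config"))
  X <- as_window_matrix(data)
  if (nrow(X) == 0L) stop_validation("training data is empty")
  T_len <- ncol(X)
  if (T_len != train_config$seq_len) {
    stop_validation("window length %d does not match train_config seq_len %d",
                    T_len, train_config$seq_len)
  }
  if (T_len != disc_spec$input_length) {
    stop_validation("window length %d does not match discriminator input_length %d",
                    T_len, disc_spec$input_length)
  }
  n <- nrow(X)
  d <- gen_config$noise_dim
  lead <- min(2L, gen_config$output_dim)   # lead channel fed to the discriminator
  gen <- build_generator(gen_config, seed = train_config$seed)
  disc <- build_discriminator(disc_spec, seed = train_config$seed + 1L)
  g_opt <- nn_adam_init(gen$params)
  d_opt <- nn_adam_init(disc$params)
  lr <- train_config$learning_rate
  hist_d <- numeric(train_config$epochs)
  hist_g <- numeric(train_config$epochs)
  with_seed(train_config$seed + 2L, {
    for (ep in seq_len(train_config$epochs)) {
      perm <- sample.int(n)
      ep_d <- c(); ep_g <- c()
      for (start in seq(1L, n, by = train_config$batch_size)) {
        idx <- perm[start:min(start + train_config$batch_size - 1L, n)]
        Xb <- X[idx, , drop = FALSE]
        B <- nrow(Xb)
        d_loss_batch <- NA_real_
        for (s in seq_len(train_config$d_steps_per_g_step)) {
          Z <- array(rnorm(B * T_len * d), c(B, T_len, d))
          fake <- generator_forward_cache(gen, Z, training = FALSE)$out[, , lead]
          if (is.null(dim(fake))) fake <- matrix(fake, nrow = B)
          inp <- rbind(Xb, fake)
          fw <- disc_forward_cache(disc, inp)
          dLogits <- ce_logit_grad(fw$probs, c(rep(1L, B), rep(2L, B)))
          bk <- disc_backward(disc, dLogits, fw$cache)
          step <- nn_adam_step(disc$params, bk$grads, d_opt, lr)
          disc$params <- step$params
          d_opt <- step$state
          d_loss_batch <- suppressWarnings(
            gan_losses(fw$probs[seq_len(B), 1L], fw$probs[B + seq_len(B), 1L])$d_loss)
        }
        # generator update through the frozen discriminator
        Z <- array(rnorm(B * T_len * d), c(B, T_len, d))
        gfw <- generator_forward_cache(gen, Z, training = TRUE)
        fake <- gfw$out[, , lead]
        if (is.null(dim(fake))) fake <- matrix(fake, nrow = B)
        dfw <- disc_forward_cache(disc, fake)
        dLogits <- if (train_config$g_loss_mode == "non-saturating") {
          ce_logit_grad(dfw$probs, rep(1L, B))        # minimize -log D(fake)
        } else {
          -ce_logit_grad(dfw$probs, rep(2L, B))       # minimize +log(1 - D(fake))
        }
        dbk <- disc_backward(disc, dLogits, dfw$cache)
        dOut <- array(0, dim(gfw$out))
        dOut[, , lead] <- dbk$dX
        g_grads <- generator_backward(gen, dOut, gfw$cache)
        step <- nn_adam_step(gen$params, g_grads, g_opt, lr)
        gen$params <- step$params
        g_opt <- step$state
        losses <- suppressWarnings(
          gan_losses(fw$probs[seq_len(B), 1L], dfw$probs[, 1L],
                     g_mode = train_config$g_loss_mode))
        ep_d <- c(ep_d, d_loss_batch)
        ep_g <- c(ep_g, losses$g_loss)
      }
      hist_d[ep] <- mean(ep_d)
      hist_g[ep] <- mean(ep_g)
    }
  })
  history <- tibble::tibble(epoch = seq_len(train_config$epochs),
                            d_loss = hist_d, g_loss = hist_g)
  class(history) <- c("gan_history", class(history))
  structure(list(generator = gen, discriminator = disc, history = history,
                 train_config = train_config, seed = train_config$seed),
            class = "ecg_gan")
}

#' Generate ECG sequences from a (trained or untrained) generator
#'
#' Draws seeded Gaussian noise, runs the generator in evaluation mode
#' (dropout off) and returns the lead channel of each generated sequence.
#' The published generation setting is noise width 5 and length 400; any
#' length works because the recurrent weights are shared across time.
#'
#' @param generator An `ecg_generator`, or an `ecg_gan` (its generator is
#'   used).
#' @param n Number of sequences (default 1).
#' @param length Samples per sequence (default 400).
#' @param seed Seed for the noise draw.
#' @return An `ecg_sequences` tibble: `sequence` (index), `length`, and a
#'   `values` list-column with the lead-channel samples.
#' @export
generate_ecgs <- function(generator, n = 1L, length = 400L, seed = 1L) {
  if (inherits(generator, "ecg_gan")) generator <- generator$generator
  stopifnot(inherits(generator, "ecg_generator"))
  n <- check_count(n, "n")
  length <- check_count(length, "length")
  Z <- sample_noise(n, length, generator$config$noise_dim, seed = seed)
  out <- generator_forward(generator, Z, training = FALSE)
  lead <- min(2L, generator$config$output_dim)
  vals <- lapply(seq_len(n), function(i) as.numeric(out[i, , lead]))
  res <- tibble::tibble(sequence = seq_len(n),
                        length = rep(as.integer(length), n),
                        values = vals)
  class(res) <- c("ecg_sequences", class(res))
  res
}

#' @export
print.ecg_gan <- function(x, ...) {
  cat(sprintf("ECG GAN: %s discriminator, %d epoch(s) trained, final d_loss %.4f, g_loss %.4f\n",
              toupper(x$discriminator$spec$kind), nrow(x$history),
              utils::tail(x$history$d_loss, 1), utils::tail(x$history$g_loss, 1)))
  invisible(x)
}
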