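# Recurrent autoencoder and variational autoencoder baselines.  The encoder
# runs a recurrent cell over the input sequence and maps its final hidden
# state to a latent code (AE) or to mean/log-sd vectors (VAE); the decoder
# cell receives the latent code at every step together with the previous
# output (teacher-forced during training) and a shared dense head emits one
# sample per step.

#' Autoencoder configuration
#'
#' @param cell Recurrent cell for encoder and decoder: `"rnn"` (vanilla tanh
#'   recurrence, the default) or `"lstm"`.
#' @param hidden_units Recurrent state width (default 32).
#' @param latent_dim Width of the latent code (default 16).
#' @param seq_len Sequence length the model is trained on.
#' @param variational If `TRUE`, a VAE: the encoder emits mean and log-sd
#'   vectors, the latent code is drawn by the reparameterization trick, and
#'   training minimizes the negative ELBO (reconstruction MSE + Gaussian KL
#'   to the standard-normal prior).
#' @return An `ae_config` object.
#' @export
ae_config <- function(cell = c("rnn", "lstm"), hidden_units = 32L,
                      latent_dim = 16L, seq_len = 3120L, variational = FALSE) {
  cell <- match.arg(cell)
  structure(list(cell = cell,
                 hidden_units = check_count(hidden_units, "hidden_units"),
                 latent_dim = check_count(latent_dim, "latent_dim"),
                 seq_len = check_count(seq_len, "seq_len"),
                 variational = isTRUE(variational)),
            class = "ae_config")
}

#' Reparameterization trick
#'
#' Expresses a Gaussian latent draw as `mu + sigma * epsilon` with
#' `epsilon ~ N(0, 1)` so that gradients pass through `mu` and `sigma`.
#'
#' @param mu Mean vector (or matrix, batch x latent).
#' @param sigma Standard-deviation vector/matrix, elementwise `>= 0`, same
#'   shape as `mu`.
#' @param epsilon Optional fixed noise of the same shape; drawn `N(0, 1)`
#'   when omitted.
#' @param seed Optional seed for the drawn noise.
#' @return `mu + sigma * epsilon`, same shape as `mu`.
#' @export
reparameterize <- function(mu, sigma, epsilon = NULL, seed = NULL) {
  if (length(mu) != length(sigma)) {
    stop_shape("mu (%d) and sigma (%d) lengths differ", length(mu), length(sigma))
  }
  if (any(sigma < 0)) stop_domain("sigma must be elementwise >= 0")
  if (is.null(epsilon)) {
    epsilon <- with_seed(seed, rnorm(length(mu)))
    if (!is.null(dim(mu))) dim(epsilon) <- dim(mu)
  }
  if (length(epsilon) != length(mu)) {
    stop_shape("epsilon (%d) and mu (%d) lengths differ", length(epsilon), length(mu))
  }
  mu + sigma * epsilon
}

#' Autoencoder reconstruction loss
#'
#' The reconstruction objective realized as mean squared error over all
#' points — the Gaussian log-likelihood with unit variance is, up to
#' additive and multiplicative constants, `-MSE`, so maximizing the average
#' per-point log-likelihood is equivalent to minimizing this value.
#'
#' @param inputs Input batch (vector, matrix, or window set).
#' @param reconstructions Matching reconstruction batch.
#' @return Non-negative scalar MSE.
#' @export
ae_loss <- function(inputs, reconstructions) {
  x <- if (is.list(inputs) || is.data.frame(inputs)) as_window_matrix(inputs) else inputs
  y <- if (is.list(reconstructions) || is.data.frame(reconstructions)) as_window_matrix(reconstructions) else reconstructions
  if (length(x) != length(y)) {
    stop_shape("inputs (%d values) and reconstructions (%d values) differ in size",
               length(x), length(y))
  }
  mean((as.numeric(x) - as.numeric(y))^2)
}

# Closed-form KL(N(mu, sigma^2) || N(0, 1)), summed over latent dimensions.
gaussian_kl <- function(mu, sigma) {
  sum(0.5 * (mu^2 + sigma^2 - 1 - 2 * log(sigma)))
}

#' Variational autoencoder loss (negative ELBO)
#'
#' Reconstruction MSE plus the closed-form Gaussian KL divergence of the
#' posterior `N(mu, sigma^2)` from the standard-normal prior,
#' `KL = 1/2 sum(mu^2 + sigma^2 - 1 - 2 log sigma)` (averaged over the batch
#' for matrix `mu`/`sigma`).  The returned value is a loss to minimize, i.e.
#' the negative evidence lower bound up to the constants absorbed into the
#' MSE reconstruction term.
#'
#' @inheritParams ae_loss
#' @param mu Posterior means: vector, or batch x latent matrix.
#' @param sigma Posterior standard deviations, strictly positive, same shape.
#' @return Scalar loss.
#' @examples
#' vae_loss(1:3, 1:3, mu = 1, sigma = 1)  # 0.5 (pure KL term)
#' @export
vae_loss <- function(inputs, reconstructions, mu, sigma) {
  if (any(sigma <= 0)) stop_domain("sigma must be strictly positive")
  if (length(mu) != length(sigma)) {
    stop_shape("mu (%d) and sigma (%d) lengths differ", length(mu), length(sigma))
  }
  recon <- ae_loss(inputs, reconstructions)
  kl <- if (is.matrix(mu)) {
    mean(vapply(seq_len(nrow(mu)), function(i) gaussian_kl(mu[i, ], sigma[i, ]), numeric(1)))
  } else {
    gaussian_kl(mu, sigma)
  }
  recon + kl
}

## ---- model internals -------------------------------------------------------

build_autoencoder_params <- function(config, seed) {
  H <- config$hidden_units
  Z <- config$latent_dim
  cell <- nn_cell(config$cell)
  with_seed(seed, {
    p <- list(
      enc = cell$init(1L, H),
      dec = cell$init(Z + 1L, H),
      out = nn_dense_init(H, 1L)
    )
    if (config$variational) {
      p$mu <- nn_dense_init(H, Z)
      p$logsig <- nn_dense_init(H, Z)
    } else {
      p$code <- nn_dense_init(H, Z)
    }
    p
  })
}

# Forward pass (teacher forcing unless free_running).  X: B x T matrix.
# Returns reconstruction, per-batch latent stats and caches for backprop.
ae_forward <- function(config, params, X, epsilon = NULL, free_running = FALSE) {
  cell <- nn_cell(config$cell)
  B <- nrow(X); T_len <- ncol(X)
  enc_fw <- cell$forward(matrix_to_steps(X), params$enc)
  h_last <- enc_fw$hs[[T_len]]
  if (config$variational) {
    mu <- nn_dense_forward(h_last, params$mu)
    logsig <- nn_dense_forward(h_last, params$logsig)
    sigma <- exp(logsig)
    if (is.null(epsilon)) epsilon <- matrix(rnorm(length(mu)), nrow(mu), ncol(mu))
    d <- mu + sigma * epsilon
  } else {
    mu <- NULL; logsig <- NULL; sigma <- NULL; epsilon <- NULL
    d <- nn_dense_forward(h_last, params$code)
  }
  if (free_running) {
    recon <- ae_decode_free(config, params, d, T_len)
    return(list(recon = recon, d = d, mu = mu, sigma = sigma))
  }
  # teacher forcing: decoder input at step t is (d, x_{t-1}), x_0 = 0
  dec_xs <- vector("list", T_len)
  dec_xs[[1L]] <- cbind(d, matrix(0, B, 1L))
  for (t in 2:max(2L, T_len)) if (T_len > 1L) dec_xs[[t]] <- cbind(d, X[, t - 1L, drop = FALSE])
  dec_fw <- cell$forward(dec_xs, params$dec)
  Hmat <- do.call(rbind, dec_fw$hs)
  Ymat <- nn_dense_forward(Hmat, params$out)
  recon <- matrix(0, B, T_len)
  for (t in seq_len(T_len)) recon[, t] <- Ymat[(t - 1L) * B + seq_len(B), 1L]
  list(recon = recon, d = d, mu = mu, sigma = sigma, logsig = logsig,
       epsilon = epsilon,
       cache = list(enc = enc_fw, dec = dec_fw, dec_xs = dec_xs,
                    h_last = h_last, Hmat = Hmat, B = B, T_len = T_len))
}

# Autoregressive decoding with explicit state threading (evaluation only).
ae_decode_free <- function(config, params, d, T_len) {
  cell_name <- config$cell
  B <- nrow(d); H <- config$hidden_units
  h <- matrix(0, B, H)
  cstate <- matrix(0, B, H)
  y_prev <- matrix(0, B, 1L)
  recon <- matrix(0, B, T_len)
  p <- params$dec
  for (t in seq_len(T_len)) {
    x <- cbind(d, y_prev)
    if (cell_name == "lstm") {
      Hn <- ncol(h)
      A <- add_bias(x %*% p$W + h %*% p$U, p$b)
      i1 <- seq_len(Hn)
      ig <- sigmoid(A[, i1, drop = FALSE])
      fg <- sigmoid(A[, Hn + i1, drop = FALSE])
      gg <- tanh(A[, 2L * Hn + i1, drop = FALSE])
      og <- sigmoid(A[, 3L * Hn + i1, drop = FALSE])
      cstate <- fg * cstate + ig * gg
      h <- og * tanh(cstate)
    } else {
      h <- tanh(add_bias(x %*% p$W + h %*% p$U, p$b))
    }
    y_prev <- nn_dense_forward(h, params$out)
    recon[, t] <- y_prev[, 1L]
  }
  recon
}

ae_backward <- function(config, params, X, fw) {
  cell <- nn_cell(config$cell)
  cc <- fw$cache
  B <- cc$B; T_len <- cc$T_len
  Z <- config$latent_dim
  n_total <- B * T_len
  dRecon <- 2 * (fw$recon - X) / n_total          # d MSE / d recon
  dYmat <- matrix(0, n_total, 1L)
  for (t in seq_len(T_len)) dYmat[(t - 1L) * B + seq_len(B), 1L] <- dRecon[, t]
  out_bk <- nn_dense_backward(dYmat, cc$Hmat, params$out)
  dhs <- lapply(seq_len(T_len), function(t) out_bk$dX[(t - 1L) * B + seq_len(B), , drop = FALSE])
  dec_bk <- cell$backward(dhs, cc$dec$cache, params$dec)
  # decoder inputs were (d, x_{t-1}); the latent part accumulates over steps
  dd <- matrix(0, B, Z)
  for (t in seq_len(T_len)) dd <- dd + dec_bk$dxs[[t]][, seq_len(Z), drop = FALSE]
  grads <- list(dec = dec_bk$grads, out = out_bk$grads)
  if (config$variational) {
    # d = mu + exp(logsig) * eps; KL averaged over batch
    dmu_rec <- dd
    dlogsig_rec <- dd * fw$epsilon * fw$sigma
    dmu_kl <- fw$mu / B
    dlogsig_kl <- (fw$sigma^2 - 1) / B
    mu_bk <- nn_dense_backward(dmu_rec + dmu_kl, cc$h_last, params$mu)
    ls_bk <- nn_dense_backward(dlogsig_rec + dlogsig_kl, cc$h_last, params$logsig)
    grads$mu <- mu_bk$grads
    grads$logsig <- ls_bk$grads
    dh_last <- mu_bk$dX + ls_bk$dX
  } else {
    code_bk <- nn_dense_backward(dd, cc$h_last, params$code)
    grads$code <- code_bk$grads
    dh_last <- code_bk$dX
  }
  enc_dhs <- vector("list", T_len)
  enc_dhs[[T_len]] <- dh_last
  enc_bk <- cell$backward(enc_dhs, cc$enc$cache, params$enc)
  grads$enc <- enc_bk$grads
  grads
}

#' Train a recurrent autoencoder or VAE
#'
#' Adam-optimized teacher-forced training on a set of equal-length windows.
#' Defaults mirror the published comparison protocol (500 epochs, mini-batch
#' 100, learning rate 1e-5); desk-scale runs should pass smaller values.
#' The per-epoch loss recorded is the mean over mini-batches of [ae_loss()]
#' (plus the KL term for a VAE, see [vae_loss()]).
#'
#' @param data Windows: `sequence_windows` tibble, matrix, or list of
#'   vectors; all the same length.
#' @param config An [ae_config()]; `seq_len` must match the window length.
#' @param epochs,batch_size,learning_rate Training hyper-parameters.
#' @param seed Seed covering initialisation, batching and latent noise.
#' @return An `ecg_autoencoder` with elements `config`, `params`, `history`
#'   (tibble `epoch`, `loss`) and `seed`.
#' @export
train_autoencoder <- function(data, config, epochs = 500L, batch_size = 100L,
                              learning_rate = 1e-5, seed = 1L) {
  stopifnot(inherits(config, "ae_config"))
  epochs <- check_count(epochs, "epochs")
  batch_size <- check_count(batch_size, "batch_size")
  learning_rate <- check_number(learning_rate, "learning_rate", min = 0, strict_min = TRUE)
  seed <- check_count(seed, "seed", min = 0L)
  X <- as_window_matrix(data)
  if (nrow(X) == 0L) stop_validation("training data is empty")
  if (ncol(X) != config$seq_len) {
    stop_validation("window length %d does not match config seq_len %d",
                    ncol(X), config$seq_len)
  }
  n <- nrow(X)
  params <- build_autoencoder_params(config, seed)
  opt <- nn_adam_init(params)
  losses <- numeric(epochs)
  with_seed(seed + 1L, {
    for (ep in seq_len(epochs)) {
      perm <- sample.int(n)
      batch_losses <- c()
      for (start in seq(1L, n, by = batch_size)) {
        idx <- perm[start:min(start + batch_size - 1L, n)]
        Xb <- X[idx, , drop = FALSE]
        fw <- ae_forward(config, params, Xb)
        loss <- if (config$variational) {
          vae_loss(Xb, fw$recon, fw$mu, fw$sigma)
        } else {
          ae_loss(Xb, fw$recon)
        }
        batch_losses <- c(batch_losses, loss)
        grads <- ae_backward(config, params, Xb, fw)
        step <- nn_adam_step(params, grads, opt, learning_rate)
        params <- step$params
        opt <- step$state
      }
      losses[ep] <- mean(batch_losses)
    }
  })
  history <- tibble::tibble(epoch = seq_len(epochs), loss = losses)
  structure(list(config = config, params = params, history = history, seed = seed),
            class = "ecg_autoencoder")
}

#' Reconstruct windows with a trained autoencoder
#'
#' @param model An `ecg_autoencoder`.
#' @param data Windows of the trained length.
#' @param free_running If `TRUE`, decode autoregressively (each step is fed
#'   the previous prediction); default `FALSE` (teacher-forced, each step is
#'   fed the previous true sample).
#' @param seed Seed for the VAE latent draw.
#' @return Reconstruction matrix, windows x samples.
#' @export
ae_reconstruct <- function(model, data, free_running = FALSE, seed = NULL) {
  stopifnot(inherits(model, "ecg_autoencoder"))
  X <- as_window_matrix(data)
  if (ncol(X) != model$config$seq_len) {
    stop_validation("window length %d does not match model seq_len %d",
                    ncol(X), model$config$seq_len)
  }
  with_seed(seed, {
    fw <- ae_forward(model$config, model$params, X, free_running = free_running)
    fw$recon
  })
}

#' @export
print.ecg_autoencoder <- function(x, ...) {
  cat(sprintf("%s %s: hidden %d, latent %d, seq_len %d, %d parameters, %d epoch(s) trained\n",
              toupper(x$config$cell),
              if (x$config$variational) "VAE" else "autoencoder",
              x$config$hidden_units, x$config$latent_dim, x$config$seq_len,
              count_parameters(x), nrow(x$history)))
  invisible(x)
}
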