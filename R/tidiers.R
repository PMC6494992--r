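#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot ggplot aes geom_line labs facet_wrap
#' @export
ggplot2::autoplot

#' Tidy a trained GAN: the per-epoch loss trace in long form
#'
#' @param x An `ecg_gan`.
#' @param ... Unused.
#' @return Tibble with `epoch`, `loss_type` (`"d_loss"`/`"g_loss"`), `loss`.
#' @export
tidy.ecg_gan <- function(x, ...) {
  tidyr::pivot_longer(tibble::as_tibble(x$history), cols = c("d_loss", "g_loss"),
                      names_to = "loss_type", values_to = "loss")
}

#' One-row summary of a trained GAN
#' @param x An `ecg_gan`.
#' @param ... Unused.
#' @export
glance.ecg_gan <- function(x, ...) {
  tibble::tibble(
    epochs = nrow(x$history),
    final_d_loss = utils::tail(x$history$d_loss, 1),
    final_g_loss = utils::tail(x$history$g_loss, 1),
    n_params_generator = count_parameters(x$generator),
    n_params_discriminator = count_parameters(x$discriminator),
    discriminator = x$discriminator$spec$kind,
    seed = x$seed
  )
}

#' Tidy a trained autoencoder: the per-epoch loss trace
#' @param x An `ecg_autoencoder`.
#' @param ... Unused.
#' @export
tidy.ecg_autoencoder <- function(x, ...) tibble::as_tibble(x$history)

#' One-row summary of a trained autoencoder
#' @param x An `ecg_autoencoder`.
#' @param ... Unused.
#' @export
glance.ecg_autoencoder <- function(x, ...) {
  tibble::tibble(
    epochs = nrow(x$history),
    final_loss = utils::tail(x$history$loss, 1),
    cell = x$config$cell,
    variational = x$config$variational,
    latent_dim = x$config$latent_dim,
    n_params = count_parameters(x),
    seed = x$seed
  )
}

#' Per-pair metric values behind a metric report
#' @param x A `metric_report` from [evaluate_generated()].
#' @param ... Unused.
#' @return Tibble with one row per (generated, reference) pair.
#' @export
tidy.metric_report <- function(x, ...) attr(x, "pairs")

#' One-row summary of a metric report
#' @param x A `metric_report`.
#' @param ... Unused.
#' @export
glance.metric_report <- function(x, ...) tibble::as_tibble(x)

#' Loss curves of a trained GAN
#' @param object An `ecg_gan`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ecg_gan <- function(object, ...) {
  ggplot(tidy.ecg_gan(object), aes(x = .data$epoch, y = .data$loss,
                                   colour = .data$loss_type)) +
    geom_line() +
    labs(x = "epoch", y = "loss", colour = NULL,
         title = "Adversarial training losses")
}

#' Loss curve of a trained autoencoder
#' @param object An `ecg_autoencoder`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ecg_autoencoder <- function(object, ...) {
  ggplot(tibble::as_tibble(object$history), aes(x = .data$epoch, y = .data$loss)) +
    geom_line() +
    labs(x = "epoch", y = "loss",
         title = sprintf("%s %s training loss", toupper(object$config$cell),
                         if (object$config$variational) "VAE" else "AE"))
}

#' Plot generated (or windowed) sequences
#' @param object An `ecg_sequences` or `sequence_windows` tibble.
#' @param max_sequences Facet at most this many sequences (default 6).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ecg_sequences <- function(object, max_sequences = 6L, ...) {
  ids <- utils::head(seq_len(nrow(object)), max_sequences)
  long <- tibble::tibble(
    sequence = rep(ids, times = lengths(object$values[ids])),
    sample = unlist(lapply(object$values[ids], seq_along)),
    value = unlist(object$values[ids])
  )
  ggplot(long, aes(x = .data$sample, y = .data$value)) +
    geom_line() +
    facet_wrap(~sequence, scales = "free_y") +
    labs(x = "sample", y = "lead value")
}

#' @rdname autoplot.ecg_sequences
#' @export
autoplot.sequence_windows <- function(object, max_sequences = 6L, ...) {
  autoplot.ecg_sequences(object, max_sequences = max_sequences, ...)
}
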