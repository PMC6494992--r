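# Model checkpoints: a single JSON file holding the full spec, seed and all
# weights (with dimensions), plus library-version provenance.  JSON keeps
# checkpoints portable and diffable; weights round-trip at full double
# precision via digits = NA.

flatten_params <- function(p) {
  if (is.list(p)) return(lapply(p, flatten_params))
  list(dim = dim(p) %||% length(p), data = as.numeric(p))
}

unflatten_params <- function(p) {
  if (!is.null(p$data) && !is.null(p$dim)) {
    v <- as.numeric(p$data)
    d <- as.integer(p$dim)
    if (length(d) > 1L) array(v, d) else v
  } else {
    lapply(p, unflatten_params)
  }
}

strip_class <- function(x) {
  if (is.list(x)) lapply(unclass(x), strip_class) else x
}

#' Save a model checkpoint
#'
#' Serializes an `ecg_generator`, `ecg_discriminator`, `ecg_gan` or
#' `ecg_autoencoder` (weights, configuration, seed, package version) to a
#' single JSON file.
#'
#' @param model The model object.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
save_model <- function(model, path) {
  type <- class(model)[1L]
  if (!type %in% c("ecg_generator", "ecg_discriminator", "ecg_gan", "ecg_autoencoder")) {
    stop_validation("cannot checkpoint objects of class %s", type)
  }
  payload <- list(type = type,
                  package_version = as.character(utils::packageVersion("ecggan")))
  if (type == "ecg_gan") {
    payload$generator <- list(config = unclass(model$generator$config),
                              seed = model$generator$seed,
                              params = flatten_params(model$generator$params))
    payload$discriminator <- list(spec = strip_class(model$discriminator$spec),
                                  seed = model$discriminator$seed,
                                  params = flatten_params(model$discriminator$params))
    payload$train_config <- unclass(model$train_config)
    payload$history <- as.list(as.data.frame(model$history))
  } else if (type == "ecg_generator") {
    payload$config <- unclass(model$config)
    payload$seed <- model$seed
    payload$params <- flatten_params(model$params)
  } else if (type == "ecg_discriminator") {
    payload$spec <- strip_class(model$spec)
    payload$seed <- model$seed
    payload$params <- flatten_params(model$params)
  } else {
    payload$config <- unclass(model$config)
    payload$seed <- model$seed
    payload$params <- flatten_params(model$params)
    payload$history <- as.list(as.data.frame(model$history))
  }
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

rebuild_generator <- function(config, seed, params) {
  cfg <- do.call(generator_config, config)
  gen <- build_generator(cfg, seed = seed %||% 1L)
  gen$params <- unflatten_params(params)
  gen
}

rebuild_discriminator <- function(spec, seed, params) {
  if (spec$kind == "cnn") {
    layers <- lapply(spec$layers, function(ly) {
      if (ly$type == "conv") conv_layer_spec(ly$n_filters, ly$filter_length, ly$stride, ly$padding)
      else pool_layer_spec(ly$window, ly$stride)
    })
    sp <- discriminator_spec("cnn", input_length = spec$input_length,
                             layers = layers, fc_units = spec$fc_units,
                             activation_slope = spec$activation_slope)
  } else {
    sp <- discriminator_spec(spec$kind, input_length = spec$input_length,
                             hidden = unlist(spec$hidden),
                             activation_slope = spec$activation_slope)
  }
  disc <- build_discriminator(sp, seed = seed %||% 1L)
  disc$params <- unflatten_params(params)
  disc
}

#' Load a model checkpoint
#'
#' @param path A file written by [save_model()].
#' @return The reconstructed model object.
#' @export
load_model <- function(path) {
  if (!file.exists(path)) stop_io("checkpoint not found: %s", path)
  payload <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE,
                                          simplifyDataFrame = FALSE,
                                          simplifyMatrix = FALSE),
                      error = function(e) stop_format("unreadable checkpoint %s: %s",
                                                      path, conditionMessage(e)))
  if (is.null(payload$type)) stop_format("checkpoint %s has no model type", path)
  if (payload$type == "ecg_generator") {
    rebuild_generator(payload$config, payload$seed, payload$params)
  } else if (payload$type == "ecg_discriminator") {
    rebuild_discriminator(payload$spec, payload$seed, payload$params)
  } else if (payload$type == "ecg_gan") {
    gen <- rebuild_generator(payload$generator$config, payload$generator$seed,
                             payload$generator$params)
    disc <- rebuild_discriminator(payload$discriminator$spec,
                                  payload$discriminator$seed,
                                  payload$discriminator$params)
    history <- tibble::as_tibble(payload$history)
    class(history) <- c("gan_history", class(history))
    tc <- payload$train_config
    structure(list(generator = gen, discriminator = disc, history = history,
                   train_config = do.call(gan_train_config, tc),
                   seed = tc$seed),
              class = "ecg_gan")
  } else if (payload$type == "ecg_autoencoder") {
    cfg <- do.call(ae_config, payload$config)
    structure(list(config = cfg, params = unflatten_params(payload$params),
                   history = tibble::as_tibble(payload$history),
                   seed = payload$seed),
              class = "ecg_autoencoder")
  } else {
    stop_format("unknown checkpoint type %s in %s", payload$type, path)
  }
}
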