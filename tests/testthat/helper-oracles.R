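# Shared helpers: independent oracles and a finite-difference gradient
# checker for the hand-written backpropagation.

# Sliding-window enumeration: count filter placements directly by walking
# the (optionally zero-padded) axis, independent of the closed-form shape
# formulas.
enumerate_conv_positions <- function(W, F, S, P = 0) {
  count <- 0L
  l <- 1L - P
  while (l + F - 1L <= W + P) {
    count <- count + 1L
    l <- l + S
  }
  count
}

enumerate_pool_positions <- function(W, F, S) enumerate_conv_positions(W, F, S, P = 0)

# Flatten / restore a nested parameter tree for numeric differentiation.
pack_tree <- function(p) unlist(p, use.names = FALSE)

unpack_tree <- function(v, template) {
  pos <- 1L
  rec <- function(tpl) {
    if (is.list(tpl)) return(lapply(tpl, rec))
    n <- length(tpl)
    out <- v[pos:(pos + n - 1L)]
    pos <<- pos + n
    if (!is.null(dim(tpl))) dim(out) <- dim(tpl)
    out
  }
  rec(template)
}

# Max abs difference between analytic gradient `grad` and the central
# finite difference of scalar `loss_fn(params)`.
max_grad_error <- function(loss_fn, params, grad, eps = 1e-5) {
  v0 <- pack_tree(params)
  ga <- pack_tree(grad)
  gn <- numeric(length(v0))
  for (i in seq_along(v0)) {
    vp <- v0; vp[i] <- vp[i] + eps
    vm <- v0; vm[i] <- vm[i] - eps
    gn[i] <- (loss_fn(unpack_tree(vp, params)) - loss_fn(unpack_tree(vm, params))) / (2 * eps)
  }
  max(abs(gn - ga)) / max(1, max(abs(gn)))
}

# Small pool of synthetic ECG windows used by several training tests.
tiny_windows <- function(n = 10L, len = 64L, seed = 1L) {
  cfg <- synth_config(duration = n * len / 360 + 1, noise_sd = 0.02, seed = seed)
  w <- generate_dataset(cfg, n_records = 2L, window_length = len)
  w[seq_len(n), ]
}
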