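#' Percent root mean square difference (PRD)
#'
#' Distortion between a reference and a generated sequence:
#' `100 * sqrt(sum((x - xhat)^2) / sum(x^2))` in the default mode.  The
#' `"as-printed"` mode follows the typeset variant with the factor 100
#' inside the radical, `sqrt(100 * sum((x - xhat)^2) / sum(x^2))`.
#' The formula is applied to the inputs as given; any normalization is the
#' caller's choice (see [evaluate_generated()], which min-max normalizes
#' both sides by default).
#'
#' @param reference Reference sequence `x` (not all zero).
#' @param generated Generated sequence `xhat`, same length.
#' @param mode `"standard"` (default) or `"as-printed"`.
#' @return Non-negative scalar.
#' @examples
#' prd(c(1, 0), c(0, 0))  # 100
#' @export
prd <- function(reference, generated, mode = c("standard", "as-printed")) {
  mode <- match.arg(mode)
  x <- as.numeric(reference); xh <- as.numeric(generated)
  if (length(x) != length(xh)) {
    stop_shape("reference (%d) and generated (%d) lengths differ", length(x), length(xh))
  }
  if (length(x) == 0L) stop_shape("sequences must be non-empty")
  energy <- sum(x^2)
  if (energy == 0) stop_domain("PRD is undefined for an all-zero reference")
  ratio <- sum((x - xh)^2) / energy
  if (mode == "standard") 100 * sqrt(ratio) else sqrt(100 * ratio)
}

#' Root mean square error (RMSE)
#'
#' `sqrt(mean((x - xhat)^2))` between two equal-length sequences.
#'
#' @inheritParams prd
#' @return Non-negative scalar.
#' @export
rmse <- function(reference, generated) {
  x <- as.numeric(reference); xh <- as.numeric(generated)
  if (length(x) != length(xh)) {
    stop_shape("reference (%d) and generated (%d) lengths differ", length(x), length(xh))
  }
  if (length(x) == 0L) stop_shape("sequences must be non-empty")
  sqrt(mean((x - xh)^2))
}

# Coerce a curve argument to an n x k coordinate matrix.  Numeric vectors
# become 2-D curves (index/(n-1), value) so that point order matters; with
# `as_curve = FALSE` they stay 1-D (value only).
curve_points <- function(p, as_curve = TRUE) {
  if (is.matrix(p)) return(p)
  if (is.data.frame(p)) return(as.matrix(p))
  p <- as.numeric(p)
  n <- length(p)
  if (as_curve) {
    t <- if (n > 1L) (seq_len(n) - 1) / (n - 1) else 0
    cbind(t = t, v = p)
  } else {
    matrix(p, ncol = 1L)
  }
}

curve_dist_matrix <- function(P, Q) {
  n <- nrow(P); m <- nrow(Q)
  D <- matrix(0, n, m)
  for (k in seq_len(ncol(P))) {
    D <- D + outer(P[, k], Q[, k], `-`)^2
  }
  sqrt(D)
}

#' Discrete Fréchet distance
#'
#' The minimum over monotone couplings of two point sequences of the maximum
#' pointwise Euclidean distance, computed by the standard dynamic programme:
#' a coupling visits `(a_i, b_i)` pairs where each index either stays or
#' advances by one, starting at the first points and ending at the last.
#'
#' Numeric-vector inputs are treated as planar curves with coordinates
#' `(index/(n-1), value)` so that the ordering of points along the curve
#' matters; pass `as_curve = FALSE` for a value-only (1-D) comparison, or
#' supply n x k coordinate matrices directly.
#'
#' @param P,Q Curves: numeric vectors or coordinate matrices (rows = points).
#' @param as_curve Whether to lift numeric vectors to (index, value) points
#'   (default `TRUE`).
#' @return Non-negative scalar.
#' @examples
#' discrete_frechet(matrix(c(0, 0), 1), matrix(c(3, 4), 1))  # 5
#' @export
discrete_frechet <- function(P, Q, as_curve = TRUE) {
  P <- curve_points(P, as_curve); Q <- curve_points(Q, as_curve)
  if (nrow(P) == 0L || nrow(Q) == 0L) stop_validation("curves must be non-empty")
  if (ncol(P) != ncol(Q)) stop_shape("curves must have the same coordinate dimension")
  D <- curve_dist_matrix(P, Q)
  n <- nrow(P); m <- nrow(Q)
  CA <- matrix(0, n, m)
  CA[1L, 1L] <- D[1L, 1L]
  if (m > 1L) for (j in 2:m) CA[1L, j] <- max(CA[1L, j - 1L], D[1L, j])
  if (n > 1L) for (i in 2:n) CA[i, 1L] <- max(CA[i - 1L, 1L], D[i, 1L])
  if (n > 1L && m > 1L) {
    for (i in 2:n) {
      for (j in 2:m) {
        CA[i, j] <- max(min(CA[i - 1L, j], CA[i - 1L, j - 1L], CA[i, j - 1L]), D[i, j])
      }
    }
  }
  CA[n, m]
}

#' Brute-force discrete Fréchet distance
#'
#' Exhaustive recursion over all monotone couplings (no dynamic-programming
#' table); exponential in the curve lengths, intended as an independent
#' cross-check of [discrete_frechet()] on short curves.
#'
#' @inheritParams discrete_frechet
#' @return Non-negative scalar.
#' @export
discrete_frechet_brute <- function(P, Q, as_curve = TRUE) {
  P <- curve_points(P, as_curve); Q <- curve_points(Q, as_curve)
  if (nrow(P) == 0L || nrow(Q) == 0L) stop_validation("curves must be non-empty")
  D <- curve_dist_matrix(P, Q)
  n <- nrow(P); m <- nrow(Q)
  rec <- function(i, j) {
    here <- D[i, j]
    if (i == n && j == m) return(here)
    best <- Inf
    if (i < n) best <- min(best, rec(i + 1L, j))
    if (j < m) best <- min(best, rec(i, j + 1L))
    if (i < n && j < m) best <- min(best, rec(i + 1L, j + 1L))
    max(here, best)
  }
  rec(1L, 1L)
}

#' Score generated sequences against a pool of real windows
#'
#' Pairs each generated sequence with a reference window, computes PRD, RMSE
#' and the discrete Fréchet distance per pair, and reports the means.  All
#' sequences are truncated to the shortest length present, and by default
#' both sides are min-max normalized to \[0, 1\] per sequence before
#' scoring (the published evaluation normalizes generated points first);
#' set `normalize = FALSE` for raw-scale metrics.
#'
#' Pairing strategies: `"best"` (default) pairs each generated sequence with
#' the real window minimizing RMSE against it — the generator is unpaired by
#' construction, so a nearest-reference protocol scores morphology rather
#' than index alignment; `"fixed"` pairs by index (generated i with real i,
#' recycling the real pool), which is reproducible and order-sensitive.
#'
#' @param real_windows Real sequences: `sequence_windows` tibble, matrix, or
#'   list of numeric vectors.
#' @param generated Generated sequences, same accepted forms.
#' @param pairing `"best"` (default) or `"fixed"`.
#' @param normalize Min-max normalize each sequence before scoring
#'   (default `TRUE`).
#' @param prd_mode Passed to [prd()].
#' @return A one-row `metric_report` tibble: `prd`, `rmse`, `fd`, `n_pairs`,
#'   `pairing`.  Per-pair values are available via `tidy()`.
#' @export
evaluate_generated <- function(real_windows, generated,
                               pairing = c("best", "fixed"),
                               normalize = TRUE,
                               prd_mode = c("standard", "as-printed")) {
  pairing <- match.arg(pairing)
  prd_mode <- match.arg(prd_mode)
  R <- as_window_matrix(real_windows)
  G <- as_window_matrix(generated)
  L <- min(ncol(R), ncol(G))
  if (L < 1L) stop_validation("sequences must be non-empty")
  R <- R[, seq_len(L), drop = FALSE]
  G <- G[, seq_len(L), drop = FALSE]
  prep <- function(x) if (normalize) minmax_normalize(x) else x
  Rn <- t(apply(R, 1L, prep))
  Gn <- t(apply(G, 1L, prep))
  if (L == 1L) { Rn <- t(Rn); Gn <- t(Gn) }
  n_g <- nrow(Gn); n_r <- nrow(Rn)
  ref_idx <- integer(n_g)
  for (i in seq_len(n_g)) {
    if (pairing == "fixed") {
      ref_idx[i] <- (i - 1L) %% n_r + 1L
    } else {
      errs <- sqrt(rowMeans((Rn - matrix(Gn[i, ], n_r, L, byrow = TRUE))^2))
      ref_idx[i] <- which.min(errs)
    }
  }
  pair_tbl <- tibble::tibble(
    generated = seq_len(n_g),
    reference = ref_idx,
    prd = vapply(seq_len(n_g), function(i) prd(Rn[ref_idx[i], ], Gn[i, ], mode = prd_mode), numeric(1)),
    rmse = vapply(seq_len(n_g), function(i) rmse(Rn[ref_idx[i], ], Gn[i, ]), numeric(1)),
    fd = vapply(seq_len(n_g), function(i) discrete_frechet(Rn[ref_idx[i], ], Gn[i, ]), numeric(1))
  )
  out <- tibble::tibble(
    prd = mean(pair_tbl$prd),
    rmse = mean(pair_tbl$rmse),
    fd = mean(pair_tbl$fd),
    n_pairs = n_g,
    pairing = pairing
  )
  attr(out, "pairs") <- pair_tbl
  class(out) <- c("metric_report", class(out))
  out
}
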