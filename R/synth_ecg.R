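default_wave_params <- function() {
  tibble::tibble(
    wave = c("P", "Q", "R", "S", "T"),
    amplitude = c(0.15, -0.10, 1.00, -0.25, 0.35),
    width = c(0.25, 0.10, 0.10, 0.10, 0.40),
    position = c(-1.30, -0.30, 0.00, 0.30, 1.40)
  )
}

#' Synthetic ECG configuration
#'
#' Parameterises the built-in single-lead ECG simulator: one cardiac cycle is
#' a sum of five Gaussian bumps (P, Q, R, S, T) on the cycle phase
#' \eqn{\theta \in [-\pi, \pi)}, `amplitude * exp(-(theta - position)^2 /
#' (2 width^2))`, traversed at `heart_rate` cycles per minute and sampled at
#' `sampling_rate`, plus optional additive white Gaussian noise and an
#' optional low-frequency baseline-wander sinusoid.  Signals are in
#' normalized lead units (R amplitude 1 by default, roughly 1 mV).
#'
#' @param heart_rate Beats per minute (default 60).
#' @param sampling_rate Samples per second (default 360, the MIT-BIH rate).
#' @param duration Seconds of signal (default 30).
#' @param wave_params Data frame with columns `wave`, `amplitude`,
#'   `width` (radians), `position` (radians, strictly increasing);
#'   exactly five rows.
#' @param noise_sd Standard deviation of additive Gaussian noise
#'   (default 0.02 lead units).
#' @param baseline_wander If `TRUE`, add a 0.33 Hz sinusoid of amplitude
#'   0.05 emulating respiratory baseline drift (default `FALSE`).
#' @param seed Integer seed making the noise reproducible.
#' @return A `synth_config` object.
#' @export
synth_config <- function(heart_rate = 60, sampling_rate = 360, duration = 30,
                         wave_params = default_wave_params(),
                         noise_sd = 0.02, baseline_wander = FALSE, seed = 1L) {
  heart_rate <- check_number(heart_rate, "heart_rate", min = 0, strict_min = TRUE)
  sampling_rate <- check_number(sampling_rate, "sampling_rate", min = 0, strict_min = TRUE)
  duration <- check_number(duration, "duration", min = 0, strict_min = TRUE)
  noise_sd <- check_number(noise_sd, "noise_sd", min = 0)
  seed <- check_count(seed, "seed", min = 0L)
  wp <- tibble::as_tibble(wave_params)
  need <- c("wave", "amplitude", "width", "position")
  if (!all(need %in% names(wp)) || nrow(wp) != 5L) {
    stop_validation("wave_params must have 5 rows and columns %s", paste(need, collapse = ", "))
  }
  if (any(diff(wp$position) <= 0)) {
    stop_validation("wave positions must be strictly increasing within a cycle")
  }
  if (any(wp$width <= 0)) stop_validation("wave widths must be positive")
  structure(list(heart_rate = heart_rate, sampling_rate = sampling_rate,
                 duration = duration, wave_params = wp, noise_sd = noise_sd,
                 baseline_wander = isTRUE(baseline_wander), seed = seed),
            class = "synth_config")
}

#' Generate one synthetic ECG signal
#'
#' Deterministic for a fixed config: the noise-free waveform is a pure
#' function of the parameters and the noise stream is seeded.
#'
#' @param config A [synth_config()].
#' @return Numeric vector of `round(duration * sampling_rate)` samples.
#' @examples
#' x <- generate_ecg(synth_config(duration = 10, noise_sd = 0))
#' length(x)  # 3600
#' @export
generate_ecg <- function(config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  n <- round(config$duration * config$sampling_rate)
  if (n < 1) stop_validation("duration x sampling_rate must give at least one sample")
  tt <- (seq_len(n) - 1) / config$sampling_rate
  # cycle phase in [-pi, pi), R wave (position 0) at mid-cycle
  phase <- 2 * pi * ((tt * config$heart_rate / 60) %% 1) - pi
  x <- numeric(n)
  wp <- config$wave_params
  for (i in seq_len(nrow(wp))) {
    d <- phase - wp$position[i]
    d <- ((d + pi) %% (2 * pi)) - pi    # angular difference, wrap-around safe
    x <- x + wp$amplitude[i] * exp(-d^2 / (2 * wp$width[i]^2))
  }
  if (config$baseline_wander) {
    x <- x + 0.05 * sin(2 * pi * 0.33 * tt)
  }
  if (config$noise_sd > 0) {
    x <- x + with_seed(config$seed, rnorm(n, 0, config$noise_sd))
  }
  x
}

#' Generate a windowed synthetic dataset
#'
#' Draws `n_records` independent synthetic signals (the noise seed is offset
#' by the record index so records differ) and segments each one into
#' non-overlapping fixed-length windows via [segment_windows()].
#'
#' @param config A [synth_config()]; `config$seed` seeds record 1, record
#'   `r` uses `seed + r - 1`.
#' @param n_records Number of records to simulate.
#' @param window_length Window length in samples (default 3120).
#' @param hop Hop between window starts (default `window_length`).
#' @return A `sequence_windows` tibble (see [segment_windows()]).
#' @export
generate_dataset <- function(config = synth_config(), n_records = 1L,
                             window_length = 3120L, hop = window_length) {
  stopifnot(inherits(config, "synth_config"))
  n_records <- check_count(n_records, "n_records")
  out <- vector("list", n_records)
  for (r in seq_len(n_records)) {
    cfg_r <- config
    cfg_r$seed <- config$seed + r - 1L
    x <- generate_ecg(cfg_r)
    out[[r]] <- segment_windows(x, window_length = window_length, hop = hop,
                                record_id = sprintf("synth%03d", r))
  }
  dplyr::bind_rows(out)
}
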