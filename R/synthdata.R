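#' 1/f ("pink") background noise
#'
#' Draws a Gaussian white series and shapes its amplitude spectrum by
#' `1/f^(exponent/2)` in the frequency domain, so the power spectrum falls
#' off as `1/f^exponent`. `exponent = 0` leaves the series white. The DC bin
#' is zeroed, so the output is exactly zero-mean.
#'
#' @param n_samples series length (>= 2).
#' @param exponent spectral slope alpha of the power law `P(f) ~ 1/f^alpha`
#'   (>= 0).
#' @param seed optional integer seed; the global RNG state is restored on
#'   exit when a seed is given.
#' @return numeric vector of length `n_samples`, zero mean.
#' @examples
#' x <- pink_noise(1024, exponent = 1, seed = 1)
#' abs(mean(x)) < 1e-12
#' @export
pink_noise <- function(n_samples, exponent = 1, seed = NULL) {
  if (!is.numeric(n_samples) || n_samples < 2)
    stop("`n_samples` must be >= 2")
  if (exponent < 0) stop("`exponent` must be >= 0")
  n <- as.integer(n_samples)
  if (!is.null(seed)) {
    old <- get0(".Random.seed", globalenv(), inherits = FALSE)
    on.exit(restore_rng(old), add = TRUE)
    set.seed(as.integer(seed))
  }
  w <- stats::rnorm(n)
  spec <- stats::fft(w)
  # frequency index of each DFT bin (two-sided), in cycles per series
  k <- c(0, seq_len(n - 1L))
  k <- pmin(k, n - k)          # fold to |f|
  amp <- c(0, 1 / k[-1L]^(exponent / 2))
  x <- Re(stats::fft(spec * amp, inverse = TRUE)) / n
  x - mean(x)
}

restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Synthetic oddball study configuration
#'
#' Describes a stimulus-locked P300 oddball recording to be emulated:
#' sampling rate, epoch duration, montage size, per-class epoch counts and
#' event-related-potential (ERP) parameters, and the 1/f background noise.
#' Defaults emulate a 256 Hz parietal five-channel two-class oddball session:
#' target epochs carry a positive Gaussian-shaped deflection (amplitude 5,
#' latency 400 +/- 40 ms, width 150 ms) over 1/f background noise; non-target
#' epochs are background only.
#'
#' @param fs sampling rate in Hz.
#' @param epoch_ms epoch duration in ms post-stimulus.
#' @param n_channels channel count; channel 1 is the "Pz-like" site carrying
#'   full ERP weight, the others carry weight 0.6.
#' @param class_spec data frame with columns `label`, `n_epochs`,
#'   `erp_amplitude`, `erp_latency_mean`, `erp_latency_sd`, `erp_width`
#'   (latency/width in ms, amplitude in the same units as `noise_sd`).
#' @param noise_sd background noise standard deviation.
#' @param pink_exponent spectral slope of the background (power ~ 1/f^alpha).
#' @param seed integer root seed; epoch `i` of the whole session depends only
#'   on `seed` and `i`, so per-class counts can change without reshuffling
#'   other epochs.
#' @return an object of class `synth_config`.
#' @export
synth_config <- function(fs = 256,
                         epoch_ms = 1000,
                         n_channels = 5,
                         class_spec = data.frame(
                           label = c(0L, 1L),
                           n_epochs = c(200L, 200L),
                           erp_amplitude = c(0, 5),
                           erp_latency_mean = c(400, 400),
                           erp_latency_sd = c(0, 40),
                           erp_width = c(150, 150)),
                         noise_sd = 2.5,
                         pink_exponent = 1,
                         seed = 1L) {
  stopifnot(fs > 0, epoch_ms > 0, n_channels >= 1)
  need <- c("label", "n_epochs", "erp_amplitude", "erp_latency_mean",
            "erp_latency_sd", "erp_width")
  if (!all(need %in% names(class_spec)))
    stop("class_spec must have columns: ", paste(need, collapse = ", "))
  if (any(class_spec$n_epochs < 1)) stop("every n_epochs must be >= 1")
  if (any(class_spec$erp_width <= 0)) stop("erp_width must be > 0")
  structure(list(fs = fs, epoch_ms = epoch_ms, n_channels = n_channels,
                 class_spec = class_spec, noise_sd = noise_sd,
                 pink_exponent = pink_exponent, seed = as.integer(seed)),
            class = "synth_config")
}

# fixed parietal emphasis: full weight on the Pz-like channel, 0.6 elsewhere
parietal_weights <- function(n_channels) {
  w <- rep(0.6, n_channels)
  w[1L] <- 1
  w
}

#' Generate a synthetic P300 oddball session
#'
#' Each epoch is independent 1/f background noise per channel; epochs of
#' classes with nonzero `erp_amplitude` additionally carry a positive
#' Gaussian-shaped deflection centred at a latency drawn from
#' `N(erp_latency_mean, erp_latency_sd^2)` (clamped to the epoch window with
#' a warning if it falls outside), with time-domain standard deviation
#' `erp_width / 2` ms so that ~95% of the bump lies within `erp_width` of the
#' centre, scaled per channel by a fixed parietal weight vector.
#'
#' Epoch `i` is generated from its own RNG substream derived from the root
#' seed, so the same epoch index always yields the same trace regardless of
#' how many epochs are requested.
#'
#' @param config a [synth_config].
#' @return an [eeg_epochs] object; labels follow `config$class_spec`.
#' @examples
#' cfg <- synth_config(fs = 64, epoch_ms = 500,
#'                     class_spec = data.frame(label = 0:1, n_epochs = c(4, 4),
#'                       erp_amplitude = c(0, 5), erp_latency_mean = 300,
#'                       erp_latency_sd = 20, erp_width = 150))
#' x <- generate_oddball(cfg)
#' dim(x)
#' @export
generate_oddball <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  cs <- config$class_spec
  n_t <- round(config$fs * config$epoch_ms / 1000)
  n_total <- sum(cs$n_epochs)
  dat <- array(0, c(n_total, config$n_channels, n_t))
  labels <- integer(n_total)
  w <- parietal_weights(config$n_channels)
  t_ms <- 1000 * (seq_len(n_t) - 1L) / config$fs
  old <- get0(".Random.seed", globalenv(), inherits = FALSE)
  on.exit(restore_rng(old), add = TRUE)
  idx <- 0L
  n_clamped <- 0L
  for (ci in seq_len(nrow(cs))) {
    for (ei in seq_len(cs$n_epochs[ci])) {
      idx <- idx + 1L
      # per-epoch substream: independent of the counts of other classes
      # (double arithmetic: the product overflows integers for large seeds)
      set.seed(as.integer((as.numeric(config$seed) * 1000003 +
                             idx * 7919) %% 2147483647))
      for (ch in seq_len(config$n_channels))
        dat[idx, ch, ] <- config$noise_sd *
          pink_noise(n_t, config$pink_exponent)
      if (cs$erp_amplitude[ci] != 0) {
        lat <- stats::rnorm(1, cs$erp_latency_mean[ci], cs$erp_latency_sd[ci])
        if (lat < 0 || lat > config$epoch_ms) {
          n_clamped <- n_clamped + 1L
          lat <- min(max(lat, 0), config$epoch_ms)
        }
        bump <- cs$erp_amplitude[ci] *
          exp(-0.5 * ((t_ms - lat) / (cs$erp_width[ci] / 2))^2)
        for (ch in seq_len(config$n_channels))
          dat[idx, ch, ] <- dat[idx, ch, ] + w[ch] * bump
      }
      labels[idx] <- cs$label[ci]
    }
  }
  if (n_clamped > 0L)
    warning(sprintf("%d ERP latencies fell outside the epoch window and were clamped",
                    n_clamped))
  nm <- c("Pz", "P3", "P4", "PO7", "PO8", paste0("ch", seq_len(1000)))
  eeg_epochs(dat, labels, config$fs, nm[seq_len(config$n_channels)], 0)
}
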