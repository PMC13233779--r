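#' FIR band-limit specification
#'
#' Band edges and taps for the zero-phase FIR filtering applied to epochs.
#' The default band, 0.01--40 Hz, keeps ERP components and removes power-line
#' noise. With second-long epochs the 0.01 Hz edge is below one cycle per
#' epoch, so the high-pass side is realized as per-epoch mean removal
#' followed by the FIR low-pass (a literal 0.01 Hz FIR would need a filter
#' far longer than the epoch).
#'
#' @param low_hz lower band edge (Hz).
#' @param high_hz upper band edge (Hz).
#' @param fir_order filter order in taps; must be odd so the zero-phase
#'   forward-backward pass has a symmetric effective response. `NULL` scales
#'   the default (129 taps at 256 Hz) with the sampling rate at filter time.
#' @param window taper used by the window design method.
#' @return an object of class `filter_spec`.
#' @export
filter_spec <- function(low_hz = 0.01, high_hz = 40, fir_order = NULL,
                        window = "hamming") {
  stopifnot(low_hz >= 0, low_hz < high_hz)
  if (!is.null(fir_order)) {
    stopifnot(fir_order >= 3)
    if (fir_order %% 2 == 0) stop("`fir_order` must be odd")
  }
  structure(list(low_hz = low_hz, high_hz = high_hz, fir_order = fir_order,
                 window = window),
            class = "filter_spec")
}

#' Zero-phase FIR band-limiting of epochs
#'
#' Filters every channel of every epoch with a linear-phase FIR designed by
#' [signal::fir1()], applied as a centered convolution with edge reflection
#' — for a symmetric odd-length kernel this is exactly zero-phase, so ERP
#' latencies are preserved. When `low_hz` amounts to less than one cycle
#' per epoch the high-pass is realized as per-epoch mean subtraction before
#' the low-pass.
#'
#' @param epochs an [eeg_epochs] object.
#' @param spec a [filter_spec].
#' @return filtered [eeg_epochs].
#' @export
bandpass_fir <- function(epochs, spec = filter_spec()) {
  stopifnot(inherits(epochs, "eeg_epochs"), inherits(spec, "filter_spec"))
  fs <- epochs$fs
  nyq <- fs / 2
  if (spec$high_hz >= nyq)
    stop(sprintf("high_hz = %g must be below the Nyquist frequency %g",
                 spec$high_hz, nyq))
  n_t <- dim(epochs$data)[3L]
  order <- spec$fir_order
  if (is.null(order)) {
    order <- 2L * floor(64 * fs / 256) + 1L   # 129 taps at 256 Hz
    order <- max(order, 5L)
  }
  if (n_t <= order)
    stop(sprintf("epoch length %d must exceed the filter order %d",
                 n_t, order))
  epoch_s <- n_t / fs
  mean_removal <- spec$low_hz * epoch_s < 1
  taper <- switch(spec$window,
                  hamming = signal::hamming(order),
                  hanning = signal::hanning(order),
                  boxcar = rep(1, order),
                  stop("unknown window: ", spec$window))
  h <- if (mean_removal || spec$low_hz == 0) {
    signal::fir1(order - 1L, spec$high_hz / nyq, type = "low", window = taper)
  } else {
    signal::fir1(order - 1L, c(spec$low_hz, spec$high_hz) / nyq,
                 type = "pass", window = taper)
  }
  out <- epochs$data
  d <- dim(out)
  for (i in seq_len(d[1L])) {
    for (ch in seq_len(d[2L])) {
      x <- out[i, ch, ]
      if (mean_removal) x <- x - mean(x)
      out[i, ch, ] <- fir_zerophase(x, h)
    }
  }
  eeg_epochs(out, epochs$labels, fs, epochs$channel_names, epochs$time0)
}

# centered convolution with a symmetric odd-length kernel, edges reflected
fir_zerophase <- function(x, h) {
  n <- length(x)
  p <- (length(h) - 1L) %/% 2L
  xe <- c(rev(x[2:(p + 1L)]), x, rev(x[(n - p):(n - 1L)]))
  y <- stats::filter(xe, h, method = "convolution", sides = 2L)
  as.numeric(y[p + seq_len(n)])
}

#' MaxAbs scaling of epochs
#'
#' Divides each channel of each epoch by its maximum absolute value, so every
#' trace lies in `[-1, 1]` (matching the tanh output head of the generators).
#' All-zero traces are left unchanged. The operation is idempotent.
#'
#' @param epochs an [eeg_epochs] object.
#' @param scope `"epoch"` (default: per epoch per channel), `"channel"`
#'   (per channel over all epochs) or `"global"`.
#' @return scaled [eeg_epochs].
#' @export
maxabs_scale <- function(epochs, scope = c("epoch", "channel", "global")) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  scope <- match.arg(scope)
  out <- epochs$data
  d <- dim(out)
  if (scope == "global") {
    m <- max(abs(out))
    if (m > 0) out <- out / m
  } else if (scope == "channel") {
    for (ch in seq_len(d[2L])) {
      m <- max(abs(out[, ch, ]))
      if (m > 0) out[, ch, ] <- out[, ch, ] / m
    }
  } else {
    for (i in seq_len(d[1L]))
      for (ch in seq_len(d[2L])) {
        m <- max(abs(out[i, ch, ]))
        if (m > 0) out[i, ch, ] <- out[i, ch, ] / m
      }
  }
  eeg_epochs(out, epochs$labels, epochs$fs, epochs$channel_names,
             epochs$time0)
}

#' Select channels by name
#'
#' @param epochs an [eeg_epochs] object.
#' @param names channel names to keep, in the requested order.
#' @return channel subset as [eeg_epochs].
#' @export
select_channels <- function(epochs, names) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  idx <- match(names, epochs$channel_names)
  if (anyNA(idx))
    stop("unknown channel(s): ",
         paste(names[is.na(idx)], collapse = ", "),
         "; available: ", paste(epochs$channel_names, collapse = ", "))
  eeg_epochs(epochs$data[, idx, , drop = FALSE], epochs$labels, epochs$fs,
             epochs$channel_names[idx], epochs$time0)
}

#' Event-related potential average
#'
#' Averages all epochs of one label per channel (cancelling the zero-mean
#' background noise, so the stimulus-locked component emerges), then min-max
#' normalizes each channel to `[0, 1]`. Set `normalize = FALSE` for the raw
#' average (used e.g. to inspect amplitudes).
#'
#' @param epochs an [eeg_epochs] object.
#' @param label the class label to average.
#' @param normalize min-max normalize each channel to `[0, 1]` (default).
#' @return matrix `[n_channels, n_samples]` with channel names as rownames.
#' @export
erp_average <- function(epochs, label, normalize = TRUE) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  keep <- epochs$labels == label
  if (!any(keep))
    stop("no epochs with label ", label, " (available: ",
         paste(sort(unique(epochs$labels)), collapse = ", "), ")")
  d <- dim(epochs$data)
  avg <- matrix(0, d[2L], d[3L], dimnames = list(epochs$channel_names, NULL))
  sub <- epochs$data[keep, , , drop = FALSE]
  for (ch in seq_len(d[2L]))
    avg[ch, ] <- colMeans(matrix(sub[, ch, ], nrow = sum(keep)))
  if (normalize) {
    for (ch in seq_len(d[2L])) {
      rng <- range(avg[ch, ])
      if (diff(rng) > 0) avg[ch, ] <- (avg[ch, ] - rng[1L]) / diff(rng)
      else avg[ch, ] <- avg[ch, ] * 0
    }
  }
  avg
}
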