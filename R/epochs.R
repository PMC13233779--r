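#' Epoched EEG container
#'
#' The universal container used throughout the package: a real-valued array
#' of stimulus-locked epochs of shape `[n_epochs, n_channels, n_samples]`
#' together with one integer class label per epoch, the sampling rate, the
#' channel names and the epoch start time relative to the stimulus.
#'
#' @param data numeric array `[n_epochs, n_channels, n_samples]`. A matrix is
#'   accepted for single-channel data and promoted to `[n, 1, t]`.
#' @param labels integer vector, one label per epoch.
#' @param fs sampling rate in Hz.
#' @param channel_names character vector of length `n_channels`; defaults to
#'   `"ch1"`, `"ch2"`, ...
#' @param time0 epoch start relative to the stimulus, in ms (default 0:
#'   epochs begin at stimulus onset).
#'
#' @return an object of class `eeg_epochs`.
#' @examples
#' x <- eeg_epochs(array(rnorm(2 * 3 * 16), c(2, 3, 16)), c(0L, 1L), fs = 16)
#' dim(x$data)
#' @export
eeg_epochs <- function(data, labels, fs, channel_names = NULL, time0 = 0) {
  if (is.matrix(data)) data <- array(data, c(nrow(data), 1L, ncol(data)))
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be an [n_epochs, n_channels, n_samples] array")
  if (!all(is.finite(data))) stop("`data` contains non-finite values")
  d <- dim(data)
  if (length(labels) != d[1L])
    stop(sprintf("length(labels) == %d but n_epochs == %d",
                 length(labels), d[1L]))
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop("`fs` must be a positive scalar (Hz)")
  if (is.null(channel_names)) channel_names <- paste0("ch", seq_len(d[2L]))
  if (length(channel_names) != d[2L])
    stop("length(channel_names) must equal n_channels")
  structure(
    list(data = data, labels = as.integer(labels), fs = fs,
         channel_names = as.character(channel_names), time0 = time0),
    class = "eeg_epochs")
}

#' @export
print.eeg_epochs <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<eeg_epochs> %d epochs x %d channels x %d samples @ %g Hz\n",
              d[1L], d[2L], d[3L], x$fs))
  cat("  channels:", paste(x$channel_names, collapse = ", "), "\n")
  tab <- table(x$labels)
  cat("  labels:  ",
      paste(sprintf("%s (n=%d)", names(tab), as.integer(tab)),
            collapse = ", "), "\n")
  cat(sprintf("  window:   %g .. %g ms post-stimulus\n",
              x$time0, x$time0 + 1000 * d[3L] / x$fs))
  invisible(x)
}

#' @export
dim.eeg_epochs <- function(x) dim(x$data)

n_epochs <- function(x) dim(x$data)[1L]

#' Subset epochs
#'
#' `epochs_subset(x, i)` keeps epochs `i` (logical or integer index).
#' @param x an [eeg_epochs] object.
#' @param i epoch index (integer or logical).
#' @return an [eeg_epochs] object.
#' @export
epochs_subset <- function(x, i) {
  stopifnot(inherits(x, "eeg_epochs"))
  eeg_epochs(x$data[i, , , drop = FALSE], x$labels[i], x$fs,
             x$channel_names, x$time0)
}

#' Time axis of an epochs container
#'
#' @param x an [eeg_epochs] object.
#' @return sample times in ms relative to the stimulus.
#' @export
epochs_time <- function(x) {
  x$time0 + 1000 * (seq_len(dim(x$data)[3L]) - 1L) / x$fs
}

#' Concatenate epoch containers
#'
#' @param ... [eeg_epochs] objects sharing fs, channel set and epoch length.
#' @return a single [eeg_epochs] object.
#' @export
epochs_rbind <- function(...) {
  xs <- list(...)
  stopifnot(length(xs) >= 1L, all(vapply(xs, inherits, TRUE, "eeg_epochs")))
  ref <- xs[[1L]]
  for (x in xs[-1L]) {
    if (!isTRUE(all.equal(x$fs, ref$fs)) ||
        !identical(dim(x$data)[2:3], dim(ref$data)[2:3]))
      stop("containers are not compatible (fs / channels / samples differ)")
  }
  dat <- do.call(abind3, lapply(xs, `[[`, "data"))
  eeg_epochs(dat, unlist(lapply(xs, `[[`, "labels")), ref$fs,
             ref$channel_names, ref$time0)
}

# bind 3-d arrays along the first margin
abind3 <- function(...) {
  arrs <- list(...)
  d <- dim(arrs[[1L]])
  n <- sum(vapply(arrs, function(a) dim(a)[1L], 1L))
  out <- array(0, c(n, d[2L], d[3L]))
  at <- 0L
  for (a in arrs) {
    out[at + seq_len(dim(a)[1L]), , ] <- a
    at <- at + dim(a)[1L]
  }
  out
}

#' Write / read the epochs container
#'
#' Epochs are stored in an HDF5 file with datasets `/data`
#' (`[n_epochs, n_channels, n_samples]`, stored as float64 so round-trips
#' are lossless) and `/labels` (int32), and root attributes `fs`, `time0_ms`
#' and `channel_names`. `read_epochs()` fails with an error naming the first
#' missing dataset or attribute.
#'
#' @param epochs an [eeg_epochs] object.
#' @param path file path (conventionally `.h5`).
#' @return `write_epochs()` returns `path` invisibly; `read_epochs()` returns
#'   an [eeg_epochs] object.
#' @export
write_epochs <- function(epochs, path) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  # store sample-major so other HDF5 readers see [n, c, t] row-major
  rhdf5::h5write(epochs$data, path, "data")
  rhdf5::h5write(epochs$labels, path, "labels")
  fid <- rhdf5::H5Fopen(path)
  on.exit(rhdf5::H5Fclose(fid), add = TRUE)
  rhdf5::h5writeAttribute(epochs$fs, fid, "fs")
  rhdf5::h5writeAttribute(epochs$time0, fid, "time0_ms")
  rhdf5::h5writeAttribute(epochs$channel_names, fid, "channel_names")
  invisible(path)
}

#' @rdname write_epochs
#' @export
read_epochs <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  have <- rhdf5::h5ls(path, recursive = FALSE)$name
  for (need in c("data", "labels"))
    if (!need %in% have)
      stop(sprintf("malformed epochs container: missing dataset '%s'", need))
  dat <- rhdf5::h5read(path, "data")
  lab <- as.integer(rhdf5::h5read(path, "labels"))
  fid <- rhdf5::H5Fopen(path)
  att <- rhdf5::h5readAttributes(fid, "/")
  rhdf5::H5Fclose(fid)
  for (need in c("fs", "time0_ms", "channel_names"))
    if (!need %in% names(att))
      stop(sprintf("malformed epochs container: missing attribute '%s'", need))
  eeg_epochs(dat, lab, as.numeric(att$fs), as.character(att$channel_names),
             as.numeric(att$time0_ms))
}
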