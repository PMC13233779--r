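#' Train the compact evaluation classifier
#'
#' Fits a small 1-D convolutional softmax classifier on real epochs. It is
#' the probabilistic label predictor `p(y|x)` required by the Mode Score;
#' it is trained once on real data, frozen, and its provenance (data
#' fingerprint and seed) is recorded so scores are comparable only within a
#' fixed classifier.
#'
#' @param real_epochs an [eeg_epochs] object with >= 2 classes.
#' @param seed integer seed (initialization and minibatches).
#' @param steps Adam steps.
#' @param batch_size minibatch size.
#' @param lr learning rate.
#' @param holdout fraction held out for the reported validation accuracy.
#' @return an object of class `eval_classifier` with a `predict()` method
#'   returning per-epoch class probabilities.
#' @export
train_eval_classifier <- function(real_epochs, seed = 1L, steps = 400L,
                                  batch_size = 32L, lr = 1e-3,
                                  holdout = 0.2) {
  stopifnot(inherits(real_epochs, "eeg_epochs"))
  classes <- sort(unique(real_epochs$labels))
  if (length(classes) < 2L) stop("need >= 2 classes to train a classifier")
  d <- dim(real_epochs$data)
  old <- get0(".Random.seed", globalenv(), inherits = FALSE)
  on.exit(restore_rng(old), add = TRUE)
  set.seed(as.integer(seed))
  n <- d[1L]
  val_idx <- sample.int(n, max(1L, round(holdout * n)))
  tr_idx <- setdiff(seq_len(n), val_idx)
  X <- real_epochs$data
  y <- match(real_epochs$labels, classes)
  C <- length(classes)
  net <- classifier_net(d[2L], d[3L], C)
  net <- nn_init(net)
  opt <- adam_new(net, lr = lr)
  for (s in seq_len(steps)) {
    idx <- tr_idx[sample.int(length(tr_idx), min(batch_size,
                                                 length(tr_idx)))]
    B <- length(idx)
    fw <- nn_forward(net, X[idx, , , drop = FALSE])
    P <- softmax_rows(fw$Y)
    dY <- (P - onehot(y[idx], C)) / B
    gr <- nn_backward(net, fw$caches, dY)$grads
    upd <- adam_step(net, opt, list(gr))
    net <- upd$net; opt <- upd$opt
  }
  Pv <- softmax_rows(nn_forward(net, X[val_idx, , , drop = FALSE],
                                keep = FALSE)$Y)
  acc <- mean(max.col(Pv) == y[val_idx])
  structure(list(net = net, classes = classes, seed = as.integer(seed),
                 val_accuracy = acc,
                 data_fingerprint = fingerprint_epochs(real_epochs)),
            class = "eval_classifier")
}

classifier_net <- function(n_channels, n_samples, n_classes) {
  t1 <- (n_samples + 2L * 2L - 5L) %/% 2L + 1L
  t2 <- (t1 + 2L * 2L - 5L) %/% 2L + 1L
  list(nn_conv1d(n_channels, 8L, 5L, 2L), nn_lrelu(),
       nn_conv1d(8L, 8L, 5L, 2L), nn_lrelu(),
       nn_flatten(), nn_dense(8L * t2, n_classes))
}

softmax_rows <- function(Y) {
  Y <- Y - apply(Y, 1L, max)
  E <- exp(Y)
  E / rowSums(E)
}

fingerprint_epochs <- function(x) {
  v <- c(dim(x$data), sum(x$data), sum(x$data^2), x$labels)
  sum(v * seq_along(v)) %% 1e9
}

#' @export
print.eval_classifier <- function(x, ...) {
  cat(sprintf("<eval_classifier> %d classes (%s); held-out accuracy %.3f\n",
              length(x$classes), paste(x$classes, collapse = ", "),
              x$val_accuracy))
  invisible(x)
}

#' @export
predict.eval_classifier <- function(object, newdata, ...) {
  X <- as_batch_array(newdata)
  P <- softmax_rows(nn_forward(object$net, X, keep = FALSE)$Y)
  colnames(P) <- as.character(object$classes)
  P
}

#' Mode Score
#'
#' Diversity metric for generated epochs:
#' `MS = exp( E_fake KL(p(y|x) || p*(y)) - KL(pbar(y) || p*(y)) )`,
#' where `p(y|x)` are the frozen classifier's label probabilities,
#' `pbar` their average over the generated set and `p*` the label marginal
#' of the real set. An uninformative classifier gives MS = 1; a perfect
#' classifier with matched uniform marginals gives MS = C, the class count.
#' Higher is more diverse.
#'
#' @param clf an [eval_classifier] (frozen).
#' @param real real [eeg_epochs] providing the label marginal.
#' @param fake generated [eeg_epochs].
#' @return scalar Mode Score (> 0).
#' @export
mode_score <- function(clf, real, fake) {
  stopifnot(inherits(clf, "eval_classifier"))
  if (n_epochs(real) == 0L || n_epochs(fake) == 0L)
    stop("real and fake sets must be nonempty")
  pstar <- tabulate(match(real$labels, clf$classes),
                    nbins = length(clf$classes))
  pstar <- pstar / sum(pstar)
  P <- predict(clf, fake)
  term1 <- mean(apply(P, 1L, kl_div, q = pstar))
  pbar <- colMeans(P)
  term2 <- kl_div(pbar, pstar)
  exp(term1 - term2)
}

kl_div <- function(p, q) {
  nz <- p > 0
  if (any(nz & q == 0)) return(Inf)
  sum(p[nz] * log(p[nz] / q[nz]))
}

#' Sliced Wasserstein distance
#'
#' Similarity metric between two sets of epochs: epochs are flattened to
#' vectors, both sets are reduced to equal counts (seeded subsampling of the
#' larger), and the mean 1-D Wasserstein-1 distance of their projections
#' onto `n_proj` random unit directions is returned. Lower is more similar;
#' identical sets give exactly 0.
#'
#' @param real,fake [eeg_epochs] objects or `[n, channels, samples]` arrays.
#' @param n_proj number of random projection directions.
#' @param seed seed for projections and subsampling.
#' @return scalar distance (>= 0).
#' @export
sliced_wasserstein <- function(real, fake, n_proj = 128L, seed = 1L) {
  A <- flatten_batch(as_batch_array(real))
  Bm <- flatten_batch(as_batch_array(fake))
  if (nrow(A) == 0L || nrow(Bm) == 0L) stop("empty sample set")
  if (ncol(A) != ncol(Bm)) stop("real and fake dimensionality differ")
  old <- get0(".Random.seed", globalenv(), inherits = FALSE)
  on.exit(restore_rng(old), add = TRUE)
  set.seed(as.integer(seed))
  n <- min(nrow(A), nrow(Bm))
  if (nrow(A) > n) A <- A[sample.int(nrow(A), n), , drop = FALSE]
  if (nrow(Bm) > n) Bm <- Bm[sample.int(nrow(Bm), n), , drop = FALSE]
  p <- ncol(A)
  proj <- matrix(stats::rnorm(p * n_proj), p, n_proj)
  proj <- sweep(proj, 2L, sqrt(colSums(proj^2)), `/`)
  PA <- A %*% proj
  PB <- Bm %*% proj
  w <- numeric(n_proj)
  for (j in seq_len(n_proj))
    w[j] <- mean(abs(sort(PA[, j]) - sort(PB[, j])))
  mean(w)
}

#' Welch power spectral density of epochs
#'
#' Splits every epoch into tapered windows of `window_sec` seconds with the
#' given overlap, averages the modified periodograms over windows and
#' epochs (per channel), and truncates the one-sided spectrum to `band`.
#' The default configuration (1-s Hamming windows, 50% overlap,
#' 0.01--40 Hz) trades frequency against temporal resolution the way ERP
#' spectra are usually summarized.
#'
#' @param epochs an [eeg_epochs] object.
#' @param window_sec window length in seconds.
#' @param overlap fractional window overlap in `[0, 1)`.
#' @param band `c(low, high)` frequency band in Hz to retain.
#' @param taper `"hamming"` or `"boxcar"`.
#' @return list with `freq` (Hz) and `psd` (`[n_channels, n_freq]`,
#'   power per Hz), of class `welch_psd`.
#' @export
welch_psd <- function(epochs, window_sec = 1, overlap = 0.5,
                      band = c(0.01, 40), taper = "hamming") {
  stopifnot(inherits(epochs, "eeg_epochs"))
  fs <- epochs$fs
  d <- dim(epochs$data)
  L <- round(fs * window_sec)
  if (d[3L] < L)
    stop(sprintf("epoch length %d is shorter than one %g-s window (%d)",
                 d[3L], window_sec, L))
  w <- switch(taper,
              hamming = 0.54 - 0.46 * cos(2 * pi * (0:(L - 1)) / (L - 1)),
              boxcar = rep(1, L),
              stop("unknown taper: ", taper))
  hop <- max(1L, round(L * (1 - overlap)))
  starts <- seq(1L, d[3L] - L + 1L, by = hop)
  scale <- fs * sum(w^2)
  nf <- L %/% 2L + 1L
  freq <- (seq_len(nf) - 1L) * fs / L
  acc <- matrix(0, d[2L], nf)
  for (i in seq_len(d[1L])) for (ch in seq_len(d[2L])) {
    x <- epochs$data[i, ch, ]
    for (s0 in starts) {
      seg <- x[s0:(s0 + L - 1L)] * w
      P <- Mod(stats::fft(seg))^2 / scale
      half <- P[seq_len(nf)]
      # one-sided: double everything except DC (and Nyquist when L even)
      dbl <- rep(2, nf); dbl[1L] <- 1
      if (L %% 2L == 0L) dbl[nf] <- 1
      acc[ch, ] <- acc[ch, ] + half * dbl
    }
  }
  psd <- acc / (d[1L] * length(starts))
  keep <- freq >= band[1L] & freq <= band[2L]
  structure(list(freq = freq[keep], psd = psd[, keep, drop = FALSE],
                 fs = fs, window_sec = window_sec, overlap = overlap,
                 channel_names = epochs$channel_names),
            class = "welch_psd")
}

#' @export
print.welch_psd <- function(x, ...) {
  cat(sprintf("<welch_psd> %d channels, %.3g-%.3g Hz (%d bins), %g-s %s\n",
              nrow(x$psd), min(x$freq), max(x$freq), length(x$freq),
              x$window_sec, "windows"))
  invisible(x)
}

#' @export
plot.welch_psd <- function(x, channel = 1L, ...) {
  graphics::plot(x$freq, x$psd[channel, ], type = "l", log = "y",
                 xlab = "frequency (Hz)", ylab = "PSD",
                 main = x$channel_names[channel], ...)
  invisible(x)
}

#' Polynomial trend of an ERP waveform
#'
#' Least-squares polynomial of the given order on an abscissa rescaled to
#' `[-1, 1]` (orthogonal-polynomial basis internally, so order 15 stays
#' well conditioned). A 15th-order trend is the conventional smooth that
#' highlights the P300 deflection in epoch averages.
#'
#' @param waveform numeric vector (one channel of an ERP average).
#' @param order polynomial order (< length of the waveform).
#' @return fitted trend values, same length as `waveform`; the model is
#'   attached as attribute `"fit"`.
#' @export
erp_trend <- function(waveform, order = 15L) {
  n <- length(waveform)
  if (n <= order)
    stop(sprintf("waveform length %d must exceed the polynomial order %d",
                 n, order))
  t <- seq(-1, 1, length.out = n)
  if (stats::sd(waveform) == 0) return(structure(rep(waveform[1L], n),
                                                 fit = NULL))
  X <- stats::poly(t, degree = order)
  fit <- stats::lm.fit(cbind(1, X), waveform)
  if (fit$rank < order + 1L)
    warning("rank-deficient polynomial basis; least-norm fit returned")
  yhat <- as.vector(cbind(1, X) %*% ifelse(is.na(fit$coefficients), 0,
                                           fit$coefficients))
  structure(yhat, fit = fit[c("coefficients", "rank")])
}

#' Classification metrics with pairwise AUC
#'
#' Accuracy, precision, recall and F1 from the confusion counts, and the
#' area under the ROC curve computed as the pairwise statistic: the mean
#' over all positive-negative pairs of the indicator that the positive
#' scores higher, counting ties as 1/2. Multiclass input (a score matrix) is
#' reduced one-vs-rest and macro-averaged.
#'
#' @param y_true true labels.
#' @param scores for binary problems a numeric vector of positive-class
#'   scores; for multiclass a `[n, C]` matrix with columns named by class.
#' @param positive_class label treated as positive (binary; defaults to the
#'   larger of the two sorted labels).
#' @param predicted optional hard predictions; by default scores are
#'   thresholded at 0.5 (binary) or arg-maxed (multiclass).
#' @return list of class `classif_metrics`: `Acc`, `Pre`, `Rec`, `F1`,
#'   `AUC`, plus the binary confusion counts when applicable.
#' @examples
#' classification_metrics(c(1, 1, 0, 0), c(0.9, 0.6, 0.4, 0.2), 1)$AUC
#' @export
classification_metrics <- function(y_true, scores, positive_class = NULL,
                                   predicted = NULL) {
  if (is.matrix(scores)) {
    classes <- colnames(scores)
    if (is.null(classes)) classes <- as.character(sort(unique(y_true)))
    if (length(unique(y_true)) < 2L)
      stop("AUC undefined: y_true contains a single class")
    per <- lapply(classes, function(cl) {
      classification_metrics(as.integer(as.character(y_true) == cl),
                             scores[, which(classes == cl)],
                             positive_class = 1L,
                             predicted = as.integer(
                               classes[max.col(scores)] == cl))
    })
    acc <- mean(as.character(y_true) == classes[max.col(scores)])
    out <- list(Acc = acc,
                Pre = mean(vapply(per, `[[`, 1, "Pre")),
                Rec = mean(vapply(per, `[[`, 1, "Rec")),
                F1 = mean(vapply(per, `[[`, 1, "F1")),
                AUC = mean(vapply(per, `[[`, 1, "AUC")),
                macro = TRUE, n_classes = length(classes))
    class(out) <- "classif_metrics"
    return(out)
  }
  if (is.null(positive_class)) positive_class <- max(y_true)
  pos <- y_true == positive_class
  if (all(pos) || !any(pos))
    stop("AUC undefined: y_true contains a single class")
  if (is.null(predicted)) predicted <- as.integer(scores >= 0.5)
  pred_pos <- predicted == 1L | predicted == positive_class
  TP <- sum(pos & pred_pos); FP <- sum(!pos & pred_pos)
  FN <- sum(pos & !pred_pos); TN <- sum(!pos & !pred_pos)
  sp <- scores[pos]; sn <- scores[!pos]
  cmp <- outer(sp, sn, `-`)
  auc <- (sum(cmp > 0) + 0.5 * sum(cmp == 0)) / (length(sp) * length(sn))
  out <- list(Acc = (TP + TN) / (TP + FP + TN + FN),
              Pre = if (TP + FP > 0) TP / (TP + FP) else 0,
              Rec = if (TP + FN > 0) TP / (TP + FN) else 0,
              F1 = if (2 * TP + FN + FP > 0) 2 * TP / (2 * TP + FN + FP)
                   else 0,
              AUC = auc, TP = TP, FP = FP, TN = TN, FN = FN,
              M = length(sp), N = length(sn))
  class(out) <- "classif_metrics"
  out
}

#' @export
print.classif_metrics <- function(x, ...) {
  cat(sprintf("Acc %.4f | Pre %.4f | Rec %.4f | F1 %.4f | AUC %.4f\n",
              x$Acc, x$Pre, x$Rec, x$F1, x$AUC))
  invisible(x)
}

#' Quantitative metric report for a real/generated pair
#'
#' Convenience wrapper computing the Mode Score and sliced Wasserstein
#' distance for one pair of containers with one frozen classifier.
#'
#' @param clf an [eval_classifier].
#' @param real,fake [eeg_epochs] objects.
#' @param n_proj,seed passed to [sliced_wasserstein()].
#' @return list of class `metric_report` with `MS`, `SWD`, `n_projections`,
#'   `seed`, and the classifier provenance.
#' @export
metric_report <- function(clf, real, fake, n_proj = 128L, seed = 1L) {
  structure(list(MS = mode_score(clf, real, fake),
                 SWD = sliced_wasserstein(real, fake, n_proj, seed),
                 n_projections = n_proj, seed = seed,
                 clf_seed = clf$seed,
                 clf_fingerprint = clf$data_fingerprint),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf("<metric_report> MS = %.4f (diversity), SWD = %.4f (similarity)\n",
              x$MS, x$SWD))
  invisible(x)
}
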