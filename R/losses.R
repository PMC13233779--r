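#' Three-point curvature of a sampled trace
#'
#' Estimates the local curvature at every interior sample of a uniformly
#' sampled trace by passing a parametric quadratic
#' `x(t) = a1 + a2 t + a3 t^2`, `y(t) = b1 + b2 t + b3 t^2` through each
#' triple of consecutive points with `t in {-1, 0, 1}` and `x` the sample
#' abscissa (so `a2 = dx`, `a3 = 0`), and evaluating
#' `k = |2 (a3 b2 - a2 b3)| / (a2^2 + b2^2)^(3/2)`
#' at the middle point. The absolute value makes `k` a magnitude, as a
#' curvature must be for the binary cross-entropy built on top of it.
#' With the three points collinear, `k = 0` exactly; as the sample spacing
#' of a smooth curve shrinks, `k` converges to the osculating-circle
#' curvature `1/r`.
#'
#' @param trace numeric vector, length >= 3 (uniform sampling assumed).
#' @param dx abscissa spacing between consecutive samples (default 1:
#'   curvature in per-sample-index units, the convention used by the
#'   time-domain regularizer).
#' @return numeric vector of length `length(trace) - 2`, the nonnegative
#'   curvature at each interior sample.
#' @examples
#' three_point_curvature(c(1, 0, 1))  # parabola: 2
#' max(three_point_curvature(seq(0, 5, by = 0.5)))  # collinear: 0
#' @export
three_point_curvature <- function(trace, dx = 1) {
  if (!is.numeric(trace) || length(trace) < 3)
    stop("`trace` must be numeric with length >= 3")
  if (!all(is.finite(trace))) stop("`trace` contains non-finite values")
  n <- length(trace)
  ym <- trace[1:(n - 2)]; y0 <- trace[2:(n - 1)]; yp <- trace[3:n]
  b2 <- (yp - ym) / 2
  b3 <- (yp + ym - 2 * y0) / 2
  2 * dx * abs(b3) / (dx^2 + b2^2)^1.5
}

#' Squash curvature into the unit interval
#'
#' Maps a nonnegative curvature `k` through `k / (1 + k)` and clips to
#' `[eps, 1 - eps]`, producing arguments valid for a binary cross-entropy.
#' The map is monotone, so curvature ordering is preserved.
#'
#' @param k nonnegative numeric vector (curvatures).
#' @param eps clip margin (default 1e-7).
#' @return values in `[eps, 1 - eps]`.
#' @export
squash_curvature <- function(k, eps = 1e-7) {
  if (any(k < 0)) stop("`k` must be nonnegative")
  pmin(pmax(k / (1 + k), eps), 1 - eps)
}

# curvature profile of a batch: [n, C, T] -> [n, C, T-2], squashed
batch_squashed_curvature <- function(batch, eps = 1e-7) {
  d <- dim(batch)
  out <- array(0, c(d[1L], d[2L], d[3L] - 2L))
  for (i in seq_len(d[1L]))
    for (ch in seq_len(d[2L]))
      out[i, ch, ] <- squash_curvature(
        three_point_curvature(batch[i, ch, ]), eps)
  out
}

as_batch_array <- function(x) {
  if (inherits(x, "eeg_epochs")) return(x$data)
  if (is.matrix(x)) return(array(x, c(nrow(x), 1L, ncol(x))))
  stopifnot(is.array(x), length(dim(x)) == 3L)
  x
}

#' Time-domain regularizer loss
#'
#' Binary cross-entropy between the squashed three-point curvature profiles
#' of a real and a generated batch, averaged over epochs, channels and
#' interior samples. Minimizing it (over the generated batch, for fixed real
#' statistics) pulls the generated curvature profile toward the real one,
#' improving time-domain similarity.
#'
#' @param real_batch,fake_batch [eeg_epochs] objects or
#'   `[n, channels, samples]` arrays of identical shape.
#' @param eps clip margin for the squashed curvatures.
#' @return scalar loss (>= 0).
#' @export
tr_loss <- function(real_batch, fake_batch, eps = 1e-7) {
  r <- as_batch_array(real_batch); f <- as_batch_array(fake_batch)
  if (!identical(dim(r), dim(f)))
    stop("real and fake batches must have identical shapes")
  kr <- batch_squashed_curvature(r, eps)
  kf <- batch_squashed_curvature(f, eps)
  -mean(kr * log(kf) + (1 - kr) * log(1 - kf))
}

#' Amplitude spectrum of a trace
#'
#' `F[k] = |sum_n x[n] exp(-i 2 pi k n / N)|` for `k = 0 .. N-1`, optionally
#' normalized to sum to one so the spectrum reads as a probability
#' distribution over frequency bins (the form consumed by the
#' frequency-domain regularizer).
#'
#' @param trace numeric vector, length >= 2.
#' @param normalize divide by the total amplitude (default `FALSE`).
#' @return nonnegative numeric vector of length `length(trace)`.
#' @examples
#' amplitude_spectrum(rep(2, 8))[1]  # N * |c| = 16 at DC
#' @export
amplitude_spectrum <- function(trace, normalize = FALSE) {
  if (length(trace) < 2) stop("`trace` must have length >= 2")
  if (!all(is.finite(trace))) stop("`trace` contains non-finite values")
  F <- Mod(stats::fft(trace))
  if (normalize) {
    s <- sum(F)
    if (s > 0) F <- F / s
  }
  F
}

# normalized spectra of a batch: [n, C, T] -> [n, C, T]
batch_norm_spectrum <- function(batch) {
  d <- dim(batch)
  out <- array(0, d)
  for (i in seq_len(d[1L]))
    for (ch in seq_len(d[2L]))
      out[i, ch, ] <- amplitude_spectrum(batch[i, ch, ], normalize = TRUE)
  out
}

#' Frequency-domain regularizer loss
#'
#' Binary cross-entropy between the batch-average normalized amplitude
#' spectrum of the real batch and the per-epoch normalized amplitude spectra
#' of the generated batch, averaged over epochs, channels and frequency
#' bins. Spectra are clipped to `[eps, 1 - eps]` before the logarithms.
#'
#' @inheritParams tr_loss
#' @param f_real optional precomputed real reference spectrum
#'   (`[channels, bins]` matrix, e.g. averaged over the whole training set);
#'   by default the average over `real_batch` (per-batch reference).
#' @return scalar loss (>= 0).
#' @export
fr_loss <- function(real_batch, fake_batch, eps = 1e-7, f_real = NULL) {
  r <- as_batch_array(real_batch); f <- as_batch_array(fake_batch)
  if (!identical(dim(r), dim(f)))
    stop("real and fake batches must have identical shapes")
  d <- dim(f)
  if (is.null(f_real)) {
    sr <- batch_norm_spectrum(r)
    f_real <- apply(sr, c(2, 3), mean)
  }
  fbar <- pmin(pmax(f_real, eps), 1 - eps)
  sf <- batch_norm_spectrum(f)
  sf <- pmin(pmax(sf, eps), 1 - eps)
  tot <- 0
  for (i in seq_len(d[1L]))
    tot <- tot + sum(fbar * log(sf[i, , ]) + (1 - fbar) * log(1 - sf[i, , ]))
  -tot / prod(d)
}

#' Average real reference spectrum
#'
#' Per-channel average of the normalized amplitude spectra of all epochs,
#' for use as a fixed whole-training-set reference in [fr_loss()].
#'
#' @param epochs an [eeg_epochs] object or `[n, channels, samples]` array.
#' @return `[channels, bins]` matrix.
#' @export
mean_norm_spectrum <- function(epochs) {
  apply(batch_norm_spectrum(as_batch_array(epochs)), c(2, 3), mean)
}

#' Latent-space dissimilarity ratio
#'
#' `ratio = (1 - cos(g1, g2)) / (1 - cos(z1, z2))`: the cosine dissimilarity
#' of two generated epochs relative to that of their latent inputs. With all
#' four vectors unit-normalized this equals
#' `||g1 - g2||^2 / ||z1 - z2||^2`, the squared-distance form used by the
#' gradient-norm bound.
#'
#' @param z1,z2 latent vectors (distinct directions required).
#' @param g1,g2 the corresponding generated epochs, flattened to vectors.
#' @return scalar ratio (>= 0).
#' @export
sr_ratio <- function(z1, z2, g1, g2) {
  den <- 1 - cos_sim(z1, z2)
  if (!is.finite(den) || den < 1e-12)
    stop("degenerate latent pair: z1 and z2 coincide after normalization")
  num <- 1 - cos_sim(g1, g2)
  num / den
}

cos_sim <- function(a, b) {
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) return(1)  # treat zero vectors as coincident
  sum(a * b) / (na * nb)
}

#' Latent-space regularizer loss
#'
#' Aggregates latent-space dissimilarity ratios into a loss. In the default
#' `"reciprocal"` (mode-seeking) direction, `L_SR = mean(1 / (ratio + eps))`,
#' so minimizing it pushes the ratios up: latent perturbations must produce
#' proportionally dissimilar outputs, counteracting mode collapse and
#' raising the generator's gradient norm. `"negative"` uses `-mean(ratio)`
#' (same direction, unbounded); `"literal"` is `+mean(ratio)` (the combined
#' objective read verbatim, kept for fidelity experiments — minimizing it
#' reduces diversity).
#'
#' @param ratios numeric vector of ratios from [sr_ratio()] (>= 1 value).
#' @param mode `"reciprocal"` (default), `"negative"` or `"literal"`.
#' @param eps stabilizer for the reciprocal mode.
#' @return scalar loss.
#' @export
sr_loss <- function(ratios, mode = c("reciprocal", "negative", "literal"),
                    eps = 1e-8) {
  if (length(ratios) < 1) stop("`ratios` must contain at least one value")
  mode <- match.arg(mode)
  switch(mode,
         reciprocal = mean(1 / (ratios + eps)),
         negative = -mean(ratios),
         literal = mean(ratios))
}

#' Regularizer weights
#'
#' The single trade-off weight `lambda` of the combined generator objective
#' and the direction convention of the latent-space term.
#'
#' @param lam trade-off weight, strictly inside (0, 1). `lam` tunes
#'   similarity (frequency/time terms, weight `1 - lam`) against diversity
#'   (latent term, weight `lam`); 0.6 is the value selected by the
#'   delta-sum rule of [lambda_grid_select()].
#' @param sr_mode direction convention for [sr_loss()].
#' @return an object of class `regularizer_weights`.
#' @export
regularizer_weights <- function(lam = 0.6,
                                sr_mode = c("reciprocal", "negative",
                                            "literal")) {
  if (!is.numeric(lam) || length(lam) != 1 || lam <= 0 || lam >= 1)
    stop("`lam` must lie strictly inside (0, 1)")
  structure(list(lam = lam, sr_mode = match.arg(sr_mode)),
            class = "regularizer_weights")
}

#' Combined generator objective
#'
#' `L_G_final = L_G + lam * L_SR + (1 - lam) * (0.5 * L_FR + 0.5 * L_TR)`:
#' the adversarial generator loss plus the metacognitive regulation terms,
#' balanced by the single trade-off weight.
#'
#' @param L_G adversarial generator loss.
#' @param L_TR time-domain regularizer loss.
#' @param L_FR frequency-domain regularizer loss.
#' @param L_SR latent-space regularizer loss.
#' @param weights a [regularizer_weights] object (or bare `lam` scalar).
#' @return an object of class `loss_breakdown` with fields `L_G`, `L_TR`,
#'   `L_FR`, `L_SR`, `L_G_final`, `lam`.
#' @examples
#' combined_generator_loss(0, 1, 1, 1, regularizer_weights(0.6))$L_G_final
#' @export
combined_generator_loss <- function(L_G, L_TR, L_FR, L_SR, weights) {
  if (is.numeric(weights)) weights <- regularizer_weights(weights)
  stopifnot(inherits(weights, "regularizer_weights"))
  vals <- c(L_G, L_TR, L_FR, L_SR)
  if (!all(is.finite(vals))) stop("loss terms must all be finite")
  lam <- weights$lam
  structure(list(L_G = L_G, L_TR = L_TR, L_FR = L_FR, L_SR = L_SR,
                 L_G_final = L_G + lam * L_SR +
                   (1 - lam) * (0.5 * L_FR + 0.5 * L_TR),
                 lam = lam),
            class = "loss_breakdown")
}

#' @export
print.loss_breakdown <- function(x, ...) {
  cat(sprintf(
    "<loss_breakdown> L_G = %.6g | TR = %.6g | FR = %.6g | SR = %.6g\n",
    x$L_G, x$L_TR, x$L_FR, x$L_SR))
  cat(sprintf("  combined (lambda = %.3g): %.6g\n", x$lam, x$L_G_final))
  invisible(x)
}

## ---- analytic gradients used by the trainers (internal) -----------------

# gradient of tr_loss wrt the fake batch, [n, C, T]
tr_loss_grad <- function(real_batch, fake_batch, eps = 1e-7) {
  r <- as_batch_array(real_batch); f <- as_batch_array(fake_batch)
  d <- dim(f)
  M <- d[1L] * d[2L] * (d[3L] - 2L)
  grad <- array(0, d)
  for (i in seq_len(d[1L])) for (ch in seq_len(d[2L])) {
    y <- f[i, ch, ]
    n <- d[3L]
    ym <- y[1:(n - 2)]; y0 <- y[2:(n - 1)]; yp <- y[3:n]
    b2 <- (yp - ym) / 2
    b3 <- (yp + ym - 2 * y0) / 2
    den <- (1 + b2^2)
    k <- 2 * abs(b3) / den^1.5
    s_raw <- k / (1 + k)
    clipped <- s_raw < eps | s_raw > 1 - eps
    s <- pmin(pmax(s_raw, eps), 1 - eps)
    sr <- squash_curvature(three_point_curvature(r[i, ch, ]), eps)
    dL_ds <- -(sr / s - (1 - sr) / (1 - s)) / M
    dL_ds[clipped] <- 0
    ds_dk <- 1 / (1 + k)^2
    dL_dk <- dL_ds * ds_dk
    dk_db3 <- 2 * sign(b3) / den^1.5
    dk_db2 <- -6 * abs(b3) * b2 / den^2.5
    dL_db3 <- dL_dk * dk_db3
    dL_db2 <- dL_dk * dk_db2
    g <- numeric(n)
    idx <- seq_len(n - 2L)
    # b2 = (y[j+2] - y[j]) / 2 ; b3 = (y[j+2] + y[j] - 2 y[j+1]) / 2
    add_at <- function(g, at, v) { g[at] <- g[at] + v; g }
    g <- add_at(g, idx,      -dL_db2 / 2 + dL_db3 / 2)
    g <- add_at(g, idx + 1L, -dL_db3)
    g <- add_at(g, idx + 2L,  dL_db2 / 2 + dL_db3 / 2)
    grad[i, ch, ] <- g
  }
  grad
}

# gradient of fr_loss wrt the fake batch, [n, C, T]
fr_loss_grad <- function(real_batch, fake_batch, eps = 1e-7, f_real = NULL) {
  r <- as_batch_array(real_batch); f <- as_batch_array(fake_batch)
  d <- dim(f)
  if (is.null(f_real)) f_real <- mean_norm_spectrum(r)
  fbar <- pmin(pmax(f_real, eps), 1 - eps)
  M <- prod(d)
  grad <- array(0, d)
  for (i in seq_len(d[1L])) for (ch in seq_len(d[2L])) {
    x <- f[i, ch, ]
    X <- stats::fft(x)
    Fm <- Mod(X)
    S <- sum(Fm)
    if (S == 0) next
    fr <- Fm / S
    clipped <- fr < eps | fr > 1 - eps
    frc <- pmin(pmax(fr, eps), 1 - eps)
    dL_df <- -(fbar[ch, ] / frc - (1 - fbar[ch, ]) / (1 - frc)) / M
    dL_df[clipped] <- 0
    # f = F / S  =>  dL/dF_m = dL/df_m / S - sum_k(dL/df_k * f_k) / S
    dL_dF <- dL_df / S - sum(dL_df * fr) / S
    dirn <- ifelse(Fm > 0, 1, 0) * dL_dF
    u <- dirn * Conj(X) / ifelse(Fm > 0, Fm, 1)
    # dF_m/dx_n = Re(conj(X_m)/|X_m| * exp(-i 2 pi m n / N))
    grad[i, ch, ] <- Re(stats::fft(u))
  }
  grad
}

# gradients of the SR loss wrt the flattened generated pair members.
# g1, g2: matrices [n_pairs, p]; z-ratios denominator precomputed.
# returns list(loss, ratios, g1_grad, g2_grad)
sr_loss_grad <- function(z1, z2, g1, g2, mode = "reciprocal", eps = 1e-8) {
  np <- nrow(g1)
  ratios <- numeric(np)
  g1g <- matrix(0, np, ncol(g1)); g2g <- matrix(0, np, ncol(g2))
  for (p in seq_len(np)) {
    den <- 1 - cos_sim(z1[p, ], z2[p, ])
    a <- g1[p, ]; b <- g2[p, ]
    na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
    if (den < 1e-12 || na == 0 || nb == 0) { ratios[p] <- 0; next }
    cth <- sum(a * b) / (na * nb)
    rho <- (1 - cth) / den
    ratios[p] <- rho
    dL_drho <- switch(mode,
                      reciprocal = -1 / (rho + eps)^2,
                      negative = -1,
                      literal = 1) / np
    drho_dc <- -1 / den
    dc_da <- b / (na * nb) - cth * a / na^2
    dc_db <- a / (na * nb) - cth * b / nb^2
    g1g[p, ] <- dL_drho * drho_dc * dc_da
    g2g[p, ] <- dL_drho * drho_dc * dc_db
  }
  loss <- switch(mode,
                 reciprocal = mean(1 / (ratios + eps)),
                 negative = -mean(ratios),
                 literal = mean(ratios))
  list(loss = loss, ratios = ratios, g1_grad = g1g, g2_grad = g2g)
}
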