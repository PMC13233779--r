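#' Network configuration for the adversarial trainers
#'
#' Reduced-scale architectures sized for CPU experiments: a 4-layer 1-D
#' transposed-convolution generator with matching strided-convolution critic
#' for `"wavegan_lite"`, and multilayer-perceptron pairs for `"wgan_gp"` /
#' `"cwgan_gp"`. Generators end in a tanh head, so they emit traces in
#' `[-1, 1]` and expect MaxAbs-scaled training data.
#'
#' @param latent_dim latent (noise) dimensionality.
#' @param n_channels,n_samples output epoch shape. `wavegan_lite` requires
#'   `n_samples` divisible by 16 (four stride-2 upsampling stages).
#' @param widths hidden widths: channel widths of the four generator
#'   deconvolution stages for `wavegan_lite` (default `c(32, 16, 8, 4)`),
#'   or the two hidden MLP widths otherwise (default `c(128, 128)`).
#' @param kernel convolution kernel length (`wavegan_lite`).
#' @param conditional condition generator and critic on class labels.
#' @param n_classes number of classes for the conditional variant.
#' @return an object of class `net_config`.
#' @export
net_config <- function(latent_dim = 16, n_channels = 1, n_samples = 256,
                       widths = NULL, kernel = 9, conditional = FALSE,
                       n_classes = 0) {
  structure(list(latent_dim = latent_dim, n_channels = n_channels,
                 n_samples = n_samples, widths = widths, kernel = kernel,
                 conditional = conditional, n_classes = n_classes),
            class = "net_config")
}

onehot <- function(idx, n) {
  m <- matrix(0, length(idx), n)
  m[cbind(seq_along(idx), idx)] <- 1
  m
}

build_nets <- function(variant, cfg) {
  p <- cfg$n_channels * cfg$n_samples
  extra <- if (cfg$conditional) cfg$n_classes else 0L
  if (variant == "wavegan_lite") {
    if (cfg$conditional)
      stop("wavegan_lite is unconditional; use cwgan_gp for labels")
    if (cfg$n_samples %% 16L != 0L)
      stop("wavegan_lite needs n_samples divisible by 16")
    w <- if (is.null(cfg$widths)) c(32L, 16L, 8L, 4L) else cfg$widths
    t0 <- cfg$n_samples %/% 16L
    k <- cfg$kernel
    gen <- list(
      nn_dense(cfg$latent_dim, w[1L] * t0), nn_lrelu(),
      nn_reshape_ct(w[1L], t0),
      nn_tconv1d(w[1L], w[2L], k, 2L), nn_lrelu(),
      nn_tconv1d(w[2L], w[3L], k, 2L), nn_lrelu(),
      nn_tconv1d(w[3L], w[4L], k, 2L), nn_lrelu(),
      nn_tconv1d(w[4L], cfg$n_channels, k, 2L), nn_tanh())
    cw <- pmax(w %/% 2L, 4L)
    critic <- list(
      nn_conv1d(cfg$n_channels, cw[4L], k, 2L), nn_lrelu(),
      nn_conv1d(cw[4L], cw[3L], k, 2L), nn_lrelu(),
      nn_conv1d(cw[3L], cw[2L], k, 2L), nn_lrelu(),
      nn_conv1d(cw[2L], cw[1L], k, 2L), nn_lrelu(),
      nn_flatten(), nn_dense(cw[1L] * t0, 1L))
  } else {
    w <- if (is.null(cfg$widths)) c(128L, 128L) else cfg$widths
    gen <- list(
      nn_dense(cfg$latent_dim + extra, w[1L]), nn_lrelu(),
      nn_dense(w[1L], w[2L]), nn_lrelu(),
      nn_dense(w[2L], p), nn_tanh(),
      nn_reshape_ct(cfg$n_channels, cfg$n_samples))
    critic <- list(
      nn_dense(p + extra, w[1L]), nn_lrelu(),
      nn_dense(w[1L], max(w[2L] %/% 2L, 8L)), nn_lrelu(),
      nn_dense(max(w[2L] %/% 2L, 8L), 1L))
  }
  list(gen = gen, critic = critic)
}

flatten_batch <- function(X) matrix(X, dim(X)[1L], prod(dim(X)[2:3]))

# critic input for a data batch (conv critics take the array; MLP critics a
# flattened matrix, with the label one-hot appended when conditional)
critic_input <- function(variant, X, oh = NULL) {
  if (variant == "wavegan_lite") return(X)
  Xm <- flatten_batch(X)
  if (!is.null(oh)) Xm <- cbind(Xm, oh) else Xm
}

#' WGAN gradient penalty
#'
#' Mean over random interpolates `xhat = u * real + (1 - u) * fake`
#' (`u` uniform per sample) of `(||grad_xhat critic(xhat)|| - 1)^2`, the
#' penalty that pushes the critic toward a 1-Lipschitz function.
#'
#' @param critic a critic network (from a fitted [mrm_gan] model via
#'   `model$critic_net`, or built internally).
#' @param real_batch,fake_batch `[n, channels, samples]` arrays or
#'   [eeg_epochs] of identical shape.
#' @param seed optional seed for the interpolation weights.
#' @return scalar penalty.
#' @export
gradient_penalty <- function(critic, real_batch, fake_batch, seed = NULL) {
  if (inherits(critic, "mrm_gan")) critic <- critic$critic_net
  r <- as_batch_array(real_batch); f <- as_batch_array(fake_batch)
  if (!identical(dim(r), dim(f)))
    stop("real and fake batches must have identical shapes")
  if (!is.null(seed)) {
    old <- get0(".Random.seed", globalenv(), inherits = FALSE)
    on.exit(restore_rng(old), add = TRUE)
    set.seed(as.integer(seed))
  }
  B <- dim(r)[1L]
  u <- stats::runif(B)
  xhat <- array(0, dim(r))
  for (i in seq_len(B)) xhat[i, , ] <- u[i] * r[i, , ] + (1 - u[i]) * f[i, , ]
  Xin <- if (critic[[1L]]$type == "dense") flatten_batch(xhat) else xhat
  gp_value_and_grads(critic, Xin)$gp
}

#' Fit an adversarially regularized EEG generator
#'
#' Trains a reduced-scale Wasserstein GAN with gradient penalty on epoched
#' EEG, with the metacognitive regulation terms added to the generator
#' objective: the combined loss is
#' `L_G + lam * L_SR + (1 - lam) * (0.5 * L_FR + 0.5 * L_TR)`,
#' where `L_G` is the adversarial term, `L_TR`/`L_FR` the curvature and
#' amplitude-spectrum similarity regularizers and `L_SR` the latent-space
#' diversity regularizer. Training alternates `critic_steps` critic updates
#' with one generator update (Adam for both) and is deterministic given
#' `seed`.
#'
#' @param data an [eeg_epochs] object scaled to `[-1, 1]` (see
#'   [maxabs_scale()]); the generators end in tanh heads.
#' @param variant `"wavegan_lite"` (1-D convolutional), `"wgan_gp"` (MLP) or
#'   `"cwgan_gp"` (label-conditional MLP).
#' @param weights a [regularizer_weights] object (trade-off weight and
#'   latent-term direction).
#' @param terms which regulation terms to apply; default all three. An empty
#'   character vector trains the plain base variant.
#' @param steps generator updates to run.
#' @param batch_size minibatch size (even, so latent pairs can be formed).
#' @param critic_steps critic updates per generator update.
#' @param lr Adam learning rate (both networks; betas 0.5 / 0.9).
#' @param gp_coef gradient-penalty coefficient.
#' @param net a [net_config]; defaults are derived from `data`.
#' @param f_real_scope `"batch"` (reference spectrum from each minibatch) or
#'   `"global"` (fixed average over the whole training set).
#' @param seed integer seed controlling all randomness of the run.
#' @param verbose print a progress line every 100 steps.
#' @param reg_multiplier scales the regulation contribution to the
#'   generator update (normally 1; 0 runs the regulation code path while
#'   nulling its effect, which must reproduce a plain run exactly).
#' @return an object of class `mrm_gan` with the trained generator/critic,
#'   per-step loss history (`$history`), optimizer and RNG state (so
#'   [mrm_gan_resume()] continues bit-identically), and sampling metadata.
#' @seealso [simulate.mrm_gan()], [mrm_gan_resume()], [sr_bound_check()]
#' @export
mrm_gan <- function(data,
                    variant = c("wavegan_lite", "wgan_gp", "cwgan_gp"),
                    weights = regularizer_weights(0.6),
                    terms = c("tr", "fr", "sr"),
                    steps = 500L, batch_size = 64L, critic_steps = 5L,
                    lr = 1e-4, gp_coef = 10, net = NULL,
                    f_real_scope = c("batch", "global"),
                    seed = 1L, verbose = FALSE, reg_multiplier = 1) {
  stopifnot(inherits(data, "eeg_epochs"))
  variant <- match.arg(variant)
  f_real_scope <- match.arg(f_real_scope)
  if (is.numeric(weights)) weights <- regularizer_weights(weights)
  stopifnot(inherits(weights, "regularizer_weights"))
  terms <- unique(as.character(terms))
  if (!all(terms %in% c("tr", "fr", "sr")))
    stop("`terms` must be a subset of c(\"tr\", \"fr\", \"sr\")")
  d <- dim(data$data)
  if (max(abs(data$data)) > 1 + 1e-6)
    warning("data exceeds [-1, 1]; apply maxabs_scale() before training")
  if (batch_size %% 2L != 0L) stop("batch_size must be even")
  cond <- variant == "cwgan_gp"
  class_levels <- sort(unique(data$labels))
  if (is.null(net))
    net <- net_config(n_channels = d[2L], n_samples = d[3L],
                      conditional = cond,
                      n_classes = if (cond) length(class_levels) else 0)
  if (cond && net$n_classes < 2L)
    stop("cwgan_gp needs >= 2 classes in the training labels")
  old_rng <- get0(".Random.seed", globalenv(), inherits = FALSE)
  on.exit(restore_rng(old_rng), add = TRUE)
  set.seed(as.integer(seed))
  nets <- build_nets(variant, net)
  state <- list(
    variant = variant, net = net, weights = weights, terms = terms,
    batch_size = as.integer(batch_size), critic_steps = as.integer(critic_steps),
    lr = lr, gp_coef = gp_coef, f_real_scope = f_real_scope,
    seed = as.integer(seed),
    generator_net = nn_init(nets$gen), critic_net = nn_init(nets$critic),
    opt_g = adam_new(nets$gen, lr = lr), opt_d = adam_new(nets$critic, lr = lr),
    step = 0L, history = NULL, aborted = FALSE,
    fs = data$fs, channel_names = data$channel_names, time0 = data$time0,
    class_levels = class_levels,
    f_real = if (f_real_scope == "global") mean_norm_spectrum(data) else NULL)
  class(state) <- "mrm_gan"
  state <- train_steps(state, data, as.integer(steps), verbose,
                       reg_multiplier = reg_multiplier)
  state$rng_state <- get(".Random.seed", globalenv())
  state
}

# runs the full regulation code path with its contribution multiplied by
# zero; used to verify that the MRM terms vanish exactly (loss history and
# final weights bit-identical to a run whose code path never computes them)
mrm_gan_zeroed <- function(data, variant, ...) {
  mrm_gan(data, variant, terms = c("tr", "fr", "sr"), ...,
          reg_multiplier = 0)
}

# core loop; `reg_multiplier` scales the regulation contribution (the
# zero-weight reduction test uses 0, which must reproduce the plain run
# bit-for-bit: the loop consumes the RNG identically whatever the terms).
train_steps <- function(state, data, steps, verbose = FALSE,
                        reg_multiplier = 1) {
  X <- data$data
  d <- dim(X)
  n <- d[1L]
  B <- state$batch_size
  half <- B %/% 2L
  cond <- state$net$conditional
  lam <- state$weights$lam
  sr_mode <- state$weights$sr_mode
  gp_select <- NULL
  if (cond)
    gp_select <- seq_len(d[2L] * d[3L])   # penalize only the data part
  hist_rows <- vector("list", steps)
  lab_idx <- match(data$labels, state$class_levels)
  G <- state$generator_net; D <- state$critic_net
  opt_g <- state$opt_g; opt_d <- state$opt_d
  use_tr <- "tr" %in% state$terms
  use_fr <- "fr" %in% state$terms
  use_sr <- "sr" %in% state$terms
  any_reg <- use_tr || use_fr || use_sr
  for (s in seq_len(steps)) {
    prevG <- G; prevD <- D; prev_og <- opt_g; prev_od <- opt_d
    loss_c <- NA_real_; gp_val <- NA_real_
    for (j in seq_len(state$critic_steps)) {
      idx <- sample.int(n, B, replace = TRUE)
      real <- X[idx, , , drop = FALSE]
      z <- matrix(stats::rnorm(B * state$net$latent_dim), B)
      oh <- if (cond) onehot(lab_idx[idx], state$net$n_classes) else NULL
      gin <- if (cond) cbind(z, oh) else z
      fake <- nn_forward(G, gin, keep = FALSE)$Y
      # fake and real share one critic pass (rows 1..B fake, B+1..2B real)
      both <- abind3(fake, real)
      ohb <- if (cond) rbind(oh, oh) else NULL
      fwb <- nn_forward(D, critic_input(state$variant, both, ohb))
      gb <- nn_backward(D, fwb$caches,
                        matrix(c(rep(1 / B, B), rep(-1 / B, B)), 2L * B,
                               1L))$grads
      u <- stats::runif(B)
      ua <- array(u, d2 <- dim(real))
      xhat <- real * ua + fake * (1 - ua)
      xin <- critic_input(state$variant, xhat, oh)
      gpg <- gp_value_and_grads(D, xin, gp_select)
      gp_val <- gpg$gp
      loss_c <- mean(fwb$Y[seq_len(B), ]) - mean(fwb$Y[B + seq_len(B), ]) +
        state$gp_coef * gpg$gp
      upd <- adam_step(D, opt_d,
                       list(gb, grads_scale(gpg$grads, state$gp_coef)))
      D <- upd$net; opt_d <- upd$opt
    }
    # generator update
    idx <- sample.int(n, B, replace = TRUE)   # real reference batch
    real <- X[idx, , , drop = FALSE]
    z <- matrix(stats::rnorm(B * state$net$latent_dim), B)
    oh <- if (cond) onehot(lab_idx[idx], state$net$n_classes) else NULL
    gin <- if (cond) cbind(z, oh) else z
    fwg <- nn_forward(G, gin)
    fake <- fwg$Y
    fin <- critic_input(state$variant, fake, oh)
    fwf <- nn_forward(D, fin)
    L_G <- -mean(fwf$Y)
    dcrit <- nn_backward(D, fwf$caches, matrix(-1 / B, B, 1L),
                         want_param_grads = FALSE)$dX
    dfake <- if (state$variant == "wavegan_lite") dcrit else
      array(dcrit[, seq_len(d[2L] * d[3L])], c(B, d[2L], d[3L]))
    L_TR <- NA_real_; L_FR <- NA_real_; L_SR <- NA_real_
    if (any_reg) {
      reg_grad <- array(0, dim(fake))
      if (use_tr) {
        L_TR <- tr_loss(real, fake)
        reg_grad <- reg_grad + (1 - lam) * 0.5 * tr_loss_grad(real, fake)
      }
      if (use_fr) {
        L_FR <- fr_loss(real, fake, f_real = state$f_real)
        reg_grad <- reg_grad +
          (1 - lam) * 0.5 * fr_loss_grad(real, fake, f_real = state$f_real)
      }
      if (use_sr) {
        g1 <- flatten_batch(fake[seq_len(half), , , drop = FALSE])
        g2 <- flatten_batch(fake[half + seq_len(half), , , drop = FALSE])
        sg <- sr_loss_grad(z[seq_len(half), , drop = FALSE],
                           z[half + seq_len(half), , drop = FALSE],
                           g1, g2, sr_mode)
        L_SR <- sg$loss
        reg_grad[seq_len(half), , ] <-
          reg_grad[seq_len(half), , , drop = FALSE] +
          lam * array(sg$g1_grad, c(half, d[2L], d[3L]))
        reg_grad[half + seq_len(half), , ] <-
          reg_grad[half + seq_len(half), , , drop = FALSE] +
          lam * array(sg$g2_grad, c(half, d[2L], d[3L]))
      }
      dfake <- dfake + reg_multiplier * reg_grad
    }
    ggr <- nn_backward(G, fwg$caches, dfake)$grads
    upd <- adam_step(G, opt_g, list(ggr))
    G <- upd$net; opt_g <- upd$opt
    total <- L_G +
      (if (any_reg) reg_multiplier *
         (lam * ifelse(use_sr, L_SR, 0) +
          (1 - lam) * (0.5 * ifelse(use_fr, L_FR, 0) +
                       0.5 * ifelse(use_tr, L_TR, 0))) else 0)
    state$step <- state$step + 1L
    hist_rows[[s]] <- data.frame(
      step = state$step, L_G = L_G, L_TR = L_TR, L_FR = L_FR, L_SR = L_SR,
      L_G_final = total, critic_loss = loss_c, gp = gp_val)
    bad <- !is.finite(L_G) ||
      (state$critic_steps > 0L && !is.finite(loss_c)) ||
      (any_reg && reg_multiplier != 0 &&
       !all(is.finite(c(L_TR, L_FR, L_SR)[c(use_tr, use_fr, use_sr)])))
    if (bad) {
      warning(sprintf("non-finite loss at step %d; reverting to step %d",
                      state$step, state$step - 1L))
      G <- prevG; D <- prevD; opt_g <- prev_og; opt_d <- prev_od
      state$step <- state$step - 1L
      state$aborted <- TRUE
      hist_rows[[s]] <- NULL
      break
    }
    if (verbose && s %% 100L == 0L)
      message(sprintf("step %d: L_G=%.4f critic=%.4f", state$step, L_G,
                      loss_c))
  }
  state$generator_net <- G; state$critic_net <- D
  state$opt_g <- opt_g; state$opt_d <- opt_d
  new_hist <- do.call(rbind, hist_rows[!vapply(hist_rows, is.null, TRUE)])
  state$history <- rbind(state$history, new_hist)
  state
}

#' Resume training from a fitted model
#'
#' Continues the alternating updates from the stored optimizer and RNG
#' state; a run interrupted at step `k` and resumed for `m` steps reproduces
#' the loss history of an uninterrupted `k + m`-step run bit-identically.
#'
#' @param model a fitted [mrm_gan] object.
#' @param data the same training [eeg_epochs] the model was fitted on.
#' @param steps additional generator updates.
#' @param verbose print progress.
#' @return the updated `mrm_gan` object.
#' @export
mrm_gan_resume <- function(model, data, steps, verbose = FALSE) {
  stopifnot(inherits(model, "mrm_gan"), inherits(data, "eeg_epochs"))
  old_rng <- get0(".Random.seed", globalenv(), inherits = FALSE)
  on.exit(restore_rng(old_rng), add = TRUE)
  assign(".Random.seed", model$rng_state, envir = globalenv())
  model <- train_steps(model, data, as.integer(steps), verbose,
                       reg_multiplier = 1)
  model$rng_state <- get(".Random.seed", globalenv())
  model
}

#' Draw generated epochs from a fitted model
#'
#' @param model a fitted [mrm_gan] object.
#' @param n number of epochs to draw (0 gives an empty container).
#' @param labels class labels for the conditional variant (recycled);
#'   supplying labels to an unconditional model is an error. Conditional
#'   draws echo the labels in the returned container; unconditional draws
#'   carry `NA` labels.
#' @param seed optional seed for the latent draws (global RNG restored).
#' @return an [eeg_epochs] object of generated epochs.
#' @export
gan_sample <- function(model, n, labels = NULL, seed = NULL) {
  stopifnot(inherits(model, "mrm_gan"))
  cond <- model$net$conditional
  if (!cond && !is.null(labels))
    stop("labels supplied to an unconditional model")
  if (!is.null(seed)) {
    old <- get0(".Random.seed", globalenv(), inherits = FALSE)
    on.exit(restore_rng(old), add = TRUE)
    set.seed(as.integer(seed))
  }
  d_ch <- model$net$n_channels; d_t <- model$net$n_samples
  if (n == 0L)
    return(eeg_epochs(array(0, c(0L, d_ch, d_t)), integer(0), model$fs,
                      model$channel_names, model$time0))
  z <- matrix(stats::rnorm(n * model$net$latent_dim), n)
  if (cond) {
    if (is.null(labels))
      labels <- model$class_levels[1L + (seq_len(n) - 1L) %%
                                     length(model$class_levels)]
    labels <- rep_len(labels, n)
    li <- match(labels, model$class_levels)
    if (anyNA(li)) stop("unknown label(s); model classes: ",
                        paste(model$class_levels, collapse = ", "))
    gin <- cbind(z, onehot(li, model$net$n_classes))
  } else {
    labels <- rep(NA_integer_, n)
    gin <- z
  }
  Y <- nn_forward(model$generator_net, gin, keep = FALSE)$Y
  eeg_epochs(Y, labels, model$fs, model$channel_names, model$time0)
}

#' @export
#' @rdname gan_sample
#' @param object,nsim,... standard [stats::simulate()] arguments; `nsim` is
#'   the number of epochs.
simulate.mrm_gan <- function(object, nsim = 1, seed = NULL, labels = NULL,
                             ...) {
  gan_sample(object, nsim, labels = labels, seed = seed)
}

#' @export
print.mrm_gan <- function(x, ...) {
  cat(sprintf("<mrm_gan> %s, %d generator steps%s\n", x$variant, x$step,
              if (x$aborted) " (aborted on non-finite loss)" else ""))
  cat(sprintf("  epochs: %d channels x %d samples @ %g Hz; latent dim %d\n",
              x$net$n_channels, x$net$n_samples, x$fs, x$net$latent_dim))
  cat(sprintf("  regulation: %s (lambda = %.3g, sr_mode = %s)\n",
              if (length(x$terms)) paste(toupper(x$terms), collapse = "+")
              else "none", x$weights$lam, x$weights$sr_mode))
  if (!is.null(x$history) && nrow(x$history) > 0) {
    tail1 <- x$history[nrow(x$history), ]
    cat(sprintf("  last step: L_G = %.4f, critic = %.4f\n",
                tail1$L_G, tail1$critic_loss))
  }
  invisible(x)
}

#' @export
summary.mrm_gan <- function(object, last = 50L, ...) {
  h <- object$history
  k <- max(1L, nrow(h) - last + 1L)
  tailh <- h[k:nrow(h), , drop = FALSE]
  out <- list(variant = object$variant, steps = object$step,
              terms = object$terms, lam = object$weights$lam,
              mean_losses = colMeans(tailh[, c("L_G", "L_TR", "L_FR",
                                               "L_SR", "critic_loss",
                                               "gp")], na.rm = TRUE),
              aborted = object$aborted)
  class(out) <- "summary.mrm_gan"
  out
}

#' @export
print.summary.mrm_gan <- function(x, ...) {
  cat(sprintf("mrm_gan %s: %d steps, terms %s, lambda %.3g%s\n",
              x$variant, x$steps,
              if (length(x$terms)) paste(x$terms, collapse = "+") else "none",
              x$lam, if (x$aborted) " [aborted]" else ""))
  cat("mean losses over the last window:\n")
  print(round(x$mean_losses, 4))
  invisible(x)
}

#' @export
plot.mrm_gan <- function(x, ...) {
  h <- x$history
  graphics::plot(h$step, h$L_G, type = "l", xlab = "generator step",
                 ylab = "loss", main = paste("mrm_gan", x$variant), ...)
  graphics::lines(h$step, h$critic_loss, lty = 2)
  if (any(is.finite(h$L_G_final)))
    graphics::lines(h$step, h$L_G_final, lty = 3)
  graphics::legend("topright", c("L_G", "critic", "L_G_final"),
                   lty = 1:3, bty = "n")
  invisible(x)
}

## ---- gradient-norm bound check ------------------------------------------

#' Check the latent regularizer's gradient-norm bound
#'
#' For unit-normalized latent pairs `z1, z2`, the latent-space
#' dissimilarity ratio of the output-normalized generator
#' `h(z) = G(z)/||G(z)||` is bounded by the squared path integral of the
#' directional Jacobian norm along the interpolation path
#' `gamma(t) = t z1 + (1 - t) z2`:
#' `ratio <= (int_0^1 ||J_h(gamma(t)) u|| dt)^2`, `u = (z1 - z2)/||z1 - z2||`.
#' The check evaluates both sides by `n_quad`-point trapezoid quadrature and
#' reports pairs violating the inequality beyond `tol * bound` — with a
#' correct generator implementation the count is zero (the inequality is a
#' theorem; quadrature error is absorbed by the tolerance).
#'
#' @param generator a fitted [mrm_gan] (unconditional), a raw generator
#'   network, or a `list(fn = function(z_matrix), jvp = function(z, v))`
#'   pair of closures mapping latent rows to flattened outputs and
#'   directional derivatives.
#' @param latent_dim latent dimensionality (required for closures; inferred
#'   otherwise).
#' @param n_pairs number of latent pairs.
#' @param n_quad quadrature points along each path.
#' @param seed RNG seed for the pairs.
#' @param tol relative violation tolerance.
#' @return an object of class `sr_bound_report`: data frame of
#'   `(ratio, bound)` plus the violation count.
#' @export
sr_bound_check <- function(generator, latent_dim = NULL, n_pairs = 100L,
                           n_quad = 128L, seed = 1L, tol = 1e-3) {
  if (inherits(generator, "mrm_gan")) {
    if (generator$net$conditional)
      stop("sr_bound_check supports unconditional generators")
    latent_dim <- generator$net$latent_dim
    net <- generator$generator_net
    fn <- function(zm) {
      flatten_batch(nn_forward(net, zm, keep = FALSE)$Y)
    }
    jvp <- function(zm, vm) {
      fw <- nn_forward(net, zm)
      flatten_batch(nn_jvp(net, fw$caches, vm))
    }
  } else if (is.list(generator) && !is.null(generator$fn)) {
    if (is.null(latent_dim)) stop("latent_dim required for closure generators")
    fn <- generator$fn; jvp <- generator$jvp
  } else if (is.list(generator) && !is.null(generator[[1L]]$type)) {
    net <- generator
    if (is.null(latent_dim)) {
      stopifnot(net[[1L]]$type == "dense")
      latent_dim <- nrow(net[[1L]]$W)
    }
    fn <- function(zm) flatten_batch2(nn_forward(net, zm, keep = FALSE)$Y)
    jvp <- function(zm, vm) {
      fw <- nn_forward(net, zm)
      flatten_batch2(nn_jvp(net, fw$caches, vm))
    }
  } else stop("unsupported generator object")
  old <- get0(".Random.seed", globalenv(), inherits = FALSE)
  on.exit(restore_rng(old), add = TRUE)
  set.seed(as.integer(seed))
  tgrid <- seq(0, 1, length.out = n_quad)
  wts <- rep(1 / (n_quad - 1), n_quad); wts[c(1L, n_quad)] <- wts[1L] / 2
  rows <- vector("list", n_pairs)
  resampled <- 0L
  for (p in seq_len(n_pairs)) {
    repeat {
      z1 <- stats::rnorm(latent_dim); z1 <- z1 / sqrt(sum(z1^2))
      z2 <- stats::rnorm(latent_dim); z2 <- z2 / sqrt(sum(z2^2))
      if (sum((z1 - z2)^2) > 1e-8) break
      resampled <- resampled + 1L
    }
    u <- (z1 - z2) / sqrt(sum((z1 - z2)^2))
    gam <- outer(tgrid, z1) + outer(1 - tgrid, z2)   # [n_quad, latent]
    gvals <- fn(gam)
    jv <- jvp(gam, matrix(u, n_quad, latent_dim, byrow = TRUE))
    gn <- sqrt(rowSums(gvals^2))
    ok <- gn > 1e-12
    # J_h v = Jv/||g|| - g (g . Jv)/||g||^3
    dots <- rowSums(gvals * jv)
    b <- numeric(n_quad)
    b[ok] <- sqrt(pmax(rowSums(jv^2)[ok] / gn[ok]^2 -
                         dots[ok]^2 / gn[ok]^4, 0))
    integral <- sum(wts * b)
    h1 <- gvals[n_quad, ]; h2 <- gvals[1L, ]
    n1 <- sqrt(sum(h1^2)); n2 <- sqrt(sum(h2^2))
    ratio <- if (n1 > 1e-12 && n2 > 1e-12)
      sum((h1 / n1 - h2 / n2)^2) / sum((z1 - z2)^2) else 0
    rows[[p]] <- c(ratio = ratio, bound = integral^2)
  }
  tab <- as.data.frame(do.call(rbind, rows))
  viol <- sum(tab$ratio > tab$bound * (1 + tol) + 1e-12)
  structure(list(pairs = tab, violations = viol, tol = tol,
                 n_quad = n_quad, resampled = resampled),
            class = "sr_bound_report")
}

flatten_batch2 <- function(Y) {
  if (is.matrix(Y)) Y else flatten_batch(Y)
}

#' @export
print.sr_bound_report <- function(x, ...) {
  cat(sprintf("<sr_bound_report> %d pairs, %d-point quadrature\n",
              nrow(x$pairs), x$n_quad))
  cat(sprintf("  violations of ratio <= bound (tol %g): %d\n",
              x$tol, x$violations))
  cat(sprintf("  ratio range: [%.4g, %.4g]; bound range: [%.4g, %.4g]\n",
              min(x$pairs$ratio), max(x$pairs$ratio),
              min(x$pairs$bound), max(x$pairs$bound)))
  invisible(x)
}
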