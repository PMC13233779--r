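# Minimal neural-network core used by the GAN trainers and the evaluation
# classifier: dense and 1-D (transposed) convolution layers, leaky-ReLU /
# tanh activations, reverse-mode gradients, forward-mode directional
# derivatives, and Adam. Everything is plain R arrays:
#   dense layers act on [batch, features] matrices,
#   conv layers act on [batch, channels, time] arrays.
# Critics are restricted to linear layers + leaky-ReLU, which makes the
# WGAN gradient-penalty double backprop exact (the activation's second
# derivative vanishes almost everywhere, so the input-gradient is a linear
# function of the parameters for fixed activation masks).

nn_dense <- function(n_in, n_out) {
  list(type = "dense",
       W = matrix(0, n_in, n_out), b = numeric(n_out))
}

nn_conv1d <- function(c_in, c_out, kernel, stride = 1L, pad = NULL) {
  if (is.null(pad)) pad <- (kernel - 1L) %/% 2L
  list(type = "conv1d", c_in = c_in, c_out = c_out, kernel = kernel,
       stride = as.integer(stride), pad = as.integer(pad),
       W = matrix(0, c_in * kernel, c_out), b = numeric(c_out))
}

# transposed convolution realized as zero-stuffing by `stride` followed by a
# stride-1 convolution; output length = stride * input length when
# kernel is even and pad = (kernel - stride) / 2 ... we instead fix the
# output length explicitly and centre-crop after the stride-1 conv.
nn_tconv1d <- function(c_in, c_out, kernel, stride = 2L) {
  list(type = "tconv1d", c_in = c_in, c_out = c_out, kernel = kernel,
       stride = as.integer(stride),
       W = matrix(0, c_in * kernel, c_out), b = numeric(c_out))
}

nn_lrelu <- function(alpha = 0.2) list(type = "lrelu", alpha = alpha)
nn_tanh <- function() list(type = "tanh")
nn_flatten <- function() list(type = "flatten")
nn_reshape_ct <- function(channels, time)
  list(type = "reshape_ct", channels = as.integer(channels),
       time = as.integer(time))

# He-style initialization, scaled for leaky-ReLU fan-in
nn_init <- function(net, gain = 1) {
  for (i in seq_along(net)) {
    ly <- net[[i]]
    if (!is.null(ly$W)) {
      fan_in <- nrow(ly$W)
      net[[i]]$W <- matrix(stats::rnorm(length(ly$W), 0,
                                        gain * sqrt(2 / fan_in)),
                           nrow(ly$W), ncol(ly$W))
    }
  }
  net
}

## ---- convolution primitives ----------------------------------------------
# lowered onto BLAS matrix products; the gathers/permutations live in
# src/conv.cpp

conv_fwd <- function(ly, X, bias = TRUE) {
  d <- dim(X)
  t_out <- (d[3L] + 2L * ly$pad - ly$kernel) %/% ly$stride + 1L
  Xcol <- im2col_cpp(X, d[1L], ly$c_in, d[3L], ly$kernel, ly$stride,
                     ly$pad, t_out)
  Y <- Xcol %*% ly$W
  if (bias) Y <- Y + rep(ly$b, each = nrow(Y))
  Y3 <- permute_out_cpp(Y, d[1L], t_out, ly$c_out)
  dim(Y3) <- c(d[1L], ly$c_out, t_out)
  list(Y = Y3, Xcol = Xcol, t_out = t_out, t_in = d[3L], B = d[1L])
}

conv_bwd <- function(ly, cache, dY) {
  dYmat <- permute_in_cpp(dY, cache$B, ly$c_out, cache$t_out)
  dW <- crossprod(cache$Xcol, dYmat)
  db <- colSums(dYmat)
  dXcol <- tcrossprod(dYmat, ly$W)
  dX <- col2im_cpp(dXcol, cache$B, ly$c_in, cache$t_in, ly$kernel,
                   ly$stride, ly$pad, cache$t_out)
  dim(dX) <- c(cache$B, ly$c_in, cache$t_in)
  list(dX = dX, dW = dW, db = db)
}

zero_stuff <- function(X, stride) {
  if (stride == 1L) return(X)
  d <- dim(X)
  out <- array(0, c(d[1L], d[2L], d[3L] * stride))
  out[, , (seq_len(d[3L]) - 1L) * stride + 1L] <- X
  out
}

## ---- forward / backward / jvp over a layer list --------------------------

# forward pass; returns list(Y = output, caches = per-layer caches)
nn_forward <- function(net, X, keep = TRUE) {
  caches <- vector("list", length(net))
  for (i in seq_along(net)) {
    ly <- net[[i]]
    if (ly$type == "dense") {
      Y <- sweep(X %*% ly$W, 2L, ly$b, `+`)
      if (keep) caches[[i]] <- list(X = X)
    } else if (ly$type == "conv1d") {
      cf <- conv_fwd(ly, X)
      Y <- cf$Y
      if (keep) caches[[i]] <- cf[c("Xcol", "t_out", "t_in", "B")]
    } else if (ly$type == "tconv1d") {
      Xs <- zero_stuff(X, ly$stride)
      eff <- list(type = "conv1d", c_in = ly$c_in, c_out = ly$c_out,
                  kernel = ly$kernel, stride = 1L,
                  pad = ly$kernel %/% 2L, W = ly$W, b = ly$b)
      cf <- conv_fwd(eff, Xs)
      Y <- cf$Y[, , seq_len(dim(Xs)[3L]), drop = FALSE]
      if (keep) caches[[i]] <- c(cf[c("Xcol", "t_out", "t_in", "B")],
                                 list(t_in_layer = dim(X)[3L],
                                      t_stuffed = dim(Xs)[3L]))
    } else if (ly$type == "lrelu") {
      mask <- ly$alpha + (1 - ly$alpha) * (X > 0)
      Y <- X * mask
      if (keep) caches[[i]] <- list(mask = mask)
    } else if (ly$type == "tanh") {
      Y <- tanh(X)
      if (keep) caches[[i]] <- list(Y = Y)
    } else if (ly$type == "flatten") {
      d <- dim(X)
      Y <- matrix(X, d[1L], d[2L] * d[3L])
      if (keep) caches[[i]] <- list(d = d)
    } else if (ly$type == "reshape_ct") {
      Y <- array(X, c(nrow(X), ly$channels, ly$time))
      if (keep) caches[[i]] <- list(n_in = ncol(X))
    } else stop("unknown layer type: ", ly$type)
    X <- Y
  }
  list(Y = X, caches = caches)
}

# reverse-mode pass; dY matches the shape of the forward output.
# returns list(dX = gradient at the input, grads = per-layer param grads,
#              deltas = per-layer output gradients at linear layers)
nn_backward <- function(net, caches, dY, want_param_grads = TRUE) {
  grads <- vector("list", length(net))
  deltas <- vector("list", length(net))
  for (i in rev(seq_along(net))) {
    ly <- net[[i]]
    cc <- caches[[i]]
    if (ly$type == "dense") {
      deltas[[i]] <- dY
      if (want_param_grads)
        grads[[i]] <- list(dW = crossprod(cc$X, dY), db = colSums(dY))
      dY <- tcrossprod(dY, ly$W)
    } else if (ly$type == "conv1d") {
      deltas[[i]] <- dY
      bb <- conv_bwd(ly, cc, dY)
      if (want_param_grads) grads[[i]] <- list(dW = bb$dW, db = bb$db)
      dY <- bb$dX
    } else if (ly$type == "tconv1d") {
      deltas[[i]] <- dY
      # un-crop: pad dY back to the stride-1 conv's full output length
      full <- array(0, c(dim(dY)[1L], ly$c_out, cc$t_out))
      full[, , seq_len(dim(dY)[3L])] <- dY
      eff <- list(type = "conv1d", c_in = ly$c_in, c_out = ly$c_out,
                  kernel = ly$kernel, stride = 1L,
                  pad = ly$kernel %/% 2L, W = ly$W, b = ly$b)
      bb <- conv_bwd(eff, cc, full)
      if (want_param_grads) grads[[i]] <- list(dW = bb$dW, db = bb$db)
      # backward of zero-stuffing: keep every stride-th sample
      dY <- bb$dX[, , (seq_len(cc$t_in_layer) - 1L) * ly$stride + 1L,
                  drop = FALSE]
    } else if (ly$type == "lrelu") {
      dY <- dY * cc$mask
    } else if (ly$type == "tanh") {
      dY <- dY * (1 - cc$Y^2)
    } else if (ly$type == "flatten") {
      dY <- array(dY, cc$d)
    } else if (ly$type == "reshape_ct") {
      dY <- matrix(dY, dim(dY)[1L], cc$n_in)
    }
  }
  list(dX = dY, grads = grads, deltas = deltas)
}

# forward-mode directional derivative: pushes a perturbation V of the input
# through the network linearization at the cached forward point.
nn_jvp <- function(net, caches, V, with_bias = FALSE) {
  for (i in seq_along(net)) {
    ly <- net[[i]]
    cc <- caches[[i]]
    if (ly$type == "dense") {
      V <- V %*% ly$W
    } else if (ly$type == "conv1d") {
      V <- conv_fwd(ly, V, bias = FALSE)$Y
    } else if (ly$type == "tconv1d") {
      Vs <- zero_stuff(V, ly$stride)
      eff <- list(type = "conv1d", c_in = ly$c_in, c_out = ly$c_out,
                  kernel = ly$kernel, stride = 1L,
                  pad = ly$kernel %/% 2L, W = ly$W, b = ly$b)
      V <- conv_fwd(eff, Vs, bias = FALSE)$Y[, , seq_len(dim(Vs)[3L]),
                                             drop = FALSE]
    } else if (ly$type == "lrelu") {
      V <- V * cc$mask
    } else if (ly$type == "tanh") {
      V <- V * (1 - cc$Y^2)
    } else if (ly$type == "flatten") {
      d <- dim(V)
      V <- matrix(V, d[1L], d[2L] * d[3L])
    } else if (ly$type == "reshape_ct") {
      V <- array(V, c(nrow(V), ly$channels, ly$time))
    }
  }
  V
}

## ---- WGAN-GP double backprop --------------------------------------------

# per-sample input gradient of a scalar-output critic, plus the backward
# deltas needed for the penalty's parameter gradients.
critic_input_grad <- function(net, caches, B) {
  bw <- nn_backward(net, caches, matrix(1, B, 1L),
                    want_param_grads = FALSE)
  list(g = bw$dX, deltas = bw$deltas)
}

# gradient-penalty value and its exact parameter gradients for a critic
# composed of linear layers and leaky-ReLU. `gp_select` optionally restricts
# the penalized norm to a subset of input columns (conditional critics:
# the label one-hot is a condition, not a penalized input).
gp_value_and_grads <- function(net, Xhat, gp_select = NULL) {
  for (ly in net)
    if (ly$type == "tanh")
      stop("gradient penalty double backprop requires piecewise-linear critics")
  fw <- nn_forward(net, Xhat)
  B <- if (is.matrix(Xhat)) nrow(Xhat) else dim(Xhat)[1L]
  ig <- critic_input_grad(net, fw$caches, B)
  g <- ig$g
  gm <- if (is.matrix(g)) g else matrix(g, B, length(g) / B)
  if (!is.null(gp_select) && is.matrix(g)) gm <- gm[, gp_select, drop = FALSE]
  norms <- sqrt(rowSums(gm^2))
  gp <- mean((norms - 1)^2)
  # v = dGP/dg, per sample
  scale <- ifelse(norms > 0, 2 * (norms - 1) / (norms * B), 0)
  vm <- gm * scale
  if (is.matrix(g)) {
    v <- matrix(0, nrow(g), ncol(g))
    if (is.null(gp_select)) v <- vm else v[, gp_select] <- vm
  } else {
    v <- array(vm, dim(g))
  }
  # push v forward (no biases, masks frozen), collecting the input seen by
  # every linear layer; param grad of layer l is <delta_l, L_l(u_{l-1})>.
  grads <- vector("list", length(net))
  U <- v
  for (i in seq_along(net)) {
    ly <- net[[i]]
    cc <- fw$caches[[i]]
    if (ly$type == "dense") {
      grads[[i]] <- list(dW = crossprod(U, ig$deltas[[i]]),
                         db = numeric(length(ly$b)))
      U <- U %*% ly$W
    } else if (ly$type == "conv1d") {
      cf <- conv_fwd(ly, U, bias = FALSE)
      dmat <- permute_in_cpp(ig$deltas[[i]], cc$B, ly$c_out, cc$t_out)
      grads[[i]] <- list(dW = crossprod(cf$Xcol, dmat),
                         db = numeric(length(ly$b)))
      U <- cf$Y
    } else if (ly$type == "tconv1d") {
      Us <- zero_stuff(U, ly$stride)
      eff <- list(type = "conv1d", c_in = ly$c_in, c_out = ly$c_out,
                  kernel = ly$kernel, stride = 1L,
                  pad = ly$kernel %/% 2L, W = ly$W, b = ly$b)
      cf <- conv_fwd(eff, Us, bias = FALSE)
      full <- array(0, c(dim(ig$deltas[[i]])[1L], ly$c_out, cc$t_out))
      full[, , seq_len(dim(ig$deltas[[i]])[3L])] <- ig$deltas[[i]]
      dmat <- permute_in_cpp(full, cc$B, ly$c_out, cc$t_out)
      grads[[i]] <- list(dW = crossprod(cf$Xcol, dmat),
                         db = numeric(length(ly$b)))
      U <- cf$Y[, , seq_len(cc$t_stuffed), drop = FALSE]
    } else if (ly$type == "lrelu") {
      U <- U * cc$mask
    } else if (ly$type == "flatten") {
      d <- dim(U)
      U <- matrix(U, d[1L], d[2L] * d[3L])
    } else if (ly$type == "reshape_ct") {
      U <- array(U, c(nrow(U), ly$channels, ly$time))
    }
  }
  list(gp = gp, grads = grads, input_grad = g, norms = norms)
}

## ---- Adam ----------------------------------------------------------------

adam_new <- function(net, lr = 1e-4, beta1 = 0.5, beta2 = 0.9, eps = 1e-8) {
  st <- vector("list", length(net))
  for (i in seq_along(net))
    if (!is.null(net[[i]]$W))
      st[[i]] <- list(mW = net[[i]]$W * 0, vW = net[[i]]$W * 0,
                      mb = net[[i]]$b * 0, vb = net[[i]]$b * 0)
  list(state = st, lr = lr, beta1 = beta1, beta2 = beta2, eps = eps, t = 0L)
}

# `grads_list` is a list of per-layer gradient lists; they are summed.
adam_step <- function(net, opt, grads_list) {
  opt$t <- opt$t + 1L
  b1 <- opt$beta1; b2 <- opt$beta2
  c1 <- 1 - b1^opt$t; c2 <- 1 - b2^opt$t
  for (i in seq_along(net)) {
    if (is.null(net[[i]]$W)) next
    dW <- net[[i]]$W * 0; db <- net[[i]]$b * 0
    for (gl in grads_list) {
      if (is.null(gl[[i]])) next
      dW <- dW + gl[[i]]$dW
      db <- db + gl[[i]]$db
    }
    st <- opt$state[[i]]
    st$mW <- b1 * st$mW + (1 - b1) * dW
    st$vW <- b2 * st$vW + (1 - b2) * dW^2
    st$mb <- b1 * st$mb + (1 - b1) * db
    st$vb <- b2 * st$vb + (1 - b2) * db^2
    net[[i]]$W <- net[[i]]$W - opt$lr * (st$mW / c1) /
      (sqrt(st$vW / c2) + opt$eps)
    net[[i]]$b <- net[[i]]$b - opt$lr * (st$mb / c1) /
      (sqrt(st$vb / c2) + opt$eps)
    opt$state[[i]] <- st
  }
  list(net = net, opt = opt)
}

# scale a grads list by a scalar
grads_scale <- function(grads, s) {
  for (i in seq_along(grads))
    if (!is.null(grads[[i]])) {
      grads[[i]]$dW <- grads[[i]]$dW * s
      grads[[i]]$db <- grads[[i]]$db * s
    }
  grads
}

grads_add <- function(a, b) {
  for (i in seq_along(a)) {
    if (is.null(a[[i]])) { a[[i]] <- b[[i]]; next }
    if (is.null(b[[i]])) next
    a[[i]]$dW <- a[[i]]$dW + b[[i]]$dW
    a[[i]]$db <- a[[i]]$db + b[[i]]$db
  }
  a
}
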