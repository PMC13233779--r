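test_that("three-point curvature matches hand-evaluated cases", {
  expect_equal(three_point_curvature(0:5), rep(0, 4))       # collinear
  expect_equal(three_point_curvature(c(1, 0, 1)), 2)        # parabola
  expect_error(three_point_curvature(c(1, 2)), "length >= 3")
  # constant offsets leave curvature unchanged
  set.seed(1)
  tr <- rnorm(50)
  expect_equal(three_point_curvature(tr + 7), three_point_curvature(tr))
})

test_that("curvature of a resampled circle converges to 1/r", {
  for (r in c(0.5, 1, 5)) {
    xg <- seq(-r / 4, r / 4, length.out = 4001)
    y <- sqrt(r^2 - xg^2)
    dx <- diff(xg)[1]
    k <- three_point_curvature(y, dx = dx)
    mid <- k[1000:3000]
    expect_lt(max(abs(mid - 1 / r)) * r, 0.01)
  }
})

test_that("curvature squashing clips, maps 1 to 0.5 and is monotone", {
  expect_equal(squash_curvature(0), 1e-7)
  expect_equal(squash_curvature(1), 0.5)
  expect_error(squash_curvature(-1), "nonnegative")
  set.seed(2)
  k <- sort(abs(rnorm(100, sd = 4)))
  expect_true(all(diff(squash_curvature(k)) >= 0))
})

test_that("time-domain loss equals the scalar-loop oracle", {
  set.seed(3)
  r <- array(rnorm(4 * 2 * 20), c(4, 2, 20))
  f <- array(rnorm(4 * 2 * 20), c(4, 2, 20))
  kr <- unlist(lapply(1:4, function(i) lapply(1:2, function(ch)
    squash_curvature(three_point_curvature(r[i, ch, ])))))
  kf <- unlist(lapply(1:4, function(i) lapply(1:2, function(ch)
    squash_curvature(three_point_curvature(f[i, ch, ])))))
  expect_equal(tr_loss(r, f), bce_loop(kr, kf), tolerance = 1e-9)
  expect_error(tr_loss(r, f[1:2, , , drop = FALSE]), "identical shapes")
  # matched flat statistics: symmetric BCE at 0.5 would give log 2; here the
  # matched case attains the entropy lower bound for fixed real statistics
  expect_equal(tr_loss(r, r), bce_loop(kr, kr), tolerance = 1e-12)
})

test_that("time/frequency losses are minimized when fake matches real", {
  set.seed(4)
  r <- array(rnorm(6 * 1 * 24), c(6, 1, 24))
  # curvature: the same batch attains the elementwise BCE minimum
  base_tr <- tr_loss(r, r)
  # spectrum: a batch whose every normalized spectrum equals the real
  # average attains the binary-entropy minimum (built by inverse FFT of the
  # symmetric average spectrum, which has exactly that amplitude spectrum)
  fbar <- mean_norm_spectrum(r)[1, ]
  trace <- Re(fft(complex(real = fbar), inverse = TRUE))
  fmatch <- aperm(array(trace, c(24, 1, 6)), c(3, 2, 1))
  expect_equal(max(abs(amplitude_spectrum(fmatch[1, 1, ], normalize = TRUE)
                       - fbar)), 0, tolerance = 1e-12)
  eps <- 1e-7
  fb <- pmin(pmax(fbar, eps), 1 - eps)
  base_fr <- -mean(fb * log(fb) + (1 - fb) * log(1 - fb))
  expect_equal(fr_loss(r, fmatch), base_fr, tolerance = 1e-9)
  for (s in 1:8) {
    f <- r + array(rnorm(length(r), sd = 0.3 * s), dim(r))
    expect_gte(tr_loss(r, f), base_tr)
    expect_gte(fr_loss(r, f), base_fr)
  }
})

test_that("amplitude spectrum matches the direct-sum DFT oracle", {
  set.seed(5)
  for (N in c(8, 33, 100, 512)) {
    x <- rnorm(N)
    F <- amplitude_spectrum(x)
    expect_lt(max(abs(F - dft_direct(x))) / max(F), 1e-9)
  }
  # closed forms
  expect_equal(amplitude_spectrum(rep(2, 8)),
               c(16, rep(0, 7)), tolerance = 1e-12)
  k0 <- 3; N <- 32
  F <- amplitude_spectrum(cos(2 * pi * k0 * (0:(N - 1)) / N))
  expect_equal(F[k0 + 1], N / 2, tolerance = 1e-9)
  expect_equal(F[N - k0 + 1], N / 2, tolerance = 1e-9)
  expect_lt(max(F[-c(k0 + 1, N - k0 + 1)]), 1e-9)
  expect_equal(sum(amplitude_spectrum(rnorm(16), normalize = TRUE)), 1,
               tolerance = 1e-12)
})

test_that("frequency-domain loss equals the scalar-loop oracle", {
  set.seed(6)
  r <- array(rnorm(5 * 2 * 16), c(5, 2, 16))
  f <- array(rnorm(5 * 2 * 16), c(5, 2, 16))
  eps <- 1e-7
  sp <- function(v) amplitude_spectrum(v, normalize = TRUE)
  fbar <- array(0, c(2, 16))
  for (ch in 1:2)
    fbar[ch, ] <- rowMeans(vapply(1:5, function(i) sp(r[i, ch, ]),
                                  numeric(16)))
  fbar <- pmin(pmax(fbar, eps), 1 - eps)
  tot <- 0
  for (i in 1:5) for (ch in 1:2) {
    ff <- pmin(pmax(sp(f[i, ch, ]), eps), 1 - eps)
    tot <- tot + sum(fbar[ch, ] * log(ff) + (1 - fbar[ch, ]) * log(1 - ff))
  }
  expect_equal(fr_loss(r, f), -tot / (5 * 2 * 16), tolerance = 1e-9)
  # identical single-bin spectra stay finite and symmetric under clipping
  pulse <- array(0, c(1, 1, 8)); pulse[1, 1, 1] <- 1
  expect_true(is.finite(fr_loss(pulse, pulse)))
})

test_that("latent ratio: identity, constant and the two equivalent forms", {
  set.seed(7)
  z1 <- rnorm(8); z2 <- rnorm(8)
  expect_equal(sr_ratio(z1, z2, z1, z2), 1)                # identity map
  expect_equal(sr_ratio(z1, z2, rep(2, 10), rep(2, 10)), 0) # constant map
  expect_error(sr_ratio(z1, 2 * z1, rnorm(4), rnorm(4)), "degenerate")
  for (i in 1:200) {
    z1 <- rnorm(6); z2 <- rnorm(6); g1 <- rnorm(15); g2 <- rnorm(15)
    cosform <- sr_ratio(z1, z2, g1, g2)
    nrm <- function(v) v / sqrt(sum(v^2))
    eucl <- sum((nrm(g1) - nrm(g2))^2) / sum((nrm(z1) - nrm(z2))^2)
    expect_equal(cosform, eucl, tolerance = 1e-9)
  }
})

test_that("latent loss directions and values", {
  expect_equal(sr_loss(1, "reciprocal"), 1 / (1 + 1e-8))
  expect_equal(sr_loss(c(1, 3), "negative"), -2)
  expect_equal(sr_loss(c(1, 3), "literal"), 2)
  expect_error(sr_loss(numeric(0)), "at least one")
  # minimizing the reciprocal form pushes ratios up: one gradient step on a
  # tiny linear generator increases the mean ratio
  set.seed(8)
  A <- diag(4) * 0.5
  z1 <- matrix(rnorm(20 * 4), 20); z2 <- matrix(rnorm(20 * 4), 20)
  ratio_of <- function(A) {
    mean(vapply(1:20, function(p)
      sr_ratio(z1[p, ], z2[p, ], A %*% z1[p, ], A %*% z2[p, ]), 0))
  }
  g1 <- t(A %*% t(z1)); g2 <- t(A %*% t(z2))
  sg <- mrmgan:::sr_loss_grad(z1, z2, g1, g2, "reciprocal")
  dA <- matrix(0, 4, 4)
  for (p in 1:20)
    dA <- dA + outer(sg$g1_grad[p, ], z1[p, ]) +
      outer(sg$g2_grad[p, ], z2[p, ])
  A2 <- A - 0.05 * dA
  expect_gt(ratio_of(A2), ratio_of(A))
})

test_that("combined objective follows the trade-off identity", {
  lb <- combined_generator_loss(0, 1, 1, 1, regularizer_weights(0.6))
  expect_equal(lb$L_G_final, 1.0)
  w_hi <- regularizer_weights(1 - 1e-12)
  expect_equal(combined_generator_loss(2, 5, 7, 3, w_hi)$L_G_final, 2 + 3,
               tolerance = 1e-9)
  w_lo <- regularizer_weights(1e-12)
  expect_equal(combined_generator_loss(2, 5, 7, 3, w_lo)$L_G_final,
               2 + 0.5 * 7 + 0.5 * 5, tolerance = 1e-9)
  expect_error(regularizer_weights(0), "inside")
  expect_error(regularizer_weights(1), "inside")
  expect_error(combined_generator_loss(Inf, 0, 0, 0,
                                       regularizer_weights(0.5)), "finite")
  # random draws satisfy the identity to float tolerance
  set.seed(9)
  for (i in 1:50) {
    v <- rnorm(4); lam <- runif(1, 0.01, 0.99)
    lb <- combined_generator_loss(v[1], v[2], v[3], v[4],
                                  regularizer_weights(lam))
    expect_equal(lb$L_G_final,
                 v[1] + lam * v[4] + (1 - lam) * (0.5 * v[3] + 0.5 * v[2]),
                 tolerance = 1e-12)
  }
})

test_that("analytic loss gradients agree with finite differences", {
  set.seed(10)
  r <- array(rnorm(2 * 1 * 16), c(2, 1, 16))
  f <- array(rnorm(2 * 1 * 16), c(2, 1, 16))
  gt <- mrmgan:::tr_loss_grad(r, f)
  gf <- mrmgan:::fr_loss_grad(r, f)
  for (j in sample(length(f), 10)) {
    fp <- f; fp[j] <- fp[j] + 1e-6
    fm <- f; fm[j] <- fm[j] - 1e-6
    expect_equal(gt[j], (tr_loss(r, fp) - tr_loss(r, fm)) / 2e-6,
                 tolerance = 1e-4)
    expect_equal(gf[j], (fr_loss(r, fp) - fr_loss(r, fm)) / 2e-6,
                 tolerance = 1e-4)
  }
})
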