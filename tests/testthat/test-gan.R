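tiny_train_data <- function(seed = 5) {
  x <- small_oddball(n_per_class = 20, fs = 64, seed = seed, n_channels = 1)
  maxabs_scale(bandpass_fir(x, filter_spec(0.01, 30)))
}

test_that("gradient penalty closed forms for linear critics", {
  set.seed(1)
  w <- rnorm(12); w <- w / sqrt(sum(w^2))
  lin <- list(mrmgan:::nn_flatten(), mrmgan:::nn_dense(12, 1))
  lin[[2]]$W <- matrix(w, 12, 1)
  r <- array(rnorm(5 * 1 * 12), c(5, 1, 12))
  f <- array(rnorm(5 * 1 * 12), c(5, 1, 12))
  expect_equal(gradient_penalty(lin, r, f, seed = 2), 0, tolerance = 1e-12)
  lin[[2]]$W <- matrix(2 * w, 12, 1)
  expect_equal(gradient_penalty(lin, r, f, seed = 2), 1, tolerance = 1e-12)
  expect_error(gradient_penalty(lin, r, f[1:2, , , drop = FALSE]),
               "identical shapes")
})

test_that("short runs keep all logged losses finite for every variant", {
  x <- tiny_train_data()
  for (v in c("wgan_gp", "cwgan_gp")) {
    m <- mrm_gan(x, v, steps = 10, batch_size = 16, seed = 3,
                 net = net_config(latent_dim = 8, n_channels = 1,
                                  n_samples = 64, widths = c(32, 32),
                                  conditional = v == "cwgan_gp",
                                  n_classes = 2))
    expect_false(m$aborted)
    h <- m$history
    expect_equal(nrow(h), 10)
    expect_true(all(is.finite(unlist(
      h[, c("L_G", "L_TR", "L_FR", "L_SR", "L_G_final", "critic_loss")]))))
  }
  m <- mrm_gan(x, "wavegan_lite", steps = 5, batch_size = 16, seed = 3,
               net = net_config(latent_dim = 8, n_channels = 1,
                                n_samples = 64, kernel = 5))
  expect_true(all(is.finite(m$history$L_G)))
})

test_that("checkpoint-resume reproduces the uninterrupted loss history", {
  x <- tiny_train_data()
  net <- net_config(latent_dim = 8, n_channels = 1, n_samples = 64,
                    widths = c(32, 32))
  full <- mrm_gan(x, "wgan_gp", steps = 12, batch_size = 16, seed = 11,
                  net = net)
  part <- mrm_gan(x, "wgan_gp", steps = 7, batch_size = 16, seed = 11,
                  net = net)
  f <- tempfile(fileext = ".rds")
  on.exit(unlink(f))
  saveRDS(part, f)                    # round-trip through a checkpoint file
  part2 <- mrm_gan_resume(readRDS(f), x, 5)
  expect_identical(part2$history, full$history)
  expect_identical(part2$generator_net, full$generator_net)
})

test_that("sampling is seeded, sized and label-aware", {
  x <- tiny_train_data()
  m <- mrm_gan(x, "wgan_gp", steps = 3, batch_size = 16, seed = 2,
               net = net_config(latent_dim = 8, n_channels = 1,
                                n_samples = 64, widths = c(32, 32)))
  empty <- gan_sample(m, 0)
  expect_equal(dim(empty)[1], 0)
  a <- gan_sample(m, 5, seed = 4)
  b <- gan_sample(m, 5, seed = 4)
  expect_identical(a$data, b$data)
  expect_true(all(is.na(a$labels)))
  expect_error(gan_sample(m, 3, labels = c(0, 1, 0)), "unconditional")
  mc <- mrm_gan(x, "cwgan_gp", steps = 3, batch_size = 16, seed = 2,
                net = net_config(latent_dim = 8, n_channels = 1,
                                 n_samples = 64, widths = c(32, 32),
                                 conditional = TRUE, n_classes = 2))
  s <- simulate(mc, nsim = 6, seed = 9, labels = rep(1L, 6))
  expect_true(all(s$labels == 1L))
})

test_that("critic and generator updates do not touch each other's weights", {
  x <- tiny_train_data()
  net <- net_config(latent_dim = 8, n_channels = 1, n_samples = 64,
                    widths = c(32, 32))
  m0 <- mrm_gan(x, "wgan_gp", steps = 1, batch_size = 16, seed = 6,
                net = net, critic_steps = 0)
  # zero critic steps: critic must equal its freshly initialized state
  set.seed(6)
  nets <- mrmgan:::build_nets("wgan_gp", net)
  ginit <- mrmgan:::nn_init(nets$gen)
  cinit <- mrmgan:::nn_init(nets$critic)
  expect_identical(m0$critic_net, cinit)
  expect_false(identical(m0$generator_net, ginit))
})

test_that("zeroed regulation reduces exactly to the plain trainer", {
  x <- tiny_train_data()
  net <- net_config(latent_dim = 8, n_channels = 1, n_samples = 64,
                    widths = c(32, 32))
  plain <- mrm_gan(x, "wgan_gp", terms = character(0), steps = 10,
                   batch_size = 16, seed = 21, net = net)
  zeroed <- mrmgan:::mrm_gan_zeroed(x, "wgan_gp", steps = 10,
                                    batch_size = 16, seed = 21, net = net)
  expect_identical(plain$history$L_G, zeroed$history$L_G)
  expect_identical(plain$history$critic_loss, zeroed$history$critic_loss)
  expect_identical(plain$generator_net, zeroed$generator_net)
  expect_identical(plain$critic_net, zeroed$critic_net)
})

test_that("gradient-norm bound holds for identity, constant and random nets", {
  idgen <- list(fn = function(z) z, jvp = function(z, v) v)
  rep1 <- sr_bound_check(idgen, latent_dim = 6, n_pairs = 50, n_quad = 64,
                         seed = 2)
  expect_equal(rep1$violations, 0)
  expect_true(all(rep1$pairs$bound >= rep1$pairs$ratio * (1 - 1e-9)))
  cgen <- list(fn = function(z) matrix(1, nrow(z), 7),
               jvp = function(z, v) matrix(0, nrow(z), 7))
  rep2 <- sr_bound_check(cgen, latent_dim = 6, n_pairs = 20, n_quad = 32,
                         seed = 3)
  expect_equal(rep2$violations, 0)
  expect_true(all(rep2$pairs$ratio == 0))
  set.seed(4)
  rnet <- mrmgan:::nn_init(list(mrmgan:::nn_dense(6, 32),
                                mrmgan:::nn_lrelu(),
                                mrmgan:::nn_dense(32, 20),
                                mrmgan:::nn_tanh(),
                                mrmgan:::nn_reshape_ct(1, 20)))
  rep3 <- sr_bound_check(rnet, n_pairs = 50, n_quad = 128, seed = 5)
  expect_equal(rep3$violations, 0)
})

test_that("the bound is tight for the identity map on close pairs", {
  # pairs drawn nearby on the sphere: the chord stays near radius one, so
  # the quadrature bound approaches the ratio (both -> 1)
  set.seed(6)
  for (i in 1:20) {
    z1 <- rnorm(8); z1 <- z1 / sqrt(sum(z1^2))
    z2 <- z1 + 0.02 * rnorm(8); z2 <- z2 / sqrt(sum(z2^2))
    u <- (z1 - z2) / sqrt(sum((z1 - z2)^2))
    tg <- seq(0, 1, length.out = 64)
    gam <- outer(tg, z1) + outer(1 - tg, z2)
    gn <- sqrt(rowSums(gam^2))
    b <- sqrt(1 / gn^2 - (rowSums(gam * matrix(u, 64, 8, byrow = TRUE)))^2 /
                gn^4)
    w <- rep(1 / 63, 64); w[c(1, 64)] <- w[1] / 2
    bound <- sum(w * b)^2
    ratio <- sum((z1 - z2)^2) / sum((z1 - z2)^2)
    expect_equal(bound, ratio, tolerance = 1e-3)
  }
})
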