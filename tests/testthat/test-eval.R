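# Stub classifiers with exactly known probability outputs: epochs are
# [n, 1, C] arrays and the network is an identity-weight dense layer, so
# the softmax sees the raw epoch values as logits.
stub_classifier <- function(C, gain = 1) {
  net <- list(mrmgan:::nn_flatten(), mrmgan:::nn_dense(C, C))
  net[[2]]$W <- diag(C) * gain
  structure(list(net = net, classes = seq_len(C) - 1L, seed = 0L,
                 val_accuracy = NA_real_, data_fingerprint = 0),
            class = "eval_classifier")
}

logit_epochs <- function(labels, C, strength = 60) {
  n <- length(labels)
  dat <- array(0, c(n, 1, C))
  for (i in seq_len(n)) dat[i, 1, labels[i] + 1L] <- strength
  eeg_epochs(dat, labels, fs = C)
}

test_that("evaluation classifier separates easy data deterministically", {
  x <- separable_epochs(n_per_class = 40)
  clf <- train_eval_classifier(x, seed = 3, steps = 250)
  expect_gt(clf$val_accuracy, 0.9)
  clf2 <- train_eval_classifier(x, seed = 3, steps = 250)
  expect_identical(clf$net, clf2$net)
  P <- predict(clf, x)
  expect_equal(rowSums(P), rep(1, dim(x)[1]), tolerance = 1e-6)
  expect_error(train_eval_classifier(
    epochs_subset(x, x$labels == 0), seed = 1), ">= 2 classes")
})

test_that("Mode Score closed forms", {
  # uninformative classifier (zero gain -> uniform probabilities): MS = 1
  for (C in c(2, 3)) {
    real <- logit_epochs(rep(seq_len(C) - 1L, each = 10), C)
    fake <- logit_epochs(rep(seq_len(C) - 1L, each = 7), C)
    expect_equal(mode_score(stub_classifier(C, gain = 0), real, fake), 1)
    # near-one-hot classifier, uniform real and fake marginals: MS = C
    expect_equal(mode_score(stub_classifier(C), real, fake), C,
                 tolerance = 1e-6)
  }
  # fake = real itself: second KL term vanishes, term-by-term oracle
  C <- 3
  real <- logit_epochs(c(0L, 0L, 1L, 2L), C, strength = 2)
  clf <- stub_classifier(C)
  P <- predict(clf, real)
  pstar <- c(2, 1, 1) / 4
  term1 <- mean(sapply(seq_len(nrow(P)), function(i)
    sum(P[i, ] * log(P[i, ] / pstar))))
  pbar <- colMeans(P)
  term2 <- sum(pbar * log(pbar / pstar))
  expect_equal(mode_score(clf, real, real), exp(term1 - term2),
               tolerance = 1e-9)
  expect_error(mode_score(clf, real, epochs_subset(real, integer(0))),
               "nonempty")
})

test_that("sliced Wasserstein distance: identity, 1-D oracle, point masses", {
  x <- separable_epochs(20)
  expect_equal(sliced_wasserstein(x, x, n_proj = 16, seed = 1), 0)
  # 1-D data: every unit projection is +/- identity, so SWD equals the
  # exact sorted-sample W1 distance
  a <- array(rnorm(30), c(30, 1, 1)); b <- array(rnorm(30), c(30, 1, 1))
  w1 <- mean(abs(sort(a[, 1, 1]) - sort(b[, 1, 1])))
  expect_equal(sliced_wasserstein(a, b, n_proj = 64, seed = 2), w1,
               tolerance = 1e-9)
  # two point masses at distance d
  d <- 1.7
  pm1 <- array(0, c(10, 1, 1)); pm2 <- array(d, c(10, 1, 1))
  expect_equal(sliced_wasserstein(pm1, pm2, n_proj = 8, seed = 3), d,
               tolerance = 1e-12)
  # symmetry under swapping, same projections
  expect_equal(sliced_wasserstein(a, b, 32, seed = 9),
               sliced_wasserstein(b, a, 32, seed = 9), tolerance = 1e-12)
})

test_that("sliced Wasserstein shrinks as fake shifts toward real", {
  set.seed(4)
  base <- matrix(rnorm(200 * 6), 200)
  shifted <- function(delta) array(base + delta, c(200, 1, 6))
  real <- array(base, c(200, 1, 6))
  ds <- vapply(c(2, 1, 0.5, 0), function(dl)
    sliced_wasserstein(real, shifted(dl), 64, seed = 5), 0)
  expect_true(all(diff(ds) < 0))
})

test_that("Welch PSD finds tones, is flat for white noise, and conserves power", {
  fs <- 128
  t <- (0:(4 * fs - 1)) / fs
  tone <- eeg_epochs(array(sin(2 * pi * 10 * t), c(1, 1, length(t))), 0L, fs)
  ps <- welch_psd(tone)
  expect_equal(ps$freq[which.max(ps$psd[1, ])], 10)
  expect_error(welch_psd(eeg_epochs(array(0, c(1, 1, 64)), 0L, 128)),
               "shorter")
  # white noise: band-averaged level flat within 20% between 1 and 40 Hz
  set.seed(6)
  wn <- eeg_epochs(array(rnorm(400 * 256), c(400, 1, 256)), rep(0L, 400),
                   256)
  pw <- welch_psd(wn, band = c(0.01, 40))
  f <- pw$freq
  lo <- mean(pw$psd[1, f >= 1 & f < 20])
  hi <- mean(pw$psd[1, f >= 20 & f <= 40])
  expect_lt(abs(lo / hi - 1), 0.2)
  # Parseval: integrated PSD over the full band approximates the variance
  pfull <- welch_psd(wn, band = c(0, 128), taper = "hamming")
  tot <- sum(pfull$psd[1, ]) * 256 / 256   # bin width = fs / L = 1 Hz
  expect_lt(abs(tot / var(as.vector(wn$data)) - 1), 0.05)
})

test_that("polynomial ERP trend reproduces polynomials and matches the
           normal-equation oracle", {
  t <- seq(-1, 1, length.out = 120)
  y <- 2 - t + 0.5 * t^3 - t^7
  tr <- erp_trend(y, order = 15)
  expect_lt(sqrt(mean((tr - y)^2)) / sd(y), 1e-6)
  cst <- erp_trend(rep(3, 50), order = 15)
  expect_equal(as.numeric(cst), rep(3, 50))
  expect_error(erp_trend(rnorm(10), order = 15), "exceed")
  set.seed(7)
  y2 <- rnorm(200)
  tr2 <- erp_trend(y2, order = 15)
  X <- outer(seq(-1, 1, length.out = 200), 0:15, `^`)
  beta <- solve(crossprod(X), crossprod(X, y2))
  expect_equal(as.numeric(tr2), as.numeric(X %*% beta), tolerance = 1e-6)
})

test_that("classification metrics reproduce the printed formulas", {
  perfect <- classification_metrics(c(1, 1, 0, 0), c(0.9, 0.8, 0.2, 0.1), 1)
  expect_equal(unlist(perfect[c("Acc", "Pre", "Rec", "F1", "AUC")]),
               c(Acc = 1, Pre = 1, Rec = 1, F1 = 1, AUC = 1))
  # constructed confusion: TP=3, FP=1, FN=1, TN=5
  y <- c(rep(1, 4), rep(0, 6))
  pred <- c(1, 1, 1, 0, 1, rep(0, 5))
  scores <- ifelse(pred == 1, 0.9, 0.1)
  m <- classification_metrics(y, scores, 1, predicted = pred)
  expect_equal(m$TP, 3); expect_equal(m$FP, 1)
  expect_equal(m$FN, 1); expect_equal(m$TN, 5)
  expect_equal(m$Acc, 0.8)
  expect_equal(m$Pre, 0.75)
  expect_equal(m$Rec, 0.75)
  expect_equal(m$F1, 0.75)
  # pairwise AUC with a tie counted 1/2
  m2 <- classification_metrics(c(1, 1, 0, 0), c(0.9, 0.5, 0.5, 0.1), 1)
  expect_equal(m2$AUC, 0.875)
  expect_error(classification_metrics(c(1, 1), c(0.2, 0.3), 1),
               "single class")
})

test_that("pairwise AUC matches pROC and survives monotone transforms", {
  set.seed(8)
  y <- rbinom(60, 1, 0.5)
  if (length(unique(y)) < 2) y[1:2] <- c(0, 1)
  s <- rnorm(60) + y
  a1 <- classification_metrics(y, s, 1)$AUC
  a_ref <- as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE,
                                          direction = "<")))
  expect_equal(a1, a_ref, tolerance = 1e-12)
  a2 <- classification_metrics(y, exp(3 * s), 1)$AUC
  expect_equal(a1, a2, tolerance = 1e-12)
})

test_that("multiclass metrics macro-average one-vs-rest", {
  set.seed(9)
  y <- rep(0:2, each = 5)
  S <- matrix(runif(45), 15, 3, dimnames = list(NULL, 0:2))
  for (i in seq_along(y)) S[i, y[i] + 1] <- S[i, y[i] + 1] + 1.2
  m <- classification_metrics(y, S)
  per <- sapply(0:2, function(cl)
    classification_metrics(as.integer(y == cl), S[, cl + 1], 1,
                           predicted = as.integer(max.col(S) == cl + 1))$F1)
  expect_equal(m$F1, mean(per), tolerance = 1e-12)
  expect_true(all(unlist(m[c("Acc", "Pre", "Rec", "F1", "AUC")]) >= 0 &
                  unlist(m[c("Acc", "Pre", "Rec", "F1", "AUC")]) <= 1))
})
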