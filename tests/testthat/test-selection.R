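test_that("weight selection matches an exhaustive-enumeration oracle", {
  set.seed(1)
  for (rep in 1:100) {
    k <- sample(3:9, 1)
    rows <- data.frame(lam = sort(runif(k, 0.05, 0.95)),
                       MS = rnorm(k, 1.5, 0.3),
                       SWD = abs(rnorm(k, 0.02, 0.01)))
    bMS <- rnorm(1, 1.4, 0.3); bSWD <- abs(rnorm(1, 0.025, 0.01))
    # oracle: brute-force z-scores and enumeration
    zm <- scale(c(bMS, rows$MS)); zs <- scale(c(bSWD, rows$SWD))
    dms <- zm[-1] - zm[1]; dsw <- zs[1] - zs[-1]
    feas <- which(dms > 0 & dsw > 0)
    got <- tryCatch(lambda_grid_select(rows, bMS, bSWD),
                    no_feasible_lambda = function(e) NULL)
    if (length(feas) == 0) {
      expect_null(got)
    } else {
      expect_equal(got$lambda,
                   rows$lam[feas[which.max((dms + dsw)[feas])]])
    }
  }
})

test_that("weight selection returns the unique feasible candidate", {
  rows <- data.frame(lam = c(0.2, 0.6, 0.8),
                     MS = c(1.0, 2.0, 1.1),
                     SWD = c(0.05, 0.01, 0.06))
  sel <- lambda_grid_select(rows, baseline_MS = 1.2, baseline_SWD = 0.03)
  expect_equal(sel$lambda, 0.6)
  expect_identical(sel$table$feasible, c(FALSE, TRUE, FALSE))
  # all diversity deltas negative: no feasible candidate
  rows2 <- data.frame(lam = c(0.3, 0.7), MS = c(0.5, 0.6),
                      SWD = c(0.01, 0.01))
  expect_error(lambda_grid_select(rows2, 2.0, 0.05),
               class = "no_feasible_lambda")
  expect_error(lambda_grid_select(rows[1, ], 1, 0.02), ">= 2")
  expect_error(lambda_grid_select(transform(rows, lam = lam + 1), 1, 0.02),
               "inside")
})

test_that("weight selection is invariant to affine metric rescaling", {
  set.seed(2)
  rows <- data.frame(lam = seq(0.1, 0.9, 0.1),
                     MS = rnorm(9, 1.5, 0.2), SWD = runif(9, 0.01, 0.05))
  sel1 <- tryCatch(lambda_grid_select(rows, 1.4, 0.04)$lambda,
                   no_feasible_lambda = function(e) NA)
  rows2 <- transform(rows, MS = 100 * MS - 7, SWD = 3 * SWD + 0.5)
  sel2 <- tryCatch(lambda_grid_select(rows2, 100 * 1.4 - 7,
                                      3 * 0.04 + 0.5)$lambda,
                   no_feasible_lambda = function(e) NA)
  expect_equal(sel1, sel2)
})

test_that("saturation fit recovers known power laws", {
  # exact recovery of a planted curve
  x <- 1:5
  y <- 8.6 * x^0.40 + 79.6
  f <- fit_saturation(x, y)
  expect_equal(f$a, 8.6, tolerance = 1e-3)
  expect_equal(f$gamma, 0.40, tolerance = 1e-3)
  expect_equal(f$b, 79.6, tolerance = 1e-3)
  expect_lt(f$SSR, 1e-10)
  # the power family contains linear curves
  fl <- fit_saturation(1:6, 2 * (1:6) + 1)
  expect_equal(fl$gamma, 1, tolerance = 1e-3)
  expect_equal(fl$a, 2, tolerance = 1e-3)
  expect_equal(fl$b, 1, tolerance = 1e-3)
  # degenerate input
  fd <- fit_saturation(1:4, rep(5, 4))
  expect_equal(c(fd$a, fd$gamma, fd$b), c(0, 1, 5))
})

test_that("saturation fit beats a dense brute-force grid and satisfies the
           first-order conditions", {
  set.seed(3)
  x <- 0:5
  y <- 4 * x^0.6 + 70 + rnorm(6, sd = 0.4)
  f <- fit_saturation(x, y)
  # brute force over (gamma, a, b)
  best <- Inf
  for (g in seq(0.05, 3, length.out = 100)) {
    X <- cbind(1, x^g)
    r <- stats::lm.fit(X, y)$residuals
    best <- min(best, sum(r^2))
  }
  expect_lte(f$SSR, best + 1e-9)
  # residuals orthogonal to the design at the optimum
  res <- y - f$fitted
  expect_lt(abs(sum(res)), 1e-6)
  expect_lt(abs(sum(res * x^f$gamma)), 1e-6)
  # cross-check against a nonlinear least-squares reference fit
  nls_fit <- minpack.lm::nlsLM(y ~ a * x^g + b,
                               start = list(a = 1, g = 0.5, b = mean(y)),
                               control = list(maxiter = 200))
  expect_lte(f$SSR, sum(residuals(nls_fit)^2) + 1e-6)
})

test_that("augmentation keeps generated epochs out of evaluation and
           reports a complete table", {
  real <- separable_epochs(n_per_class = 25, seed = 4)
  # 'generated' surrogate: fresh draws from the same process, relabeled ids
  gen <- separable_epochs(n_per_class = 130, seed = 5)
  res <- run_augmentation(real, gen, ratios = c(0, 2), k = 3, seed = 6,
                          clf_steps = 120)
  expect_s3_class(res, "augmentation_result")
  expect_setequal(unique(res$cv$ratio), c(0, 2))
  expect_setequal(unique(res$cv$metric), c("Acc", "Pre", "Rec", "F1", "AUC"))
  expect_true(all(res$cv$mean >= 0 & res$cv$mean <= 1))
  expect_true(all(res$cv$sd >= 0))
  expect_equal(nrow(res$test), 2 * 5)
  expect_true(all(res$test$value >= 0 & res$test$value <= 1))
  # insufficient generated epochs is a named error
  expect_error(run_augmentation(real, epochs_subset(gen, 1:10),
                                ratios = c(0, 5), k = 3, seed = 6,
                                clf_steps = 50),
               "insufficient generated")
  # unlabeled generated epochs are rejected
  gu <- gen; gu$labels <- rep(NA_integer_, length(gu$labels))
  expect_error(run_augmentation(real, gu, ratios = 0:1, seed = 1),
               "labeled")
})
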