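#' Select the regularization trade-off weight from a metric grid
#'
#' Given Mode Score and sliced Wasserstein distance measured at each
#' candidate weight and for the unregularized baseline, both metric columns
#' are z-score standardized jointly with the baseline (so the two scales are
#' comparable), the gains `dMS = MS_lam - MS_baseline` and
#' `dSWD = SWD_baseline - SWD_lam` are formed, and the weight maximizing
#' `dSum = dMS + dSWD` over the feasible set `{dMS > 0 and dSWD > 0}` is
#' returned. With no feasible candidate an error of class
#' `"no_feasible_lambda"` is thrown (widen the grid).
#'
#' @param rows data frame with columns `lam`, `MS`, `SWD` (one row per
#'   candidate weight, all in (0, 1)).
#' @param baseline_MS,baseline_SWD metrics of the unregularized model.
#' @return list with `lambda` (the selected weight) and `table` (the grid
#'   with standardized deltas and feasibility flags).
#' @export
lambda_grid_select <- function(rows, baseline_MS, baseline_SWD) {
  stopifnot(is.data.frame(rows), all(c("lam", "MS", "SWD") %in% names(rows)))
  if (nrow(rows) < 2L) stop("need >= 2 grid points")
  if (any(rows$lam <= 0 | rows$lam >= 1))
    stop("candidate weights must lie inside (0, 1)")
  zms <- scale(c(baseline_MS, rows$MS))
  zsw <- scale(c(baseline_SWD, rows$SWD))
  if (any(!is.finite(zms))) zms[] <- 0   # all-equal column
  if (any(!is.finite(zsw))) zsw[] <- 0
  dMS <- zms[-1L] - zms[1L]
  dSWD <- zsw[1L] - zsw[-1L]
  feasible <- dMS > 0 & dSWD > 0
  tab <- data.frame(lam = rows$lam, MS = rows$MS, SWD = rows$SWD,
                    dMS = dMS, dSWD = dSWD, dSum = dMS + dSWD,
                    feasible = feasible)
  if (!any(feasible)) {
    cond <- structure(
      class = c("no_feasible_lambda", "error", "condition"),
      list(message = "no candidate improves both diversity and similarity",
           call = sys.call(-1), table = tab))
    stop(cond)
  }
  best <- which(feasible)[which.max(tab$dSum[feasible])]
  list(lambda = tab$lam[best], table = tab)
}

#' Augmentation experiment over generated-to-real mixing ratios
#'
#' Reproduces the mixing-ratio protocol: the real epochs are split 80/20
#' (stratified); within the 80% training part a stratified `k`-fold
#' cross-validation runs, and each fold's training portion is augmented
#' with `r` times as many generated epochs (label-matched) for every
#' mixing ratio `r`. Generated epochs enter training folds only — metrics
#' are always computed on real-only validation folds and on the real-only
#' 20% test split.
#'
#' @param real real labeled [eeg_epochs].
#' @param generated generated labeled [eeg_epochs] (e.g. from a conditional
#'   model); must contain at least `max(ratios)` times the real training
#'   epochs of every class.
#' @param ratios integer mixing ratios (0 = real only).
#' @param k cross-validation folds.
#' @param seed seed controlling the split, folds, sampling and classifier.
#' @param clf_steps training steps of the compact classifier per fit.
#' @return object of class `augmentation_result`: data frame `cv` (ratio x
#'   metric mean/SD over folds) and data frame `test` (ratio x metric on
#'   the held-out split).
#' @export
run_augmentation <- function(real, generated, ratios = 0:5, k = 5L,
                             seed = 1L, clf_steps = 300L) {
  stopifnot(inherits(real, "eeg_epochs"), inherits(generated, "eeg_epochs"))
  if (anyNA(generated$labels))
    stop("generated epochs must be labeled for augmentation")
  old <- get0(".Random.seed", globalenv(), inherits = FALSE)
  on.exit(restore_rng(old), add = TRUE)
  set.seed(as.integer(seed))
  classes <- sort(unique(real$labels))
  n <- n_epochs(real)
  # stratified 80/20 split
  test_idx <- unlist(lapply(classes, function(cl) {
    ii <- which(real$labels == cl)
    sample(ii, max(1L, round(0.2 * length(ii))))
  }))
  train_idx <- setdiff(seq_len(n), test_idx)
  # stratified folds over the training part
  fold <- integer(n)
  for (cl in classes) {
    ii <- intersect(which(real$labels == cl), train_idx)
    fold[ii] <- sample(rep_len(seq_len(k), length(ii)))
  }
  gen_by_class <- split(seq_len(n_epochs(generated)), generated$labels)
  draw_generated <- function(lab_counts, r) {
    take <- integer(0)
    for (cl in names(lab_counts)) {
      need <- r * lab_counts[[cl]]
      pool <- gen_by_class[[cl]]
      if (is.null(pool) || length(pool) < need)
        stop(sprintf(
          "insufficient generated epochs for class %s: need %d, have %d",
          cl, need, length(pool %||% integer(0))))
      take <- c(take, sample(pool, need))
    }
    take
  }
  fit_and_eval <- function(tr_real_idx, ev_idx, r) {
    counts <- as.list(table(real$labels[tr_real_idx]))
    train <- epochs_subset(real, tr_real_idx)
    if (r > 0) {
      gidx <- draw_generated(counts, r)
      train <- epochs_rbind(train, epochs_subset(generated, gidx))
    }
    clf <- train_eval_classifier(train, seed = sample.int(1e6, 1),
                                 steps = clf_steps, holdout = 0.1)
    P <- predict(clf, epochs_subset(real, ev_idx))
    m <- classification_metrics(real$labels[ev_idx], P)
    unlist(m[c("Acc", "Pre", "Rec", "F1", "AUC")])
  }
  cv_rows <- list()
  for (r in ratios) {
    per_fold <- matrix(NA_real_, k, 5L,
                       dimnames = list(NULL,
                                       c("Acc", "Pre", "Rec", "F1", "AUC")))
    for (f in seq_len(k)) {
      ev_idx <- which(fold == f)
      tr_idx <- setdiff(train_idx, ev_idx)
      per_fold[f, ] <- fit_and_eval(tr_idx, ev_idx, r)
    }
    cv_rows[[length(cv_rows) + 1L]] <- data.frame(
      ratio = r, metric = colnames(per_fold),
      mean = colMeans(per_fold), sd = apply(per_fold, 2L, stats::sd),
      row.names = NULL)
  }
  test_rows <- list()
  for (r in ratios) {
    m <- fit_and_eval(train_idx, test_idx, r)
    test_rows[[length(test_rows) + 1L]] <-
      data.frame(ratio = r, metric = names(m), value = unname(m),
                 row.names = NULL)
  }
  structure(list(cv = do.call(rbind, cv_rows),
                 test = do.call(rbind, test_rows),
                 ratios = ratios, k = k, seed = seed),
            class = "augmentation_result")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.augmentation_result <- function(x, ...) {
  cat(sprintf("<augmentation_result> ratios %s, %d-fold CV\n",
              paste(x$ratios, collapse = ","), x$k))
  acc <- x$cv[x$cv$metric == "Acc", ]
  cat("CV accuracy by ratio:\n")
  print(data.frame(ratio = acc$ratio,
                   mean = round(acc$mean, 4), sd = round(acc$sd, 4)),
        row.names = FALSE)
  invisible(x)
}

#' Saturation power-law fit of accuracy versus mixing ratio
#'
#' Fits `y = a * x^gamma + b` by least squares: for every candidate
#' `gamma` the conditional problem in `(a, b)` is linear and solved in
#' closed form; `gamma` itself is found on a grid over `(0, 3]` refined by
#' golden-section search. Points at `x = 0` contribute through the
#' intercept only (`0^gamma = 0`). Degenerate input (all `y` equal) returns
#' `a = 0, gamma = 1, b = mean(y)`.
#'
#' @param x mixing ratios (>= 3 points).
#' @param y mean accuracies at each ratio.
#' @return object of class `saturation_fit`: `a`, `gamma`, `b`, `SSR`, and
#'   the fitted values.
#' @examples
#' f <- fit_saturation(1:5, 8.6 * (1:5)^0.4 + 79.6)
#' unlist(f[c("a", "gamma", "b")])
#' @export
fit_saturation <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3, all(x >= 0))
  if (stats::sd(y) == 0) {
    return(structure(list(a = 0, gamma = 1, b = mean(y), SSR = 0,
                          fitted = rep(mean(y), length(y)),
                          x = x, y = y),
                     class = "saturation_fit"))
  }
  ssr_of <- function(g) {
    X <- cbind(1, x^g)
    fit <- stats::lm.fit(X, y)
    sum(fit$residuals^2)
  }
  grid <- seq(0.02, 3, length.out = 150)
  ss <- vapply(grid, ssr_of, 0)
  i0 <- which.min(ss)
  lo <- grid[max(1L, i0 - 1L)]; hi <- grid[min(length(grid), i0 + 1L)]
  # golden-section refinement
  phi <- (sqrt(5) - 1) / 2
  a1 <- hi - phi * (hi - lo); a2 <- lo + phi * (hi - lo)
  f1 <- ssr_of(a1); f2 <- ssr_of(a2)
  for (it in seq_len(80L)) {
    if (f1 < f2) {
      hi <- a2; a2 <- a1; f2 <- f1
      a1 <- hi - phi * (hi - lo); f1 <- ssr_of(a1)
    } else {
      lo <- a1; a1 <- a2; f1 <- f2
      a2 <- lo + phi * (hi - lo); f2 <- ssr_of(a2)
    }
    if (hi - lo < 1e-10) break
  }
  g <- (lo + hi) / 2
  X <- cbind(1, x^g)
  fit <- stats::lm.fit(X, y)
  structure(list(a = unname(fit$coefficients[2L]), gamma = g,
                 b = unname(fit$coefficients[1L]),
                 SSR = sum(fit$residuals^2),
                 fitted = as.vector(X %*% fit$coefficients),
                 x = x, y = y),
            class = "saturation_fit")
}

#' @export
print.saturation_fit <- function(x, ...) {
  cat(sprintf("<saturation_fit> y = %.4g * x^%.4g + %.4g  (SSR %.4g)\n",
              x$a, x$gamma, x$b, x$SSR))
  invisible(x)
}

#' @export
plot.saturation_fit <- function(x, ...) {
  graphics::plot(x$x, x$y, xlab = "mixing ratio", ylab = "accuracy", ...)
  xs <- seq(min(x$x), max(x$x), length.out = 200)
  graphics::lines(xs, x$a * xs^x$gamma + x$b)
  invisible(x)
}
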