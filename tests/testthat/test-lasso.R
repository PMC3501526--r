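test_that("orthonormal designs give soft-thresholded path coefficients", {
  set.seed(41)
  n <- 40; p <- 8
  # orthonormal columns spanning a centered space (zero column means)
  M <- matrix(rnorm(n * p), n, p)
  Q <- qr.Q(qr(sweep(M, 2, colMeans(M))))
  expect_lt(max(abs(crossprod(Q) - diag(p))), 1e-10)
  y <- ifelse(drop(Q %*% c(3, -2, 1.5, 1, 0, 0, 0, 0)) + rnorm(n, 0, 0.1) > 0,
              1, -1)
  fit <- lasso_path(Q, y, k_max = p, standardize = FALSE)
  cvec <- drop(crossprod(Q, y - mean(y)))
  # with X'X = I the lasso solution at penalty L is soft(c, L)
  for (j in seq_along(fit$lambda)) {
    L <- fit$lambda[j]
    expect_equal(fit$beta[, j], sign(cvec) * pmax(abs(cvec) - L, 0),
                 tolerance = 1e-8, ignore_attr = TRUE)
  }
})

test_that("the first entering feature maximizes absolute correlation", {
  set.seed(43)
  for (rep in 1:5) {
    X <- matrix(rnorm(30 * 20), 30, 20)
    y <- ifelse(rnorm(30) > 0, 1, -1)
    fit <- lasso_path(X, y, k_max = 5)
    expect_equal(unname(fit$entry_order[1]),
                 unname(which.max(abs(cor(scale(X), y - mean(y))))))
  }
})

test_that("path coefficients match a coordinate-descent oracle at breakpoints", {
  skip_if_not_installed("glmnet")
  set.seed(47)
  for (rep in 1:5) {
    X <- scale(matrix(rnorm(20 * 50), 20, 50))
    y <- ifelse(rnorm(20) > 0, 1, -1)
    yc <- y - mean(y)
    fit <- lasso_path(X, y, k_max = 10, standardize = FALSE)
    lam <- fit$lambda[fit$lambda > 1e-8]
    g <- glmnet::glmnet(X, yc, lambda = lam / nrow(X), standardize = FALSE,
                        intercept = FALSE, thresh = 1e-14)
    expect_lt(max(abs(as.matrix(g$beta) - fit$beta[, seq_along(lam)])), 1e-6)
  }
})

test_that("classifier extraction respects marker counts and entry order", {
  set.seed(51)
  X <- matrix(rnorm(30 * 10), 30, 10)
  colnames(X) <- letters[1:10]
  y <- ifelse(X[, 3] + 0.8 * X[, 7] + rnorm(30, 0, 0.4) > 0, 1, -1)
  fit <- lasso_path(X, y, k_max = 6)
  # k = 0 predicts the majority label
  cls0 <- classifier_at_k(fit, 0)
  expect_equal(unique(predict(cls0, X)), ifelse(mean(y) >= 0, 1, -1))
  for (k in 1:4) {
    cls <- classifier_at_k(fit, k)
    expect_length(cls$markers, k)
    expect_true(all(cls$beta != 0))
  }
  expect_error(classifier_at_k(fit, 50), "never")
  # separable 1-D problem: one marker suffices for zero training error
  x1 <- matrix(c(rep(-2, 10), rep(2, 10)) + rnorm(20, 0, 0.1), ncol = 1)
  colnames(x1) <- "m"
  y1 <- rep(c(-1, 1), each = 10)
  f1 <- lasso_path(x1, y1, k_max = 1)
  expect_equal(predict(classifier_at_k(f1, 1), x1), y1)
})

test_that("duplicate and constant columns are handled deterministically", {
  set.seed(53)
  base <- rnorm(24)
  X <- cbind(a = base, b = base, c = rnorm(24), d = rep(1, 24))
  y <- ifelse(base + rnorm(24, 0, 0.3) > 0, 1, -1)
  expect_warning(fit <- lasso_path(X, y, k_max = 2), "constant")
  # the earlier of two identical columns enters (deterministic tie-break)
  expect_equal(fit$features[fit$entry_order[1]], "a")
  fit2 <- suppressWarnings(lasso_path(X, y, k_max = 2))
  expect_identical(fit$entry_order, fit2$entry_order)
})

test_that("cross-validation is chance-level under shuffled labels and deterministic", {
  pm <- sim_matrix(n_peak = 40, n1 = 22, n2 = 23, ratio = 1.8, n_diff = 3,
                   seed = 55)
  x <- t(pm$intensity)
  set.seed(56)
  y_shuf <- sample(as_pm_labels(pm$samples$group))
  cv <- cross_validate(x, y_shuf, k_max = 5, n_repeats = 150, train_n = 36,
                       seed = 57)
  expect_true(all(cv$mean_error >= 0 & cv$mean_error <= 1))
  expect_true(all(abs(cv$mean_error[cv$k > 0] - 0.5) < 0.1))
  cv2 <- cross_validate(x, y_shuf, k_max = 5, n_repeats = 150, train_n = 36,
                        seed = 57)
  expect_identical(cv$mean_error, cv2$mean_error)
  # real labels with planted effects beat chance
  cv3 <- cross_validate(pm, k_max = 5, n_repeats = 150, train_n = 36, seed = 58)
  expect_lt(min(cv3$mean_error), 0.25)
})

test_that("selection frequencies are proportions with collinearity splitting", {
  pm <- sim_matrix(n_peak = 30, n1 = 22, n2 = 23, ratio = 2.2, n_diff = 2,
                   seed = 61)
  sf1 <- selection_frequency(pm, k = 3, n_repeats = 1, train_n = 36, seed = 62)
  expect_true(all(sf1$frequency %in% c(0, 1)))
  sf <- selection_frequency(pm, k = 3, n_repeats = 100, train_n = 36, seed = 63)
  expect_true(all(sf$frequency >= 0 & sf$frequency <= 1))
  expect_true(all(c("pk_0001", "pk_0002") %in% sf$peak_id[1:3]))
  # duplicated informative column splits frequency with its twin
  x <- t(pm$intensity)
  x <- cbind(x, pk_dup = x[, "pk_0001"] * (1 + rnorm(45, 0, 0.01)))
  y <- as_pm_labels(pm$samples$group)
  sfd <- selection_frequency(x, y, k = 3, n_repeats = 100, train_n = 36,
                             seed = 64)
  f_orig <- sfd$frequency[sfd$peak_id == "pk_0001"]
  f_dup <- sfd$frequency[sfd$peak_id == "pk_dup"]
  f_single <- sf$frequency[sf$peak_id == "pk_0001"]
  expect_gt(f_orig + f_dup, 0.6 * f_single)
  expect_lt(abs((f_orig + f_dup) - f_single), 0.5)
})
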