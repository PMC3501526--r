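# Homotopy (LARS) solution path of the squared-error LASSO, sparse
# classifiers cut from the path at a chosen marker count, and
# repeated-subsampling cross-validation with marker selection frequencies.

# Coerce labels to -1/+1 with ENU (or the second factor level) positive.
as_pm_labels <- function(y) {
  if (is.factor(y) || is.character(y)) {
    u <- sort(unique(as.character(y)))
    if (length(u) != 2) stop("labels must have exactly two classes")
    pos <- if ("ENU" %in% u) "ENU" else u[2L]
    ifelse(as.character(y) == pos, 1, -1)
  } else {
    if (!all(y %in% c(-1, 1))) stop("numeric labels must be -1/+1")
    as.numeric(y)
  }
}

#' Homotopy LASSO solution path
#'
#' Traces the piecewise-linear solution path of the squared-error LASSO
#' `1/2 ||y - X b||^2 + lambda ||b||_1` from `lambda = max |X'y|` downward,
#' adding or dropping one feature per breakpoint (LARS with the lasso
#' modification). The path terminates once `k_max` distinct features are
#' active and the segment they span is complete, so a classifier with the
#' desired number of markers can be cut from the path without computing the
#' rest.
#'
#' @param x Numeric matrix, samples x features (column names are feature
#'   ids). Standardized internally by default; duplicate-correlation ties
#'   break deterministically toward the earlier column (columns ordered by
#'   increasing m/z in peak matrices).
#' @param y Two-class labels: -1/+1 numeric, or factor/character (ENU is
#'   coded +1).
#' @param k_max Maximum number of distinct active features (default
#'   `min(n - 1, p)`).
#' @param standardize Center/scale columns to unit variance before fitting
#'   (training parameters are stored for prediction).
#' @param eps Numerical tolerance for breakpoint arithmetic.
#' @param warn_constant Warn when constant columns are removed.
#' @return An object of class `lasso_path`: `lambda` (breakpoint penalties,
#'   strictly decreasing, starting at the first entry), `beta` (features x
#'   breakpoints coefficient matrix on the standardized scale), `active`
#'   (list of active-feature index vectors per breakpoint), `entry_order`
#'   (feature indices in order of first entry), plus centering/scaling
#'   information.
#' @export
lasso_path <- function(x, y, k_max = NULL, standardize = TRUE, eps = 1e-9,
                       warn_constant = TRUE) {
  x <- as.matrix(x)
  y <- as_pm_labels(y)
  n <- nrow(x); p <- ncol(x)
  if (length(y) != n) stop("length of y must match rows of x")
  if (is.null(colnames(x))) colnames(x) <- sprintf("V%d", seq_len(p))
  keep <- apply(x, 2L, function(v) sd(v) > 0)
  if (!all(keep)) {
    if (warn_constant)
      warning(sprintf("removing %d constant column(s)", sum(!keep)))
    x <- x[, keep, drop = FALSE]
  }
  p_eff <- ncol(x)
  if (p_eff == 0L) stop("no non-constant features")
  if (is.null(k_max)) k_max <- min(n - 1L, p_eff)
  k_max <- min(k_max, n - 1L, p_eff)
  centers <- colMeans(x)
  scales <- if (standardize) apply(x, 2L, sd) else rep(1, p_eff)
  xs <- sweep(sweep(x, 2L, centers), 2L, scales, "/")
  ybar <- mean(y)
  yc <- y - ybar

  cvec <- drop(crossprod(xs, yc))
  lambda <- max(abs(cvec))
  j0 <- which.max(abs(cvec)) # ties: first column wins
  A <- j0
  sA <- sign(cvec[j0])
  beta <- numeric(p_eff)
  bp_lambda <- numeric(0)
  bp_beta <- list()
  bp_active <- list()
  entry_order <- j0
  max_steps <- 50L * (k_max + 1L)

  for (step in seq_len(max_steps)) {
    GA <- crossprod(xs[, A, drop = FALSE])
    dA <- tryCatch(solve(GA, sA), error = function(e)
      drop(MASS_ginv(GA) %*% sA))
    v <- xs[, A, drop = FALSE] %*% dA
    a <- drop(crossprod(xs, v))
    notA <- setdiff(seq_len(p_eff), A)
    gamma_entry <- Inf; j_entry <- NA_integer_
    if (length(notA)) {
      g1 <- (lambda - cvec[notA]) / (1 - a[notA])
      g2 <- (lambda + cvec[notA]) / (1 + a[notA])
      cand <- c(g1, g2)
      jj <- c(notA, notA)
      ok <- is.finite(cand) & cand > eps
      if (any(ok)) {
        gamma_entry <- min(cand[ok])
        j_entry <- jj[ok][which.min(cand[ok])]
      }
    }
    gamma_drop <- Inf; j_drop <- NA_integer_
    gd <- -beta[A] / dA
    okd <- is.finite(gd) & gd > eps
    if (any(okd)) {
      gamma_drop <- min(gd[okd])
      j_drop <- A[okd][which.min(gd[okd])]
    }
    # next event along the path: a coefficient hits zero (drop), a new
    # feature's correlation catches up (entry), or lambda reaches zero
    event <- if (gamma_drop <= gamma_entry && gamma_drop <= lambda) "drop"
      else if (gamma_entry <= lambda) "entry"
      else "end"
    gamma <- switch(event, drop = gamma_drop, entry = gamma_entry, end = lambda)

    beta[A] <- beta[A] + gamma * dA
    # recompute correlations from the residual at every breakpoint; the
    # incremental update drifts by ~1e-6 over a long path
    cvec <- drop(crossprod(xs, yc - xs[, A, drop = FALSE] %*% beta[A]))
    lambda <- if (event == "end") 0 else max(abs(cvec))
    bp_lambda <- c(bp_lambda, lambda)
    bp_beta[[length(bp_beta) + 1L]] <- beta
    bp_active[[length(bp_active) + 1L]] <- A

    if (event == "drop") {
      beta[j_drop] <- 0
      sA <- sA[A != j_drop]
      A <- A[A != j_drop]
      if (!length(A)) break
    } else if (event == "entry") {
      if (length(A) >= k_max) break # segment with k_max markers is complete
      A <- c(A, j_entry)
      sA <- c(sA, sign(cvec[j_entry]))
      if (!j_entry %in% entry_order) entry_order <- c(entry_order, j_entry)
    } else {
      break # lambda reached 0
    }
    if (lambda <= eps) break
  }

  structure(list(
    lambda = bp_lambda,
    beta = do.call(cbind, bp_beta),
    active = bp_active,
    entry_order = entry_order,
    features = colnames(x),
    centers = centers, scales = scales, y_mean = ybar,
    standardize = standardize, n = n, k_max = k_max
  ), class = "lasso_path")
}

# Minimal Moore-Penrose fallback for (near-)singular active Gram matrices.
MASS_ginv <- function(m, tol = 1e-10) {
  s <- svd(m)
  pos <- s$d > tol * s$d[1L]
  s$v[, pos, drop = FALSE] %*% (t(s$u[, pos, drop = FALSE]) / s$d[pos])
}

#' @export
print.lasso_path <- function(x, ...) {
  cat(sprintf("<lasso_path> %d breakpoints, %d features entered (k_max %d)\n",
              length(x$lambda), length(x$entry_order), x$k_max))
  cat("entry order:", paste(head(x$features[x$entry_order], 10L),
                            collapse = ", "),
      if (length(x$entry_order) > 10L) "..." else "", "\n")
  invisible(x)
}

#' @export
coef.lasso_path <- function(object, k = NULL, ...) {
  b <- object$beta
  rownames(b) <- object$features
  if (is.null(k)) return(b)
  classifier_at_k(object, k)$beta
}

#' @export
plot.lasso_path <- function(x, ...) {
  b <- x$beta
  matplot(x$lambda, t(b), type = "l", lty = 1, xlim = rev(range(x$lambda)),
          xlab = expression(lambda), ylab = "standardized coefficient", ...)
  abline(h = 0, col = "grey70")
  invisible(x)
}

#' Cut a k-marker classifier from a LASSO path
#'
#' Returns the path solution at the first breakpoint (in decreasing penalty)
#' with exactly `k` nonzero coefficients — the end of the segment in which
#' the k-th marker carries weight, just before the (k+1)-th would enter.
#' Prediction is the sign of the linear score; the intercept is the training
#' label mean, so `k = 0` predicts the majority label.
#'
#' @param path A [lasso_path()] object.
#' @param k Number of markers (0 <= k <= markers reached by the path).
#' @return An object of class `seldi_classifier`: `markers` (feature names),
#'   `beta` (named coefficients, standardized scale), `centers`, `scales`,
#'   `intercept`.
#' @export
classifier_at_k <- function(path, k) {
  stopifnot(inherits(path, "lasso_path"), k >= 0)
  if (k == 0) {
    cls <- list(markers = character(0), beta = numeric(0),
                centers = numeric(0), scales = numeric(0),
                intercept = path$y_mean)
    class(cls) <- "seldi_classifier"
    return(cls)
  }
  nz <- colSums(path$beta != 0)
  hit <- which(nz == k)
  if (!length(hit))
    stop(sprintf("path never fits exactly %d markers (max %d)", k, max(nz)))
  b <- path$beta[, hit[1L]]
  sel <- which(b != 0)
  cls <- list(markers = path$features[sel], beta = setNames(b[sel], path$features[sel]),
              centers = path$centers[sel], scales = path$scales[sel],
              intercept = path$y_mean)
  class(cls) <- "seldi_classifier"
  cls
}

#' @export
print.seldi_classifier <- function(x, ...) {
  cat(sprintf("<seldi_classifier> %d markers, intercept %.3f\n",
              length(x$markers), x$intercept))
  if (length(x$beta)) print(round(x$beta, 4))
  invisible(x)
}

#' @export
predict.seldi_classifier <- function(object, newx, type = c("class", "score"),
                                     ...) {
  type <- match.arg(type)
  newx <- as.matrix(newx)
  if (!length(object$markers)) {
    score <- rep(object$intercept, nrow(newx))
  } else {
    cols <- match(object$markers, colnames(newx))
    if (anyNA(cols)) stop("newx lacks marker columns")
    xs <- sweep(sweep(newx[, cols, drop = FALSE], 2L, object$centers),
                2L, object$scales, "/")
    score <- drop(xs %*% object$beta) + object$intercept
  }
  if (type == "score") score else ifelse(score >= 0, 1, -1)
}

# Group-proportional (or simple) subsample of size train_n; returns indices.
draw_train <- function(y, train_n, proportional) {
  n <- length(y)
  if (proportional) {
    idx_pos <- which(y > 0); idx_neg <- which(y < 0)
    n_pos <- round(train_n * length(idx_pos) / n)
    n_pos <- min(max(n_pos, 1L), length(idx_pos), train_n - 1L)
    n_neg <- train_n - n_pos
    c(sample(idx_pos, n_pos), sample(idx_neg, n_neg))
  } else {
    repeat {
      tr <- sample.int(n, train_n)
      if (length(unique(sign(y[tr]))) == 2L) return(tr)
    }
  }
}

# Shared engine: repeated subsample -> fit path on train -> held-out error
# per marker count, and active sets at k_select. With refit = TRUE the k
# selected markers are refit by unpenalized least squares on the training
# subsample (LARS-OLS hybrid) before evaluation; FALSE evaluates the shrunk
# path coefficients.
subsample_runs <- function(x, y, k_max, n_repeats, train_n, seed,
                           proportional = TRUE, k_select = NULL,
                           refit = TRUE) {
  n <- nrow(x)
  stopifnot(train_n < n, n_repeats >= 1)
  err <- matrix(NA_real_, n_repeats, k_max + 1L,
                dimnames = list(NULL, paste0("k", 0:k_max)))
  sel_count <- setNames(numeric(ncol(x)), colnames(x))
  n_success <- 0L
  with_seed(seed, {
    for (rep_i in seq_len(n_repeats)) {
      tr <- draw_train(y, train_n, proportional)
      te <- setdiff(seq_len(n), tr)
      fit <- suppressWarnings(
        lasso_path(x[tr, , drop = FALSE], y[tr], k_max = k_max,
                   warn_constant = FALSE))
      nz <- colSums(fit$beta != 0)
      err[rep_i, 1L] <- mean(ifelse(fit$y_mean >= 0, 1, -1) != y[te])
      for (k in seq_len(k_max)) {
        hit <- which(nz == k)
        if (!length(hit)) next
        if (refit) {
          sel <- match(fit$features[fit$beta[, hit[1L]] != 0], colnames(x))
          cf <- lm.fit(cbind(1, x[tr, sel, drop = FALSE]), y[tr])$coefficients
          cf[is.na(cf)] <- 0
          score <- drop(cbind(1, x[te, sel, drop = FALSE]) %*% cf)
          pred <- ifelse(score >= 0, 1, -1)
        } else {
          pred <- predict(classifier_at_k(fit, k), x[te, , drop = FALSE])
        }
        err[rep_i, k + 1L] <- mean(pred != y[te])
      }
      if (!is.null(k_select)) {
        hit <- which(nz == k_select)
        if (length(hit)) {
          mk <- fit$features[fit$beta[, hit[1L]] != 0]
          sel_count[mk] <- sel_count[mk] + 1
          n_success <- n_success + 1L
        }
      }
    }
  })
  list(err = err, sel_count = sel_count, n_success = n_success)
}

# Accept either a peak_matrix (+ implicit ENU/control labels) or a plain
# samples x features matrix with labels.
as_xy <- function(x, labels = NULL) {
  if (inherits(x, "peak_matrix")) {
    mat <- t(x$intensity)
    colnames(mat) <- x$peaks$peak_id
    y <- as_pm_labels(x$samples$group)
    ok_cols <- colSums(is.na(mat)) == 0
    list(x = mat[, ok_cols, drop = FALSE], y = y)
  } else {
    if (is.null(labels)) stop("labels required for a plain matrix")
    list(x = as.matrix(x), y = as_pm_labels(labels))
  }
}

#' Cross-validated error versus marker count
#'
#' Repeatedly subsamples a training set (group-proportional by default),
#' fits the homotopy LASSO path on the training samples only (standardization
#' parameters are estimated on the training folds, avoiding leakage), and
#' records the held-out misclassification fraction of the k-marker classifier
#' for every k. The reported curve is the mean over repeats.
#'
#' @param x A `peak_matrix` (ENU vs control labels implied) or samples x
#'   features matrix.
#' @param labels Labels when `x` is a plain matrix.
#' @param k_max Largest marker count evaluated (default 15).
#' @param n_repeats Number of subsampling repeats (default 1000).
#' @param train_n Training-set size per repeat (default 36; e.g. 36 of 45
#'   leaves 9 held out).
#' @param seed Integer seed.
#' @param proportional Group-proportional subsampling (default) or simple
#'   random with redraw on degenerate draws.
#' @param refit Refit the k selected markers by unpenalized least squares on
#'   the training subsample before evaluating held-out error (default TRUE;
#'   the LARS-OLS hybrid). With FALSE the shrunk path coefficients are
#'   evaluated, whose held-out error decreases quasi-monotonically in k as
#'   the penalty relaxes, masking the marker-count trade-off the curve is
#'   meant to expose.
#' @return An object of class `seldi_cv`: data frame `k`, `mean_error`,
#'   `n_eval`; attributes record the configuration.
#' @export
cross_validate <- function(x, labels = NULL, k_max = 15, n_repeats = 1000,
                           train_n = 36, seed = NULL, proportional = TRUE,
                           refit = TRUE) {
  xy <- as_xy(x, labels)
  runs <- subsample_runs(xy$x, xy$y, k_max = k_max, n_repeats = n_repeats,
                         train_n = train_n, seed = seed,
                         proportional = proportional, refit = refit)
  out <- data.frame(k = 0:k_max,
                    mean_error = colMeans(runs$err, na.rm = TRUE),
                    n_eval = colSums(!is.na(runs$err)))
  structure(out, n_repeats = n_repeats, train_n = train_n,
            class = c("seldi_cv", "data.frame"))
}

#' @export
print.seldi_cv <- function(x, ...) {
  cat(sprintf("<seldi_cv> %d repeats, train n = %d\n",
              attr(x, "n_repeats"), attr(x, "train_n")))
  print.data.frame(x, row.names = FALSE, digits = 4)
  best <- x$k[which.min(x$mean_error)]
  cat(sprintf("minimum mean error %.3f at k = %d\n", min(x$mean_error), best))
  invisible(x)
}

#' @export
plot.seldi_cv <- function(x, ...) {
  plot(x$k, x$mean_error, type = "b", pch = 19,
       xlab = "number of markers", ylab = "mean held-out error", ...)
  abline(v = x$k[which.min(x$mean_error)], lty = 2, col = "grey50")
  invisible(x)
}

#' Marker selection frequencies at a fixed classifier size
#'
#' Fraction of subsampling repeats in which each peak belongs to the k-marker
#' classifier, sorted descending — a stability-selection view of which
#' markers the LASSO relies on. Aliased peaks compete as separate features;
#' join alias annotations afterwards for reporting.
#'
#' @inheritParams cross_validate
#' @param k Classifier size at which selection is recorded (default 5).
#' @return An object of class `selection_table`: data frame `peak_id`,
#'   `frequency` (in \[0, 1\]); attribute `n_success` counts repeats that
#'   reached k markers.
#' @export
selection_frequency <- function(x, labels = NULL, k = 5, n_repeats = 1000,
                                train_n = 36, seed = NULL,
                                proportional = TRUE, k_max = NULL) {
  if (is.null(k_max)) k_max <- k
  xy <- as_xy(x, labels)
  runs <- subsample_runs(xy$x, xy$y, k_max = k_max, n_repeats = n_repeats,
                         train_n = train_n, seed = seed,
                         proportional = proportional, k_select = k)
  freq <- runs$sel_count / n_repeats
  out <- data.frame(peak_id = names(freq), frequency = as.numeric(freq),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$frequency), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, k = k, n_repeats = n_repeats, n_success = runs$n_success,
            class = c("selection_table", "data.frame"))
}

#' @export
print.selection_table <- function(x, n = 10, ...) {
  cat(sprintf("<selection_table> k = %d, %d repeats (%d reached k)\n",
              attr(x, "k"), attr(x, "n_repeats"), attr(x, "n_success")))
  print.data.frame(head(x, n), row.names = FALSE, digits = 3)
  invisible(x)
}
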