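# Nonparametric per-peak testing and permutation-based global/local false
# discovery rates, plus the contingency and suppression diagnostics.

#' Mann-Whitney U test (two-sided)
#'
#' Rank-sum comparison of two intensity groups. Uses the exact null
#' distribution (no-tie case, total n <= 12) and otherwise a tie-corrected
#' normal approximation with continuity correction. When every pooled value
#' is identical the test is degenerate and p = 1.
#'
#' @param x,y Numeric vectors (each of length >= 2).
#' @return List with `statistic` (U for `x`), `p.value`, and `method`.
#' @examples
#' mann_whitney(c(5, 6, 7), c(1, 2, 3)) # U = 9, p = 0.1
#' @export
mann_whitney <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  if (n1 < 2 || n2 < 2) stop("each group needs at least 2 values")
  pooled <- c(x, y)
  r <- rank(pooled)
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  tt <- tabulate(match(pooled, unique(pooled)))
  tiesum <- sum(tt^3 - tt)
  N <- n1 + n2
  if (tiesum == 0 && N <= 12) {
    p <- min(1, 2 * min(pwilcox(U, n1, n2), 1 - pwilcox(U - 1, n1, n2)))
    method <- "exact"
  } else {
    sigma2 <- n1 * n2 / 12 * ((N + 1) - tiesum / (N * (N - 1)))
    if (sigma2 <= 0) {
      p <- 1
      method <- "degenerate"
    } else {
      z <- U - n1 * n2 / 2
      z <- (z - sign(z) * 0.5) / sqrt(sigma2)
      p <- min(1, 2 * pnorm(-abs(z)))
      method <- "normal approximation, tie-corrected"
    }
  }
  list(statistic = U, p.value = p, method = method, n1 = n1, n2 = n2)
}

# Vectorized Mann-Whitney p-values for all rows of a matrix, for one or many
# group-1 membership indicator columns (label permutations reuse the rank
# matrix). Branch rules identical to mann_whitney().
mwu_pmat <- function(mat, masks) {
  masks <- as.matrix(masks)
  storage.mode(masks) <- "double"
  ns <- ncol(mat)
  np <- nrow(mat)
  R <- t(apply(mat, 1L, rank))
  if (np == 1L) R <- matrix(R, nrow = 1L)
  n1 <- colSums(masks)
  n2 <- ns - n1
  U <- R %*% masks - matrix(n1 * (n1 + 1) / 2, np, ncol(masks), byrow = TRUE)
  tiesum <- apply(mat, 1L, function(v) {
    tt <- tabulate(match(v, unique(v)))
    sum(tt^3 - tt)
  })
  rowfac <- (ns + 1) - tiesum / (ns * (ns - 1))
  sigma2 <- outer(rowfac, n1 * n2 / 12)
  mu <- matrix(n1 * n2 / 2, np, ncol(masks), byrow = TRUE)
  z <- U - mu
  z <- (z - sign(z) * 0.5) / sqrt(pmax(sigma2, .Machine$double.eps))
  p <- 2 * pnorm(-abs(z))
  p[p > 1] <- 1
  p[sigma2 <= 0] <- 1
  if (ns <= 12) {
    exact_rows <- which(tiesum == 0)
    if (length(exact_rows)) {
      for (k in seq_len(ncol(masks))) {
        u <- U[exact_rows, k]
        pe <- pmin(1, 2 * pmin(pwilcox(u, n1[k], n2[k]),
                               1 - pwilcox(u - 1, n1[k], n2[k])))
        p[exact_rows, k] <- pe
      }
    }
  }
  list(p = p, U = U)
}

# Complete-case rows of a peak matrix restricted to one age.
pm_for_test <- function(pm, age, exclude = NULL) {
  sub <- pm_subset(pm, age = age, exclude = exclude)
  groups <- unique(sub$samples$group)
  if (!all(c("ENU", "control") %in% groups))
    stop(sprintf("both groups must be present at age %s", age))
  sub
}

#' Rank all peaks by Mann-Whitney tests at one age
#'
#' Tests every complete peak (ENU vs control) at the given age and returns a
#' table of group means, standard errors, U statistics and two-sided
#' p-values, sorted by ascending p. `local_fdr` is left `NA` (see
#' [local_fdr()]). Peaks with missing cells at this age are excluded from
#' testing and reported with `NA` p at the bottom.
#'
#' @param pm A `peak_matrix`.
#' @param age Age label to test.
#' @param exclude Sample ids to exclude (e.g. blood-flagged).
#' @return Data frame with one row per peak: `peak_id`, `mz`, `age`,
#'   `n_enu`, `n_ctl`, `mean_enu`, `sem_enu`, `mean_ctl`, `sem_ctl`,
#'   `u_stat`, `p_value`, `local_fdr`.
#' @export
test_all_peaks <- function(pm, age, exclude = NULL) {
  sub <- pm_for_test(pm, age, exclude)
  g1 <- sub$samples$group == "ENU"
  mat <- sub$intensity
  complete <- rowSums(is.na(mat)) == 0
  res <- data.frame(
    peak_id = sub$peaks$peak_id, mz = sub$peaks$mz, age = age,
    n_enu = sum(g1), n_ctl = sum(!g1),
    mean_enu = rowMeans(mat[, g1, drop = FALSE], na.rm = TRUE),
    sem_enu = apply(mat[, g1, drop = FALSE], 1, sd, na.rm = TRUE) / sqrt(sum(g1)),
    mean_ctl = rowMeans(mat[, !g1, drop = FALSE], na.rm = TRUE),
    sem_ctl = apply(mat[, !g1, drop = FALSE], 1, sd, na.rm = TRUE) / sqrt(sum(!g1)),
    u_stat = NA_real_, p_value = NA_real_, local_fdr = NA_real_,
    stringsAsFactors = FALSE)
  if (any(complete)) {
    mp <- mwu_pmat(mat[complete, , drop = FALSE], matrix(as.numeric(g1)))
    res$u_stat[complete] <- mp$U[, 1L]
    res$p_value[complete] <- mp$p[, 1L]
  }
  res <- res[order(res$p_value, na.last = TRUE), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# Permutation masks preserving group sizes within the age stratum.
perm_masks <- function(ns, n1, n_perm) {
  m <- matrix(0, ns, n_perm)
  for (k in seq_len(n_perm)) m[sample.int(ns, n1), k] <- 1
  m
}

#' Global false-discovery curve from label permutations
#'
#' Compares the number of peaks discovered at each p-value threshold (up to
#' 0.05) with the average number discovered when group labels are randomly
#' permuted within the age stratum. Permutations preserve group sizes by
#' construction.
#'
#' @param pm A `peak_matrix`.
#' @param age Age label.
#' @param n_perm Number of label permutations (default 100).
#' @param seed Integer seed for the permutations.
#' @param thresholds Ascending p-value grid (max 0.05 by convention).
#' @param exclude Sample ids to exclude.
#' @return An object of class `fdr_curve`: data frame with `threshold`,
#'   `observed`, `null_mean`; attributes `n_perm`, `n_peaks`, `age`.
#' @export
global_fdr_curve <- function(pm, age, n_perm = 100, seed = NULL,
                             thresholds = seq(0.001, 0.05, by = 0.001),
                             exclude = NULL) {
  stopifnot(n_perm >= 1)
  sub <- pm_for_test(pm, age, exclude)
  g1 <- sub$samples$group == "ENU"
  mat <- sub$intensity
  mat <- mat[rowSums(is.na(mat)) == 0, , drop = FALSE]
  obs <- mwu_pmat(mat, matrix(as.numeric(g1)))$p[, 1L]
  null_p <- with_seed(seed, {
    masks <- perm_masks(ncol(mat), sum(g1), n_perm)
    mwu_pmat(mat, masks)$p
  })
  observed <- vapply(thresholds, function(t) sum(obs <= t), numeric(1))
  null_mean <- vapply(thresholds, function(t) mean(colSums(null_p <= t)),
                      numeric(1))
  structure(data.frame(threshold = thresholds, observed = observed,
                       null_mean = null_mean),
            n_perm = n_perm, n_peaks = nrow(mat), age = age,
            class = c("fdr_curve", "data.frame"))
}

#' @export
print.fdr_curve <- function(x, ...) {
  cat(sprintf("<fdr_curve> age %s: %d peaks, %d permutations\n",
              attr(x, "age"), attr(x, "n_peaks"), attr(x, "n_perm")))
  sel <- x$threshold %in% c(0.001, 0.005, 0.01, 0.02, 0.05)
  print.data.frame(x[sel | seq_len(nrow(x)) == nrow(x), ], row.names = FALSE)
  invisible(x)
}

#' @export
plot.fdr_curve <- function(x, ...) {
  matplot(x$threshold, cbind(x$observed, x$null_mean), type = "b",
          pch = c(3, 1), lty = 1, col = c("black", "grey50"),
          xlab = "p-value threshold", ylab = "number of discoveries", ...)
  legend("topleft", c("observed", "permutation null"), pch = c(3, 1),
         col = c("black", "grey50"), bty = "n")
  invisible(x)
}

#' Local false discovery rate by permutation density ratio
#'
#' For each peak with observed p-value p_i, the local FDR is estimated as the
#' permutation-null density of p-values around p_i divided by the observed
#' density: counts are taken in a multiplicative window
#' \[p_i / c, p_i * c\] (symmetric on the log-p scale, window factor
#' `bandwidth`), the null count is averaged over label permutations of all
#' peaks, and the ratio is clipped to \[0, 1\] and monotonized to be
#' non-decreasing in p by an isotonic regression pass. Windows holding fewer
#' than 5 observed p-values are widened until they do.
#'
#' @param pm A `peak_matrix`.
#' @param age Age label.
#' @param n_perm Number of label permutations (default 100).
#' @param bandwidth Multiplicative window half-width factor c > 1 on the
#'   p-scale (default 2).
#' @param seed Integer seed.
#' @param exclude Sample ids to exclude.
#' @return The [test_all_peaks()] table with the `local_fdr` column filled.
#' @export
local_fdr <- function(pm, age, n_perm = 100, bandwidth = 2, seed = NULL,
                      exclude = NULL) {
  stopifnot(n_perm >= 1, bandwidth > 1)
  tests <- test_all_peaks(pm, age, exclude = exclude)
  sub <- pm_for_test(pm, age, exclude)
  g1 <- sub$samples$group == "ENU"
  mat <- sub$intensity
  mat <- mat[rowSums(is.na(mat)) == 0, , drop = FALSE]
  null_p <- with_seed(seed, {
    masks <- perm_masks(ncol(mat), sum(g1), n_perm)
    as.numeric(mwu_pmat(mat, masks)$p)
  })
  have <- !is.na(tests$p_value)
  p_obs <- tests$p_value[have]
  lfdr <- vapply(p_obs, function(p) {
    cc <- bandwidth
    repeat {
      lo <- p / cc; hi <- min(1, p * cc)
      n_obs <- sum(p_obs >= lo & p_obs <= hi)
      if (n_obs >= 5 || cc > 1e6) break
      cc <- cc * 1.5
    }
    n_null <- sum(null_p >= lo & null_p <= hi) / n_perm
    min(1, n_null / max(n_obs, 1))
  }, numeric(1))
  # isotonic monotonization in p (tests are already sorted by ascending p)
  ord <- order(p_obs)
  lfdr[ord] <- isoreg(lfdr[ord])$yf
  tests$local_fdr[have] <- pmin(pmax(lfdr, 0), 1)
  tests
}

#' Pearson chi-square test of homogeneity
#'
#' Homogeneity of outcome proportions across groups (e.g. microtumor
#' incidence across ages), df = (rows - 1)(cols - 1), no continuity
#' correction.
#'
#' @param counts Matrix or data frame of non-negative integer cell counts
#'   (rows = groups, columns = outcomes).
#' @return List with `statistic`, `df`, `p.value` and `expected`.
#' @examples
#' chi_square_homogeneity(rbind(P30 = c(0, 20), P60 = c(4, 18), P90 = c(14, 7)))
#' @export
chi_square_homogeneity <- function(counts) {
  m <- as.matrix(counts)
  if (any(m < 0) || any(m != round(m))) stop("counts must be non-negative integers")
  if (any(rowSums(m) == 0) || any(colSums(m) == 0))
    stop("zero marginal total")
  ht <- suppressWarnings(chisq.test(m, correct = FALSE))
  if (any(ht$expected <= 0)) stop("all expected counts must be positive")
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p.value = unname(ht$p.value), expected = ht$expected)
}

#' Ion-suppression diagnostic for a peak pair
#'
#' Least-squares regression of peak `b` on peak `a` across every sample
#' (all ages and both groups pooled), with the Pearson correlation. A strong
#' negative correlation between an abundant peak and a co-detected peak is
#' the signature of ionization suppression rather than a true group effect.
#'
#' @param pm A `peak_matrix`.
#' @param peak_a,peak_b Peak ids (suppressor, target).
#' @return List with `r`, `slope`, `intercept`, `n`.
#' @export
suppression_diagnostic <- function(pm, peak_a, peak_b) {
  ia <- match(peak_a, pm$peaks$peak_id)
  ib <- match(peak_b, pm$peaks$peak_id)
  if (is.na(ia) || is.na(ib)) stop("peak id not found")
  a <- pm$intensity[ia, ]
  b <- pm$intensity[ib, ]
  ok <- is.finite(a) & is.finite(b)
  a <- a[ok]; b <- b[ok]
  if (sd(a) == 0 || sd(b) == 0) stop("zero variance in one of the peaks")
  fit <- lm(b ~ a)
  list(r = cor(a, b), slope = unname(coef(fit)[2L]),
       intercept = unname(coef(fit)[1L]), n = length(a))
}

#' Group test on the per-sample sum of a proteoform family
#'
#' Sums the intensities of a family of related peaks (e.g. the unmodified
#' protein and its adducts) within each sample, then applies the
#' Mann-Whitney test at one age. When the family redistributes mass among
#' its forms but conserves the total, this test should be null even though
#' individual forms differ.
#'
#' @param pm A `peak_matrix`.
#' @param family Character vector of peak ids (non-empty).
#' @param age Age label.
#' @param exclude Sample ids to exclude.
#' @return One-row data frame in the [test_all_peaks()] layout with
#'   `peak_id = "sum(<k> peaks)"`.
#' @export
proteoform_sum_test <- function(pm, family, age, exclude = NULL) {
  stopifnot(length(family) >= 1)
  idx <- match(family, pm$peaks$peak_id)
  if (anyNA(idx)) stop("unknown peak id in family: ",
                       paste(family[is.na(idx)], collapse = ", "))
  sub <- pm_for_test(pm, age, exclude)
  g1 <- sub$samples$group == "ENU"
  sums <- colSums(sub$intensity[idx, , drop = FALSE])
  mw <- mann_whitney(sums[g1], sums[!g1])
  data.frame(
    peak_id = sprintf("sum(%d peaks)", length(family)),
    mz = NA_real_, age = age, n_enu = sum(g1), n_ctl = sum(!g1),
    mean_enu = mean(sums[g1]), sem_enu = sd(sums[g1]) / sqrt(sum(g1)),
    mean_ctl = mean(sums[!g1]), sem_ctl = sd(sums[!g1]) / sqrt(sum(!g1)),
    u_stat = mw$statistic, p_value = mw$p.value, local_fdr = NA_real_,
    stringsAsFactors = FALSE)
}
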