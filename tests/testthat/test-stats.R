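test_that("Mann-Whitney matches its exact enumeration oracle and rank invariance", {
  mw <- mann_whitney(c(5, 6, 7), c(1, 2, 3))
  expect_equal(mw$statistic, 9)
  expect_equal(mw$p.value, 0.1)
  # identical groups are degenerate
  expect_equal(mann_whitney(c(2, 2, 2), c(2, 2, 2))$p.value, 1)
  # exact branch vs exhaustive enumeration for every split with N <= 10
  set.seed(21)
  for (n1 in 2:8) for (n2 in 2:(10 - n1)) {
    if (n1 + n2 > 10) next
    for (rep in 1:3) {
      x <- rnorm(n1); y <- rnorm(n2, 0.5)
      expect_equal(mann_whitney(x, y)$p.value, mwu_exact_oracle(x, y),
                   tolerance = 1e-12,
                   label = sprintf("split %d/%d", n1, n2))
    }
  }
  # invariance under strictly monotone transforms of the pooled data
  x <- rlnorm(8); y <- rlnorm(9, 0.4)
  p0 <- mann_whitney(x, y)$p.value
  expect_equal(mann_whitney(log(x), log(y))$p.value, p0)
  expect_equal(mann_whitney(x^3, y^3)$p.value, p0)
  expect_error(mann_whitney(1, c(1, 2)), "at least 2")
})

test_that("tie-corrected approximation agrees with wilcox.test", {
  set.seed(5)
  for (rep in 1:10) {
    x <- round(rnorm(15, 5, 2)) # ties on purpose
    y <- round(rnorm(18, 6, 2))
    ours <- mann_whitney(x, y)
    ref <- suppressWarnings(wilcox.test(x, y, correct = TRUE, exact = FALSE))
    expect_equal(ours$statistic, unname(ref$statistic))
    expect_equal(ours$p.value, ref$p.value, tolerance = 1e-9)
  }
})

test_that("chi-square homogeneity reproduces closed forms", {
  cs <- chi_square_homogeneity(rbind(P30 = c(0, 20), P60 = c(4, 18),
                                     P90 = c(14, 7)))
  expect_equal(cs$statistic, 24.097, tolerance = 1e-3)
  expect_equal(cs$df, 2)
  expect_lt(cs$p.value, 0.001)
  eq <- chi_square_homogeneity(rbind(c(5, 10), c(10, 20)))
  expect_equal(eq$statistic, 0, tolerance = 1e-12)
  expect_equal(eq$p.value, 1)
  diag2 <- chi_square_homogeneity(rbind(c(10, 0), c(0, 10)))
  expect_equal(diag2$statistic, 20)
  expect_equal(diag2$df, 1)
  expect_error(chi_square_homogeneity(rbind(c(0, 0), c(5, 5))), "marginal")
})

test_that("peak ranking orders by p and flags degenerate groups", {
  pm <- sim_matrix(n_peak = 60, n1 = 10, n2 = 10, ratio = 4, n_diff = 1,
                   cv = 0.2, seed = 3)
  tests <- test_all_peaks(pm, "P90")
  expect_equal(tests$peak_id[1], "pk_0001") # huge effect ranks first
  expect_true(!is.unsorted(tests$p_value))
  expect_equal(tests$n_enu[1], 10)
  pm_one <- pm_subset(pm, exclude = pm$samples$sample_id[pm$samples$group == "ENU"])
  expect_error(test_all_peaks(pm_one, "P90"), "both groups")
})

test_that("null matrices give binomial-consistent discovery counts", {
  counts <- vapply(1:10, function(s) {
    pm <- sim_matrix(n_peak = 100, seed = 400 + s)
    sum(test_all_peaks(pm, "P90")$p_value < 0.05)
  }, numeric(1))
  # mean near 5 per 100 peaks; generous Monte-Carlo band
  expect_gt(mean(counts), 2)
  expect_lt(mean(counts), 9)
})

test_that("the permutation null curve matches its analytic expectation", {
  pm <- sim_matrix(n_peak = 150, seed = 17)
  fc <- global_fdr_curve(pm, "P90", n_perm = 300, seed = 18)
  at <- function(curve, t) which.min(abs(curve$threshold - t))
  null05 <- fc$null_mean[at(fc, 0.05)]
  expect_equal(null05, 0.05 * 150, tolerance = 0.2)
  expect_true(!is.unsorted(fc$observed))
  expect_true(!is.unsorted(fc$null_mean))
  # under the null, observed within Monte-Carlo reach of the null curve
  expect_lt(abs(fc$observed[at(fc, 0.05)] - null05), 3 * sqrt(null05) + 3)
  # with planted effects the observed curve dominates the null
  pm2 <- sim_matrix(n_peak = 150, n_diff = 25, ratio = 1.8, seed = 19)
  fc2 <- global_fdr_curve(pm2, "P90", n_perm = 100, seed = 20)
  expect_gt(fc2$observed[at(fc2, 0.01)], 3 * fc2$null_mean[at(fc2, 0.01)])
})

test_that("local FDR separates planted effects from nulls and is monotone", {
  pm <- sim_matrix(n_peak = 150, n_diff = 25, ratio = 1.9, cv = 0.25, seed = 23)
  lf <- local_fdr(pm, "P90", n_perm = 100, seed = 24)
  planted <- lf$peak_id %in% sprintf("pk_%04d", 1:25)
  expect_gt(mean(lf$local_fdr[planted] < 0.05), 0.8)
  expect_gte(median(lf$local_fdr[!planted]), 0.25)
  expect_true(all(lf$local_fdr >= 0 & lf$local_fdr <= 1))
  expect_true(!is.unsorted(lf$local_fdr)) # rows sorted by p; lfdr monotone
  # all-identical intensities: local FDR 1 everywhere
  flat <- make_pm(matrix(5, 20, 20), rep(c("ENU", "control"), each = 10),
                  rep("P90", 20))
  lf_flat <- local_fdr(flat, "P90", n_perm = 20, seed = 1)
  expect_true(all(lf_flat$local_fdr == 1))
  # under the global null the average local FDR is high
  pm0 <- sim_matrix(n_peak = 150, seed = 29)
  lf0 <- local_fdr(pm0, "P90", n_perm = 100, seed = 30)
  expect_gte(mean(lf0$local_fdr), 0.8)
})

test_that("suppression diagnostic recovers exact and null relationships", {
  n <- 40
  a <- seq(1, 5, length.out = n)
  mat <- rbind(a = a, b = -2 * a + 10)
  pm <- make_pm(mat, rep(c("ENU", "control"), each = n / 2), rep("P90", n))
  d <- suppression_diagnostic(pm, "pk_0001", "pk_0002")
  expect_equal(d$r, -1)
  expect_equal(d$slope, -2)
  expect_equal(d$intercept, 10)
  # independent peaks: |r| small in most seeds
  rs <- vapply(1:20, function(s) {
    set.seed(s)
    m <- rbind(rlnorm(45, 2, 0.3), rlnorm(45, 1, 0.3))
    suppression_diagnostic(
      make_pm(m, rep(c("ENU", "control"), c(22, 23)), rep("P90", 45)),
      "pk_0001", "pk_0002")$r
  }, numeric(1))
  expect_gte(mean(abs(rs) < 0.3), 0.9)
  const <- make_pm(rbind(rep(1, 10), rnorm(10)),
                   rep(c("ENU", "control"), each = 5), rep("P90", 10))
  expect_error(suppression_diagnostic(const, "pk_0001", "pk_0002"), "variance")
})

test_that("proteoform sum tests behave additively and match single peaks", {
  pm <- sim_matrix(n_peak = 10, n1 = 8, n2 = 8, ratio = 2, n_diff = 1, seed = 31)
  single <- proteoform_sum_test(pm, "pk_0001", "P90")
  direct <- test_all_peaks(pm, "P90")
  expect_equal(single$p_value, direct$p_value[direct$peak_id == "pk_0001"])
  fam <- proteoform_sum_test(pm, c("pk_0002", "pk_0003"), "P90")
  g <- pm$samples$group == "ENU"
  sums <- colSums(pm$intensity[c("pk_0002", "pk_0003"), ])
  expect_equal(fam$mean_enu, mean(sums[g]))
  expect_error(proteoform_sum_test(pm, "nope", "P90"), "unknown")
})
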