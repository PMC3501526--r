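# Shared fixtures and independent oracles, all built in code.

# Tiny fast cohort: one age, a handful of proteins, small groups.
small_panel <- function() {
  list(
    protein_spec("big", 66110, 15, effect = c(P90 = 1.5), cv = 0.2,
                 aliases = c(z2 = 0.3, dimer = 0.05)),
    protein_spec("mid", 13601, 40, effect = c(P90 = 1), cv = 0.2,
                 aliases = c(z2 = 0.2)),
    protein_spec("small", 3493, 6, effect = c(P90 = 1.8), cv = 0.4),
    protein_spec("flat", 22893, 20, effect = c(P90 = 1), cv = 0.15)
  )
}

small_cohort <- function(seed = 42, n = 6, noise_sd = 0.1, cv_scale = 1,
                         panel = small_panel()) {
  if (cv_scale != 1)
    panel <- lapply(panel, function(p) { p$cv <- p$cv * cv_scale; p })
  simulate_cohort(
    cohort_design(ages = "P90", n_enu = n, n_control = n, seed = seed),
    proteins = panel,
    model = spectrum_model(noise_sd = noise_sd),
    suppression = list()
  )
}

# Printed peak list of the P90 top-27 table (plus the doubly-charged alias
# parent 13840 named in its notes), with laser-energy tier and ENU mean
# intensity. The printed table is an input.
table2_peaks <- function() {
  df <- data.frame(
    mz = c(6909, 6859, 22054, 66110, 46643, 13725, 3493, 27410, 22893,
           21365, 6823, 33109, 36781, 14120, 110080, 13670, 131938, 3504,
           38453, 21593, 6795, 13913, 27538, 2887, 6865, 13788, 13601,
           13840),
    tier = c("med", "med", "med", "high", "high", "med", "low", "med",
             "high", "high", "med", "high", "high", "med", "high", "med",
             "high", "low", "high", "high", "med", "med", "med", "low",
             "low", "med", "med", "med"),
    mean_enu = c(9.97, 14.07, 1.00, 17.04, 0.24, 74.09, 12.17, 0.59, 17.94,
                 3.39, 9.85, 5.24, 0.74, 24.90, 0.03, 49.70, 0.76, 2.75,
                 0.65, 3.30, 16.26, 122.75, 0.81, 2.38, 11.02, 51.29,
                 80.66, NA),
    stringsAsFactors = FALSE
  )
  df$peak_id <- sprintf("%s_%d", df$tier, df$mz)
  df$lo <- df$mz * 0.997
  df$hi <- df$mz * 1.003
  df$snr <- NA_real_
  df
}

# The alias annotations printed in italics in that table: alias m/z ->
# (parent m/z, relation).
table2_alias_truth <- function() {
  data.frame(
    alias = c(6909, 6859, 22054, 27410, 6823, 33109, 131938, 6795, 6865),
    parent = c(13840, 13725, 66110, 13725, 13670, 66110, 66110, 13601, 13725),
    relation = c("z2", "z2", "z3", "dimer", "z2", "z2", "dimer", "z2", "z2"),
    stringsAsFactors = FALSE
  )
}

# Exhaustive-enumeration oracle for the two-sided Mann-Whitney p-value
# (independent of the package's branch logic).
mwu_exact_oracle <- function(x, y) {
  n1 <- length(x)
  N <- n1 + length(y)
  r <- rank(c(x, y))
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combs <- utils::combn(N, n1)
  us <- apply(combs, 2, function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2)
  min(1, 2 * min(mean(us <= u_obs), mean(us >= u_obs)))
}

# Build a peak_matrix directly from an intensity matrix (for stats-layer
# tests that do not need rendered spectra).
make_pm <- function(mat, groups, ages, mz = NULL) {
  n_peak <- nrow(mat)
  if (is.null(mz)) mz <- seq(3000, 90000, length.out = n_peak)
  ids <- sprintf("pk_%04d", seq_len(n_peak))
  rownames(mat) <- ids
  colnames(mat) <- sprintf("s%02d", seq_len(ncol(mat)))
  structure(list(
    intensity = mat,
    peaks = data.frame(peak_id = ids, tier = "med", mz = mz,
                       lo = mz * 0.997, hi = mz * 1.003, snr = NA_real_,
                       stringsAsFactors = FALSE),
    samples = data.frame(sample_id = colnames(mat), group = groups,
                         age = ages, stringsAsFactors = FALSE),
    missing = which(is.na(mat), arr.ind = TRUE)
  ), class = "peak_matrix")
}

# Lognormal two-group intensity matrix: `ratio` applied to the first
# `n_diff` peaks in the ENU group.
sim_matrix <- function(n_peak = 100, n1 = 22, n2 = 23, ratio = 1.6,
                       n_diff = 0, cv = 0.25, seed = 1) {
  set.seed(seed)
  sdlog <- sqrt(log(1 + cv^2))
  base <- exp(runif(n_peak, log(1), log(50)))
  mat <- matrix(rlnorm(n_peak * (n1 + n2), -sdlog^2 / 2, sdlog),
                n_peak, n1 + n2) * base
  if (n_diff > 0) mat[seq_len(n_diff), seq_len(n1)] <-
    mat[seq_len(n_diff), seq_len(n1)] * ratio
  make_pm(mat, groups = rep(c("ENU", "control"), c(n1, n2)),
          ages = rep("P90", n1 + n2))
}

# Coordinate-descent LASSO oracle for 1/2||y - Xb||^2 + L||b||_1 (unit-free,
# no standardization): plain cyclic soft-threshold updates iterated to
# convergence. `b0` is a warm start (e.g. a glmnet estimate to be polished).
cd_lasso <- function(X, y, L, b0 = numeric(ncol(X)), tol = 1e-12,
                     max_sweep = 5000) {
  b <- b0
  xx <- colSums(X^2)
  r <- y - drop(X %*% b)
  for (sweep in seq_len(max_sweep)) {
    delta <- 0
    for (j in seq_len(ncol(X))) {
      bj_old <- b[j]
      rho <- sum(X[, j] * r) + xx[j] * bj_old
      bj <- sign(rho) * max(abs(rho) - L, 0) / xx[j]
      if (bj != bj_old) {
        r <- r - X[, j] * (bj - bj_old)
        b[j] <- bj
        delta <- max(delta, abs(bj - bj_old))
      }
    }
    if (delta < tol) break
  }
  b
}

# Nearest detected peak id within a relative tolerance, or NA.
match_peak <- function(peakdefs, mz, tol = 0.005) {
  d <- abs(peakdefs$mz - mz) / mz
  if (min(d) <= tol) peakdefs$peak_id[which.min(d)] else NA_character_
}
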