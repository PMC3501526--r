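test_that("a single noiseless Gaussian yields one centred peak definition", {
  panel <- list(protein_spec("only", 13601, 25, effect = c(P90 = 1), cv = 0))
  co <- simulate_cohort(
    cohort_design(ages = "P90", n_enu = 3, n_control = 3, seed = 1),
    proteins = panel, model = spectrum_model(noise_sd = 0),
    suppression = list())
  pp <- preprocess_cohort(co)$cohort
  pd <- detect_peaks(pp)
  pd_med <- pd[pd$tier == "med", ]
  expect_equal(nrow(pd_med), 1)
  grid_step <- 5000 / 400 / 6
  expect_lt(abs(pd_med$mz - 13601), grid_step + 1e-9)
  expect_error(detect_peaks(list()), "spectra|empty")
})

test_that("planted peaks are detected with few spurious calls", {
  recov <- spur <- numeric(3)
  for (i in 1:3) {
    co <- simulate_cohort(cohort_design(seed = 300 + i))
    pp <- preprocess_cohort(co)$cohort
    pd <- merge_cross_tier(detect_peaks(pp))$peaks
    tr <- co$truth$peaks
    near <- vapply(tr$mz, function(m) min(abs(pd$mz - m) / m), numeric(1))
    recov[i] <- mean(near < 0.003)
    spur[i] <- mean(vapply(pd$mz, function(m)
      min(abs(tr$mz - m) / m), numeric(1)) > 0.005)
  }
  expect_gte(mean(recov), 0.9)
  expect_lte(mean(spur), 0.05)
})

test_that("noise-only spectra yield at most ~1 peak per tier", {
  co <- simulate_cohort(
    cohort_design(ages = "P90", n_enu = 5, n_control = 5, seed = 2),
    proteins = list(protein_spec("ghost", 50000, 1e-6)),
    suppression = list())
  pp <- preprocess_cohort(co)$cohort
  pd <- tryCatch(detect_peaks(pp), error = function(e) NULL)
  expect_lte(if (is.null(pd)) 0 else nrow(pd), 3) # <= 1 per tier on average
})

test_that("peak windows are disjoint within each tier", {
  co <- small_cohort(seed = 31)
  pd <- detect_peaks(preprocess_cohort(co)$cohort)
  for (t in unique(pd$tier)) {
    w <- pd[pd$tier == t, ]
    w <- w[order(w$mz), ]
    if (nrow(w) > 1) expect_true(all(w$lo[-1] >= w$hi[-nrow(w)] - 1e-9))
  }
})

test_that("quantification is faithful, linear and sample-order invariant", {
  co <- small_cohort(seed = 33, noise_sd = 0)
  bc <- subtract_baseline(co)
  pd <- detect_peaks(bc)
  pm <- quantify(bc, pd)
  # zero spectra -> zero matrix
  zl <- lapply(bc$spectra[1:3], function(s) { s$intensity[] <- 0; s })
  expect_true(all(quantify(zl, pd)$intensity == 0))
  # noiseless planted heights recovered within 5% (unnormalized route)
  tr <- co$truth
  for (i in seq_len(nrow(tr$peaks))) {
    id <- match_peak(pd, tr$peaks$mz[i], 0.003)
    if (is.na(id)) next
    truth <- tr$observed[i, pm$samples$sample_id]
    got <- pm$intensity[id, ]
    big <- truth > 0.5
    if (any(big))
      expect_lt(max(abs(got[big] - truth[big]) / truth[big]), 0.05)
  }
  # doubling one spectrum doubles only its column
  sl2 <- lapply(bc$spectra, function(s) {
    if (s$sample_id == bc$samples$sample_id[1]) s$intensity <- s$intensity * 2
    s
  })
  pm2 <- quantify(sl2, pd)
  expect_equal(pm2$intensity[, 1], 2 * pm$intensity[, 1], tolerance = 1e-12)
  expect_equal(pm2$intensity[, -1], pm$intensity[, -1], tolerance = 1e-12)
  # permutation invariance in sample (spectrum) order
  pm3 <- quantify(rev(bc$spectra), pd)
  expect_equal(pm3$intensity[, colnames(pm$intensity)], pm$intensity)
})

test_that("alias arithmetic links the albumin charge/dimer family", {
  pd <- data.frame(peak_id = c("a", "b", "c", "d"),
                   mz = c(66110, 33109, 22054, 131938),
                   stringsAsFactors = FALSE)
  intensity <- c(a = 17, b = 5.2, c = 1.0, d = 0.76)
  ag <- find_aliases(pd, rel_tol = 0.005, intensity = intensity)
  edge <- function(alias) ag[ag$alias_id == alias, ]
  expect_equal(edge("b")$parent_id, "a")
  expect_equal(edge("b")$relation, "z2")
  expect_lt(edge("b")$deviation_rel, 0.002) # 0.16%
  expect_equal(edge("c")$parent_id, "a")
  expect_equal(edge("c")$relation, "z3")
  expect_lt(edge("c")$deviation_rel, 0.001) # 0.08%
  expect_equal(edge("d")$parent_id, "a")
  expect_equal(edge("d")$relation, "dimer")
  expect_lt(edge("d")$deviation_rel, 0.0025) # 0.21%
})

test_that("uncorrelated peaks at an accidental 2:1 ratio are not linked", {
  set.seed(4)
  n <- 30
  mat <- rbind(p1 = rlnorm(n, 3, 0.3), p2 = rlnorm(n, 1, 0.3))
  pm <- make_pm(mat, groups = rep(c("ENU", "control"), each = n / 2),
                ages = rep("P90", n), mz = c(40000, 20000.5))
  ag <- find_aliases(pm$peaks, pm, rel_tol = 0.005)
  expect_equal(nrow(ag), 0)
  # the same geometry with correlated intensities is linked
  mat2 <- rbind(p1 = mat["p1", ], p2 = mat["p1", ] * 0.3)
  pm2 <- make_pm(mat2, groups = rep(c("ENU", "control"), each = n / 2),
                 ages = rep("P90", n), mz = c(40000, 20000.5))
  ag2 <- find_aliases(pm2$peaks, pm2, rel_tol = 0.005)
  expect_equal(nrow(ag2), 1)
  expect_gte(ag2$correlation[1], 0.5)
})

test_that("planted alias and adduct structure is recovered from simulation", {
  co <- small_cohort(seed = 35, n = 10)
  pp <- preprocess_cohort(co)$cohort
  pd <- merge_cross_tier(detect_peaks(pp))$peaks
  pm <- quantify(pp, pd)
  ag <- find_aliases(pd, pm)
  # the big protein's z2 and dimer and the mid protein's z2 are planted
  id_main <- match_peak(pd, 66110)
  id_z2 <- match_peak(pd, (66110 + 1) / 2)
  id_dim <- match_peak(pd, 2 * 66110 - 1)
  expect_equal(ag$parent_id[ag$alias_id == id_z2], id_main)
  expect_equal(ag$relation[ag$alias_id == id_z2], "z2")
  expect_equal(ag$parent_id[ag$alias_id == id_dim], id_main)
  expect_equal(ag$relation[ag$alias_id == id_dim], "dimer")
  # adduct annotation around a base peak
  pd_a <- data.frame(peak_id = c("base", "x1", "x2"),
                     mz = c(13601, 13720, 13906), stringsAsFactors = FALSE)
  hits <- annotate_adducts(pd_a, "base", rel_tol = 0.001)
  expect_setequal(hits$adduct, c("cysteinyl", "glutathionyl"))
})

test_that("cross-tier duplicates merge into the optimizing tier", {
  pd <- data.frame(
    peak_id = c("low_6859", "med_6865", "med_22890", "high_22893"),
    tier = c("low", "med", "med", "high"),
    mz = c(6859, 6865, 22890, 22893),
    lo = c(6859, 6865, 22890, 22893) * 0.997,
    hi = c(6859, 6865, 22890, 22893) * 1.003,
    snr = c(10, 12, 30, 20), stringsAsFactors = FALSE)
  mg <- merge_cross_tier(pd, rel_tol = 0.005)
  expect_equal(nrow(mg$peaks), 2)
  # 6.8 kDa is optimized by the low tier; 22.9 kDa by the med tier
  expect_setequal(mg$peaks$peak_id, c("low_6859", "med_22890"))
  expect_equal(nrow(mg$merged), 2)
})
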