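flat_spec <- function(c0 = 3, n = 4000, tier = "med") {
  tr <- tier_ranges()
  lo <- tr$lo[tr$tier == tier]; hi <- tr$hi[tr$tier == tier]
  new_spectrum(seq(lo, hi, length.out = n), rep(c0, n), "s1", "control",
               "P90", tier)
}

test_that("baseline subtraction zeroes a flat spectrum and rejects bad windows", {
  out <- subtract_baseline(flat_spec(3))
  expect_true(all(out$intensity == 0))
  expect_true("baseline_done" %in% out$flags)
  expect_error(subtract_baseline(flat_spec(), window = 1e9), "wider")
  expect_error(subtract_baseline(flat_spec(), window = -1), "positive")
})

test_that("baseline subtraction recovers apex heights on baseline-ridden peaks", {
  tr <- tier_ranges(); lo <- 5000; hi <- 30000
  mz <- seq(lo, hi, by = 2)
  peaks <- data.frame(m = c(8000, 13601, 22000), h = c(12, 40, 5))
  y <- 4 * exp(-(mz - lo) / 6000) + 0.5
  for (i in seq_len(nrow(peaks))) {
    sigma <- peaks$m[i] / 400 / 2.3548
    y <- y + peaks$h[i] * exp(-0.5 * ((mz - peaks$m[i]) / sigma)^2)
  }
  sp <- new_spectrum(mz, y, "s1", "control", "P90", "med")
  bs <- subtract_baseline(sp)
  for (i in seq_len(nrow(peaks))) {
    apex <- max(bs$intensity[abs(bs$mz - peaks$m[i]) < 100])
    expect_equal(apex, peaks$h[i], tolerance = 0.05)
  }
  # idempotence: a second pass changes apexes by < 1% of peak height
  bs2 <- subtract_baseline(bs)
  expect_lt(max(abs(bs2$intensity - bs$intensity)) / max(peaks$h), 0.01)
})

test_that("noise estimation is robust to peaks and smooth baseline", {
  n <- 8000
  mz <- seq(5000, 30000, length.out = n)
  expect_true(all(estimate_noise(
    new_spectrum(mz, rep(1, n), "s", "g", "a", "med"))$noise_sd == 0))
  set.seed(11)
  noise <- rnorm(n, 0, 0.7)
  est <- estimate_noise(new_spectrum(mz, noise, "s", "g", "a", "med"), 8)
  expect_true(all(abs(est$noise_sd - 0.7) / 0.7 < 0.15))
  # invariant to adding a smooth baseline
  est2 <- estimate_noise(new_spectrum(mz, noise + 5 * exp(-(mz - 5000) / 8000),
                                      "s", "g", "a", "med"), 8)
  expect_equal(est$noise_sd, est2$noise_sd, tolerance = 0.02)
})

test_that("group normalization equalizes TICs and reports correct factors", {
  # three identical spectra, one doubled: factors 1, 1, 0.5
  mz <- seq(5000, 30000, length.out = 2000)
  y <- exp(-((mz - 13601) / 80)^2) * 20 + 0.1
  mk <- function(id, scale) new_spectrum(mz, y * scale, id, "control", "P90", "med")
  nb <- normalize_by_group(list(mk("a", 1), mk("b", 1), mk("c", 2)))
  expect_equal(nb$report$factor, c(1, 1, 0.5), tolerance = 1e-12)
  # within-group TICs equal after normalization on a simulated cohort
  co <- small_cohort(seed = 8, n = 4)
  nb2 <- normalize_by_group(subtract_baseline(co))
  tic <- vapply(nb2$spectra$spectra, function(s)
    sum(s$intensity[s$mz >= 1500]), numeric(1))
  key <- vapply(nb2$spectra$spectra, function(s) paste(s$age, s$tier),
                character(1))
  for (k in unique(key)) {
    sel <- key == k
    expect_lt(diff(range(tic[sel])) / mean(tic[sel]), 1e-9)
  }
})

test_that("globin QC flags contaminated samples, monotonically in dose", {
  co <- small_cohort(seed = 12, n = 5)
  pp <- preprocess_cohort(co)$cohort
  clean <- qc_blood(pp)
  expect_false(any(clean$flagged))
  victim <- co$samples$sample_id[1]
  doped <- inject_blood_contamination(co, 0.01, samples = victim)
  qc1 <- qc_blood(preprocess_cohort(doped)$cohort)
  expect_true(qc1$flagged[qc1$sample_id == victim])
  expect_equal(sum(qc1$flagged), 1)
  # flags monotone in injected fraction
  doped_hi <- inject_blood_contamination(co, 0.05, samples = victim)
  qc2 <- qc_blood(preprocess_cohort(doped_hi)$cohort)
  expect_true(all(qc1$flagged <= qc2$flagged | qc2$flagged[qc1$flagged]))
  g1 <- qc1$globin_intensity[qc1$sample_id == victim]
  g2 <- qc2$globin_intensity[qc2$sample_id == victim]
  expect_gt(g2, g1)
})

test_that("normalization preserves within-spectrum peak-height ratios", {
  co <- small_cohort(seed = 20, n = 3)
  pp <- preprocess_cohort(co)$cohort
  bc <- subtract_baseline(co)
  sp_n <- Filter(function(s) s$tier == "med", pp$spectra)[[1]]
  sp_b <- Filter(function(s) s$tier == "med", bc$spectra)[[1]]
  h <- function(s, m) max(s$intensity[abs(s$mz - m) < 60])
  r_n <- h(sp_n, 13601) / h(sp_n, 6801)
  r_b <- h(sp_b, 13601) / h(sp_b, 6801)
  expect_equal(r_n, r_b, tolerance = 1e-9)
})
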