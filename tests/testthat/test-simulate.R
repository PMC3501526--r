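test_that("cohort design defaults to the study group sizes and validates input", {
  d <- cohort_design()
  expect_equal(d$counts$n[d$counts$group == "ENU"], c(13, 16, 22))
  expect_equal(d$counts$n[d$counts$group == "control"], c(11, 16, 23))
  expect_error(cohort_design(n_enu = c(0, 16, 22)), "positive")
  expect_error(protein_spec("x", -5, 1), "base_mz")
  expect_error(protein_spec("x", 5000, 1, aliases = c(z5 = 0.2)), "subset")
  bad <- data.frame(label = c("a", "b"), delta = c(0, 100),
                    frac = c(0.6, 0.3), shift = c(0, 0))
  expect_error(protein_spec("x", 5000, 1, proteoforms = bad), "sum to 1")
})

test_that("no-noise no-effect cohorts give identical group spectra within a tier", {
  panel <- list(protein_spec("p1", 8000, 10, effect = c(P90 = 1), cv = 0),
                protein_spec("p2", 25000, 5, effect = c(P90 = 1), cv = 0))
  co <- simulate_cohort(
    cohort_design(ages = "P90", n_enu = 3, n_control = 3, seed = 1),
    proteins = panel, model = spectrum_model(noise_sd = 0),
    suppression = list())
  for (t in tier_ranges()$tier) {
    sl <- Filter(function(s) s$tier == t, co$spectra)
    ref <- sl[[1]]$intensity
    for (s in sl) expect_identical(s$intensity, ref)
  }
})

test_that("invalid panels are rejected", {
  dup <- list(protein_spec("a", 8000, 1), protein_spec("a", 9000, 1))
  expect_error(simulate_cohort(cohort_design(seed = 1), dup,
                               suppression = list()), "duplicate")
  out <- list(protein_spec("far", 500000, 1))
  expect_error(simulate_cohort(cohort_design(seed = 1), out,
                               suppression = list()), "outside")
  expect_error(suppression_spec("a", "a", 0.5), "differ")
  expect_error(suppression_spec("a", "b", 1.2), "strength")
})

test_that("ground-truth alias map is acyclic with one parent per alias", {
  co <- small_cohort(seed = 3)
  pk <- co$truth$peaks
  aliases <- pk[!is.na(pk$parent_peak), ]
  expect_true(all(table(aliases$peak_id) == 1))
  # parents are primaries/proteoforms, never aliases themselves
  expect_true(all(aliases$parent_peak %in%
                    pk$peak_id[pk$kind %in% c("primary", "proteoform")]))
})

test_that("proteoform family conserves the expected total when shifts sum to zero", {
  forms <- data.frame(label = c("u", "cys", "gsh"),
                      delta = c(0, 119.004, 305.068),
                      frac = c(0.3, 0.3, 0.4), shift = c(0.05, 0.05, -0.1))
  panel <- list(protein_spec("fam", 13601, 100, effect = c(P90 = 1),
                             cv = 0, proteoforms = forms))
  co <- simulate_cohort(
    cohort_design(ages = "P90", n_enu = 8, n_control = 8, seed = 2),
    proteins = panel, model = spectrum_model(noise_sd = 0),
    suppression = list())
  tr <- co$truth
  prim <- tr$peaks$kind %in% c("primary", "proteoform")
  tot <- colSums(tr$intensity[prim, ])
  g <- co$samples$group == "ENU"
  # cv = 0: totals equal exactly across groups
  expect_equal(mean(tot[g]), mean(tot[!g]), tolerance = 1e-10)
  # individual forms differ between groups
  cys <- tr$intensity[match("fam.cys", tr$peaks$peak_id), ]
  expect_gt(mean(cys[g]) / mean(cys[!g]), 1.1)
})

test_that("pathology incidence matches the specified probabilities in expectation", {
  p <- c(P30 = 0, P60 = 0.18, P90 = 0.67)
  n <- c(P30 = 20, P60 = 22, P90 = 21)
  counts <- t(vapply(1:200, function(s) {
    incidence_table(simulate_pathology(n, p, seed = s))[, "microtumor"]
  }, numeric(3)))
  expect_equal(colMeans(counts), c(P30 = 0, P60 = 3.96, P90 = 14.07),
               tolerance = 0.08)
  # degenerate and deterministic cases
  none <- simulate_pathology(n, c(P30 = 0, P60 = 0, P90 = 0), seed = 1)
  expect_false(any(none$microtumor))
  expect_true(all(none$nests))
  expect_identical(simulate_pathology(n, p, seed = 9),
                   simulate_pathology(n, p, seed = 9))
})

test_that("blood contamination adds a monotone globin peak and flags samples", {
  co <- small_cohort(seed = 5, n = 5)
  sp <- Filter(function(s) s$tier == "med", co$spectra)[[1]]
  expect_identical(inject_blood_contamination(sp, 0), sp)
  expect_error(inject_blood_contamination(sp, -0.1), "non-negative")
  g_int <- function(s) max(s$intensity[abs(s$mz - 15216) < 40])
  i0 <- g_int(sp)
  i1 <- g_int(inject_blood_contamination(sp, 0.005))
  i2 <- g_int(inject_blood_contamination(sp, 0.02))
  i3 <- g_int(inject_blood_contamination(sp, 0.1))
  expect_true(i0 < i1 && i1 < i2 && i2 < i3)
})
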