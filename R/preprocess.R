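# Spectrum preprocessing: morphological baseline subtraction, robust noise
# estimation, age-grouped total-ion-current normalization and a blood
# contamination QC on the globin peak region.

# Coerce "a cohort or a list of spectra" to the list, remembering the wrapper.
spectra_list <- function(x) {
  if (inherits(x, "seldi_cohort")) x$spectra
  else if (inherits(x, "seldi_spectrum")) list(x)
  else if (is.list(x) && all(vapply(x, inherits, logical(1), "seldi_spectrum"))) x
  else stop("expected a seldi_cohort, a seldi_spectrum, or a list of them")
}

set_spectra <- function(x, spectra) {
  if (inherits(x, "seldi_cohort")) { x$spectra <- spectra; x }
  else if (inherits(x, "seldi_spectrum")) spectra[[1L]]
  else spectra
}

#' Subtract a morphological-opening baseline
#'
#' Estimates the baseline by a morphological opening (rolling minimum followed
#' by rolling maximum) whose window scales proportionally with the local m/z,
#' then subtracts it and clips at zero. Features narrower than the window
#' (i.e. real peaks, whose width is about m/z / resolution) ride on top of the
#' opening and survive; the slowly varying chemical baseline is removed.
#'
#' @param x A `seldi_cohort`, `seldi_spectrum`, or list of spectra.
#' @param window Window size: a fraction of the local m/z when `< 1`
#'   (default 0.02, i.e. 2 percent of m/z), or an absolute width in Da when `>= 1`.
#' @return `x` with baseline-subtracted intensities; spectra gain the flag
#'   `"baseline_done"`.
#' @export
subtract_baseline <- function(x, window = 0.02) {
  if (!is.numeric(window) || window <= 0) stop("'window' must be positive")
  sl <- spectra_list(x)
  sl <- lapply(sl, function(sp) {
    n <- length(sp$mz)
    span <- sp$mz[n] - sp$mz[1L]
    w_da <- if (window < 1) window * sp$mz else rep(window, n)
    if (min(w_da) > span) stop("baseline window wider than the spectrum span")
    spacing <- (sp$mz[n] - sp$mz[1L]) / (n - 1L)
    half <- pmax(1L, as.integer(ceiling(w_da / spacing / 2)))
    opened <- roll_max_var(roll_min_var(sp$intensity, half), half)
    sp$intensity <- pmax(sp$intensity - opened, 0)
    sp$flags <- union(sp$flags, "baseline_done")
    sp
  })
  set_spectra(x, sl)
}

#' Robust per-segment noise estimate
#'
#' Splits the m/z axis into `segment_count` equal segments and estimates the
#' point noise standard deviation in each as `1.4826 * MAD(first differences)
#' / sqrt(2)`, which is insensitive to peaks and smooth baseline.
#' Segments with fewer than 8 points are merged with their neighbour.
#'
#' @param spectrum A `seldi_spectrum`.
#' @param segment_count Number of m/z segments (>= 1).
#' @return Data frame with `mz_lo`, `mz_hi`, `noise_sd` per segment.
#' @export
estimate_noise <- function(spectrum, segment_count = 8) {
  stopifnot(inherits(spectrum, "seldi_spectrum"), segment_count >= 1)
  n <- length(spectrum$mz)
  segment_count <- as.integer(segment_count)
  bounds <- unique(round(seq(1L, n + 1L, length.out = segment_count + 1L)))
  # merge segments shorter than 8 points into the previous one
  keep <- c(TRUE, diff(bounds) >= 8)[seq_along(bounds)]
  keep[1L] <- TRUE; keep[length(bounds)] <- TRUE
  bounds <- bounds[keep]
  m <- length(bounds) - 1L
  out <- data.frame(mz_lo = numeric(m), mz_hi = numeric(m), noise_sd = numeric(m))
  for (i in seq_len(m)) {
    idx <- bounds[i]:(bounds[i + 1L] - 1L)
    d <- diff(spectrum$intensity[idx])
    out$mz_lo[i] <- spectrum$mz[idx[1L]]
    out$mz_hi[i] <- spectrum$mz[idx[length(idx)]]
    out$noise_sd[i] <- 1.4826 * median(abs(d - median(d))) / sqrt(2)
  }
  out
}

# Noise sd at given m/z positions, from an estimate_noise() table.
noise_at <- function(noise_tab, mz) {
  idx <- findInterval(mz, c(noise_tab$mz_lo[1L], noise_tab$mz_hi))
  idx <- pmin(pmax(idx, 1L), nrow(noise_tab))
  noise_tab$noise_sd[idx]
}

#' Normalize spectra to the group median total ion current
#'
#' Scales every spectrum so that its total ion current (sum of intensities
#' over the tier's analysis range, excluding the matrix region below m/z
#' 1,500) equals the median TIC of its (age, tier) group. Age-grouped
#' normalization respects the age-dependence of overall CSF peak intensity.
#'
#' @param x A `seldi_cohort` or list of `seldi_spectrum`.
#' @param min_mz Lower bound of the TIC analysis range (Da).
#' @return List with `spectra` (same container type as `x`, scaled, flagged
#'   `"normalized"`) and `report` (data frame: `sample_id`, `age`, `tier`,
#'   `tic`, `factor`, `reference`). Spectra with zero TIC are dropped with a
#'   warning.
#' @export
normalize_by_group <- function(x, min_mz = 1500) {
  sl <- spectra_list(x)
  tic <- vapply(sl, function(sp) sum(sp$intensity[sp$mz >= min_mz]), numeric(1))
  key <- vapply(sl, function(sp) paste(sp$age, sp$tier, sep = "|"), character(1))
  zero <- tic <= 0
  if (any(zero)) {
    warning(sprintf("excluding %d spectra with zero TIC", sum(zero)))
    sl <- sl[!zero]; tic <- tic[!zero]; key <- key[!zero]
  }
  ref <- tapply(tic, key, median)
  factor <- as.numeric(ref[key] / tic)
  sl <- lapply(seq_along(sl), function(i) {
    sp <- sl[[i]]
    sp$intensity <- sp$intensity * factor[i]
    sp$flags <- union(sp$flags, "normalized")
    sp
  })
  report <- data.frame(
    sample_id = vapply(sl, `[[`, character(1), "sample_id"),
    age = vapply(sl, `[[`, character(1), "age"),
    tier = vapply(sl, `[[`, character(1), "tier"),
    tic = tic, factor = factor, reference = as.numeric(ref[key]),
    stringsAsFactors = FALSE
  )
  list(spectra = set_spectra(x, sl), report = report)
}

#' Flag blood-contaminated samples by the globin peak
#'
#' Measures the apex intensity in a narrow window around the globin m/z in
#' each sample's covering-tier spectrum and flags samples exceeding
#' `threshold` times the cohort median. Flagged samples should be excluded
#' from group comparisons, since even minimal blood admixture distorts the
#' CSF protein profile.
#'
#' @param x A `seldi_cohort` or list of `seldi_spectrum`.
#' @param globin_mz Globin peak m/z (default 15216 Da).
#' @param threshold Multiple of the cohort median globin-window intensity
#'   above which a sample is flagged (default 3).
#' @param window_frac Half-window around `globin_mz` as a fraction of m/z.
#' @return Data frame with `sample_id`, `globin_intensity`, `flagged`.
#' @export
qc_blood <- function(x, globin_mz = 15216, threshold = 3, window_frac = 0.005) {
  stopifnot(threshold > 0)
  sl <- spectra_list(x)
  covering <- tiers_covering(globin_mz)
  use <- vapply(sl, function(sp) sp$tier %in% covering[1L], logical(1))
  sl <- sl[use]
  if (!length(sl)) stop("no spectra in the tier covering the globin m/z")
  ids <- vapply(sl, `[[`, character(1), "sample_id")
  val <- vapply(sl, function(sp) {
    idx <- which(abs(sp$mz - globin_mz) <= window_frac * globin_mz)
    if (!length(idx)) return(0)
    max(sp$intensity[idx])
  }, numeric(1))
  val <- tapply(val, ids, max)
  med <- median(val)
  data.frame(sample_id = names(val),
             globin_intensity = as.numeric(val),
             flagged = as.numeric(val) > threshold * max(med, .Machine$double.eps),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' One-call preprocessing of a cohort
#'
#' Applies [subtract_baseline()] then [normalize_by_group()]; convenience
#' wrapper for the standard order of operations.
#'
#' @param cohort A `seldi_cohort`.
#' @param baseline_window Passed to [subtract_baseline()].
#' @return List with `cohort` (processed) and `normalization` (report).
#' @export
preprocess_cohort <- function(cohort, baseline_window = 0.02) {
  bc <- subtract_baseline(cohort, window = baseline_window)
  nb <- normalize_by_group(bc)
  list(cohort = nb$spectra, normalization = nb$report)
}
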