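# Peak finding on recombined (mean) spectra, per-sample quantification, and
# annotation of charge-state/dimer alias structure and proteoform adducts.

# Non-overlapping "optimization" partition of the overlapping tier ranges,
# used to decide which tier keeps a cross-tier duplicate peak. Boundaries are
# the geometric midpoints of the overlap regions.
.TIER_OPT_BREAKS <- c(2000, sqrt(10000 * 5000), sqrt(30000 * 20000), 200000)

optimizing_tier <- function(mz) {
  idx <- findInterval(mz, .TIER_OPT_BREAKS, rightmost.closed = TRUE)
  idx <- pmin(pmax(idx, 1L), 3L)
  c("low", "med", "high")[idx]
}

#' Detect peaks on per-tier mean spectra
#'
#' Averages all (preprocessed) spectra of each laser-energy tier across every
#' sample and age — the "recombined" design, which guarantees a complete
#' peaks-by-samples matrix downstream — and reports local maxima whose height
#' exceeds `snr_min` times the local robust noise of the mean spectrum.
#' Each peak gets a quantification window of apex +/- 0.3 percent of m/z, clipped
#' at the midpoint between adjacent apexes so windows never overlap within a
#' tier.
#'
#' @param x A `seldi_cohort` or list of preprocessed `seldi_spectrum`.
#' @param snr_min Minimum signal-to-noise ratio on the mean spectrum.
#' @param min_fraction_present Optional filter: keep only peaks whose window
#'   intensity exceeds `snr_min` times the tier's median per-spectrum noise in
#'   at least this fraction of samples (0 disables).
#' @param window_frac Half-window as a fraction of the apex m/z.
#' @return Data frame of peak definitions: `peak_id`, `tier`, `mz`, `lo`,
#'   `hi`, `snr`.
#' @export
detect_peaks <- function(x, snr_min = 5, min_fraction_present = 0,
                         window_frac = 0.003) {
  stopifnot(snr_min > 0, window_frac > 0)
  sl <- spectra_list(x)
  if (!length(sl)) stop("no spectra supplied")
  tiers <- unique(vapply(sl, `[[`, character(1), "tier"))
  defs <- list()
  for (t in tiers) {
    st <- sl[vapply(sl, function(sp) sp$tier == t, logical(1))]
    mz <- st[[1L]]$mz
    if (!all(vapply(st, function(sp) length(sp$mz) == length(mz), logical(1))))
      stop("spectra within a tier must share one m/z grid")
    avg <- Reduce(`+`, lapply(st, `[[`, "intensity")) / length(st)
    # flatten the residual pedestal of the mean spectrum (per-spectrum
    # baseline subtraction biases each spectrum upward by a few noise sd)
    # so the SNR gate sees apex height above local background
    mean_sp <- subtract_baseline(
      new_spectrum(mz, avg, "mean", "all", "all", t), window = 0.02)
    avg <- mean_sp$intensity
    noise <- estimate_noise(mean_sp, segment_count = 8)
    # residual background of the opened mean spectrum (a few noise sd),
    # estimated as the per-segment median; SNR is apex height above it
    noise$bg <- vapply(seq_len(nrow(noise)), function(i) {
      idx <- mz >= noise$mz_lo[i] & mz <= noise$mz_hi[i]
      median(avg[idx])
    }, numeric(1))
    n <- length(avg)
    is_max <- c(FALSE, avg[2:(n - 1)] > avg[1:(n - 2)] &
                  avg[2:(n - 1)] >= avg[3:n], FALSE)
    cand <- which(is_max)
    floor_sd <- max(noise$noise_sd) * 1e-3 + .Machine$double.eps
    seg <- pmin(pmax(findInterval(mz[cand], c(noise$mz_lo[1L], noise$mz_hi)), 1L),
                nrow(noise))
    snr <- (avg[cand] - noise$bg[seg]) /
      pmax(noise$noise_sd[seg], floor_sd)
    cand <- cand[snr >= snr_min]
    snr <- snr[snr >= snr_min]
    if (!length(cand)) next
    # enforce minimum separation: keep the tallest apex within each window
    ord <- order(avg[cand], decreasing = TRUE)
    keep <- logical(length(cand))
    kept_mz <- numeric(0)
    for (i in ord) {
      m <- mz[cand[i]]
      if (!length(kept_mz) || all(abs(kept_mz - m) > window_frac * m)) {
        keep[i] <- TRUE
        kept_mz <- c(kept_mz, m)
      }
    }
    cand <- cand[keep]; snr <- snr[keep]
    # shoulder suppression: a candidate within two windows of a much taller
    # neighbour is a flank maximum of that peak (FWHM is ~0.25% of m/z, so
    # noise can raise side maxima just beyond the window separation);
    # comparable-height neighbours (e.g. adduct ladders) are kept
    if (length(cand) > 1L) {
      drop <- logical(length(cand))
      for (i in seq_along(cand)) {
        m <- mz[cand[i]]
        nb <- which(abs(mz[cand] - m) <= 2 * window_frac * m)
        if (any(avg[cand[nb]] > 2 * avg[cand[i]])) drop[i] <- TRUE
      }
      cand <- cand[!drop]; snr <- snr[!drop]
    }
    o <- order(mz[cand])
    cand <- cand[o]; snr <- snr[o]
    apex <- mz[cand]
    lo <- apex * (1 - window_frac)
    hi <- apex * (1 + window_frac)
    if (length(apex) > 1L) {
      mid <- (apex[-length(apex)] + apex[-1L]) / 2
      hi[-length(hi)] <- pmin(hi[-length(hi)], mid)
      lo[-1L] <- pmax(lo[-1L], mid)
    }
    defs[[t]] <- data.frame(
      peak_id = sprintf("%s_%.0f", t, apex),
      tier = t, mz = apex, lo = lo, hi = hi, snr = snr,
      stringsAsFactors = FALSE)
  }
  if (!length(defs)) stop("no peaks detected")
  out <- do.call(rbind, defs)
  rownames(out) <- NULL
  if (min_fraction_present > 0) {
    pm <- quantify(x, out)
    med_noise <- vapply(tiers, function(t) {
      st <- sl[vapply(sl, function(sp) sp$tier == t, logical(1))]
      median(vapply(st, function(sp) median(estimate_noise(sp)$noise_sd),
                    numeric(1)))
    }, numeric(1))
    frac <- vapply(seq_len(nrow(out)), function(i) {
      thr <- snr_min * med_noise[[out$tier[i]]]
      mean(pm$intensity[i, ] > thr, na.rm = TRUE)
    }, numeric(1))
    out <- out[frac >= min_fraction_present, , drop = FALSE]
    rownames(out) <- NULL
  }
  out
}

#' Quantify every sample at every peak
#'
#' Apex-height quantification: for each peak window, the maximum intensity
#' within the window minus the residual local baseline (the smaller of the
#' two window-edge intensities), clipped at zero. Samples missing a tier are
#' set `NA` and flagged.
#'
#' @param x A `seldi_cohort` or list of preprocessed `seldi_spectrum`.
#' @param peakdefs Peak definitions from [detect_peaks()].
#' @return An object of class `peak_matrix`: list with `intensity`
#'   (peaks x samples matrix), `peaks` (the definitions) and `samples`
#'   (metadata with `sample_id`, `group`, `age`).
#' @export
quantify <- function(x, peakdefs) {
  sl <- spectra_list(x)
  stopifnot(is.data.frame(peakdefs), nrow(peakdefs) > 0)
  ids <- unique(vapply(sl, `[[`, character(1), "sample_id"))
  meta <- do.call(rbind, lapply(sl, function(sp)
    data.frame(sample_id = sp$sample_id, group = sp$group, age = sp$age,
               stringsAsFactors = FALSE)))
  meta <- unique(meta)
  meta <- meta[match(ids, meta$sample_id), , drop = FALSE]
  rownames(meta) <- NULL
  mat <- matrix(NA_real_, nrow = nrow(peakdefs), ncol = length(ids),
                dimnames = list(peakdefs$peak_id, ids))
  for (sp in sl) {
    rows <- which(peakdefs$tier == sp$tier)
    if (!length(rows)) next
    j <- match(sp$sample_id, ids)
    i0 <- findInterval(peakdefs$lo[rows], sp$mz) + 1L
    i1 <- findInterval(peakdefs$hi[rows], sp$mz)
    for (k in seq_along(rows)) {
      if (i0[k] > i1[k]) { mat[rows[k], j] <- 0; next }
      w <- sp$intensity[i0[k]:i1[k]]
      remnant <- min(w[1L], w[length(w)])
      mat[rows[k], j] <- max(max(w) - remnant, 0)
    }
  }
  missing <- which(is.na(mat), arr.ind = TRUE)
  structure(list(intensity = mat, peaks = peakdefs, samples = meta,
                 missing = missing),
            class = "peak_matrix")
}

#' @export
print.peak_matrix <- function(x, ...) {
  cat(sprintf("<peak_matrix> %d peaks x %d samples (%d missing cells)\n",
              nrow(x$intensity), ncol(x$intensity), nrow(x$missing)))
  print(table(x$samples$age, x$samples$group))
  invisible(x)
}

#' Subset a peak matrix by age and optionally drop samples
#'
#' @param pm A `peak_matrix`.
#' @param age Age label(s) to keep (default all).
#' @param exclude Sample ids to drop (e.g. blood-flagged samples).
#' @return A `peak_matrix` restricted to the selected samples.
#' @export
pm_subset <- function(pm, age = NULL, exclude = NULL) {
  keep <- rep(TRUE, nrow(pm$samples))
  if (!is.null(age)) keep <- keep & pm$samples$age %in% age
  if (!is.null(exclude)) keep <- keep & !pm$samples$sample_id %in% exclude
  pm$intensity <- pm$intensity[, keep, drop = FALSE]
  pm$samples <- pm$samples[keep, , drop = FALSE]
  rownames(pm$samples) <- NULL
  pm
}

#' Merge cross-tier duplicate peaks
#'
#' Peaks detected in different tiers at the same m/z (within `rel_tol`
#' relative) are the same species read out at two laser energies; this keeps,
#' for each duplicate cluster, the peak in the tier whose optimization range
#' contains the m/z (tier ranges overlap; the non-overlapping partition uses
#' the geometric midpoints of the overlaps).
#'
#' @param peakdefs Peak definitions from [detect_peaks()].
#' @param rel_tol Relative m/z tolerance for duplication.
#' @return List with `peaks` (deduplicated definitions) and `merged` (data
#'   frame `dropped`, `kept`, `deviation_rel`).
#' @export
merge_cross_tier <- function(peakdefs, rel_tol = 0.005) {
  ord <- order(peakdefs$mz)
  pd <- peakdefs[ord, , drop = FALSE]
  n <- nrow(pd)
  cluster <- integer(n)
  cl <- 0L
  for (i in seq_len(n)) {
    if (i > 1L && (pd$mz[i] - pd$mz[i - 1L]) / pd$mz[i] <= rel_tol &&
        cluster[i - 1L] > 0L) {
      cluster[i] <- cluster[i - 1L]
    } else {
      cl <- cl + 1L
      cluster[i] <- cl
    }
  }
  keep <- logical(n)
  merged <- list()
  for (c0 in unique(cluster)) {
    idx <- which(cluster == c0)
    if (length(idx) == 1L || length(unique(pd$tier[idx])) == 1L) {
      keep[idx] <- TRUE
      next
    }
    pref <- optimizing_tier(median(pd$mz[idx]))
    cand <- idx[pd$tier[idx] == pref]
    pick <- function(ix) { # highest SNR, tolerating missing SNR
      s <- pd$snr[ix]
      s[is.na(s)] <- -Inf
      ix[which.max(s)]
    }
    kept <- if (length(cand)) pick(cand) else pick(idx)
    keep[kept] <- TRUE
    for (d in setdiff(idx, kept))
      merged[[length(merged) + 1L]] <- data.frame(
        dropped = pd$peak_id[d], kept = pd$peak_id[kept],
        deviation_rel = abs(pd$mz[d] - pd$mz[kept]) / pd$mz[kept],
        stringsAsFactors = FALSE)
  }
  merged <- if (length(merged)) do.call(rbind, merged)
    else data.frame(dropped = character(), kept = character(),
                    deviation_rel = numeric(), stringsAsFactors = FALSE)
  peaks <- pd[keep, , drop = FALSE]
  rownames(peaks) <- NULL
  list(peaks = peaks, merged = merged)
}

#' Annotate charge-state and dimer alias relationships
#'
#' Tests every ordered peak pair for the singly-protonated alias arithmetic:
#' a doubly charged alias of a parent at m sits at (m+1)/2, a triply charged
#' alias at (m+2)/3, and a non-covalent dimer at 2m-1. A candidate within
#' `rel_tol` relative deviation becomes an edge if (when intensity evidence is
#' available) the parent is at least as intense as the alias and the
#' across-sample Pearson correlation of their intensities reaches `cor_min` —
#' aliases are the same protein, so they co-vary; the correlation gate rejects
#' coincidental mass ratios. Each alias is linked to at most one parent (the
#' smallest deviation).
#'
#' @param peakdefs Peak definitions (`peak_id`, `mz`, ...).
#' @param peak_matrix Optional `peak_matrix` supplying intensity evidence.
#' @param rel_tol Relative m/z tolerance (default 0.005).
#' @param cor_min Minimum across-sample correlation with the parent.
#' @param intensity Optional named mean-intensity vector (used when no matrix
#'   is available, e.g. printed table values) to orient ambiguous pairs.
#' @return An object of class `alias_graph`: data frame of edges (`alias_id`,
#'   `alias_mz`, `parent_id`, `parent_mz`, `relation`, `deviation_rel`,
#'   `correlation`), with cross-tier duplicate pairs recorded in
#'   `attr(, "duplicates")`.
#' @export
find_aliases <- function(peakdefs, peak_matrix = NULL, rel_tol = 0.005,
                         cor_min = 0.5, intensity = NULL) {
  stopifnot(rel_tol > 0)
  pd <- peakdefs
  n <- nrow(pd)
  if (!is.null(peak_matrix)) {
    stopifnot(inherits(peak_matrix, "peak_matrix"))
    im <- peak_matrix$intensity[match(pd$peak_id, rownames(peak_matrix$intensity)), ,
                                drop = FALSE]
    intensity <- rowMeans(im, na.rm = TRUE)
    names(intensity) <- pd$peak_id
  }
  mz <- pd$mz
  edges <- list()
  for (a in seq_len(n)) {
    best <- NULL
    for (p in seq_len(n)) {
      if (a == p) next
      expected <- c(z2 = (mz[p] + 1) / 2, z3 = (mz[p] + 2) / 3,
                    dimer = 2 * mz[p] - 1)
      dev <- abs(mz[a] - expected) / expected
      r <- which.min(dev)
      if (dev[r] > rel_tol) next
      ia <- if (!is.null(intensity)) unname(intensity[pd$peak_id[a]])[1L] else NA_real_
      ip <- if (!is.null(intensity)) unname(intensity[pd$peak_id[p]])[1L] else NA_real_
      if (!is.na(ia) && !is.na(ip)) {
        if (ip < ia) next # parent must dominate in intensity
      } else if (names(expected)[r] == "dimer") {
        # a 2:1 m/z pair matches both "alias is dimer of parent" and the
        # reverse "parent is z2 alias of alias"; without intensity evidence
        # for the pair, orient the higher-m/z peak as the charge-state alias
        alt_dev <- abs(mz[p] - (mz[a] + 1) / 2) / ((mz[a] + 1) / 2)
        if (alt_dev <= rel_tol) next
      }
      corr <- NA_real_
      if (!is.null(peak_matrix)) {
        xa <- im[a, ]; xp <- im[p, ]
        ok <- is.finite(xa) & is.finite(xp)
        if (sum(ok) >= 3 && sd(xa[ok]) > 0 && sd(xp[ok]) > 0)
          corr <- cor(xa[ok], xp[ok])
        if (is.na(corr) || corr < cor_min) next
      }
      cand <- data.frame(alias_id = pd$peak_id[a], alias_mz = mz[a],
                         parent_id = pd$peak_id[p], parent_mz = mz[p],
                         relation = names(expected)[r],
                         deviation_rel = unname(dev[r]),
                         correlation = corr, stringsAsFactors = FALSE)
      if (is.null(best) || cand$deviation_rel < best$deviation_rel) best <- cand
    }
    if (!is.null(best)) edges[[length(edges) + 1L]] <- best
  }
  edges <- if (length(edges)) do.call(rbind, edges)
    else data.frame(alias_id = character(), alias_mz = numeric(),
                    parent_id = character(), parent_mz = numeric(),
                    relation = character(), deviation_rel = numeric(),
                    correlation = numeric(), stringsAsFactors = FALSE)
  # drop edges whose parent is itself an alias of something else (keep the
  # deepest parent instead), guaranteeing an acyclic one-parent mapping
  if (nrow(edges)) {
    guard <- 0L
    repeat {
      reroot <- match(edges$parent_id, edges$alias_id)
      idx <- which(!is.na(reroot))
      if (!length(idx) || guard >= 5L) break
      prev <- edges # frozen copy for consistent lookup
      edges$parent_id[idx] <- prev$parent_id[reroot[idx]]
      edges$parent_mz[idx] <- prev$parent_mz[reroot[idx]]
      edges$relation[idx] <- paste0(prev$relation[reroot[idx]], "+",
                                    edges$relation[idx])
      guard <- guard + 1L
    }
    edges <- edges[edges$alias_id != edges$parent_id, , drop = FALSE]
    rownames(edges) <- NULL
  }
  dup <- merge_cross_tier(pd, rel_tol = rel_tol)$merged
  structure(edges, duplicates = dup, class = c("alias_graph", "data.frame"))
}

#' @export
print.alias_graph <- function(x, ...) {
  cat(sprintf("<alias_graph> %d alias edges, %d cross-tier duplicates\n",
              nrow(x), nrow(attr(x, "duplicates"))))
  if (nrow(x)) print.data.frame(x, digits = 4)
  invisible(x)
}

#' Annotate proteoform adduct peaks around a base peak
#'
#' Labels peaks lying at `base + delta` for the fixed cysteine-adduct deltas
#' (see [adduct_table()]) within `rel_tol`; ambiguous double matches are
#' reported for every matching delta and flagged.
#'
#' @param peakdefs Peak definitions.
#' @param base_peak A `peak_id` present in `peakdefs`, or a base m/z value.
#' @param rel_tol Relative tolerance on the summed mass (default 0.001).
#' @return Data frame of labels: `peak_id`, `mz`, `adduct`, `expected_mz`,
#'   `deviation_rel`, `ambiguous`, plus the base peak as attribute `"base"`.
#' @export
annotate_adducts <- function(peakdefs, base_peak, rel_tol = 0.001) {
  if (is.character(base_peak)) {
    i <- match(base_peak, peakdefs$peak_id)
    if (is.na(i)) stop("base_peak not found in peakdefs")
    base_mz <- peakdefs$mz[i]
  } else base_mz <- as.numeric(base_peak)
  others <- peakdefs[peakdefs$mz != base_mz, , drop = FALSE]
  hits <- match_adducts(base_mz, others$mz, rel_tol = rel_tol)
  if (nrow(hits))
    hits <- cbind(peak_id = others$peak_id[match(hits$mz, others$mz)], hits,
                  stringsAsFactors = FALSE)
  else hits <- data.frame(peak_id = character(), mz = numeric(),
                          adduct = character(), expected_mz = numeric(),
                          deviation_rel = numeric(), ambiguous = logical(),
                          stringsAsFactors = FALSE)
  attr(hits, "base") <- base_mz
  hits
}
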