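# Synthetic SELDI-TOF cohort generator. Emulates the statistical structure of
# an age-structured two-group (ENU-exposed vs saline control) CSF discovery
# study: three laser-energy tiers, ~250 detectable peaks, charge-state and
# dimer alias peaks, a proteoform adduct family with a conserved total,
# ion-suppression of a co-detected peak by an abundant protein, and optional
# blood contamination marked by a globin peak.

.TIERS <- data.frame(
  tier = c("low", "med", "high"),
  lo = c(2000, 5000, 20000),
  hi = c(10000, 30000, 200000),
  stringsAsFactors = FALSE
)

#' Laser-energy tier m/z ranges
#'
#' The three acquisition tiers and their analysis ranges: low m/z
#' 2,000--10,000, medium 5,000--30,000, high 20,000--200,000 Da. Ranges
#' overlap, so one protein may be observed in more than one tier.
#'
#' @return Data frame with columns `tier`, `lo`, `hi`.
#' @export
tier_ranges <- function() .TIERS

# Tiers whose range contains an m/z value.
tiers_covering <- function(mz) .TIERS$tier[mz >= .TIERS$lo & mz <= .TIERS$hi]

#' Cohort design: ages and group sizes
#'
#' Defines the per-age sample counts for the two exposure groups. Defaults are
#' the study sizes: P30 13 ENU / 11 control, P60 16/16, P90 22/23.
#'
#' @param ages Ordered character vector of age labels.
#' @param n_enu,n_control Named (by age) or positional integer counts.
#' @param seed Optional integer seed stored with the design.
#' @return An object of class `cohort_design`.
#' @examples
#' cohort_design()
#' @export
cohort_design <- function(ages = c("P30", "P60", "P90"),
                          n_enu = c(13, 16, 22),
                          n_control = c(11, 16, 23),
                          seed = NULL) {
  stopifnot(length(ages) >= 1, !anyDuplicated(ages))
  n_enu <- as.integer(if (!is.null(names(n_enu))) n_enu[ages] else n_enu)
  n_control <- as.integer(if (!is.null(names(n_control))) n_control[ages] else n_control)
  if (length(n_enu) != length(ages) || length(n_control) != length(ages) ||
      anyNA(n_enu) || anyNA(n_control) || any(n_enu <= 0) || any(n_control <= 0))
    stop("group counts must be positive and given for every age")
  structure(list(
    ages = as.character(ages),
    counts = data.frame(age = rep(ages, 2L),
                        group = rep(c("ENU", "control"), each = length(ages)),
                        n = c(n_enu, n_control), stringsAsFactors = FALSE),
    seed = seed
  ), class = "cohort_design")
}

#' @export
print.cohort_design <- function(x, ...) {
  cat("Cohort design:", paste(x$ages, collapse = ", "), "\n")
  tab <- matrix(x$counts$n, nrow = 2L, byrow = TRUE,
                dimnames = list(c("ENU", "control"), x$ages))
  print(tab)
  invisible(x)
}

#' Specification of one simulated protein
#'
#' Describes a protein contributing peaks to the simulated spectra: its
#' singly-protonated base m/z, mean intensity, per-age multiplicative group
#' effect (ENU/control ratio), biological coefficient of variation, alias
#' peaks (doubly/triply charged and dimer, with relative abundances), and an
#' optional proteoform family given as baseline fractions plus zero-sum
#' fraction shifts applied to the ENU group.
#'
#' @param name Unique protein label.
#' @param base_mz Base peak m/z in Da; must fall inside at least one tier.
#' @param base_intensity Mean apex intensity (arbitrary microampere-like units).
#' @param effect Named (by age) multiplicative ENU/control ratio; ages not
#'   named default to 1.
#' @param cv Lognormal coefficient of variation of the per-sample intensity.
#' @param aliases Named numeric vector, subset of `c(z2=, z3=, dimer=)`, giving
#'   alias relative abundances in (0, 1].
#' @param proteoforms Optional data frame with columns `label`, `delta` (Da),
#'   `frac` (baseline fractions summing to 1) and `shift` (ENU fraction
#'   shifts summing to 0).
#' @param shift_scale Named (by age) scaling of the proteoform shift, so the
#'   fraction redistribution can grow with age; defaults to full shift at
#'   every age.
#' @param age_scale Named (by age) multiplicative scaling of the baseline
#'   intensity applied to both groups — the developmental age trend of a
#'   protein's CSF level (overall peak intensities differ across ages, which
#'   is why normalization is age-grouped). Default: no trend.
#' @return An object of class `protein_spec`.
#' @export
protein_spec <- function(name, base_mz, base_intensity,
                         effect = c(P30 = 1, P60 = 1, P90 = 1),
                         cv = 0.25, aliases = NULL, proteoforms = NULL,
                         shift_scale = NULL, age_scale = NULL) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (!is.numeric(base_mz) || base_mz <= 0) stop("base_mz must be positive")
  if (!is.numeric(base_intensity) || base_intensity <= 0)
    stop("base_intensity must be positive")
  if (cv < 0) stop("cv must be non-negative")
  if (!is.null(aliases)) {
    if (is.null(names(aliases)) || !all(names(aliases) %in% c("z2", "z3", "dimer")))
      stop("aliases must be named with a subset of z2, z3, dimer")
    if (any(aliases <= 0 | aliases > 1))
      stop("alias relative abundances must be in (0, 1]")
  }
  if (!is.null(proteoforms)) {
    stopifnot(is.data.frame(proteoforms),
              all(c("label", "delta", "frac", "shift") %in% names(proteoforms)))
    if (abs(sum(proteoforms$frac) - 1) > 1e-6)
      stop("proteoform fractions must sum to 1")
    if (abs(sum(proteoforms$shift)) > 1e-6)
      stop("proteoform fraction shifts must sum to 0 (conserved total)")
    if (any(proteoforms$frac < 0) || any(proteoforms$frac + proteoforms$shift < 0))
      stop("proteoform fractions must stay non-negative in both groups")
  }
  structure(list(name = name, base_mz = base_mz,
                 base_intensity = base_intensity,
                 effect = effect, cv = cv, aliases = aliases,
                 proteoforms = proteoforms, shift_scale = shift_scale,
                 age_scale = age_scale),
            class = "protein_spec")
}

#' Spectrum acquisition model
#'
#' Physical model for simulated spectra: Gaussian peaks of full width at half
#' maximum `m/z / resolution`, a uniform m/z grid with `points_per_fwhm`
#' samples across the narrowest peak of each tier, a decaying-exponential
#' baseline, and additive Gaussian grid noise.
#'
#' @param resolution Linear-TOF-like resolving power (FWHM = m/z / resolution).
#' @param points_per_fwhm Grid oversampling of the narrowest peak per tier.
#' @param baseline_amplitude,baseline_offset Baseline `A * exp(-(mz-lo)/tau) + offset`.
#' @param baseline_tau_frac Baseline decay constant as a fraction of the tier span.
#' @param noise_sd Standard deviation of additive Gaussian noise per grid point.
#' @return An object of class `spectrum_model`.
#' @export
spectrum_model <- function(resolution = 400, points_per_fwhm = 6,
                           baseline_amplitude = 2, baseline_tau_frac = 0.25,
                           baseline_offset = 0.2, noise_sd = 0.1) {
  stopifnot(resolution > 0, points_per_fwhm > 0, baseline_amplitude >= 0,
            baseline_tau_frac > 0, baseline_offset >= 0, noise_sd >= 0)
  structure(list(resolution = resolution, points_per_fwhm = points_per_fwhm,
                 baseline_amplitude = baseline_amplitude,
                 baseline_tau_frac = baseline_tau_frac,
                 baseline_offset = baseline_offset, noise_sd = noise_sd),
            class = "spectrum_model")
}

#' Ion-suppression specification
#'
#' One directed suppression artifact: the observed intensity of `target` is
#' `true * (1 - strength * S)` where `S` is the suppressor's per-sample
#' intensity scaled to its cohort maximum. Models the depression of a
#' co-detected peak's apparent signal by an abundant protein competing for
#' ionization.
#'
#' @param suppressor,target Protein names (must differ).
#' @param strength Fraction of target signal lost at the suppressor's cohort
#'   maximum; in \[0, 1).
#' @return An object of class `suppression_spec`.
#' @export
suppression_spec <- function(suppressor, target, strength) {
  stopifnot(is.character(suppressor), is.character(target))
  if (identical(suppressor, target)) stop("suppressor and target must differ")
  if (!is.numeric(strength) || strength < 0 || strength >= 1)
    stop("strength must be in [0, 1)")
  structure(list(suppressor = suppressor, target = target, strength = strength),
            class = "suppression_spec")
}

#' Default simulated protein panel
#'
#' Builds the panel of proteins whose peaks populate the default simulated
#' cohorts: named anchors (an albumin-like abundant protein at m/z 66110 with
#' z=2/z=3/dimer aliases and an ENU increase at P90; a transthyretin-like
#' proteoform family at 13601 whose total is conserved while the
#' glutathionylated fraction shifts to the other forms; a PGD2S-like brain
#' protein at 22893 with no true group effect, exposed to suppression by
#' albumin; a protease-generated peptide fragment at 3493 strongly elevated in
#' ENU) plus background proteins, a subset of which carry planted group
#' effects that grow with age. Panel composition is deterministic given
#' `panel_seed`.
#'
#' @param n_background Number of background proteins.
#' @param n_strong,n_weak Numbers of background proteins planted with strong
#'   (P90 ratio 1.3--1.8) and weak (1.15--1.3) differential effects.
#' @param cv Default biological coefficient of variation.
#' @param panel_seed Seed fixing the background composition.
#' @return List of [protein_spec()] objects.
#' @export
default_protein_panel <- function(n_background = 245, n_strong = 20,
                                  n_weak = 10, cv = 0.25, panel_seed = 101) {
  stopifnot(n_background >= n_strong + n_weak)
  ttr_forms <- data.frame(
    label = c("unmodified", "sulfonated", "cysteinyl", "cys_gly", "glutathionyl"),
    delta = c(0, 79.957, 119.004, 176.026, 305.068),
    frac = c(0.199, 0.109, 0.164, 0.125, 0.403),
    shift = c(0.014, 0.022, 0.032, 0.011, -0.079),
    stringsAsFactors = FALSE
  )
  anchors <- list(
    protein_spec("albumin", 66110, 13,
                 effect = c(P30 = 1, P60 = 1.15, P90 = 1.30), cv = 0.28,
                 aliases = c(z2 = 0.30, z3 = 0.06, dimer = 0.045),
                 age_scale = c(P30 = 0.35, P60 = 1, P90 = 1.8)),
    protein_spec("transthyretin", 13601, 356,
                 effect = c(P30 = 1, P60 = 1, P90 = 1), cv = 0.20,
                 aliases = c(z2 = 0.20),
                 proteoforms = ttr_forms,
                 shift_scale = c(P30 = 0, P60 = 0.5, P90 = 1)),
    protein_spec("PGD2S", 22893, 23,
                 effect = c(P30 = 1, P60 = 1, P90 = 1), cv = 0.08),
    protein_spec("a1m_fragment", 3493, 6.5,
                 effect = c(P30 = 1, P60 = 1.35, P90 = 1.85), cv = 0.60)
  )
  # the anchors are the study's resolvable, purifiable proteins: background
  # peaks must not bury their primary, proteoform or alias positions (nor the
  # globin QC position), or the artifacts they carry are no longer measurable
  protect <- unlist(lapply(anchors, function(p) {
    forms <- if (is.null(p$proteoforms)) 0 else p$proteoforms$delta
    m <- p$base_mz + forms
    c(m, (m + 1) / 2, (m + 2) / 3, 2 * m - 1)
  }))
  protect <- c(protect, 15216)
  background <- with_seed(panel_seed, {
    mz <- exp(runif(n_background, log(2100), log(190000)))
    for (i in seq_len(n_background)) {
      while (any(abs(protect - mz[i]) / mz[i] < 0.008))
        mz[i] <- exp(runif(1, log(2100), log(190000)))
    }
    planted <- seq_len(n_strong + n_weak)
    # planted differential markers must be resolvable peaks (the study's
    # identified markers were): keep them clear of every other panel
    # position; null-vs-null collisions remain as realistic clutter
    for (i in planted) {
      repeat {
        clash <- c(protect, mz[-i], mz[-i] / 2)
        if (all(abs(clash - mz[i]) / mz[i] > 0.008)) break
        mz[i] <- exp(runif(1, log(2100), log(190000)))
      }
    }
    base_int <- exp(runif(n_background, log(0.3), log(60)))
    # planted markers are drawn from the quantifiable intensity range
    base_int[planted] <- exp(runif(length(planted), log(3), log(60)))
    r90 <- rep(1, n_background)
    r90[seq_len(n_strong)] <- runif(n_strong, 1.4, 1.85)
    if (n_weak > 0)
      r90[n_strong + seq_len(n_weak)] <- runif(n_weak, 1.15, 1.3)
    dir_down <- runif(n_background) < 0.25
    r90 <- ifelse(dir_down, 1 / r90, r90)
    has_z2 <- runif(n_background) < 0.30
    has_dimer <- runif(n_background) < 0.10
    z2_ab <- runif(n_background, 0.1, 0.4)
    dim_ab <- runif(n_background, 0.03, 0.15)
    lapply(seq_len(n_background), function(i) {
      al <- c(
        if (has_z2[i]) c(z2 = z2_ab[i]),
        if (has_dimer[i] && 2 * mz[i] - 1 <= 200000) c(dimer = dim_ab[i])
      )
      eff <- c(P30 = 1, P60 = exp(0.45 * log(r90[i])), P90 = r90[i])
      protein_spec(sprintf("bg%03d", i), mz[i], base_int[i], effect = eff,
                   cv = cv, aliases = if (length(al)) al)
    })
  })
  c(anchors, background)
}

#' Benchmark panel with a fixed number of informative peaks
#'
#' Panel for classifier benchmarking: exactly `n_informative` proteins carry
#' a group effect (at every age) and the remainder are null. The informative
#' proteins are alias-free, carry the same effect ratio, and are placed away
#' from every other peak (minimum 1.5 percent m/z separation), so the number of
#' informative, individually resolvable features is exactly
#' `n_informative` and each contributes comparable signal; null proteins
#' keep the usual alias structure so the feature space has realistic
#' correlation clutter.
#'
#' @param n_null Number of null background proteins.
#' @param n_informative Number of informative proteins (default 5).
#' @param ratio Common ENU/control intensity ratio of the informative
#'   proteins.
#' @param cv Lognormal coefficient of variation.
#' @param panel_seed Seed fixing the panel composition.
#' @return List of [protein_spec()] objects.
#' @export
informative_panel <- function(n_null = 200, n_informative = 5,
                              ratio = 1.7, cv = 0.3, panel_seed = 202) {
  with_seed(panel_seed, {
    mz_null <- exp(runif(n_null, log(2100), log(190000)))
    # place informative proteins clear of every null peak and each other
    mz_inf <- numeric(0)
    while (length(mz_inf) < n_informative) {
      m <- exp(runif(1, log(2100), log(180000)))
      others <- c(mz_null, mz_null / 2, mz_inf) # null primaries + z2 region
      if (all(abs(others - m) / m > 0.015)) mz_inf <- c(mz_inf, m)
    }
    base_int <- exp(runif(n_null, log(0.3), log(60)))
    int_inf <- exp(runif(n_informative, log(5), log(60)))
    has_z2 <- runif(n_null) < 0.30
    z2_ab <- runif(n_null, 0.1, 0.4)
    inf <- lapply(seq_len(n_informative), function(i)
      protein_spec(sprintf("inf%03d", i), mz_inf[i], int_inf[i],
                   effect = c(P30 = ratio, P60 = ratio, P90 = ratio),
                   cv = cv))
    nul <- lapply(seq_len(n_null), function(i)
      protein_spec(sprintf("null%03d", i), mz_null[i], base_int[i],
                   effect = c(P30 = 1, P60 = 1, P90 = 1), cv = cv,
                   aliases = if (has_z2[i]) c(z2 = z2_ab[i])))
    c(inf, nul)
  })
}

#' Global-null version of the default panel
#'
#' The [default_protein_panel()] with every group effect set to 1 and every
#' proteoform fraction shift zeroed: the full peak structure (anchors,
#' aliases, adduct family, background) with no true ENU/control difference
#' anywhere. Used to study the permutation null behaviour of the testing
#' stages.
#'
#' @param ... Passed to [default_protein_panel()].
#' @return List of [protein_spec()] objects with all effects = 1.
#' @export
null_panel <- function(...) {
  panel <- default_protein_panel(...)
  lapply(panel, function(p) {
    p$effect[] <- 1
    if (!is.null(p$proteoforms)) p$proteoforms$shift <- 0
    p
  })
}

#' Default suppression artifacts
#'
#' The single default artifact: albumin suppresses the PGD2S-like peak with
#' strength 0.6, producing a strong inverse intensity correlation across
#' samples without any true PGD2S group effect.
#'
#' @return List of [suppression_spec()] objects.
#' @export
default_suppression <- function() {
  list(suppression_spec("albumin", "PGD2S", 0.6))
}

new_spectrum <- function(mz, intensity, sample_id, group, age, tier,
                         flags = character()) {
  structure(list(mz = mz, intensity = intensity, sample_id = sample_id,
                 group = group, age = age, tier = tier, flags = flags),
            class = "seldi_spectrum")
}

#' @export
print.seldi_spectrum <- function(x, ...) {
  cat(sprintf("<seldi_spectrum> %s [%s, %s] tier %s: %d points, m/z %.0f-%.0f\n",
              x$sample_id, x$group, x$age, x$tier, length(x$mz),
              min(x$mz), max(x$mz)))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

# Grid for a tier under a spectrum model: uniform spacing of
# FWHM(tier lower edge) / points_per_fwhm.
tier_grid <- function(tier, model) {
  tr <- .TIERS[.TIERS$tier == tier, ]
  spacing <- (tr$lo / model$resolution) / model$points_per_fwhm
  seq(tr$lo, tr$hi, by = spacing)
}

# Expand a protein list into the latent peak table (one row per generated
# peak, aliases included), validating names and tier coverage.
build_peak_table <- function(proteins) {
  nm <- vapply(proteins, function(p) p$name, character(1))
  if (anyDuplicated(nm)) stop("duplicate protein names: ",
                              paste(unique(nm[duplicated(nm)]), collapse = ", "))
  rows <- list()
  for (p in proteins) {
    if (length(tiers_covering(p$base_mz)) == 0L)
      stop(sprintf("protein '%s' base m/z %.1f lies outside all tier ranges",
                   p$name, p$base_mz))
    forms <- p$proteoforms
    if (is.null(forms))
      forms <- data.frame(label = "", delta = 0, frac = 1, shift = 0,
                          stringsAsFactors = FALSE)
    for (f in seq_len(nrow(forms))) {
      fmz <- p$base_mz + forms$delta[f]
      flab <- forms$label[f]
      pid <- if (nzchar(flab)) paste0(p$name, ".", flab) else p$name
      kind <- if (nzchar(flab)) "proteoform" else "primary"
      rows[[length(rows) + 1L]] <- data.frame(
        peak_id = pid, protein = p$name, form = flab, kind = kind,
        parent_peak = NA_character_, mz = fmz, rel_abundance = 1,
        frac = forms$frac[f], shift = forms$shift[f],
        stringsAsFactors = FALSE)
      for (al in names(p$aliases)) {
        amz <- switch(al,
                      z2 = (fmz + 1) / 2,
                      z3 = (fmz + 2) / 3,
                      dimer = 2 * fmz - 1)
        if (length(tiers_covering(amz)) == 0L) next
        rows[[length(rows) + 1L]] <- data.frame(
          peak_id = paste0(pid, ".", al), protein = p$name, form = flab,
          kind = al, parent_peak = pid, mz = amz,
          rel_abundance = unname(p$aliases[[al]]),
          frac = forms$frac[f], shift = forms$shift[f],
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

#' Simulate a SELDI-TOF cohort
#'
#' Generates one spectrum per sample per laser-energy tier for an
#' age-structured two-group cohort, together with the latent ground truth.
#' Per-sample protein intensity is `base_intensity * group effect *
#' lognormal(cv)`, split across proteoforms by group-specific fractions;
#' alias peaks carry a fixed relative abundance of their parent form;
#' ion suppression is applied multiplicatively before spectra are rendered;
#' each peak appears as a Gaussian (FWHM = m/z / resolution) in every tier
#' covering its m/z, on a decaying-exponential baseline with additive
#' Gaussian noise.
#'
#' @param design A [cohort_design()].
#' @param proteins List of [protein_spec()]; default [default_protein_panel()].
#' @param model A [spectrum_model()].
#' @param suppression List of [suppression_spec()]; default
#'   [default_suppression()] (set `list()` for none).
#' @param seed Integer seed; defaults to the design's seed.
#' @return An object of class `seldi_cohort`: list with `spectra` (list of
#'   `seldi_spectrum`), `samples` (metadata data frame), `truth` (ground
#'   truth: peak table with per-age effective ENU/control ratios and
#'   differential flags, plus latent intensity matrices before and after
#'   suppression), `model` and `seed`.
#' @export
simulate_cohort <- function(design = cohort_design(),
                            proteins = default_protein_panel(),
                            model = spectrum_model(),
                            suppression = default_suppression(),
                            seed = design$seed) {
  stopifnot(inherits(design, "cohort_design"), inherits(model, "spectrum_model"))
  peaks <- build_peak_table(proteins)
  pnames <- vapply(proteins, function(p) p$name, character(1))
  for (sp in suppression) {
    if (!sp$suppressor %in% pnames || !sp$target %in% pnames)
      stop("suppression references unknown protein")
  }

  samples <- do.call(rbind, lapply(seq_len(nrow(design$counts)), function(i) {
    with(design$counts[i, ], data.frame(
      sample_id = sprintf("%s_%s_%02d", age, ifelse(group == "ENU", "ENU", "CTL"),
                          seq_len(n)),
      group = group, age = age, stringsAsFactors = FALSE))
  }))
  samples <- samples[order(match(samples$age, design$ages),
                           samples$group != "ENU"), , drop = FALSE]
  rownames(samples) <- NULL
  ns <- nrow(samples)

  with_seed(seed, {
    # latent per-sample protein totals
    totals <- matrix(0, nrow = length(proteins), ncol = ns,
                     dimnames = list(pnames, samples$sample_id))
    for (i in seq_along(proteins)) {
      p <- proteins[[i]]
      eff <- vapply(seq_len(ns), function(s) {
        a <- samples$age[s]
        e <- if (!is.null(names(p$effect)) && a %in% names(p$effect))
          p$effect[[a]] else 1
        asc <- if (!is.null(p$age_scale) && a %in% names(p$age_scale))
          p$age_scale[[a]] else 1
        asc * if (samples$group[s] == "ENU") e else 1
      }, numeric(1))
      sdlog <- sqrt(log(1 + p$cv^2))
      jit <- rlnorm(ns, meanlog = -sdlog^2 / 2, sdlog = sdlog)
      totals[i, ] <- p$base_intensity * eff * jit
    }

    # per-peak latent intensities (before suppression)
    np <- nrow(peaks)
    true_int <- matrix(0, nrow = np, ncol = ns,
                       dimnames = list(peaks$peak_id, samples$sample_id))
    scale_of <- function(p, age) {
      if (is.null(p$shift_scale)) 1
      else if (age %in% names(p$shift_scale)) p$shift_scale[[age]] else 1
    }
    for (i in seq_along(proteins)) {
      p <- proteins[[i]]
      prows <- which(peaks$protein == p$name)
      multi_form <- !is.null(p$proteoforms) && nrow(p$proteoforms) > 1L
      # independent per-form jitter at half the protein cv, shared between a
      # form's primary peak and its aliases
      form_sdlog <- if (multi_form && p$cv > 0) sqrt(log(1 + (p$cv / 2)^2)) else 0
      form_labels <- unique(peaks$form[prows])
      form_jit <- lapply(form_labels, function(f) {
        if (form_sdlog > 0)
          rlnorm(ns, meanlog = -form_sdlog^2 / 2, sdlog = form_sdlog)
        else rep(1, ns)
      })
      sc <- vapply(samples$age, function(a) scale_of(p, a), numeric(1))
      for (r in prows) {
        pk <- peaks[r, ]
        frac <- pk$frac + pk$shift * sc * (samples$group == "ENU")
        jit <- form_jit[[match(pk$form, form_labels)]]
        true_int[r, ] <- totals[p$name, ] * frac * jit * pk$rel_abundance
      }
    }

    # suppression (multiplicative, before noise)
    obs_int <- true_int
    for (sp in suppression) {
      s_tot <- totals[sp$suppressor, ]
      S <- s_tot / max(s_tot)
      trows <- which(peaks$protein == sp$target)
      obs_int[trows, ] <- obs_int[trows, , drop = FALSE] *
        rep(1 - sp$strength * S, each = length(trows))
    }

    # render spectra
    grids <- lapply(.TIERS$tier, tier_grid, model = model)
    names(grids) <- .TIERS$tier
    rows_in_tier <- lapply(.TIERS$tier, function(t) {
      which(peaks$mz >= .TIERS$lo[.TIERS$tier == t] &
              peaks$mz <= .TIERS$hi[.TIERS$tier == t])
    })
    names(rows_in_tier) <- .TIERS$tier
    base_curves <- lapply(.TIERS$tier, function(t) {
      tr <- .TIERS[.TIERS$tier == t, ]
      tau <- model$baseline_tau_frac * (tr$hi - tr$lo)
      model$baseline_amplitude * exp(-(grids[[t]] - tr$lo) / tau) +
        model$baseline_offset
    })
    names(base_curves) <- .TIERS$tier
    spectra <- vector("list", ns * nrow(.TIERS))
    k <- 0L
    for (s in seq_len(ns)) {
      for (t in .TIERS$tier) {
        grid <- grids[[t]]
        tr <- .TIERS[.TIERS$tier == t, ]
        y <- base_curves[[t]]
        in_tier <- rows_in_tier[[t]]
        spacing <- grid[2] - grid[1]
        for (r in in_tier) {
          h <- obs_int[r, s]
          if (h <= 0) next
          mzp <- peaks$mz[r]
          sigma <- (mzp / model$resolution) / 2.354820045
          i0 <- max(1L, floor((mzp - 5 * sigma - tr$lo) / spacing) + 1L)
          i1 <- min(length(grid), ceiling((mzp + 5 * sigma - tr$lo) / spacing) + 1L)
          if (i0 > i1) next
          idx <- i0:i1
          y[idx] <- y[idx] + h * exp(-0.5 * ((grid[idx] - mzp) / sigma)^2)
        }
        if (model$noise_sd > 0) y <- y + rnorm(length(grid), 0, model$noise_sd)
        k <- k + 1L
        spectra[[k]] <- new_spectrum(grid, y, samples$sample_id[s],
                                     samples$group[s], samples$age[s], t)
      }
    }

    # ground truth: effective ENU/control ratio per age per peak
    ratios <- sapply(design$ages, function(a) {
      vapply(seq_len(np), function(r) {
        p <- proteins[[match(peaks$protein[r], pnames)]]
        e <- if (!is.null(names(p$effect)) && a %in% names(p$effect))
          p$effect[[a]] else 1
        fr <- peaks$frac[r]
        sc <- scale_of(p, a)
        if (fr > 0) e * (fr + peaks$shift[r] * sc) / fr else e
      }, numeric(1))
    })
    ratios <- matrix(ratios, nrow = np,
                     dimnames = list(peaks$peak_id, design$ages))
    truth <- list(
      peaks = peaks[, c("peak_id", "protein", "form", "kind", "parent_peak",
                        "mz", "rel_abundance")],
      ratio = ratios,
      differential = abs(log(ratios)) > 1e-12,
      intensity = true_int,
      observed = obs_int
    )

    structure(list(spectra = spectra, samples = samples, truth = truth,
                   model = model, design = design, seed = seed),
              class = "seldi_cohort")
  })
}

#' @export
print.seldi_cohort <- function(x, ...) {
  cat(sprintf("<seldi_cohort> %d samples x %d tiers = %d spectra; %d latent peaks\n",
              nrow(x$samples), nrow(tier_ranges()), length(x$spectra),
              nrow(x$truth$peaks)))
  print(table(x$samples$age, x$samples$group))
  invisible(x)
}

#' Simulate a pathology incidence table
#'
#' Per-rat Bernoulli microtumor outcomes for ENU-exposed animals at each age;
#' nestin-positive precursor nests are present in every exposed rat at every
#' age. Defaults match the histology cohort: 20, 22 and 21 rats at P30, P60
#' and P90 with microtumor probabilities 0, 0.18 and 0.67.
#'
#' @param n Named integer vector of rats per age, or a [cohort_design()]
#'   (its ENU counts are used).
#' @param p_microtumor Named probability of a microtumor per age.
#' @param seed Integer seed.
#' @return Data frame with one row per rat: `rat_id`, `age`, `nests` (all
#'   `TRUE`), `microtumor` (logical).
#' @export
simulate_pathology <- function(n = c(P30 = 20, P60 = 22, P90 = 21),
                               p_microtumor = c(P30 = 0, P60 = 0.18, P90 = 0.67),
                               seed = NULL) {
  if (inherits(n, "cohort_design")) {
    cc <- n$counts[n$counts$group == "ENU", ]
    n <- setNames(cc$n, cc$age)
  }
  ages <- names(n)
  if (is.null(ages)) stop("'n' must be named by age")
  p <- p_microtumor[ages]
  if (anyNA(p) || any(p < 0 | p > 1)) stop("probabilities must be in [0, 1]")
  with_seed(seed, {
    do.call(rbind, lapply(ages, function(a) {
      data.frame(rat_id = sprintf("%s_%02d", a, seq_len(n[[a]])), age = a,
                 nests = TRUE,
                 microtumor = runif(n[[a]]) < p[[a]],
                 stringsAsFactors = FALSE)
    }))
  })
}

#' Tabulate microtumor incidence by age
#'
#' @param pathology Output of [simulate_pathology()], or any data frame with
#'   `age` and logical `microtumor` columns.
#' @return Integer matrix with one row per age and columns `microtumor`,
#'   `none`.
#' @export
incidence_table <- function(pathology) {
  stopifnot(all(c("age", "microtumor") %in% names(pathology)))
  ages <- unique(pathology$age)
  out <- t(vapply(ages, function(a) {
    m <- pathology$microtumor[pathology$age == a]
    c(microtumor = sum(m), none = sum(!m))
  }, c(microtumor = 0, none = 0)))
  rownames(out) <- ages
  out
}

#' Microtumor incidence percentages
#'
#' @param counts Matrix as returned by [incidence_table()].
#' @return Named numeric vector of percentages (0--100) per age.
#' @export
incidence_percent <- function(counts) {
  100 * counts[, "microtumor"] / rowSums(counts)
}

#' Inject blood contamination into a spectrum or cohort
#'
#' Adds a globin peak at m/z 15216 whose apex intensity increases
#' monotonically (saturating) with the blood:CSF ratio, and scales designated
#' blood-borne peaks (albumin-like, by default the m/z 66110 region) upward.
#'
#' @param x A `seldi_spectrum` or a `seldi_cohort`.
#' @param fraction Blood:CSF volume ratio, `>= 0`; 0 leaves `x` unchanged.
#' @param globin_mz Globin peak position (Da).
#' @param globin_max Asymptotic globin apex intensity.
#' @param half_saturation Blood fraction at which the globin peak reaches half
#'   of `globin_max`.
#' @param blood_mz m/z positions of blood-borne peaks boosted by
#'   contamination.
#' @param blood_boost Fractional intensity gain of blood-borne peaks per unit
#'   blood fraction (factor `1 + blood_boost * fraction`).
#' @param samples For cohorts: sample ids to contaminate (default all).
#' @return Object of the same class with modified intensities; contaminated
#'   spectra carry the flag `"blood_injected"`.
#' @export
inject_blood_contamination <- function(x, fraction, globin_mz = 15216,
                                       globin_max = 50, half_saturation = 0.02,
                                       blood_mz = 66110, blood_boost = 30,
                                       samples = NULL) {
  if (!is.numeric(fraction) || length(fraction) != 1L || is.na(fraction) ||
      fraction < 0)
    stop("'fraction' must be a single non-negative number")
  if (inherits(x, "seldi_cohort")) {
    ids <- if (is.null(samples)) x$samples$sample_id else samples
    x$spectra <- lapply(x$spectra, function(sp) {
      if (sp$sample_id %in% ids)
        inject_blood_contamination(sp, fraction, globin_mz, globin_max,
                                   half_saturation, blood_mz, blood_boost)
      else sp
    })
    return(x)
  }
  stopifnot(inherits(x, "seldi_spectrum"))
  if (fraction == 0) return(x)
  res <- 400 # peak width convention follows the default acquisition model
  tr <- .TIERS[.TIERS$tier == x$tier, ]
  if (globin_mz >= tr$lo && globin_mz <= tr$hi) {
    h <- globin_max * fraction / (fraction + half_saturation)
    sigma <- (globin_mz / res) / 2.354820045
    x$intensity <- x$intensity + h * exp(-0.5 * ((x$mz - globin_mz) / sigma)^2)
  }
  for (bm in blood_mz) {
    if (bm < tr$lo || bm > tr$hi) next
    sigma <- (bm / res) / 2.354820045
    idx <- which(abs(x$mz - bm) <= 5 * sigma)
    if (length(idx))
      x$intensity[idx] <- x$intensity[idx] * (1 + blood_boost * fraction)
  }
  x$flags <- union(x$flags, "blood_injected")
  x
}
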