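# End-to-end orchestration: simulate (or load) -> preprocess -> detect ->
# quantify -> alias/adduct annotation -> rank + FDR per age -> LASSO
# cross-validation -> report tables shaped like the study's Tables 1-3 and
# the FDR / CV-curve figures.

#' Pipeline configuration
#'
#' Collects every tunable of the full pipeline with its default. The seed is
#' mandatory: every stochastic stage derives its own stream from it, making
#' the whole run reproducible.
#'
#' @param seed Integer seed (mandatory).
#' @param design A [cohort_design()].
#' @param proteins Protein panel (default [default_protein_panel()]).
#' @param model A [spectrum_model()].
#' @param suppression List of [suppression_spec()].
#' @param baseline_window Baseline opening window (fraction of m/z).
#' @param snr_min Peak-detection signal-to-noise threshold.
#' @param rel_tol_alias,rel_tol_adduct Relative m/z tolerances.
#' @param n_perm Label permutations for the FDR stages.
#' @param fdr_bandwidth Local-FDR window factor.
#' @param cv_age Age analysed by the classifier stage (default the last age).
#' @param k_max,cv_repeats,train_n,k_select Classifier stage settings.
#' @param qc_blood_threshold Globin QC threshold (multiple of cohort median).
#' @param pathology_n,pathology_p Pathology simulation settings.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed,
                            design = cohort_design(),
                            proteins = default_protein_panel(),
                            model = spectrum_model(),
                            suppression = default_suppression(),
                            baseline_window = 0.02,
                            snr_min = 5,
                            rel_tol_alias = 0.005,
                            rel_tol_adduct = 0.001,
                            n_perm = 100,
                            fdr_bandwidth = 2,
                            cv_age = NULL,
                            k_max = 15,
                            cv_repeats = 1000,
                            train_n = 36,
                            k_select = 5,
                            qc_blood_threshold = 3,
                            pathology_n = c(P30 = 20, P60 = 22, P90 = 21),
                            pathology_p = c(P30 = 0, P60 = 0.18, P90 = 0.67)) {
  if (missing(seed)) stop("a seed is mandatory")
  if (is.null(cv_age)) cv_age <- design$ages[length(design$ages)]
  cfg <- list(seed = as.integer(seed), design = design, proteins = proteins,
              model = model, suppression = suppression,
              baseline_window = baseline_window, snr_min = snr_min,
              rel_tol_alias = rel_tol_alias, rel_tol_adduct = rel_tol_adduct,
              n_perm = n_perm, fdr_bandwidth = fdr_bandwidth, cv_age = cv_age,
              k_max = k_max, cv_repeats = cv_repeats, train_n = train_n,
              k_select = k_select, qc_blood_threshold = qc_blood_threshold,
              pathology_n = pathology_n, pathology_p = pathology_p)
  class(cfg) <- "pipeline_config"
  cfg
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE))
}

#' Run the full discovery pipeline
#'
#' Executes simulate -> preprocess -> detect -> quantify -> alias/adduct
#' annotation -> per-age Mann-Whitney ranking with permutation global and
#' local FDR -> pathology chi-square -> homotopy-LASSO cross-validation and
#' selection frequencies, deterministic given the config seed. When
#' `out_dir` is given every report table is persisted as CSV stamped with a
#' configuration fingerprint.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Optional output directory for CSV tables.
#' @param cohort Optional pre-simulated `seldi_cohort` (skips the simulate
#'   stage; the config's design/panel are then ignored).
#' @return An object of class `seldi_report`; see `print()` for a summary.
#'   Fields: `fdr_counts` (ages x local-FDR thresholds), `tests` (per-age
#'   ranked peak tables with alias/adduct annotations), `fdr_curves`,
#'   `aliases`, `cv`, `selection`, `pathology`, `qc`, `n_peaks`, `config`,
#'   `config_hash`.
#' @export
run_pipeline <- function(config, out_dir = NULL, cohort = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  seed <- config$seed
  hash <- config_hash(config[setdiff(names(config), "proteins")])

  cohort <- run_stage("simulate", {
    if (is.null(cohort))
      simulate_cohort(config$design, config$proteins, config$model,
                      config$suppression, seed = derive_seed(seed, 1))
    else cohort
  })
  ages <- unique(cohort$samples$age)

  pp <- run_stage("preprocess",
                  preprocess_cohort(cohort, config$baseline_window))
  qc <- run_stage("qc_blood",
                  qc_blood(pp$cohort, threshold = config$qc_blood_threshold))
  excluded <- qc$sample_id[qc$flagged]

  peakdefs <- run_stage("detect", {
    pd <- detect_peaks(pp$cohort, snr_min = config$snr_min)
    merge_cross_tier(pd, rel_tol = config$rel_tol_alias)$peaks
  })
  pm <- run_stage("quantify", quantify(pp$cohort, peakdefs))
  aliases <- run_stage("aliases",
                       find_aliases(peakdefs, pm, rel_tol = config$rel_tol_alias))

  tests <- list(); curves <- list()
  for (a in ages) {
    tests[[a]] <- run_stage(paste0("fdr_", a),
      local_fdr(pm, a, n_perm = config$n_perm,
                bandwidth = config$fdr_bandwidth,
                seed = derive_seed(seed, 10 + match(a, ages)),
                exclude = excluded))
    curves[[a]] <- run_stage(paste0("fdr_curve_", a),
      global_fdr_curve(pm, a, n_perm = config$n_perm,
                       seed = derive_seed(seed, 20 + match(a, ages)),
                       exclude = excluded))
    # join alias annotation
    m <- match(tests[[a]]$peak_id, aliases$alias_id)
    tests[[a]]$alias_of <- aliases$parent_id[m]
    tests[[a]]$alias_relation <- aliases$relation[m]
  }

  thresholds <- c(0.25, 0.10, 0.05)
  fdr_counts <- t(vapply(ages, function(a) {
    vapply(thresholds, function(t)
      sum(tests[[a]]$local_fdr < t, na.rm = TRUE), numeric(1))
  }, numeric(3)))
  colnames(fdr_counts) <- sprintf("lfdr<%.2f", thresholds)

  pathology <- run_stage("pathology", {
    pt <- simulate_pathology(config$pathology_n, config$pathology_p,
                             seed = derive_seed(seed, 30))
    tab <- incidence_table(pt)
    list(table = pt, counts = tab, percent = incidence_percent(tab),
         chisq = chi_square_homogeneity(tab))
  })

  pm_cv <- pm_subset(pm, age = config$cv_age, exclude = excluded)
  cv <- run_stage("lasso_cv",
    cross_validate(pm_cv, k_max = config$k_max,
                   n_repeats = config$cv_repeats, train_n = config$train_n,
                   seed = derive_seed(seed, 40)))
  selection <- run_stage("lasso_selection",
    selection_frequency(pm_cv, k = config$k_select,
                        n_repeats = config$cv_repeats,
                        train_n = config$train_n,
                        seed = derive_seed(seed, 41)))
  m <- match(selection$peak_id, aliases$alias_id)
  selection$alias_of <- aliases$parent_id[m]

  report <- structure(list(
    fdr_counts = fdr_counts, tests = tests, fdr_curves = curves,
    aliases = aliases, cv = cv, selection = selection, pathology = pathology,
    qc = qc, n_peaks = nrow(peakdefs), peakdefs = peakdefs,
    config = config, config_hash = hash
  ), class = "seldi_report")

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    stamp <- sprintf("seldimark report | config %s | seed %d", hash, seed)
    write_table_stamped(as.data.frame(fdr_counts),
                        file.path(out_dir, "fdr_counts.csv"), stamp)
    for (a in ages)
      write_table_stamped(tests[[a]],
                          file.path(out_dir, sprintf("peak_tests_%s.csv", a)),
                          stamp)
    for (a in ages)
      write_table_stamped(as.data.frame(curves[[a]]),
                          file.path(out_dir, sprintf("fdr_curve_%s.csv", a)),
                          stamp)
    write_table_stamped(as.data.frame(aliases),
                        file.path(out_dir, "aliases.csv"), stamp)
    write_table_stamped(as.data.frame(cv), file.path(out_dir, "cv_curve.csv"),
                        stamp)
    write_table_stamped(as.data.frame(selection),
                        file.path(out_dir, "selection.csv"), stamp)
    write_table_stamped(pathology$table,
                        file.path(out_dir, "pathology.csv"), stamp)
  }
  report
}

#' @export
print.seldi_report <- function(x, ...) {
  cat("== seldimark pipeline report (config", x$config_hash, ") ==\n")
  cat(sprintf("%d peaks quantified; %d samples flagged by blood QC\n",
              x$n_peaks, sum(x$qc$flagged)))
  cat("\nPeaks below local-FDR thresholds per age:\n")
  print(x$fdr_counts)
  cat(sprintf("\nPathology chi-square: X2 = %.1f, df = %d, p = %.2g\n",
              x$pathology$chisq$statistic, x$pathology$chisq$df,
              x$pathology$chisq$p.value))
  best <- x$cv$k[which.min(x$cv$mean_error)]
  cat(sprintf("\nCV (%s): minimum mean error %.3f at %d markers\n",
              x$config$cv_age, min(x$cv$mean_error), best))
  cat("Top selection frequencies:\n")
  print.data.frame(head(as.data.frame(x$selection), 7), row.names = FALSE,
                   digits = 3)
  invisible(x)
}
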