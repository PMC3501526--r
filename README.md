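# seldimark

Biomarker discovery from SELDI-TOF peak intensities in cerebrospinal fluid
(CSF), built around the presymptomatic rodent glioma setting: rats exposed
*in utero* to ethylnitrosourea (ENU) all develop brain tumors, and their
CSF proteome is compared with saline controls at postnatal days 30, 60 and
90 — before any tumor is visible by imaging. The package is for
proteomics/biostatistics researchers who want a reproducible, fully
scriptable version of this analysis: from raw (or simulated) spectra to
ranked differential peaks with permutation false-discovery control and a
sparse marker panel.

## What it implements

* **Synthetic cohorts.** A generative model of linear-TOF spectra in three
  laser-energy tiers (m/z 2,000–200,000): Gaussian peaks with
  FWHM = m/z / 400 on a decaying-exponential baseline, lognormal
  between-animal variation, charge-state (z=2, z=3) and dimer alias peaks
  at (m+1)/2, (m+2)/3 and 2m−1, a transthyretin-like proteoform family
  (cysteinyl +119.004, Cys-Gly +176.026, glutathionyl +305.068, sulfo
  +79.957 Da) whose total is conserved while fractions shift with
  exposure, albumin-driven ion suppression of a co-detected peak, and
  optional blood contamination marked by a globin peak at m/z 15,216.
* **Preprocessing.** Morphological-opening baseline subtraction (window
  proportional to local m/z), robust MAD noise estimation, and
  total-ion-current normalization within (age, tier) groups; globin-window
  blood QC.
* **Peaks.** Detection on per-tier mean spectra (SNR gate, shoulder
  suppression), apex-height quantification of every sample at every peak,
  cross-tier duplicate merging, and alias/adduct annotation with mass
  arithmetic plus correlation and intensity-dominance gates.
* **Statistics.** Two-sided Mann-Whitney U tests (exact small-sample
  branch, tie-corrected normal approximation otherwise), permutation
  global FDR curves, a permutation density-ratio **local FDR** with
  isotonic monotonization, Pearson chi-square for pathology incidence, and
  an ion-suppression regression diagnostic.
* **Marker selection.** A homotopy (LARS) solution path of the
  squared-error LASSO, 1/2‖y − Xβ‖² + λ‖β‖₁, adding or dropping one marker
  per breakpoint; repeated-subsampling cross-validation (36 train / 9 held
  out by default) of the k-marker classifier with least-squares refit, and
  marker selection-frequency tables.
* **Mass arithmetic.** Peptide monoisotopic/average masses, \[M+H\]+
  convention, fragment-to-parent coordinate mapping.

## Worked example

```r
library(seldimark)
cfg <- pipeline_config(seed = 2026, n_perm = 100, cv_repeats = 200)
report <- run_pipeline(cfg)
print(report)
```

```
== seldimark pipeline report (config 332dea8a ) ==
255 peaks quantified; 0 samples flagged by blood QC

Peaks below local-FDR thresholds per age:
    lfdr<0.25 lfdr<0.10 lfdr<0.05
P30         0         0         0
P60         5         0         0
P90        28        22        22

Pathology chi-square: X2 = 38.8, df = 2, p = 3.7e-09

CV (P90): minimum mean error 0.000 at 6 markers
Top selection frequencies:
     peak_id frequency alias_of
  high_30883     1.000     <NA>
  high_36433     1.000     <NA>
 high_160642     0.990     <NA>
  high_31525     0.710     <NA>
 high_139633     0.325     <NA>
  high_96325     0.260     <NA>
  high_29275     0.170     <NA>
```

Reading the output: the simulated cohort delivers ~250 quantifiable peaks;
no sample trips the blood-contamination QC. The local-FDR table is the
age gradient the design plants — at P30 nothing survives false-discovery
control, by P90 twenty-odd peaks are confident discoveries. The pathology
table (microtumor incidence 0%/18%/67% by age) is strongly heterogeneous
by chi-square. The cross-validation stage selects a small marker panel;
peaks selected in the majority of subsampling rounds are the stable
markers, and the `alias_of` column joins charge-state/dimer annotations
when a selected peak is an alias of another.

Individual stages are ordinary functions returning classed objects with
`print`/`plot` methods — `simulate_cohort()`, `subtract_baseline()`,
`normalize_by_group()`, `detect_peaks()`, `quantify()`, `find_aliases()`,
`test_all_peaks()`, `local_fdr()`, `lasso_path()` (with `coef`, `predict`,
`plot`), `cross_validate()`, `selection_frequency()` — so any slice of the
pipeline can be run and inspected on its own. Real data enter either as
long-form spectra CSV (`read_spectra_csv()`) or as a pre-quantified
peaks × samples table (`read_peak_matrix_csv()`).
A shell entry point for full runs is in `inst/scripts/run_pipeline.R`.

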