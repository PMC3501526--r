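Package: seldimark
Title: SELDI-TOF CSF Biomarker Discovery with Permutation FDR and
    Homotopy LASSO Marker Selection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for SELDI-TOF peak-intensity
    biomarker discovery in cerebrospinal fluid, modelled on age-structured
    rodent glioma cohorts. Generates synthetic multi-laser-energy spectra
    with charge-state and dimer alias peaks, proteoform adduct families and
    ion-suppression artifacts; preprocesses spectra (morphological baseline,
    robust noise, age-grouped total-ion-current normalization); detects and
    quantifies peaks; annotates alias and adduct relationships; ranks peaks
    with Mann-Whitney tests and permutation-based global and local false
    discovery rates; and builds sparse classifiers with a homotopy (LARS)
    LASSO path, repeated-subsampling cross-validation and marker
    selection-frequency tables. Includes peptide mass arithmetic for
    adduct and fragment annotation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    glmnet,
    jsonlite,
    yaml
Config/testthat/edition: 3
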