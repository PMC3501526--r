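---
title: "Methods: simulation, testing and marker selection in seldimark"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulation, testing and marker selection in seldimark}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

seldimark implements a complete discovery pipeline for SELDI-TOF
peak-intensity biomarker studies of cerebrospinal fluid (CSF) in an
age-structured two-group design: carcinogen-exposed (ENU) versus control
rats sampled at three postnatal ages. This vignette is the package's own
account of the underlying models and of the choices made where the design
was genuinely open. The worked numbers shown in the README are produced by
the code; this document explains *why* the pieces look the way they do.

## The measurement model behind the simulator

A linear-TOF SELDI spectrum is modelled as

$$ y(m) = B(m) + \sum_j h_j \, \exp\!\left( -\tfrac{1}{2}
  \left(\tfrac{m - m_j}{\sigma_j}\right)^2 \right) + \varepsilon(m), $$

with a decaying-exponential chemical baseline
$B(m) = A e^{-(m - m_0)/\tau} + c$, Gaussian peaks whose full width at half
maximum grows linearly with $m/z$ (FWHM $= m/z / R$, default resolving
power $R = 400$), and additive white noise $\varepsilon$ (default sd 0.1
intensity units). Spectra are acquired in three overlapping laser-energy
tiers — low ($m/z$ 2,000–10,000), medium (5,000–30,000) and high
(20,000–200,000) — and one protein can appear in more than one tier. The
$m/z$ grid is uniform per tier with spacing FWHM/6 at the tier's lower
edge, so the narrowest peak is always sampled by at least six points.

Per-sample protein intensity is multiplicative:
$I = I_0 \cdot a(\text{age}) \cdot e(\text{age})^{[\text{ENU}]} \cdot
L(\text{cv})$, where $I_0$ is the panel intensity, $a$ an optional
developmental age trend applied to both groups, $e$ the planted ENU/control
effect ratio, and $L$ a mean-one lognormal with coefficient of variation
`cv`. The lognormal respects the strict positivity and right skew of real
peak intensities and reproduces the mean ± SEM structure of published peak
tables.

Three structural features of real CSF SELDI data are planted explicitly:

* **Alias peaks.** A singly protonated parent at $m$ (≈ $M$+H) also appears
  as a doubly charged ion at $(m+1)/2$, a triply charged ion at $(m+2)/3$,
  and a non-covalent dimer at $2m-1$; alias intensities are fixed fractions
  of the parent's, so alias and parent co-vary across samples. This is the
  standard protonation arithmetic; observed alias positions in real tables
  deviate from it by up to ~0.2%, which is why downstream matching uses a
  0.5% relative tolerance.
* **A proteoform family with a conserved total.** A transthyretin-like
  protein at 13,601 Da carries cysteine-thiol adducts (sulfonation +79.957,
  cysteinylation +119.004, Cys-Gly +176.026, glutathionylation
  +305.068 Da). Exposure shifts mass *between* forms — the glutathionylated
  fraction drops and the others rise — while the per-sample total is
  conserved in expectation (fraction shifts sum to zero). The shift scales
  with age (0 at P30, half at P60, full at P90).
* **Ion suppression.** An abundant albumin-like protein (66,110 Da)
  depresses the apparent intensity of a co-detected PGD2S-like peak
  (22,893 Da): observed $=$ true $\times (1 - s\,S)$ with strength
  $s = 0.6$ and $S$ the suppressor intensity scaled to its cohort maximum.
  The albumin anchor also carries a developmental age trend
  (0.35×/1×/1.8× at P30/P60/P90, both groups): overall peak intensities in
  developing-rat CSF differ strongly by age — the very reason
  normalization is age-grouped — and it is this pooled, all-ages albumin
  range that makes the suppression artifact appear as a near-linear inverse
  correlation when all samples are plotted together. With the default
  conditions the quantified Pearson correlation is about −0.82 to −0.91
  across seeds. The PGD2S-like target has a tight biological cv (0.08),
  as expected for a constitutively secreted choroid-plexus protein; its
  apparent group difference is pure artifact (its true effect ratio is 1).

The default panel adds ~245 background proteins (30% with a z=2 alias, 10%
with a dimer) so that roughly 245 peaks are detectable after cross-tier
deduplication — the scale of a real unfractionated-CSF peak set. Thirty
background proteins carry planted group effects that grow with age: 20
"strong" markers with P90 ratios drawn from 1.4–1.85 (the upper half of the
effect-ratio range seen in published differential-peak tables; the
pipeline's own total-ion-current normalization attenuates high-tier
up-effects by roughly 10%, so the delivered post-normalization ratios are
≥ ~1.3) and 10 "weak" markers at 1.15–1.3, with 25% of effects pointing
down. P60 effects are the P90 effects at 45% log-scale strength; P30
effects are null. Planted markers and the named anchors are placed at
least 0.8% away from every other panel position: the study-identified
markers were resolvable peaks, and a marker sharing a quantification window
with an unrelated peak is not recoverable even in principle. Background
null peaks still collide with each other — that clutter is realistic and
stays.

Blood contamination is modelled as an optional spike: a globin peak at
$m/z$ 15,216 with a saturating dose–response in the blood:CSF ratio, plus
an upward scaling of blood-borne (albumin-like) peaks.

What the generator does **not** emulate: isotope fine structure, adduct
chemistry of the energy-absorbing matrix, detector saturation, mass
calibration drift or peak-position warping between spectra, and replicate
spot-to-spot variation (one spectrum per sample per tier). Passing tests
on simulated cohorts therefore demonstrate the pipeline's statistical
behaviour under a realistic intensity model, not robustness to calibration
error or batch structure in real instrument data.

## Preprocessing

The vendor software that produced the original spectra is not
reproducible, so standard open equivalents are used for each named step:

* **Baseline**: morphological opening — a rolling minimum followed by a
  rolling maximum with a window proportional to local $m/z$ (default 2%).
  The window is an order of magnitude wider than any peak (FWHM ≈ 0.25% of
  $m/z$), so peaks ride on top of the opening and survive within 5% of
  their height, while the smooth chemical baseline is removed exactly on
  flat regions. Results are clipped at zero. The rolling extremes are
  computed in C++ (a monotone-deque pass, linear time even with the
  position-dependent window).
* **Noise**: per-segment robust sd, $1.4826 \cdot \mathrm{MAD}(\Delta y) /
  \sqrt{2}$, insensitive to peaks and smooth baseline by construction.
* **Normalization**: each spectrum is scaled so its total ion current (TIC,
  summed intensity above $m/z$ 1,500 — the region below is dominated by
  matrix artifacts in real data) equals the median TIC of its (age, tier)
  group. Normalization is age-grouped, never global, because overall CSF
  peak intensities differ by age; a global reference would mix
  developmental trends into every group comparison.
* **Blood QC**: samples whose globin-window intensity exceeds 3× the
  cohort median are flagged and excluded from group testing. The threshold
  is conservative; even small blood admixtures distort the CSF proteome.

## Peak detection, quantification and annotation

Peaks are found on the per-tier **mean spectrum over all samples and
ages** ("recombined" detection). This is what makes the peaks × samples
matrix complete: every sample is quantified at every peak window, so no
missing-data imputation is ever needed. Candidate local maxima must rise
`snr_min` (default 5) noise-sd above the local background of the mean
spectrum (the mean spectrum is itself opened first, and a per-segment
median absorbs the small positive pedestal left by per-spectrum baseline
clipping). A candidate within two windows of a neighbour more than twice
its height is discarded as a flank maximum of that bigger peak —
comparable-height neighbours, such as an adduct ladder, are kept.
Quantification windows span apex ± 0.3% of $m/z$, clipped at midpoints so
windows never overlap within a tier.

Quantification is apex height (max within the window minus the residual
edge baseline, clipped at zero) — not area — matching the µA "peak
intensity" convention of linear-TOF instruments.

Cross-tier duplicates (same $m/z$ within 0.5%, different tiers) are merged
after detection, keeping the tier whose *optimization range* contains the
peak; since acquisition ranges overlap, the non-overlapping optimization
partition uses the geometric midpoints of the overlaps (low < 7,071 ≤
med < 24,495 ≤ high).

Alias annotation tests every ordered peak pair against the three expected
positions at 0.5% relative tolerance. Two gates guard against coincidence:
the across-sample Pearson correlation with the putative parent must reach
0.5 (aliases are the same molecule, so they co-vary), and the parent must
be at least as intense as the alias. The intensity gate also resolves an
intrinsic ambiguity: a 2:1 $m/z$ pair matches both "alias is a dimer of
parent" and the reverse "parent is the z=2 ion of alias"; intensity
dominance orients it. When no intensity evidence exists at all, the z=2
orientation (higher-$m/z$ peak as parent) is preferred, as charge
satellites are far more common than dimers. Alias edges are computed
*before* cross-tier merging, so printed tables that list the same alias in
two tiers retain both annotations. Adduct annotation around a base peak
uses the fixed delta table at a tighter 0.1% tolerance, since adducts are
same-tier and better calibrated; double matches are reported and flagged
ambiguous rather than silently resolved.

## Ranking and false discovery rates

Group differences per peak use the two-sided Mann-Whitney U test: the
exact null distribution when the pooled sample is small (≤ 12) and
tie-free, otherwise the tie-corrected normal approximation with continuity
correction. Permutation analogues reuse the per-peak rank vectors, so a
whole matrix × many label permutations costs one matrix product.

The **global FDR curve** compares the observed number of discoveries at
each p threshold (up to 0.05) with the average over label permutations
within the age stratum (100 by default); permuting labels preserves group
sizes by construction.

The **local FDR** of peak $i$ is a permutation density ratio: the mean
number of permutation-null p-values (across all peaks) falling in a
multiplicative window $[p_i/c,\; p_i c]$ — symmetric on the log-p scale,
window factor $c = 2$ — divided by the number of observed p-values in the
same window, clipped to $[0,1]$. Windows holding fewer than five observed
p-values are widened by factors of 1.5 until they do; a final isotonic
regression pass makes the estimate non-decreasing in p, as any sensible
local FDR must be. The permutation null is pooled across peaks: with only
100 permutations a per-peak-only null cannot resolve local FDRs of order
10^-3, so pooling is the only reading consistent with the small printed
values in this kind of analysis. Under a global null the estimator sits
near 1 everywhere; identical intensities give exactly 1.

Pathology incidence (microtumor counts per age) is tested with the Pearson
chi-square test of homogeneity, no continuity correction.

## Marker selection

The classifier stage is a least-squares LASSO on ±1 labels,

$$ \tfrac{1}{2}\lVert y - X\beta \rVert^2 + \lambda \lVert \beta \rVert_1, $$

whose full solution path is traced by the homotopy (LARS-lasso) algorithm:
starting at $\lambda = \max_j |x_j^\top y|$, coefficients move piecewise
linearly in $\lambda$, and at each breakpoint exactly one feature enters
(its correlation catches up with the active set's) or drops (its
coefficient hits zero). Ties between duplicate columns break
deterministically toward the earlier column; columns are ordered by
increasing $m/z$ in peak matrices. Constant columns are removed with a
warning. The path stops once the segment with `k_max` distinct active
features completes, so fitting a small classifier never pays for the full
path. Correctness is pinned in the tests by closed-form soft-thresholding
on orthonormal designs and by breakpoint-for-breakpoint agreement (10^-6)
with an independent coordinate-descent solver.

"The classifier with $k$ markers" is the path solution at the breakpoint
that *ends* the size-$k$ segment — the point just before marker $k+1$
would enter — because at the segment-opening breakpoint the newly entered
feature still has coefficient exactly zero. Prediction is the sign of the
linear score with the training label mean as intercept ($k = 0$ therefore
predicts the majority label).

Cross-validation repeatedly subsamples a training set (default 36 of the
45 P90 animals, group-proportional 18+18 so no draw is degenerate; simple
random subsampling with redraw is available by flag), fits the path on the
training subsample only — standardization parameters included, so there is
no leakage into the held-out 9 — and records held-out misclassification
for every $k$, averaged over repeats (1,000 by default). One design choice
deserves emphasis: by default the $k$ selected markers are **refit by
unpenalized least squares** on the training subsample before evaluation
(the LARS-OLS hybrid). Evaluating the shrunk path coefficients instead
(`refit = FALSE`) makes held-out error decrease quasi-monotonically in
$k$, because moving further down the path mostly *un-shrinks* the true
markers; the refit removes that confound and lets the error-versus-$k$
curve express the real trade-off, with its minimum near the true marker
count. Selection frequencies — the fraction of repeats in which a peak
sits in the size-$k$ classifier — do not depend on the refit at all.
Aliased peaks are deliberately *not* collapsed before selection; they
compete as separate features and split selection frequency, and reporting
joins the alias annotation afterwards.

## Numerical and degenerate-input conventions

* All-identical intensities: Mann-Whitney p = 1, local FDR = 1.
* Zero-TIC spectra are excluded from normalization with a warning.
* Samples missing a tier yield NA cells; affected peaks are excluded from
  testing rather than imputed.
* Empty local-FDR windows widen geometrically; the estimate is clipped to
  $[0,1]$ before and after monotonization.
* Near-singular active-set Gram matrices in the path solver fall back to a
  pseudo-inverse direction.
* Every stochastic operation takes an explicit seed; the pipeline derives
  per-stage seeds from the single config seed, so whole runs are
  bit-reproducible and persisted tables carry a config fingerprint in
  their header.

## Problem sizes used by the test suite

The shipped tests exercise the full study design (13/11, 16/16, 22/23
animals at the three ages; ~245 detectable peaks) where the property under
test concerns the study scale: the global-null calibration uses one P90
cohort with 1,000 label permutations; planted-effect recovery uses 20
simulated cohorts with 100 permutations each; the marker-count experiment
uses 10 cohort replications with 1,000 subsampling repeats each. Unit
tests of individual operations run on deliberately small panels and
groups. These sizes are the package's chosen balance between
Monte-Carlo resolution and a test suite that runs in a few minutes.

## Known limitations

* The simulator's peak positions are exact (no calibration error), so
  alias matching on simulated data is easier than on real spectra; the
  0.5% tolerance is exercised instead by the printed-table fixtures.
* Local FDR values depend on the pooled-null reading and the log-window
  bandwidth; other local-FDR estimators (kernel or empirical-Bayes) would
  give somewhat different values with the same ordering.
* The suppression model is linear in the scaled suppressor and cannot
  saturate; real ionization competition can.
* Cross-validation within one cohort rewards chance within-cohort
  separations: in roughly one to two cohort draws in ten, the
  error-minimizing marker count overshoots the planted count because a few
  null peaks carry genuine (chance) separation in that finite cohort. This
  is a property of subsample CV itself, not a solver defect.
* Subsampling CV error is granular (multiples of 1/9 per repeat); curves
  flatten near their minimum and need on the order of 1,000 repeats for a
  stable argmin.
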