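---
title: "Serum FTIR classification: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Serum FTIR classification: models, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ftirserum)
```

# Scope

`ftirserum` implements a complete small-cohort serum FTIR classification
workflow: per-spectrum quality control, composable preprocessing,
unsupervised structure diagnostics, and a nested feature-selection +
Naïve Bayes supervised core evaluated by leave-one-out cross-validation
(LOOCV) with label-permutation validity testing. This vignette explains
the underlying models, the parameters that matter, the numerical and
design choices made where the field's practice is genuinely open, and
what the synthetic-cohort tests do and do not establish about real data.

# The data model

A `spectrum_set` holds a strictly ascending wavenumber grid (cm⁻¹), an
absorbance matrix (samples × wavenumbers), unique sample IDs and optional
binary labels normalized to 0 (control, "No-Stop") / 1 (positive,
"Start&Stop"). One fixed positive class keeps every downstream metric
unambiguous. All window arithmetic uses closed intervals `[lo, hi]`;
overlapping windows merge, and restriction keeps exactly the grid points
inside the union. Wide CSV (samples as rows, numeric wavenumbers in the
header) is the canonical exchange format; JCAMP-DX import is a
single-spectrum convenience covering the common AFFN `XYDATA`/`XYPOINTS`
subset with `XFACTOR`/`YFACTOR` applied.

# Quality control

Four complementary metrics are computed per spectrum, inspected jointly
rather than thresholded singly, and never used to exclude samples
automatically — post hoc exclusions on tiny cohorts are a classic source
of optimistic bias, so the report flags and a human decides.

* **Amide-I SNR.** Numerator: maximum of the rubber-band-corrected
  spectrum in the signal window (default 1600–1700 cm⁻¹). The correction
  makes the numerator a baseline-free peak height. Denominator: SD of the
  residuals after linear detrending in the noise window (default
  1800–1900 cm⁻¹) — detrending stops baseline slope from masquerading as
  noise. If the noise window is degenerate (SD < 1e−12 or too few
  points), a fallback window (2000–2200 cm⁻¹) is tried; if that is also
  degenerate the value is `Inf` with a `degenerate_snr` flag.
* **Spike burden.** First differences of the 900–1800 cm⁻¹ segment are
  z-scored against their median using the Gaussian-consistent MAD
  (scale 1.4826). Differences with |z| > 6 are flagged and *runs* of
  consecutive flagged differences merge into one event, because a
  single-point spike produces two adjacent large differences and must
  count once. A zero MAD (perfectly smooth signal) returns zero events
  with a `degenerate_mad` flag rather than dividing by zero.
* **Cosine coherence.** Each spectrum, restricted to the fingerprint
  window and scaled to unit norm, is compared to the pointwise median of
  the normalized cohort. The similarity is scale-invariant by
  construction; the review threshold (default 0.99) is configurable
  because no universal cutoff exists.
* **Baseline-area fraction.** 100 · area(rubber-band baseline) /
  area(raw) by trapezoidal integration inside the fingerprint window.
  For a nonnegative spectrum this lies in [0, 100]; spectra that dip
  below zero (e.g. derivative-like inputs or noise around zero) can
  produce values outside that range, and a nonpositive raw area is an
  error with instructions to shift the spectrum first.

The fingerprint window for the cosine and baseline metrics defaults to
900–1800 cm⁻¹ (matching the spike window); the wider 600–1900 cm⁻¹
modeling window is equally defensible, so the choice is exposed in
`qc_config()`. Beyond the per-metric flags, any sample whose metric sits
more than 3.5 robust z-units (median/MAD across the cohort) from the rest
is flagged as an outlier on that metric.

# Preprocessing

All steps are per-sample and deterministic, so they can be applied before
cross-validation without leaking information across samples.

* **Rubber-band baseline**: the lower convex hull of the (wavenumber,
  absorbance) points, linearly interpolated between hull vertices. This
  is the deterministic, oracle-checkable reading of the method; no
  iterative suction variant is used. Guarantees: baseline ≤ spectrum,
  corrected ≥ 0, corrected = 0 at hull vertices including both
  endpoints; a convex spectrum is its own baseline.
* **Vector normalization**: unit Euclidean norm per spectrum, removing
  multiplicative film-thickness/scatter gain. The literal Euclidean
  reading is used; SNV is deliberately not implemented.
* **Savitzky–Golay derivatives**: polynomial order 2, 15-point window by
  default, derivative 0/1/2, scaled per cm⁻¹ using the grid spacing
  (delegated to `signal::sgolayfilt`, which is exact on degree-≤2
  polynomials and extends edges with the terminal window fits so output
  length equals input length and feature indices stay aligned with
  wavenumbers). The grid must be uniform to 1e−6 relative tolerance;
  with a two-window configuration the filter runs per contiguous
  segment and never across the 1900 → 2800 cm⁻¹ gap, where filtering
  would be physically meaningless.
* **Atmospheric masking**: the CO₂ region (2300–2400 cm⁻¹) and
  water-vapor band (1790–1960 cm⁻¹) are replaced by linear interpolation
  between the region-edge values. This is a pragmatic stand-in for
  vendor atmospheric compensation, which requires reference line
  libraries that are out of scope.

Window restriction order is genuinely undetermined in common practice;
this package applies windows **before** the steps in every named variant,
so secondary normalization acts on the concatenated in-window points and
derivative/baseline steps act per contiguous segment. The opposite order
remains available via `preprocess_config(window_stage = "after")`. Nine
named variants (`raw`, `atmospheric`, `vector_norm`, `sg1`, `sg1_norm`,
`sg2`, `sg2_norm`, `rubberband`, `rubberband_norm`) reproduce the
customary sensitivity grid; `variant_grid()` tabulates LOOCV metrics per
variant.

# Unsupervised diagnostics

Cosine distance `1 − cos(xᵢ, xⱼ)` (range [0, 2], scale-invariant) feeds
three label-blind views: Ward-type hierarchical clustering, classical
MDS, and t-SNE. "Ward-type" deserves its qualifier: Ward's variance
criterion assumes Euclidean distances, which cosine distances are not.
The implementation applies Lance–Williams Ward updates to the *squared*
cosine distances (`stats::hclust`, `method = "ward.D"` on `d²`) — the
standard practice for spectral cosine heatmaps — and documents rather
than "fixes" the violation. Classical MDS uses the double-centered Gram
eigendecomposition; negative eigenvalues (expected for non-Euclidean
input) are clipped with a warning, and fewer than the requested positive
eigenvalues produce a lower-dimensional embedding with a warning. The
t-SNE is an exact implementation suited to n in the tens (perplexity
bisection, symmetrized affinities, early exaggeration, momentum descent)
and is deterministic under its seed; it is a visualization diagnostic,
not part of the inferential surface. None of these functions accept
labels — the API makes the masking structural.

# The supervised core

The estimator is a nested LOOCV of the chain *discretize → rank/select →
Gaussian Naïve Bayes*, fitted from scratch on every fold of n − 1
samples:

1. **Equal-frequency discretization** (default 4 bins) supplies the
   discrete codes that symmetric uncertainty needs. Cut points are
   quantiles of the training fold only, computed with the averaging
   convention (`quantile(type = 2)`, so values 1..8 with 4 bins cut at
   2.5/4.5/6.5); codes use right-closed half-open intervals and the cuts
   transfer to the held-out sample. Equal-frequency binning is robust at
   ~23 training samples, where equal-width bins can end up empty.
2. **Symmetric uncertainty** SU = 2·I(X;Y)/(H(X)+H(Y)) with plug-in
   entropies in bits; SU = 0 when both variables are constant. **FCBF**
   keeps features with SU(f, label) > δ (default δ = 0), sorts by SU
   (ties broken by feature index), and removes any feature f for which a
   retained higher-ranked g satisfies SU(f, g) ≥ SU(f, label). The
   univariate alternative (`rank_top_k`) and no selection are also
   available; FCBF is the default selector.
3. **Gaussian Naïve Bayes** on the *continuous* selected features:
   per-class means and variances, variances floored at 1e−9 times the
   largest pooled feature variance (tiny absolute floor if everything is
   constant), class-frequency priors, posteriors via log-sum-exp.
   Modeling the continuous values (rather than the discretized codes)
   keeps the classifier deterministic and standard; a discretized NB
   would be a config extension, not the default.

Aggregate metrics are computed once over the n out-of-fold
probabilities: AUC by Mann–Whitney rank statistics with midrank ties
(all probabilities equal gives exactly 0.5), confusion metrics at the
fixed 0.5 threshold (balanced design; predicted positive when
p ≥ 0.5), per-class and macro-averaged precision/recall/F1.
Resubstitution metrics (select and fit on all n, predict all n) are
recorded separately as the optimism reference. An internal,
deliberately leaky variant (selection once on all n before the folds)
exists purely so the tests can demonstrate that the nesting matters; it
is not exported.

**Permutation testing** shuffles the labels (preserving class counts),
reruns the entire nested pipeline per permutation (default 10), and
reports per-permutation training and LOOCV AUC next to the true-label
values. **Reliability** uses quantile bins (default 5, giving ~5
predictions per bin at n = 24; ties collapse bins) of the out-of-fold
probabilities, with the Brier score `mean((p − y)²)` as the summary; the
output carries an explicit note that under 1:1 case-control sampling
these are internal discriminative scores, not population risks.
**Discriminant bands** are reported by per-wavenumber selection
frequency across folds, merging contiguous selections (gap ≤ 2 grid
steps, never across a window gap) into bands ranked by mean SU.

# The synthetic cohort generator

`synthetic_truth()` fixes every parameter of the generative model; the
defaults *are* the study conditions used throughout the tests:

* **Grid** 400–4000 cm⁻¹ at 2 cm⁻¹ (1801 points), the standard
  transmission-mode acquisition range and resolution.
* **Composition**: eleven Gaussian bands emulating a dried-serum film —
  amide I (1655, the dominant band, amplitude 1.0), amide II (1545),
  amide III (1300), carbohydrate/glycoprotein fingerprint bands
  (960/1050/1160), lipid C–H stretches (2852/2925/2960), amide B
  (3075) and the broad N–H envelope (3290). Gaussian (not Voigt)
  shapes: their second derivatives are analytic, which keeps test
  oracles sharp, and shape realism is irrelevant to pipeline
  correctness.
* **Planted class effect**: additive amplitude deltas on the 960, 1050,
  1300, 2925 and 3075 cm⁻¹ bands — inside the carbohydrate block
  (~946–1161 cm⁻¹), the amide III region (~1300 cm⁻¹) and the C–H/N–H
  stretching region (~2865–3163 cm⁻¹) where serum discriminant signal
  is typically reported. No published effect size exists for such
  signatures, so the default deltas (0.030–0.052 absorbance units,
  3–17% of the carrier band amplitudes) were fixed once so that the
  default pipeline spans chance to near-perfect discrimination as the
  `effect_scale` multiplier goes 0 → 1, and were not revisited.
* **Artifacts**: multiplicative gain uniform in 0.95–1.05 (film
  thickness), convex quadratic baseline (intercept 0–0.05, tilt ±0.04,
  curvature 0–0.08 on a normalized coordinate — convex because that is
  exactly what rubber-band correction removes), white noise SD 0.004
  (≈0.4% of the amide-I peak, a realistic high-SNR acquisition), and
  Poisson-distributed single-grid-point spikes (mean 2 per spectrum,
  amplitude 0.05–0.4) matching the single-point detector-glitch model
  the spike counter assumes.
* **Reproducibility**: one named generator (R's Mersenne-Twister), a
  required seed, and a sidecar recording every realized draw (gain,
  baseline coefficients, per-sample noise sub-seed, spike positions and
  amplitudes) from which each corrupted spectrum can be rebuilt
  bit-identically.

What the generator does **not** emulate: Mie/EMSC-type scatter
distortions, water-vapor rotational line structure, correlated
(pink/drift) noise, plate-position or batch effects, and any biological
covariance between bands. Consequently, passing the synthetic test
battery demonstrates that the *pipeline machinery* is correct and
leakage-free under the stated artifact model — it does not certify
performance on real clinical spectra, where those unmodeled effects
dominate the difficulty.

# Numerical choices and degenerate inputs

* Hull computation: monotone-chain with cross-product test `≤ 0`, so
  collinear points collapse onto the chord without affecting the
  baseline.
* Grid uniformity for Savitzky–Golay: 1e−6 relative; segment detection
  uses gaps > 1.5× the median spacing.
* Zero-norm spectra are errors naming the offending sample everywhere a
  normalization is required (vector normalization, cosine metrics).
* Constant features discretize to a single code with a flag; FCBF simply
  never selects them (SU = 0).
* Empty FCBF selections fall back to the class-prior prediction for that
  fold rather than failing the whole cross-validation.
* A training fold missing one class is skipped and flagged (cannot occur
  in balanced LOOCV but guarded for general designs).
* AUC tie handling is midrank; Brier and probabilities are bounded by
  construction and asserted in tests.

# Problem sizes used by the test battery

The package's own acceptance checks run at the design size the generator
encodes (24 samples, 12 per class): 50 null cohorts for the calibration
and leakage contrast, 20 strong-effect cohorts for signal/band recovery
and for the preprocessing-variant ordering, one strong-effect cohort
with 10 label permutations for the collapse check, and 50-fixture oracle
sweeps for the exact-equivalence properties. These sizes give stable
pass/fail behavior at fixed seeds while keeping the full suite in the
minutes range on a single CPU.

# Known limitations

* "Ward-type" clustering on cosine distances is heuristic, as discussed.
* The atmospheric mask is interpolation, not compensation; it cannot
  recover signal under the masked regions.
* Gaussian NB ignores feature covariance; with the strongly collinear
  features FCBF leaves after predominance pruning this is mitigated but
  not eliminated.
* LOOCV scores pooled across folds carry a known pessimistic bias on
  null data (each held-out sample depresses its own class's fit); the
  null-calibration test bounds, but does not remove, this effect.
* Probability outputs are internal to the matched design; no
  prevalence-adjusted calibration is attempted, by design.
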