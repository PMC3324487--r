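---
title: "Methods: urinary peptidome biomarker discovery with nephropep"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: urinary peptidome biomarker discovery with nephropep}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem this package addresses

Capillary electrophoresis coupled to mass spectrometry (CE-MS) profiles the
naturally occurring peptides of urine — mostly collagen fragments and other
protease products — as triples of molecular mass (Da), CE migration time
(min) and signal intensity (arbitrary units). Drug-induced kidney injury
changes this peptidome: tubular damage and matrix-remodelling protease
activity transiently up-regulate specific collagen fragments, which makes
urinary peptide panels attractive non-invasive nephrotoxicity biomarkers in
preclinical rat studies.

`nephropep` implements the full desk-side analysis of such a study pair —
one acute two-group cohort (a single-injection nephrotoxin such as
cis-platin, cases vs controls) and one dosing time course (e.g. gentamicin
at 0/150/300 mg/kg, sampled over ~6 weeks):

1. **Calibration** of each peak list against housekeeping peptides
   (migration time, mass) and internal-standard peptides (intensity).
2. **Matching** of features across samples into a consensus *master list*
   using mass- and time-dependent tolerance windows.
3. **Discovery** of differential peptides: detection-frequency filter,
   Wilcoxon rank-sum on ln intensities, Benjamini–Hochberg FDR, AUC and
   regulation factor.
4. **Selection** of a cross-toxin panel: temporal response screen,
   two-study intersection, direction concordance.
5. **Classification**: a linear "distance-2" panel score and a linear
   soft-margin SVM score, with take-one-out cross-validation and
   time-course scoring.
6. **Annotation plausibility**: charge-based migration-time prediction and
   the ±50 ppm / ±2 min acceptance gate for sequence assignments.
7. **Endpoint correlation**: Spearman rank correlation of markers and
   model scores against histopathology and clinical chemistry.

Because no raw rat CE-MS data accompany the original studies, the package
ships a first-class synthetic-cohort generator that emulates the study
structure; every stage is tested against it and against brute-force
oracles.

## The synthetic world

`study_config()` states the simulated world once; tests never tune it to
pass.

* **Design**: doses 0/150/300 mg/kg; collection days
  1,2,3,7,10,15,18,22,29,36,44; 3 animals per dose, each sampled at every
  day (the emulated study used 3–4). The two-group generator defaults to
  14 controls vs 25 treated.
* **Intensity model**: per-peptide ln-intensity baselines drawn
  log-uniform over [10, 10⁴] AU, Gaussian ln-scale noise around them.
  The default noise SD is 0.5 ln-units — the realistic 30–60 % CV range of
  internal-standard-normalized CE-MS amplitudes. The default planted
  effect is 4 noise SDs = 2.0 ln-units at the top dose and full temporal
  effect, i.e. a regulation factor of ≈ 7.4, central in the published
  range for this kind of marker (≈ 2 to > 1000).
* **Temporal profile** (`temporal_profile()`): 0 at day 0, linear rise to
  the start of the peak window (day 3), plateau at 1 across days 3–10,
  then exponential decay calibrated to exactly 0.05 at `resolve_day`
  (29). The shape is a codification of qualitative dynamics (rapid onset,
  days 3–10 maximum, resolution by ~4 weeks); only the plateau window and
  resolve day are treated as stated facts.
* **Dose response**: the planted shift scales linearly with dose relative
  to the top dose, giving shift(300) ≥ shift(150) > shift(0) = 0.
* **References**: 37 internal-standard peptides and 30 housekeeping
  peptides, abundant (upper intensity decade) and never treatment-shifted;
  internal standards are never missing. Their ln-noise SD is 0.1 (stable
  species; technical variation only).
* **Distortions**: per-sample affine migration-time distortion (slope
  1 ± 0.05, offset ± 1 min), multiplicative dilution factor
  (ln-SD 0.3), 10 ppm multiplicative mass noise, 0.1 min time jitter,
  and 10 % independent feature missingness.
* **Peptide universe**: masses and times are drawn uniformly but kept at
  least six tolerance units apart, so distinct true peptides cannot
  collide inside a matching window. Real peptidomes do have near-isobaric
  neighbours; a green matching test therefore establishes correctness of
  the clustering rule, not robustness to dense interference.

What the generator does **not** emulate: charge-state deconvolution and
isotope envelopes (inputs are already deconvoluted single masses),
within-run drift, batch effects, correlated missingness, and
peptide-specific variance heterogeneity (noise is homoscedastic on the ln
scale by an explicit open-question decision).

## Calibration

"Local and global linear regression" is realized as a global affine fit
(time) and a global linear fit of the relative ppm error against mass; an
optional lowess residual refinement (`local = TRUE`) stands in for the
local component and is off by default because the global fit is the
minimal, exactly testable reading. Reference matching before calibration
uses deliberately wide windows (± 300 ppm, ± 5 min), nearest neighbour by
the smaller of the two normalized deviations.

Amplitude normalization fits a single multiplicative factor through the
origin (least squares of reference on observed intensities). A dilution
model is multiplicative, and a free intercept could produce negative
calibrated intensities; fixing the intercept at zero also preserves the
rank order of every sample's intensities.

## Matching

Tolerance windows: ± 50 ppm below 4000 Da, ramping linearly to ± 150 ppm
at 6000 Da, constant above; ± 1.0 min at/below 19 min ramping to ± 2.5 min
at 50 min, constant above. "Gradually increasing" is read as linear
between the anchors.

The clustering algorithm is unstated upstream; the package uses greedy
centroid clustering: features processed in descending intensity (ties by
mass, time, sample id, so results are independent of input order), each
assigned to the nearest centroid within both windows under
`max(|Δm|/tol_m, |Δt|/tol_t)`, centroids updated as intensity-weighted
running means, orphans seeding new consensus peptides. A sample
contributes at most one feature per consensus peptide. On
window-consistent instances this reproduces the transitive-closure
partition exactly (property-tested against a brute-force oracle);
divergence is confined to window-boundary cases.

## Discovery statistics

* Zeros (undetected) enter the rank test as minimum tied values after the
  classifier's ln-floor (values < 1 AU → ln 1 = 0): absence is treated as
  informative, consistent with the detection-frequency filter. The
  alternative (drop zeros) is available as `include_zeros = FALSE`.
* The Wilcoxon p-value is exact (null rank-sum distribution) when
  min(n₁, n₂) ≤ 8 without ties, otherwise the midrank normal approximation
  with tie and continuity corrections.
* BH adjustment is applied **only** over the frequency-surviving peptides
  — the filter defines the tested family and runs strictly first.
* The regulation factor floors both group means at 1 AU, so an
  all-undetected control group yields a large finite factor rather than a
  division by zero.

## The selection screen

The upstream screen was visual inspection of per-dose mean-amplitude
trajectories. The codified rule: (a) the top-dose level across the peak
window must differ from the control reference level by at least a factor
`r_min = 2` (either direction); (b) the top-dose level across the late
window (days ≥ 29) must be back within a factor `r_return = 2`.

Two implementation choices matter and are deliberate: levels are
**geometric means of floored dose/day cell means**, and the control
reference pools **all** control cells. With 3 animals per cell, ratios of
arithmetic lognormal cell means are so heavy-tailed that ~25 % of
genuinely transient markers failed the late-window band in simulation;
geometric averaging plus the pooled (time-stable) control reference brings
the estimator variance in line with what a human reading the whole
trajectory effectively does. Thresholds stay configurable in
`screen_criteria()`.

Direction concordance removes candidates whose regulation signs disagree
between the studies; candidates significant in only one study pass
vacuously (the workflow keeps single-toxin markers). Consequently a
cross-study direction flip is only *observable* — and only removable — for
candidates significant in both studies.

## Classifiers

Both models operate on ln-floored intensities (`log(max(x, 1))`, natural
log throughout).

**Linear distance-2 model.** Marker *i* is centred at
m&#8321; = (μ_case + μ_ctrl)/2 and scaled by w&#8321; = 2/(μ_case − μ_ctrl); a
sample's score is the unweighted mean of scaled values. Every marker's
scaled case-mean minus control-mean is exactly 2 — the stated purpose of
the normalization is to prevent high-amplitude markers from carrying
artificial weight — so controls score ≈ −1 and cases ≈ +1. Markers with
training contrast |μ_case − μ_ctrl| < 0.5 ln-units are dropped with a
warning: their scale 2/Δ amplifies noise without bound and a single
contrast-free marker can otherwise dominate the panel mean, which is the
exact pathology the normalization exists to avoid.

One inherited sharp edge: an *undetected* marker scores w·(0 − m), which
for an abundant marker is the most extreme value a sample can take. This
is what the ln-floor formula prescribes; time-course conclusions should
therefore be read from late-window means, not single 3-animal cells.

**Margin model.** A linear soft-margin SVM (hinge loss, C = 1) trained by
deterministic dual coordinate descent on per-marker standardized
ln-floored intensities, bias handled by an augmented constant feature. No
SVM library is required; the solver is ~40 lines, deterministic (fixed
sweep order, convergence at max α-change < 1e−8), and exercises the same
contract as any large-margin implementation: separable training data reach
training AUC 1, permuted labels drive cross-validated AUC to chance.
A linear kernel is the default because nothing upstream indicates a
nonlinear one.

**Take-one-out cross-validation** refits the *entire* model — including
per-marker centres/scales — on each fold, so no normalization constant
ever sees the held-out sample. The per-fold models are exposed
(`keep_fits = TRUE`) for leakage audits.

## Annotation plausibility

At the CE working pH of 2, migration is governed by charge: lysine
(including hydroxylysine `k`), arginine and histidine are counted as
basic; the N-terminal amine charges every peptide equally and is absorbed
into the stratum intercepts. The migration model fits, per basic-residue
stratum, a linear regression of time on log(mass) — the simplest family
honouring "charge and size determine mobility" — and the acceptance gate
requires ≤ 50 ppm mass deviation, ≤ 2 min deviation from the predicted
(calibrated) time, and agreement of both search engines (an input flag;
database searching is out of scope). Theoretical masses use average
residue masses; `p`/`k`/`m` modifications add one oxygen.

## Endpoint correlation

Spearman rho on midranks; exact permutation p for n ≤ 9 without ties,
t-approximation otherwise; pairwise-complete deletion for missing
endpoint values; **no** multiplicity correction across the marker ×
endpoint matrix (raw p-values are reported there, matching the targeted,
hypothesis-driven use). Synthetic endpoints are driven by the same latent
injury signal as the planted markers, with BUN and serum creatinine only
mildly responsive — classical serum markers were insensitive in the
emulated studies — and albumin responding more strongly.

## Numerical and degenerate-input choices

* Exact Wilcoxon switch at min(n) ≤ 8 and no ties; continuity correction
  clamps at zero rather than crossing.
* `bh_adjust` is the hand-rolled step-up (tested to 1e−12 against both a
  literal-definition oracle and `p.adjust`).
* SVM non-convergence raises an error with diagnostics instead of
  returning a half-trained model.
* Degenerate discovery inputs: identical groups return p = 1 with a
  warning; empty selector sets and missing design rows are errors naming
  the offending samples.
* Pipeline stage toggles must be prefix-closed (a stage cannot run
  without its inputs); every artifact directory carries a
  `MANIFEST.json` with the configuration hash and seed.

## What a green test establishes — and what it does not

The test suite demonstrates that the implemented procedures are correct
(oracle equivalence to enumeration/brute force), that the generator has
the statistical structure the analysis assumes (FDR control on null
cohorts, parameter recovery of injected distortions), and that the
two-study workflow recovers planted biology end to end at realistic noise.
It does **not** reproduce the published cohort counts (493/557/88/147/101
markers) or the real-data linear-model AUCs — those depend on raw data
that were never deposited — and the synthetic world's simplifications
(well-separated peptide universe, independent missingness, homoscedastic
noise) are exactly the places where real data can be harder.
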