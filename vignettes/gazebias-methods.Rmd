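---
title: "Methods: smoothed endpoint time courses, mixture comparison, and the synthetic gaze generator"
author: "gazebias"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette documents the statistical machinery of `gazebias`, the
choices that were genuinely open when it was built, and what the synthetic
generator does and does not emulate.

## The scientific problem

When an image appears in the periphery and an observer saccades to it, the
landing position depends on the saccade's latency. Short-latency saccades
are pulled toward salient objects and toward the center of the image
outline (a center-of-gravity / global-effect computation on the priority
map); long-latency saccades land on the instructed goal. Measuring this
requires (i) reconstructing endpoint-versus-latency time courses from
trials that sample latency irregularly, (ii) testing them without choosing
analysis windows post hoc, and (iii) distinguishing a *bias* of the whole
endpoint distribution from *capture* of a fraction of trials, which
produce identical means but different distribution shapes.

## Smoothed time courses and cluster inference

**Smoothing.** Each participant's endpoints are smoothed onto a 1-ms grid
with a Gaussian kernel (SD 16 ms for primary-saccade analyses; 32 ms for
secondary saccades, whose onset times are more dispersed), truncated at
4 SD. The kernel mass `w_p(g)` at grid point `g` records how much data
supports participant `p`'s estimate there.

**Weighting.** The group time course is the kernel-mass-weighted mean
across participants, so a participant contributes at a latency in
proportion to how much data they have there. The pointwise test statistic
is a weighted one-sample *t*: with weights normalized to sum to one,
mean `m = Σ u_p v_p`, variance `s² = Σ u_p (v_p − m)² / (1 − Σ u_p²)`,
effective N `= 1/Σ u_p²`, `t = m / sqrt(s² Σ u_p²)`, df `= N − 1`. With
uniform weights this reduces exactly to the ordinary one-sample *t*, which
is also how the dense (unsmoothed) distance-time-course test is run.

**Clusters and permutation.** Grid points with |t| above the two-tailed
α = 0.05 quantile of t(N−1) form maximal contiguous clusters; cluster
strength is the summed |t|. The null distribution of the *maximum*
cluster strength is built by independently sign-flipping each
participant's deviation series (equivalently, swapping condition labels in
paired tests). Reported per test: the permutation *p* of the strongest
cluster with the add-one convention `p = (1 + #{null ≥ t_obs})/(n_perm + 1)`
(never exactly 0), the observed strength, the 95th percentile of the null
(the criterion value), and the cluster's time window. When several
clusters exceed the criterion all are retained; the headline quadruple
refers to the strongest.

**Open choices made here.** The exact internals of the published
smoothing-based time-course method are not fully specified by its users'
descriptions; two choices are documented stand-ins: (i) the pointwise
confidence band is the weighted mean ± t(0.975, N−1) × weighted SE, and
(ii) the kernel masses enter the pointwise *t* as normalized weights with
an effective-N correction. Both reduce to the textbook quantities for
uniform weights. Grid points where a participant has zero kernel mass
contribute zero weight; grid points with zero *total* mass are flagged as
gaps.

## Unimodal vs. bimodal endpoint distributions

In-window endpoints are binned into 20 equal bins on [−2.5°, +2.5°]
(half-open bins, last bin closed) and fit with

* single: `a · φ((c − μ)/σ)` — 3 free parameters,
* dual: `a₁ · φ((c − μ₁)/σ) + a₂ · φ((c − μ₂)/σ)` — 5 free parameters,
  shared σ because oculomotor variability should not depend on which
  target won the competition (a free-σ variant is available and, in our
  simulations, does not change conclusions).

**Loss.** The default objective is the Poisson deviance of the bin
counts; BIC = deviance + k·ln(20). Plain least squares on the counts is
available (`loss = "least_squares"`, BIC = 20·ln(RSS/20) + k·ln(20)) but
is *not* the default for a measured reason: bin-count noise scales with
the expected count, and under an unweighted quadratic loss the
five-parameter dual model absorbs that noise in the well-filled central
bins. In simulation (150 trials, σ = 0.7°, 2° separation) least squares
attributed unimodal data to the unimodal model only ~60% of the time,
while the deviance loss achieves ~93% (and ~95% for genuinely bimodal
data) — so the likelihood-consistent loss is the default and the
quadratic loss is the flag.

**Optimization.** L-BFGS-B, bounds μ ∈ [−2.5, 2.5], σ ∈ [0.05, 3],
scales ∈ [0, 10·max count]; the single model starts from moment
estimates, the dual from mean pairs (0, d) and (−d/2, d/2) with d the
nominal goal–attractor separation, each with 8 jittered restarts. Dual
means are reported in canonical order μ₁ ≤ μ₂; a σ estimate at its lower
bound flags a degenerate fit. Model evidence is summarized as BIC
information weights (they sum to 1), compared across participants with a
Wilcoxon signed-rank test: zero differences dropped, average ranks for
ties, exact enumeration below N = 10 and a continuity-corrected normal
approximation with tie correction otherwise.

## Geometry and designs

Pixel–degree conversion uses the display's own printed linear equivalence
(240 px = 7.04°), because it is internally consistent with every other
printed value (75 px → 2.2°, 136 px → 3.99°, 800 px → 23.5°), whereas a
tangent conversion from the stated physical screen geometry gives 7.21°
for 240 px. The tangent conversion is available behind a flag; the
discrepancy in the source display's specification is documented, not
resolved. Crop-induced displacements follow from the object staying put
while the image center moves by half the cropped extent.

Design presets enumerate the full factorial crossings (one Exp1-style
block: 25 images × direction × displacement × mirroring = 200 trials,
8 per image; Exp2-style: 16 backgrounds × object × contrast × shift ×
fixation position × mirroring = 512 trials).

## Saccade detection

The published analyses delegate parsing to the tracker vendor's
proprietary algorithm, of which only the thresholds are known (30°/s,
8000°/s², 0.15°). The detector here is therefore a documented stand-in
validated against the synthetic generator, not against vendor output:
velocity is a 5-point Savitzky–Golay derivative of position, acceleration
the same derivative of smoothed speed; a sample is saccadic if *either*
threshold is exceeded; runs longer than 4 ms with net displacement
≥ 0.15° become events; events closer than 20 ms merge. The OR-combination
and the two parsing constants (4 ms, 20 ms) are conventions, exposed in
the configuration. On generator traces with 0.05° sample noise the
detector's onset recall and precision (±10 ms) exceed 0.95, with onset
errors of ~1 ms.

## Repeated-measures ANOVAs

Endpoint means and variabilities (the within-cell SD across trials, per
participant — "variability" is not given a formula in the source
description, so the per-cell SD is the documented choice) for saccades
2–5 enter 2 (object) × 2 (contrast) × 4 (saccade number) within-subject
ANOVAs, evaluated against a corrected α = 0.0125 (four dependent
measures). Sphericity can only be violated by the 4-level factor, so
Greenhouse–Geisser-corrected p-values are reported for effects involving
it and uncorrected ones for the 1-df effects. The machinery is the
type-III multivariate-model route (`car::Anova` with an `idesign`);
a constant input table is reported as degenerate rather than producing
0/0 F ratios, and missing cells are an error — no imputation.

## The synthetic generator

The generator produces data with the statistical structure the analyses
assume, so that every stage has ground truth:

* **Latencies**: ex-Gaussian, defaults μ = 110, σ = 20, τ = 40 ms —
  chosen to put the latency mass inside the 50–300 ms analysis window;
  an optional two-component mixture reproduces the saccadic-inhibition
  dip that makes latency distributions bimodal in gap/cue paradigms.
* **Endpoints**: goal and attractor combined under a Gaussian bias window
  `w(t) = A·exp(−(t − t_peak)²/(2σ_w²))` (defaults A = 0.75,
  t_peak = 150 ms, σ_w = 50 ms — a symmetric two-parameter profile
  consistent with reported bias windows; the true rise/decay is likely
  asymmetric, an extension point). *Bias* mode shifts every endpoint by
  `w·d`; *capture* mode sends a fraction `w` of trials to the attractor.
  Both have the same mean time course; capture adds `w(1−w)d²` of
  variance (law of total variance), which is exactly what the mixture
  comparison detects. Motor noise is isotropic Gaussian, σ = 0.7° per
  axis.
* **Scanpaths**: 1-kHz traces from fixation schedules; saccade durations
  follow the main sequence D = 2.2·amplitude + 21 ms (standard literature
  constants, not estimated from this package's target datasets) with
  minimum-jerk position profiles and additive sample noise.
* **Exp2-style exploration schedules**: anticipatory-saccade
  probabilities per condition (≈ 11–14%), regular latency means 149.7 /
  133.5 ms (object present / absent), first-fixation durations 226.5 /
  183.1 ms, subsequent fixations Gamma with mean 300 ms, a 30%
  refixation (<1°) rate, exploration targets drawn from an attractor
  mixture (object or image center vs. the central image region), and a
  wider horizontal target scatter under low image–monitor contrast.
  These constants parameterize the generator to the summary statistics
  the emulated paradigm reports; they were set from those printed values
  and then frozen. The emergent dataset reproduces them: ≈13%
  anticipatory saccades, a saccade-rate plateau near 0.09–0.10, mean
  amplitude ≈ 6.8°, ≈ 4.8 saccades ≥ 1° per trial.

What the generator does **not** emulate: image content and saliency maps
(attractors are geometric points), blinks and tracker dropouts, drift and
calibration error, pupil dynamics, sequential dependencies between trials,
and any repeated-exposure learning. Passing tests therefore certify the
*pipeline* — detection, recoding, smoothing, inference, model comparison —
on data whose generating process is known; they do not certify robustness
to artifacts real recordings contain.

## Numerical choices and problem sizes

* Kernel truncation at 4 SD; grid points without kernel mass are NA and
  carry zero weight.
* Zero-variance grid points yield t = 0 (no cluster) rather than 0/0.
* t_crit is the type-7 sample quantile of the permutation maxima.
* Permutation p-values use the add-one convention; with n permutations
  the smallest attainable p is 1/(n+1).
* Seeds: one master seed; every stage derives a child seed from a
  label hash passed through two Lehmer scrambling rounds, and the first
  eight uniforms after seeding are discarded (first draws after
  `set.seed` are visibly correlated across nearby seeds, which biased
  cross-trial summaries before this was fixed).
* Blink handling is unspecified in the emulated paradigm; trials with
  missing samples are excluded from sample-based analyses beyond a 10%
  missingness tolerance, and this is a package choice with no claim of
  fidelity.
* Simulation-based tests and the acceptance script use 200 permutations
  (scaled down from the 10,000 default), 500 null repetitions for type-I
  error, 100 repetitions for bias recovery, 100 simulated participants
  per mode for discrimination, and 30 traces for detector fidelity —
  sizes chosen to give stable estimates at desk scale.

## Known limitations

* The detector is not a re-implementation of the vendor algorithm; onset
  conventions can differ by a few ms from vendor output on real data.
* The weighted-t and CI construction are plausible readings of the
  smoothing method's description, not a verified re-implementation.
* The mixture comparison's discrimination rate depends on the true
  separation-to-noise ratio; at 2°/0.7° the capture-recovery rate sits
  near 90% and individual seeds can fall slightly below it.
* The asymmetric bias-window shapes seen in real time courses are not
  modelled; recovered windows are symmetric around the injected peak.
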