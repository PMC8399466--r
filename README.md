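# gazebias

Analysis pipeline for saccadic orienting toward images: where do the eyes
land when an image appears, and how does that depend on *when* the saccade
is launched?

When people saccade to a photograph, short-latency responses are pulled
involuntarily — toward a salient object in the image, or toward the center
of the image itself (the central fixation bias). `gazebias` implements the
complete analysis chain needed to measure these biases from eye-tracking
data, and a synthetic gaze-data generator that makes every stage verifiable
without raw recordings. It is written for oculomotor / eye-tracking
researchers, but the statistical core (cluster-based permutation tests on
smoothed response time courses, mixture-model comparison via BIC
information weights) is general.

## What it computes

**Saccade detection.** Samples (1 kHz gaze positions) are parsed into
saccades with the standard velocity (30°/s), acceleration (8000°/s²) and
displacement (0.15°) criteria, using Savitzky–Golay differentiation.

**Endpoint time courses (SMART-style).** Each participant's endpoints
`v_i` at latencies `t_i` are kernel-smoothed onto a 1-ms grid,

    value(g) = Σ_i K(g − t_i) v_i / Σ_i K(g − t_i),   K = Gaussian, SD 16 ms,

and the summed kernel mass weights both the group average and a pointwise
weighted one-sample *t* statistic (df = N − 1). Maximal runs with
|t| above the two-tailed α quantile form clusters; cluster strength is the
summed |t|; significance comes from a sign-flipping permutation null of
the maximum cluster strength (10,000 permutations by default). Every test
reports the quadruple (*p*, *t*, *t*<sub>crit</sub> = 95th percentile of
the null, time window).

**Bias vs. capture.** Is a mean endpoint shift a continuous bias of the
whole distribution (center-of-gravity averaging) or oculomotor capture on
a fraction of trials? Endpoints are binned (20 bins on [−2.5°, +2.5°]) and
fit with a single scaled Gaussian (3 parameters) and a dual scaled
Gaussian with shared SD (5 parameters); the models are compared with BIC
information weights `w_i = exp(−Δ_i/2) / Σ_j exp(−Δ_j/2)` and a
group-level Wilcoxon signed-rank test.

**Exploration analyses.** Distance-to-image-center time courses with a
dense (unsmoothed) paired cluster permutation test, saccade rate, 40-px
spatial dwell heatmaps, exploration metrics (amplitude ≥ 1°, 16 sequential
trial bins), and 2 × 2 × 4 repeated-measures ANOVAs on endpoint means and
variabilities (Greenhouse–Geisser corrected, α = 0.0125).

**Synthetic data.** Latencies are ex-Gaussian (optionally bimodal to mimic
saccadic inhibition); endpoints mix a goal and an attractor under a
latency-dependent Gaussian bias window `w(t)`; full 1-kHz scanpaths follow
the main sequence (duration = 2.2·amplitude + 21 ms) with minimum-jerk
profiles. Generators are pure functions of (parameters, seed).

## Worked example

Simulate a small experiment (8 participants, 100 trials per condition) and
run the full analysis:

```r
library(gazebias)
cfg <- analysis_config(n_permutations = 1000, rng_seed = 42)
rep <- run_pipeline("run1", "exp1", cfg, n_participants = 8, n_trials = 100)
```

The report (also written to `run1/report.json`) contains, per condition,
the cluster quadruple and the mixture comparison. This exact call prints:

```
look_center: p = 0.000999, t = 5555.8, t_crit = 419.1, window 50-274 ms
mixture: 8/8 favor unimodal, Z = 2.52, p = 0.007812, mean w_single = 0.87
look_object: p = 0.008991, t = 2202.4, t_crit = 413.3, window 50-230 ms
```

Read: when told to look at the image center, endpoints were significantly
biased toward the salient object for saccades launched ~50–270 ms after
image onset (the cluster strength 5556 far exceeds the permutation
criterion 419); the endpoint distribution is unimodal for every simulated
participant — a continuous bias, not capture on a fraction of trials. The
weaker pull of the image center in the look-at-object condition is also
detected. Under the add-one convention the smallest attainable *p* at
1,000 permutations is 1/1001 ≈ 0.001.

A command-line wrapper for the main stages is in `inst/cli/gazebias.R`
(`simulate`, `design`, `detect`, `run`).

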