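---
title: "Interpretable Takagi-Sugeno models for tremor severity: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Interpretable Takagi-Sugeno models for tremor severity: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(fuzzytremor)
```

# The problem

Essential Tremor (ET) produces involuntary 7–12 Hz oscillation of the upper
limbs. Clinical severity is scored with questionnaires — the clinician-rated
ETRS (0–154) and the patient-reported QUEST — which are subjective and limit
inter-rater reliability. An alternative is to strap a smartphone to the
patient's wrist, record triaxial acceleration (g) and rotation speed (rad/s)
at a nominal 100 Hz during a fixed battery of five tests (rest, two postural
holds, a glass-lifting task, and a finger–nose task, each with both hands),
and learn a model that maps signal features to the severity score.

`fuzzytremor` implements that chain end to end, with a first-order
Takagi–Sugeno (TS) fuzzy model as the regression core. TS models are chosen
for transparency: the fitted model is a short list of IF/THEN rules over
linguistic terms ("dominant frequency IS high"), each with an affine local
model, that a clinician can read.

# The model

A first-order TS model over inputs $x = (x_1, \dots, x_N)$ has rules

$$R_j: \text{IF } x_1 \text{ is } A_{j1} \text{ and } \dots \text{ and }
x_N \text{ is } A_{jN} \text{ THEN } y_j = a_j^T x + b_j,$$

with Gaussian membership functions
$\mu_{A}(x) = \exp\{-(x-\mu_0)^2/2\sigma^2\}$. The degree of fulfillment of
rule $j$ uses the minimum t-norm,
$\beta_j = \min_n \mu_{A_{jn}}(x_n)$, don't-care clauses contributing 1, and
the model output is the firing-weighted average

$$y^* = \frac{\sum_j \beta_j y_j}{\sum_j \beta_j}.$$

Where the total firing underflows to zero the weighted average is undefined;
`infer()` then returns the unweighted mean of the rule outputs and warns.
This keeps inference total while making the anomaly visible — silent
extrapolation would be worse, and refusing to answer would make batch
prediction brittle.

# Pipeline stages and their parameters

## Signal conditioning

Starting and stopping a capture requires tapping the phone, which
contaminates the record's edges; the first and last 50 samples (0.5 s at
100 Hz) are discarded (`trim_edges()`). The ET band is then isolated with an
equiripple (Parks–McClellan) linear-phase FIR band-pass, 7–12 Hz, designed
per recording sample rate (`design_bandpass()`). Defaults: 1.5 Hz transition
bands, 1 dB pass ripple, 40 dB stop attenuation, tap count from the Kaiser
estimate forced odd (149 taps at 100 Hz). The filter is applied forward and
backward (`apply_filter()`), so the output is zero-phase and feature timing
is undistorted; the effective stop attenuation doubles. Finite records are
padded by odd reflection before the forward–backward pass to suppress edge
transients. Recordings shorter than three filter lengths are rejected, not
padded: padding would fabricate data.

## The scalar signal for feature extraction

Features are computed per (test, hand, sensor) on a single orientation-
invariant scalar signal. Two reductions are offered. The Euclidean norm of
the three axes (`vector_magnitude()`) is the field's habitual choice, but
applied *after* band-pass filtering it rectifies the zero-mean oscillation:
the norm of a narrow-band signal concentrates its energy at DC and at twice
the tremor frequency, so frequency-domain features no longer see the 7–12 Hz
band. The default is therefore the first-principal-component projection
(`principal_signal()`): linear, invariant to how the phone was strapped on
(up to sign, fixed by convention), and frequency-preserving. The norm
remains available via `extract_features(..., signal = "magnitude")`.

## Features

Five scalars summarize each signal (`extract_features()`):

* `signal_rms` — root mean square, the overall tremor strength;
* `signal_period` — mean interval between successive upward crossings of the
  signal mean, a robust reading of "average duration of one wave"; constants
  have no crossings and yield a missing value, never a silent zero;
* `dominant_frequency`, `dominant_magnitude` — from a Daubechies-8
  wavelet-packet decomposition at depth 5 (uniform 1.5625 Hz bands at
  100 Hz), the center frequency of the maximal-energy band and the peak
  coefficient magnitude in it. Packets (rather than the plain wavelet tree)
  give uniform bands, so "dominant frequency" is well defined; depth 5 is the
  coarsest depth that still splits the 7–12 Hz band into three bands. The
  transform is orthonormal on the analysed window (signals are truncated to a
  multiple of $2^5$ samples), so band energies sum to the signal energy;
* `power_growth` — the OLS slope of mean signal power in 1 s windows with
  50% overlap against window mid-time, capturing intensification over the
  recording; 1 s resolves at least 7 tremor cycles per window.

With the default one-sensor-per-(test, feature) policy a complete patient
yields exactly 50 features (2 hands × 5 tests × 5 features); the
policy's rotation-speed picks are exactly the combinations the reference
severity models use, so those variables are always reachable. The `"both"`
policy exposes all 100 candidates.

## Table preparation

Missing features (e.g. a test added to the protocol mid-study) are imputed
by cubic-spline interpolation over the patient row index (`impute_missing()`).
Interpolating over exchangeable rows is statistically debatable — rows are
patients, not a time axis — so the imputer is isolated behind a `method`
switch with a column-median alternative; spline remains the default for
fidelity to the reference pipeline. Columns with fewer than four observed
values are rejected with advice to drop them.

Features and targets are min–max normalized to $[0, 1]$ using *training*
statistics only (`fit_normalizer()` / `apply_normalizer()`); test values
outside the training range are clipped to $[-0.1, 1.1]$ with a warning.
The split is 75/25 (`split_train_test()`), seeded.

Variable selection is sequential forward selection wrapped around CART
regression trees under 5-fold cross-validation (`select_features()`): a
candidate is accepted only if it strictly decreases the incumbent CV MSE,
and selection runs on training rows only, so no test information leaks. CV
fold count and CART controls (minsplit 4, minbucket 2, cp 1e-4) are fixed
and recorded; the reference variable sets for ETRS and QUEST are shipped as
presets (`preset_variables()`) so the fuzzy stage can run on them directly.
Severity is one value per patient while features are per hand, so preset
columns average the two hands (`collapse_hands()`).

## Structure identification: FCM + FST-PSO

Rules come from fuzzy c-means clustering of the joint (input, normalized
target) space: one cluster per rule, two by default (small cohorts overfit
with more). Plain alternating FCM is prone to premature convergence, so the
centers are optimized by a particle swarm whose per-particle inertia,
cognitive and social factors, and speed clamps are re-derived each iteration
by a small zero-order Sugeno rule base from two normalized state
descriptors: the particle's recent fitness change and its distance from the
global best (fuzzy self-tuning PSO). The rule levels and the rule base are
fixed package constants (see `fstpso.R`); the swarm size heuristic is
$\lfloor 10 + 2\sqrt{D}\rfloor$ over the $D$ concatenated center
coordinates, 100 iterations by default, velocities clamped to the data's
bounding box. The fitness is the standard FCM objective
$J_m = \sum_i \sum_c u_{ic}^m d_{ic}^2$ with fuzziness $m = 2$, partition
matrix in closed form from the centers. An optional `polish` step refines
the swarm's best centers with alternating FCM; it is off by default and, in
our property tests, does not change the attained objective on well-separated
data.

## Parameter identification

Antecedents: each cluster is projected onto each variable and a Gaussian set
is fitted. The default estimator is membership-weighted moments (weights
$u^m$): for a crisp partition this reduces to the cluster's empirical mean
and standard deviation. A nonlinear least-squares refinement on the
$(x, u)$ scatter is available (`method = "nls"`), but is *not* the default:
on crisp partitions the best-fitting Gaussian to a 0/1 membership profile
widens far beyond the cluster spread (the fit trades the plateau of ones
against the far zeros), which distorts the sets that the firing degrees are
built from. Spreads are floored at $10^{-3}$ normalized units so degenerate
single-point clusters stay valid. Linguistic labels ("low", "medium",
"high") are assigned by ranking set centers per variable — the labeling is
cosmetic but deterministic.

Consequents: two estimators are provided. `fit_consequents()` is the
per-rule weighted least squares with the rule's firing degrees as weights
(ridge $10^{-8}$ on the normal equations for rank safety); it yields
autonomous local models but is biased wherever rules overlap, because the
observed response there is the firing-weighted *blend*, not the rule's own
line. `build_ts_model()` therefore defaults to global joint least squares on
the mixture $y \approx \sum_j \gamma_j(x)(a_j^T x + b_j)$ with
$\gamma_j = \beta_j / \sum_k \beta_k$, which is linear in all consequent
parameters and recovers the generating parameters when the model class
matches the data. `consequent_fit = "local"` selects the per-rule route.
Firing degrees for either estimator come from the *fitted Gaussian
antecedents*, not the raw partition matrix, so the final model is
self-consistent (`weighting = "partition"` switches this). Consequents are
fitted on normalized inputs against the *unnormalized* target, so rule
outputs are on the clinical score scale and the printed intercepts have
score magnitudes.

## Rule-base simplification (graph-based)

After estimation, near-duplicate fuzzy sets are merged
(`simplify_rules()`): per variable, sets are nodes, pairs with Jaccard
similarity $\ge \theta$ (default 0.9) are edges, and each connected
component is replaced by one representative set — the parameter-wise mean by
default (symmetric and order-independent; `keep_first` is available).
Similarity is $\int \min(\mu_a, \mu_b) / \int \max(\mu_a, \mu_b)$ on a
1000-point grid over the variable's universe. Because components chain,
two sets below the threshold can end up merged through an intermediate; the
component's minimum pairwise similarity is reported so this is visible.
When, after merging, every rule carries the same set for a variable, the
clause no longer discriminates and is rendered don't-care ("IS any value").
The rule count never changes, and consequents are not refitted by default
(simplification is a structure-only edit; `refit_with` re-estimates them).
Simplification is idempotent, and lowering $\theta$ never merges fewer
pairs.

# The synthetic cohort generator

No public recording corpus exists for this protocol, so
`gen_recording()` / `gen_cohort()` emulate the study conditions: 20
patients, one-minute recordings at 100 Hz, five tests × two hands. Each
recording is a tremor sinusoid with frequency uniform in 7–12 Hz, random
per-axis phase, and amplitude tied to a latent severity in $[0,1]$ by a
linear map (no severity–amplitude law is established; linear is the minimal
monotone choice), plus white sensor noise, a constant gravity component on
the accelerometer, tap-artifact bursts confined to the first/last 50
samples, and — in the glass and finger–nose tests only — three large
raised-cosine excursions below 1.5 Hz, mimicking a thrice-repeated voluntary
movement. ETRS- and QUEST-scale targets are two noisy monotone transforms of
the same latent severity, so the two scores share structure the way clinical
scores do. `missing_fingernose = k` drops that test for the first $k$
patients, emulating a protocol extended mid-study.

What the generator does *not* emulate: harmonic structure and
amplitude-frequency coupling of real tremor, intermittent tremor bursts,
sensor drift and quantization, and any biomechanics of the limb. Passing
tests on this generator therefore demonstrate that the pipeline recovers the
structure it assumes — monotone severity-amplitude coupling in a known band
— not that it matches clinical accuracy figures, which require the original
cohort.

`gen_ts_dataset()` is the feature-space recovery harness: inputs uniform on
the unit hypercube, target from a known TS model plus Gaussian noise.

## Planted-model design for recovery tests

Recovery tests plant a two-rule model with antecedents at 0.25/0.75
($\sigma = 0.15$) and consequent lines $y = x + 1$ and $y = 2 - x$ that
intersect at the regime boundary. The intersection matters: when the two
local lines disagree at the boundary, the TS blend has a steep transition
that neither affine form can represent, and the generating parameters are
only weakly identifiable — every estimator, local or global, then disagrees
with the "truth" without being wrong about the function. Locally
intersecting lines keep the recovery problem well-posed, which is what a
parameter-recovery test should measure.

# Numerical choices

* Coincident point and cluster center: crisp membership (the FCM closed form
  has a removable singularity there).
* Zero total firing in inference: unweighted rule mean plus a warning.
* Constant feature columns: flagged and mapped to 0.5 rather than dropped
  silently.
* Jaccard denominator numerically zero (both sets vanish on the universe):
  an error — the similarity is undefined and merging would be arbitrary.
* Ties in linguistic-label ranking: first-come ordering (deterministic).
* All stochastic stages (generation, splitting, fold assignment, swarm) are
  seeded through a single user-visible seed.

# Problem sizes used in the shipped checks

The property suite runs at deliberately desk-scale sizes chosen to exercise
every code path while keeping a full run in minutes: cohorts of 8–20
patients with 12 s to 60 s recordings, recovery studies at $n = 200$ rows
over 20 seeds, swarm runs with the default 100 iterations. These sizes are
the package's own test design; the statistical thresholds they assert
(e.g. blob centers within 0.05 in ≥ 19/20 seeds, median intercept recovery
within 10%) were fixed alongside the generator defaults.

# Known limitations

* The severity mapping is validated on synthetic data only; the headline
  accuracy of the clinical study it mirrors is not reproducible without the
  original cohort.
* Spline imputation over patient index is kept for fidelity but is hard to
  defend statistically; prefer `method = "median"` for new data.
* Similarity chaining can merge dissimilar end sets; inspect
  `min_similarity` in the attached graph when lowering the threshold.
* The min t-norm makes inference non-differentiable along clause-crossing
  boundaries; this is inherent to the model family, not a defect.
* Wavelet-packet band edges are ideal-filter approximations; energy near a
  band boundary can land in either neighbor (the dominant-frequency tests
  allow half a band of slack accordingly).
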