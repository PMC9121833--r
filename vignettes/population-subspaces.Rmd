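---
title: "Methods: population activity subspaces across task phases"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: population activity subspaces across task phases}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(popsubspace)
```

This vignette documents the models, conventions, and numerical choices
behind `popsubspace`. The package asks, for a population of simultaneously
recorded neurons in a trial-based maze task, whether activity during trials
and during the self-paced return (the intertrial interval, ITI) occupies
separable subspaces of population rate space; what task information each
phase encodes; how distinct the two codes are geometrically; and whether
phase-specific activity patterns are preferentially reactivated in
post-training slow-wave sleep.

## Data model and conventions

A session couples four streams: spike trains (0.1 ms resolution), position
tracking (nominally 30 Hz), a trial event table, and slow-wave-sleep
intervals taken as given (sleep staging is out of scope). All times are in
seconds and every interval is half-open `[start, end)`, so a spike landing
exactly on a phase boundary is counted once, in the later phase. Trial `i`
spans `[t_start, t_armend)`; its ITI spans `[t_armend, t_iti_end)`. The
label conventions for decoding follow the task's temporal logic: the trial
"preceding" ITI `i` is trial `i` itself (the trial that just ended), so
past-trial decoding from ITI activity attaches label `i` to ITI row `i`, and
"following" attaches label `i + 1`.

Active neurons are those that fire at least one spike in every *trial*
interval. ITIs are deliberately excluded from the criterion: including them
would shrink populations well below the 4–22 neuron range the analyses are
designed for, because ITI firing is sparser.

Serialization writes times at 0.1 ms precision (half-even rounding).
Sessions whose times already lie on that grid — including everything the
generator produces — round-trip bit-exactly.

## Subspace separability

The interleaved matrix `X` (rows trial(1), ITI(1), …, trial(T), ITI(T)) is
column mean-centered and decomposed by PCA; rows are projected onto the top
`d` axes and a linear maximum-margin classifier (soft-margin SVM, fixed cost
1000, effectively hard-margin when separable) reports the *training-set*
misclassification proportion. This is intentional: the quantity of interest
is geometric separability of the recorded vectors, not out-of-sample
generalization.

Three numerical choices matter here:

- **Centering.** PCA on the centered matrix is standard practice; the
  uncentered eigendecomposition of `X'X` is available via
  `pca_axes(..., center = FALSE)` for sensitivity analyses. Rates are not
  z-scored before PCA — all columns share units (Hz).
- **Scale invariance.** Projections are rescaled to unit root-mean-square
  before the SVM fit, making the reported error exactly invariant to a
  common rescaling of all rate vectors; a soft-margin SVM with fixed cost is
  otherwise not scale-invariant.
- **Intercept recalibration.** The hinge loss penalizes margin violations
  that the misclassification count ignores, so after fitting, the decision
  threshold is recalibrated by an exact scan along the SVM's normal
  direction (only cuts between distinct projected values are considered).
  On one-dimensional projections this makes the reported error equal to the
  optimal linear-threshold error.

Degenerate inputs error out explicitly: single-class labels, fewer than two
vectors per class, or `d` above the matrix rank (detected at a relative
singular-value tolerance of 1e-10).

Section-resolved separability projects each pair of section vector sets to
`d = 2`; rows with zero section occupancy are dropped pairwise and a pair is
skipped below 3 vectors per side. Maze sections are fixed locations
(1 = start region, 5 = arm end); trials traverse 1→5 and ITIs 5→1, and
position-resolved results are reported in that temporal order.

## Decoding

The decoder is an L2-regularized logistic regression with unpenalized
intercept and inverse penalty C = 1, fit by damped Newton iterations
(backtracking line search; gradient tolerance 1e-10, at most 100
iterations). For leave-one-out decoding, features are standardized with the
*training fold's* mean and SD (zero-SD columns get SD 1), the held-out
vector is transformed with the same statistics, and ties at predicted
probability exactly 0.5 go to the positive class — the alphabetically or
numerically larger label, fixed so reruns are deterministic. Chance levels
come from 50 label shuffles (uniform permutations, seeded), refitting the
full leave-one-out loop each time; *relative accuracy* subtracts the mean of
the 50 shuffle accuracies, which absorbs label imbalance.

**Axis fits are not standardized by default.** For the decoding-axis
geometry, the full-data logistic fit runs on raw rates (a
`standardize = TRUE` switch exists). The reason is structural: when a
neuron's between-class signal dominates its variance — which is the typical
regime for ITI vectors, integrated over tens of seconds of low Poisson
noise — the per-neuron SD is itself dominated by the coding magnitude, and
back-transforming standardized weights divides it out, sending the weight
toward `1/c_i` for coding loading `c_i` and destroying the axis direction.
Fitting in the shared rate units preserves it; implanted-axis recovery in
the test suite quantifies this. Angles use
`acos` of the cosine clipped to `[-1, 1]`; zero vectors are an error.

Within-phase axis variability (the stability of a feature's axis across
cross-validation folds) is summarized as the SD over folds of the angle
between each fold's axis and the full-data axis; an all-pairs variant would
be a straightforward extension but the fold-vs-full definition is the one
implemented.

Cross-phase decoding trains on one phase's vectors and scores the other's,
either on all rows or leaving out the `i`-th trial/ITI pair; its chance
level permutes the shared per-trial labels once per repetition, applied to
both sides.

## Behavior

A session is *learning* if some trial starts three consecutive correct
trials and performance from that trial to the session end is at least 80%;
the first trial of the run is the learning trial. The criterion window
includes the three-trial run itself (`include_run = FALSE` gives the
variant starting after the run). Otherwise the session is *rule-change* if
metadata carries a rule-switch trial, and *other* with the split placed
where the increase in reward-accumulation slope is maximized, requiring at
least 5 trials on each side and breaking ties toward the earliest trial.
Slopes are fit to the cumulative reward curve by iteratively reweighted
least squares with bisquare weights (tuning constant 4.685, at most 50
iterations), falling back to ordinary least squares when the robust fit
degenerates (exact lines have zero residual scale).

A known property of the learning-trial rule, visible in the synthetic
change-point checks: with pre-change success probability 0.4, spurious
three-correct runs occur at ~6% per pre-change position and often satisfy
the 80% window when post-change performance is strong, so the detected
learning trial can precede the true change point by several trials. This is
a property of the criterion itself on noisy sequences, not of the
implementation; the acceptance suite reports the recovery rate honestly
rather than papering over it.

## Sleep reactivation

For each feature value, the mean trial (or ITI) rate vector is compared by
Spearman correlation (average ranks on ties) with the population vector of
every sleep bin. Bins tile each slow-wave-sleep interval from its start;
the trailing partial bin is dropped so all bins in a comparison have exactly
equal duration, and bins are anchored per interval rather than on a global
grid. Bins with constant rate vectors (typically all-zero) have undefined
rank correlation and are excluded, with counts reported. The statistic
`M_post − M_pre` is the difference of median correlations; being rank-based
it is invariant to any monotone transform of the feature vector. The two
distributions are also compared by a two-sample Kolmogorov–Smirnov test,
and within-epoch paired-feature differences (e.g. right-choice minus
left-choice against the same sleep epoch) serve as a control that should
center on zero. The bin-size sweep covers 0.1 s to 10 s in 0.15 s steps
(67 sizes), spanning below and above the mean trial duration. This is
*reactivation* — rank alignment of sleep activity with phase subspaces —
not sequence replay; no temporal order within bins is examined.

## The synthetic-session generator

`generate_session()` implants exactly the structure the analyses assume,
with ground truth returned alongside:

- **Rates.** Per-neuron baseline log-rates are drawn from
  N(log 5, 0.5) and passed through a softplus (≈1.8 Hz typical baseline).
  Trial and ITI mean-rate vectors sit at ±s/2 (default s = 6 Hz) along a
  random unit direction — the phase offset that makes the two subspaces
  linearly separable — plus, per feature, ±β_f (default 1 Hz) along
  per-phase unit coding axes with a controllable trial↔ITI angle α_f
  (default π/2). ITI coding uses the just-finished trial's labels. Rates
  are floored at 0.1 Hz; the default gains keep the floor rarely binding so
  the active-neuron criterion retains most of the population, matching the
  4–22 range the analyses expect.
- **Spiking** is homogeneous Poisson within each phase. Real cortical
  spike trains are over-dispersed and history-dependent; Poisson is the
  simplest process consistent with rate-vector analyses, so passing tests
  demonstrate correctness of the pipeline, not robustness to super-Poisson
  variability.
- **Behavior.** Outcomes are Bernoulli(0.4) before the configured learning
  trial and Bernoulli(0.85) from it on; the lit arm is pseudorandom; the
  chosen direction is the outcome-consistent arm under the session rule,
  flipped with a 5% lapse rate so direction and outcome labels decouple.
  Trials last 6.5 ± 0.5 s and ITIs 55.6 ± 5 s (truncated below at
  feasibility), with the ITI spread chosen as a realistic per-trial value.
- **Position** runs out and back along the two-segment maze skeleton
  (85 cm arms at 120°) at uniform speed, dwelling at the arm end for
  `outbound_delay` (default 1.14 s) before the return. Tracking noise
  defaults to 0 cm: at the ~3 cm/s synthetic return speed, realistic jitter
  would exceed the per-sample displacement and the heading-reversal
  detector's single-sample contract is a geometry property; noise is a
  config knob for robustness exploration.
- **Sleep.** Each epoch (default 1200 s, split into two slow-wave
  intervals) is tiled with 1 s segments; with probability ρ_epoch a
  segment's rate vector is a feature-specific trial mean vector under
  multiplicative lognormal noise (SD 0.3, preserving nonnegativity and the
  rank structure Spearman probes), otherwise a random permutation of the
  baseline vector. Defaults ρ_pre = 0.1, ρ_post = 0.4 implant preferential
  post-training reactivation at the 1 s granularity the default analysis
  bin uses.

What the generator does *not* emulate: place/position tuning within
sections (feature coding is constant across a phase), theta rhythms,
refractoriness, behavioral state changes within sleep, and the unknown
light-off time during the ITI (not modeled at all). Results on synthetic
sessions therefore validate the estimators and their calibration, not the
biology.

## Outbound-phase detection

Heading is estimated from centered finite differences of the 3-sample
moving-average-smoothed trajectory — 30 Hz tracking is noisy and no
estimator is canonical, so the simplest smoother is used. A sample counts
as "toward the start" when its heading makes an angle below 90° with the
vector to the start-arm origin and the displacement is nonzero (dwell
samples never qualify). The outbound start is the first sample after the
arm end opening a run of at least 400 ms toward the start. Because the
smoothed centered difference responds one to two samples away from the true
reversal, the run onset is refined against the raw per-sample displacement
(extended backward, then advanced past leading dwell samples), which makes
the detected delay accurate to one sample on noiseless trajectories. Trials
with no qualifying run return the ITI end and are flagged degenerate.

## Null constructions and calibration

Two subtleties discovered while calibrating the tests are worth recording:

- **Zero-separation null.** With the realistic 6.5 s vs 55.6 s phase
  durations, trial and ITI rate vectors differ in *variance* even when the
  implanted mean separation is zero, and a soft-margin classifier exploits
  heteroscedasticity in training error. The zero-separation null check
  therefore matches the two durations, making the phase distributions
  exchangeable so the shuffled-label comparison is exact.
- **LOO shuffle nulls are not binomial.** Leave-one-out folds share almost
  all training rows, so held-out predictions are correlated: shuffle-null
  accuracies are over-dispersed relative to a binomial with the same trial
  count (measured SD ≈ 1.3–1.5× binomial at T = 40) and slightly
  below-chance on average. The package's relative-accuracy convention —
  comparing against the mean of 50 shuffles rather than against 0.5 —
  exists precisely because 0.5 is the wrong reference; the acceptance
  script reports the observed in-band fraction for transparency.

## Problem sizes

The validation suite uses N = 12 neurons and T = 30–40 trials per synthetic
session (matching the recorded populations of 4–22 neurons and the median
of ~29 trials), 10–20 seeds for recovery medians, 100–200 seeds for rate
estimates, and 50 label shuffles throughout — sizes chosen so the full
suite and the acceptance script each run in minutes on a single core while
keeping Monte-Carlo error well inside the asserted tolerances. Implanted
angle recovery uses a high-gain, low-heterogeneity configuration
(baseline softplus(N(5, 0.3)) ≈ 5 Hz, β = 3 Hz, s = 4 Hz): axis recovery
requires coding signal well above the per-trial Poisson noise, and that
regime is the meaningful one for testing the geometry estimators.

## Known limitations

- The decoder's regularization and standardization settings are package
  conventions; other reasonable settings change absolute accuracies
  slightly (never the shuffle-relative logic).
- Section rate vectors use occupancy-normalized rates; a spike-count
  variant is a plausible alternative left as a sensitivity switch for
  future work.
- Reported separability is training-set separability by design; do not
  read it as a generalization estimate.
- The learning-trial criterion has a material false-trigger rate on noisy
  pre-change sequences (see Behavior above).
- Cohort-level tests treat sessions as exchangeable; per-rat structure is
  a grouping view, not a mixed model.
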