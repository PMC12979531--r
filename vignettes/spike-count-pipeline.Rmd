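---
title: "Spike-count mixed models and population state-space analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spike-count mixed models and population state-space analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(popspike)
```

popspike implements, as reusable and tested components, the analysis chain
of a passive-viewing electrophysiology experiment: head-fixed pigeons watch
short videos of conspecifics — and of an abstract control shape (a
"greeble") reproducing the same motion — performing courtship, eating,
flying and walking, while single units are recorded in three forebrain
regions (MVL, visual Wulst, NCL). The package covers the experimental
design (stimulus enumeration and pseudorandomized session schedules), a
count-GLMM engine, a per-unit selectivity taxonomy, population time-course
models, pseudo-simultaneous state-space trajectories, low-level stimulus
equalization, and a synthetic-data generator with planted ground truth that
every downstream stage is validated against.

## The experimental design

The stimulus set is fully determined by its factorial structure: 4
behaviors x 4 exemplar videos x 2 actors (pigeon, greeble) gives 32
visually unique behavior videos; 4 auxiliary "two pigeons, no specific
behavior" videos bring the visually unique count to 36; every unique video
exists with its natural sound on or off, for 72 videos in total. A session
presents each video 6 times (3 per monitor) — 432 trials — in a
pseudorandom order in which no behavioral category repeats more than 3
times in a row, with a 6 s inter-trial interval and a randomly chosen 10%
of trials rewarded with 2.4 s of water access.

```{r design}
stim <- build_stimulus_set(seed = 1)
stim
sched <- schedule_session(stim, seed = 2)
sched
```

Two scheduling details are resolved as follows. 10% of 432 is 43.2 trials;
the scheduler draws exactly `round(0.10 * 432) = 43` reward trials without
replacement, so the realized fraction is 9.95%. The run-length constraint
is enforced by random permutation followed by constraint repair — any trial
inside an over-long category run is swapped with a random position where
neither side violates the constraint — bounded by a retry budget so an
infeasible request (e.g. a single-category set) fails with an explicit
scheduling error rather than looping.

Only trials shown on the monitor contralateral to a neuron's implanted
hemisphere enter analysis (near-complete optic decussation), i.e. 3 of the
6 presentations per video — 3 sound-on and 3 sound-off presentations of
each visually unique video; a flag on the simulator keeps all trials
instead.

## The generative model of the synthetic data

Spike counts are generated per 200 ms bin from an NB2 negative binomial
with log link:

$$\log \mu = \beta_0 + u_{trial} + \mathbb{1}[\text{video}]\,\bigl(
\Delta_{a,b} + g\,\phi_{bin} + s\,\mathbb{1}[\text{sound on}]\bigr),
\qquad y \sim \mathrm{NB2}(\mu, \theta),$$

with `u_trial ~ N(0, sigma_trial^2)` drawn per neuron and trial,
`Delta_{a,b}` the neuron's log-rate increment for actor `a` performing
behavior `b`, `g` an event gain applied with weight `phi` (the fraction of
the bin overlapping a stimulus event window), and `s` a sound effect for
sound-on presentations. Each trial contributes the middle 2 s of its
baseline (10 bins) plus the full video presentation, with the last partial
200 ms bin dropped; bins are 0-based, left-aligned, half-open.

Choices the recorded data could not pin down, fixed once:

* **Baseline log-rates** across neurons are Normal(log 2, 0.7^2) per
  200 ms bin (2 counts / 200 ms = 10 spikes/s), spanning near-silent units
  so that zero-heavy fits are exercised. This range is a plausible stand-in
  for forebrain visual neurons, not a reproduction of the recorded
  populations, whose rate distributions are unknown.
* **Dispersion** is drawn log-normally around `theta = 2` (marked
  overdispersion; smaller theta means more), and `sigma_trial = 0.3` by
  default.
* **Event windows** — the analogues of bowing, wing-flapping and
  head-bobbing moments — are 1 to 3 non-overlapping windows of 200–600 ms
  per video, shared between a pigeon video and its greeble control.
* **Event responses ride on a neuron's tuning**: the event gain applies in
  the conditions whose effect-map entry is excitatory (all conditions for
  neurons with an empty map, which lets tests plant purely event-locked
  responders), restricted to the neuron's `event_actors`. Without this
  restriction every unit would look broadly visually modulated, since
  every video contains event windows.

Planted labels mirror the selectivity taxonomy: actor-selective units get
one actor's increment across all behaviors (a mixed-sign variant is
excited by one actor and inhibited by the other), behavior-selective units
one behavior under both actors, actor-and-behavior-selective units a
single cell, visually selective units every cell, and "other" units either
two behaviors or the two-pigeon videos. What the generator does *not*
emulate: spike waveforms, adaptation trends over a session, eye or body
movements, correlated noise between simultaneously recorded units, and
kinematics-driven rate fluctuations inside a video beyond the discrete
event windows. Passing recovery tests therefore demonstrates the
*analysis* is correct and powered under the stated generative model, not
that the biological conclusions transfer.

## The count-GLMM engine

All models are Poisson or NB2 log-link regressions with Gaussian random
intercepts, estimated by a Laplace approximation. For variance parameters
`(log theta, log sigma_g)` the fixed effects and random-effect modes are
found jointly by a penalized Newton iteration (score tolerance 1e-8); the
Laplace log-likelihood at that mode,

$$\ell_{L} = \ell(y \mid \hat\eta) - \tfrac{1}{2}\hat u^\top \Lambda^{-1}
\hat u - \tfrac{1}{2}\log\det\Lambda - \tfrac{1}{2}\log\det(Z^\top W Z +
\Lambda^{-1}),$$

is then maximized over the variance parameters alone with `nlminb`. This
profiled scheme was chosen over a quasi-Newton search of the full
parameter vector because the population time-course model carries ~50
fixed effects, for which finite-difference gradients are prohibitively
expensive, while the joint-mode profile (the scheme popularized by lme4's
fastest mode) solves one sparse system per Newton step regardless of the
fixed-effect count. Accuracy is checked in the test suite against three
independent oracles: `stats::glm` (exact agreement when the variance is
pinned to zero, where the Laplace likelihood collapses to the exact GLM
likelihood), `MASS::glm.nb` (no-random-effect NB fits), and `glmmTMB` —
the implementation a practitioner would use directly — on mixed fits.

Numerical details worth knowing:

* NB2 parameterization: variance `mu + mu^2/theta`, estimated on
  `log theta`; linear predictors are clamped at +/-30 to keep the
  exponential finite during early iterations.
* Convergence failures are reported through `converged = FALSE`, never an
  error; a failed first outer pass is restarted once from its solution
  (flat variance directions commonly trigger a spurious "false
  convergence").
* Singular fits: an estimated random-intercept SD below 1e-4 flags
  `singular = TRUE`; because the profile is flat near zero the optimizer
  can stall just above the threshold, so any SD below 0.01 that can be
  moved to the boundary at a likelihood cost under 1e-4 is snapped there.
  Singular per-unit fits are excluded from classification.
* Treatment contrasts with explicit reference levels; rank-deficient
  designs raise an error naming the aliased columns.
* `AIC = 2k - 2 logL` with `k` counting fixed effects, the NB dispersion
  when estimated, and the estimated variance components.

Inference helpers follow the conventions used throughout: Wald z tests per
coefficient; likelihood-ratio / AIC comparison of nested fits (used for
the Poisson-vs-NB decision); a simulation-based zero-inflation diagnostic
(observed zeros over the mean of model-simulated zeros, two-sided
empirical p); estimated marginal means as equal-weight averages over the
fixed-effect factor grid with covariance propagated from the coefficient
covariance; Holm step-down adjustment; and 2x2 proportion tests that use
the chi-squared statistic without continuity correction when all expected
counts are at least 5 and Fisher's exact test otherwise. The
no-continuity-correction convention is the simplest documented choice; the
original statistics could not be reconstructed under either convention.

## Per-unit selectivity

The per-unit model (`fit_m1`) uses a single combined condition factor —
level "baseline" for inter-trial bins, one level per actor x behavior cell
(the two-pigeon videos are a fifth behavior level) — plus one sound-on
indicator per actor and a trial random intercept:

```
count ~ condition + pigeonSound + greebleSound + (1 | trialNumber)
```

With the pooled baseline as reference level, every cell coefficient *is*
the baseline-vs-condition contrast, so the marginal-means machinery and
the coefficient table coincide for this design. The baseline is pooled
across trials rather than anchored to one specific video's baseline: the
alternative reading (the first courtship video's baseline as intercept)
differs only in the labeling of the reference cell for a balanced design
and makes the intercept estimate noisier; both preparations are a
one-line change in the condition coding.

Classification applies Holm (alpha = 0.05) across the nine cell contrasts
within each unit, then a deterministic rule on the significant pattern:
exclusively one actor across >= 2 behaviors (or opposite uniform signs
between the actors) gives actor-selective; exactly one behavior under both
actors gives behavior-selective; exactly one significant cell gives
actor-and-behavior-selective; all behaviors under both actors with a
common sign gives visually selective; multi-behavior and two-pigeon-
dominant patterns fall under "other"; anything else is non-selective. The
two sound coefficients form their own Holm family for the sound-modulated
flag. Region summaries report percentages over task-modulated units, and
between-region comparisons run the pairwise proportion tests with Holm
adjustment across the three region pairs.

```{r selectivity, eval = FALSE}
pop <- make_population(n_neurons_per_region = 30, seed = 1)
rec <- simulate_spike_counts(sched, pop, stim, seed = 2)
labels <- classify_population(rec, alpha = 0.05)
region_summary(labels)
compare_regions(labels, "sound_modulated")
```

## Population time-course

For the subpopulation of pigeon-selective units, the time-course model
(`fit_m2`) asks which 200 ms bins of a given video depart from baseline
and whether the departure differs between the actors:

```
count ~ cell + (1 | trialNumber:bin) + (1 | subjectID:neuronID)
```

where `cell` again has the pooled baseline as reference plus one level per
actor x bin. Baseline bins enter as data rows of the reference level, so
"differs from baseline" is a within-model Wald contrast, Holm-adjusted
across the bins of the video; the pigeon-vs-greeble contrast is then
evaluated only in the flagged bins, with its own Holm family per video.
The adjustment procedure within each family is Holm throughout — the
package's single multiple-comparison convention. The subject:neuron
intercept absorbs per-unit baseline differences; a single-subject input
degrades gracefully (warning, neuron-level intercept). Detection uses the
pigeon marginals by default while both actors are fit jointly.

## State-space trajectories

The population analysis re-bins each trial on a 200 ms window advanced in
40 ms steps (counts attributed uniformly within their base bin), averages
across the trials of each condition (video x actor, the two sound versions
pooled, two-pigeon videos excluded), smooths with a Gaussian kernel, and
z-scores each neuron against the mean and SD of its baseline bins. "200 ms
Gaussian kernel" is read plainly as SD = 200 ms truncated at +/-3 SD
(`kernel_kind = "fwhm"` gives the narrower reading); a 600 ms baseline
prefix is retained per condition. The per-neuron series are concatenated
into a pseudo-simultaneous neurons x (condition x time) matrix,
row-centered (on top of the baseline z-scoring, making the
eigendecomposition well-defined), and decomposed by SVD; the top three
components' projections form one trajectory per condition, and the
pigeon-vs-greeble divergence of a video is the per-timepoint Euclidean
distance between its two trajectories. Component signs are fixed
(largest-magnitude loading positive) so results are reproducible;
distances are invariant to any rotation of the component space. Neurons
with baseline SD below 1e-6 are excluded and listed in the result.

```{r statespace, eval = FALSE}
ssa <- state_space_analysis(rec[rec$region == "MVL", ])
ssa$pca
head(ssa$distances$courtship1)
ssa$top2$courtship1   # two largest divergences, ties to the earliest time
```

## The pipeline

`run_pipeline(analysis_config(...))` executes simulate → equalize →
classify → compare → timecourse → statespace with one YAML-configurable
parameter set (alpha = 0.05 and the timing constants above as defaults),
persists every intermediate artifact (CSV/JSON/PNG) under the output
directory, records per-stage status, timing, seeds and artifact checksums
in `report.json`, and returns a partial report when a stage fails rather
than erroring. Reruns with the same configuration are bit-identical for
the deterministic stages. The exported functions are the package's
interface; the pipeline is callable from `Rscript -e` one-liners where a
shell entry point is wanted.

## Stimulus equalization

Low-level correction operates in HSV space on the value channel only.
Luminance: the mean value over all foreground (subject) pixels and all
background pixels of the pigeon stacks is imposed on the control stacks by
an additive shift per region (mean-matching only — the smallest
transformation consistent with matching average luminance; matching the
SD as well would be a different, stronger normalization). Values are
clipped to [0, 1] afterwards, which can pull the realized mean slightly
off-target for near-saturated frames; absent clipping the match is exact
and idempotent. Spatial frequency: each frame's FFT amplitude is rescaled
per radial annulus (integer radii; normalized-radius annuli for non-square
frames) to the grand-average rotational profile, leaving phases — the
orientation content — and each frame's DC component untouched; SF-matched
values are deliberately not clipped so the profile equality is exact, and
clipping happens only on PNG output. Frame-by-frame dissimilarity between
a video and its control is the Pearson correlation of the value channels,
with zero-variance frames reported as missing.

## Simulation sizes and what the tests show

The test suite validates each operation against independent oracles
(closed forms, brute-force loops, `glm`/`glm.nb`/`glmmTMB`, covariance
eigendecompositions) and runs recovery studies at these sizes: 200
generative replicates for coefficient coverage, 1000 null fits for the
Wald size, 40 planted units plus 20 null units for classification
recovery (effect size 1.0 log-units, 3 repetitions per video per sound
condition, baseline 2 counts/bin — the reference simulation), 12 null
video fits for the time-course family-wise error, and a 50-neuron
population with 20% pigeon-selective event responders (gain 1.0) for the
state-space divergence localization. `scripts/acceptance.R` re-runs the
same computations from scratch against the installed package and writes
the resulting quantities as JSON. These sizes are the package's chosen
trade-off between statistical resolution and a test suite that runs in
minutes.

Known limitations: random slopes, zero-inflated mixture families and
Bayesian estimation are out of scope; the formula interface covers
factors, interactions and random intercepts only; Laplace (not adaptive
quadrature) is the single integration scheme; and the paper-reported
region-specific unit counts and variance-explained values depend on the
recorded dataset and are deliberately not targets of the synthetic
validation.
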