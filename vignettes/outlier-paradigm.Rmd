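---
title: "The outlier paradigm: task model, encoding metric, and directional Bayes factors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The outlier paradigm: task model, encoding metric, and directional Bayes factors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(outlierlift)
```

## The paradigm

Participants anticipate the weights of cylindrical objects by stretching a
virtual spring before the object is released. Four objects form a
constant-density *family* — height predicts weight linearly (300, 400, 600,
700 g at 5, 6, 8, 9 cm) — while the middle-height object (7 cm) is an
*outlier* weighing 800 g, more than the largest family member. After a
family-only pre-training phase (40 trials), the outlier is interleaved one
trial per block. The striking phenomenon is that many participants never
learn the outlier's weight: their anticipatory responses stay pinned to the
family's size–weight line. The *strength of categorical encoding* quantifies
this, and twelve conditions manipulate factors (color similarity, family
cardinality, outlier frequency, family structure, feedback noise, time
pressure, object persistence, concurrent introduction) that might change it.

This vignette documents how the package models each stage, the parameters
that matter, and the design choices made where the published description
left the design open.

## Trial physics

At release, the object and spring form a damped harmonic oscillator:
`m x'' + c x' + k x = 0` for the displacement `x` of the spring length from
its equilibrium stretch `L = m g / k`, with initial displacement equal to
the participant's spring-length error `e` and zero initial velocity. We
interpret the task's `k = 100` and `c = 3` in SI units (N/m, N·s/m) with
masses in kg; all reported lengths are cm. This convention puts the
equilibrium lengths of the 300–800 g objects at 2.94–7.85 cm, commensurate
with the 2.5 cm and 6 cm scales in the score and penalty functions, which is
why we adopt it (the published parameters are unitless; `physics_params()`
accepts others). The trajectory is evaluated in closed form — underdamped
branch at task parameters, with critically/overdamped branches implemented
for completeness — and the test suite verifies it against a fourth-order
numerical integration to 10⁻⁶ cm.

Score and release-phase duration follow the task's truncated quadratic
losses on the error `e` in cm: `y = 100 (1 - min((|e|/2.5)^2, 1))`, rounded
half-away-from-zero to an integer, and `t = 1 + 5 min((|e|/6)^2, 1)`
seconds. In the added-noise condition the presented mass is perturbed
uniformly on ±150 g before feedback is computed; in the speeded condition
responses after trial 12 exceeding 2.25 s cost 100 points and a timeout of
6 s growing by 2 s per violation.

## Schedules and analysis windows

Each block presents every family object once plus the outlier
`outlier_per_block` times after its introduction. Randomization is rejection
sampling of within-block permutations until the boundary constraint holds:
the last object of a block never opens the next one, so no object repeats on
consecutive trials — except that the frequent-outlier condition (three
outlier presentations per block, 103 trials: 10 pre-blocks of 4 + 9 blocks
of 7, the only integer decomposition consistent with the 3:4 ratio) permits
outlier–outlier repeats. Seeds are recorded in the schedule so every
schedule is reproducible.

Analysis windows are defined block-wise:

* *post window* (family regression and outlier mean): every block after the
  first outlier-containing block — blocks 12–22 in the standard design,
  blocks 11–20 in the concurrent conditions (where the outlier is present
  throughout, so "after the tenth block" is the convention). For conditions
  with one outlier per block this coincides with "all outlier trials after
  the very first presentation"; in the frequent-outlier condition we exclude
  the whole introduction block rather than only the first outlier trial, so
  that the family window remains a set of whole blocks.
* *pre window* (pre-introduction regression): the family blocks covering
  trials 21–40.
* *participant window* (exclusion rule): block 11 onward, generalized to
  "from the outlier's introduction onward" for the small-family condition,
  whose pre-phase spans 20 blocks of 2.

The small-family condition's post-introduction structure is not fully
specified by the published design; we fix 20 pre-blocks of two trials
(honoring the 40 family-only trials) followed by 20 blocks of three, which
keeps the number of outlier exposures comparable to the standard design.
This is a package convention, not an empirical fact.

## The generative model of participants

The published study fits no behavioral model; ours is invented plumbing
whose only purpose is to give the analysis stack data with the structure it
assumes, with a *known* ground truth to recover. A participant holds an
internal line mapping height to spring length (the category
representation). It starts flat at the equilibrium length of the mean family
mass, and its error relative to the true family line decays by
`learning_rate` (default 0.5 per family encounter — acquisition within a few
blocks, as observed empirically). Because the initial line crosses the true
line at the mean family height, which is also the outlier's height in the
symmetric designs, the category prediction at the outlier height is correct
from the start; the transient lives in the slope.

Responses:

* family object: the internal line's value plus Gaussian motor noise
  (`motor_noise_sd`, default 0.4 cm — chosen so that per-participant metric
  estimates have a few points of spread, enough to make recovery
  non-trivial; real per-participant noise magnitudes are unpublished);
* outlier: the category prediction at the outlier's height plus
  `(1 - latent_ce/100)` times the true family–outlier separation, plus
  noise. At `latent_ce = 100` the response sits on the category line; at 0
  it reaches the outlier's true equilibrium length.

Each outlier encounter updates the category line by a delta rule on the raw
regressors (1, h): the feedback error shifts the intercept by
`gain * err` and the slope by `gain * err * h_out` (default gain 0.0005).
This reproduces the empirically observed signature that repeated outlier
errors pull the category line *up and steeper* — measurable with
`slope_shift()` — while leaving the latent strength recoverable: the
outlier response is defined relative to the *drifted* line, so drift cancels
between the outlier mean and the family regression.

With zero motor noise, zero update gain, and complete acquisition
(`learning_rate = 1`), the full pipeline — simulation, exclusion,
regression, metric — returns the latent strength exactly; the tests assert
this to 10⁻⁹. At the default learning rate the acquisition transient decays
below 10⁻¹² by the analysis window, so the identity is near-exact. At
default noise, cohort means of 20 participants recover latent strengths
across 0–100 to within ±5 points, and per-participant estimates
rank-correlate with heterogeneous latents above 0.9.

What the model does *not* emulate: explicit strategies, trial-by-trial
error-driven learning of individual objects, color perception (color
schemes are metadata only), or heavy-tailed response distributions. Passing
recovery tests therefore demonstrates that the pipeline measures what it
claims on data satisfying its assumptions — not that real data satisfy
them.

## Exclusion rules and the metric

Trial exclusion flags family-object responses beyond 4 scaled MADs
(constant 1.4826, the normal-consistency convention) of their
participant × object cell median, in a single pass, never touching outlier
trials (learning can move them legitimately). Cells with fewer than three
trials are exempt — the MAD is degenerate there — and reported with a
warning. Note a corollary the tests exercise: on noise-free data the cell
MAD is 0 and any deviation would be flagged, so noiseless fixtures disable
trial exclusion. Participant exclusion then flags participants whose mean
family response over the participant window is beyond 5 scaled MADs of the
cohort median; on synthetic cohorts it singles out injected max-stretch and
min-stretch low-effort responders and nobody in homogeneous cohorts. Trial
exclusion precedes participant exclusion, matching the published order.

The metric regresses family responses on height over the post window
(ordinary least squares) and computes

`CE = 100 (1 - (mean outlier response - regression prediction at h_out) /
(true outlier length - true family prediction at h_out))`.

The true family prediction is the least-squares line through the family
objects' equilibrium lengths — exact for linear families, the best linear
summary for the sigmoidal one (whose true denominator is unchanged because
the design is symmetric). In the symmetric balanced designs the regression
prediction at the outlier height equals the plain mean of family responses
(`family_mean_equivalence()` verifies the identity to 10⁻⁹ and detects when
unbalanced exclusion breaks it).

## Directional Bayes factors

Inference is on summary statistics. For a condition vs. reference
comparison of per-participant encoding strengths, `welch_summary()` returns
the mean difference, its unequal-variance standard error
`sqrt(s1²/n1 + s2²/n2)`, and Welch–Satterthwaite degrees of freedom. The
likelihood of an effect δ is the scaled, shifted Student-t
`dt((m - δ)/se, df)/se`; the null is the point δ = 0; the alternative is a
half-normal over δ, truncated toward the hypothesized direction, with scale
chosen so that 99% of its mass lies inside the theoretically admissible
range: `σ = range / qnorm(0.995)`, where the range is the reference mean
(decrease) or 100 minus it (increase). From the two reference conditions'
means of 89.1% and 59.5% this rule yields the published scales 34.58, 15.71,
and 4.24 to within rounding of the reference means.

The Bayes factor B₁₀ is the prior-averaged likelihood over the half-line
divided by the null likelihood, computed by adaptive quadrature at relative
tolerance 10⁻⁸ on the interval (0, 14σ) — prior mass beyond 14 scales is
below 10⁻⁴⁰, and a finite interval keeps the quadrature reliable when the
prior is much narrower than the likelihood. The engine's limits
(σ → 0 ⇒ B₁₀ → 1), sign symmetry, monotonicity in the effect magnitude, and
agreement with a Monte-Carlo prior-averaging oracle are all under test, and
all thirteen published comparisons are reproduced from their printed
summary statistics within 1% (or to the two-decimal printed precision for
the two smallest values, where printing granularity exceeds 1%).

Combined comparisons center each condition–reference pair on its reference
mean, pool the centered groups, and set the prior scale from the mean
variance of the separate alternatives, `sqrt((σ1² + σ2²)/2)` — 11.51 from
(4.24, 15.71). Evidence labels follow the conventional bands (anecdotal to
extreme, with reciprocals for the null).

## Power analysis

`estimate_power()` simulates Bayesian experiments: two groups of n
participant-level outcomes drawn from normal distributions, Welch summary,
directional Bayes factor, and a decision at B₁₀ > 3 (alternative-true
scenarios) or B₁₀ < 1/3 (null-true scenarios). The pilot means behind the
original design (84% vs. 47%) are known but the pilot SDs are not, so the
scenario requires SDs as inputs rather than defaulting to guesses; the
properties under test are structural — power increases with n and with the
group separation, the false-evidence rate under a true null stays below
0.1, and the Monte-Carlo standard error follows `sqrt(p(1-p)/reps)`. The
test suite uses 150–1000 replicates; `power_scenario()` defaults to 10,000
for design use.

## Numerical choices and limitations

* Score rounding is half-away-from-zero ("nearest integer" convention).
* The scaled-MAD constant is fixed at 1.4826; thresholds 4 (trials) and
  5 (participants) are the published conservative choices.
* Quadrature failure raises an error rather than returning a value;
  regression degeneracies (no family trials in a window, a single height)
  are errors naming the window.
* Schedules for degenerate designs (fewer than two family objects) are
  rejected: the no-repeat constraint would be unsatisfiable.
* Simulation sizes in the tests (20-participant cohorts, 150–1000 power
  replicates, 1000 schedule seeds per condition) were chosen as the
  smallest sizes at which each property is sharply testable.
* The package does not ingest the original study's deposited raw data; the
  empirical condition means are inputs (summary statistics), not
  reproduction targets. The synthetic generative model is the package's
  own; conclusions about real data require the real data.
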