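---
title: "Playback-vigilance analysis: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Playback-vigilance analysis: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(vigilr)
```

This vignette is the package's account of its science: the response
statistic, the hierarchical model, the matched pseudo-control design, the
synthetic-data generator, and the choices made where the design was
genuinely open.

## The experimental setting

A playback experiment presents a recorded sound to a free-ranging animal
and measures its behavioral response to the acoustic cue alone, with the
loudspeaker concealed. The design this package serves is a multisite,
within-subject one: each focal animal hears a natural control stimulus
(dove coos) and one anthropogenic stimulus (drone, vehicle, or people
talking) per session, sites differ in chronic human exposure
(`low_exposure` / `moderate_exposure` / `high_exposure`), and each
stimulus type is represented by 8 rotated exemplars to avoid
pseudoreplicating a single recording. Vigilance — interrupting feeding or
rumination to monitor the surroundings — is the focal response.

Trials are admissible when the animal stood 30–100 m from the speaker
(closer risks startle via constructive interference; farther, attenuation
and masking) and wind stayed below 25 km/h. External-disturbance rules:
a look toward a disturbance of at most 5 s is ordinary scanning and is
retained; at least 10 s, or moving away, terminates and excludes the
trial. The two anchors leave 5–10 s undefined; `apply_trial_filters()`
retains such trials with an explicit `flag_disturbance` column rather
than silently discarding them, so the choice is auditable downstream.

## From video coding to the response variable

Coded behavior bouts are converted to one-zero samples on a 1-s grid over
a 180-s window from playback onset (120 s playback + 60 s post). Second
`i` is the half-open interval `[i, i + 1)`; a bout registers in a second
only when it overlaps with positive measure, so a zero-length touch at a
boundary does not count. This makes the sampling deterministic and
idempotent, and the convention is enforced in the tests by a brute-force
overlap oracle.

Behaviors carry intensities 0–12 from the packaged ethogram
(`inst/extdata/ethogram.csv`, editable): 0 is continued
feeding/rumination, 1–5 minimal changes (ear movements, head turns while
still chewing), 6–9 cessation of natural behavior with sustained
attention, and 10–12 relocation up to flight. `categorize()` groups
scores into A (0–5), B (6–9), C (10–12).

The primary response, the *time-weighted reaction score*, emphasizes
acute, stimulus-evoked responses: among the first three distinct
behaviors with intensity ≥ 1 (distinct *codes*, so one repeated behavior
cannot fill all three slots), each is weighted by a decreasing logistic
function of its latency,

$$ w(t) = \frac{1}{1 + e^{k (t - t_0)}}, \qquad t_0 = 12\ \mathrm{s}, $$

and the maximum weighted score is kept. The steepness default
`k = log(19) / 3 ≈ 0.98` per second is the tightest smooth logistic
consistent with "full weight within about 9 s, minimal weight after about
15 s": it gives exactly `w(9) = 0.95` and `w(15) = 0.05`, with
`w(3) > 0.999` and `w(20) < 0.001`, so a head-up at 3 s keeps essentially
full intensity while the same behavior at 20 s is annulled. Both `t0` and
`k` are exposed in `weight_params()` so a different calibration can be
substituted exactly. Latencies are reported at whole-second resolution,
consistent with the one-zero grid.

Two further features are derived per trial: latency to first response
(first second with any intensity ≥ 1 behavior; intensity-0 maintenance
behavior never counts) and reaction duration. Duration is not uniquely
defined by a bout stream; the package counts total seconds with any
behavior of intensity ≥ 6 active (cessation of natural behavior — the B/C
range), with the threshold configurable, and treats duration throughout
as a secondary, descriptive response: it is far more variable across
individuals than the time-weighted intensity and does not support sharp
stimulus comparisons.

## The hierarchical model

The response is modeled as Gaussian:

$$ y = X\beta + Z_g u_g + Z_e u_e + Z_x u_x + \varepsilon, $$

with *crossed* (non-nested) random intercepts for the focal individual
(`giraffe_id`, repeated measures), the playback event (`playback_event_id`,
shared context when several animals respond to the same video), and the
sound exemplar (`exemplar_id`, reuse of the same file across trials).
Fixed effects are sound type × site (treatment coding; dove and the
low-exposure site as default references), the 4-level sex-age factor,
and standardized covariates: group size, wind speed, date, and a degree-2
polynomial in speaker distance (sound attenuation is non-linear in
distance). Standardization uses the population-SD convention (divide by
n); either convention is defensible and the choice is pinned and
symmetric across covariates. The polynomial uses raw `(z, z²)` rather
than orthogonal polynomials: all downstream quantities are contrasts of
fitted values at fixed covariate settings, which are invariant to that
choice. Date is standardized *within* site × sound strata so temporal
trends are expressed relative to when that condition was sampled;
degenerate (singleton or constant) strata standardize to 0 with a
warning. The 0–12 score is treated as continuous; an ordinal model is a
possible alternative but is not implemented.

Priors are weakly informative and internally rescaled by the response:
fixed effects `Normal(0, (2.5 sd(y) / sd(x_j))²)`, intercept
`Normal(mean(y), (2.5 sd(y))²)`, and every variance-component SD
(including residual) `half-Student-t(3)` scaled by `sd(y)`. All scales
are exposed in `model_spec()`.

### Sampler

`fit_lmm()` uses a marginal blocked sampler written for exactly this
model class. The variance-component SDs move by adaptive random-walk
Metropolis under their *marginal* posterior, with all coefficients
(fixed effects and every random intercept) integrated out analytically
through the normal–normal conjugacy; the coefficients are then drawn
jointly from their exact multivariate-normal conditional. Integrating the
coefficients out of the variance update matters: a vanilla
centered-parameterization Gibbs sampler mixes very slowly here because
the playback-event SD is weakly identified against the residual SD (most
events contribute only 1–3 observations). Numerical choices:

- The large playback-event block has mutually orthogonal indicator
  columns, so it is eliminated by a Schur complement and each likelihood
  evaluation factors only a small matrix (fixed effects + the smaller
  factors), keeping a full fit to a few hundred trials in the tens of
  seconds.
- The random walk runs on the natural SD scale folded at zero rather
  than on log-SD: a weakly identified SD has substantial mass near zero,
  which on the log scale becomes an infinite flat tail that traps the
  walker, while on the natural scale it is a finite stretch crossed
  quickly.
- The proposal covariance adapts during warmup only (history covariance
  plus a Robbins–Monro global scale targeting ~30% acceptance), and the
  initial scale comes from the OLS residual SD so near-noiseless data do
  not start the walker orders of magnitude off.
- Chains are seeded `seed + chain`; given `model_spec()` the fit is
  bit-reproducible.

Convergence is checked with split-Rhat on every reported parameter
(default threshold 1.01, one automatic retry with doubled iterations,
then a hard error carrying the diagnostics); effective sample size uses
the chain-averaged autocorrelation sequence with Geyer's initial
positive-sequence truncation, and `MCSE = sd / sqrt(ESS)`. SD components
that have collapsed below `10⁻³ sd(y)` are exempt from the Rhat check:
their chains sit at numerically different near-zero values and Rhat is
meaningless there. The test suite cross-checks the sampler against
`lme4::lmer` REML point estimates and the ESS estimator against
`coda::effectiveSize`.

### Contrasts and partial dependence

All site-specific quantities derive from the single interaction model,
never from per-site refits. A contrast such as "drone − dove at the
low-exposure site" is computed draw-by-draw as the difference of linear
predictors with standardized covariates at 0 (their sample means) and the
sex-age factor averaged with *equal* weights over its four levels — the
reference-grid convention, describing an average animal of unspecified
demography; observed-frequency weighting is the alternative and can be
obtained by fixing levels via `partial_dependence()`'s grid. μ_diff
denotes the posterior mean of a contrast, as distinct from a regression
coefficient β. Support is declared when the 95% credible interval
excludes zero; no p-values are reported. Because contrasts are linear
functionals of the same draws, antisymmetry, transitivity, and invariance
to the treatment-coding references hold by construction and are asserted
draw-by-draw in the tests.

## Matched pseudo-control analysis

Dove controls are not uniformly available across conditions, so a
complementary analysis pairs each anthropogenic trial with its most
similar same-individual dove trial (`match_controls()`). Similarity is a
weighted Mahalanobis distance over standardized wind, speaker distance,
group size, and date; the covariance of the metric is estimated from the
pooled standardized covariate matrix with a `1e-8` ridge for numerical
positive-definiteness. Open parameters were fixed as follows:

- **Date weight 3.0** — date should dominate ("temporally close trials
  first") but not erase the other covariates; 3× its standardized scale
  achieves that, and the weight multiplies the date *difference* after
  covariance estimation, since rescaling a column before estimating the
  covariance would be absorbed by the metric and have no effect. The
  weight is configurable, and as it grows matching provably degenerates
  to nearest-date matching (tested).
- **Matching with replacement** by default: a dove trial may anchor
  several tests, which keeps every admissible test trial in the analysis;
  greedy without-replacement matching is available behind a flag.
- **Ties** break by smaller absolute date difference, then lexicographic
  trial id — matching is fully deterministic.
- **Sex-age** is not a distance term: within-individual matching makes it
  constant within every candidate set. If within-individual matching is
  disabled, sex-age becomes an exact-match constraint instead.
- Test trials with no admissible control are reported unmatched and
  excluded, never force-matched.

The difference scores (test minus control reaction intensity) are modeled
with a mean per populated sound × site cell (cell-means coding), additive
sex-age effects, and a random intercept per individual, using the same
sampler. The reported effect per cell is the predicted mean difference
marginalized equally over sex-age; empty cells are reported absent, not
zero. An exhaustive-search oracle in the test suite verifies the matcher,
including tie-breaks, on hundreds of simulated instances.

## The synthetic-data generator

`simulate_trials()` generates the study the models assume: 3 sites with
19/10/4 individuals (low/moderate/high exposure), 7 sessions per
individual, each session presenting a dove and one random anthropogenic
stimulus (in random order) to a randomly formed group of 1–3 co-observed
individuals who share the playback-event effect — reproducing the
clustering that motivates the event random intercept. Covariates are
drawn on their admissible supports: distance Uniform(30, 100) m, wind
Uniform(0, 25) km/h, group size 1–15, dates across an 11-month window.
The response is the fixed linear predictor plus the three random
intercepts plus Gaussian noise, clamped to [0, 12].

Ground-truth defaults encode the habituation gradient that motivates the
design: anthropogenic effects of +4.3 / +5.3 / +1.9 (drone / vehicle /
talking) at the low-exposure site, about +1 at the moderate site, and
about +0.3 at the high-exposure site; distance is the only strong
covariate (−0.8 z⁻¹ with +0.15 curvature), group size and wind are near
null (−0.17, +0.05), and sex-age effects are zero. The baseline (dove)
response is 3 with SDs 0.5 / 0.4 / 0.3 (individual / event / exemplar)
and residual SD 1.5 — values chosen once so that variance components are
realistic relative to the effect sizes and the [0, 12] clamping affects
under 5% of responses (the realized fraction is recorded in the returned
ground truth). `null_sim_config()` zeroes all sound effects for
calibration checks.

`simulate_event_stream()` goes one level deeper and emits behavior bouts
realizing a latent intensity: the score-carrying behavior has intensity
`floor(latent + 0.5)` with onset inside the full-weight region (< 3 s),
plus optional strictly-lower-intensity later behaviors (which provably
cannot overtake the maximum) and a maintenance behavior. Running the full
ingest-and-scoring pipeline on these streams recovers the latent
intensity to within half a score point, which is the round-trip property
the acceptance checks assert on 500 random trials.

What the generator does *not* emulate: ordinal discreteness of real
scores, habituation within a session (order effects are generated as
null), observer error and missed bouts, non-uniform covariate
distributions, and unequal dove availability across sites (every
individual always has same-individual controls, so the unmatched path is
exercised only by dedicated unit tests). Passing the simulation suite
therefore validates the machinery, not the field realism of any
particular dataset.

## Validation problem sizes

The package's replicate study fits the full model on 20 datasets at the
field design's size (~460 trials, 33 individuals, 32 exemplars) with the
default effect pattern and 20 more under the null, using 2 chains × 1000
iterations per fit and a relaxed stability threshold (Rhat ≤ 1.05) —
short-chain settings appropriate when only aggregate coverage of many
intervals is consumed. Across replicates × 9 within-site effects, 95%
credible intervals cover the generating values at ≥ 85% and contain zero
under the null at ≥ 90%; single production fits use the defaults
(4 chains × 2000, Rhat ≤ 1.01). One acceptance check refits the original
field study's published dataset and compares against its printed
estimates; that export is not redistributable with the package, so the
check reports the data as absent unless the user supplies the CSVs under
`inst/extdata/field_study/` (`trials.csv` plus `features.csv` or
`events.csv`) and reinstalls.

## Known limitations

- Gaussian likelihood on a bounded 0–12 score: adequate for the bulk of
  the scale, but boundary cells (near-universal no-reaction under a
  habituated condition) attenuate estimated effects slightly, as the
  worked example shows.
- The matched analysis assumes the matching covariates capture the
  relevant context; unmeasured confounding between test and control
  occasions is reduced, not removed, by Mahalanobis matching.
- The event-stream generator writes clean bouts; it cannot surface
  coding-software idiosyncrasies (overlapping duplicate annotations,
  out-of-window exports), which the ingest validators handle but the
  round-trip tests do not stress.
- Duration's operationalization (total vigilant seconds at intensity ≥ 6)
  is one defensible reading among several; first-bout length is the main
  alternative and both are computable from the one-zero matrix.
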