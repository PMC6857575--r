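---
title: "Methods: ring-network TAE prediction and psychometric analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ring-network TAE prediction and psychometric analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ringtae)
```

This vignette documents the scientific and numerical choices behind
`ringtae`: the network model and its assumptions, the perceptual
readout, the rate-suppression extension, the psychometric analysis
chain, and what the synthetic observer does and does not emulate.

## The recurrent ring model

The network is a bank of `n_units` rate-based neurons, one passive
voltage compartment each, whose preferred orientations evenly tile
`[0, 180)` degrees (`theta_i = i * 180 / n`, no duplicated endpoint —
orientation is periodic with period 180°, which is also why every von
Mises profile in the package uses doubled angles). Unit `theta` obeys

$$\tau \frac{dV^\theta}{dt} + V^\theta = V^\theta_{lgn} + V^\theta_{cortex},$$

with a weakly tuned feedforward drive
$V^\theta_{lgn} = c\,J_{lgn}\,f(\omega\,|\,\theta,\kappa_{lgn})$ and a
Mexican-hat recurrent input built from the difference of a narrow
excitatory and a broad inhibitory von Mises profile. Firing is the
rectified-linear readout $R = \alpha\,\max(V, 0)$. Within an epoch the
drive is constant; at epoch boundaries it switches instantaneously
(afferent delays are ignored). Every simulation starts from rest
(`V = 0`): the paradigm the package targets randomizes the adapter
orientation across trials precisely so that orientation-specific state
cannot carry over, and the model mirrors that.

**Recurrent sum normalization.** The recurrent input is implemented as
the discretized integral
$V^\theta_{cortex} = \sum_\phi F_\theta(\phi)\,R^\phi\,\Delta\phi$ with
$\Delta\phi = \pi / n$. This is a deliberate design choice: with the
default constants, the leading Fourier mode of the coupling then has
gain ≈ 0.84 — the marginal-amplification regime in which the network
sharpens its input, forms a stable hill, and moves that hill slowly
after a stimulus switch. An unnormalized sum over 256 units would
multiply the same coupling by `n/π ≈ 81` and the dynamics diverge;
the normalized form also makes the dynamics independent of `n_units`,
which is how the test suite can exercise the same regime with 32–64
units. Because the published constants were nevertheless *calibrated*
with 256 units, `simulate_ring()` warns when the default constants are
used with a different unit count.

**Default constants.** τ = 8 ms, α = 3.88 Hz/mV, J_lgn = 11.04,
κ_lgn = 0.47, J_cortex = 2.84, r_IE = 1.24, κ_E = 1.12, κ_I = 0.56,
n = 256 — the set fitted to adaptation-induced tuning-curve shifts in
macaque V1, taken as given here (no fitting code is provided). With
these constants the connection profile is maximal and excitatory at
0°, crosses into inhibition and reaches its trough near 59°, and stays
inhibitory out to 90° — broad inhibition, but not minimal exactly at
the orthogonal orientation. Stimulus contrast is a free config field
and defaults to `c = 1`; the TAE predictions below are insensitive to
its exact value because the decoder is scale-invariant and the
dynamics are close to contrast-proportional below saturation.

**Integration.** Each epoch is integrated separately with the adaptive
Dormand–Prince Runge–Kutta pair (`deSolve::rkMethod("ode45")`,
`rtol = 1e-6`, `atol = 1e-9`), the previous epoch's final state
serving as the initial state, so the solver never steps across the
drive discontinuity. Output is reported on a regular 1 ms grid
(configurable). The test suite checks the solver against an
independent fixed-step forward-Euler integration at `dt = 0.01` ms.
One subtlety worth recording: the residual of that comparison is
dominated by the *oracle's* first-order truncation error, which scales
with the firing rates (tightening the RK tolerances 1000-fold moves
the RK solution by less than 5 × 10⁻⁵ Hz, while halving the Euler step
halves the residual). The equivalence fixture therefore uses a
moderate drive (contrast 0.3, peak rates ≈ 3 Hz), where the oracle's
own error is a few 10⁻⁴ Hz, and the O(dt) convergence of the residual
is asserted alongside the bound.

## Labeled-line readout

The percept is read out by a labeled line: each unit's rate is
evidence for its own preferred orientation. We implement the
"rate-weighted sum of preferred orientations" as the rate-weighted
*circular mean on doubled angles* (the population vector), not an
arithmetic weighted mean of angle values: orientation is circular, and
the arithmetic mean depends on where the `[0, 180)` frame is cut,
breaking rotation equivariance. For activity concentrated away from
the wrap point the two coincide (the package ships the arithmetic
variant as an alternative mode for sensitivity checks). Normalization
by total rate is implicit; a sample decodes to `NA` with flag
`"undefined"` when all rates are zero and `"degenerate"` when the mean
resultant length of the doubled-angle population vector falls below
`1e-6` (near-uniform activity, e.g. two equal rates 90° apart).

## Rate suppression

Adaptation-induced suppression is modeled phenomenologically: after
the adapter offsets at `t0`, each unit's rate is reduced by
$\beta\,\langle R^\theta\rangle\,e^{-(t-t_0)/\rho}$, where
$\langle R^\theta\rangle$ is the unit's own mean rate over the
adaptation window (the adapter epoch, averaged over the grid samples
in `[start, end)`). Three choices deserve comment:

* **Post-hoc, not fed back.** The correction modifies the readout
  rates only; it is not injected into the recurrent input. The
  suppression law is specified as an output-rate correction, and a
  feedback coupling would require assumptions (about conductances and
  their dynamics) the rate-level description does not license.
* **Clipping.** The subtraction can cross zero for weakly driven
  units; rates are clipped at 0. Consequently the suppressed
  trajectory no longer equals `alpha * max(V, 0)` and the voltage
  matrix is dropped from the result.
* **Presets.** `"weak"` (β = 0.20, ρ = 100 ms) encodes the regime
  measured for brief, sub-second adapters, `"strong"` (β = 0.50,
  ρ = 500 ms) the regime for adapters of seconds. The one published
  mention of "σ = 500 ms" is read as the recovery constant ρ (a
  notational slip); no separate σ parameter exists in the law.

Untuned suppression (equal $\langle R\rangle$ across units) provably
leaves the circular decode unchanged while no clipping occurs, because
the subtracted pattern sums to zero on the doubled circle; this is
tested.

## TAE prediction pipeline

`predict_tae()` simulates the paired conditions — adapter at
test ± Δ (default Δ = 20°, 200 ms) followed by the test (default 0°)
— applies the chosen suppression preset with `t0` at test onset (the
protocol is back-to-back, so adapter offset and test onset coincide;
whether suppression should behave differently across a gap epoch is
left unspecified because no gap exists in this protocol), decodes
both, and reports their difference on the post-onset grid. The TAE is
the *full* difference between the two conditions (not halved),
matching the behavioral PSE-difference definition, so a per-condition
perceptual shift of `s` appears as a TAE of `2s`. Positive = attractive.

Three open choices were resolved as follows:

* **Evaluation time.** The "early" TAE is operationalized as the
  instantaneous decode 50 ms after test onset — the shortest test
  duration in the behavioral design. A time-averaged mode
  (`tae_at(..., mode = "averaged")`) is provided for readouts that
  integrate over the whole test presentation.
* **Window.** The post-onset window defaults to 500 ms so that decay
  times beyond 300 ms remain measurable. `tae_decay_time()` returns
  the first time the |TAE| falls below threshold *and stays below*,
  `0` when it never reaches the threshold, and `Inf` when it has not
  decayed by the end of the window.
* **Suppression ordering.** At every time strictly after onset,
  stronger suppression yields a smaller (more repulsive) TAE; at the
  onset sample itself both hills still sit on the adapter and
  zero-clipping of the suppressed flank can nudge the decode by a few
  hundredths of a degree in either direction, so the monotonicity
  property is asserted for `t > 0`.

With the default constants this pipeline predicts an attractive TAE of
≈ 3.9° at 50 ms that decays below 1° within ≈ 80 ms, and a repulsive
TAE (≈ −11° at 50 ms) under the strong-suppression preset — the
qualitative reversal that motivates isolating short-term adaptation
behaviorally.

## Psychometric analysis chain

Responses are modeled as
$P(\mathrm{CW}) = \lambda + (1 - 2\lambda)\,\mathrm{logistic}(s\,(x - \mathrm{PSE}))$
with a single symmetric lapse rate λ — one lapse parameter per
subject implies symmetry between the two asymptotes. Conventions:
positive angles are clockwise, `ref_offset_deg` is reference minus
adapter, and trials are grouped by the *sign* of the reference offset
only, ignoring the 17–23° jitter, exactly as in the main analysis the
package mirrors.

* **Two-stage fitting.** λ is first estimated by a single
  three-parameter fit to the pooled CW+CCW trials, bounded at 0.1 to
  prevent the slope–lapse trade-off, then held fixed in the
  per-condition refits. Estimates are maximum likelihood under the
  Bernoulli model on per-offset aggregated counts, optimized with
  L-BFGS-B and an analytic gradient.
* **Determinism.** Starts come from a probit fit on the aggregated
  proportions (slope, rescaled by 1.7 to the logistic scale) and the
  50% crossing of a linear interpolation (PSE), plus two perturbed
  starts with best-likelihood selection; the fit is therefore a pure
  function of the data. Bootstrap refits restart from the observed
  fit with a single start.
* **Degeneracy.** Fits are rejected (classed error) when the slope is
  indistinguishable from zero (≤ 0.005/°; the PSE is then
  unidentifiable, e.g. exactly 50/50 responses everywhere) or hits
  the separation bound (≥ 49/°).
* **Monte Carlo comparison.** The PSE difference is tested by
  parametric bootstrap: simulate binomial response sets from each
  fitted curve at the observed placements, refit, re-center the
  resampled differences at their mean, and take the two-sided tail
  probability `(1 + #{|d*| ≥ |d|}) / (B + 1)` (default B = 2000;
  500 minimum). Failed refits are counted and the test errors out
  above 5%. This is a documented stand-in for the classic
  Monte-Carlo psychometric-comparison routine — its exact settings
  (core shape, priors, bootstrap variant) are not public — validated
  by calibration: over 200 null replications the type-I error at
  α = 0.05 lies within [0.03, 0.07] (tested).
* **Catch trials.** Visibility is the proportion of catch-trial
  responses consistent with the adapter–reference relation minus 50%,
  with an exact two-sided binomial test against chance.

## Synthetic observer

`generate_session()` emulates the trial structure of the brief-adapter
paradigm: a fresh uniform adapter orientation on every trial, reference
offsets of ±17–23° (uniform jitter, sign equiprobable), test durations
interleaved in equal proportion, 10% catch trials, and test offsets
from the constant-stimuli grid `{-12, …, +12}` in 4° steps. The
generative observer responds through the same lapse-padded logistic
the analysis fits, with its PSE displaced by `sign(ref_offset) ×
shift(duration)`; `model_linked_observer()` sets `shift = TAE/2` from
a model prediction, closing the loop so that the fitted TAE-vs-duration
curve recovers the model's in expectation. One RNG stream per session,
consumed in a fixed vectorized column order, makes tables reproducible
from the seed alone.

What the generator does *not* emulate — and hence what passing tests
do not establish about real data: adaptive (psi-method) stimulus
placement (sessions use the method of constant stimuli, as in the
visible-adapter control), stimulus rendering and spatial-frequency
dependent visibility, eye-movement screening, sequential dependencies
or drift in observer state across trials, and asymmetric lapses. The
observer is a statistical emulation of the analysis's assumptions, so
end-to-end recovery tests validate the *analysis chain*, not the
psychophysics of any particular subject.

## Problem sizes and runtimes

Defaults reproduce the published configuration (256 units, 200 ms
adapter, 500 ms post-onset window; a pair of such simulations takes
roughly a second). The test suite exercises the same dynamics at
32–64 units and 30–250 ms protocols, the Euler-oracle comparison on a
50 ms, 32-unit protocol, psychometric recovery at 200–4000 trials per
condition, Monte-Carlo calibration with 200 null replications × 500
resamples, and 50-replicate coverage checks at 4000 trials per
session — sizes chosen so the full suite completes in a few minutes
while keeping every statistical check adequately powered.

## Known limitations

* The model is rate-based and deterministic: no spiking, no noise, no
  conductance-level mechanism for suppression, no
  spatial-frequency-dependent connectivity.
* Suppression is induced only by the single adapter epoch of the
  simulated protocol; accumulation across trials (deliberately
  minimized by the randomized-adapter design) is not modeled.
* The decoder assumes a labeled-line code with evenly tiled labels;
  maximum-likelihood or Bayesian population decoding is out of scope.
* Group-level inference (t-tests, repeated-measures ANOVA, normality
  checks) is intentionally left to base R on the tidy outputs this
  package produces.
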