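---
title: "Models and methods behind evcddm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind evcddm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(evcddm)
```

# The task and the decision model

The package simulates a rewarded two-attribute random-dot task. Each
trial shows a dot field with two independent evidence streams — motion
direction (up/down) and majority color (blue/red) — at one of four
coherence levels per attribute, fully crossed (16 cells) and balanced for
congruency, so a single left/right response can be correct for neither,
one, or both attributes. A session has three 192-trial epochs (four
48-trial blocks each): equal per-attribute rewards of $0.15 in epoch 1,
then $0.20 vs $0.10 in epochs 2 and 3 with the assignment reversed
between them. Responses must arrive within 3 s; inter-trial intervals are
uniform on 1.2–7.2 s with a 0.5 s preparatory cue.

Choice and response time come from a single-accumulator diffusion with
symmetric absorbing boundaries. The attributes combine linearly in the
drift:

$$d_t = A_m \, Cm_t + A_c \, Cc_t,$$

where $Cm_t, Cc_t$ are the trial's signed coherence magnitudes and
$A_m, A_c \ge 0$ are attention intensities. Default diffusion parameters
are boundary $a = 0.45$ (interpreted as symmetric bounds at $\pm 0.45$
with the start at 0 — the only geometry consistent with a stated zero
starting point between two response boundaries), noise $\sigma = 0.5$
(diffusion SD per unit time), and non-decision time $t_0 = 0.2$ s.
Simulated coherence magnitudes for ordinal levels 1–4 are 0.3, 0.53,
0.77, 1.0.

For this geometry the first-passage quantities have standard closed
forms, used throughout for speed and determinism:

$$P(\text{upper}) = \frac{1}{1 + e^{-2 d a / \sigma^2}}, \qquad
  E[T] = \frac{a}{d} \tanh\!\left(\frac{a d}{\sigma^2}\right),$$

with the limits $1/2$ and $a^2/\sigma^2$ at $d = 0$ (the code switches to
the limit below $|d| < 10^{-8}$; both functions are continuous there).
The general starting-point forms are implemented as well. Because the two
attributes share one accumulator, the color-correct probability equals
the motion-correct probability on congruent trials and its complement on
incongruent trials.

## The Monte-Carlo oracle

`simulate_first_passage()` is the package's independent stochastic check
on those closed forms, and the sampler behind the behavioral generator.
It is an Euler–Maruyama scheme with a Brownian-bridge crossing test: after
each step that ends inside the boundaries, the path is additionally
absorbed with the exact bridge probability
$\exp(-2 (a - x_0)(a - x_1)/\sigma^2 \Delta t)$ of having crossed within
the step. A naive discrete-time walk at $\Delta t = 1$ ms systematically
overshoots absorption — the classic $O(\sqrt{\Delta t})$ boundary
displacement — inflating mean decision times by about 4% at the default
parameters, which would swamp the 2% agreement the test suite demands.
With the bridge test the residual discretization error is a few tenths of
a percent. The default step is $\Delta t = 1$ ms; steps above 10 ms
trigger a warning.

# Expected Value of Control

A policy $(A_m, A_c)$ is scored by the reward rate it earns over the
task's trial distribution, minus an exponential cost of each intensity:

$$\mathrm{EVC} = \overline{\left(\frac{EV_t}{RT_t}\right)}
  - \left[e^{k A_m} + e^{k A_c}\right], \qquad
  EV_t = P(\text{M correct}) R_m + P(\text{C correct}) R_c,$$

with $k = 2$ by default and $RT_t$ the mean decision time plus $t_0$
(inter-trial intervals and the response deadline are excluded; a deadline
plays no role in the expected-value calculus and the closed forms have no
censoring). Two genuinely open choices are resolved as follows:

* **Aggregation.** EVC averages the *per-trial* reward rates
  $EV_t/RT_t$ (linear in the per-trial quantities). The alternative —
  total expected reward over total expected time, $\sum EV_t / \sum RT_t$
  — is available via `evc_config(aggregate = "session")`; the two agree
  to within a few percent at the default parameters and never change the
  qualitative optima.
* **Trial set.** The 32 distinct trial types (4 × 4 coherence levels ×
  congruent/incongruent) enter with equal weight, matching the balanced
  design.

`optimize_policy()` evaluates the full grid ($A_m, A_c \in [0, 2]$, step
0.01; 40,401 policies) and breaks exact ties toward the smallest $A_m$,
then the smallest $A_c$. Two numerical facts are worth knowing. First,
with equal rewards the surface is exactly symmetric under policy swap,
and the continuum optimum lies on the diagonal near $A_m = A_c \approx
0.504$ — but the *grid* maximum is the symmetric off-diagonal pair
(0.50, 0.51)/(0.51, 0.50), which beats (0.50, 0.50) by ~2.5e-5. The
reported optimum is therefore within one grid step of the diagonal, not
on it. Second, with rewards 10 vs 5 and $k = 2$ the optimum is
(0.69, 0.18): attention nearly four times as asymmetric as the 2:1
rewards, because attending both streams strongly is exponentially
expensive — concentrating on the richer stream is normative. With $k = 0$
(costs removed) attention saturates at the grid corner (2, 2); with
rewards 8.5 vs 6.5 the optimum stays motion-dominant (these are the two
published parameter variants exposed through `evc_config()` arguments).

# The calibration staircase

`run_staircase()` implements the 3-down/1-up rule — coherence down 1.5%
after three consecutive correct responses, up 1.5% after each error,
floored at zero — starting at 40% (motion) or 33% (color), with the
threshold estimate defined as the mean of the last 12 presented
coherences. Stopping requires all four published criteria: at least 300
trials; estimate below 30%; estimate within 6% (four steps) of the lowest
rolling estimate over the previous 400 trials; and no significant linear
trend over the last 15 coherences. Two details the rule's description
leaves open: the trend statistic is a two-tailed Spearman rank
correlation with $p > 0.10$ (Kendall selectable via
`staircase_config(trend_method = "kendall")`), and the "lowest threshold
reached" in the drift criterion is the minimum of the same rolling
12-trial mean used by the estimator. With fewer than 15 trials the trend
criterion is false by definition; a constant 15-trial window counts as
trend-free.

The simulated calibree is a logistic observer:
$P(\text{correct}) = \gamma + (1 - \gamma - \lambda)\,F(c; c_{50}, s)$
with guess rate $\gamma = 0.5$, lapse rate $\lambda = 0.01$, midpoint
$c_{50} = 15\%$ and scale $s = 6\%$. The midpoint sits in the plausible
range for these stimuli; the scale is chosen so that one 1.5% staircase
step moves accuracy by only ~3 percentage points near threshold — i.e.
the staircase step is small relative to the psychometric width, which is
the regime the procedure assumes.

**A property worth knowing.** The 3-down/1-up rule's stationary point is
the accuracy $p$ with $p^3 = 1/2$, i.e. 79.4%, and long-run simulation of
the package's staircase confirms stationary accuracy ≈ 79.6%. The
*returned* threshold, however, averages 3–4 accuracy points lower
(≈ 75.5–77% across realistic observers). This is selection bias built
into the stopping rule, not an implementation artifact: slow three-down
descents are always trend-significant while noisy post-error ascents
often are not, so the no-trend criterion preferentially permits stopping
in low-coherence excursions, and the drift criterion additionally caps
the estimate near the recent rolling minimum. Users who need an unbiased
threshold should average over a fixed post-convergence window rather than
relying on the stopping rule's terminal estimate.

# The synthetic cohort

`simulate_participant()` draws one first passage per trial (same bridge
sampler; horizon = deadline − $t_0$, first passages beyond it recorded as
misses), with attention following the epoch's reward structure. Defaults
are the EVC-optimal intensities under the standard constants: 0.50 per
attribute in the equal epoch, 0.69/0.18 (high/low) in the unequal epochs
— i.e. the default cohort behaves normatively. Lapses (2% by default;
uniform choice, uniform RT) keep regression slopes finite; between-
participant variability is lognormal scaling of the attention
intensities (SD 0.1 on the log scale); `gain_sd` optionally adds
trialwise lognormal fluctuation (unit mean) to low-reward attention — the
generative hook for analyses linking trialwise activity to the low-reward
attribute's influence on choice. All generators are bit-reproducible: a
master seed yields per-participant and per-region sub-seeds through
`derive_seed()`'s documented hash, so any stage can be regenerated in
isolation.

Trialwise region activity is generated by `generate_roi_betas()` as an
explicit linear-Gaussian model over the analysis design variables (signed
and unsigned coherences in the reward frame, congruency, high-reward
errors, misses, lag-1 signed coherence, the attention gain), plus
Gaussian noise (`noise_sd = 1`). This reproduces the *regression
structure* of trialwise ROI beta series and nothing else — no
hemodynamics, no voxels, no spatial structure. The preset specs encode
the qualitative patterns the analyses are built to recover: a vmPFC-like
region with positive signed-coherence weights in the 2:1 reward ratio; a
dACC-like region with negative signed weights in a 4:1 ratio (twice the
reward ratio); caudal regions tracking high-reward coherence negatively;
rostral regions tracking low-reward coherence positively. Preset
magnitudes (0.2–0.45) are deliberately larger than the group-level
coefficients reported for real data (0.03–0.11): at realistic
trialwise-beta noise, ratios of coefficients that small have
denominators within ~2 standard errors of zero and are not estimable per
participant. The presets keep the sign and ratio structure at a scale
where each region's primary effect is ~5 within-participant standard
errors at 384 trials.

What passing recovery tests does and does not show: they demonstrate
that the analysis pipeline is consistent — it recovers the parameters of
data generated under its own assumptions (linear-Gaussian encoding,
logistic choice, two-stage group inference) at the study's problem sizes.
They cannot show robustness to the ways real data violate those
assumptions: autocorrelated scanner noise, hemodynamic bleed-through
between trials, non-stationary attention, slow errors, or mixed-effects
shrinkage differences.

# Analyses

All analyses are two-stage: ordinary per-participant fits (maximum
likelihood logistic or least squares) followed by one- or two-sample
t-tests across participants. This summary-statistics surrogate preserves
the estimands of the mixed-effects models used with real data at
simulation scale without committing to a particular random-effects
implementation; the price is less shrinkage and slightly conservative
group inference.

Conventions, matching standard practice for this task family: coherence
enters regressions as ordinal levels (unsigned 1–4; signed −4..+4, with
no zero), signed either toward a fixed reference response (choice models,
psychometric tables) or toward the response actually made (RT and
encoding models); beta series are arcsinh-transformed before regression
to reduce kurtosis; encoding models include per-block intercepts and
linear trends as nuisance terms; missed trials are excluded everywhere
except when a miss regressor is explicitly requested. The weight-ratio
test excludes participants whose low-reward coefficient is smaller in
magnitude than 0.1 of its standard error (near-zero denominators make
per-participant ratios meaningless; how real analyses handled this is
unstated, so the floor — and its exclusion count — is reported). In a
degenerate cohort whose ratios are all identical (e.g. noiseless
generators) the t-statistic is defined as 0 with p = 1 on the reference,
±∞ with p = 0 off it.

One modelling fact surfaced by the recovery tests deserves note: for a
*pure* diffusion agent, signed (chosen-frame) evidence has only a weak
linear effect on log RT, because error and correct first-passage times
are identical at matched drift — RT depends on |drift|, and the signed
effect arises only through the asymmetric frequency of choices with and
against the evidence. Group-level coefficients are reliably negative, as
the analyses expect, but much smaller than unsigned-coherence effects.
Strong signed RT effects in real data reflect processes (e.g. slow
errors) outside this generator.

# Problem sizes and test design

The suite exercises the study-scale conditions directly: 192-trial
epochs, 576-trial sessions, grids of 201 × 201 policies, a 30-participant
cohort for choice-weight recovery, 100 seeded staircase runs for the
calibration average, 100 simulated cohorts for the ratio-test
calibration, and 10^5 Monte-Carlo paths for the oracle comparison.
Smaller cohorts (4–12 participants) are used where a property is about
structure rather than power. Expected values in tests are either exact
(closed forms, arithmetic), frozen from independent oracles (brute-force
EVC recomputation, closed-form population coefficients fit to exact cell
probabilities), or statistical with explicit tolerance (3–4 standard
errors, binomial bands).

# Known limitations

* No full RT distributions (densities, quantiles), collapsing bounds, or
  inter-trial parameter variability in the diffusion.
* No learning dynamics: attention is set per epoch, not adapted
  trial-by-trial (except the optional exogenous gain fluctuation).
* The neural generator is a design-matrix model, not a biophysical one;
  sensory-region accounts (e.g. attention-modulated MT+/V4 responses) are
  representable only as condition-dependent encoding weights.
* Group inference is two-stage, not hierarchical; per-participant
  estimates are unshrunk.
* The staircase's terminal estimate inherits the stopping-rule bias
  described above; the package reports it rather than correcting it.
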