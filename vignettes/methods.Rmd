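---
title: "Simulating automated operant training and psychoacoustic threshold estimation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating automated operant training and psychoacoustic threshold estimation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(autrain)
```

`autrain` simulates, end to end, an automated home-cage training system for
marmosets: a stepwise shaping schedule, alternative-choice and detection
tasks, simulated subjects, and the analysis pipeline. This vignette
explains the models and procedures, the tunable parameters and their
defaults, the numerical choices, and what the simulations can and cannot
say about real animal data.

## The training schedule and its progression rule

The automated unsupervised training (AUT) schedule has 49 positions — an
entry step plus 48 dynamic steps — in four milestones:

* **size** (steps 1–15): the touch trigger shrinks linearly from 6 × 6 cm
  to 3 × 3 cm. The ramp is linear because only the endpoints are fixed by
  the protocol; any monotone interpolation with those endpoints would
  serve, and linear is the simplest.
* **position** (16–30): the trigger moves 5 mm per step from the vertical
  meridian toward a screen edge, capped at the configured edge offset
  (default 75 mm, which the 15 position steps reach exactly).
* **delay** (31–45): a two-touch sequence begins (centre trigger, then
  peripheral target). From step 36 a sound precedes the visual target by
  1–1.5 s, its level rising 32 → 72 dB SPL in 10-dB steps to step 40 and
  holding through step 45 for prolonged exposure.
* **choice** (46–49): a visual distractor appears on the opposite edge,
  growing linearly from 0.3 to 2.8 cm (again only the endpoints are fixed).

Completing step 49 places the subject at the virtual step 50, where the
discrimination experiment proper begins. The expanded table is fully
deterministic for a fixed configuration and can be written as a 12-column
CSV (`write_schedule_csv()`).

Progression is evaluated on a sliding window of the 10 most recent scored
trials: at least 8 correct advances one step; 2 or fewer correct (fewer
than 3) retreats one. Three behaviours are deliberate design choices where
the protocol description is silent:

* **No transition before the window fills.** A fresh window (after entry
  or any step change) must accumulate `window_len` scored trials before a
  decision is taken; otherwise three lucky trials could advance a step.
* **The window clears on every step change**, so consecutive transitions
  each require ten fresh trials of evidence. Without this, a single hot
  streak would cascade through several steps. Whether the original device
  cleared its window is not documented; clearing is the conservative
  choice and the package's contract.
* **Ignored trials never enter the window.** A trial aborted after 7 s
  without response carries no choice, so it carries no evidence either.

The progression state (current step plus window) serialises to one JSON
document per subject, and `simulate_training()` accepts a restored state,
so runs resume across breaks exactly as on the device.

## Trial logic and reward rules

A trial moves through: optional sound lead (uniform 1–1.5 s) → options
displayed → response window (default 7 s) → reward, or a gray-screen
timeout (default 5 s) after a wrong touch → inter-trial interval drawn
uniformly from 0.8–2.5 s. The original protocol used 2.5-s timeouts in
early sessions and 5 s later; the package keeps a single configurable
value and defaults to the later one. The ITI distribution within its
stated range and the per-trial side of the target are both undocumented in
the protocol; independent uniform draws are used for each.

Timing runs against an injectable simulated clock, so a 10,000-trial
session takes a fraction of a second of wall time while still producing
monotone, realistic session-relative timestamps.

The detection task plays a vocalization at one of
{0, 15, 30, 45, 60, 70, 80} dB SPL (0 dB being the silent-trial type) and
the subject reports presence (face) or absence (triangles). Because the
mid-range levels sit near or below a typical facility's background noise,
the reward rule is level-dependent: 15–45 dB rewarded regardless of
choice, 0 dB rewarded only for "absent", ≥ 60 dB only for "present". A
uniformly random responder therefore earns reward on
(3 · 1 + 4 · 0.5)/7 ≈ 71.4% of trials — a closed form the test suite
checks by simulation. In the 2AC and 3AC tasks reward is simply
choice-contingent, with chance rates 1/2 and 1/3.

## Simulated subjects

Agents replace animals. The response policies are:

| policy | behaviour | main parameters |
|---|---|---|
| `random` | uniform over displayed options | — |
| `ideal` | always the target | — |
| `fixed-accuracy` | target with probability p | `p_correct` |
| `learning-curve` | p(t) = p∞ − (p∞ − p₀)·exp(−t/τ) | `p_start`, `p_asymptote`, `tau_trials` |
| `psychometric-observer` | "present" with probability ψ(level) | `psychometric` |

The saturating exponential is the canonical improving-learner model; real
learning curves are plotted, not modelled, in the source protocol, so the
exponential is this package's choice of a smooth monotone family with
interpretable start, asymptote and time constant. Defaults (p₀ = 0.5,
p∞ = 0.9, τ = 200 trials) give AUT completion in a few hundred to a few
thousand trials, matching the order of magnitude real subjects need.

Latencies are log-normal with a per-sound location (`rt_meanlog`) and
common spread, so reaction-time contrasts between stimuli have a true
effect for the Kruskal–Wallis analysis to detect. Each trial is ignored
with probability `p_ignore` before any choice is generated, independent of
the stimulus. Both are simplifications: real ignore rates vary with
motivation and stimulus, and real latency distributions are heavier-tailed.

`simulate_session()` runs every trial through the full `run_trial()` phase
machine. `simulate_training()`, which may need tens of thousands of
trials, instead draws each outcome directly from the agent's accuracy
model (one available option before the distractor milestone, two from step
46, so a random agent succeeds trivially early on and at 50% late) and
feeds it to the progression engine; this keeps multi-session runs fast
while exercising the identical progression code path. Session s of a run
seeds its RNG stream with `seed + s`, which is what makes a resumed run
reproduce the original trajectory exactly.

## Analysis pipeline

`hit_rate_table()` aggregates logs per (animal, task, sound): trial
counts, ignored counts, hit rate over scored trials, d′, and a one-sided
exact binomial test against chance with Bonferroni adjustment. The d′ for
a stimulus uses the standard yes/no form z(H) − z(FA), taking as false
alarms the pooled errors on the other stimuli of the same animal and task;
rates are clipped to [1/(2N), 1 − 1/(2N)] so perfect performance stays
finite. The protocol source does not state its d′ formula, so these values
should be read as the conventional index, not a byte-exact reproduction of
any published per-animal table.

`learning_curve_bins()` maps each subject's scored trials 1..N onto a
percent-of-total axis (5% or 10% bins), the standardization that lets
subjects with very different trial counts share one learning-curve axis.
`engagement_summary()` computes per-session trial counts, median
trial timestamps normalized by the scheduled session duration (a value
near 0.5 means engagement was spread evenly through the session), and
zero-trial session tallies; scheduled duration, not first-to-last-trial
span, is the normalizer, since an unused session still counts as
scheduled. `partial_pearson()` correlates two quantities after linear
removal of one covariate, with a t-test on n − 3 degrees of freedom and a
Fisher-transform interval using SE = 1/sqrt(n − 4).

Standard machinery is delegated to base R: `pbinom` for exact binomial
tails, `kruskal.test` for the rank test (tie-corrected H, chi-square
reference), `p.adjust` for Bonferroni. The test suite cross-checks these
against independent brute-force oracles (pmf enumeration by `choose()`,
hand rank sums).

## Psychometric function and fitting

The detection analysis fits

$$\psi(x; m, w, \lambda, \gamma) = \gamma + (1-\lambda-\gamma)\,
\Phi\!\left(c\,\frac{x-m}{w}\right)$$

where m is the threshold (level at which the core crosses 0.5), w the
width, λ the lapse rate and γ the guess rate. Two width conventions exist
in the field; here w is by default the level difference between core
values 0.5 and 0.95, so c = Φ⁻¹(0.95) ≈ 1.645, with the 0.05–0.95
convention (c = 2Φ⁻¹(0.95)) selectable. Detection data are fitted as the
probability of the "present" (face) response versus level; the
false-alarm floor at 0 dB is absorbed by γ.

Numerical choices:

* **Objective.** Binomial log-likelihood plus weak Beta(1, 10) priors on
  λ/0.5 and γ/0.5. The priors contribute nothing at 0, pull gently away
  from the 0.5 bound, and stabilise the all-parameters-free fit at the
  small per-level counts (~60 trials/level) a realistic session yields.
* **Optimisation.** L-BFGS-B from a deterministic grid of starts spanning
  the level range (about 12 starts). Box constraints: m within the level
  range ± one range-width, w in [range/100, 4·range], λ, γ in [0, 0.5).
  Among starts reaching the best objective (within 10⁻⁶), one with a clean
  convergence code is preferred — L-BFGS-B occasionally ends a line search
  abnormally *at* the optimum, and that code alone should not mark a fit
  failed.
* **Degenerate data.** If the response proportions carry no level
  information (all 0, all 1, or constant), the fit is flagged
  non-converged with `NA` estimates rather than silently returning a
  boundary solution. Fewer than three distinct levels is an error.
* **Confidence intervals.** Parametric bootstrap: counts are resampled
  from the fitted curve at each level, refitted (single start at the
  original estimate — adequate because bootstrap data are draws from that
  very model), and 95% percentile intervals taken. Intervals are flagged
  unreliable if more than 20% of refits fail. Percentile intervals on m
  undercover slightly at small n; the test suite requires ≥ 90% empirical
  coverage at nominal 95%, which this scheme meets at 200 trials/level.

## Problem sizes and reproducibility

Every stochastic result in the package flows from explicit integer seeds:
sessions from `seed`, training sessions from `seed + s`, bootstrap and CLI
workflows from their own `--seed` flags. Identical seeds give
byte-identical serialized logs.

The package's own verification uses: 10,000-trial sessions for
chance-rate checks; 100 seeded replicates (7 levels × 200 trials,
bootstrap of 100) for threshold-recovery coverage; 1,000 replicates of
100-trial sessions for the binomial test's type-I behaviour, compared
against the exact size of the discrete test (which is below 5% at finite
n) within Monte-Carlo error; and exhaustive enumeration for the 2¹⁰
sliding windows and the binomial tail at n ≤ 20. These sizes make the
statistical assertions sharp while keeping a full run in minutes on one
CPU.

## What the simulations do not show

Agents are stationary (or smoothly improving) stochastic responders. They
have no motivation, satiety, side bias, exploration, or strategy switching
— so passing tests demonstrate that the *software* is correct: schedules
expand to specification, progression follows the windowed rule,
reward/timeout contingencies are enforced, statistics match their
definitions, and the fitting machinery recovers known parameters. They do
not validate claims about real marmoset learning. In particular, during
the final AUT steps a real animal can exploit the target/distractor size
difference; the engine scores only the identity of the touched visual.
Speaker calibration, RFID identification, and all other hardware concerns
are out of scope.
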