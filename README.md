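# autrain

`autrain` is a headless, hardware-free R implementation of an automated
home-cage training and psychoacoustic testing system for common marmosets.
It is aimed at behavioral neuroscientists and psychophysicists who want to
prototype, simulate, and analyze touchscreen-based operant protocols —
without a device, animals, or data collection. Everything the physical
system does in software is reproduced here: the staircase-like training
schedule, the trial state machine with reward and timeout contingencies,
the session log format, and the statistics used to judge performance and
estimate hearing thresholds. Simulated subjects with configurable response
policies stand in for the animals.

## What it implements

**Automated unsupervised training (AUT).** A 49-position step schedule
(entry step plus 48 dynamic steps) in four milestones: the touch trigger
shrinks from 6 × 6 cm to 3 × 3 cm (steps 1–15), moves laterally by 5 mm per
step to the screen edge (16–30), a sound is introduced 1–1.5 s before a
delayed visual target with its level ramping 32 → 72 dB SPL in 10-dB steps
(31–45), and a visual distractor grows from 0.3 to 2.8 cm (46–49).
Progression is performance-based on a sliding window of the 10 most recent
scored trials: ≥ 8 correct advances a step, ≤ 2 correct retreats one, and
the state is persisted so subjects resume where they left off across
sessions. Completion (step 50) hands over to the discrimination experiment.

**Task logic.** Two- and three-alternative-choice (2AC/3AC) audio-visual
association trials, generalization variants with novel stimulus pairs, and
a vocalization-detection task using the method of constant stimuli over
levels {0, 15, 30, 45, 60, 70, 80} dB SPL with a level-dependent reward
scheme (15–45 dB rewarded regardless of choice; 0 dB rewarded only for the
"absent" response; ≥ 60 dB only for "present"). Wrong touches trigger a
gray-screen timeout; no response within 7 s marks the trial ignored;
inter-trial intervals are drawn from 0.8–2.5 s.

**Analysis.** Per-stimulus hit-rate tables, the signal-detection
sensitivity index d′ = z(H) − z(FA) with 1/(2N) extreme-rate correction,
exact one-sided binomial tests against chance, Bonferroni correction,
Kruskal–Wallis rank tests for reaction-time contrasts, engagement summaries
(trials per session, normalized trial timestamps, zero-trial sessions),
learning curves on a standardized percent-of-trials axis, and partial
Pearson correlations.

**Psychometric fitting.** The four-parameter psychometric function

ψ(x; m, w, λ, γ) = γ + (1 − λ − γ) · S(x; m, w)

with a cumulative-normal core S, threshold *m* (level at S = 0.5), width
*w* (level difference between S = 0.5 and S = 0.95 by default), lapse rate
λ and guess rate γ. `fit_psychometric()` maximizes the binomial likelihood
with all parameters free and returns a classed model object with the usual
`coef`/`predict`/`plot`/`simulate`/`confint` methods; confidence intervals
come from a parametric bootstrap.

## Worked example

Train a learning simulated subject through the AUT, analyze a
discrimination session, and estimate a hearing threshold:

```r
library(autrain)

# 1. drive a subject whose accuracy rises from 0.5 to 0.95 through the AUT
run <- simulate_training(agent_learning(p_start = 0.5, p_asymptote = 0.95,
                                        tau_trials = 300), seed = 42)
run
#> <training_run> 650 trials over 4 session(s); final step 50 (completed)
run$milestone_trials
#> choice    delay position     size
#>     41      165      160      284

# 2. a 2AC session at 85% accuracy, with slower responses to the vocalization
log <- simulate_session(task_audiovisual_2ac(),
                        agent_fixed(0.85, rt_meanlog = c(voc = log(2.2),
                                                         sTr = log(1.5))),
                        800, seed = 42)
hit_rate_table(log, family_size = 26)
#>   animal_id task sound_id n_trials n_scored n_correct n_ignored hit_rate d_prime p_value_raw p_value_adjusted
#> 1       sim  2ac      sTr      365      365       302         0    0.827    1.89    7.64e-39         1.99e-37
#> 2       sim  2ac      voc      435      433       358         2    0.827    1.89    1.38e-45         3.58e-44

# 3. hearing threshold of a simulated observer (true m = 37 dB SPL)
obs <- agent_observer(psychometric_params(m = 37, w = 15,
                                          lambda = 0.02, gamma = 0.05))
det <- simulate_session(task_detection(), obs, 450, seed = 42)
fit <- fit_psychometric(level_counts(det))
fit
#> <psychfit> cumulative-normal psychometric fit
#>   threshold m = 37.05, width w = 12.61 (0.5-0.95), lambda = 0.023, gamma = 0.041
#>   log-likelihood -108.68 over 7 levels
confint(fit, "m", n_boot = 200, seed = 1)
#>      lower    upper
#> m 34.90542 39.44445
```

The training run completed all four milestones in 650 trials; the fixed
0.85-accuracy subject shows matching hit rates, a d′ near 1.9, and
performance far above chance after Bonferroni adjustment over a
26-comparison family (corrected α = 0.0019); and the fitted threshold
(37.05 dB SPL, 95% CI 34.9–39.4) recovers the observer's true 37 dB SPL.

A command-line interface wraps the same workflows (`simulate-aut`,
`simulate-task`, `analyze`, `fit-psychometric`, `make-fixtures`); see
`inst/exec/autrain` and `?autrain_cli`.

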