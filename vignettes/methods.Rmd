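---
title: "Methods: models, fitting, and the synthetic cohort"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, fitting, and the synthetic cohort}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(aalearn)
```

`aalearn` simulates and analyses an intergroup approach–avoidance task in
which the response is a *continuous* signed distance rather than a binary
choice. This vignette documents the modelling conventions so that every
number the package produces can be traced to an explicit formula.

## The task

A participant completes 3 blocks of 40 trials. On each trial one of two
symbols (an in-group or out-group face) appears and the participant moves
an avatar toward or away from it. Symbols appear 20 times per block in a
pseudorandom order with at most `max_run = 2` consecutive repetitions.
The scheduled reward probability depends on the arm:

```{r}
task_design("social_conflict")$reward_schedule
task_design("social_control")$reward_schedule
```

In the conflict arm, approaching the out-group face is rewarded 80% of
the time while approaching the in-group face is rewarded only 20% — so
learning must override the initial in-group preference. Each reward is
worth +0.05 EUR, each non-reward −0.05 EUR; with a 1 EUR retained
dictator-game endowment the maximum variable payout is
`r max_variable_payout(task_design("social_conflict"))` EUR.

### Sequence generation

Rather than rejection-sampling whole blocks (which has a vanishing
acceptance rate at 20 + 20 symbols with `max_run = 2`), sequences are
built constructively: at each position a symbol is drawn with probability
proportional to its remaining count, restricted to choices after which a
completion still exists. The feasibility condition for `a` remaining of
the just-placed symbol with run length `l`, `b` of the other, and maximum
run `m` is exact:

> a completion exists iff `a <= (m - l) + m * b` and `b <= m * (a + 1)`.

This was verified against brute-force enumeration of all sequences for
small block sizes. The constructive sampler is uniform enough for design
purposes (counts and run-length constraints are what the task requires)
and is deterministic given a seed.

### Response geometry

The raw excursion `d` lies in `[-D, D]` with `D = 0.6`. It is normalised
affinely to `[0, 1]` via `(d + D) / (2D)` and then *oriented* so that
larger values always mean "learned the schedule": in-group values are
inverted (`1 - u`). Orientation is an involution, so the mapping from raw
distance to oriented value is a bijection and can be round-tripped:

```{r}
d <- task_design("social_conflict")
y <- orient_value(normalize_distance(-0.3, d), "ingroup")
y
oriented_to_raw(y, "ingroup", d)
```

## The model space

All six models are variants of the delta rule with a retention factor:

$$V_t = \left[ V_{t-1} + \alpha\,\delta_t \right]\beta,
\qquad \delta_t = r_t - V_{t-1}$$

with all parameters bounded in `[0, 1]` and two free starting values
(`v1_in`, `v1_out`), one per symbol. The variants free different
parameters:

| model | free parameters | K |
|---|---|---|
| 1 | one α (β fixed at 1) | 3 |
| 2 | α, β | 4 |
| 3 | α, β per symbol | 5 |
| 4 | α per symbol, β | 5 |
| 5 | α⁺/α⁻ by prediction-error valence, β | 5 |
| 6 | α⁺/α⁻ per symbol, β | 7 |

```{r}
vapply(1:6, param_count, integer(1))
```

Models 3–6 all reduce exactly to model 2 when their split parameters are
equal, and model 2 with β = 1 reduces to model 1; the test suite checks
these nesting identities to 1e−12 on random data.

### Teacher-forced versus latent prediction

Fitting a learning model to a *continuous* response permits two carried
values:

- **teacher-forced** (the default): the value carried into trial *t* is
  the participant's *observed* response on the previous encounter. The
  model predicts one step ahead from data, each prediction depends only
  on observed history, and the whole series is vectorisable.
- **latent**: the model carries its *own* previous prediction, so
  parameter effects compound across the block.

Teacher forcing is the default because the response *is* the value scale
here (no observation model separates them), it makes the SSE surface much
better behaved, and it matches how one-step-ahead fit quality (R²) is
reported. The latent mode is provided (`mode = "latent"`) for sensitivity
analyses. In both modes the first encounter of a symbol is predicted by
the unscaled starting value and its residual counts in the SSE.

## Fitting

`fit_participant()` minimises the sum of squared one-step-ahead errors
with `optim(method = "L-BFGS-B")` from `n_starts = 10` uniform random
starts (seeded, with the nested-prefix property: more starts can only
improve the optimum), a coordinate-refinement fallback if the gradient
method fails, and a deterministic tie-break. Fit quality is summarised by

$$\mathrm{BIC} = n \ln(\mathrm{SSE}/n) + k \ln n, \qquad
R^2 = 1 - \mathrm{SSE}/\mathrm{SST}.$$

`compare_models()` sums BIC over participants (listwise over models) and
flags the winner, breaking exact ties toward the smaller K.

```{r}
co <- simulate_cohort(task_design("social_conflict"), 4, seed = 1)
fits <- fit_cohort(co$trials, models = c(1, 2, 5), n_starts = 5, seed = 2)
compare_models(fits)
```

## The synthetic cohort

The generator is the package's substitute for participant data, and its
defaults are the study conditions, not tuning knobs:

- **conflict arm** (model 5): α⁺ mean 0.38, α⁻ mean 0.01, β mean 0.67,
  `v1_in` 0.70, `v1_out` 0.80 — an initial in-group preference (after
  orientation, in-group starting values sit *below* out-group ones)
  that fast positive-PE learning overrides.
- **response noise**: Gaussian with σ = 0.10 on the oriented value,
  clamped to `[0, 1]`. At this level single-participant R² lands near
  the modest values typical of continuous-response fits.
- **invalid trials**: each trial is invalid with probability 0.01; an
  invalid trial has no outcome and the avatar stays put. Participants
  with more than one invalid trial in any block × symbol cell are
  excluded, mirroring the preregistered rule.

### The random-reward control arm

The control-arm population deserves a note because it is *derived*, not
copied. Under teacher forcing with 50/50 rewards the emitted response has
the stationary point

$$y^* = \frac{0.5\,\alpha\beta}{1 - \beta(1 - \alpha)},$$

which for the conflict-arm α mean (0.38, symmetric across valences, as a
random schedule provides no valence signal to exploit) and β = 0.67 gives
y* ≈ 0.22. Setting both starting values to that stationary point makes
the generated control responses mean-stationary with flat per-symbol
slopes — the behaviour a random schedule should produce. Earlier drafts
that reused the conflict-arm asymmetric α⁺/α⁻ drifted upward under 50/50
rewards and manufactured a spurious symbol contrast; the derivation above
removes the drift at its source rather than papering over it.

```{r}
a <- 0.38; b <- 0.67
0.5 * a * b / (1 - b * (1 - a))
```

## Validation studies

Two recovery studies validate the full chain on package-internal data:

- `parameter_recovery()` simulates agents from a known population,
  refits the generating model, and reports bias, RMSE, and true–recovered
  correlations per parameter.
- `model_recovery()` simulates cohorts from chosen generating models,
  fits the whole model space, and tabulates which model wins the summed
  BIC — a confusion matrix whose diagonal should dominate.

Problem sizes in the examples (50 agents, 10 cohorts) are package
defaults chosen to finish in minutes on one CPU; they are smaller than a
full study but large enough for the qualitative conclusions to be stable
across seeds.

## Limitations

The generator assumes a single generating model per cohort, Gaussian
response noise, and independence across trials beyond the carried value.
It reproduces design-level quantities and qualitative learning patterns;
it does not (and cannot) reproduce fitted statistics of any particular
empirical sample.
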