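# aalearn

Simulation and model-based analysis of an intergroup approach–avoidance
learning task with a **continuous** distance response.

In the task, a participant repeatedly moves an avatar toward or away
from an in-group or out-group face. In the conflict condition the reward
schedule opposes the initial preference: approaching the out-group face
is rewarded 80% of the time, approaching the in-group face only 20%, so
participants must learn to override their in-group bias. `aalearn`
provides everything needed to study this computationally:

- **Task designs** — conflict (80/20), random social control (50/50) and
  non-social control arms; pseudorandom trial sequences with a
  run-length constraint; the distance → value geometry (normalisation
  and group-specific orientation).
- **A synthetic cohort generator** — agents with biased starting values,
  reinforcement-driven drift, Gaussian response noise and occasional
  invalid trials, plus the preregistered exclusion rule.
- **Six Rescorla–Wagner model variants** — from a single learning rate
  up to valence- × group-specific learning rates (K = 3, 4, 5, 5, 5, 7),
  in teacher-forced (default) or latent prediction mode.
- **Fitting and comparison** — bound-constrained multi-start SSE
  minimisation per participant, BIC and R², summed-BIC model comparison,
  Welch parameter contrasts, per-symbol learning slopes, and a
  noncentral-t paired-samples power calculator.
- **Validation** — parameter-recovery and model-recovery studies, and a
  CSV-in/CSV-out pipeline with a markdown run report.

## Worked example

```r
library(aalearn)

d <- task_design("social_conflict")
d
#> <aal_design> arm=social_conflict, 3 blocks x 40 trials (max run 2), outcome +/-0.05 EUR
#>          approach avoid
#> ingroup       0.2   0.8
#> outgroup      0.8   0.2

co   <- simulate_cohort(d, 8, seed = 42)          # 8 synthetic participants
kept <- exclude_participants(co$trials)           # preregistered exclusion rule
fits <- fit_cohort(kept, models = c(1, 2, 5), n_starts = 5, seed = 99)
compare_models(fits)
#> Model comparison (summed BIC; lower is better)
#> # A tibble: 3 x 6
#>   model_id     k mean_r2 sum_bic n_participants winner
#> *    <int> <int>   <dbl>   <dbl>          <int> <lgl>
#> 1        1     3   0.449  -4022.              8 FALSE
#> 2        2     4   0.688  -4392.              8 FALSE
#> 3        5     5   0.729  -4498.              8 TRUE
#> winner: model 5 (0 participant(s) dropped for failed fits)
```

The cohort was generated by model 5 (valence-split learning rates), and
model 5 wins the comparison. Learning is also visible model-free as a
slope contrast between symbols:

```r
per_symbol_slopes(kept)$contrast
#> $t
#> [1] -5.252782
#> $df
#> [1] 13.93504
#> $p
#> [1] 0.0001241139
```

And the design-level power calculation:

```r
required_sample_size_paired_t(0.444, 0.05, 0.80)
#> [1] 42
```

One call runs the whole simulate → exclude → fit → compare → report
chain:

```r
res <- run_pipeline(run_config(arm = "social_conflict", seed = 1))
```

## Command line

A thin CLI lives in `inst/cli/aal.R` (installed under
`system.file("cli", "aal.R", package = "aalearn")`):

```sh
Rscript aal.R power   --effect-size 0.444
Rscript aal.R simulate --arm social_conflict --n 20 --seed 7 --out run/
Rscript aal.R fit      --trials run/trials.csv --models 1,2,5 --out run/
Rscript aal.R compare  --fits run/fits.csv --out run/
Rscript aal.R report   --arm social_conflict --seed 1 --out run/
```

## Tests and reproduction

The testthat suite covers worked numeric oracles, property-based checks
(nesting identities, geometry round trips, seed reproducibility) and the
recovery studies:

```sh
Rscript -e 'testthat::test_dir("tests/testthat", package = "aalearn", load_package = "installed")'
```

`scripts/acceptance.R` recomputes the headline design-level quantities
(required sample size; empirical reward percentages under the conflict
and control schedules) from the installed package and writes them as
JSON:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

See the `methods` vignette (`vignettes/methods.Rmd`) for the modelling
conventions: the model space and its nesting structure, teacher-forced
versus latent prediction, the response geometry, and how the generator
defaults — including the control-arm stationary-point derivation — were
chosen.
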