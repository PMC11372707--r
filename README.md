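# forcefluct

Magnitude and structure of force fluctuations in bimanual force-tracking
tasks.

## The problem

In role-differentiated bimanual movements (RDBM) — think holding a cup
steady with one hand while pouring with the other — one hand stabilizes a
constant force while the other manipulates a time-varying one. How steadily
the stabilizing hand holds its target, and *how* its fluctuations are
organized in time, are informative about sensorimotor control: aging and
cognitive decline are associated with a *loss of complexity* in
physiological signals. This package provides a tested, reusable pipeline
for that analysis, aimed at motor-control and aging researchers who record
isometric force during bimanual visuomotor tracking (20-s trials at 120 Hz,
constant target at 12% of maximum voluntary contraction, manipulating
target a 0.2 Hz sine spanning 5–12% MVC, the first 6 s of ramp excluded).

Three outcomes are computed per constant-force series `x`:

- **Coefficient of variation** (magnitude of variability):
  `CV = 100 · SD(x) / mean(x)` (sample SD).
- **DFA scaling exponent** (fractal structure): the series is integrated,
  cut into non-overlapping windows of length `m`, linearly detrended per
  window, and the mean per-window RMS deviation `F(m)` is regressed on `m`
  in log–log space over 30 exponentially spaced windows from 10 to 200:
  `F(m) ∝ m^α`. White noise gives `α ≈ 0.5`, Brownian noise `α ≈ 1.5`;
  higher α = less complex.
- **Sample entropy** (randomness): `SEn = ln(Cm / Cm+1)` with template
  length `m = 2`, radius `r = 0.25` on the z-scaled series, Euclidean
  segment distance, self-matches excluded; lower SEn = more predictable =
  less complex. (`SEn > 2` for white noise, `< 0.5` for Brownian noise.)

Group-level inference uses a Gaussian linear mixed model with a participant
random intercept over the factors condition (bimanual constant vs
role-differentiated), group (CHI = cognitively healthy vs MCI = mild
cognitive impairment, screened as MoCA < 26 plus ≥ 1 CERAD-NP z-score
below −1.5), hand, sex, and timepoint (cohort-sequential design, 1–4
visits). Models are built stepwise, compared by AIC and likelihood-ratio
tests (ML), and the selected model's REML contrasts are reported with the
t-based effect size `r = √(t²/(t²+df))`.

Because no raw data accompany the design the package emulates, a
first-class synthetic generator produces benchmark noise, single trials
(with optional crosstalk leakage of the manipulating oscillation into the
stabilizing hand — the mirror-movement signature), and whole cohorts with
the design's group/timepoint structure, so every stage is exercisable
offline.

## Worked example

```r
library(forcefluct)

x <- gen_noise(noise_spec("white", 1680, seed = 1))
dfa_alpha(x)
#> DFA: alpha = 0.5304 (R^2 = 0.9968, 30 windows 10..200)
sample_entropy(zscale(x))
#> SEn = 2.3614 nats (m = 2, r = 0.25, euclidean; Cm = 43506, Cm+1 = 4102)
```

The white-noise anchors land where they should: `α` near 0.5 and entropy
well above 2 (Brownian noise with the same seed gives `alpha = 1.4596` and
`SEn = 0.3093`).

```r
pair <- gen_bimanual_trial(trial_config(seed = 3))
res <- analyze_trial(pair$stabilizing)
sprintf("CV = %.2f %%MVC, DFA-alpha = %.3f, SEn = %.3f",
        res$cv, res$dfa_alpha, res$sen)
#> "CV = 7.19 %MVC, DFA-alpha = 1.391, SEn = 0.539"
```

A simulated stabilizing-hand series looks like real data: CV around 7% of
MVC and a strongly self-correlated structure (`α ≈ 1.39`), matching the
observed range for this task. End to end on a small synthetic cohort:

```r
co <- gen_cohort(cohort_config(
  counts = matrix(c(12L, 8L, 10L, 6L), nrow = 2, byrow = TRUE,
                  dimnames = list(c("CHI", "MCI"), NULL)),
  seed = 42))
inf <- stepwise_inference(co$observations)
inf$contrasts[, c("label", "beta", "se", "df", "t", "p", "r")]
#>               label beta    se  df     t        p     r
#> 1         Intercept 3.00 1.084 120 2.772 6.46e-03 0.245
#> 2 Condition (RD-BC) 3.39 0.438 120 7.735 3.57e-12 0.577
#> 3   Group (MCI-CHI) 1.17 1.543  20 0.758 4.57e-01 0.167
#> 4 Hand (right-left) 1.45 0.438 120 3.301 1.27e-03 0.289
```

AIC selected the model with condition, group and hand; the generative
condition effect (+2.4 %CV in the role-differentiated task) is recovered
as 3.39 ± 0.44, and `r` is the t-based effect size per row (e.g.
`effect_size_r(5.13, 129)` returns 0.41).

## Command line

```sh
Rscript inst/cli/forcefluct.R all --out-dir run1 --seed 3 \
    --subjects-chi 2,1 --subjects-mci 2,1 --trials-bc 1 --trials-rd 1
```

Subcommands `simulate` / `measure` / `infer` / `all` / `fixtures`; every
CSV opens with a `# forcefluct v… | seed=… | config=…` provenance header
and each run writes a JSON manifest. Exit codes: 0 success, 2 config
error, 3 stage failure.

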