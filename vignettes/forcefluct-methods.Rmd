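---
title: "Methods: quantifying the magnitude and structure of bimanual force fluctuations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying the magnitude and structure of bimanual force fluctuations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(forcefluct)
```

## Scope and model

`forcefluct` analyzes constant-force production in bimanual visuomotor
tracking along two complementary axes: the **magnitude** of fluctuations
(coefficient of variation) and their **temporal structure** or complexity,
indexed jointly by the detrended-fluctuation-analysis scaling exponent
(DFA-α, higher = less complex) and sample entropy (SEn, lower = less
complex). The two structure measures are complementary — fractal scaling
is frequency-based and tolerant of nonstationarity, entropy is
information-based — and are expected to correlate negatively across
signals, which the test-suite verifies on a sweep of synthetic power-law
noises.

The task geometry is fixed by the experimental design the package
emulates: 20-s trials sampled at 120 Hz; the stabilizing hand holds 12% of
the participant's maximum voluntary contraction (MVC); in the
role-differentiated condition the other hand tracks a 0.2 Hz sine between
5% and 12% MVC; the initial 6-s ramp is excluded from every analysis.

## Preprocessing

* **Ramp exclusion** uses a half-open-interval convention: the first
  retained sample is the one at exactly `t = ramp_s` (0-based start index
  `floor(ramp_s * rate_hz)`), which yields the deterministic count
  `120 × (20 − 6) = 1680` at the defaults.
* **%MVC normalization** (`100·force/MVC`) and ramp exclusion commute;
  both orders are supported and tested for elementwise equality.
* **z-scaling** (mean 0, SD 1, sample SD with `n − 1`) precedes sample
  entropy only. The sample-SD convention is used everywhere, consistent
  with the CV definition.
* **No detrending or filtering** is applied before any measure: the
  analysis chain the package mirrors describes none, and silent filtering
  would change both structure measures.
* **Aggregation**: when several trials fall into one
  participant × condition × hand × timepoint cell, measures are combined
  as the unweighted mean (one observation per cell, matching a
  repeated-measures model with cell-level rows). Whether the original
  analysis averaged trials or entered them individually is not knowable
  from the outside; trial-level passthrough is available via
  `pipeline_config(aggregate_trials = FALSE)`.

## The three measures

**CV** is `100·SD/mean`; it errors on zero-mean input rather than
returning an arbitrary value.

**DFA** integrates the mean-centered series, partitions the profile into
`floor(N/m)` non-overlapping windows *taken forward from the start* (the
trailing remainder is discarded; no backward pass), detrends each window
with a least-squares line, and aggregates per-window RMS deviations into
`F(m)`. Two aggregation rules are provided:

* `mean_rms` (default): the mean of per-window RMS values — a literal
  reading of "root-mean-square deviation … average over all segments";
* `pooled_rms`: the canonical Peng variant (RMS over all pooled
  residuals).

Their slopes agree asymptotically; the default is the literal reading. The
exponent is the OLS slope of `log F(m)` on `log m` with equal weight per
retained window — base-invariant and matching the log-linear definition.
The default grid is 30 log-spaced integer windows from 10 to 200
(duplicates after rounding removed). A precondition requires at least four
distinct windows and `N ≥ 2·max(m)`; a fluctuation of exactly zero at any
window (deterministic-after-detrending input) is a classed error rather
than `-Inf` in the fit.

**Sample entropy** uses template length `m = 2` and radius `r = 0.25` by
default. Both template sets (lengths `m` and `m+1`) are taken at the same
`N − m` starting positions so that `Cm/Cm+1` is a genuine conditional
probability; self-matches are excluded; `SEn = ln(Cm/Cm+1)`. Two design
points deserve note:

* **Distance norm.** The definition followed here states Euclidean
  distance between segments, so Euclidean is the default; the
  Richman–Moorman convention (and most reference implementations) use the
  Chebyshev maximum norm, which is available via
  `sen_config(norm = "chebyshev")` for cross-tool comparison. Defaults are
  documented rather than silently canonical.
* **Radius units.** `r` is an absolute threshold applied *after*
  z-scaling, which makes the absolute and SD-relative interpretations
  coincide; unscaled input is rejected, not silently scaled.
* **Undefined cells.** If no `m+1` matches exist the entropy is undefined
  and is reported as missing (classed error at the single-series level,
  `NA` in batch/grid output), never imputed as 0 — imputing would bias
  group means toward regularity.

The robustness grid (`m ∈ {2,3,4} × r ∈ {0.2, 0.25, 0.3}`) recomputes SEn
over the neighborhood of the defaults; undefined cells stay `NA` and never
abort the remaining cells.

## Synthetic data: what it emulates, what it does not

The generator is a *stated world*, not a tuning dial; its defaults encode
the design it emulates and are not adjusted to make tests pass.

* **Benchmark noise**: white (i.i.d. Gaussian), Brownian (its cumulative
  sum), and power-law noise synthesized in the frequency domain with
  amplitudes `∝ f^(−β/2)`, `β = 2α − 1`, and uniform random phases. The
  spectral route gives analytic control of the target exponent; an
  independent periodogram-slope oracle (not DFA) verifies the synthesized
  spectrum in the tests. `target_alpha` is restricted to `[0.3, 1.7]`,
  bracketing the white-to-Brownian range of interest.
* **Trials**: ramp → target + colored noise (default exponent 1.38 and SD
  0.8 %MVC, chosen to reproduce the observed DFA-α ≈ 1.38 and CV ≈ 6–7%
  for real constant-force series in this task) + white measurement noise
  (0.05 %MVC, a small sensor floor). Crosstalk is additive linear leakage
  of the mean-centered manipulating oscillation into the stabilizing
  channel — the simplest mechanism that produces excess stabilizing-hand
  power at 0.2 Hz (the mirror-movement signature) without committing to a
  neural model.
* **Cohort**: group sizes 77/52/33/11 (CHI) and 55/34/15/3 (MCI) at
  timepoints 1–4 with *nested* dropout (later samples are subsets of
  earlier ones). Screening scores are drawn by rejection sampling so that
  the MCI rule (MoCA < 26 **and** min CERAD-NP z < −1.5) reproduces the
  assigned label by construction — scores and labels can never contradict.
  MoCA means/SDs (27.7 ± 1.2 vs 22.6 ± 1.8), ages, MVC and the female
  fractions per group follow the published cohort description. MoCA drift
  over time is deliberately not modeled.
* **Outcomes** are generated *directly on the measure scale*
  (`X·β + b_i + ε`, treatment coding) because the generative betas are
  defined there; the defaults are the published CV-scale effects
  (intercept 4.33, condition +2.40, group +1.76, hand −0.36, sex +2.20,
  timepoint −0.10, condition×group −0.42, condition×hand +1.24), with
  random-intercept SD 3.5 and residual SD 2.5 chosen once to match the
  observed total CV spread of ≈ 4–5. Signal-level synthesis
  (`signals = TRUE`) exists for end-to-end smoke tests on reduced cohorts;
  it is not the path used for parameter recovery, because the mapping from
  signal parameters to measure-scale betas is not analytically invertible.

A green recovery test therefore establishes that the *inference machinery*
is correct under the stated generative model; it does not establish that
real force signals satisfy that model (no heteroscedasticity, no
autocorrelated residuals, no informative dropout — all absent from the
generator by design).

All randomness flows from one per-run seed through named substreams
(`substream_seed`), so adding a stage never perturbs another stage's
stream, and identical configs give byte-identical outputs.

## Mixed-effects inference

One Gaussian random intercept per participant; fixed effects built
stepwise: intercept → main effects one at a time (condition, group, hand,
sex, timepoint) → the ten 2-way interactions one at a time → condition ×
group × timepoint → the four 3-way interactions among condition, group,
hand, sex. The phrase "3-way interactions … condition, group, hand, and
sex" is ambiguous about a 4-way product; the package implements the 3-way
set and exposes the 4-way term behind `include_four_way = TRUE`, asserting
neither as canonical.

* **Coding**: treatment (dummy) coding, reference levels bimanual
  constant, CHI, left, male; timepoint numeric 1–4 (a single slope). This
  reproduces the conventional contrast-table row structure
  ("Condition (RD-BC)" etc.).
* **ML vs REML**: model comparison (AIC, likelihood-ratio tests) uses ML;
  the selected model is refitted by REML for the reported coefficient
  table. `likelihood_ratio_test` refuses REML fits.
* **Denominator df**: a containment-style rule with two strata. A
  fixed-effect column constant within every participant is tested against
  the participant stratum (`n_participants − p_between − 1`); columns that
  vary within participants — and the intercept, which is estimated at the
  innermost level — use the observation stratum
  (`n_obs − n_participants − p_within`). This reproduces the two df strata
  visible in published tables of this kind (≈ participant-level for group
  and sex, ≈ observation-level for hand); the exact df algorithm of any
  given historical fit is unknowable, so printed df are treated as fixed
  inputs when checking effect-size arithmetic, never re-derived.
* **Effect size**: `r = √(t²/(t²+df))`, sign discarded. The acceptance
  suite verifies this conversion reproduces every published (t, df) → r
  row at 2 decimals.
* **Singular designs** raise a classed error naming the aliased columns;
  during stepwise runs on small data, aliased steps are skipped (`NA` in
  the trace) rather than fatal. Non-convergence is recorded as a status
  flag, and contrast summaries refuse non-converged fits.
* **Ties in AIC** break toward the smaller model; no multiple-testing
  correction is applied (none is applied in the analysis being mirrored).
* Missing cells (undefined SEn) are dropped listwise per outcome — mixed
  models tolerate the resulting imbalance.

## Numerical choices and degenerate inputs

* Boundary fits with zero residual variance can make `lme4`'s
  variance–covariance extraction fail; the package then reports zero
  standard errors (the correct degenerate limit) rather than aborting.
* `exclude_ramp` errors when nothing remains; `zscale` errors on constant
  input; CV errors on zero mean. All errors carry classed conditions
  (`forcefluct_*`) so callers can distinguish them programmatically.
* The DFA brute-force oracle and the production routine share no code
  (literal `lm()` loops vs closed-form vectorized OLS); likewise for
  sample entropy (triple loop vs `dist()`-based counting). Equivalence is
  asserted to 1e-10 on ≤128-sample fixtures.
* The bundled 64-sample DFA fixture uses windows {4, 8, 16, 32}: the
  production precondition requires at least four distinct window sizes
  for a meaningful log–log fit, so a three-window fixture would be
  rejected by the very routine it is meant to exercise.

## Known limitations

* Trials shorter than ~30 s are at the lower edge of what sample entropy
  resolves reliably; the 14-s analyzed segment follows the emulated
  design, not entropy best practice.
* The containment df rule is one defensible convention among several
  (Satterthwaite and Kenward–Roger being others); df-sensitive quantities
  (p, r) therefore match other software only approximately.
* The generator's measure-scale route cannot detect errors that live only
  in the signal-to-measure mapping; the end-to-end smoke path covers that
  mapping but with loose assertions (realistic ranges, not betas).
* Inphase/antiphase coordination modes, MVC measurement, artifact
  rejection and plotting aesthetics are out of scope.
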