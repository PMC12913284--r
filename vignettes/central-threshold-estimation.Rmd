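---
title: "Estimating the central timing threshold from ternary-response judgments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating the central timing threshold from ternary-response judgments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(centhresh)
```

## The problem

When two stimuli `x` and `y` (say, a light and a click) are presented
with a stimulus-onset difference `d = t_y - t_x`, the precision of
temporal-order perception is limited by two distinct sources: variability
in the peripheral latencies with which the two sensory signals reach a
central comparator, and the temporal resolution (threshold) of that
comparator itself. Binary tasks — "which came first?" or "simultaneous or
not?" — measure a compound of both sources: the slope or width of a
single psychometric function reflects peripheral *and* central noise, so
it cannot tell us whether the central threshold depends on how the
periphery was stimulated.

The ternary-response task resolves this. The observer reports `xy`
(`x` first), `yx` (`y` first), or `si` (simultaneous), which yields two
psychometric functions:

* the right function `F_R(d) = P(xy | d)`, and
* the left function `F_L(d) = P(xy | d) + P(si | d) = 1 - P(yx | d)`.

Under independent-channels models the central arrival-time difference is
`DA = DL + d`, the sum of the peripheral latency difference `DL` and the
physical offset `d`, and the comparator judges `DA` against a threshold
`C`: `xy` when `DA >= C`, `yx` when `DA <= -C`, `si` otherwise. The key
consequence is additivity: the location of `F_R` involves the latency
term plus `C`, that of `F_L` the same latency term minus `C`, so

```
E(F_R) - E(F_L) = 2 E(C),
```

with the peripheral term cancelling exactly. **Half the horizontal
distance between the two functions therefore estimates the central
threshold free of peripheral latencies** — no distributional assumptions
about `DL` required. This identity is the backbone of every estimator in
the package, and its empirical violation across stimulus conditions
(threshold *invariance* testing) is the scientific question the pipeline
answers.

## Nonparametric estimator: monotonized Spearman–Kärber

`sk_threshold()` estimates `E(F_R)` and `E(F_L)` by treating the
increments of each (monotone) empirical function as a discrete
probability distribution on the `d` axis and taking its mean:

1. **Monotonization.** Sampling noise makes raw proportions non-monotone,
   and the mean-of-increments formula requires a CDF-like input. We use
   weighted pool-adjacent-violators (`pav_monotonize()`), with weights
   equal to the per-`d` trial totals; for binomial data this is the
   maximum-likelihood monotone fit. `F_R` and `F_L` are monotonized
   separately (each as a nondecreasing function, which for `F_L` is
   equivalent to forcing `P(yx | d)` nonincreasing). Because the two
   fits are separate, the monotonized `F_R` can in principle exceed
   `F_L` at some `d` in extreme samples; the means are still computed
   independently and a diagnostic warning is emitted.
2. **Anchoring.** The method needs the `d` values at which the functions
   reach exactly 0 and 1. These anchors are hard constraints appended
   outside the observed grid (defaults: one grid step beyond the
   extremes; the built-in layouts use ±225 ms for the ±200 ms grid and
   ±400 ms for the ±350 ms grid). Observed proportions are never
   clipped. Anchor placement matters only through the mass the true
   function leaves outside the grid; with the built-in designs and
   realistic slopes this is well below a millisecond of bias, and the
   anchor-perturbation test (±25 ms) confirms that invariance
   conclusions do not flip.
3. **Threshold and PSS.** With means `m_R` and `m_L`, the central
   threshold is `(m_R - m_L) / 2` and the midpoint `(m_R + m_L) / 2`
   estimates the point of subjective simultaneity (it equals `-E(DL)`
   under the model).

## Parametric estimator: the two-threshold observer model

Empirical psychometric functions in this task are sometimes genuinely
non-monotone, which the single-threshold observer cannot produce. The
two-threshold model (`ttm_probabilities()`, `fit_two_threshold()`)
generalizes the decision rule: with `DL ~ Normal(mu, sigma^2)`,

* `|DA| < c_su`: simultaneity is perceived (`si`);
* `|DA| >= c_o`: order is perceived veridically;
* `c_su <= |DA| < c_o`: successiveness is detected but order must be
  guessed — `xy` with probability `gamma`.

This yields closed-form trinomial probabilities via the Gaussian CDF and
separates a *successiveness* threshold `c_su` from an *order* threshold
`c_o >= c_su`, each of which can be tested for invariance on its own.
Our form is deliberately minimal: fixed thresholds, a Gaussian latency
difference, and a single `gamma` shared by both guess regions (the
simplest parameterization consistent with "order must be guessed");
side-specific guessing biases or trial-variable thresholds are not
modelled. Lapses and finger errors are handled by data cleaning before
fitting, not by extra model parameters, mirroring the pipeline order of
the task's standard analysis. Parameter-recovery simulations, not any
external implementation, define the correctness of this component.

Fitting maximizes the multinomial log-likelihood over
`(mu, log sigma, c_su, delta, logit gamma)` with `c_o = c_su + delta`,
`c_su, delta >= 0` enforced by L-BFGS-B box constraints — the ordering
`c_o >= c_su` therefore holds by construction. A probability floor of
1e-9 keeps boundary values finite. The likelihood is multimodal when the
guess region is nearly flat, so the optimizer restarts (default 20) from
a data-driven base start — location from the Spearman–Kärber midpoint,
scale from the quartile span of the monotonized right function — plus
Latin-hypercube jitter, and keeps the best optimum. Convergence uses a
relative log-likelihood tolerance of 1e-6.

## Bootstrap inference

All interval estimates are percentile bootstraps: trials are resampled
within each `(condition, d)` cell — multinomial draws with the observed
cell proportions and the observed cell size, the natural nonparametric
scheme for a fixed-design psychophysics experiment — the estimator is
recomputed on each of `B = 1000` resamples (parametric refits warm-start
at the full-data fit), and the 2.5% and 97.5% points of the bootstrap
distribution form the 95% CI. Percentiles are inverse-empirical-CDF
(type 1) quantiles, i.e. exact order statistics of the draws.
`invariance_test()` bootstraps the *difference* between two conditions,
resampling both on every iteration, and declares threshold invariance
violated exactly when the difference CI excludes zero. Simulation shows
the nonparametric CI covers the generating threshold in about 93–96% of
replications at the built-in design sizes, close to nominal.

Group-level aggregation uses the ordinary paired two-sided t test with
the within-subject effect size `d_z = mean(diff) / sd(diff)`
(`paired_t_dz()`); `practice_curve()` splits sessions into consecutive
levels (e.g. 20 sessions into four levels of five) and estimates a
threshold with CI per level and condition.

## What the synthetic observer does and does not emulate

`simulate_observer()` generates complete trial-level runs of the two
built-in layouts: the intramodal-vs-intermodal design (25 `d` values,
-200 to +200 ms in steps of 16.6 ms, 400 trials per `d` per condition,
20 sessions of 20 condition-alternating blocks) and the strong-vs-weak
intensity design (15 `d` values, ±350 ms in 50 ms steps, 180 trials per
`d` per condition, 5 sessions of 18 blocks with intensities interleaved
within block). Responses come from the two-threshold decision rule;
contamination — premature (RT < 150 ms) and delayed (RT > 5,000 ms)
responses, double-click lapses, and corrected finger errors — is applied
independently per trial afterwards at the mean rates reported for
trained observers (0.2%, 0.1%, 0.2%, 1.0%). Corrected trials keep their
valid final response, and cleaning must not discard them.

Defaults that the design itself does not pin down were chosen once on
subject-matter grounds: the latency-difference SD defaults to
`sigma = 40` ms, a realistic value for practiced observers whose
psychometric functions are steep relative to a ±200 ms grid (and which
keeps essentially all function mass inside the anchored range, so the
Spearman–Kärber anchoring bias is negligible); `gamma` defaults to 0.5
(unbiased guessing).

The simulator is a model organism, not a human: it has no sequential
dependencies, criterion drift, practice effects, or RT structure beyond
the contamination thresholds, and its latency difference is exactly
Gaussian. Passing tests therefore certify the *estimators* — that they
recover known thresholds, ignore latency shifts, and attain nominal
coverage under the model — not that real observers satisfy the model's
assumptions.

## Numerical and design choices

* **Tie-breaking.** `DA` exactly at a threshold responds on the weak
  side of the detect rule (`xy` at `DA >= c_o`, `si` strictly inside
  `(-c_su, c_su)`); measure-zero under the Gaussian but fixed for
  reproducibility.
* **Exclusion boundaries are strict** (`rt < 150`, `rt > 5000`): an RT
  of exactly 150 or 5,000 ms is retained. Exclusion categories are
  applied in a fixed priority order (practice, block exclusion,
  premature, delayed, lapse) so the cleaning report is additive.
* **Block exclusions** (hardware failures and the like) are declared
  explicitly via `exclude_blocks`, never auto-detected.
* **Degenerate inputs.** Zero-trial cells abort estimation with the
  offending cells named; perfectly separated data produce a zero-width
  bootstrap CI; parametric fitting requires at least five occupied `d`
  cells; a collapsed guess region (`c_su = c_o`) leaves `gamma`
  unidentified, which is expected and harmless.
* **Determinism.** Every stochastic function takes a seed, restores the
  caller's RNG state, and is bit-reproducible; pipeline JSON output is
  byte-identical across repeated runs of the same config.
* **Problem sizes.** Validation simulations in the test-suite use the
  full built-in designs where the check concerns them (20,000-trial
  end-to-end runs), and 20 replicate datasets for parameter recovery /
  200 replications at `B = 500` for CI coverage — sizes at which
  Monte-Carlo error is small relative to the tolerances being asserted.

## Known limitations

* The per-subject thresholds shipped in `load_fixture_tables()` are
  ms-rounded published values; group statistics computed from them agree
  with the published ones to the last printed digit, but raw-data
  reanalysis is out of scope.
* Alternative observer models (separate simultaneity/order centres,
  latency-mixture error models, variable moment models) and model
  comparison are not implemented.
* The bootstrap is percentile-only; BCa or studentized intervals are not
  provided, matching the task's standard analysis.
* RTs are modelled only as far as the contamination thresholds require;
  do not use the simulator to study RT distributions.
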