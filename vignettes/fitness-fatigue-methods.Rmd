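---
title: "Methods: the optimized fitness-fatigue model and its estimation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the optimized fitness-fatigue model and its estimation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fitfatigue)
```

## The model

`fitfatigue` models daily training performance as the difference between an
adaptation component and a fatigue component:

$$P_n = \underbrace{(a\,e^{-\tau_a t} + K_a W_n + C_1)}_{A_n} -
        \underbrace{(f\,e^{-\tau_f t} + K_f W_n + C_2)}_{F_n}$$

with $t$ the calendar day within the training period (first attended session
on day 1), $W_n$ the day's normalized external load, decay rates
$\tau_a, \tau_f > 0$ per day, specificity coefficients $a, f$ of
unconstrained sign, load gains $K_a, K_f$, and integration constants
$C_1, C_2$ treated as adjustable parameters. The modelling assumptions are:
(1) no overtraining occurs, so one smooth adaptation and one smooth fatigue
trajectory suffice; (2) both components decay over the training period at
individual rates while each day's load contributes an instantaneous gain;
(3) performance is their difference.

Two points deserve emphasis because they are easy to misread:

* **This is not the classic impulse-response convolution.** The decay terms
  are single global exponentials in the day index, not convolutions over the
  history of past loads. The closed form above is implemented verbatim
  (`evaluate_optimized()`), and the convolution variant is out of scope. A
  formal caveat: the decay building blocks are used in the affine form
  $a\,e^{-\tau t} + C$; taking the additive constant as part of the
  component (rather than as a multiplicative initial condition of the
  underlying first-order decay ODE) is part of the model's definition here.
* **The day index is global.** $t$ accumulates from the first session and is
  never reset per session. Users expecting per-impulse dynamics should treat
  the fitted exponentials as period-level trends.

### Identifiability and canonicalization

Adding any constant to both gains, or to both integration constants, leaves
every prediction unchanged: only $\Delta K = K_a - K_f$ and
$\Delta C = C_1 - C_2$ are identifiable, alongside the exponential pair.
The estimator therefore works in the 6-parameter space
$(a, \tau_a, f, \tau_f, \Delta K, \Delta C)$ and reports 8 coefficients
under the convention $K_f = 0$, $C_2 = 0$. The two exponential components
can additionally be relabelled: swapping the decay rates while negating both
specificity coefficients preserves all predictions. `canonicalize()` fixes
the labels so the fatigue slot decays at least as fast as the adaptation
slot ($\tau_f \ge \tau_a$), which matches the physiological reading. An
exact rate tie is resolved by specificity magnitude ($|a| \ge |f|$) — with
equal rates the two components are genuinely indistinguishable and only
$a - f$ matters, so any sign-preserving relabelling is a convention; the
magnitude rule is the one achievable without changing predictions.

## Indicators and normalization

External load is the 1 s rectangular sum of speed × resistance over the
session (the data are 1 Hz samples; a trapezoid rule differs negligibly and
is not offered). The internal-load indicators follow their defining formulas
on raw measurements:

* `ΔHRR1` and `HRr%` read "average heart rate 1 minute / 15 seconds after
  training" as window means over post-exercise seconds 1–60 and 1–15. An
  instantaneous second-15 reading is available via
  `compute_hrr_indicators(..., stage1_mode = "instant")`.
* `TL_HRV` is computed on raw RMSSD values of the three rest windows; the
  0.1–1 normalization applies to the resulting indicator series, not to its
  RMSSD inputs. A day with `Post30 = Post5` has an undefined indicator and
  is flagged (`NA`) and dropped before fitting, with a logged count.
  Negative values (`Post30 < Post5`, i.e. HRV still depressed at 30 min) are
  passed through; they are physiologically meaningful and the model places
  no sign constraint on the output.

Normalization maps each subject's series affinely onto $[0.1, 1]$. The 0.1
floor exists so that the output indicator $P = W_{norm} / I_{norm}$ can
never divide by zero and is bounded in $[0.1, 10]$. By default the min/max
are taken over the subject's full series — learning and test days alike —
mirroring the study design of normalizing before splitting. This leaks the
test days' range into the learning phase; `enrich_day_table(scope =
"learning")` restricts the map to the learning window (test values are then
clipped to $[0.1, 1]$) for users who want a strictly causal pipeline.

## Estimation

`fit_optimized()` minimizes the sum of squared errors with bounded
Levenberg–Marquardt least squares (`minpack.lm::nls.lm`), the standard R
analogue of a bounded trust-region NLS. The landscape of a two-exponential
difference is multimodal, so the fit uses 32 seeded multistarts: decay rates
drawn log-uniformly within their bounds, linear coefficients from N(0, 1).
Start 1 is always the closed-form solution of the nested original model
($a = f = 0$, $\Delta K = \sum P W / \sum W^2$, $\Delta C = 0$), which
guarantees SSE(optimized) ≤ SSE(original) on every dataset rather than only
with high probability. Bounds default to $\tau \in [10^{-4}, 5]$ per day and
$|a|, |f|, |\Delta K|, |\Delta C| \le 100$; they are wide relative to any
plausible training response and exist to keep the optimizer out of
degenerate flat regions. All bounds, the start count, the seed, and the
minimum learning size (10 observations) are exposed via `fit_options()`.

The chronological split takes the first $\lfloor 0.8 n \rfloor$ observations
as the learning set; the floor convention keeps the test set non-empty for
any fraction below 1. Days with undefined indicators are dropped before
splitting. $R^2$ is $1 - SSE / \sum (P_{obs} - \bar P_{obs})^2$; it can be
negative on pathological fits and is flagged `NA` on a constant observed
series.

## Evaluation battery

Test-set quality is summarized by RMSE and MAPE; the per-day absolute
percentage errors feed a Spearman rank correlation against the prediction
horizon (days since the last learning session). The Spearman p-value is
computed by exhaustive permutation enumeration for 8 or fewer test days and
by the t approximation otherwise; test-set $R^2$ is also emitted by the CLI
report but is a convenience output, not part of the core battery. The
optimized-versus-original comparison takes one metric value per subject per
model, tests the paired differences with Shapiro–Wilk, then applies a paired
t-test (normality not rejected at 0.05) or a Wilcoxon signed-rank test
(zeros discarded, average ranks for ties, exact p for small samples as
provided by `stats::wilcox.test`), and Bonferroni-corrects with family size
$m = 3$ by default — the three indicators compared per metric. $m$ is
config-exposed because the family definition is a design choice.

## The synthetic-data generator

The generator's defaults are the reference study conditions: 13 subjects,
12 weeks, 3 planned sessions/week on a Monday/Wednesday/Friday grid, 30 min
sessions, and an attendance rate of 0.885 realized as uniform random removal
of planned days (misses in such cohorts are idiosyncratic — illness,
schedule clashes — not structured). Attended counts are exactly
`round(rate × planned)`.

Stream-level emulation produces what a heart-rate strap and ergometer would
record: constant speed/resistance at the session's set point (so the
external-load integral is exactly speed × resistance × duration), heart rate
ramping linearly from 60% to the 85% HR\_max submaximal target in the final
minute, single-exponential post-exercise recovery
$HR(s) = HR_{rest} + (HR_{peak} - HR_{rest}) e^{-s/\tau_{rec}}$ with
$\tau_{rec}$ drawn per session from U(40, 90) s (day-to-day autonomic
variation is what makes the HRR indicators informative), and R-R windows of
$60000 / HR$ ms plus iid Gaussian jitter. The jitter standard deviation is
the target RMSSD divided by $\sqrt 2$, because the RMSSD of iid jitter
converges to $sd \cdot \sqrt 2$ — this analytic relation is what makes the
generator calibratable and testable.

The day-level noise model is additive Gaussian on the performance
observation with sd 0.05 by default — roughly 5% of the output indicator's
dynamic range, a magnitude consistent with day-to-day biological variation
in HRV/HRR-derived quantities. No published noise magnitude exists for this
design, so the value is a package choice, exposed via `noise_model()` and
held fixed across all simulation studies.

Ground-truth parameters for recovery studies (`default_subject_parameters()`)
are drawn once per cohort from ranges chosen for identifiability on a
12-week horizon: slow adaptation decay $\tau_a \sim U(0.02, 0.08)$/day
(half-life 9–35 days), faster fatigue decay $\tau_f \sim U(0.15, 0.40)$/day
(half-life 2–5 days), specificity $\sim U(0.6, 1.4)$, $\Delta K \sim
U(0.3, 0.8)$, $\Delta C \sim U(0.1, 0.4)$. Rates much slower than
$\tau_a$'s lower bound are indistinguishable from a constant over 12 weeks;
rates much faster than $\tau_f$'s upper bound decay inside the first week
and leave no signal on a 2–3-day sampling grid.

**What the generator does not emulate:** ectopic beats and measurement
artefacts in R-R series, heart-rate drift within sessions, menstrual-cycle
or seasonal attendance structure, overtraining dynamics, and any coupling
between the day-level performance noise and the stream-level noise. Passing
recovery tests therefore show that the estimator inverts the generative
model under realistic noise — not that real wearable data meet these
assumptions.

## Numerical choices and problem sizes

* Serialized numbers carry 12 significant digits so byte-level determinism
  checks on reports are meaningful.
* The recovery study used in tests and the acceptance script runs 13
  subjects × 36 sessions with noise sd 0.05 and checks median relative
  errors (≤ 25% on the decay rates, ≤ 10% on $\Delta K$, $\Delta C$); the
  decay rates are intrinsically harder than the linear coefficients because
  their information concentrates in the early weeks. Noise-free refits reach
  SSE below $10^{-8}$ (in practice $10^{-30}$, i.e. interpolation).
* The grid-search oracle for the fitter uses 11 points per axis over the
  6-D bounded box; the fitted SSE must not exceed the grid minimum.
* All randomness flows through explicit integer seeds; package functions
  save and restore the caller's RNG state.

## Known limitations

The model is a period-level description: it cannot express super-compensation
timing after individual sessions, and the global-$t$ exponentials absorb any
early-period trend regardless of cause. The default normalization is
non-causal (see above). Parameter recovery degrades when the true decay
rates fall outside the window the sampling design can see, and the reported
8-coefficient form is a convention over a 6-dimensional identifiable family
— individual gain coefficients should never be interpreted in isolation.
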