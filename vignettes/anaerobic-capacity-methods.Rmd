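---
title: "Estimating anaerobic capacity: models, assumptions and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating anaerobic capacity: models, assumptions and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(anaerocap)
```

Anaerobic capacity (AC) — the finite amount of ATP resynthesis available
from phosphocreatine, stored ATP and anaerobic glycolysis during short
exhaustive exercise — cannot be measured directly. `anaerocap` implements
the four estimators in common use for constant-load cycling, together with
the gas-exchange plumbing they stand on and a synthetic physiology
generator that makes every stage testable by parameter recovery.

## The four estimators

**Maximal accumulated oxygen deficit (MAOD).** End-bout VO~2~ (last-30-s
mean) from five submaximal bouts (Δ10–Δ80, where Δx = GET + x% of the
GET-to-VO~2~peak interval) is regressed on power by ordinary least
squares. Extrapolating the line to the supramaximal power (120%
VO~2~peak) and multiplying by that bout's time to exhaustion gives the
total O~2~ demand in litres; subtracting the measured accumulated VO~2~
(trapezoidal integral of the bout) gives the O~2~ deficit. The deficit is
reduced by 10% for the contribution of body oxygen stores and converted
at 20.9 kJ·L^−1^:

$$\mathrm{MAOD} = (\mathrm{demand} - \mathrm{accumulated\ VO_2})
  \times 0.90 \times 20.9\ \mathrm{kJ}.$$

In a two-condition crossover the demand line and the criterion bout can
come from different arms, giving the three variants CAF–CAF, CAF–PLA and
PLA–PLA (`maod_matrix()`). To remove any effect of exhaustion itself on
the Δ80 VO~2~, that bout is evaluated at *isotime* — the shorter of the
two conditions' Δ80 exhaustion times; isotime truncation is applied only
to the Δ80 point, nowhere else.

**Alternative MAOD.** The 10-min recovery VO~2~ after the supramaximal
bout is fitted with a biexponential with a shared delay δ,

$$\dot VO_2(t) = \dot VO_{2\mathrm{base}} + A_1 e^{-(t-\delta)/\tau_1}
  + A_2 e^{-(t-\delta)/\tau_2}, \qquad t \ge \delta,$$

whose fast component is the alactic (phosphagen) energy,
$A_1\tau_1/60 \times 20.9$ kJ. The lactic component converts blood
lactate accumulation (peak post-exercise minus rest) at
3 mL O~2~·kg^−1^ per mmol·L^−1^. The slow term (A~2~, τ~2~) is estimated
but deliberately carries no energy. A note on the delay: evaluated
verbatim for *all* t the expression above is not identifiable — shifting
δ only rescales the amplitudes by $e^{\delta/\tau}$ — so the package
adopts the standard delayed-onset reading in which the curve holds
$\dot VO_{2\mathrm{base}} + A_1 + A_2$ before the delay and decays after
it. The generator and the fitter share this form. A per-component-delay
variant is exposed (`per_component_delay = TRUE`) but is not the default.

**Critical power.** Three algebraically equivalent two-parameter models
of the power–duration relationship are fitted to the (power, time to
exhaustion) points of the Δ80, 100% and 120% VO~2~peak bouts:
$t = W'/(P - \mathrm{CP})$ (nonlinear), $W = W' + \mathrm{CP}\,t$ (work
on time) and $P = W'/t + \mathrm{CP}$ (power on 1/t). On exact hyperbolic
data all three return identical parameters; under noise they weight
errors differently, and the model with the lowest standard error of W′
is selected. W′ of the selected model (in kJ) is the AC estimate.

**Gross efficiency.** Metabolic power is
$\mathrm{MetP}(W) = \dot VO_2 \times (4940\,\mathrm{RER} + 16040)/60$.
GE is the warm-up external power divided by MetP of the warm-up
(last-30-s means), valid only while RER < 1.00 — which is why the
warm-up sits at 90% GET. During the supramaximal bout MetP is computed
from VO~2~(t) assuming RER = 1.00 and GE is assumed stable above the
GET; the anaerobic mechanical power $P_{ext} - \mathrm{GE}\cdot
\mathrm{MetP}(t)$ is integrated over the full bout from t = 0 (the
on-transient seconds included), negatives integrated as-is, since
clamping would bias the total upward.

## Gas-exchange conventions

All averaging and integration happens after linear interpolation onto a
1-s grid (`resample_uniform()`): irregular breath timing would otherwise
weight the statistics, and a 1-Hz grid preserves 30-s windows and the
breath-level structure. Summary VO~2~ values are time-weighted last-30-s
means. Accumulated VO~2~ is a trapezoidal integral of L·min^−1^ over
seconds, divided by 60. Time is t = 0 at bout onset; recovery series
restart at t = 0 at exercise end. Units are fixed throughout: s,
L·min^−1^, W, kJ.

The gas exchange threshold is automated as the v-slope breakpoint: a
continuous two-segment regression of VCO~2~ on VO~2~ scanned over every
interior candidate breakpoint, minimising total SSE, with the first and
last 10% of samples excluded to avoid edge artifacts and a declared
failure ("no GET detected") when the second slope does not exceed the
first. This is a single-criterion automation of what is classically a
multi-criterion visual call (ventilatory equivalents and end-tidal
pressures are not implemented), and downstream reports should treat the
returned `confidence` (1 − SSE~2seg~/SSE~1seg~) accordingly.

## Numerical choices

* **Off-kinetics fit** (`fit_off_kinetics()`): bounded
  Levenberg–Marquardt on the 1-Hz series. Bounds τ~1~ ∈ [10, 120] s,
  τ~2~ ∈ [120, 1200] s (this enforces component identifiability),
  δ ∈ [0, 30] s, amplitudes ∈ [0, 5] L·min^−1^. Starts: baseline = mean
  of the last 60 s, A~1~ = first sample − baseline, τ~1~ = 40 s,
  A~2~ = A~1~/4, τ~2~ = 400 s, δ = 5 s, with up to four perturbed
  restarts if the initial Jacobian is singular. Non-convergence is
  reported in the result (`converged = FALSE`); energy computation
  refuses unconverged fits.
* **Hyperbolic CP fit**: started from the inverse-of-time
  linearisation; the W′ standard error comes from the linearised
  covariance at the optimum. Standard errors tied within a relative
  1e-9 (e.g. all three models on noiseless data) are broken in the
  fixed order inverse-of-time, work–time, hyperbolic — the first being
  the model the selection favours in practice on three-point data.
* **Degenerate inputs** are errors, not silent results: fewer than
  three power–duration points (SEE undefined), duplicate durations,
  a demand line from a single power, accumulated VO~2~ exceeding
  estimated demand (a mis-specified demand line), negative lactate
  accumulation, RER outside [0.6, 1.3].
* **Repeated-measures ANOVA** uses the classical univariate
  within-subject partition (each effect against its own
  subject-interaction stratum) with no sphericity correction — a
  documented limitation, matching common practice in this literature.
  A zero effect sum of squares is reported as F = 0, p = 1 even when
  its error stratum is also zero (the 0/0 case on noise-free additive
  data). Bonferroni adjustment is min(1, p·m).

## The synthetic physiology generator

`make_participant()` draws a ground-truth physiology centred on a
recreationally active male cohort: body mass 74.1 ± 7.0 kg, VO~2~peak
2.99 ± 0.39 L·min^−1^, GET near 52% of VO~2~peak, demand slope
10.3 ± 0.6 mL·min^−1^·W^−1^, on-kinetics τ 30 ± 4 s, slow-component
amplitude 0.25 ± 0.05 L·min^−1^ (ramping linearly to saturation over
180 s, applied only above the GET power — the simplest shape consistent
with a slow component), W′ 19.3 ± 3 kJ, off-kinetics parameters centred
on A~1~ ≈ 1.05 L·min^−1^ and τ~1~ ≈ 52 s, resting lactate
1.4 mmol·L^−1^ and 0.133 mmol·L^−1^ per kJ of anaerobic energy (so that
a ~63 kJ supramaximal deficit yields the typical ~8.4 mmol·L^−1^
accumulation). Breath timestamps are jittered uniformly ±0.5 s around a
2-s mean; VO~2~ and VCO~2~ carry i.i.d. Gaussian noise of sd
0.05 L·min^−1^ per breath. Draws are clamped into physiological ranges.

Two derived-consistency constraints keep the truth fields mutually
coherent for *every* seed rather than just on average:

* CP is drawn as a fraction (0.72 ± 0.06, clamped to [0.55, 0.80]) of
  the Δ80 power and additionally capped at Δ80 power − 35 W, so every
  to-exhaustion workload stays above CP even after a condition's +25 W
  shift; the resulting CP mean (~160 W) and the Δ80/CP ratio (~139%)
  match the cohort the defaults emulate.
* W′ is floored at 150 s × (Δ80 power − CP): severe-domain Δ80 bouts
  last minutes, not seconds. An algebraic consequence worth recording:
  with condition shifts of +25 W CP and −3 kJ W′, the caffeine Δ80 bout
  outlasts placebo exactly when the placebo bout exceeds 120 s, so this
  realism floor is also what makes the Δ80 prolongation hold
  participant-by-participant.
* Gross efficiency is not an independent dial: `ge_true` is derived
  from the drawn demand line as external power over metabolic power at
  the 90% GET warm-up with the generator's sub-GET RER (0.88), ~0.19 on
  average. Overriding `ge_true` back-solves the demand slope in closed
  form instead.

Condition effects are additive CP/W′ shifts only (+25 W, −3 kJ for the
caffeine arm by default); submaximal VO~2~ generation is
condition-independent. Times to exhaustion are exact hyperbolic
arithmetic, `t = W'_{eff}/(P - CP_{eff})` — breath noise does not
perturb them, so duration noise for robustness studies is applied by the
caller. The supramaximal (120% VO~2~peak) protocol additionally carries
the recovery off-transient, generated exactly from the truth's
biexponential at the breath times, and deterministic lactate samples at
1, 3 and 5 min post-exercise peaking at rest + slope × anaerobic energy.
One master seed fans out to per-trial RNG streams keyed by (participant,
workload, condition), so removing one trial does not shift the others.

**What the generator does not emulate** — and hence what passing
recovery tests do and do not show about real data: no VO~2~ drift below
GET, no day-to-day or circadian variability, no pharmacokinetics (the
condition shift is a modelling convenience, not a mechanism claim), no
lactate kinetics beyond the affine peak (production/clearance balance is
not modelled), no analyzer artifacts or outlier breaths, and breath
noise that is white rather than serially correlated. Recovery of truth
parameters here demonstrates the estimators' correctness and their
noise behaviour under these stated conditions, not field accuracy on
human data.

## Problem sizes used in the checks

The end-to-end checks simulate 20 replicate crossover studies of 9
participants (7 workloads × 2 conditions each, plus warm-ups), verify
the Δ80 prolongation and the CP/W′ shift directions per participant, and
require the CAF–CAF vs PLA–PLA MAOD paired t to stay non-significant in
at least 90% of replicates. Off-kinetics noisy recovery uses 100
simulated transients (a 20-replicate median of the τ~1~ error has a
sampling sd of ~1.5 percentage points, which would make the 5% check
itself a coin-flip near the boundary); CP robustness uses 50 replicates
of 5% multiplicative duration noise. These sizes were chosen so the
Monte Carlo error of each checked statistic is small relative to its
threshold.

## Other resolved ambiguities

* The 10% body-store correction is applied to the *deficit*, not to the
  estimated demand (the reading of the analysis description's sentence
  order).
* 30-s averages are computed on the 1-Hz resampled series, not raw
  breaths.
* The ramp-test VO~2~–power line (`analyze_incremental()`) absorbs the
  kinetic lag into its intercept; it is a prescription tool, and the
  demand line for MAOD always comes from the constant-load bouts.
* Isotime truncation applies only to the Δ80 regression point.
* GE anaerobic work integrates from t = 0 over the whole bout.

## Known limitations

GET automation uses the v-slope criterion alone. The RM-ANOVA applies no
sphericity correction. No three-parameter or all-out CP variants, no
alternative lactate O~2~ equivalents, and no intensity-dependent GE are
implemented; these are documented scope boundaries, not oversights.
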