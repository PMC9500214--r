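---
title: "fpclamp methods: the calibrated clamp-experiment model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{fpclamp methods: the calibrated clamp-experiment model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fpclamp)
```

## Scope and model overview

`fpclamp` implements the computational chain of treadmill "clamp" walking
experiments: prescribe either belt speed (speed clamp) or a peak
propulsive-force target via biofeedback on a self-paced treadmill (F_P
clamp), record raw signals, reduce them to final-window trial summaries, and
analyze the pooled relations between peak propulsive force (F_P), walking
speed, and walking economy. Because the package ships no human data, it
includes a synthetic cohort generator whose statistical structure is
calibrated so that the *processing pipeline* — raw waveforms → step peaks →
trial summaries → statistics — recovers a realistic set of group statistics.

The unit of analysis is the trial summary: each participant × clamp ×
intensity cell yields one row (mean speed, mean F_P and F_B in %body weight,
stride length and duration, within-trial speed SD, net metabolic power,
cost of transport), averaged over the final 2 min of a 5-min trial.

## The generative model

### Participants

Anthropometrics are drawn from normal distributions (age 24.7 ± 5.2 yr,
height 1.77 ± 0.11 m, mass 75.6 ± 13.7 kg), preferred overground speed
$V_i \sim N(1.41, 0.09)$ m/s. Habitual F_P is placed on a common pooled
line plus an individual offset:

$$\mathrm{F_P}(v) = \beta_0 + \beta_1 v + \eta_i + \varepsilon,\qquad
\beta_1 = 14.74\ \%\mathrm{BW\,(m/s)^{-1}},$$

with $\beta_0$ fixed so the line passes through 22.0 %BW at 1.41 m/s. This
"common line + participant offset" structure is what makes *pooled*
trial-level regressions meaningful: if instead each participant's F_P were
independent of their preferred speed, between-participant heterogeneity
alone would cap the pooled R² far below the targeted 0.84. Braking force
F_B and stride duration follow the same pattern with slopes 16.99 %BW/(m/s)
and −0.29 s/(m/s).

A note on the stride-timing law: stride duration is *linear* in speed with
the −0.29 s/(m/s) slope (rather than a square-root cadence law), because the
linear form makes the stride-duration variance decomposition analytic and the
slope is the natural calibration anchor. Stride metrics are measured, not
assumed, downstream, so any smooth monotone law would serve.

### Variance calibration

Residual standard deviations are chosen by variance decomposition,

$$R^2 = \frac{\sigma^2_{signal}}{\sigma^2_{signal} + \sigma^2_{resid}}
\quad\Longleftrightarrow\quad
\sigma_{resid} = \sigma_{signal}\sqrt{\tfrac{1-R^2}{R^2}},$$

(`residual_sd_for_r2()`), where $\sigma_{signal} = \beta_1 \sigma_v$ and
$\sigma_v$ is the pooled trial-mean speed SD implied by the population
parameters and the intensity design (±20, ±10, 0%). The F_P residual is set
from the speed-clamp target R² = 0.84 and the F_B residual from 0.63; both
are computed live in `calibration_params()`. Each residual is split equally
between a participant-level offset and trial-level noise; the split does not
affect pooled R² but distributes variance between ANOVA strata plausibly.

The remaining constants interlock several targets at once and were solved
once, at design time, by least squares on a trial-level simulation of the
full design (no waveforms), then frozen in `calibration_params()`:

| constant | value | role |
|---|---|---|
| `econ_curvature` | 3.323 | CoT curvature (J·s²·kg⁻¹·m⁻³) |
| `cot_min_frac` | 0.92 | CoT minimum at 0.92 × preferred speed |
| `np_fp_coupling` | 0.226 | W/kg per %BW of F_P residual off the line |
| net-power residual SD | 0.697 | W/kg |
| stride-duration residual SD | 0.0684 | s (joint stride-length/duration compromise) |
| speed-intent SD | 0.0774 | fractional, F_P-clamp self-selected speed |
| `np_clamp_extra` | 1.0262 | F_P-clamp metabolic surcharge |

The jointly targeted statistics were: F_P-clamp speed~F_P R² 0.76,
cross-clamp averages 0.72 (stride length), 0.46 (stride duration), 0.54
(net power ~ speed), 0.59 (net power ~ F_P), 0.17 (CoT ~ F_P), and the
F_P-clamp net-power offset +8.9%.

Two compromises are inherent and worth stating. First, on a treadmill,
stride length is identically speed × stride duration (belt-travel
correction), so the stride-length and stride-duration R² targets share one
noise knob; the joint solution lands near 0.72 for stride length and ~0.53
for stride duration. Second, requiring the CoT surface to be U-shaped with
its minimum near preferred speed (so CoT at ±20% ≥ CoT at Norm, the "broad
minimum" behaviour) bounds how much monotone CoT-vs-speed trend the model
can carry; the emergent speed~CoT R² is ≈ 0.08 rather than 0.12. Both
sacrificed quantities are secondary; the jointly targeted set above is
recovered within ±0.08.

### Metabolic response surface

Net metabolic power (W/kg) is generated as

$$\mathrm{NP} = v\,\big(c_0 + c_2 (v - 0.92\,V_i)^2\big)
 + n_u\,\big(\mathrm{F_P} - \widehat{\mathrm{F_P}}(v)\big) + \eta_i + \varepsilon,$$

with $c_0 = 2.35$ J·kg⁻¹·m⁻¹: cost of transport CoT = NP/v is a quadratic
with a broad minimum just below preferred speed, and trials whose F_P sits
above the pooled line for their speed cost slightly more. Breath series are
built by *inverting* this surface through the Brockway equation
(16.58/4.51 kJ/L, RER 0.85): steady-state V̇O₂ is set so that final-window
averaging, Brockway conversion, standing-baseline subtraction and mass
normalization return exactly the target net power under zero noise. A 30 s
single-exponential onset occupies the pre-window minutes; the residual
transient (≤ 0.25% at the window boundary) is truncated to zero there so the
zero-noise round trip is exact rather than approximate. Breath intervals are
uniform on 2–5 s (fixed 3.5 s under zero noise) with 1.5% multiplicative
noise per gas channel.

### The F_P clamp and its offsets

F_P-clamp targets follow the protocol: the measured mean peak F_P of the
corresponding speed-clamp trial. The virtual walker realizes the target with
a 2% tracking SD times a 1.4% overshoot (the calibrated F_P offset), then
self-selects the speed its own F_P line implies, times a small surcharge
(+1.1%) so the total speed offset is +2.6%, times 7.7% trial-to-trial intent
noise — the latter is what lowers the F_P-clamp speed~F_P R² from 0.84 to
0.76. Net power in F_P-clamp trials carries a 2.6% direct surcharge
(`np_clamp_extra`); the remaining ~6 percentage points of the +8.9% offset
emerge from walking 2.6% faster on a convex response surface and from
speed-intent variance through that convexity (a Jensen term of ≈ 2%). The
CoT offset (+6.2%) is then implied: CoT = NP/v gives 1.089/1.026 ≈ 1.061.

### Waveforms

Each stance is built from a fixed low-order basis. Vertical GRF:
$A(\sin \pi x + 0.25 \sin 3\pi x)$, $x \in [0,1]$ over the stance — a
smooth, non-negative, double-humped curve peaking at 1.12 body weights that
stays far above the 20 N event threshold except in ~10 ms edge ramps.
AP GRF: one negative half-sine braking lobe centered at 26% of stance and
one positive propulsive lobe spanning 60–90% of stance whose *sampled*
maximum equals the step's F_P peak exactly (the lobe is normalized on the
grid). The braking lobe's width scales as fp/fb and its amplitude is
rescaled (≈1%) for exact discrete impulse balance, as in steady-speed
walking; braking peaks therefore honour their calibrated value to ~1–2%,
which is well inside the F_B residual SD of 2.85 %BW. Stance occupies 60% of
the stride (each double support 10%), sides alternate every half stride, and
step-level noise (3% on peaks, 1% on intervals) averages out across the
~110 steps in the analysis window.

### Controller and walker closed loop

The controller is a dead-zone proportional law applied once per double
support: no change while the double-support average CoP lies within 0.10 m
of treadmill center; otherwise ΔSpeed = sign(CoP) · |CoP| · 0.1 m/s, clipped
to [0.2, 3.0] m/s. Distance is measured from treadmill *center*, as defined,
which makes ΔSpeed jump from 0 to 0.01 m/s at the dead-zone edge; the
discontinuity is accepted as written. Updates are instantaneous steps (the
alternative, ramping between updates, is unspecified) and occur only at
double supports.

The virtual walker drifts fore/aft proportionally to its speed-intent
mismatch, CoP offset = 1.5 m·(m/s)⁻¹ × (v_intent − belt) + 0.03 m positional
noise: a 5% speed mismatch at preferred speed (≈ 0.07 m/s) produces an
excursion just beyond the dead-zone half-width, so the loop converges in
tens of steps and the group-average relative speed stabilizes within the
first minute. Step-to-step intent wander is an AR(1) process in *absolute*
m/s (innovation 0.035 m/s, persistence 0.85). The additive form matters: a
proportional wander would make within-trial speed variability scale with
trial speed and thereby correlate with net power, and the speed-variability
check is null *by construction* in this model.

## Processing pipeline

Gait events: heel strike at upward 20 N crossings of the vertical GRF, toe
off at the subsequent downward crossing, with a 50 ms debounce (sub-debounce
dips within a stance are merged, sub-debounce spikes dropped) — synthetic
data do not need it, noisy force data do. Peak F_P is the maximum anterior
force over the full stance; peak F_B the largest posterior force in the
first half of stance, split at the temporal midpoint (HS+TO)/2. Stride
duration is the time between consecutive ipsilateral heel strikes; stride
length adds the trapezoid-integrated belt travel to the lab-frame heel
displacement (without the correction, treadmill stride lengths would be
near zero). Summaries use only events inside the final window; the same
window bounds the time-weighted breath averaging, so gait and metabolic
quantities describe the same steady-state segment. %BW normalization uses
static weight m·g with g = 9.81 m/s². No GRF filtering is applied to
synthetic data.

Statistics: per-clamp pooled regressions over trial summaries (n = 100
points per clamp at default scale, consistent with trial-level pooling);
the "average R²" is the arithmetic mean of the two clamp-specific values.
The repeated-measures ANOVA computes each effect against its own
subject-interaction stratum (no sphericity correction, α = 0.05), with
ηp² = SS_effect/(SS_effect + SS_error); Tukey post-hocs (studentized range
on the stratum mean square) compare intensity levels, and paired
comparisons between clamps run at each intensity, each with a paired
Cohen's d. The implementation is cross-checked in the test suite against
`stats::aov()` with `Error()` strata.

## Numerical and design choices

* **Analog rate** defaults to 100 Hz (the emulated instrument's native rate
  is 1000 Hz and remains available); event-time quantization at 100 Hz is
  ±5 ms, negligible against stride durations of ~1.1 s, and a default
  20-participant run takes ~20 s on one CPU.
* **Determinism**: one root seed; participant and trial streams are derived
  by fixed integer offsets (`child_seed()`), so identical configurations
  yield byte-identical raw trials regardless of execution order.
* **Degenerate inputs**: stances shorter than 4 samples, empty CoP windows,
  non-finite CoP averages, zero-variance regressors, incomplete ANOVA cells
  and sub-minimum breath counts are rejected with messages; a stance with no
  positive AP force yields peak F_P = 0 and a flag; summaries with fewer
  than 10 window steps carry a low-confidence flag; a constant dependent
  variable yields F = 0, ηp² = 0 rather than 0/0.
* **Bound handling**: hitting a controller speed bound is logged
  (`meta$bound_events`) and the trial continues at the bound.
* **Boundary conventions**: the biofeedback tolerance is inclusive
  ("within 5%"); R² strength boundaries take the lower bin's label
  (0.8 → "strong").

## What the synthetic cohort does and does not establish

The generator encodes the targeted group statistics; the acceptance checks
verify that the *pipeline faithfully recovers that structure from raw
signals* — peak extraction, windowing, stride computation, calorimetric
inversion and pooling introduce no material bias or excess variance. A green
run is a statement about the software chain, not a re-derivation of the
physiology: the F_P–speed coupling, the metabolic surface and the clamp
offsets are inputs, calibrated once from printed group statistics, not
outcomes. Features of real data the generator deliberately omits: marker
dropout and soft-tissue artifact, GRF crosstalk and drift, RER drift and
breath-gas transients beyond first-order kinetics, fatigue and learning
across trials, carry-over between trials (rest periods are irrelevant here),
and any joint-level kinematics.

## Known limitations

* Stride-duration and speed~CoT pooled R² sit ~0.05–0.07 from their nominal
  values, for the structural reasons given above.
* The F_B waveform peak is honoured to ~1–2% (impulse balance takes
  precedence); F_B statistics absorb this inside their residual SD.
* Tukey's procedure is applied per effect family (intensity pairs; clamp
  contrasts at each intensity as paired tests); with only two clamp levels
  the clamp "family" reduces to paired t-tests.
* Whether pooled regressions should average within participant first is a
  genuine analysis choice; trial-level pooling is implemented and flagged.
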