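# fpclamp

Walking speed and the peak propulsive ground-reaction force (F_P) generated at
push-off are tightly coupled, and both shape the metabolic cost of walking.
"Clamp" experiments probe this coupling causally: a **speed clamp** fixes the
treadmill belt speed and lets F_P emerge, while an **F_P clamp** prescribes a
propulsive-force target through real-time biofeedback and lets walking speed
emerge on a self-paced treadmill. `fpclamp` is an R package for biomechanics
and human-movement researchers that implements the complete computational
chain of such experiments — and, because raw human data are not required, a
calibrated synthetic-cohort generator that exercises the chain end to end.

The package provides:

* **Synthetic gait generator** — virtual participants with calibrated
  anthropometrics and behaviour; raw trials as bilateral vertical and
  anterior-posterior GRFs, center-of-pressure, heel-marker, belt-speed and
  breath-by-breath gas-exchange series.
* **Self-paced controller** — the dead-zone proportional law
  `ΔSpeed = R · D · L` (R the sign of the double-support average
  center-of-pressure position, D its distance from treadmill center, L = 0.1),
  with a 20 cm dead zone, plus F_P-targeting biofeedback with a 5% tolerance
  band and streak counter.
* **Gait processing** — heel strike / toe off at 20 N vertical-GRF crossings,
  peak propulsive force over stance, peak braking force in the first half of
  stance, stride length/duration from heel markers with belt-travel
  correction, all summarized over the final 2 min of each 5-min trial.
* **Metabolics** — Brockway power from V̇O₂/V̇CO₂
  (16.58/4.51 kJ·L⁻¹), time-weighted final-window averaging, standing-baseline
  subtraction and mass normalization (net power, W/kg), and cost of transport
  CoT = net power / speed (J·kg⁻¹·m⁻¹).
* **Statistics** — pooled trial-level squared Pearson correlations per clamp
  with strength labels, 2 (clamp) × 5 (intensity) repeated-measures ANOVA with
  partial eta squared, Tukey post-hocs and paired Cohen's d, and the
  speed-variability null check.

## Worked example

Five virtual participants, five condition intensities (−20, −10, Norm, +10,
+20% of preferred speed / habitual F_P), both clamps:

```r
library(fpclamp)
rc  <- run_config(n_participants = 5, seed = 7)
run <- run_full_experiment(rc, "run_demo", write_raw = FALSE)
an  <- run$analysis

subset(an$associations, x == "mean_speed" & y == "mean_fp")
#>    group          x       y  n    r2        p slope intercept    strength
#>       fp mean_speed mean_fp 25 0.728 5.86e-08  11.7    4.3728      strong
#>    speed mean_speed mean_fp 25 0.801 1.61e-09  14.9    0.0334 very strong
#>  average mean_speed mean_fp 50 0.765 5.86e-08  13.3    2.2031      strong
```

Walking speed explains ~77% of the variance in F_P (%body weight) at this
small cohort size; the per-clamp slopes (~15 %BW per m/s) are the pooled
F_P–speed response the generator is calibrated to. The metabolic ANOVA:

```r
an$anovas$net_power
#> Two-way repeated-measures ANOVA on 'net_power'
#>   clamp            F(1,4) =    2.92, p = 0.1629, eta_p^2 = 0.422
#>   intensity        F(4,16) =   15.43, p = 2.375e-05, eta_p^2 = 0.794
#>   clamp:intensity  F(4,16) =    3.92, p = 0.02096, eta_p^2 = 0.495
#>   15 post-hoc contrasts (see $posthoc)

metrics_from_summaries(run$summaries)$np_offset_pct
#> 9.3   # F_P-clamp trials cost ~9% more net metabolic power
```

Net metabolic power rises strongly with condition intensity, and F_P-clamp
(self-paced) trials carry a ~9% metabolic surcharge over speed-clamp trials
— at n = 5 the clamp main effect is not yet significant; at the default
n = 20 it is.

At the default scale (20 participants, 200 five-minute trials per run) the
pipeline recovers the calibrated group statistics: speed-clamp speed~F_P
R² ≈ 0.84, cross-clamp averages ≈ 0.80 (F_P), 0.67 (F_B), 0.72 (stride
length), 0.54/0.59 (net power vs speed/F_P), 0.17 (F_P vs CoT), and the
+8.9% F_P-clamp net-power offset. `validate_targets()` checks any run
against these targets.

## Command line

```sh
Rscript inst/cli/fpclamp.R all      --n 20 --seed 1 --out myrun
Rscript inst/cli/fpclamp.R validate --out myrun
```

Subcommands `simulate`, `process`, `analyze` run the stages separately on a
run directory of plain-text trial tables (`trials/*.tsv` + JSON sidecars);
`config.yaml` stores the resolved configuration and seed for exact
reproduction.

## Documentation

The methods vignette (`vignettes/fpclamp-methods.Rmd`) documents the
calibrated generative model, the variance-decomposition calibration, the
controller and walker closed loop, numerical choices, and what a green test
does and does not establish.
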