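# rhpav

Simulation and analysis of the **reactive-hyperemia peripheral arterial
volume (RH-PAV)** index — a noninvasive, finger-photoplethysmography (PPG)
measure of peripheral endothelial function, conceptually related to
flow-mediated dilation (FMD) and peripheral arterial tonometry (PAT).

The measurement protocol: a two-channel infrared finger probe records the
digital volume pulse of both index fingers while a cuff on the test arm is
inflated to 50 mmHg above systolic pressure for 5 min. The index is built
from per-beat **pulse-wave amplitudes (PWA)**:

```
             mean PWA [t_deflate+40, t_deflate+80) / mean PWA [t_base+40, t_base+80)   (test arm)
RH-PAV  =   ─────────────────────────────────────────────────────────────────────────
             same ratio on the contralateral (control) arm
```

The contralateral division cancels systemic amplitude changes during the
test; a blunted hyperemic response (low RH-PAV) indicates endothelial
dysfunction. The nitroglycerin analogue (NTG-PAV) compares a 40-s window
3 min after sublingual nitroglycerin with a second baseline, without
contralateral correction. `%FMD = (max post-deflation diameter − baseline) /
baseline × 100` is provided as companion arithmetic.

The package provides, as testable components:

- **Simulator** — a Beer–Lambert optical model of the finger
  (`I = I0·exp(−ε_eff·c·(d_static + d_venous + d(t)))`, ε_eff mixing oxy-
  and deoxyhemoglobin by saturation) driving two-channel synthetic sessions
  with programmed hyperemia gain, common-mode drift, venous pooling during
  occlusion, noise and baseline wander (`simulate_session()`).
- **Waveform processing** — zero-phase band-limiting, adaptive-threshold
  beat detection, windowed PWA means (`preprocess_ppg()`, `detect_beats()`,
  `window_mean_pwa()`).
- **Indices** — `compute_rh_pav()`, `compute_ntg_pav()`,
  `compute_fmd_percent()`, and `analyze_recording()` for the full chain.
- **Cohort model** — binormal mixture cohorts with within-group PAV–FMD
  correlation (`simulate_cohort()`, `mixture_moments()`), defaulting to the
  published CAD (n = 53, PAV 1.05 ± 0.23, FMD 6.7 ± 2.9 %) and non-CAD
  (n = 40, 1.41 ± 0.37, 10.4 ± 2.9 %) groups.
- **Statistics** — in-house Pearson/Spearman correlation, Welch t-test,
  empirical ROC with AUC, Youden cutoffs, sensitivity/specificity at fixed
  cutoffs, and DeLong paired AUC comparison.
- **CLI** — `inst/cli/rhpav` with subcommands `simulate`, `compute`,
  `cohort`, `roc`, `analyze`, `run`.

## Worked example

```r
library(rhpav)

# a session with programmed hyperemia gain 1.41 and 20% systemic drift
rec <- simulate_session(subject_params(hyperemia_gain = 1.41, drift_gain = 1.2),
                        seed = 42)
analyze_recording(rec)
#> RH-PAV result
#>   test arm:    baseline 0.007138, hyperemia 0.01201, ratio 1.683
#>   control arm: baseline 0.007157, hyperemia 0.008573, ratio 1.198
#>   RH-PAV (contralaterally normalized): 1.405
```

The raw test-arm ratio (1.683) is inflated by the systemic drift; the
control arm measures that drift (1.198 ≈ 1.2), and their quotient recovers
the programmed gain: 1.405 ≈ 1.41.

```r
coh <- simulate_cohort(cad_group_specs(), seed = 42)
roc_curve(coh$pav, coh$cad, "lower")
#> ROC (lower score indicates disease): AUC = 0.847 (53 diseased / 40 controls)
#>   Youden cutoff 1.23: sensitivity 88.7%, specificity 67.5%
pearson_r(coh$pav, coh$fmd_percent)
#> pearson correlation: r = 0.659 (n = 93, two-sided p = 6.89e-13)
mixture_moments(cad_group_specs())   # closed-form pooled moments
#> $pav: mean 1.20, sd 0.348;  $fmd: mean 8.29, sd 3.43;  $r: 0.686
```

A single 93-subject cohort scatters around the population values (here AUC
0.847, r 0.659); the closed-form mixture moments give the implied pooled
summaries exactly.

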