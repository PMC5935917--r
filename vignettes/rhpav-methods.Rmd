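---
title: "Models and methods behind rhpav"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind rhpav}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rhpav)
```

# The measurement and the index

Reactive-hyperemia peripheral arterial volume (RH-PAV) assesses peripheral
endothelial function from the digital volume pulse. Two infrared
transmission PPG probes record both index fingers; a cuff on the test arm
is inflated 50 mmHg above systolic pressure for 5 min, abolishing the
test-arm pulse. After deflation, reactive hyperemia transiently enlarges
the pulse. Per arm, the hyperemia-to-baseline ratio is the mean per-beat
pulse-wave amplitude (PWA) in the 40-s window starting 40 s after
deflation, divided by the mean PWA in the 40-s window starting 40 s into
the pre-occlusion baseline. RH-PAV is the test-arm ratio divided by the
control-arm ratio; the division cancels systemic amplitude changes common
to both arms. The nitroglycerin analogue compares the 40-s window starting
3 min after sublingual NTG with a second-baseline window, with no
contralateral correction (NTG acts systemically on both arms).

Two conventions the protocol wording leaves open are fixed here and
recorded in every result object:

* *Time zero of "reactive hyperemia"* is the cuff-deflation instant, the
  standard convention for cuff-occlusion tests.
* *Contralateral normalization* is the ratio of ratios,
  `(test hyperemia/baseline) / (control hyperemia/baseline)`, the
  established form for paired-arm devices. The per-arm window means are
  stored in `pav_result` so alternative normalizations can be compared.
* The reported RH-PAV is the **normalized** value; published cohort ranges
  (0.60–2.22) are treated as normalized.
* The *second baseline precedes NTG administration*: the NTG response is
  referenced to it, so the timeline enforces
  baseline < inflate < deflate < second baseline < NTG. The published
  protocol does not state the gap; the default timeline places the second
  baseline 230 s after deflation (hyperemia decayed to < 1 % residual at
  the default decay constant) and NTG 100 s later.

# The optical simulator

No public recordings of this device class exist, so every downstream stage
is validated against a generative model with known ground truth.

**Pulse train.** One cardiac cycle is a raised-cosine systolic upstroke
over the first 30 % of the cycle followed by an exponential diastolic decay
rescaled to end at 0 (`pulse_template()`), giving the foot-to-peak
morphology of a digital volume pulse. Published traces are only
qualitative, so the shape is a modelling choice; beat detection depends
only on one prominent maximum per cycle.

**Protocol envelope.** The per-beat amplitude of the test arm is 0 during
occlusion (the cuff is suprasystolic; partial occlusion is out of scope),
then `1 + (g_h − 1) · S(τ) · D(τ)` after deflation: a logistic onset
`S` (10 s delay, 2 s scale), a plateau through 90 s, and exponential decay
`D` (τ = 40 s). The plateau strictly covers the 40–80 s measurement
window, so the programmed gain `g_h` is identifiable there by
construction. The systemic drift gain `g_s` ramps geometrically from 1 at
the end of the baseline window to `g_s` at the start of the hyperemia
window on *both* arms — the worst case for an uncorrected single-arm
ratio, and exactly what contralateral normalization removes. The NTG gain
ramps in over 2 min on both arms.

**Optics.** Detected intensity follows the Beer–Lambert law,
`I(t) = I0·exp(−ε_eff·c·(d_static + d_venous(t) + d(t)))`, with
`ε_eff = s·ε_HbO2 + (1−s)·ε_Hb` at saturation `s`. Absorptivities at the
nominal 940 nm wavelength are arbitrary positive constants (default 1.1 /
0.8): the index is a ratio, so only the products `ε·c·d` matter. The
default pulsatile modulation is small (`ε·c·Δd ≈ 0.02`), keeping the
AC-intensity amplitude proportional to the volume amplitude to first
order; the residual linearization error on a 1.41-fold gain is ≈ 0.04 %.
Venous pooling adds a non-pulsatile path increment during occlusion only,
ramped over 10 s — it shifts the DC level by ≈ 18 % but, being
non-pulsatile, leaves per-beat amplitudes untouched (verified as a
property test).

**Noise.** White noise (default SD 2 % of the nominal AC amplitude) plus
sinusoidal baseline wander (default 2× AC at 0.05 Hz). One session seed
streams to all stochastic components; identical seeds give bit-identical
recordings.

**Defaults.** 100 Hz sampling (typical PPG practice; 50 Hz minimum
enforced), 70 bpm, 300 s occlusion, 480 s records (960 s with the NTG
phase). What the generator does *not* emulate: arrhythmia, motion
artifacts, probe-coupling changes, multi-wavelength effects, partial
occlusion. Passing tests therefore demonstrate correctness of the
*computation*, not robustness to every artifact of real recordings.

# Waveform processing

Conditioning normalizes polarity (intensity is inverted relative to
volume), removes the mean, and applies zero-phase (forward–backward)
Butterworth filters: 0.3 Hz order-2 high-pass for wander, 10 Hz order-4
low-pass for out-of-band noise. Zero-phase filtering preserves beat times
and hence the 40-s window semantics; odd-reflection padding suppresses the
edge transients that forward–backward filtering otherwise produces.

Beat detection accepts a candidate local maximum when its foot-to-peak
amplitude exceeds 20 % of the median PWA of beats accepted in the trailing
60 s (falling back to the median of all accepted beats, with an absolute
floor of 5× the robust sample-to-sample deviation before any beat
exists). The trailing median makes the threshold track the 2-fold
amplitude swings of the protocol while rejecting filtered noise in the
occluded epoch, which correctly yields *no* beats rather than an error.
Candidates closer than 0.3 s to the previous beat replace it if taller.
PWA is the foot-to-peak amplitude — the standard PPG AC measure — with the
foot as the minimum between consecutive peaks (2 s look-back across long
gaps). Window membership is by **peak** time in a half-open interval
`[start, start + length)`: deterministic, no double counting.
Inter-beat intervals outside 0.3–2.0 s flag the beat without dropping it.

# Cohort model and statistics

Subject-level cohorts are drawn from a two-group bivariate normal mixture
(per group: PAV and FMD means/SDs and within-group correlation), with PAV
truncated positive by resampling — negligible at the published parameters
(the CAD group mean sits 4.6 SDs above zero). The bivariate normal is the
minimal family matching everything the source reports (means, SDs,
correlations; printed ranges are consistent with near-normal spread).
`mixture_moments()` gives the implied pooled summaries in closed form via
the laws of total variance and covariance; with the published group
parameters the pooled values are PAV 1.205 ± 0.348, FMD 8.29 ± 3.43 %,
r = 0.686 — matching the published pooled 1.21 ± 0.35, 8.3 ± 3.4 %,
r = 0.69 to printed rounding. Risk-factor strata (`crf_group_specs()`) are
univariate PAV groups; within-stratum risk-factor distributions are not
published, so the count–PAV association is checked only as a monotone
trend, not a numeric target.

The statistics module is deliberately self-contained (the statistics *are*
part of what is being validated); `cor.test`, `t.test` and `pROC` serve as
independent cross-checks in the test suite only. Choices where the source
names none:

* **Welch** (unequal-variance) two-sample t-test — the group SDs differ
  (0.23 vs 0.37).
* **ROC orientation**: lower PAV/FMD indicates disease. At a cutoff `c`,
  sensitivity counts diseased subjects with score `< c`, specificity
  non-diseased with score `≥ c`.
* **AUC** by trapezoid over all distinct thresholds, equal to the
  Mann–Whitney estimator with ties weighted ½.
* **Youden cutoff**: maximizes J = sensitivity + specificity − 1 over
  midpoints between adjacent distinct scores; ties break toward the score
  median. On replicate published-parameter cohorts the mean optimal PAV
  cutoff falls in 1.15–1.40, bracketing the published 1.28.
* **DeLong** placement-value covariance for the paired AUC comparison,
  with Z defined as 0 when both the AUC difference and its variance vanish
  (identical scores). The published paired Z (0.54) is not a numeric
  target — it depends on an unpublished paired covariance — but the
  non-significance (|Z| < 1.96) is reproduced in ≥ 90 % of replicates.
* Correlation p-values use the exact t-transform with n − 2 df (for
  Spearman, applied to the rank correlation — adequate at n ≥ 40 here).

# Problem sizes and numerical checks

The test suite and acceptance script run at desk scale, chosen so the
Monte-Carlo error is well inside each tolerance: 200 replicate 93-subject
cohorts for the cohort-level statistics (replicate-mean SEs ≈ 0.002 for
AUC, ≈ 0.4 percentage points for operating points), 10,000 replicates for
the Welch type-I calibration, and 20 simulated sessions (five hyperemia
gains 0.8–2.0 × four seeds each, 2 % noise, randomized drift) for
end-to-end ground-truth recovery within 5 %. The empirical specificity of
FMD at the 9.8 % cutoff concentrates near its binormal value
`1 − Φ((9.8 − 10.4)/2.9) = 58.2 %` rather than the published 63 % — the
published estimate sits within its own n = 40 sampling error (SE ≈ 7.6
points) of that population value, and the package reports what the model
implies.

# Known limitations

Single-wavelength optics (saturation enters only through ε_eff; the
low-saturation bias the 940 nm choice incurs in real devices is out of
scope), no arrhythmia or motion-artifact handling beyond interval
flagging, no ultrasound image analysis for FMD (diameters are inputs), and
cohort simulation captures printed group moments, not covariate structure
(age, sex, individual risk factors).
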