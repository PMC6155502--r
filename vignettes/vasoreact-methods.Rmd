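---
title: "vasoreact: methods, models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{vasoreact: methods, models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vasoreact)
```

# The scientific problem

The vasomotor response — the capacity of a vessel to regulate its tone —
is governed by two control layers: autonomic (sympatho-vagal) drive, read
out non-invasively through heart-rate variability (HRV), and endothelial
function, read out through flow-mediated dilation (FMD) of the brachial
artery after release of a 5-min supra-systolic cuff occlusion. Training
interventions such as respiratory muscle training (RMT) by isocapnic
hyperpnoea can act on either layer. Because the dilation response depends
on the magnitude of the hyperaemic shear stimulus, %FMD must be normalized
by the cumulative shear rate before pre/post or between-group comparisons
are meaningful: an intervention can leave %FMD unchanged while reducing
the shear dose needed to produce it, which is itself an improvement in
vascular responsiveness.

`vasoreact` implements this complete analysis chain plus the
synthetic-data layer needed to validate it.

# Vascular stage

## Definitions

With diameter $d$ (cm) and mean blood velocity $\bar v$ (cm/s):

* blood flow $= \bar v \,\pi (d/2)^2 \cdot 60$ (ml/min),
* shear rate $\mathrm{SR} = 8\bar v / d$ (s$^{-1}$), the Poiseuille wall
  estimate,
* $\%\mathrm{FMD} = (d_{peak}-d_{base})/d_{base}\cdot 100$,
* cumulative SR $=$ trapezoidal integral of SR from cuff release
  ($t = 0$) to the time of peak diameter,
* $\%\mathrm{FMD}/\mathrm{SR} =$ the dilation per unit shear dose,
* BVC $=$ flow / MAP (ml·min$^{-1}$·mmHg$^{-1}$).

## Numerical and procedural choices

**Baseline averaging.** The baseline diameter is the mean over the full
30-s pre-deflation window. The source protocol does not state an averaging
rule; the full window maximizes noise suppression while staying inside the
occluded plateau.

**Peak detection.** The diameter series is smoothed with a centered
moving average (default `smooth_window = 3` s, converted to an odd sample
count; edge windows shrink) before the post-release maximum is taken, ties
broken by earliest time. The reference analysis software is proprietary
and its smoothing unknown, so the window is a user-visible parameter;
`smooth_window = 0` disables smoothing.

**Integration bounds.** Cumulative SR integrates from cuff release
($t=0$), not from the hyperaemia onset a few seconds later — "release to
time of peak" is the operative definition. The published formula for this
integral is typographically corrupted in the source; the surrounding text
names the trapezoidal rule, which is what `cumulative_shear_rate()`
implements, and the suite pins it to an explicit per-interval oracle at
machine precision.

**Units of the flow AUC.** Flow is in ml/min, so time is converted to
minutes before integrating: a constant 100 ml/min over the 2-min
post-release window gives an AUC of 200 ml. The binned flow curve returned
by `hyperaemia_flow_curve()` is for display; the AUC is always computed on
the sample-resolution mean curve so that the rectangle identity holds
exactly (integrating the bin-centre curve would clip half a bin at each
end).

**Retrograde flow.** Negative instantaneous velocities are clipped to
zero with a warning inside the analysis windows; the flow and shear
formulas assume antegrade $\bar v$ and scalar inputs reject negatives
outright.

**Allometric check.** Expressing FMD as a ratio presumes
$d_{peak} \propto d_{base}$. `allometric_scaling_check()` regresses
$\ln d_{peak}$ on $\ln d_{base}$ (OLS), forms the two-sided
$(1-\alpha)$ CI of the slope with the $t$ distribution on $n-2$ df
(default $\alpha = 0.05$) and accepts ratio scaling when the upper limit
reaches 1. A $10^{-12}$ guard on that boundary keeps an exactly
proportional cohort (zero residuals up to machine epsilon) on the valid
side. In the pipeline the check is a gate that *flags* — never
suppresses — the %FMD columns, and is skipped with a logged reason below
$n = 3$.

# HRV stage

The tachogram (RR in ms) is interpolated onto an even 4-Hz grid with a
cubic spline over cumulative beat time, mean-removed, and the power
spectral density estimated by Welch's method: 120-s segments, 50% overlap,
periodic Hann taper, one-sided scaling. Band powers are rectangle sums of
the PSD over VLF (0.01–0.04 Hz), LF (0.04–0.15 Hz) and HF (0.15–0.40 Hz),
with half-open `[lo, hi)` bins and an inclusive upper edge for HF.

These are standard settings in HRV practice; the reference analysis
delegated to external software without reporting its spectral
configuration, and an autoregressive spectrum would be an equally
defensible choice. Welch was chosen for robustness and transparency; the
estimator lives behind `hrv_band_powers()` so the method can be swapped
without touching the rest of the chain.

**Normalized units** are defined on the LF+HF total:
$\mathrm{LF}_{nu} = \mathrm{LF}/(\mathrm{LF}+\mathrm{HF})\cdot 100$, so
LF n.u. and HF n.u. sum to 100 by construction — the convention under
which published LF/HF n.u. pairs sum to ~100.

**Segment selection.** "Clearest 5 minutes" is operationalized as the
contiguous window minimizing an artifact count: beats whose RR jumps by
more than 20% of the local median (11-beat window) are flagged; ties are
broken by lower RR variance, then earliest start. The 20% threshold is a
configurable stand-in for an expert's visual selection. A window is the
span from a starting beat to the first beat at or beyond 300 s so the
segment always covers the full length.

**Degenerate input.** A constant RR series has zero spectral power; the
result carries zero band powers, `NA` normalized units and ratio, and a
`degenerate` flag instead of throwing.

# Reliability stage

The test-retest chain is ICC → SEM% → MDC95%:

* **ICC form.** "Two-way mixed model" admits several forms; the package
  fixes ICC(3,1) — consistency, single measures:
  $(MS_S - MS_E)/(MS_S + (k-1)MS_E)$ — the usual companion of SEM/MDC
  reporting. The absolute-agreement form ICC(2,1) is available via
  `type = "agreement"`. A matrix with all cells equal returns 1 by
  convention, flagged.
* **SEM.** $SD_{pooled}\sqrt{1-ICC}$ as a percent of the grand mean
  (default), with $\sqrt{MS_E}$ selectable; on tables of this kind the two
  agree within rounding, and the published values cannot discriminate
  between them.
* **MDC95%** $= 1.96\sqrt{2}\cdot SEM\%$.
* **Classification.** very high $> 0.90$; high $[0.70, 0.90]$; moderate
  $[0.50, 0.70)$; low below. The printed bands leave the gaps
  $(0.69, 0.70)$ and $(0.89, 0.90]$ unassigned; the package treats the
  printed edges as inclusive interval boundaries.

# Prescription stage

The isocapnic-hyperpnoea starting dose is tidal volume $= 0.5\,$FVC,
target minute volume $MV = 0.6\,$MVV, and breath frequency
$f_b = MV/(1.3 \cdot 0.5\,\mathrm{FVC})$, where 1.3 is a duty-cycle
correction kept as a named parameter. Note the algebraic consequence that
the raw product $V_t f_b$ equals $MV/1.3$: the returned object therefore
carries both `target_mv` (the 60%-of-MVV quantity the identity and the
growth law govern) and `minute_ventilation` ($V_t f_b$).

Progression multiplies the workload by 1.15 weekly, alternating volume
(even weeks) and frequency (odd weeks); whether the published protocol
alternated volume or frequency first is unstated, so volume-first is the
default and per-week increments can be overridden. Because the increments
are multiplicative, $MV$ after $w$ weeks is $MV_1 \cdot 1.15^{w-1}$
regardless of the alternation.

# Group statistics

Within-group changes use paired Student's t-tests; between-group
comparisons use the pooled-variance unpaired test; the factorial analysis
is a mixed-design (split-plot) two-way ANOVA with group between subjects
and time within, implemented as `aov(value ~ group*time + Error(subject))`
and verified in the suite against hand-computed split-plot sums of
squares. "Training × time" is interpreted as group × time: both factorial
questions reported in this literature are the same mixed design under
different factor labels.

When the interaction is significant at $\alpha = 0.05$ the four pairwise
contrasts (pre vs post within each group; RMT vs SHAM at each time) are
adjusted by the Holm–Šidák step-down rule
$p^{adj}_{(i)} = \max_{j \le i}\,[1-(1-p_{(j)})^{m-j+1}]$.

Shapiro–Wilk p-values of the within-group changes are reported for
inspection but never switch the pipeline to a non-parametric branch —
no such fallback is defined in the emulated protocol.

**Degenerate paired data.** `post == pre` returns $t = 0, p = 1$ with a
degenerate flag (the natural reading of a no-change dataset); a constant
*non-zero* shift has zero error variance and no valid t statistic, so it
raises an error rather than reporting spurious certainty.

# The synthetic-data layer

The generators encode a stated world chosen once from the emulated study:

* **FMD traces** (`simulate_fmd_trace()`): baseline diameter 0.30 cm and
  time to peak ~30 s (the reported ranges are 0.28–0.31 cm and 28–35 s);
  programmed %FMD default 8; occluded velocity 0 before release; a step to
  a 60 cm/s hyperaemic peak decaying exponentially ($\tau = 25$ s) toward
  a resting 11 cm/s (which reproduces a resting flow of ~47 ml/min at
  0.30 cm); Gaussian sensor noise (defaults 0.002 cm, 0.8 cm/s in the
  pipeline).

  The diameter kinetic is a logistic rise into a **flat plateau** of
  width `peak_plateau` (default 3 s) centred at the programmed time to
  peak, then an exponential relaxation. A strictly single-peaked curve
  cannot survive a moving-average smoother with both its peak value and
  its peak time intact; a plateau exactly as wide as the analyzer's
  default smoothing window does, so noiseless traces recover the
  programmed %FMD and time to peak exactly under default settings — the
  invariant the test suite asserts. Changing the smoothing window away
  from the plateau width makes the recovery approximate, as it would be
  for any real vessel.
* **RR series** (`simulate_rr_series()`): mean RR 0.92 s (~65 bpm, the
  reported resting heart rate), one LF and one HF sinusoid
  (defaults 0.10 and 0.25 Hz) plus beat-to-beat Gaussian noise;
  non-positive draws are redrawn, not clipped, to avoid spectral
  artifacts; 10-min duration as recorded in the protocol.
* **Cohorts** (`simulate_cohort()`): multiplicative log-normal draws so
  physiological variables stay positive, with a shared log-scale subject
  effect giving a pre/post correlation `within_subject_rho` (default 0.8 —
  a free simulation parameter: the source reports no within-subject
  correlation, and nothing downstream is calibrated to it). Default means
  and effects follow the published pre-training values and responses
  (MIP 48 cmH₂O ×1.31 post-RMT, MVV 134 l/min ×1.16, null MAP/SV effects).
* **The study default** programs the headline physiology: post-RMT
  hyperaemic velocity ×0.75 (lowering cumulative SR by ~25%) with %FMD
  unchanged, so %FMD/SR rises after RMT and the flow AUC falls — the
  pattern the pipeline's report reproduces end to end.

What the generators do **not** emulate: ultrasound image artifacts and
wall-tracking failures, respiration-locked or broadband (1/f) HRV power,
ectopy beyond simple RR jumps, drift in baseline diameter, menstrual-phase
or circadian effects, and any correlation between a subject's FMD kinetics
and their scalar physiology. A green test therefore establishes that the
*computational chain* is correct and recovers programmed truth under
plausible noise — not that the generators reproduce every property of
clinical recordings.

# Pipeline and configuration

`run_study()` is deterministic given `config$seed` (sub-seeds for each
stage are derived arithmetically and kept below $2^{31}$), persists every
table as full-precision CSV when `output_dir` is set, and keeps a
structured log of stages and parameters. Configuration is an R list or a
JSON file merged over `default_study_config()`; JSON replaces the YAML
configuration one might expect because no YAML reader is available in the
supported dependency set, and `jsonlite` is. The exported functions and
`run_study()` are the package's interface; no shell entry point is
shipped, since the intended users work in R.

The reliability table is built from the pre-training session plus a
simulated retest with independent measurement noise (3% of the mean by
default, 9% for cumulative SR, whose published test-retest reliability is
markedly lower than the other variables').

# Known limitations

* Welch PSD on a spline-resampled tachogram mildly attenuates power near
  the upper HF edge relative to the true modulation amplitude; the
  two-sine equal-amplitude test bounds this leakage (LF/HF within
  [0.8, 1.25]) rather than eliminating it.
* The ICC is the consistency form; studies requiring absolute agreement
  must opt in and will see lower values under systematic trial shifts.
* `windowed_hemodynamics()` recomputes derived quantities from averaged
  primitives, which differs from averaging the derived series when the
  primitives co-vary within a window.
* The mixed ANOVA assumes a complete, balanced design and rejects
  anything else; there is no missing-data machinery.
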