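---
title: "Methods: repolarization, variability and arrhythmia severity in the chronic AV-block dog model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: repolarization, variability and arrhythmia severity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(torsadex)
```

## The analysis problem

The chronic atrioventricular-block (AV-block) dog is a standard preclinical
model for drug-induced Torsade de Pointes (TdP). After His-bundle ablation
the ventricles are paced at a fixed bradycardic rate (VVI 60, RR = 1000 ms)
while the atria beat independently, and repolarization is stressed with the
IKr blocker dofetilide. The quantitative readouts are:

* **ECG intervals** — RR, PP, QRS, QT measured on lead II over a fixed
  number of consecutive complexes (5 under anesthesia; 10 for awake RR/PP);
  JT = QT − QRS; the Van de Water rate correction
  QTc = QT − 0.087·(RR − 1000); JTc = QTc − QRS.
* **MAP duration** — monophasic action potential duration at 80 % of
  repolarization (MAPD80) from LV and RV contact catheters, and spatial
  dispersion ΔMAPD = LV MAPD − RV MAPD.
* **STV** — beat-to-beat short-term variability of a repolarization
  duration series, STV = Σ|D~n+1~ − D~n~| / (N·divisor) over N = 30
  consecutive beat pairs (a Poincaré-plot dispersion statistic). Ectopic
  complexes and complexes with a P wave in the T-wave end are excluded, and
  excluded beats break consecutiveness.
* **Arrhythmia score (AS)** — the mean of the three highest-scored
  arrhythmic events in the 10 minutes after dofetilide onset (rubric
  below).
* **Hemodynamics** — LV dP/dt extrema over 5 consecutive pressure cycles,
  QLVPend (QRS onset to pressure-cycle end) and the electromechanical
  window EMW = QLVPend − QT.
* **Cellular electrophysiology** — peak tail current at −50 mV after a
  +60 mV step, capacitance-normalized; pharmacological decomposition
  (IKs = HMR 1556-sensitive, IKr = dofetilide-sensitive on top of HMR);
  APD90/APD50 and cellular STV from paced action potentials.

No raw recordings accompany the study this pipeline replicates, so the
package ships a seeded synthetic-signal generator with exact ground truth;
every analysis module is validated against it.

## The STV divisor: `[30∗2]` vs 30·√2

The study prints the STV denominator as "30∗2" while the originating STV
literature divides by 30·√2 (the Poincaré-plot projection onto the
line-of-identity normal). The two conventions differ by the exact factor
√2 and cannot be disambiguated from the printed text, so both are
implemented: `stv(..., divisor_mode = "sqrt2")` (default, matching the
method's origin and the magnitude of typically reported values) and
`divisor_mode = "literal"` (reproducing the printed formula). Every STV
result records which divisor produced it, and the identity
`stv_sqrt2 = stv_literal · √2` is enforced by tests.

## The arrhythmia-score rubric

A regular beat scores 1, a single ectopic beat (sEB) 2, multiple ectopic
beats (mEB, runs of 2–5) 3–5, TdP (runs of ≥ 6) 6–49, and defibrillated TdP
(> 10 s, shocked) 50/75/100 for 1/2/≥3 shocks. The exact within-range
mapping for mEB and TdP is defined in prior literature the study cites but
does not restate; the package adopts

* mEB: points = run length + 1, capped at 5 (consistent with sEB = 1 + 1),
* TdP: points = run length, capped at 49 (consistent with the 6-point floor
  of a 6-complex TdP and with a published 17-point self-terminating TdP),

and keeps the mapping in one function (`score_event()`) so an alternative
convention is a one-line change. A 5-complex run scores 5 under the mEB cap,
closing the gap between the mEB and TdP ranges explicitly. With fewer than
three arrhythmic events in the 10-minute window, the remaining slots carry
regular-beat scores of 1 — this reproduces the baseline AS of exactly 1 in
event-free windows.

## What the synthetic generator emulates

`generate_rhythm()` renders, at 1 kHz:

* a ventricular beat train at the paced rate (default 60/min, RR = 1000 ms
  exactly);
* an independent atrial P-wave train (default 127/min, PP ≈ 472 ms,
  emulating AV dissociation with control-baseline PP near 471 ms); P-on-T
  coincidences arise naturally and are annotated;
* per-beat durations (QT, LV/RV MAPD) as a mean plus a stationary AR(1)
  process. The AR(1) innovation SD is calibrated in closed form so the
  expected STV equals the configured target: for successive differences
  with SD σ~Δ~, E[STV] = σ~Δ~/√π, so σ~Δ~ = target·√π and the innovation SD
  is σ~Δ~·√((1+φ)/2) (default φ = 0.5). The realized series is re-centred
  so the mean duration is exact. Default targets: QT 364 ms, QRS 123 ms,
  STV 0.70 ms (control-baseline values); LV/RV MAPD are generated at fixed
  ratios 0.68/0.61 of the QT mean, matching the control-baseline ratios;
* an optional drug ramp: exponential saturation of the QT/MAPD increment
  (default +126 ms asymptote, reproducing the 364→490 ms control
  challenge). The study reports endpoint means, not a time course, so the
  60 s time constant is a documented stand-in;
* scheduled ectopic runs (sEB/mEB/TdP/defibrillated TdP) at a 250 ms cycle
  length — inside the 200–300 ms range typical of TdP in this model — with
  alternating polarity as a minimal stand-in for the twisting QRS axis.
  Run length and class are ground truth in the annotations; a
  defibrillated event must outlast 10 s, i.e. ≥ 41 complexes at this cycle
  length.

**Beat templates** are piecewise-analytic with exactly compact support so
fiducial ground truth is exact: a raised-cosine P wave (70 ms, 0.15 mV), a
*triangular* QRS (sharp onset/offset, so threshold-plus-extrapolation
fiducials are unbiased), and a T wave with a half-cosine ascending limb and
a *linear* descending limb ending exactly at the true T end. The linear
terminal limb makes the tangent method's steepest-downslope line intersect
the baseline at the true T end, i.e. the delineation convention is exact on
the synthetic shapes by construction. MAP and cellular-AP beats are
plateau templates (half-cosine upstroke, plateau, linear repolarization)
calibrated so the threshold-crossing duration at the calibration fraction
equals the configured duration exactly.

What the generator does **not** emulate: recorded dog morphologies, rate
dependence/restitution of APD, respiratory or motion artifacts, sinus-rate
variability of the atrial train (it is strictly periodic), and
biophysically detailed TdP morphology. A green recovery test therefore
establishes that the analysis code measures what the templates encode at
realistic amplitudes and noise — not that it would delineate arbitrary
clinical ECGs.

One consequence of the strictly periodic trains is worth noting: at the
default rates (RR 1000, PP 472.4 ms) the P wave advances ≈ 55 ms per beat
relative to the T end, so a P-on-T exclusion recurs roughly every 9 beats
and a 31-beat run of consecutive clean beats may never occur. This is
faithful to the exclusion rule's definition; analyses that need long clean
runs should use rate combinations without coincidences (e.g. atrial
120/min against RR 1000) or a different exclusion window.

## Delineation under AV dissociation

The study placed markers manually; the package delineates algorithmically
(ground-truth annotations always take precedence when supplied). R peaks
are threshold-detected; Q onset and QRS end are found by a threshold scan
followed by linear extrapolation of the limb to baseline; T end uses the
tangent method (least-squares line through the 15–85 %-amplitude stretch of
the descending limb, extrapolated to the isoelectric baseline).

Because the atrial train marches through the QRS-T complex, the delineator
first estimates the P train: candidate P peaks are prominent small maxima
in late diastole; the period is the *smallest* value under which the
candidate inter-peak gaps are integer multiples (scored over a grid, which
rejects rational subharmonics that explain only part of the gaps); phase
and period are refined by least squares with one outlier-rejection pass; an
averaged P template is then subtracted at every predicted P position, and
all fiducials are measured on the cleaned signal. On default-condition
synthetic recordings this recovers per-beat QT within ±4 ms for ≥ 99 % of
beats, including beats with P-on-T overlap.

## Numerical choices

* Intervals are half-open `[onset, offset)`, times in ms from recording
  start, 0-based samples at 1 kHz.
* The Van de Water coefficient is fixed at 0.087 (the study names the
  formula; the coefficient comes from its cited source).
* MAPD: baseline = median of the 40 ms diastolic segment preceding the
  upstroke; amplitude = plateau peak − baseline; crossing linearly
  interpolated. Activation is the steepest-upstroke midpoint; on sampled
  symmetric upstrokes this carries a ≤ 0.5 ms quantization offset,
  irrelevant for STV (constant across beats).
* Pressure derivative: Savitzky–Golay (order 2, 15 ms window) before the
  extremum search. Cycle end: crossing of baseline + 5 % of cycle amplitude
  on the descending limb (the study does not define "end of the pressure
  cycle"; this is the documented choice), searched within 900 ms of QRS
  onset.
* Tail currents: the reference is the settled level (mean of the final
  10 % of the −50 mV segment), because the recording convention does not
  fix a zero-current baseline; the peak search runs on a 15 ms running
  mean, which suppresses noise-maximum bias while remaining exact on the
  template's brief peak plateau. Negative decomposition components beyond
  a 10 pA tolerance are flagged as rundown, never clipped. The default
  sweep set includes a blocker-insensitive residual component (30 % of the
  baseline tail at defaults), as observed after both blockers in real
  cells.
* The P-on-T exclusion window is ±40 ms around the T end (the study does
  not define one; configurable).
* Reported intervals are rounded half-away-from-zero only at display time;
  all internal computation keeps full precision.

## Design decisions made where the design was open

* The time-point rule ("5 min after infusion onset, or the first ectopic
  beat within those 5 min") is implemented literally; ectopy *before* the
  onset does not move the anchor.
* Defibrillation marks are supplied in the annotation file; a mark inside
  an event upgrades it to defibrillated TdP, and a mark outside any event
  is preserved as an orphan-shock warning record rather than dropped.
* Group inferential statistics (t-tests, ANOVA) are out of scope; the
  pipeline emits mean ± SD with per-cell n plus per-subject values so any
  statistics package can consume them.
* Every dropped beat, signal or subject carries a machine-readable reason
  code; a study run continues past unreadable subjects and fails only if
  all subjects are excluded.

## Known limitations

* The delineator assumes a strictly periodic atrial train when subtracting
  P waves; marked sinus arrhythmia would degrade the template fit.
* STV measured from the trace (MAPD per beat, then STV) carries the MAPD
  measurement noise; at very small STV targets this inflates the statistic
  (at the defaults the inflation is a few percent at a 2 ms target). The
  generator's duration series is the reference for calibration checks.
* The dofetilide ramp shape (exponential saturation) is a stand-in; only
  its endpoint is anchored to reported means.
* `delineate()` requires 1 kHz traces, the study's acquisition rate.
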