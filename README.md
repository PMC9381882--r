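# torsadex

Quantitative analysis of drug-induced proarrhythmia experiments in the
**chronic AV-block dog model**, for safety pharmacologists and cardiac
electrophysiologists. After His-bundle ablation the ventricles are paced at
a fixed bradycardic rate (VVI 60, RR = 1000 ms) while the atria beat
independently; repolarization is stressed with the IKr blocker dofetilide
and the question is how severely a chronically administered compound
destabilizes repolarization.

The package implements the model's full quantitative readout:

* **ECG intervals** per timepoint over n consecutive complexes:
  RR, PP, QRS, QT, JT = QT − QRS, the Van de Water rate correction
  QTc = QT − 0.087·(RR − 1000), and JTc = QTc − QRS;
* **MAP analysis**: monophasic action potential duration at 80 % of
  repolarization (MAPD80), spatial dispersion ΔMAPD = LV − RV, and
  beat-to-beat **short-term variability**

  STV = Σ|D<sub>n+1</sub> − D<sub>n</sub>| / (30·√2)

  over 30 consecutive beat pairs (the printed-formula divisor 30·2 is
  available as `divisor_mode = "literal"`), with the model's exclusion
  rules (ectopic beats; P wave in the T-wave end);
* **arrhythmia score (AS)**: the mean of the three highest-scored events in
  the 10 min after dofetilide onset — regular beat 1, sEB 2, mEB 3–5,
  TdP 6–49, defibrillated TdP 50/75/100 by shock count;
* **hemodynamics**: LV dP/dt extrema, QLVPend and the electromechanical
  window EMW = QLVPend − QT;
* **cellular electrophysiology**: peak tail currents at −50 mV,
  capacitance-normalized densities, pharmacological IKs/IKr decomposition
  (HMR 1556 / dofetilide subtraction), APD90/APD50 and cellular STV;
* a seeded **synthetic-signal generator** (ECG + LV/RV MAP + LV pressure +
  patch-clamp sweeps) with exact ground truth, standing in for raw study
  recordings; every analysis module is validated against it.

See `vignettes/methods.Rmd` for the model, assumptions and numerical
choices.

## Worked example

```r
library(torsadex)

# 2 min of paced rhythm (VVI 60) with AV dissociation (atrial 120/min),
# a dofetilide ramp starting at 30 s, and two scheduled arrhythmic events
spec  <- rhythm_spec(duration_s = 120, atrial_rate = 120,
                     drug_onset_s = 30, seed = 42)
sched <- event_schedule(onset_s = c(70, 95), kind = c("sEB", "TdP"),
                        run_length = c(1L, 9L))
rec <- generate_rhythm(spec, sched)

measure_intervals(rec$annotations, n = 5, timepoint = "baseline")
#> <interval_summary> timepoint 'baseline' (n = 5 complexes)
#>   RR: 1000.0 ms
#>   PP: 500.0 ms
#>   QRS: 123.0 ms
#>   QT: 364.8 ms
#>   JT: 241.8 ms
#>   QTC: 364.8 ms
#>   JTC: 241.8 ms
```

RR is exactly the paced cycle length; PP reflects the independent atrial
train; JT and JTc satisfy their subtraction identities exactly; QTc equals
QT because the correction is the identity at RR = 1000 ms.

```r
ser <- exclude_beats(measure_mapd_series(rec$trace, rec$annotations,
                                         "LV-MAP"), rec$annotations)
stv(ser, n_beats = 30)
#> <stv_result> STV = 0.728 ms (30 pairs, divisor 'sqrt2')
```

Close to the generator's configured 0.70 ms target (the small excess is
MAPD measurement noise).

```r
ev <- classify_runs(rec$annotations)
ev
#>   kind onset_ms offset_ms run_length shocks duration_s points
#> 1  sEB    70000     70250          1      0       0.25      2
#> 2  TdP    95000     97250          9      0       2.25      9

arrhythmia_score(ev, window_start_ms = 30000, window_s = 600)
#> <as_result> AS = 4.00 (events: 9, 2, 1) over [30000, 630000) ms

select_timepoint(rec$annotations, infusion_onset_ms = 30000)$anchor_ms
#> [1] 70000
```

The 9-complex run is a TdP (≥ 6 complexes) scoring 9 points; with only two
arrhythmic events the third AS slot carries the regular-beat score 1, so
AS = (9 + 2 + 1)/3 = 4. The dofetilide analysis anchor moves from
onset + 300 s to the first ectopic beat (70 s) because it falls inside the
5-min rule window.

An automatic delineator (`delineate()`) measures the same fiducials without
annotations — including under AV dissociation, where it estimates and
subtracts the periodic P train before applying the tangent method to the
T wave.

## Command line

```sh
inst/cli/torsadex simulate --out run1 --duration 120 --seed 7
inst/cli/torsadex analyze-ecg --trace run1/trace.csv --annotations run1/annotations.json
inst/cli/torsadex score-arrhythmia --annotations run1/annotations.json --out as.csv
```

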