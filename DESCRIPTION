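Package: torsadex
Title: Repolarization, Variability and Arrhythmia-Severity Analysis for
    the Chronic AV-Block Dog Model
Version: 0.1.0
Authors@R: person("torsadex", "maintainers", email = "maintainers@torsadex.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for preclinical proarrhythmia studies in the
    chronic atrioventricular-block dog model. Provides a seeded generator of
    in-silico surface ECG, monophasic action potential (MAP), left-ventricular
    pressure and patch-clamp recordings with known ground truth; ECG interval
    measurement (RR, PP, QRS, QT, JT, and Van de Water rate-corrected QTc and
    JTc); MAP duration at a configurable repolarization fraction and
    beat-to-beat short-term variability (STV) with the exclusion rules used in
    the model; an arrhythmia severity score over a 10-minute dofetilide
    challenge window; hemodynamic indices (LV dP/dt extrema, QLVPend, the
    electromechanical window); and pharmacological tail-current decomposition
    of delayed-rectifier potassium currents (IKs/IKr) with action-potential
    metrics for isolated cardiomyocytes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
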