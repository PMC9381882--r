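# Parameter objects for the synthetic-signal generators. Defaults encode the
# study conditions the generator emulates: continuous RV pacing at 60
# beats/min (RR = 1000 ms), AV dissociation with an independent atrial rate
# (PP around 470 ms at control baseline), control-baseline QT 364 ms with
# QRS 123 ms and STV about 0.7 ms, and a saturating QT increment of ~126 ms
# under the IKr-blocker challenge.

#' Rhythm generator specification
#'
#' @param ventricular_rate paced ventricular rate, beats/min (> 0)
#' @param atrial_rate independent atrial rate, beats/min (0 disables P waves)
#' @param duration_s recording length in seconds
#' @param qt_baseline_ms baseline QT interval (must exceed `qrs_width_ms` by
#'   at least 160 ms so the T wave fits after the QRS, and be shorter than the
#'   ventricular cycle length)
#' @param qrs_width_ms QRS duration
#' @param stv_target_ms expected short-term variability of the duration
#'   series (ms, >= 0); applies to the QT and both MAPD series independently
#' @param drug_onset_s infusion onset (NA for no drug ramp)
#' @param drug_qt_increment_ms asymptotic QT increment of the drug ramp
#' @param drug_tau_s time constant of the exponential saturation
#' @param noise_sd amplitude noise SD added to every channel (mV)
#' @param ar_phi AR(1) coefficient of the beat-to-beat duration model
#' @param seed integer seed; identical spec + seed gives identical traces
#' @return an object of class `rhythm_spec`
#' @export
rhythm_spec <- function(ventricular_rate = 60, atrial_rate = 127,
                        duration_s = 120, qt_baseline_ms = 364,
                        qrs_width_ms = 123, stv_target_ms = 0.70,
                        drug_onset_s = NA_real_, drug_qt_increment_ms = 126,
                        drug_tau_s = 60, noise_sd = 0.002, ar_phi = 0.5,
                        seed = 1L) {
  assert_that(is_number(ventricular_rate) && ventricular_rate > 0, "spec",
              "ventricular_rate must be > 0")
  assert_that(is_number(duration_s) && duration_s > 0, "spec",
              "duration_s must be > 0")
  assert_that(is_number(qt_baseline_ms) &&
                qt_baseline_ms < 60000 / ventricular_rate, "spec",
              "qt_baseline_ms must be shorter than the ventricular cycle length")
  assert_that(qt_baseline_ms >= qrs_width_ms + 160, "spec",
              "qt_baseline_ms must exceed qrs_width_ms by at least 160 ms")
  assert_that(is_number(stv_target_ms) && stv_target_ms >= 0, "spec",
              "stv_target_ms must be >= 0")
  assert_that(is_number(atrial_rate) && atrial_rate >= 0, "spec",
              "atrial_rate must be >= 0")
  structure(
    list(ventricular_rate = ventricular_rate, atrial_rate = atrial_rate,
         duration_s = duration_s, qt_baseline_ms = qt_baseline_ms,
         qrs_width_ms = qrs_width_ms, stv_target_ms = stv_target_ms,
         drug_onset_s = drug_onset_s,
         drug_qt_increment_ms = drug_qt_increment_ms,
         drug_tau_s = drug_tau_s, noise_sd = noise_sd, ar_phi = ar_phi,
         seed = as.integer(seed)),
    class = "rhythm_spec"
  )
}

#' Arrhythmic-event schedule for the rhythm generator
#'
#' Events are runs of consecutive ectopic complexes: a single ectopic beat
#' (sEB, run length 1), multiple ectopic beats (mEB, 2-5), torsade de
#' pointes (TdP, >= 6) or a defibrillated TdP (>= 1 shock). Events must not
#' overlap; at least one regular beat must separate successive runs.
#'
#' @param onset_s numeric vector of event onsets (seconds)
#' @param kind character vector in `c("sEB", "mEB", "TdP", "defib-TdP")`
#' @param run_length integer vector of run lengths (complexes)
#' @param shocks integer vector of shock counts (defib-TdP only)
#' @return an object of class `event_schedule`
#' @export
event_schedule <- function(onset_s = numeric(0), kind = character(0),
                           run_length = integer(0),
                           shocks = rep(0L, length(onset_s))) {
  n <- length(onset_s)
  assert_that(length(kind) == n && length(run_length) == n &&
                length(shocks) == n, "spec",
              "onset_s, kind, run_length and shocks must have equal length")
  bad <- setdiff(kind, setdiff(EVENT_KINDS, "regular"))
  assert_that(length(bad) == 0, "spec",
              sprintf("unknown event kind(s): %s", paste(bad, collapse = ", ")))
  run_length <- as.integer(run_length)
  shocks <- as.integer(shocks)
  ok_len <- (kind == "sEB" & run_length == 1L) |
    (kind == "mEB" & run_length >= 2L & run_length <= 5L) |
    (kind %in% c("TdP", "defib-TdP") & run_length >= 6L)
  assert_that(all(ok_len), "spec",
              "run_length inconsistent with kind (sEB=1, mEB=2-5, TdP>=6)")
  assert_that(all(shocks[kind == "defib-TdP"] >= 1L), "spec",
              "defib-TdP events require shocks >= 1")
  assert_that(all(shocks[kind != "defib-TdP"] == 0L), "spec",
              "only defib-TdP events may carry shocks")
  if (n > 1) {
    o <- order(onset_s)
    onset_s <- onset_s[o]; kind <- kind[o]
    run_length <- run_length[o]; shocks <- shocks[o]
  }
  structure(
    list(onset_s = as.numeric(onset_s), kind = kind,
         run_length = run_length, shocks = shocks),
    class = "event_schedule"
  )
}

#' Voltage-clamp step protocol
#'
#' Default follows the whole-cell potassium-current protocol: hold -80 mV,
#' -80 mV for 100 ms, -40 mV for 500 ms, a variable test step (-20 to +60 mV
#' in 10 mV increments) for 2000 ms, tail at -50 mV for 1000 ms, -80 mV for
#' 150 ms, -100 mV for 200 ms, -80 mV for 100 ms.
#'
#' @param levels_mv step levels; `NA` marks the variable test step
#' @param durations_ms step durations (> 0), same length as `levels_mv`
#' @param test_levels_mv levels the variable step sweeps through
#' @return an object of class `voltage_protocol`
#' @export
voltage_protocol <- function(
    levels_mv = c(-80, -40, NA, -50, -80, -100, -80),
    durations_ms = c(100, 500, 2000, 1000, 150, 200, 100),
    test_levels_mv = seq(-20, 60, by = 10)) {
  assert_that(length(levels_mv) == length(durations_ms), "spec",
              "levels_mv and durations_ms must have equal length")
  assert_that(all(durations_ms > 0), "spec", "step durations must be > 0")
  assert_that(sum(is.na(levels_mv)) == 1L, "spec",
              "exactly one variable (NA) test step is required")
  structure(
    list(levels_mv = levels_mv, durations_ms = durations_ms,
         test_levels_mv = test_levels_mv),
    class = "voltage_protocol"
  )
}

#' Patch-clamp sweep generator specification
#'
#' @param capacitance_pf cell capacitance (pF, > 0)
#' @param iks_amplitude_pa IKs tail amplitude at the +60 mV step (pA, >= 0)
#' @param ikr_amplitude_pa IKr tail amplitude at the +60 mV step (pA, >= 0)
#' @param residual_amplitude_pa blocker-insensitive background tail current,
#'   present in every drug condition (pA, >= 0); the default makes the
#'   IKs/IKr/residual fractions of the baseline tail 0.30/0.40/0.30
#' @param leak_amplitude_pa constant leak offset (pA)
#' @param noise_sd_pa Gaussian current noise SD (pA)
#' @param seed integer seed
#' @return an object of class `sweep_spec`
#' @export
sweep_spec <- function(capacitance_pf = 150, iks_amplitude_pa = 300,
                       ikr_amplitude_pa = 400, residual_amplitude_pa = 300,
                       leak_amplitude_pa = 20, noise_sd_pa = 0, seed = 1L) {
  assert_that(is_number(capacitance_pf) && capacitance_pf > 0, "spec",
              "capacitance_pf must be > 0")
  assert_that(iks_amplitude_pa >= 0 && ikr_amplitude_pa >= 0 &&
                residual_amplitude_pa >= 0, "spec",
              "current amplitudes must be >= 0")
  structure(
    list(capacitance_pf = capacitance_pf,
         iks_amplitude_pa = iks_amplitude_pa,
         ikr_amplitude_pa = ikr_amplitude_pa,
         residual_amplitude_pa = residual_amplitude_pa,
         leak_amplitude_pa = leak_amplitude_pa,
         noise_sd_pa = noise_sd_pa, seed = as.integer(seed)),
    class = "sweep_spec"
  )
}
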