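# Seeded generators of in-silico recordings with known ground truth.
#
# Beat morphologies are piecewise-analytic with exactly compact support:
#  - P wave: raised cosine (70 ms, 0.15 mV);
#  - QRS: triangle (sharp onset/offset, so threshold-extrapolated fiducials
#    are exact);
#  - T wave: half-cosine ascending limb (60 ms) + linear descending limb
#    (80 ms) ending exactly at the true T end, so the tangent method's
#    steepest-downslope line intersects baseline at the true T end;
#  - MAP / cellular AP: half-cosine upstroke, plateau, linear repolarization,
#    calibrated so the threshold-crossing duration at the calibration
#    fraction equals the configured duration exactly.
# Sampling is 1 kHz; times are ms from recording start.

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

TDP_CYCLE_MS <- 250   # ectopic/TdP cycle length (within the 200-300 ms range)

# render `amp * shape` onto sample vector x (1 ms grid, 0-based time)
render_raised_cosine <- function(x, t0, width, amp) {
  i <- max(0L, ceiling(t0)):min(length(x) - 1L, floor(t0 + width))
  if (!length(i)) return(x)
  ph <- (i - t0) / width
  x[i + 1L] <- x[i + 1L] + amp * 0.5 * (1 - cos(2 * pi * ph))
  x
}

render_triangle <- function(x, t0, width, amp) {
  i <- max(0L, ceiling(t0)):min(length(x) - 1L, floor(t0 + width))
  if (!length(i)) return(x)
  ph <- (i - t0) / width
  x[i + 1L] <- x[i + 1L] + amp * (1 - abs(2 * ph - 1))
  x
}

# T wave ending exactly at t_end: half-cosine rise then linear fall
render_t_wave <- function(x, t_end, amp = 0.30, fall = 80, rise = 60) {
  t_peak <- t_end - fall
  t_start <- t_peak - rise
  i <- max(0L, ceiling(t_start)):min(length(x) - 1L, floor(t_end))
  if (!length(i)) return(x)
  tt <- i
  v <- numeric(length(i))
  up <- tt <= t_peak
  v[up] <- amp * 0.5 * (1 - cos(pi * (tt[up] - t_start) / rise))
  v[!up] <- amp * (1 - (tt[!up] - t_peak) / fall)
  x[i + 1L] <- x[i + 1L] + v
  x
}

# plateau beat (MAP or cellular AP); duration_ms is the threshold-crossing
# duration at `frac` of repolarization, measured from the steepest upstroke
# (t_act). Returns the modified vector; repolarization is complete at
# t_act + duration_ms + (1 - frac) * decay_frac * duration_ms.
render_plateau_beat <- function(x, t_act, duration_ms, frac = 0.80,
                                amp = 25, decay_frac = 0.5, rise = 6) {
  d <- decay_frac * duration_ms
  dstart <- t_act + duration_ms - frac * d
  dend <- dstart + d
  t0 <- t_act - rise / 2
  i <- max(0L, ceiling(t0)):min(length(x) - 1L, floor(dend))
  if (!length(i)) return(x)
  tt <- i
  v <- numeric(length(i))
  ris <- tt < t_act + rise / 2
  dec <- tt >= dstart
  plat <- !ris & !dec
  v[ris] <- amp * 0.5 * (1 - cos(pi * (tt[ris] - t0) / rise))
  v[plat] <- amp
  v[dec] <- amp * (1 - (tt[dec] - dstart) / d)
  x[i + 1L] <- x[i + 1L] + v
  x
}

map_end_time <- function(t_act, duration_ms, frac = 0.80, decay_frac = 0.5) {
  d <- decay_frac * duration_ms
  t_act + duration_ms - frac * d + d
}

drug_ramp_ms <- function(t_ms, spec) {
  if (is.na(spec$drug_onset_s)) return(rep(0, length(t_ms)))
  dt <- (t_ms / 1000 - spec$drug_onset_s)
  ifelse(dt > 0,
         spec$drug_qt_increment_ms * (1 - exp(-dt / spec$drug_tau_s)), 0)
}

#' Generate an annotated in-silico ECG/MAP recording
#'
#' Emulates the study's recording conditions: ventricular pacing at a fixed
#' rate with AV dissociation (an independent atrial P-wave train), optional
#' saturating drug-induced QT/MAPD prolongation, AR(1) beat-to-beat duration
#' variability calibrated to an STV target, and scheduled runs of ectopic
#' complexes (sEB/mEB/TdP) at a 250 ms cycle length. Ground-truth fiducials
#' and per-beat durations are returned in the annotations.
#'
#' @param spec a [rhythm_spec()]
#' @param schedule an [event_schedule()]; must fit within the recording
#' @return a list with elements `trace` (a `signal_trace` with channels
#'   `ECG`, `LV-MAP`, `RV-MAP`) and `annotations` (a `beat_annotations` whose
#'   beats carry `qt_true`, `lv_mapd_true`, `rv_mapd_true` ground truth)
#' @export
generate_rhythm <- function(spec, schedule = event_schedule()) {
  stopifnot(inherits(spec, "rhythm_spec"), inherits(schedule, "event_schedule"))
  dur_ms <- round(spec$duration_s * 1000)
  rr <- 60000 / spec$ventricular_rate
  n_ev <- length(schedule$onset_s)

  # --- validate the schedule against this spec -----------------------------
  if (n_ev) {
    onset_ms <- schedule$onset_s * 1000
    end_ms <- onset_ms + (schedule$run_length - 1L) * TDP_CYCLE_MS
    if (any(onset_ms < rr + 600))
      tdx_error("schedule", "event onset precedes the first stable beats")
    if (any(end_ms + spec$qt_baseline_ms + 600 > dur_ms))
      tdx_error("schedule", sprintf(
        "duration too short: event ending at %.0f ms does not fit in %d ms",
        max(end_ms), dur_ms))
    if (n_ev > 1) {
      gap <- onset_ms[-1] - end_ms[-n_ev]
      if (any(gap < rr + 1000))
        tdx_error("schedule", sprintf(
          "overlapping or abutting events: a regular beat must separate runs (min gap %.0f ms)",
          rr + 1000))
    }
    long <- schedule$kind == "defib-TdP" &
      (schedule$run_length * TDP_CYCLE_MS) <= 10000
    if (any(long))
      tdx_error("schedule",
                "defib-TdP events must outlast 10 s (run_length >= 41 at the 250 ms TdP cycle)")
  }

  with_seed(spec$seed, {
    # --- beat grid ---------------------------------------------------------
    t0 <- 100
    grid_end <- dur_ms - spec$qt_baseline_ms - 200
    reg_q <- if (grid_end >= t0) seq(t0, grid_end, by = rr) else numeric(0)
    beats <- data.frame(q_on = reg_q,
                        class = rep("regular", length(reg_q)),
                        stringsAsFactors = FALSE)
    defib_marks <- numeric(0)
    events <- empty_events_df()
    if (n_ev) {
      keep <- rep(TRUE, nrow(beats))
      ect <- list()
      for (k in seq_len(n_ev)) {
        e_q <- schedule$onset_s[k] * 1000 + seq_len(schedule$run_length[k]) *
          TDP_CYCLE_MS - TDP_CYCLE_MS
        keep <- keep & !(beats$q_on > min(e_q) - 500 & beats$q_on < max(e_q) + 600)
        ect[[k]] <- data.frame(q_on = e_q, class = "ectopic",
                               stringsAsFactors = FALSE)
        off <- max(e_q) + TDP_CYCLE_MS
        events <- rbind(events, data.frame(
          kind = schedule$kind[k], onset_ms = min(e_q), offset_ms = off,
          run_length = schedule$run_length[k], shocks = schedule$shocks[k],
          stringsAsFactors = FALSE))
        if (schedule$kind[k] == "defib-TdP")
          defib_marks <- c(defib_marks,
                           off - 60 - 120 * (seq_len(schedule$shocks[k]) - 1L))
      }
      beats <- rbind(beats[keep, , drop = FALSE], do.call(rbind, ect))
      beats <- beats[order(beats$q_on), , drop = FALSE]
    }
    n_beats <- nrow(beats)
    reg <- beats$class == "regular"
    n_reg <- sum(reg)

    # --- per-beat durations (ground truth) ---------------------------------
    lv_ratio <- 0.68; rv_ratio <- 0.61
    if (n_reg > 0) {
      ramp <- drug_ramp_ms(beats$q_on[reg], spec)
      qt <- simulate_duration_series(n_reg, spec$qt_baseline_ms,
                                     spec$stv_target_ms, spec$ar_phi, ramp)
      qt <- pmax(qt, spec$qrs_width_ms + 145)
      lv <- simulate_duration_series(n_reg, lv_ratio * spec$qt_baseline_ms,
                                     spec$stv_target_ms, spec$ar_phi,
                                     lv_ratio * ramp)
      rv <- simulate_duration_series(n_reg, rv_ratio * spec$qt_baseline_ms,
                                     spec$stv_target_ms, spec$ar_phi,
                                     rv_ratio * ramp)
    } else {
      qt <- lv <- rv <- numeric(0)
    }

    # --- atrial train ------------------------------------------------------
    p_waves <- numeric(0)
    if (spec$atrial_rate > 0) {
      pp <- 60000 / spec$atrial_rate
      p_waves <- seq(37, dur_ms - 80, by = pp)
    }

    # --- assemble channels -------------------------------------------------
    n_samp <- dur_ms
    ecg <- numeric(n_samp); lvm <- numeric(n_samp); rvm <- numeric(n_samp)
    for (p in p_waves) ecg <- render_raised_cosine(ecg, p, 70, 0.15)

    ann <- data.frame(beat = seq_len(n_beats), class = beats$class,
                      p_on = rep(NA_real_, n_beats), q_on = beats$q_on,
                      qrs_end = rep(NA_real_, n_beats),
                      t_end = rep(NA_real_, n_beats),
                      lv_map_up = rep(NA_real_, n_beats),
                      lv_map_end = rep(NA_real_, n_beats),
                      rv_map_up = rep(NA_real_, n_beats),
                      rv_map_end = rep(NA_real_, n_beats),
                      qt_true = rep(NA_real_, n_beats),
                      lv_mapd_true = rep(NA_real_, n_beats),
                      rv_mapd_true = rep(NA_real_, n_beats),
                      stringsAsFactors = FALSE)
    ri <- 0L; ect_sign <- 1
    for (b in seq_len(n_beats)) {
      q <- beats$q_on[b]
      if (reg[b]) {
        ri <- ri + 1L
        w <- spec$qrs_width_ms
        ecg <- render_triangle(ecg, q, w, 1.0)
        ecg <- render_t_wave(ecg, q + qt[ri])
        lvm <- render_plateau_beat(lvm, q + 5, lv[ri])
        rvm <- render_plateau_beat(rvm, q + 15, rv[ri])
        ann$qrs_end[b] <- q + w
        ann$t_end[b] <- q + qt[ri]
        ann$qt_true[b] <- qt[ri]
        ann$lv_map_up[b] <- q + 5
        ann$lv_map_end[b] <- map_end_time(q + 5, lv[ri])
        ann$rv_map_up[b] <- q + 15
        ann$rv_map_end[b] <- map_end_time(q + 15, rv[ri])
        ann$lv_mapd_true[b] <- lv[ri]
        ann$rv_mapd_true[b] <- rv[ri]
      } else {
        ecg <- render_triangle(ecg, q, 90, 1.3 * ect_sign)
        ect_sign <- -ect_sign
        m_e <- 0.5 * spec$qt_baseline_ms * lv_ratio
        lvm <- render_plateau_beat(lvm, q + 5, m_e)
        rvm <- render_plateau_beat(rvm, q + 15, m_e)
        ann$qrs_end[b] <- q + 90
      }
      prior <- p_waves[p_waves <= q]
      if (length(prior)) ann$p_on[b] <- max(prior)
    }
    if (spec$noise_sd > 0) {
      ecg <- ecg + stats::rnorm(n_samp, 0, spec$noise_sd)
      lvm <- lvm + stats::rnorm(n_samp, 0, spec$noise_sd * 25)
      rvm <- rvm + stats::rnorm(n_samp, 0, spec$noise_sd * 25)
    }
    trace <- signal_trace(cbind(`ECG` = ecg, `LV-MAP` = lvm, `RV-MAP` = rvm),
                          1000, units = c("mV", "mV", "mV"))
    list(trace = trace,
         annotations = beat_annotations(ann, p_waves, events, defib_marks))
  })
}

#' Generate an in-silico left-ventricular pressure trace
#'
#' One half-sine pressure cycle per ventricular beat, placed 30 ms after QRS
#' onset on the same beat grid as [generate_rhythm()]. The analytic peak
#' derivative of a half-sine of amplitude A over half-period T is A*pi/T, so
#' the amplitude is chosen as `contractility * T / pi` and the configured
#' contractility is the exact ground-truth dP/dt max.
#'
#' @param spec a [rhythm_spec()] (rates, duration, seed and noise are used)
#' @param contractility_mmhg_s ground-truth LV dP/dt max in mmHg/s (> 0)
#' @param systole_ms half-sine cycle length in ms
#' @param baseline_mmhg diastolic pressure level
#' @param noise_sd_mmhg Gaussian amplitude noise (0 gives a deterministic
#'   trace)
#' @return a `signal_trace` with channel `LV-P` (mmHg); its `"truth"`
#'   attribute records dP/dt extrema, cycle onsets and the ground-truth
#'   QLVPend implied by the 5 %-of-amplitude cycle-end threshold
#' @export
generate_pressure <- function(spec, contractility_mmhg_s = 1500,
                              systole_ms = 350, baseline_mmhg = 8,
                              noise_sd_mmhg = 0) {
  stopifnot(inherits(spec, "rhythm_spec"))
  assert_that(is_number(contractility_mmhg_s) && contractility_mmhg_s > 0,
              "spec", "contractility must be > 0")
  dur_ms <- round(spec$duration_s * 1000)
  rr <- 60000 / spec$ventricular_rate
  q_on <- seq(100, dur_ms - spec$qt_baseline_ms - 200, by = rr)
  t_sys <- systole_ms / 1000
  amp <- contractility_mmhg_s * t_sys / pi
  x <- rep(baseline_mmhg, dur_ms)
  onsets <- q_on + 30
  for (t0 in onsets) {
    i <- max(0L, ceiling(t0)):min(dur_ms - 1L, floor(t0 + systole_ms))
    x[i + 1L] <- x[i + 1L] + amp * sin(pi * (i - t0) / systole_ms)
  }
  if (noise_sd_mmhg > 0) {
    x <- with_seed(spec$seed, x + stats::rnorm(dur_ms, 0, noise_sd_mmhg))
  }
  trace <- signal_trace(cbind(`LV-P` = x), 1000, units = "mmHg")
  # 5%-of-amplitude crossing on the descending limb of sin(pi*t/T)
  x_end <- 1 - asin(0.05) / pi
  attr(trace, "truth") <- list(
    dpdt_max = contractility_mmhg_s, dpdt_min = -contractility_mmhg_s,
    qrs_onsets_ms = q_on, cycle_onsets_ms = onsets,
    qlvp_end_ms = 30 + x_end * systole_ms, amplitude_mmhg = amp)
  trace
}

act_iks <- function(v) stats::plogis((v - 10) / 10) / stats::plogis(5)
act_ikr <- function(v) stats::plogis((v + 15) / 8) / stats::plogis(75 / 8)
act_res <- function(v) stats::plogis((v + 20) / 12) / stats::plogis(80 / 12)

# deactivating tail template: a brief peak plateau (20 ms, so a smoothed
# peak search recovers the amplitude exactly), exponential deactivation,
# and identically 0 over the final 10 % of the tail segment (so the
# settled-level reference recovers amplitudes exactly in noiseless data)
tail_shape <- function(t_ms, tail_ms, tau, plateau_ms = 20) {
  tcut <- 0.9 * tail_ms
  tt <- pmax(t_ms - plateau_ms, 0)
  denom <- 1 - exp(-(tcut - plateau_ms) / tau)
  s <- (exp(-tt / tau) - exp(-(tcut - plateau_ms) / tau)) / denom
  pmax(s, 0)
}

#' Generate a three-condition patch-clamp sweep set
#'
#' Produces sweeps under `baseline`, `+HMR1556` and `+HMR1556+dofetilide`
#' for every test level of the protocol. The IKs component is absent in the
#' HMR condition and both components are absent with dofetilide added, so
#' pharmacological subtraction recovers the configured amplitudes. Component
#' amplitudes scale with a sigmoidal activation curve normalized to 1 at the
#' +60 mV step; `iks_amplitude_pa`/`ikr_amplitude_pa` are the exact tail
#' amplitudes after the +60 mV step.
#'
#' @param spec a [sweep_spec()]
#' @param protocol a [voltage_protocol()]
#' @return an object of class `patch_clamp_recording`: sweep matrices per
#'   condition (one column per test level), the protocol, capacitance, and a
#'   `truth` element with per-level component amplitudes
#' @export
generate_sweeps <- function(spec, protocol = voltage_protocol()) {
  stopifnot(inherits(spec, "sweep_spec"), inherits(protocol, "voltage_protocol"))
  fs <- 1000
  n_samp <- round(sum(protocol$durations_ms))
  bounds <- cumsum(protocol$durations_ms)
  starts <- c(0, bounds[-length(bounds)])
  var_i <- which(is.na(protocol$levels_mv))
  tail_i <- var_i + 1L
  assert_that(tail_i <= length(protocol$levels_mv), "spec",
              "protocol must contain a tail step after the variable step")
  tail_ms <- protocol$durations_ms[tail_i]
  t_rel <- seq_len(n_samp) - 1  # ms at 1 kHz
  with_seed(spec$seed, {
    conds <- c("baseline", "hmr1556", "hmr1556_dofetilide")
    out <- lapply(conds, function(cond) {
      has_ks <- cond == "baseline"
      has_kr <- cond %in% c("baseline", "hmr1556")
      m <- sapply(protocol$test_levels_mv, function(v) {
        lev <- protocol$levels_mv
        lev[var_i] <- v
        seg <- findInterval(t_rel, bounds) + 1L
        i_leak <- spec$leak_amplitude_pa * (lev[seg] + 80) / 140
        cur <- i_leak
        # activating current during the test step (rendered for realism)
        in_step <- seg == var_i
        tau_act <- 300
        a_ks <- spec$iks_amplitude_pa * act_iks(v)
        a_kr <- spec$ikr_amplitude_pa * act_ikr(v)
        a_rs <- spec$residual_amplitude_pa * act_res(v)
        amp_step <- a_rs + (if (has_ks) a_ks else 0) +
          (if (has_kr) a_kr else 0)
        cur[in_step] <- cur[in_step] +
          amp_step * (1 - exp(-(t_rel[in_step] - starts[var_i]) / tau_act))
        in_tail <- seg == tail_i
        tt <- t_rel[in_tail] - starts[tail_i]
        # blocker-insensitive residual current, present in every condition
        cur[in_tail] <- cur[in_tail] + a_rs * tail_shape(tt, tail_ms, tau = 120)
        if (has_ks) cur[in_tail] <- cur[in_tail] +
            a_ks * tail_shape(tt, tail_ms, tau = 200)
        if (has_kr) cur[in_tail] <- cur[in_tail] +
            a_kr * tail_shape(tt, tail_ms, tau = 50)
        if (spec$noise_sd_pa > 0)
          cur <- cur + stats::rnorm(n_samp, 0, spec$noise_sd_pa)
        cur
      })
      colnames(m) <- paste0(protocol$test_levels_mv, "mV")
      m
    })
    names(out) <- conds
    structure(
      list(conditions = out, protocol = protocol,
           capacitance_pf = spec$capacitance_pf, sampling_rate_hz = fs,
           truth = list(
             iks_pa = spec$iks_amplitude_pa * act_iks(protocol$test_levels_mv),
             ikr_pa = spec$ikr_amplitude_pa * act_ikr(protocol$test_levels_mv),
             residual_pa = spec$residual_amplitude_pa *
               act_res(protocol$test_levels_mv),
             test_levels_mv = protocol$test_levels_mv)),
      class = "patch_clamp_recording")
  })
}

#' Generate a paced cellular action-potential train
#'
#' Stimulation at `rate_hz` (default 0.5 Hz as in current-clamp recordings
#' of isolated cardiomyocytes), with AR(1) beat-to-beat APD variability.
#'
#' @param n_beats number of action potentials
#' @param apd90_ms mean APD at 90 % repolarization
#' @param stv_target_ms expected STV of the APD90 series
#' @param amplitude_mv AP amplitude above resting potential
#' @param rest_mv resting membrane potential
#' @param rate_hz stimulation rate
#' @param noise_sd_mv sample noise SD
#' @param phi AR(1) coefficient
#' @param seed integer seed
#' @return a `signal_trace` with channel `AP` (mV); its `"truth"` attribute
#'   carries the per-beat APD90/APD50 ground truth and upstroke times
#' @export
generate_ap_train <- function(n_beats = 40, apd90_ms = 300,
                              stv_target_ms = 0.5, amplitude_mv = 120,
                              rest_mv = -80, rate_hz = 0.5, noise_sd_mv = 0,
                              phi = 0.5, seed = 1L) {
  cl_ms <- 1000 / rate_hz
  assert_that(apd90_ms < cl_ms - 200, "spec",
              "apd90_ms must fit within the stimulation cycle")
  with_seed(seed, {
    apd90 <- simulate_duration_series(n_beats, apd90_ms, stv_target_ms, phi)
    n_samp <- round(n_beats * cl_ms)
    x <- numeric(n_samp)
    t_act <- 100 + (seq_len(n_beats) - 1) * cl_ms
    for (b in seq_len(n_beats)) {
      x <- render_plateau_beat(x, t_act[b], apd90[b], frac = 0.90,
                               amp = amplitude_mv, decay_frac = 0.3,
                               rise = 4)
    }
    x <- x + rest_mv
    if (noise_sd_mv > 0) x <- x + stats::rnorm(n_samp, 0, noise_sd_mv)
    trace <- signal_trace(cbind(`AP` = x), 1000, units = "mV")
    attr(trace, "truth") <- list(
      apd90_ms = apd90, apd50_ms = apd90 * (1 - 0.3 * (0.9 - 0.5)),
      upstroke_ms = t_act)
    trace
  })
}
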