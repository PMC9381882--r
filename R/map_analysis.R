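# Monophasic action potential duration, beat-to-beat short-term variability
# (STV) of repolarization, spatial dispersion, and the exclusion rules.
#
# STV is the Poincare-plot dispersion statistic
#   STV = sum |D_{n+1} - D_n| / (N * divisor)
# over N consecutive beat pairs (default N = 30). The divisor is sqrt(2) in
# `sqrt2` mode (the convention of the originating STV literature, default)
# or 2 in `literal` mode; the two differ by the exact factor sqrt(2).

#' Construct a per-beat duration series
#'
#' @param durations_ms ordered per-beat durations (ms, > 0; NA allowed for
#'   beats without a resolvable duration, which count as masked)
#' @param source one of `"LV-MAP"`, `"RV-MAP"`, `"cellular-AP"`
#' @param beat_index optional beat indices
#' @param mask logical exclusion mask (TRUE = excluded)
#' @param reason character reason codes for masked beats
#' @return an object of class `duration_series`
#' @export
duration_series <- function(durations_ms, source = "LV-MAP",
                            beat_index = seq_along(durations_ms),
                            mask = rep(FALSE, length(durations_ms)),
                            reason = rep(NA_character_, length(durations_ms))) {
  assert_that(length(mask) == length(durations_ms) &&
                length(reason) == length(durations_ms), "spec",
              "mask and reason must match the series length")
  assert_that(all(durations_ms > 0 | is.na(durations_ms)), "spec",
              "durations must be > 0")
  mask <- mask | is.na(durations_ms)
  reason[is.na(durations_ms) & is.na(reason)] <- "unresolved"
  structure(
    list(durations_ms = as.numeric(durations_ms),
         source = source, beat_index = beat_index,
         mask = mask, reason = reason),
    class = "duration_series")
}

#' @export
print.duration_series <- function(x, ...) {
  cat(sprintf("<duration_series> %s: %d beat(s), %d masked, mean %.1f ms\n",
              x$source, length(x$durations_ms), sum(x$mask),
              mean(x$durations_ms[!x$mask])))
  invisible(x)
}

#' MAP (or AP) duration at a repolarization fraction
#'
#' Duration from activation (the steepest upstroke) to the first crossing of
#' `baseline + amplitude * (1 - fraction)` on the repolarizing limb, linearly
#' interpolated between samples. Baseline is the median of the diastolic
#' segment preceding the upstroke; amplitude is the plateau peak minus
#' baseline.
#'
#' @param waveform numeric vector, one beat window at 1 kHz
#' @param repolarization_fraction fraction of repolarization (default 0.80)
#' @param baseline_window_ms diastolic samples used for the baseline estimate
#' @return duration in ms
#' @export
mapd <- function(waveform, repolarization_fraction = 0.80,
                 baseline_window_ms = 40) {
  assert_that(is_number(repolarization_fraction) &&
                repolarization_fraction > 0 && repolarization_fraction < 1,
              "domain", "repolarization_fraction must lie in (0, 1)")
  n <- length(waveform)
  assert_that(n >= 10, "domain", "waveform too short")
  up <- which.max(diff(waveform))  # steepest upstroke, sample index
  nb <- min(baseline_window_ms, max(up - 2L, 1L))
  baseline <- stats::median(waveform[seq_len(nb)])
  pk <- up + which.max(waveform[up:n]) - 1L
  amp <- waveform[pk] - baseline
  assert_that(amp > 0, "unresolved_repolarization",
              "no upstroke above baseline in beat window")
  level <- baseline + amp * (1 - repolarization_fraction)
  below <- which(waveform[pk:n] <= level)
  if (!length(below))
    tdx_error("unresolved_repolarization",
              sprintf("no crossing of the %.0f%% repolarization level within the beat window",
                      100 * repolarization_fraction))
  j <- pk + below[1] - 1L  # first sample at/below level after the peak
  t_cross <- interp_crossing_ms(j - 2L, waveform[j - 1L], waveform[j], level)
  t_act <- up - 0.5  # 0-based ms of the steepest-slope midpoint
  t_cross - t_act
}

#' Apply the study's beat-exclusion rules to a duration series
#'
#' Masks ectopic beats and complexes with a P wave in the T-wave-end
#' neighbourhood (default +/- 40 ms), with machine-readable reason codes.
#' All other beats are untouched.
#'
#' @param series a `duration_series` aligned with `beats$beats`
#' @param beats a `beat_annotations`
#' @param p_on_t_window_ms half-width of the P-on-T window
#' @return the masked `duration_series`
#' @export
exclude_beats <- function(series, beats, p_on_t_window_ms = 40) {
  stopifnot(inherits(series, "duration_series"),
            inherits(beats, "beat_annotations"))
  df <- beats$beats
  assert_that(nrow(df) == length(series$durations_ms), "spec",
              "annotations must cover the series (one beat per duration)")
  ect <- df$class == "ectopic" & !series$mask
  series$mask[ect] <- TRUE
  series$reason[ect] <- "ectopic"
  if (length(beats$p_waves)) {
    for (b in seq_len(nrow(df))) {
      if (series$mask[b] || is.na(df$t_end[b])) next
      if (any(abs(beats$p_waves - df$t_end[b]) <= p_on_t_window_ms)) {
        series$mask[b] <- TRUE
        series$reason[b] <- "p_on_t"
      }
    }
  }
  series
}

#' Short-term variability of a repolarization-duration series
#'
#' Uses the first window of `n_beats + 1` consecutive unmasked beats; masked
#' beats break consecutiveness (a masked beat invalidates both adjacent
#' pairs, because the statistic is defined on consecutive beats only).
#'
#' @param series a `duration_series` (or bare numeric vector)
#' @param n_beats number of successive-difference pairs (default 30)
#' @param divisor_mode `"sqrt2"` (divide by `n_beats * sqrt(2)`, default) or
#'   `"literal"` (divide by `n_beats * 2`)
#' @return an `stv_result` with fields `stv`, `n_pairs`, `divisor_mode`
#' @export
stv <- function(series, n_beats = 30, divisor_mode = c("sqrt2", "literal")) {
  divisor_mode <- match.arg(divisor_mode)
  if (is.numeric(series)) series <- duration_series(series)
  stopifnot(inherits(series, "duration_series"))
  run <- first_run(!series$mask, n_beats + 1L)
  if (is.null(run)) {
    tdx_error("insufficient_data", sprintf(
      "need %d consecutive unmasked beats, longest run is %d",
      n_beats + 1L, longest_run(!series$mask)))
  }
  d <- series$durations_ms[run]
  total <- sum(abs(diff(d)))
  div <- if (divisor_mode == "sqrt2") n_beats * sqrt(2) else n_beats * 2
  structure(
    list(stv = total / div, n_pairs = n_beats, divisor_mode = divisor_mode),
    class = "stv_result")
}

#' @export
print.stv_result <- function(x, ...) {
  cat(sprintf("<stv_result> STV = %.3f ms (%d pairs, divisor '%s')\n",
              x$stv, x$n_pairs, x$divisor_mode))
  invisible(x)
}

#' Spatial dispersion of repolarization: LV MAPD minus RV MAPD
#' @param lv_mapd_ms left-ventricular MAP duration (ms)
#' @param rv_mapd_ms right-ventricular MAP duration (ms)
#' @return signed difference in ms
#' @export
delta_mapd <- function(lv_mapd_ms, rv_mapd_ms) {
  assert_that(all(is.finite(lv_mapd_ms)) && all(is.finite(rv_mapd_ms)),
              "domain", "both MAPD values must be finite")
  lv_mapd_ms - rv_mapd_ms
}

#' Measure a MAPD series from a MAP channel using beat annotations
#'
#' Applies [mapd()] to a window around each annotated MAP upstroke.
#'
#' @param trace a `signal_trace`
#' @param beats a `beat_annotations`
#' @param channel `"LV-MAP"` or `"RV-MAP"`
#' @param repolarization_fraction passed to [mapd()]
#' @return a `duration_series` (ectopic/unresolvable beats masked as NA)
#' @export
measure_mapd_series <- function(trace, beats, channel = "LV-MAP",
                                repolarization_fraction = 0.80) {
  x <- trace_channel(trace, channel)
  df <- beats$beats
  up_col <- if (channel == "RV-MAP") "rv_map_up" else "lv_map_up"
  out <- rep(NA_real_, nrow(df))
  rr <- if (nrow(df) > 1) stats::median(diff(df$q_on)) else 1000
  for (b in seq_len(nrow(df))) {
    t_up <- df[[up_col]][b]
    if (is.na(t_up)) t_up <- df$q_on[b] + 5
    # window must end before the next upstroke so the steepest-slope search
    # stays within this beat
    lo <- max(1L, round(t_up) - 49L)
    hi <- min(length(x), round(t_up + 0.9 * rr))
    w <- x[lo:hi]
    out[b] <- tryCatch(mapd(w, repolarization_fraction),
                       torsadex_error = function(e) NA_real_)
  }
  duration_series(out, source = channel, beat_index = df$beat)
}
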