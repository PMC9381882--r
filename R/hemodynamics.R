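# Left-ventricular pressure cycle metrics and the electromechanical window.
#
# The derivative is taken with a Savitzky-Golay filter (order 2, default
# 15 ms window) before the extremum search; the cycle end is the crossing of
# baseline + 5 % of cycle amplitude on the descending limb.

#' dP/dt extrema of consecutive pressure cycles
#'
#' Detects cycles as excursions above baseline + 50 % of amplitude, computes
#' the smoothed first derivative and reports per-cycle extrema averaged over
#' `n_cycles` consecutive cycles.
#'
#' @param trace a `signal_trace` with an `LV-P` channel (or a bare numeric
#'   vector at 1 kHz)
#' @param n_cycles number of consecutive cycles to average (default 5)
#' @param sg_window_ms derivative smoothing window
#' @return a list with `dpdt_max` and `dpdt_min` (mmHg/s) and `n_cycles`
#' @export
dpdt_extrema <- function(trace, n_cycles = 5, sg_window_ms = 15) {
  x <- pressure_vector(trace)
  fs <- if (inherits(trace, "signal_trace")) trace$sampling_rate_hz else 1000
  rng <- range(x)
  if (diff(rng) < 1e-9) {
    return(list(dpdt_max = 0, dpdt_min = 0, n_cycles = 0L))
  }
  thr <- rng[1] + 0.5 * diff(rng)
  above <- x >= thr
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cyc <- which(r$values)
  # complete cycles only: below-threshold data on both sides
  cyc <- cyc[cyc > 1 & cyc < length(r$values)]
  if (length(cyc) < 1)
    tdx_error("insufficient_data", "no complete pressure cycle in segment")
  if (length(cyc) < n_cycles)
    tdx_error("insufficient_data", sprintf(
      "need %d complete cycles, found %d", n_cycles, length(cyc)))
  d <- sg_derivative(x, fs, sg_window_ms) * 1000  # mmHg/s
  mx <- mn <- numeric(n_cycles)
  for (k in seq_len(n_cycles)) {
    lo <- max(1L, starts[cyc[k]] - 60L)
    hi <- min(length(x), ends[cyc[k]] + 60L)
    mx[k] <- max(d[lo:hi]); mn[k] <- min(d[lo:hi])
  }
  list(dpdt_max = mean(mx), dpdt_min = mean(mn), n_cycles = n_cycles)
}

pressure_vector <- function(trace) {
  if (inherits(trace, "signal_trace")) trace_channel(trace, "LV-P")
  else as.numeric(trace)
}

#' QLVPend: QRS onset to the end of the pressure cycle
#'
#' The cycle end is where pressure returns to baseline on the descending
#' limb, defined as the interpolated crossing of baseline + 5 % of cycle
#' amplitude.
#'
#' @param qrs_onset_ms QRS onset time (ms, same clock as the trace)
#' @param trace pressure trace (or numeric vector at 1 kHz) containing the
#'   cycle that follows the QRS onset
#' @param end_fraction threshold fraction of cycle amplitude (default 0.05)
#' @param search_window_ms how far past the QRS onset to search for the
#'   cycle (bounds the analysis to the cycle belonging to this beat)
#' @return QLVPend in ms
#' @export
qlvp_end <- function(qrs_onset_ms, trace, end_fraction = 0.05,
                     search_window_ms = 900) {
  x <- pressure_vector(trace)
  n <- length(x)
  i_on <- max(1L, round(qrs_onset_ms) + 1L)
  assert_that(i_on < n, "domain", "QRS onset must precede the cycle end")
  seg <- x[i_on:min(n, i_on + search_window_ms)]
  base <- min(seg)
  amp <- max(seg) - base
  assert_that(amp > 0, "unresolved_cycle", "no pressure cycle after QRS onset")
  level <- base + end_fraction * amp
  pk <- which.max(seg)
  below <- which(seg[pk:length(seg)] <= level)
  if (!length(below))
    tdx_error("unresolved_cycle",
              "pressure does not return to baseline after the peak")
  j <- pk + below[1] - 1L
  t_cross <- interp_crossing_ms(i_on - 1L + j - 2L, seg[j - 1L],
                                seg[j], level)
  t_cross - qrs_onset_ms
}

#' Electromechanical window: QLVPend minus QT
#'
#' Negative values (electrical repolarization outlasting mechanical systole)
#' are reported as such.
#'
#' @param qlvp_end_ms QLVPend (ms)
#' @param qt_ms QT interval (ms)
#' @return EMW in ms (may be negative)
#' @export
emw <- function(qlvp_end_ms, qt_ms) {
  assert_that(all(is.finite(qlvp_end_ms)) && all(is.finite(qt_ms)),
              "domain", "both arguments must be finite")
  qlvp_end_ms - qt_ms
}
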