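# Patch-clamp current decomposition and action-potential metrics.
#
# Tail currents are measured on the -50 mV tail segment that follows the
# variable test step (the +60 mV sweep feeds the headline density). The
# reference level is the settled current over the final 10 % of the tail
# segment, because the recording convention does not fix a zero-current
# baseline; the peak is the largest deviation from that level,
# sign-preserving. IKs is the HMR 1556-sensitive difference, IKr the
# dofetilide-sensitive difference, and the residual is what remains after
# both blockers.

tail_segment_bounds <- function(protocol) {
  var_i <- which(is.na(protocol$levels_mv))
  tail_i <- var_i + 1L
  bounds <- cumsum(protocol$durations_ms)
  start_ms <- if (tail_i == 1L) 0 else bounds[tail_i - 1L]
  c(start_ms, bounds[tail_i])
}

#' Peak tail current after a test step
#'
#' @param recording a `patch_clamp_recording`
#' @param condition one of `"baseline"`, `"hmr1556"`, `"hmr1556_dofetilide"`
#' @param test_level_mv test-step level whose sweep to use (default +60 mV)
#' @param settle_fraction final fraction of the tail segment defining the
#'   settled reference level (default 0.10)
#' @param smooth_ms running-mean width applied before the peak search
#'   (default 15 ms); suppresses noise-maximum bias in the peak estimate
#' @return peak tail current in pA, relative to the settled level
#' @export
tail_current <- function(recording, condition = "baseline",
                         test_level_mv = 60, settle_fraction = 0.10,
                         smooth_ms = 15) {
  stopifnot(inherits(recording, "patch_clamp_recording"))
  assert_that(condition %in% names(recording$conditions), "spec",
              sprintf("unknown condition '%s'", condition))
  m <- recording$conditions[[condition]]
  col <- paste0(test_level_mv, "mV")
  assert_that(col %in% colnames(m), "protocol_mismatch",
              sprintf("no sweep for the %d mV test step", test_level_mv))
  b <- tail_segment_bounds(recording$protocol)
  fs <- recording$sampling_rate_hz
  i0 <- round(b[1] * fs / 1000) + 1L
  i1 <- round(b[2] * fs / 1000)
  seg <- m[i0:i1, col]
  ns <- length(seg)
  settled <- mean(seg[(ns - ceiling(settle_fraction * ns) + 1L):ns])
  w <- max(1L, round(smooth_ms * fs / 1000))
  sm <- if (w > 1L) running_mean(seg, w) else seg
  dev <- sm - settled
  dev[which.max(abs(dev))]
}

# centred running mean with truncated edges (exact on flat segments)
running_mean <- function(x, w) {
  n <- length(x)
  h <- w %/% 2L
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - h, 1L)
  hi <- pmin(seq_len(n) + h, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Current density: tail current normalized by cell capacitance
#' @param tail_pa tail current (pA)
#' @param capacitance_pf cell capacitance (pF, > 0)
#' @return density in pA/pF
#' @export
current_density <- function(tail_pa, capacitance_pf) {
  assert_that(all(capacitance_pf > 0), "domain", "capacitance must be > 0")
  tail_pa / capacitance_pf
}

#' Pharmacological decomposition of the delayed-rectifier tail current
#'
#' IKs is the component blocked by HMR 1556 (baseline minus +HMR tails),
#' IKr the component blocked by dofetilide on top of HMR (+HMR minus
#' +HMR+dofetilide), and the residual is the remaining tail. Components are
#' returned as densities (pA/pF) along with their fractions of the baseline
#' tail. Negative components beyond the noise tolerance are flagged as
#' rundown, not clipped.
#'
#' @param recording a `patch_clamp_recording` with all three conditions
#' @param test_level_mv test-step level (default +60 mV)
#' @param rundown_tolerance_pa negative-component tolerance before a rundown
#'   warning is raised (pA)
#' @return a list with `iks`, `ikr`, `residual`, `total` (pA/pF),
#'   `fractions` (of the baseline tail) and a `rundown` flag
#' @export
decompose_currents <- function(recording, test_level_mv = 60,
                               rundown_tolerance_pa = 10) {
  need <- c("baseline", "hmr1556", "hmr1556_dofetilide")
  assert_that(all(need %in% names(recording$conditions)), "spec",
              "all three drug conditions are required")
  t_base <- tail_current(recording, "baseline", test_level_mv)
  t_hmr <- tail_current(recording, "hmr1556", test_level_mv)
  t_both <- tail_current(recording, "hmr1556_dofetilide", test_level_mv)
  iks_pa <- t_base - t_hmr
  ikr_pa <- t_hmr - t_both
  rundown <- FALSE
  if (min(iks_pa, ikr_pa) < -rundown_tolerance_pa) {
    rundown <- TRUE
    warning(sprintf(
      "negative current component beyond tolerance (IKs %.1f, IKr %.1f pA): possible rundown",
      iks_pa, ikr_pa), call. = FALSE)
  }
  cm <- recording$capacitance_pf
  fr <- if (abs(t_base) > .Machine$double.eps) {
    c(iks = iks_pa, ikr = ikr_pa, residual = t_both) / t_base
  } else c(iks = NA_real_, ikr = NA_real_, residual = NA_real_)
  list(iks = current_density(iks_pa, cm),
       ikr = current_density(ikr_pa, cm),
       residual = current_density(t_both, cm),
       total = current_density(t_base, cm),
       fractions = fr, rundown = rundown)
}

#' Action-potential metrics of a paced cellular recording
#'
#' Detects upstrokes on the `AP` channel, measures APD at 90 % and 50 % of
#' repolarization per beat with the threshold rule of [mapd()], and computes
#' the STV of the APD90 series.
#'
#' @param trace a `signal_trace` with an `AP` channel (1 kHz)
#' @param stv_beats pairs used for STV (default 30; requires
#'   `stv_beats + 1` resolvable APs)
#' @param divisor_mode STV divisor mode, see [stv()]
#' @return an `ap_metrics` list: `apd90`, `apd50` (mean ms), `stv` (ms),
#'   `apd90_series` (a `duration_series`), `n_aps`
#' @export
ap_metrics <- function(trace, stv_beats = 30,
                       divisor_mode = c("sqrt2", "literal")) {
  divisor_mode <- match.arg(divisor_mode)
  x <- trace_channel(trace, "AP")
  n <- length(x)
  d <- diff(x)
  thr <- 0.5 * max(d)
  assert_that(thr > 0, "no_beats", "no upstroke found in AP channel")
  ups <- local_maxima(d, thr, 400)
  assert_that(length(ups) >= 2, "no_beats", "fewer than two action potentials")
  cl <- stats::median(diff(ups))
  apd90 <- apd50 <- rep(NA_real_, length(ups))
  for (b in seq_along(ups)) {
    lo <- max(1L, ups[b] - 49L)
    hi <- min(n, ups[b] + round(0.9 * cl))
    w <- x[lo:hi]
    apd90[b] <- tryCatch(mapd(w, 0.90), torsadex_error = function(e) NA_real_)
    apd50[b] <- tryCatch(mapd(w, 0.50), torsadex_error = function(e) NA_real_)
  }
  ser <- duration_series(apd90, source = "cellular-AP")
  stv_val <- if (sum(!ser$mask) >= stv_beats + 1) {
    stv(ser, n_beats = stv_beats, divisor_mode = divisor_mode)$stv
  } else NA_real_
  structure(
    list(apd90 = mean(apd90, na.rm = TRUE), apd50 = mean(apd50, na.rm = TRUE),
         stv = stv_val, apd90_series = ser, n_aps = length(ups)),
    class = "ap_metrics")
}

#' @export
print.ap_metrics <- function(x, ...) {
  cat(sprintf("<ap_metrics> APD90 %.1f ms, APD50 %.1f ms, STV %s ms (%d APs)\n",
              x$apd90, x$apd50,
              if (is.na(x$stv)) "NA" else sprintf("%.3f", x$stv), x$n_aps))
  invisible(x)
}
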