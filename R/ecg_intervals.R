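# ECG interval measurement and derived repolarization indices.
#
# Intervals are averaged over a configurable number of consecutive usable
# complexes (5 under anesthesia, 10 for awake RR/PP analysis). JT and JTc
# are defined by exact subtraction identities on the summary means, so every
# reported row satisfies JT + QRS = QT and JTc + QRS = QTc.

#' JT interval: QT minus QRS
#' @param qt QT interval (ms), `qt >= qrs`
#' @param qrs QRS duration (ms), `>= 0`
#' @return JT in ms
#' @export
jt <- function(qt, qrs) {
  assert_that(all(qrs >= 0), "domain", "qrs must be >= 0")
  assert_that(all(qt >= qrs), "domain", "qt must be >= qrs")
  qt - qrs
}

#' Van de Water heart-rate-corrected QT
#'
#' `QTc = QT - 0.087 * (RR - 1000)` with all quantities in ms; the identity
#' correction at RR = 1000 ms makes QTc equal QT at the model's paced
#' bradycardic rate of 60 beats/min.
#'
#' @param qt QT interval (ms, > 0)
#' @param rr RR interval (ms, > 0)
#' @param coefficient correction slope (ms per ms of RR)
#' @return QTc in ms
#' @export
qtc_van_de_water <- function(qt, rr, coefficient = 0.087) {
  assert_that(all(qt > 0) && all(rr > 0), "domain", "qt and rr must be > 0")
  qt - coefficient * (rr - 1000)
}

#' JTc interval: QTc minus QRS
#' @param qtc rate-corrected QT (ms)
#' @param qrs QRS duration (ms), `qtc >= qrs`
#' @return JTc in ms
#' @export
jtc <- function(qtc, qrs) {
  assert_that(all(qtc >= qrs), "domain", "qtc must be >= qrs")
  qtc - qrs
}

#' Per-timepoint interval summary over consecutive complexes
#'
#' Takes the first run of `n` consecutive usable complexes (regular class,
#' not masked by the exclusion rules) and returns their mean RR, PP, QRS,
#' QT plus derived JT, QTc and JTc. RR uses the interval preceding each
#' complex; PP is measured on the independent atrial train.
#'
#' @param beats a `beat_annotations`
#' @param n number of consecutive complexes (default 5; use 10 for awake
#'   RR/PP analysis)
#' @param timepoint label attached to the summary
#' @param p_on_t_window_ms half-width of the P-on-T exclusion window
#' @return an `interval_summary` (one-row data.frame)
#' @export
measure_intervals <- function(beats, n = 5, timepoint = "baseline",
                              p_on_t_window_ms = 40) {
  stopifnot(inherits(beats, "beat_annotations"))
  df <- beats$beats
  usable <- usable_mask(beats, p_on_t_window_ms)
  run <- first_run(usable, n)
  if (is.null(run)) {
    tdx_error("insufficient_data", sprintf(
      "need %d consecutive usable complexes, longest run is %d of %d beats",
      n, longest_run(usable), nrow(df)))
  }
  idx <- run
  qt_i <- df$t_end[idx] - df$q_on[idx]
  qrs_i <- df$qrs_end[idx] - df$q_on[idx]
  # preceding RR interval per complex (first beat of the record has none)
  rr_all <- c(NA_real_, diff(df$q_on))
  rr_i <- rr_all[idx]
  rr <- mean(rr_i, na.rm = TRUE)
  pp <- if (length(beats$p_waves) > n) {
    mean(diff(beats$p_waves)[seq_len(n)])
  } else NA_real_
  qt <- mean(qt_i); qrs <- mean(qrs_i)
  qtc <- qtc_van_de_water(qt, rr)
  out <- data.frame(
    timepoint = timepoint, rr = rr, pp = pp, qrs = qrs, qt = qt,
    jt = jt(qt, qrs), qtc = qtc, jtc = jtc(qtc, qrs),
    n_complexes = length(idx), stringsAsFactors = FALSE)
  class(out) <- c("interval_summary", class(out))
  out
}

# complexes usable for interval/duration analysis: regular class, T end
# resolved, and no P wave in the T-end neighbourhood
usable_mask <- function(beats, p_on_t_window_ms = 40) {
  df <- beats$beats
  if (!nrow(df)) return(logical(0))
  ok <- df$class %in% c("regular", "paced") & !is.na(df$t_end) &
    !is.na(df$q_on)
  if (length(beats$p_waves)) {
    for (b in which(ok)) {
      if (any(abs(beats$p_waves - df$t_end[b]) <= p_on_t_window_ms))
        ok[b] <- FALSE
    }
  }
  ok
}

first_run <- function(mask, n) {
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  hit <- which(r$values & r$lengths >= n)
  if (!length(hit)) return(NULL)
  start <- ends[hit[1]] - r$lengths[hit[1]] + 1L
  start:(start + n - 1L)
}

longest_run <- function(mask) {
  r <- rle(mask)
  m <- r$lengths[r$values]
  if (length(m)) max(m) else 0L
}

#' Select baseline and drug-challenge analysis windows
#'
#' The baseline window ends strictly before the infusion onset. The
#' drug-timepoint anchor is 5 min after the onset of infusion, or the first
#' ectopic beat occurring within those 5 min, whichever comes first; ectopy
#' before the onset does not move the anchor.
#'
#' @param beats a `beat_annotations`
#' @param infusion_onset_ms infusion onset (ms, within the recording)
#' @param trace optional `signal_trace` used to bound the onset
#' @param window_ms length of the 5-min rule window (default 300000)
#' @return a list with `baseline_window` (c(start, end)), `drug_window`
#'   (c(onset, anchor)) and `anchor_ms`
#' @export
select_timepoint <- function(beats, infusion_onset_ms, trace = NULL,
                             window_ms = 300000) {
  stopifnot(inherits(beats, "beat_annotations"))
  extent <- if (!is.null(trace)) trace_duration_ms(trace) else
    max(beats$beats$q_on, infusion_onset_ms, na.rm = TRUE) + window_ms
  assert_that(infusion_onset_ms >= 0 && infusion_onset_ms < extent, "domain",
              "infusion onset lies outside the recording")
  ect <- beats$beats$q_on[beats$beats$class == "ectopic"]
  ect <- ect[ect > infusion_onset_ms & ect <= infusion_onset_ms + window_ms]
  anchor <- if (length(ect)) min(ect) else infusion_onset_ms + window_ms
  list(baseline_window = c(0, infusion_onset_ms),
       drug_window = c(infusion_onset_ms, anchor),
       anchor_ms = anchor)
}

#' @export
print.interval_summary <- function(x, ...) {
  cat(sprintf("<interval_summary> timepoint '%s' (n = %d complexes)\n",
              x$timepoint, x$n_complexes))
  v <- vapply(c("rr", "pp", "qrs", "qt", "jt", "qtc", "jtc"),
              function(k) x[[k]], 0)
  cat(paste(sprintf("  %s: %s ms", toupper(names(v)),
                    ifelse(is.na(v), "NA", sprintf("%.1f", v))),
            collapse = "\n"), "\n")
  invisible(x)
}
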