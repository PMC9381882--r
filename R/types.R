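# Core containers: uniformly sampled multichannel traces and per-beat
# annotations. Time convention throughout: milliseconds from recording
# start, 0-based sample indexing, intervals half-open [onset, offset).

#' Construct a multichannel signal trace
#'
#' @param samples numeric matrix, one column per channel
#' @param sampling_rate_hz sampling rate in Hz (> 0)
#' @param channels character vector of channel names (column order)
#' @param units character vector of physical units, one per channel
#' @return an object of class `signal_trace`
#' @export
signal_trace <- function(samples, sampling_rate_hz = 1000,
                         channels = colnames(samples),
                         units = rep("mV", ncol(samples))) {
  samples <- as.matrix(samples)
  assert_that(is_number(sampling_rate_hz) && sampling_rate_hz > 0, "spec",
              "sampling_rate_hz must be a positive number")
  assert_that(!is.null(channels) && length(channels) == ncol(samples), "spec",
              "one channel name per column is required")
  assert_that(length(units) == ncol(samples), "spec",
              "one unit per channel is required")
  colnames(samples) <- channels
  structure(
    list(samples = samples, sampling_rate_hz = sampling_rate_hz,
         channels = as.character(channels), units = as.character(units)),
    class = "signal_trace"
  )
}

#' @export
print.signal_trace <- function(x, ...) {
  cat(sprintf("<signal_trace> %d channel(s) x %d samples @ %g Hz (%.3f s)\n",
              ncol(x$samples), nrow(x$samples), x$sampling_rate_hz,
              nrow(x$samples) / x$sampling_rate_hz))
  cat("  channels:", paste(sprintf("%s [%s]", x$channels, x$units),
                           collapse = ", "), "\n")
  invisible(x)
}

#' Duration of a trace in ms
#' @param trace a `signal_trace`
#' @export
trace_duration_ms <- function(trace) {
  nrow(trace$samples) * 1000 / trace$sampling_rate_hz
}

#' Extract one channel of a trace as a numeric vector
#' @param trace a `signal_trace`
#' @param channel channel name
#' @export
trace_channel <- function(trace, channel) {
  assert_that(channel %in% trace$channels, "channel",
              sprintf("channel '%s' not present (have: %s)", channel,
                      paste(trace$channels, collapse = ", ")))
  trace$samples[, channel]
}

BEAT_CLASSES <- c("regular", "paced", "ectopic", "defib_artifact")
EVENT_KINDS  <- c("regular", "sEB", "mEB", "TdP", "defib-TdP")

empty_beats_df <- function() {
  data.frame(beat = integer(0), class = character(0), p_on = numeric(0),
             q_on = numeric(0), qrs_end = numeric(0), t_end = numeric(0),
             lv_map_up = numeric(0), lv_map_end = numeric(0),
             rv_map_up = numeric(0), rv_map_end = numeric(0),
             qt_true = numeric(0), lv_mapd_true = numeric(0),
             rv_mapd_true = numeric(0), stringsAsFactors = FALSE)
}

empty_events_df <- function() {
  data.frame(kind = character(0), onset_ms = numeric(0), offset_ms = numeric(0),
             run_length = integer(0), shocks = integer(0),
             stringsAsFactors = FALSE)
}

#' Construct a per-beat annotation set
#'
#' Beats carry fiducial times in ms (`p_on`, `q_on`, `qrs_end`, `t_end`,
#' MAP upstroke/end per ventricle; NA where not applicable) and a beat
#' class. `p_waves` is the full atrial P-onset train, which under AV
#' dissociation is not in one-to-one correspondence with ventricular
#' beats. `events` records classified arrhythmic episodes.
#'
#' @param beats data.frame of per-beat records (see [empty_beats_df()] columns;
#'   missing columns are filled with NA)
#' @param p_waves numeric vector of atrial P-onset times (ms)
#' @param events data.frame of episode records
#' @param defib_marks_ms numeric vector of defibrillation shock times (ms)
#' @return an object of class `beat_annotations`
#' @export
beat_annotations <- function(beats = empty_beats_df(), p_waves = numeric(0),
                             events = empty_events_df(),
                             defib_marks_ms = numeric(0)) {
  template <- empty_beats_df()
  beats <- as.data.frame(beats, stringsAsFactors = FALSE)
  for (col in setdiff(names(template), names(beats))) {
    beats[[col]] <- rep(if (col == "class") NA_character_ else NA_real_,
                        nrow(beats))
  }
  if (nrow(beats) && !all(is.na(beats$class))) {
    bad <- setdiff(unique(stats::na.omit(beats$class)), BEAT_CLASSES)
    assert_that(length(bad) == 0, "validation",
                sprintf("unknown beat class(es): %s", paste(bad, collapse = ", ")))
  }
  validate_fiducial_order(beats)
  events <- as.data.frame(events, stringsAsFactors = FALSE)
  for (col in setdiff(names(empty_events_df()), names(events))) {
    events[[col]] <- rep(if (col == "kind") NA_character_ else NA_real_,
                         nrow(events))
  }
  structure(
    list(beats = beats, p_waves = as.numeric(p_waves), events = events,
         defib_marks_ms = as.numeric(defib_marks_ms)),
    class = "beat_annotations"
  )
}

validate_fiducial_order <- function(beats) {
  chk <- function(a, b, lab, strict = TRUE) {
    ok <- is.na(a) | is.na(b) | (if (strict) a < b else a <= b)
    if (!all(ok)) {
      tdx_error("validation",
                sprintf("fiducial ordering violated (%s) for beat(s) %s",
                        lab, paste(which(!ok), collapse = ", ")))
    }
  }
  chk(beats$p_on, beats$q_on, "P onset <= Q onset", strict = FALSE)
  chk(beats$q_on, beats$qrs_end, "Q onset < QRS end")
  chk(beats$qrs_end, beats$t_end, "QRS end < T end")
  invisible(TRUE)
}

#' @export
print.beat_annotations <- function(x, ...) {
  cls <- table(factor(x$beats$class, levels = BEAT_CLASSES))
  cat(sprintf("<beat_annotations> %d beat(s) [%s], %d P wave(s), %d event(s)\n",
              nrow(x$beats),
              paste(sprintf("%s: %d", names(cls), cls), collapse = ", "),
              length(x$p_waves), nrow(x$events)))
  invisible(x)
}
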