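# Arrhythmic-event taxonomy and the arrhythmia score (AS).
#
# Rubric: a regular beat scores 1 point; a single ectopic beat (sEB) 2; a
# run of 2-5 ectopic complexes (mEB) 3-5; a TdP of k >= 6 complexes 6-49;
# a defibrillated TdP 50, 75 or 100 points for 1, 2 or >= 3 shocks. Within
# the mEB and TdP ranges the adopted convention (configurable) is
# points = run_length + 1 capped at 5 for mEB and points = run_length capped
# at 49 for TdP, consistent with sEB = 2 = 1 + 1, the 6-point floor of a
# 6-complex TdP, and a 17-complex self-terminating TdP scoring 17.
# The AS is the mean of the three highest-scored events in the 10 min after
# the onset of the challenge; with fewer than three arrhythmic events the
# remaining slots are filled with regular-beat scores of 1, so an event-free
# window scores exactly 1.

#' Construct an arrhythmia event
#'
#' @param kind one of `"regular"`, `"sEB"`, `"mEB"`, `"TdP"`, `"defib-TdP"`
#' @param run_length consecutive ectopic complexes in the run
#' @param onset_ms,offset_ms episode extent (ms); `duration_s` is derived
#' @param shocks defibrillation shock count (defib-TdP only, >= 1)
#' @return one-row data.frame of class `arrhythmia_events`, with points
#' @export
arrhythmia_event <- function(kind, run_length = 1L, onset_ms = 0,
                             offset_ms = onset_ms + run_length * 250,
                             shocks = 0L) {
  ev <- data.frame(kind = kind, onset_ms = onset_ms, offset_ms = offset_ms,
                   run_length = as.integer(run_length),
                   shocks = as.integer(shocks), stringsAsFactors = FALSE)
  validate_events(ev)
  ev$duration_s <- (ev$offset_ms - ev$onset_ms) / 1000
  ev$points <- score_event(ev)
  class(ev) <- c("arrhythmia_events", class(ev))
  ev
}

validate_events <- function(ev) {
  bad <- setdiff(ev$kind, EVENT_KINDS)
  assert_that(length(bad) == 0, "validation",
              sprintf("unknown event kind(s): %s", paste(bad, collapse = ", ")))
  ok <- (ev$kind == "regular") |
    (ev$kind == "sEB" & ev$run_length == 1L) |
    (ev$kind == "mEB" & ev$run_length >= 2L & ev$run_length <= 5L) |
    (ev$kind == "TdP" & ev$run_length >= 6L) |
    (ev$kind == "defib-TdP" & ev$run_length >= 6L & ev$shocks >= 1L)
  assert_that(all(ok), "validation",
              "kind/run_length/shocks inconsistent with the event taxonomy")
  dur_ok <- ev$kind != "defib-TdP" | (ev$offset_ms - ev$onset_ms) > 10000
  assert_that(all(dur_ok), "validation",
              "defib-TdP events must last longer than 10 s")
  invisible(TRUE)
}

#' Points assigned to an event by the severity rubric
#'
#' @param event an `arrhythmia_events` row set (or data.frame with `kind`,
#'   `run_length`, `shocks`)
#' @return numeric vector of points, one per event
#' @export
score_event <- function(event) {
  validate_events(event)
  vapply(seq_len(nrow(event)), function(i) {
    k <- event$kind[i]; rl <- event$run_length[i]; s <- event$shocks[i]
    switch(k,
           "regular" = 1,
           "sEB" = 2,
           "mEB" = min(rl + 1, 5),
           "TdP" = min(rl, 49),
           "defib-TdP" = if (s >= 3) 100 else if (s == 2) 75 else 50)
  }, numeric(1))
}

#' Group annotated beats into classified arrhythmic events
#'
#' Maximal runs of consecutive ectopic complexes become one event each; the
#' kind follows the run length (1 sEB, 2-5 mEB, >= 6 TdP). A defibrillation
#' mark falling within an event makes it a defib-TdP and sets the shock
#' count; marks outside any event are recorded as orphan-shock warnings.
#'
#' @param beats a `beat_annotations` (beat classes are taken from it)
#' @param defib_marks_ms shock times (ms); defaults to the annotation's marks
#' @return an `arrhythmia_events` data.frame with a `warnings` attribute
#'   listing orphan shocks
#' @export
classify_runs <- function(beats, defib_marks_ms = NULL) {
  stopifnot(inherits(beats, "beat_annotations"))
  df <- beats$beats
  if (is.null(defib_marks_ms)) defib_marks_ms <- beats$defib_marks_ms
  ect <- df$class == "ectopic"
  out <- empty_events_df()
  out$duration_s <- numeric(0); out$points <- numeric(0)
  used_marks <- rep(FALSE, length(defib_marks_ms))
  if (any(ect)) {
    r <- rle(ect)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in which(r$values)) {
      i0 <- starts[k]; i1 <- ends[k]
      rl <- i1 - i0 + 1L
      onset <- df$q_on[i0]
      cyc <- if (rl > 1) stats::median(diff(df$q_on[i0:i1])) else TDP_CYCLE_MS
      offset <- df$q_on[i1] + cyc
      in_ev <- defib_marks_ms >= onset & defib_marks_ms <= offset + 500
      used_marks <- used_marks | in_ev
      shocks <- sum(in_ev)
      kind <- if (shocks > 0) "defib-TdP"
      else if (rl >= 6) "TdP" else if (rl >= 2) "mEB" else "sEB"
      out <- rbind(out, data.frame(
        kind = kind, onset_ms = onset, offset_ms = offset,
        run_length = rl, shocks = as.integer(shocks),
        duration_s = (offset - onset) / 1000,
        points = NA_real_, stringsAsFactors = FALSE))
    }
    out$points <- score_event(out)
  }
  class(out) <- c("arrhythmia_events", class(out))
  orphans <- defib_marks_ms[!used_marks]
  if (length(orphans)) {
    attr(out, "warnings") <- data.frame(
      type = "orphan_shock", time_ms = orphans, stringsAsFactors = FALSE)
    warning(sprintf("%d defibrillation mark(s) outside any event (orphan shocks)",
                    length(orphans)), call. = FALSE)
  }
  out
}

#' Arrhythmia score over a 10-minute challenge window
#'
#' The mean of the three highest-scored arrhythmic events whose onset lies
#' in `[window_start_ms, window_start_ms + window_s * 1000)`. With fewer
#' than three events the remaining slots carry regular-beat scores of 1, so
#' an event-free window scores exactly 1.
#'
#' @param events an `arrhythmia_events` data.frame (may be empty)
#' @param window_start_ms start of the window (challenge onset)
#' @param window_s window length in seconds (default 600)
#' @return an `as_result`: `as_value`, `contributing` points, the window and
#'   per-kind incidence flags
#' @export
arrhythmia_score <- function(events, window_start_ms = 0, window_s = 600) {
  pts <- numeric(0)
  kinds <- character(0)
  if (!is.null(events) && nrow(events)) {
    validate_events(events)
    if (is.null(events$points)) events$points <- score_event(events)
    keep <- events$onset_ms >= window_start_ms &
      events$onset_ms < window_start_ms + window_s * 1000
    pts <- events$points[keep]
    kinds <- events$kind[keep]
  }
  top <- sort(pts, decreasing = TRUE)[seq_len(min(3, length(pts)))]
  contributing <- c(top, rep(1, 3 - length(top)))
  structure(
    list(as_value = mean(contributing), contributing = contributing,
         window_ms = c(window_start_ms, window_start_ms + window_s * 1000),
         incidence = c(sEB = any(kinds == "sEB"),
                       mEB = any(kinds == "mEB"),
                       TdP = any(kinds %in% c("TdP", "defib-TdP")))),
    class = "as_result")
}

#' @export
print.as_result <- function(x, ...) {
  cat(sprintf("<as_result> AS = %.2f (events: %s) over [%.0f, %.0f) ms\n",
              x$as_value, paste(x$contributing, collapse = ", "),
              x$window_ms[1], x$window_ms[2]))
  invisible(x)
}

#' Cohort incidence of arrhythmic-event kinds
#'
#' Fraction of subjects with at least one event of each kind; defibrillated
#' TdP counts as TdP. A subject with TdP that began as single ectopy counts
#' in every kind it exhibited.
#'
#' @param subject_events named list of `arrhythmia_events`, one per subject
#' @return named numeric vector of fractions (`sEB`, `mEB`, `TdP`)
#' @export
incidence_summary <- function(subject_events) {
  assert_that(length(subject_events) >= 1, "spec",
              "at least one subject is required")
  has <- vapply(subject_events, function(ev) {
    k <- if (is.null(ev) || !nrow(ev)) character(0) else ev$kind
    c(sEB = any(k == "sEB"), mEB = any(k == "mEB"),
      TdP = any(k %in% c("TdP", "defib-TdP")))
  }, logical(3))
  rowMeans(has)
}
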