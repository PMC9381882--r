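# Shared fixtures, built once per test run (all synthetic, generated in code).

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- build()
  .fixtures[[name]]
}

# 120 s paced rhythm with AV dissociation at the study's default rates
fx_rhythm_default <- function() {
  fixture("rhythm_default", function() {
    generate_rhythm(rhythm_spec(duration_s = 120, seed = 3))
  })
}

# annotations with hand-set fiducials: n regular beats, RR 1000 ms,
# QRS 123 ms, QT as given
make_beats <- function(qt, rr = 1000, qrs = 123, class = rep("regular", length(qt)),
                       p_waves = numeric(0), t0 = 100) {
  n <- length(qt)
  q_on <- t0 + (seq_len(n) - 1) * rr
  beat_annotations(
    data.frame(beat = seq_len(n), class = class, q_on = q_on,
               qrs_end = q_on + qrs, t_end = q_on + qt,
               stringsAsFactors = FALSE),
    p_waves = p_waves)
}

# event list rows for scoring tests
make_events <- function(points_kinds) {
  do.call(rbind, lapply(points_kinds, function(x) {
    arrhythmia_event(x$kind, x$run_length %||% 1L, x$onset_ms %||% 0,
                     x$offset_ms %||% ((x$onset_ms %||% 0) +
                                         (x$run_length %||% 1L) * 250),
                     x$shocks %||% 0L)
  }))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
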