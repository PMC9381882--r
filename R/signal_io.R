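# Read/write recordings and annotations in stable text formats.
#
# Trace: CSV with '#'-prefixed header lines:
#   # torsadex-trace
#   # version: 1.0
#   # sampling_rate_hz: 1000
#   # channel: ECG:mV
#   ...
# followed by one CSV column per channel. Round trips are lossless (numbers
# are written with shortest round-trippable precision).
#
# Annotations: a JSON document with `beats`, `p_waves`, `events` and
# `defib_marks_ms` members plus `format`/`version`.

TRACE_FORMAT_MAGIC <- "torsadex-trace"
ANN_FORMAT_MAGIC <- "torsadex-annotations"
IO_MAJOR_VERSION <- 1L

#' Write a signal trace to a delimited text file
#' @param trace a `signal_trace`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "signal_trace"))
  hdr <- c(
    sprintf("# %s", TRACE_FORMAT_MAGIC),
    sprintf("# version: %d.0", IO_MAJOR_VERSION),
    sprintf("# sampling_rate_hz: %.10g", trace$sampling_rate_hz),
    sprintf("# channel: %s:%s", trace$channels, trace$units)
  )
  writeLines(hdr, path)
  # %.17g guarantees bit-exact double round trips through the text format
  txt <- data.table::as.data.table(
    lapply(seq_len(ncol(trace$samples)),
           function(j) sprintf("%.17g", trace$samples[, j])))
  data.table::setnames(txt, trace$channels)
  data.table::fwrite(txt, path, append = TRUE, col.names = TRUE,
                     quote = FALSE)
  invisible(path)
}

#' Read a signal trace written by [write_trace()]
#' @param path input path
#' @return a `signal_trace`
#' @export
read_trace <- function(path) {
  assert_that(file.exists(path), "io", sprintf("no such file: %s", path))
  lines <- readLines(path, n = 64)
  hdr <- grep("^#", lines, value = TRUE)
  assert_that(length(hdr) >= 3 && grepl(TRACE_FORMAT_MAGIC, hdr[1], fixed = TRUE),
              "parse", sprintf("line 1: not a %s file", TRACE_FORMAT_MAGIC))
  ver <- sub("^# version:\\s*", "", grep("^# version:", hdr, value = TRUE)[1])
  assert_that(!is.na(ver), "parse", "header: missing version field")
  major <- as.integer(strsplit(ver, ".", fixed = TRUE)[[1]][1])
  assert_that(!is.na(major) && major == IO_MAJOR_VERSION, "parse",
              sprintf("header: unsupported major version %s (reader supports %d)",
                      ver, IO_MAJOR_VERSION))
  fs <- as.numeric(sub("^# sampling_rate_hz:\\s*", "",
                       grep("^# sampling_rate_hz:", hdr, value = TRUE)[1]))
  assert_that(is_number(fs) && fs > 0, "parse",
              "header: missing or invalid sampling_rate_hz field")
  ch_lines <- sub("^# channel:\\s*", "", grep("^# channel:", hdr, value = TRUE))
  assert_that(length(ch_lines) >= 1, "parse", "header: no channel fields")
  parts <- strsplit(ch_lines, ":", fixed = TRUE)
  bad <- which(lengths(parts) != 2)
  assert_that(length(bad) == 0, "parse",
              sprintf("header: channel field %d must be name:unit", bad[1]))
  channels <- vapply(parts, `[[`, "", 1L)
  units <- vapply(parts, `[[`, "", 2L)
  dt <- data.table::fread(path, skip = length(hdr), header = TRUE)
  assert_that(identical(names(dt), channels), "parse",
              sprintf("column names (%s) do not match declared channels (%s)",
                      paste(names(dt), collapse = ","),
                      paste(channels, collapse = ",")))
  m <- as.matrix(dt)
  for (j in seq_along(channels)) {
    nas <- is.na(m[, j])
    assert_that(!any(nas), "parse",
                sprintf("channel '%s' is short or non-numeric at row %d",
                        channels[j], which(nas)[1]))
  }
  signal_trace(m, fs, channels, units)
}

#' Write annotations to JSON
#' @param annotations a `beat_annotations`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_annotations <- function(annotations, path) {
  stopifnot(inherits(annotations, "beat_annotations"))
  doc <- list(
    format = ANN_FORMAT_MAGIC,
    version = sprintf("%d.0", IO_MAJOR_VERSION),
    beats = annotations$beats,
    p_waves = annotations$p_waves,
    events = annotations$events,
    defib_marks_ms = annotations$defib_marks_ms
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}

#' Read annotations written by [write_annotations()]
#'
#' Validates the format marker, major version and per-beat fiducial
#' ordering (P onset <= Q onset < QRS end < T end).
#' @param path input path
#' @return a `beat_annotations`
#' @export
read_annotations <- function(path) {
  assert_that(file.exists(path), "io", sprintf("no such file: %s", path))
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  assert_that(identical(doc$format, ANN_FORMAT_MAGIC), "parse",
              sprintf("field 'format': not a %s document", ANN_FORMAT_MAGIC))
  major <- as.integer(strsplit(doc$version %||% "", ".", fixed = TRUE)[[1]][1])
  assert_that(!is.na(major) && major == IO_MAJOR_VERSION, "parse",
              sprintf("field 'version': unsupported major version %s", doc$version))
  beats <- if (length(doc$beats)) as.data.frame(doc$beats) else empty_beats_df()
  events <- if (length(doc$events)) as.data.frame(doc$events) else empty_events_df()
  beat_annotations(beats, doc$p_waves %||% numeric(0), events,
                   doc$defib_marks_ms %||% numeric(0))
}

#' Write a parameter-by-timepoint summary table as CSV
#'
#' Layout mirrors the study's summary tables: one row per parameter, one
#' column pair (mean, sd) plus n per timepoint.
#' @param summary a data.frame as produced by [run_study()]
#' @param path output path
#' @return `path`, invisibly
#' @export
write_summary_table <- function(summary, path) {
  data.table::fwrite(summary, path)
  invisible(path)
}
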