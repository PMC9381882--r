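# Study orchestration: run every subject/timepoint through the interval,
# MAP and arrhythmia analyses and emit summary tables in the layout of the
# study's result tables (parameter x timepoint, mean +/- SD, n per cell).
# Group inferential statistics are deliberately out of scope: the pipeline
# persists per-subject values so any stats package can consume them.

#' Assemble a study configuration
#'
#' @param subjects list of subject entries; each a list with `id`,
#'   `timepoints` (named list mapping a timepoint label to
#'   `list(trace = path, annotations = path)`) and optionally
#'   `infusion_onset_ms` per scored timepoint
#' @param n_complexes consecutive complexes per interval summary
#' @param stv_beats pairs for STV
#' @param stv_divisor `"sqrt2"` or `"literal"`
#' @param as_window_s arrhythmia-score window (s)
#' @param as_timepoints timepoint labels whose events are scored
#' @param out_dir optional output directory for persisted results
#' @return a `study_config`
#' @export
study_config <- function(subjects, n_complexes = 5, stv_beats = 30,
                         stv_divisor = "sqrt2", as_window_s = 600,
                         as_timepoints = grep("dofetilide",
                                              unique(unlist(lapply(subjects, function(s)
                                                names(s$timepoints)))),
                                              value = TRUE),
                         out_dir = NULL) {
  assert_that(length(subjects) >= 1, "spec", "at least one subject required")
  for (s in subjects) {
    assert_that(!is.null(s$id) && length(s$timepoints) >= 1, "spec",
                "every subject needs an id and at least one timepoint")
    for (tp in s$timepoints) {
      assert_that(file.exists(tp$trace), "spec",
                  sprintf("trace not resolvable: %s", tp$trace))
      assert_that(file.exists(tp$annotations), "spec",
                  sprintf("annotations not resolvable: %s", tp$annotations))
    }
  }
  structure(list(subjects = subjects, n_complexes = n_complexes,
                 stv_beats = stv_beats, stv_divisor = stv_divisor,
                 as_window_s = as_window_s, as_timepoints = as_timepoints,
                 out_dir = out_dir),
            class = "study_config")
}

analyze_subject_timepoint <- function(trace, ann, label, config) {
  iv <- measure_intervals(ann, n = config$n_complexes, timepoint = label)
  res <- list(intervals = iv)
  for (ch in intersect(c("LV-MAP", "RV-MAP"), trace$channels)) {
    ser <- exclude_beats(measure_mapd_series(trace, ann, ch), ann)
    run <- first_run(!ser$mask, config$n_complexes)
    m <- if (is.null(run)) NA_real_ else mean(ser$durations_ms[run])
    s <- tryCatch(stv(ser, config$stv_beats, config$stv_divisor)$stv,
                  torsadex_error = function(e) NA_real_)
    key <- if (ch == "LV-MAP") "lv" else "rv"
    res[[paste0(key, "_mapd")]] <- m
    res[[paste0(key, "_stv")]] <- s
  }
  if (!is.null(res$lv_mapd) && !is.null(res$rv_mapd) &&
      is.finite(res$lv_mapd) && is.finite(res$rv_mapd)) {
    res$delta_mapd <- delta_mapd(res$lv_mapd, res$rv_mapd)
  } else res$delta_mapd <- NA_real_
  res
}

#' Run a full control-vs-treatment study
#'
#' Deterministic given its inputs: reads every subject/timepoint recording,
#' measures intervals and MAP parameters, scores arrhythmic outcome over the
#' challenge window, and assembles cohort summary tables. Unreadable or
#' invalid subject recordings are excluded with a logged reason and the run
#' continues; the run fails only if every subject is excluded.
#'
#' @param config a `study_config`
#' @return a `study_result`: `summary` (parameter x timepoint grid),
#'   `as_table`, `incidence`, `per_subject`, `exclusions`
#' @export
run_study <- function(config) {
  stopifnot(inherits(config, "study_config"))
  per_subject <- list()
  exclusions <- data.frame(subject = character(0), timepoint = character(0),
                           reason = character(0), stringsAsFactors = FALSE)
  as_rows <- list()
  subj_events <- list()
  for (s in config$subjects) {
    res_tp <- list()
    events_all <- empty_events_df()
    for (label in names(s$timepoints)) {
      tp <- s$timepoints[[label]]
      got <- tryCatch({
        trace <- read_trace(tp$trace)
        ann <- read_annotations(tp$annotations)
        out <- analyze_subject_timepoint(trace, ann, label, config)
        if (label %in% config$as_timepoints) {
          ev <- classify_runs(ann)
          onset <- s$infusion_onset_ms %||% 0
          asr <- arrhythmia_score(ev, onset, config$as_window_s)
          as_rows[[length(as_rows) + 1L]] <- data.frame(
            subject = s$id, timepoint = label, as_value = asr$as_value,
            stringsAsFactors = FALSE)
          events_all <- rbind(events_all,
                              ev[, names(empty_events_df()), drop = FALSE])
        }
        out
      }, error = function(e) e)
      if (inherits(got, "error")) {
        exclusions <- rbind(exclusions, data.frame(
          subject = s$id, timepoint = label,
          reason = conditionMessage(got), stringsAsFactors = FALSE))
      } else {
        res_tp[[label]] <- got
      }
    }
    if (length(res_tp)) per_subject[[s$id]] <- res_tp
    subj_events[[s$id]] <- events_all
  }
  if (!length(per_subject))
    tdx_error("fatal", "all subjects excluded; nothing to summarize")

  timepoints <- unique(unlist(lapply(per_subject, names)))
  params <- c("RR", "PP", "QRS", "QT", "JT", "QTc", "JTc",
              "LV MAPD", "RV MAPD", "dMAPD", "STV LV MAPD", "STV RV MAPD")
  value_of <- function(res, p) {
    iv <- res$intervals
    switch(p,
           "RR" = iv$rr, "PP" = iv$pp, "QRS" = iv$qrs, "QT" = iv$qt,
           "JT" = iv$jt, "QTc" = iv$qtc, "JTc" = iv$jtc,
           "LV MAPD" = res$lv_mapd %||% NA_real_,
           "RV MAPD" = res$rv_mapd %||% NA_real_,
           "dMAPD" = res$delta_mapd %||% NA_real_,
           "STV LV MAPD" = res$lv_stv %||% NA_real_,
           "STV RV MAPD" = res$rv_stv %||% NA_real_)
  }
  summary <- do.call(rbind, lapply(params, function(p) {
    row <- data.frame(parameter = p, stringsAsFactors = FALSE)
    for (tp in timepoints) {
      vals <- vapply(per_subject, function(res)
        if (!is.null(res[[tp]])) value_of(res[[tp]], p) else NA_real_, 0)
      vals <- vals[is.finite(vals)]
      row[[paste0(tp, ".mean")]] <- if (length(vals)) mean(vals) else NA_real_
      row[[paste0(tp, ".sd")]] <- if (length(vals) > 1) stats::sd(vals) else NA_real_
      row[[paste0(tp, ".n")]] <- length(vals)
    }
    row
  }))
  as_table <- if (length(as_rows)) do.call(rbind, as_rows) else
    data.frame(subject = character(0), timepoint = character(0),
               as_value = numeric(0), stringsAsFactors = FALSE)
  incidence <- if (length(subj_events)) incidence_summary(subj_events) else
    c(sEB = 0, mEB = 0, TdP = 0)
  out <- structure(
    list(summary = summary, as_table = as_table, incidence = incidence,
         per_subject = per_subject, exclusions = exclusions,
         config = config),
    class = "study_result")
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    write_summary_table(summary, file.path(config$out_dir, "summary.csv"))
    data.table::fwrite(as_table, file.path(config$out_dir, "as_table.csv"))
    data.table::fwrite(exclusions, file.path(config$out_dir, "exclusions.csv"))
  }
  out
}

#' Render a study result as a human-readable report
#'
#' Formatting only; no computation beyond rounding for display.
#' @param results a `study_result`
#' @return character vector of report lines, invisibly; also printed
#' @export
report <- function(results) {
  stopifnot(inherits(results, "study_result"))
  s <- results$summary
  tps <- unique(sub("\\.(mean|sd|n)$", "",
                    grep("\\.mean$", names(s), value = TRUE)))
  lines <- c("Study summary (mean ± SD [n])",
             paste(rep("-", 60), collapse = ""))
  header <- sprintf("%-14s %s", "parameter",
                    paste(sprintf("%-22s", tps), collapse = ""))
  lines <- c(lines, header)
  for (i in seq_len(nrow(s))) {
    cells <- vapply(tps, function(tp) {
      m <- s[[paste0(tp, ".mean")]][i]
      sd <- s[[paste0(tp, ".sd")]][i]
      n <- s[[paste0(tp, ".n")]][i]
      if (!is.finite(m)) return(sprintf("%-22s", "-"))
      sprintf("%-22s", sprintf("%.1f ± %s [%d]", m,
                               if (is.finite(sd)) sprintf("%.1f", sd) else "NA",
                               n))
    }, "")
    lines <- c(lines, sprintf("%-14s %s", s$parameter[i],
                              paste(cells, collapse = "")))
  }
  if (nrow(results$as_table)) {
    lines <- c(lines, "", "Arrhythmia scores:")
    lines <- c(lines, sprintf("  %s @ %s: AS = %.2f",
                              results$as_table$subject,
                              results$as_table$timepoint,
                              results$as_table$as_value))
  }
  lines <- c(lines, "", sprintf(
    "Incidence: sEB %.0f%%, mEB %.0f%%, TdP %.0f%%",
    100 * results$incidence["sEB"], 100 * results$incidence["mEB"],
    100 * results$incidence["TdP"]))
  if (nrow(results$exclusions)) {
    lines <- c(lines, "", sprintf("Exclusions (%d):", nrow(results$exclusions)),
               sprintf("  %s/%s: %s", results$exclusions$subject,
                       results$exclusions$timepoint, results$exclusions$reason))
  }
  cat(paste(lines, collapse = "\n"), "\n")
  invisible(lines)
}

#' @export
print.study_result <- function(x, ...) {
  cat(sprintf("<study_result> %d subject(s), %d timepoint column(s), %d exclusion(s)\n",
              length(x$per_subject),
              sum(grepl("\\.mean$", names(x$summary))), nrow(x$exclusions)))
  invisible(x)
}
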