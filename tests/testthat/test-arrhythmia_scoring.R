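# Event taxonomy, severity rubric and the arrhythmia score.

test_that("classify_runs groups maximal ectopic runs by length", {
  # R R E R -> one sEB
  ann <- make_beats(qt = rep(364, 4),
                    class = c("regular", "regular", "ectopic", "regular"))
  ev <- classify_runs(ann)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$kind, "sEB")
  expect_equal(ev$run_length, 1L)

  # a run of 6 ectopic complexes is a TdP
  cls <- c(rep("regular", 3), rep("ectopic", 6), rep("regular", 3))
  ev2 <- classify_runs(make_beats(qt = rep(364, 12), class = cls))
  expect_equal(ev2$kind, "TdP")
  expect_equal(ev2$run_length, 6L)
  expect_equal(ev2$points, 6)

  # two runs separated by one regular beat stay distinct events
  cls3 <- c("regular", "ectopic", "ectopic", "regular", "ectopic", "regular")
  ev3 <- classify_runs(make_beats(qt = rep(364, 6), class = cls3))
  expect_equal(ev3$kind, c("mEB", "sEB"))
})

test_that("defibrillation marks upgrade events and orphan shocks warn", {
  sched <- event_schedule(20, "defib-TdP", 48L, 1L)
  rec <- generate_rhythm(rhythm_spec(duration_s = 60, seed = 31), sched)
  ev <- classify_runs(rec$annotations)
  expect_equal(ev$kind, "defib-TdP")
  expect_equal(ev$shocks, 1L)
  expect_gt(ev$duration_s, 10)
  expect_equal(ev$points, 50)

  # a mark outside any event is an orphan-shock warning record
  ann <- make_beats(qt = rep(364, 4),
                    class = c("regular", "ectopic", "regular", "regular"))
  expect_warning(ev2 <- classify_runs(ann, defib_marks_ms = 1e6),
                 "orphan")
  expect_equal(attr(ev2, "warnings")$type, "orphan_shock")
})

test_that("the rubric scores every event kind as published", {
  expect_identical(score_event(arrhythmia_event("regular")), 1)
  expect_identical(score_event(arrhythmia_event("sEB")), 2)
  # mEB: run k of 2-5 scores min(k + 1, 5)
  expect_identical(score_event(arrhythmia_event("mEB", 2L)), 3)
  expect_identical(score_event(arrhythmia_event("mEB", 4L)), 5)
  expect_identical(score_event(arrhythmia_event("mEB", 5L)), 5)
  # TdP: run k >= 6 scores min(k, 49); a 17-complex TdP scores 17
  expect_identical(score_event(arrhythmia_event("TdP", 6L)), 6)
  expect_identical(score_event(arrhythmia_event("TdP", 17L)), 17)
  expect_identical(score_event(arrhythmia_event("TdP", 60L)), 49)
  # defibrillated TdP: 50 / 75 / 100 by shock count
  dt <- function(s) arrhythmia_event("defib-TdP", 48L, 0, 12000, shocks = s)
  expect_identical(score_event(dt(1L)), 50)
  expect_identical(score_event(dt(2L)), 75)
  expect_identical(score_event(dt(3L)), 100)
  expect_identical(score_event(dt(5L)), 100)
  # score is non-decreasing in run length and shocks
  expect_true(all(diff(vapply(2:5, function(k)
    score_event(arrhythmia_event("mEB", k)), 0)) >= 0))
  expect_true(all(diff(vapply(6:55, function(k)
    score_event(arrhythmia_event("TdP", k)), 0)) >= 0))
  # inconsistent kind/run_length rejected
  expect_error(arrhythmia_event("sEB", 3L), class = "torsadex_validation")
  expect_error(arrhythmia_event("TdP", 3L), class = "torsadex_validation")
  expect_error(arrhythmia_event("defib-TdP", 48L, 0, 5000, shocks = 1L),
               class = "torsadex_validation")
})

test_that("arrhythmia_score averages the three highest events, padding with 1", {
  # event-free window scores exactly 1
  expect_identical(arrhythmia_score(NULL)$as_value, 1)
  expect_identical(arrhythmia_score(classify_runs(make_beats(rep(364, 5))))$as_value, 1)

  # printed worked examples: {50, 3, 3} -> 18.67, {9, 8, 6} -> 7.67
  ev1 <- make_events(list(
    list(kind = "defib-TdP", run_length = 48L, onset_ms = 1000,
         offset_ms = 13000, shocks = 1L),
    list(kind = "mEB", run_length = 2L, onset_ms = 20000),
    list(kind = "mEB", run_length = 2L, onset_ms = 30000)))
  expect_equal(arrhythmia_score(ev1)$as_value, (50 + 3 + 3) / 3)
  expect_equal(round(arrhythmia_score(ev1)$as_value, 1), 18.7)

  ev2 <- make_events(list(
    list(kind = "TdP", run_length = 9L, onset_ms = 1000),
    list(kind = "TdP", run_length = 8L, onset_ms = 20000),
    list(kind = "TdP", run_length = 6L, onset_ms = 30000),
    list(kind = "sEB", onset_ms = 40000)))
  expect_equal(arrhythmia_score(ev2)$as_value, (9 + 8 + 6) / 3)
  expect_equal(round(arrhythmia_score(ev2)$as_value, 1), 7.7)

  # only events with onset inside the half-open window count
  late <- make_events(list(list(kind = "TdP", run_length = 20L,
                                onset_ms = 600000)))
  expect_identical(arrhythmia_score(late, 0, 600)$as_value, 1)
  expect_equal(arrhythmia_score(late, 1, 600)$as_value, (20 + 1 + 1) / 3)
})

test_that("arrhythmia_score agrees with a brute-force 3-subset oracle", {
  # oracle: maximum over all 3-subsets of the padded score list
  oracle <- function(pts) {
    pool <- c(pts, rep(1, 3))
    max(apply(utils::combn(seq_along(pool), 3), 2,
              function(ix) mean(pool[ix])))
  }
  set.seed(99)
  for (i in 1:1000) {
    n <- sample(0:6, 1)
    pts <- sample(c(1:49, 50, 75, 100), n, replace = TRUE)
    ev <- if (n) data.frame(
      kind = "TdP", run_length = 49L, onset_ms = seq_len(n) * 1000,
      offset_ms = seq_len(n) * 1000 + 2000, shocks = 0L,
      points = pts, stringsAsFactors = FALSE) else NULL
    expect_identical(arrhythmia_score(ev, 0, 600)$as_value, oracle(pts))
  }
})

test_that("AS is monotone and bounded in [1, 100]", {
  set.seed(5)
  base_pts <- c(10, 20, 30)
  mk <- function(pts) data.frame(
    kind = "TdP", run_length = 49L, onset_ms = seq_along(pts) * 1000,
    offset_ms = seq_along(pts) * 1000 + 2000, shocks = 0L, points = pts,
    stringsAsFactors = FALSE)
  as0 <- arrhythmia_score(mk(base_pts))$as_value
  # raising any event's points never decreases AS
  expect_gte(arrhythmia_score(mk(c(10, 45, 30)))$as_value, as0)
  # adding an event never decreases AS
  expect_gte(arrhythmia_score(mk(c(base_pts, 5)))$as_value, as0)
  # bounds; AS = 100 iff three events score 100
  expect_identical(arrhythmia_score(mk(c(100, 100, 100)))$as_value, 100)
  expect_lt(arrhythmia_score(mk(c(100, 100, 99)))$as_value, 100)
  for (i in 1:50) {
    pts <- sample(1:100, sample(1:5, 1), replace = TRUE)
    v <- arrhythmia_score(mk(pts))$as_value
    expect_gte(v, 1); expect_lte(v, 100)
  }
})

test_that("incidence bookkeeping counts subjects per kind", {
  seb <- make_events(list(list(kind = "sEB")))
  tdp <- rbind(make_events(list(list(kind = "sEB"))),
               make_events(list(list(kind = "TdP", run_length = 8L,
                                     onset_ms = 5000))))
  subjects <- c(rep(list(NULL), 7), list(seb), list(tdp), list(tdp))
  frac <- incidence_summary(subjects)
  expect_equal(unname(frac["sEB"]), 0.30)
  expect_equal(unname(frac["TdP"]), 0.20)
  expect_equal(unname(incidence_summary(list(NULL, NULL))), c(0, 0, 0))
  expect_equal(unname(incidence_summary(list(make_events(list(
    list(kind = "TdP", run_length = 10L)))))["TdP"]), 1)
})
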