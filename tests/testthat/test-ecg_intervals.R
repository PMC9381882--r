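# Interval arithmetic (verified against the study's printed tables),
# summary measurement, timepoint selection and delineation accuracy.

test_that("jt/jtc reproduce printed table arithmetic and reject domain errors", {
  # anesthetized twice-daily group rows
  expect_identical(jt(364, 123), 241)
  expect_identical(jt(607, 134), 473)
  # once-daily group rows
  expect_identical(jt(379, 113), 266)
  expect_identical(jt(489, 114), 375)
  expect_identical(jt(5, 5), 0)
  expect_error(jt(100, 200), class = "torsadex_domain")

  # awake-dog JTc cells across all four timepoints
  expect_identical(jtc(247, 77), 170)
  expect_identical(jtc(308, 124), 184)
  expect_identical(jtc(290, 116), 174)
  expect_identical(jtc(302, 121), 181)
  expect_identical(jtc(42, 0), 42)
  expect_error(jtc(100, 200), class = "torsadex_domain")
})

test_that("Van de Water correction is the identity at RR 1000 and monotone in RR", {
  expect_identical(qtc_van_de_water(300, 1000), 300)
  # hand arithmetic on awake sinus-rhythm and paced means
  expect_equal(qtc_van_de_water(212, 604), 212 + 0.087 * 396)
  expect_equal(qtc_van_de_water(212, 604), 246.452)
  expect_equal(qtc_van_de_water(277, 653), 307.189)
  # within 2 ms of the printed per-animal means (247, 308)
  expect_lt(abs(qtc_van_de_water(212, 604) - 247), 2)
  expect_lt(abs(qtc_van_de_water(277, 653) - 308), 2)
  rr <- seq(400, 1400, by = 50)
  expect_true(all(diff(qtc_van_de_water(300, rr)) < 0))
  expect_error(qtc_van_de_water(-1, 1000), class = "torsadex_domain")
})

test_that("measure_intervals averages exactly n consecutive complexes", {
  ann <- make_beats(qt = c(360, 362, 364, 366, 368))
  iv <- measure_intervals(ann, n = 5)
  expect_equal(iv$qt, 364)
  expect_equal(iv$qrs, 123)
  expect_equal(iv$jt, 241)
  expect_equal(iv$n_complexes, 5)
  # subtraction identities hold exactly on every summary row
  expect_identical(iv$jt, iv$qt - iv$qrs)
  expect_identical(iv$jtc, iv$qtc - iv$qrs)
  expect_error(measure_intervals(make_beats(qt = rep(364, 3)), n = 5),
               "consecutive", class = "torsadex_insufficient_data")
})

test_that("AV-dissociated rhythm separates PP and RR", {
  rec <- generate_rhythm(rhythm_spec(duration_s = 30, atrial_rate = 120,
                                     seed = 2))
  iv <- measure_intervals(rec$annotations, n = 10)
  expect_equal(iv$rr, 1000)
  expect_equal(iv$pp, 500)
})

test_that("supplied annotations pass through delineation unchanged", {
  rec <- generate_rhythm(rhythm_spec(duration_s = 10, seed = 4))
  expect_identical(delineate(rec$trace, rec$annotations), rec$annotations)
})

test_that("algorithmic delineation recovers QT within 4 ms for >= 95% of beats", {
  rec <- fx_rhythm_default()
  det <- delineate(rec$trace)
  truth <- rec$annotations$beats
  expect_equal(nrow(det$beats), nrow(truth))
  err <- (det$beats$t_end - det$beats$q_on) - truth$qt_true
  frac_ok <- mean(!is.na(err) & abs(err) <= 4)
  expect_gte(frac_ok, 0.95)
  # the estimated atrial train matches the generated one
  expect_equal(length(det$p_waves), length(rec$annotations$p_waves))
})

test_that("delineation errors on traces without a full beat", {
  flat <- signal_trace(cbind(ECG = rep(0, 500)), 1000)
  expect_error(delineate(flat), class = "torsadex_no_beats")
  short <- generate_rhythm(rhythm_spec(duration_s = 0.5, seed = 1))
  expect_error(delineate(short$trace), class = "torsadex_no_beats")
})

test_that("timepoint selection follows the 5-min-or-first-ectopic rule", {
  # no ectopy: anchor at onset + 300 s
  ann <- make_beats(qt = rep(364, 20))
  w <- select_timepoint(ann, infusion_onset_ms = 5000)
  expect_equal(w$anchor_ms, 5000 + 300000)
  expect_lt(w$baseline_window[2], 5000 + 1)

  # first ectopic within the window moves the anchor
  cls <- rep("regular", 20); cls[10] <- "ectopic"
  ann2 <- make_beats(qt = rep(364, 20), class = cls)
  on <- ann2$beats$q_on[10] - 2000
  w2 <- select_timepoint(ann2, infusion_onset_ms = on)
  expect_equal(w2$anchor_ms, ann2$beats$q_on[10])

  # ectopy before the onset only: the rule does not apply
  cls3 <- rep("regular", 20); cls3[2] <- "ectopic"
  ann3 <- make_beats(qt = rep(364, 20), class = cls3)
  on3 <- ann3$beats$q_on[5]
  w3 <- select_timepoint(ann3, infusion_onset_ms = on3)
  expect_equal(w3$anchor_ms, on3 + 300000)

  expect_error(select_timepoint(ann, infusion_onset_ms = 1e9,
                                trace = signal_trace(cbind(ECG = rep(0, 100)), 1000)),
               class = "torsadex_domain")
})
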