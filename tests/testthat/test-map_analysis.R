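# MAP duration, exclusion rules and the STV statistic.

test_that("mapd matches analytic threshold crossings", {
  # instantaneous upstroke to A, linear decay to baseline over T:
  # MAPD80 crosses the 20%-amplitude level at 0.8 * T
  T_dec <- 400
  w <- c(rep(0, 50), 10 - 10 * (0:T_dec) / T_dec, rep(0, 50))
  expect_equal(mapd(w, 0.80), 0.8 * T_dec, tolerance = 1e-2)
  expect_equal(mapd(w, 0.50), 0.5 * T_dec, tolerance = 1e-2)

  # square pulse of width d: MAPD at any fraction equals d
  sq <- c(rep(0, 60), rep(5, 250), rep(0, 60))
  for (f in c(0.5, 0.8, 0.9)) {
    expect_equal(mapd(sq, f), 250, tolerance = 1.1)
  }

  # threshold ordering on any monotone-repolarizing beat
  expect_true(mapd(w, 0.90) >= mapd(w, 0.80))
  expect_true(mapd(w, 0.80) >= mapd(w, 0.50))

  # no crossing within the window
  unresolved <- c(rep(0, 50), rep(10, 300))
  expect_error(mapd(unresolved), class = "torsadex_unresolved_repolarization")
})

test_that("measured MAPD series matches generator ground truth", {
  rec <- generate_rhythm(rhythm_spec(duration_s = 40, atrial_rate = 120,
                                     seed = 12))
  truth <- rec$annotations$beats
  for (ch in c("LV-MAP", "RV-MAP")) {
    ser <- measure_mapd_series(rec$trace, rec$annotations, ch)
    tcol <- if (ch == "LV-MAP") truth$lv_mapd_true else truth$rv_mapd_true
    err <- ser$durations_ms - tcol
    expect_lt(max(abs(err), na.rm = TRUE), 2)
  }
})

test_that("exclusion rules mask ectopic and P-on-T beats with reason codes", {
  # identity when nothing to exclude
  ann <- make_beats(qt = rep(364, 31))
  ser <- duration_series(rep(250, 31))
  expect_identical(exclude_beats(ser, ann)$mask, rep(FALSE, 31))

  # exactly the annotated ectopic index is masked
  cls <- rep("regular", 31); cls[17] <- "ectopic"
  ann2 <- make_beats(qt = rep(364, 31), class = cls)
  out <- exclude_beats(ser, ann2)
  expect_identical(which(out$mask), 17L)
  expect_identical(out$reason[17], "ectopic")

  # a P fiducial within +/-40 ms of the T end masks that beat as p_on_t
  ann3 <- make_beats(qt = rep(364, 31),
                     p_waves = c(50, make_beats(rep(364, 31))$beats$t_end[5] + 25))
  out3 <- exclude_beats(ser, ann3)
  expect_identical(which(out3$mask), 5L)
  expect_identical(out3$reason[5], "p_on_t")
})

test_that("P-on-T coincidences from the AV-dissociated generator are masked", {
  rec <- fx_rhythm_default()  # PP 472.4 vs RR 1000: coincidences recur
  truth <- rec$annotations$beats
  ser <- duration_series(truth$lv_mapd_true)
  out <- exclude_beats(ser, rec$annotations)
  pot <- vapply(seq_len(nrow(truth)), function(b)
    any(abs(rec$annotations$p_waves - truth$t_end[b]) <= 40), logical(1))
  expect_true(any(pot))  # the stated world produces coincidences
  expect_identical(out$mask, pot)
  expect_true(all(out$reason[pot] == "p_on_t"))
})

test_that("stv matches closed forms and both divisor conventions", {
  # constant series: 0 in both modes
  const <- duration_series(rep(250, 31))
  expect_identical(stv(const)$stv, 0)
  expect_identical(stv(const, divisor_mode = "literal")$stv, 0)

  # alternating +a/-a about a mean: sum |dD| = 60a over 30 pairs
  a <- 3
  alt <- duration_series(250 + a * (-1)^(1:31))
  expect_equal(stv(alt)$stv, sqrt(2) * a)
  expect_equal(stv(alt, divisor_mode = "literal")$stv, a)

  # linear ramp with step s: 30 identical differences
  s <- 0.8
  ramp <- duration_series(200 + s * (0:30))
  expect_equal(stv(ramp)$stv, s / sqrt(2))

  # modes differ by exactly sqrt(2), property-checked on random series
  set.seed(42)
  for (i in 1:20) {
    d <- duration_series(250 + cumsum(rnorm(40)))
    expect_equal(stv(d)$stv, stv(d, divisor_mode = "literal")$stv * sqrt(2))
  }
})

test_that("stv is shift-invariant, positively homogeneous and >= 0", {
  set.seed(7)
  d <- 250 + cumsum(rnorm(40))
  base <- stv(duration_series(d))$stv
  expect_gt(base, 0)
  expect_equal(stv(duration_series(d + 57))$stv, base)
  expect_equal(stv(duration_series(3.5 * d))$stv, 3.5 * base)
})

test_that("masked beats break consecutiveness and trigger informative errors", {
  d <- 250 + (1:40) * 0.1
  m <- rep(FALSE, 40); m[20] <- TRUE
  ser <- duration_series(d, mask = m)
  expect_error(stv(ser, n_beats = 30), "longest run is 20",
               class = "torsadex_insufficient_data")
  # a shorter window still fits in the first clean run
  expect_equal(stv(ser, n_beats = 10)$stv, 0.1 / sqrt(2))
})

test_that("delta_mapd is a signed, antisymmetric difference", {
  expect_identical(delta_mapd(250, 250), 0)
  expect_identical(delta_mapd(248, 222), 26)
  expect_identical(delta_mapd(222, 248), -26)
})
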