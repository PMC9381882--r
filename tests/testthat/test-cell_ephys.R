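# Tail-current measurement, pharmacological decomposition and AP metrics.

test_that("tail_current measures the peak relative to the settled level", {
  sw <- generate_sweeps(sweep_spec(iks_amplitude_pa = 300,
                                   ikr_amplitude_pa = 400,
                                   residual_amplitude_pa = 0,
                                   leak_amplitude_pa = 50, noise_sd_pa = 0))
  expect_equal(tail_current(sw, "baseline"), 700, tolerance = 1e-9)
  # flat tail (no currents): 0 regardless of the leak offset
  sw0 <- generate_sweeps(sweep_spec(iks_amplitude_pa = 0,
                                    ikr_amplitude_pa = 0,
                                    residual_amplitude_pa = 0,
                                    leak_amplitude_pa = 50, noise_sd_pa = 0))
  expect_equal(tail_current(sw0, "baseline"), 0, tolerance = 1e-9)
  expect_error(tail_current(sw, "baseline", test_level_mv = 70),
               class = "torsadex_protocol_mismatch")
})

test_that("noisy tail estimates are unbiased within 2 SE over 20 replicates", {
  est <- vapply(1:20, function(k) {
    sw <- generate_sweeps(sweep_spec(iks_amplitude_pa = 300,
                                     ikr_amplitude_pa = 400,
                                     noise_sd_pa = 5, seed = 1000 + k))
    c(tail_current(sw, "baseline") - tail_current(sw, "hmr1556"),
      tail_current(sw, "hmr1556") - tail_current(sw, "hmr1556_dofetilide"))
  }, numeric(2))
  for (j in 1:2) {
    truth <- c(300, 400)[j]
    se <- stats::sd(est[j, ]) / sqrt(ncol(est))
    expect_lt(abs(mean(est[j, ]) - truth), 2 * se + 1e-9)
  }
})

test_that("current_density divides by capacitance with domain checks", {
  expect_identical(current_density(1500, 150), 10)
  expect_identical(current_density(0, 150), 0)
  expect_identical(current_density(2 * 1500, 2 * 150), 10)
  expect_error(current_density(100, 0), class = "torsadex_domain")
})

test_that("decomposition telescopes and recovers configured fractions", {
  sw <- generate_sweeps(sweep_spec(capacitance_pf = 150,
                                   iks_amplitude_pa = 300,
                                   ikr_amplitude_pa = 400, noise_sd_pa = 0))
  dc <- decompose_currents(sw)
  expect_equal(dc$iks + dc$ikr + dc$residual, dc$total, tolerance = 1e-12)
  expect_equal(sum(dc$fractions), 1, tolerance = 1e-12)
  # default residual 300 pA: fractions 0.30 / 0.40 / 0.30 of the 1000 pA tail
  expect_equal(unname(dc$fractions), c(0.30, 0.40, 0.30), tolerance = 1e-9)
  expect_equal(dc$iks, 300 / 150, tolerance = 1e-9)
  expect_equal(dc$total, 1000 / 150, tolerance = 1e-9)
  expect_false(dc$rundown)

  # iks = 0 in the generator: recovered IKs is zero within noise
  swn <- generate_sweeps(sweep_spec(iks_amplitude_pa = 0,
                                    ikr_amplitude_pa = 400,
                                    noise_sd_pa = 2, seed = 3))
  dcn <- decompose_currents(swn)
  expect_lt(abs(dcn$iks) * swn$capacitance_pf, 10)

  # strong rundown (negative component) is flagged, not clipped
  sw_rd <- sw
  sw_rd$conditions$baseline <- sw$conditions$hmr1556
  sw_rd$conditions$hmr1556 <- sw$conditions$baseline
  expect_warning(dc_rd <- decompose_currents(sw_rd), "rundown")
  expect_true(dc_rd$rundown)
  expect_lt(dc_rd$iks, 0)
})

test_that("ap_metrics matches analytic threshold crossings", {
  # amplitude 120 mV, instantaneous upstroke, linear repolarization over
  # 300 ms: APD90 = 270 ms, APD50 = 150 ms
  ap <- c(rep(-80, 100), -80 + 120 - 120 * (0:300) / 300, rep(-80, 1600),
          rep(-80, 100), -80 + 120 - 120 * (0:300) / 300, rep(-80, 1599))
  m <- ap_metrics(signal_trace(cbind(AP = ap), 1000), stv_beats = 30)
  expect_equal(m$apd90, 270, tolerance = 1.1)
  expect_equal(m$apd50, 150, tolerance = 1.1)
  expect_true(is.na(m$stv))  # only 2 APs: STV needs 31
  expect_true(m$apd90 >= m$apd50)
})

test_that("generated AP trains recover APD and STV ground truth", {
  tr <- generate_ap_train(n_beats = 35, apd90_ms = 300, stv_target_ms = 0,
                          seed = 6)
  m <- ap_metrics(tr, stv_beats = 30)
  expect_equal(m$apd90, 300, tolerance = 1)
  expect_identical(m$stv, 0)  # constant APD train
  truth <- attr(tr, "truth")
  expect_equal(m$apd50, mean(truth$apd50_ms), tolerance = 1)
  expect_true(all(m$apd90_series$durations_ms >= 250))
})
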