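test_that("Severinghaus curve has the right anchor points and inverse", {
  # half-saturation tension from bisection on the closed form
  expect_equal(severinghaus_sao2(severinghaus_pao2(0.5)), 0.5,
               tolerance = 1e-9)
  expect_lt(abs(severinghaus_pao2(0.5) - 26.9), 0.05)
  # direct evaluation at a normoxic end-tidal level
  expect_lt(abs(severinghaus_sao2(116) - 0.98539), 1e-4)
  # asymptote and monotonicity
  expect_gt(severinghaus_sao2(5000), 0.9999)
  p <- seq(20, 600, by = 5)
  expect_true(all(diff(severinghaus_sao2(p)) > 0))
  expect_error(severinghaus_sao2(0), "positive")
  # round trip over the physiological range
  pao2 <- seq(30, 600, length.out = 40)
  back <- severinghaus_pao2(severinghaus_sao2(pao2))
  expect_lt(max(abs(back - pao2) / pao2), 1e-6)
})

test_that("pH and P50 follow the bicarbonate chain", {
  expect_equal(ph_from_paco2(41.6), 6.1 + log10(24 / (0.03 * 41.6)),
               tolerance = 1e-12)
  expect_lt(abs(ph_from_paco2(41.6) - 7.384), 1e-3)
  expect_equal(ph_from_paco2(24 / 0.03), 6.1)   # log of 1
  expect_lt(abs(ph_from_paco2(40) - 7.401), 1e-3)
  expect_error(ph_from_paco2(-3), "positive")
  # resting P50 reproduces the in-vivo group value within 0.1 mmHg
  expect_lt(abs(p50_from_ph(ph_from_paco2(41.6)) - 27.1), 0.1)
  expect_lt(abs(p50_from_ph(7.40) - 26.73), 0.01)
  expect_lt(abs(suppressWarnings(p50_from_ph(221.87 / 26.37))), 1e-9)
  expect_warning(p50_from_ph(6.2), "range")
  # decreasing in pH, and in PaCO2 through the chain
  expect_lt(p50_from_ph(7.5), p50_from_ph(7.3))
})

test_that("arterial oxygen content assembles bound and dissolved terms", {
  bc <- blood_constants(hb = 0.143)
  expect_equal(cao2_from_state(0, 1, hb = 0.143, constants = bc),
               1.34 * 0.143, tolerance = 1e-12)
  expect_equal(cao2_from_state(100, 0, hb = 0.143, constants = bc),
               0.0031, tolerance = 1e-12)    # epsilon rescaled per ml
  full <- cao2_from_state(116, severinghaus_sao2(116), hb = 0.143,
                          constants = bc)
  expect_lt(abs(full - 0.192), 1e-3)
  # monotone in each argument
  expect_gt(cao2_from_state(200, 0.99, 0.143, bc),
            cao2_from_state(100, 0.99, 0.143, bc))
  expect_gt(cao2_from_state(100, 0.99, 0.143, bc),
            cao2_from_state(100, 0.95, 0.143, bc))
  expect_gt(cao2_from_state(100, 0.99, 0.16, bc),
            cao2_from_state(100, 0.99, 0.13, bc))
  # g/dl passed as g/ml is caught
  expect_error(cao2_from_state(100, 0.99, hb = 14.3, constants = bc),
               "hb")
  expect_equal(hb_to_g_ml(14.3), 0.143)
  expect_equal(hb_to_g_ml(0.143), 0.143)
  expect_error(hb_to_g_ml(1.2), "not interpretable")
})

test_that("blood T1 responds to oxygen tension and desaturation", {
  expect_equal(t1_blood_from_oxygenation(0, 1), 1 / 0.5848,
               tolerance = 1e-12)
  r1 <- 1.527e-4 * 116 + 0.1713 * (1 - 0.98539) + 0.5848
  expect_equal(t1_blood_from_oxygenation(116, 0.98539), 1 / r1,
               tolerance = 1e-9)
  # hyperoxia shortens T1; desaturation shortens T1
  expect_lt(t1_blood_from_oxygenation(500, 0.999),
            t1_blood_from_oxygenation(100, 0.98))
  expect_lt(t1_blood_from_oxygenation(100, 0.8),
            t1_blood_from_oxygenation(100, 0.98))
  # physiological range over the protocol envelope
  grid <- expand.grid(pao2 = seq(60, 500, by = 40),
                      sao2 = seq(0.8, 1, by = 0.05))
  t1 <- t1_blood_from_oxygenation(grid$pao2, grid$sao2)
  expect_true(all(t1 > 1.0 & t1 < 2.2))
})

test_that("end-tidal traces validate their physiological envelope", {
  tr <- end_tidal_trace(0:10, rep(40, 11), rep(110, 11))
  expect_s3_class(tr, "end_tidal_trace")
  expect_error(end_tidal_trace(c(0, 0, 1), rep(40, 3), rep(110, 3)),
               "increasing")
  expect_error(end_tidal_trace(0:2, c(40, 150, 40), rep(110, 3)), "petco2")
  expect_error(end_tidal_trace(0:2, rep(40, 3), c(110, 20, 110)), "peto2")
})

test_that("trace alignment recovers a known shift and flags degeneracy", {
  trace <- make_protocol()
  tr <- 4.4
  n <- 240
  tv <- (seq_len(n) - 0.5) * tr
  # flow timecourse generated from the shifted trace: the trace arrives
  # 6 s late relative to the MR signal it drives
  co2_at <- function(t) approx(trace$time, trace$petco2, xout = t,
                               rule = 2)$y
  asl <- 1 + 0.024 * (co2_at(tv) - 41.6)
  shifted <- end_tidal_trace(trace$time + 6, trace$petco2, trace$peto2)
  art <- align_traces(shifted, asl, tr = tr)
  expect_lt(abs(attr(art, "lag") + 6), 1.01)  # one trace sample
  expect_s3_class(art, "arterial_ts")
  expect_equal(nrow(art), n)
  # zero shift: lag 0
  art0 <- align_traces(trace, asl, tr = tr)
  expect_lt(abs(attr(art0, "lag")), 1.01)
  # pure noise: warning about unreliable alignment (a boundary-lag warning
  # may accompany it)
  set.seed(1)
  w <- testthat::capture_warnings(align_traces(trace, rnorm(n), tr = tr))
  expect_true(any(grepl("unreliable", w)))
})

test_that("arterial state derives baseline scalars from air periods", {
  trace <- make_protocol()
  tv <- (seq_len(244) - 0.5) * 4.4
  res <- qdcm:::resample_trace(trace, tv)
  art <- arterial_state(res$petco2, res$peto2, time = tv)
  expect_true(all(art$sao2 > 0 & art$sao2 <= 1))
  expect_true(all(art$t1_blood > 1.0 & art$t1_blood < 2.2))
  expect_gt(attr(art, "p50"), 20)
  expect_lt(attr(art, "p50"), 35)
  # baseline CO2 near the air plateau, not dragged up by hypercapnia
  expect_lt(abs(attr(art, "paco2_0") - 41.6), 0.5)
  # content ceiling: bound + dissolved cannot exceed the physical maximum
  bc <- attr(art, "constants")
  expect_true(all(art$cao2 <= bc$phi * bc$hb +
                    bc$epsilon / 100 * art$pao2 + 1e-9))
})
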