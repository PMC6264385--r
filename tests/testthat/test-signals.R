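test_that("CO2-driven flow timecourse is linear in the excursion", {
  expect_equal(as.numeric(cbf_timecourse(60, 2.4, rep(0, 5))), rep(60, 5))
  expect_equal(as.numeric(cbf_timecourse(60, 2.4, 10)), 60 * 1.24)
  expect_equal(as.numeric(cbf_timecourse(60, 0, c(-5, 0, 10))), rep(60, 3))
  # non-physical excursions clip at the floor with a warning
  expect_warning(out <- cbf_timecourse(60, 5, -30), "clipped")
  expect_gt(min(out), 0)
})

test_that("deoxyhaemoglobin ratio has the right baseline and signs", {
  hb <- 0.143
  cao2_0 <- 0.192
  # baseline identity
  expect_equal(dhb_ratio(60, 60, cao2_0, cao2_0, hb, 0.38, 0.985), 1,
               tolerance = 1e-12)
  # hypercapnic washout lowers the ratio
  expect_lt(dhb_ratio(60 * 1.24, 60, cao2_0, cao2_0, hb, 0.38, 0.985), 1)
  # hyperoxic content gain lowers the ratio; magnitude follows the model
  r_ho <- dhb_ratio(60, 60, cao2_0 + 0.003, cao2_0, hb, 0.38, 0.985)
  dhb0 <- dhb_baseline(hb, 0.38, 0.985)
  expect_equal(r_ho, 1 - 0.003 / (1.34 * dhb0), tolerance = 1e-12)
  expect_lt(r_ho, 1)
  # inconsistent inputs error unless floored
  expect_error(dhb_ratio(60, 60, cao2_0 + 1, cao2_0, hb, 0.38, 0.985),
               "non-positive")
  expect_equal(dhb_ratio(60, 60, cao2_0 + 1, cao2_0, hb, 0.38, 0.985,
                         floor = 1e-6), 1e-6)
})

test_that("BOLD model is zero at baseline and scales linearly in kappa", {
  dhb0 <- dhb_baseline(0.143, 0.38, 0.985)
  expect_equal(bold_signal(0.065, 30, dhb0, 1, 1), 0)
  b1 <- bold_signal(0.065, 30, dhb0, 0.8, 1.24)
  expect_gt(b1, 0)                       # hypercapnia: positive response
  expect_equal(bold_signal(0.13, 30, dhb0, 0.8, 1.24), 2 * b1,
               tolerance = 1e-12)
})

test_that("pCASL difference signal evaluates the kinetic model", {
  # hand computation at representative values
  t1b <- 1.65
  hand <- 2 * 0.85 * 0.88 * 60 * t1b * 1 * (1 - exp(-1.5 / t1b)) *
    exp(-1.5 / t1b) / (6000 * 0.9)
  expect_equal(asl_difference_signal(60, t1b, 1), hand, tolerance = 1e-12)
  expect_lt(abs(hand - 6.598e-3), 1e-5)
  expect_equal(asl_difference_signal(0, 1.65, 1), 0)
  # shorter blood T1 (hyperoxia) attenuates the signal at these timings
  expect_lt(asl_difference_signal(60, 1.60, 1),
            asl_difference_signal(60, 1.65, 1))
})

test_that("forward model is internally consistent on the gas protocol", {
  lut <- get_lut()
  ph <- get_phantom_noiseless()
  arterial <- ph$arterial
  state <- list(cbf0 = 55.6, dc = 0.092, kappa = 0.065, cvr = 2.4, m0 = 1)
  fm <- forward_model(state, arterial, lut)
  base <- attr(arterial, "baseline")
  # baseline identity: BOLD near zero (air volumes sit within 1 mmHg of
  # the plateau, an order of magnitude below the hypercapnic response)
  expect_lt(max(abs(fm$bold[base])), 3e-3)
  asl0 <- asl_difference_signal(fm$cbf[base], arterial$t1_blood[base], 1)
  expect_equal(fm$asl[base], asl0, tolerance = 1e-9)
  # flat modulation: constant ASL, zero BOLD everywhere
  art_flat <- arterial_state(rep(41.6, 50), rep(116, 50),
                             baseline = 1:50)
  fm_flat <- forward_model(state, art_flat, lut)
  expect_equal(max(abs(fm_flat$bold)), 0, tolerance = 1e-12)
  expect_equal(stats::sd(fm_flat$asl), 0, tolerance = 1e-12)
  # hypercapnia: both channels rise
  hc <- which(arterial$paco2 - attr(arterial, "paco2_0") > 8)
  expect_true(all(fm$bold[hc] > 0))
  expect_true(all(fm$asl[hc] > max(fm$asl[base])))
  # hyperoxia: BOLD positive, ASL slightly reduced via blood T1
  ho <- which(arterial$pao2 - attr(arterial, "pao2_0") > 150)
  expect_true(all(fm$bold[ho] > 0))
  expect_lt(mean(fm$asl[ho]), mean(fm$asl[base]))
  # raising diffusivity at fixed flow raises OEF and the BOLD scale
  fm_hi <- forward_model(modifyList(state, list(dc = 0.12)), arterial, lut)
  expect_gt(fm_hi$oef0, fm$oef0)
  expect_gt(fm_hi$dhb0, fm$dhb0)
})

test_that("generator output equals the forward model exactly at zero noise", {
  ph <- get_phantom_noiseless()
  lut <- get_lut()
  v <- 2
  st <- list(cbf0 = ph$truth$cbf0[v], dc = ph$truth$dc[v],
             kappa = ph$truth$kappa[v], cvr = ph$truth$cvr[v],
             m0 = ph$truth$m0[v])
  fm <- forward_model(st, ph$arterial, lut, ph$spec$acq)
  expect_identical(fm$asl, ph$truth$asl[, v])
  expect_identical(fm$bold, ph$truth$bold[, v])
})

test_that("acquisition parameter validation enforces physical ranges", {
  expect_s3_class(acq_params(), "acq_params")
  expect_error(acq_params(alpha = 1.2), "alpha")
  expect_error(acq_params(theta = 0.8), "theta")
  expect_error(acq_params(te2 = -1), "positive")
})
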