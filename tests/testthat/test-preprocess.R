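test_that("surround subtraction isolates the alternating component", {
  # constant series: nothing to subtract
  expect_equal(surround_subtract(rep(5, 8)), rep(0, 8))
  # alternating square wave of amplitude a: difference signal 2a,
  # consistent sign (hand-computed on a 6-sample toy series)
  a <- 0.3
  x <- rep(c(-a, a), 3)          # tag low, control high
  expect_equal(surround_subtract(x, tag_first = TRUE), rep(2 * a, 6))
  # linear drift cancels exactly in the interior
  drift <- 0.01 * (1:10)
  out <- surround_subtract(rep(c(-a, a), 5) + drift, tag_first = TRUE)
  expect_equal(out[2:9], rep(2 * a, 8), tolerance = 1e-12)
  # matrix input preserved shape
  m <- cbind(x, x)
  expect_equal(dim(surround_subtract(m)), dim(m))
})

test_that("surround averaging removes the alternating component", {
  a <- 0.3
  x <- rep(c(-a, a), 3)
  expect_equal(surround_average(x), rep(0, 6))
  expect_equal(surround_average(rep(7, 6)), rep(7, 6))
  # superposition: constant + alternating -> constant (6-sample toy)
  expect_equal(surround_average(rep(7, 6) + x), rep(7, 6))
  # slow component survives with < 1% distortion: the 3-point kernel
  # attenuates frequency w by (1 - cos w)/2, below 1% for periods over
  # ~32 samples
  n <- 80
  slow <- sin(2 * pi * (1:n) / 40)
  out <- surround_average(slow + rep(c(-a, a), n / 2))
  expect_lt(max(abs(out[2:(n - 1)] - slow[2:(n - 1)])), 0.01)
})

test_that("preprocessing a phantom separates ASL and BOLD components", {
  ph <- get_phantom_noiseless()
  data <- preprocess_dexi(ph$series,
                          baseline = attr(ph$arterial, "baseline"))
  mid <- 5:240
  rms <- function(x) sqrt(mean(x^2))
  for (v in c(1, 2, 4)) {
    # separation crosstalk: RMS recovery error of each component below 2%
    # of its RMS amplitude (instantaneous errors peak at gas transitions,
    # where the slow-signal assumption of surround processing is weakest)
    expect_lt(rms(data$asl[mid, v] - ph$truth$asl[mid, v]),
              0.02 * rms(ph$truth$asl[mid, v]))
    expect_lt(rms(data$bold[mid, v] - ph$truth$bold[mid, v]),
              0.02 * rms(ph$truth$bold[mid, v]))
    expect_lt(max(abs(data$asl[mid, v] - ph$truth$asl[mid, v])),
              0.15 * max(ph$truth$asl[, v]))
  }
  # pure ASL-only series: averaging leaves residual below 2% of amplitude
  v <- 2
  s <- qdcm:::interleave_sign(nrow(ph$truth$asl))
  te1_asl <- 1 + s * ph$truth$asl[, v] / 2
  resid <- surround_average(te1_asl) - 1
  expect_lt(max(abs(resid[mid])), 0.02 * max(ph$truth$asl[, v]))
})

test_that("wrong tag/control ordering is flagged by polarity", {
  ph <- get_phantom_noiseless()
  flipped <- ph$series
  flipped$tag_first <- FALSE
  expect_warning(preprocess_dexi(flipped,
                                 baseline = attr(ph$arterial, "baseline")),
                 "ordering")
})

test_that("initial perfusion inverts the kinetic model and builds priors", {
  acq <- acq_params()
  t1b0 <- 1.65
  cbf_true <- c(30, 45, 60, 55, 20)
  scale <- 2 * acq$alpha * acq$alpha_inv * t1b0 *
    (1 - exp(-acq$tau / t1b0)) * exp(-acq$pld / t1b0) /
    (6000 * acq$lambda_bp)
  asl <- cbf_true * scale
  out <- suppressWarnings(
    initial_perfusion_and_gm_pv(asl, m0 = rep(1, 5), t1_blood_0 = t1b0,
                                acq = acq))
  expect_equal(out$cbf_init, cbf_true, tolerance = 1e-9)
  # uniform perfusion: partial volume 1 everywhere, prior at the scale cap
  uni <- suppressWarnings(
    initial_perfusion_and_gm_pv(rep(0.006, 12), rep(1, 12), t1b0, acq))
  expect_equal(uni$gm_pv, rep(1, 12))
  expect_equal(uni$dc_prior, rep(0.15, 12))
  # a voxel far above the normalising median is clipped to 1
  expect_lte(max(out$gm_pv), 1)
  expect_equal(out$dc_prior, 0.15 * out$gm_pv)
  # phantom round trip: baseline ASL mean inverts to the true flow map
  ph <- get_phantom_noiseless()
  data <- preprocess_dexi(ph$series,
                          baseline = attr(ph$arterial, "baseline"))
  base <- attr(ph$arterial, "baseline")
  prior <- suppressWarnings(initial_perfusion_and_gm_pv(
    colMeans(data$asl[base, ]), data$m0,
    attr(ph$arterial, "t1_blood_0"), acq))
  expect_lt(max(abs(prior$cbf_init - ph$truth$cbf0) / ph$truth$cbf0), 0.05)
})

test_that("gaussian smoother preserves means and flattens structure", {
  set.seed(5)
  vol <- array(stats::rnorm(16 * 16 * 4, 10, 2), dim = c(16, 16, 4))
  sm <- smooth_gaussian(vol, fwhm = 2)
  expect_equal(dim(sm), dim(vol))
  expect_lt(stats::sd(sm), stats::sd(vol))
  expect_equal(mean(sm), mean(vol), tolerance = 0.02)
})
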