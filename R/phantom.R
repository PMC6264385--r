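#' Default interleaved gas-challenge schedule
#'
#' An 18-minute protocol with two hypercapnic and two hyperoxic blocks
#' (180 s each) separated by 90 s of medical air, after a 90 s air lead-in.
#' Plateau targets default to representative group values: air CO2
#' 41.6 mmHg / O2 116 mmHg, hypercapnic CO2 51.7 mmHg, hyperoxic O2
#' 325.2 mmHg.
#'
#' @param air_co2,air_o2 Air-breathing plateau targets, mmHg.
#' @param hc_co2 Hypercapnic CO2 target, mmHg.
#' @param ho_o2 Hyperoxic O2 target, mmHg.
#' @return Data frame with columns `start`, `end` (s), `co2`, `o2` (mmHg
#'   targets), class `gas_protocol`.
#' @export
default_protocol <- function(air_co2 = 41.6, air_o2 = 116,
                             hc_co2 = 51.7, ho_o2 = 325.2) {
  starts <- c(0, 90, 270, 360, 540, 630, 810, 900)
  ends <- c(90, 270, 360, 540, 630, 810, 900, 1080)
  gas <- c("air", "hc", "air", "ho", "air", "hc", "air", "ho")
  co2 <- ifelse(gas == "hc", hc_co2, air_co2)
  o2 <- ifelse(gas == "ho", ho_o2, air_o2)
  structure(data.frame(start = starts, end = ends, gas = gas,
                       co2 = co2, o2 = o2),
            class = c("gas_protocol", "data.frame"))
}

#' Synthesize an end-tidal trace from a block schedule
#'
#' Builds a piecewise-plateau end-tidal recording with first-order
#' exponential transitions between block targets (default washin/washout
#' time constant 15 s, mimicking gas delivery dynamics).
#'
#' @param protocol A block schedule as returned by [default_protocol()].
#' @param dt Trace sampling interval, s.
#' @param transition_tau Exponential transition time constant, s.
#' @return An [end_tidal_trace()] spanning the schedule.
#' @export
make_protocol <- function(protocol = default_protocol(), dt = 1,
                          transition_tau = 15) {
  if (any(protocol$end <= protocol$start))
    stop("blocks must have positive duration")
  if (nrow(protocol) > 1 &&
      any(protocol$start[-1] < protocol$end[-nrow(protocol)]))
    stop("overlapping gas blocks")
  times <- seq(0, max(protocol$end), by = dt)
  target_at <- function(t, col) {
    i <- findInterval(t, protocol$start)
    protocol[[col]][pmax(i, 1)]
  }
  relax <- function(col) {
    v <- numeric(length(times))
    v[1] <- target_at(times[1], col)
    a <- exp(-dt / transition_tau)
    for (i in 2:length(times)) {
      tgt <- target_at(times[i], col)
      v[i] <- tgt + (v[i - 1] - tgt) * a
    }
    v
  }
  end_tidal_trace(times, petco2 = relax("co2"), peto2 = relax("o2"))
}

#' Ground-truth parameter maps for a digital phantom
#'
#' Emulates a brain-like voxel population: each voxel draws a grey-matter
#' partial volume uniformly on (0.1, 1); flow, reactivity and the BOLD
#' calibration parameter scale with it between white-matter-like and
#' grey-matter-like levels with lognormal scatter (a full grey-matter voxel
#' lands near representative group means: CBF ~55 ml/100g/min, CVR
#' ~2.4 %/mmHg, kappa ~0.065). The true extraction fraction is drawn
#' narrowly around 0.39 irrespective of tissue class — resting OEF is
#' spatially near-uniform in the healthy brain — and the effective
#' diffusivity is derived from (OEF, CBF) by lookup-table inversion, so
#' diffusivity co-varies with flow and hence capillary density.
#'
#' @param n_vox Number of voxels.
#' @param lut An `oxygen_lut` used to derive the true diffusivity from the
#'   drawn extraction fraction and flow.
#' @param seed RNG seed.
#' @return List of numeric vectors `cbf0`, `dc`, `kappa`, `cvr`, `m0`,
#'   plus the generating partial volume `gm_pv` and drawn `oef0`.
#' @export
default_truth <- function(n_vox, lut, seed = 1) {
  set.seed(seed)
  clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)
  jit <- function(s) exp(stats::rnorm(n_vox, 0, s))
  pv <- stats::runif(n_vox, 0.1, 1)
  cbf0 <- clip((15 + 45 * pv) * jit(0.08), 5, 150)
  oef0 <- clip(stats::rnorm(n_vox, 0.39, 0.03), 0.30, 0.50)
  dc <- as.numeric(invert_lookup_for_dc(oef0, cbf0, lut))
  list(cbf0 = cbf0,
       dc = dc,
       kappa = clip((0.02 + 0.05 * pv) * jit(0.10), 0.005, 0.2),
       cvr = clip((0.6 + 2.0 * pv) * jit(0.10), 0.2, 6),
       m0 = rep(1, n_vox),
       gm_pv = pv,
       oef0 = oef0)
}

#' Specification of a digital phantom experiment
#'
#' @param shape Voxel grid dimensions (3-vector).
#' @param truth List of per-voxel true parameters (`cbf0`, `dc`, `kappa`,
#'   `cvr`, `m0`); left `NULL`, [default_truth()] draws are generated at
#'   synthesis time (the lookup table is needed to derive diffusivity).
#' @param protocol Gas block schedule ([default_protocol()]).
#' @param tsnr Temporal SNR of the baseline BOLD (second-echo) signal.
#' @param noise_ratio First-echo to second-echo thermal noise SD ratio.
#' @param seed RNG seed for the noise draws.
#' @param acq An [acq_params()] object.
#' @param hb Haemoglobin concentration, g/ml.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(10, 10, 1), truth = NULL,
                         protocol = default_protocol(), tsnr = 200,
                         noise_ratio = 1, seed = 1, acq = acq_params(),
                         hb = 0.143) {
  n_vox <- prod(shape)
  if (!is.null(truth) && !all(lengths(truth) == n_vox))
    stop("truth maps must match the voxel grid size")
  if (tsnr <= 0) stop("tsnr must be strictly positive")
  structure(list(shape = shape, truth = truth, protocol = protocol,
                 tsnr = tsnr, noise_ratio = noise_ratio, seed = seed,
                 acq = acq, hb = hb),
            class = "phantom_spec")
}

#' Synthesize a noisy dual-excitation phantom dataset
#'
#' Generates the full interleaved tag/control acquisition implied by a
#' phantom specification: the end-tidal protocol is converted to a
#' per-volume arterial state, every voxel's ASL difference and BOLD
#' fractional signals are produced by [forward_model()] (the same code path
#' the fitter uses, so phantom-based recovery isolates estimation error),
#' and the components are interleaved into tag/control volume pairs with
#' the ASL difference alternating in sign at the first echo and the BOLD
#' component common to both echoes (scaled by echo time at TE1). White
#' Gaussian noise is added per channel at the requested baseline tSNR.
#'
#' @param spec A [phantom_spec()].
#' @param lut An `oxygen_lut` built with the phantom's Hb and P50 linking
#'   diffusivity to extraction fraction.
#' @param s1_scale,s2_scale Static first/second-echo tissue signal as a
#'   fraction of `m0` (crude T2* decay at the two echo times).
#' @return List with `series` (a [dexi_series()]), `arterial` (true aligned
#'   arterial state), `trace` (the end-tidal recording), `truth` (including
#'   derived true `oef0` and noiseless `asl`/`bold` matrices) and `spec`.
#' @export
synthesize_dataset <- function(spec, lut, s1_scale = 0.7, s2_scale = 0.35) {
  stopifnot(inherits(spec, "phantom_spec"), inherits(lut, "oxygen_lut"))
  acq <- spec$acq
  trace <- make_protocol(spec$protocol)
  n_vol <- floor(max(trace$time) / acq$tr)
  n_vol <- n_vol - n_vol %% 2
  tv <- (seq_len(n_vol) - 0.5) * acq$tr
  res <- resample_trace(trace, tv)
  constants <- blood_constants(hb = spec$hb)
  arterial <- arterial_state(paco2 = res$petco2, pao2 = res$peto2,
                             constants = constants, time = tv, lag = 0)
  n_vox <- prod(spec$shape)
  truth <- spec$truth
  if (is.null(truth)) truth <- default_truth(n_vox, lut, seed = spec$seed)
  asl_true <- matrix(0, n_vol, n_vox)
  bold_true <- matrix(0, n_vol, n_vox)
  oef0 <- numeric(n_vox)
  for (v in seq_len(n_vox)) {
    st <- list(cbf0 = truth$cbf0[v], dc = truth$dc[v],
               kappa = truth$kappa[v], cvr = truth$cvr[v],
               m0 = truth$m0[v])
    fm <- forward_model(st, arterial, lut, acq)
    asl_true[, v] <- fm$asl
    bold_true[, v] <- fm$bold
    oef0[v] <- fm$oef0
  }
  s <- interleave_sign(n_vol, tag_first = TRUE)
  s1 <- s1_scale * truth$m0
  s2 <- s2_scale * truth$m0
  te1 <- sweep(1 + bold_true * (acq$te1 / acq$te2), 2, s1, "*") +
    (s * asl_true) / 2
  te2 <- sweep(1 + bold_true, 2, s2, "*")
  set.seed(spec$seed)
  sd2 <- s2 / spec$tsnr
  sd1 <- sd2 * spec$noise_ratio
  te1 <- te1 + sweep(matrix(stats::rnorm(n_vol * n_vox), n_vol), 2, sd1, "*")
  te2 <- te2 + sweep(matrix(stats::rnorm(n_vol * n_vox), n_vol), 2, sd2, "*")
  series <- dexi_series(te1 = te1, te2 = te2, m0 = truth$m0,
                        mask = rep(TRUE, n_vox), dim = spec$shape,
                        tr = acq$tr, tag_first = TRUE)
  truth$oef0 <- oef0
  truth$asl <- asl_true
  truth$bold <- bold_true
  list(series = series, arterial = arterial, trace = trace, truth = truth,
       spec = spec)
}
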