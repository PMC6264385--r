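#' Percent signal change of a block-design timeseries
#'
#' Ordinary least squares fit of a constant plus boxcar regressor; the
#' percent change is 100 times the boxcar amplitude over the constant term.
#' This is a deliberately simple substitute for a full GLM analysis with
#' autocorrelation modelling.
#'
#' @param timeseries Numeric vector.
#' @param design Boxcar regressor (0/1 or logical), same length; must
#'   contain at least two on-blocks.
#' @return Percent change (scalar) with the standard error of the estimate
#'   in `attr(, "se")`.
#' @export
block_percent_change <- function(timeseries, design) {
  design <- as.numeric(design)
  if (length(design) != length(timeseries))
    stop("design must cover the series")
  r <- rle(design > 0)
  if (sum(r$values) < 2) stop("design must contain at least two on-blocks")
  fit <- stats::lm(timeseries ~ design)
  b <- stats::coef(fit)
  if (b[1] <= 0) stop("non-positive baseline term: percent change undefined")
  se <- suppressWarnings(summary(fit))$coefficients[2, 2]
  structure(unname(100 * b[2] / b[1]), se = unname(100 * se / b[1]))
}

#' Task-state CMRO2 from the modified calibration model
#'
#' \deqn{CMRO_2 = CMRO_{2,0}\left(1 -
#'   \frac{\Delta BOLD/BOLD_0}{TE\,\kappa\,[dHb]_0}\right)
#'   \left(\frac{CBF}{CBF_0}\right)^{1-\theta},}
#' where kappa and the baseline deoxyhaemoglobin concentration come from
#' the resting-state fit of the same voxels.
#'
#' @param cmro2_0 Baseline CMRO2, umol/100g/min.
#' @param dbold_frac Task BOLD change as a fraction of baseline signal
#'   (\eqn{\Delta BOLD / BOLD_0}).
#' @param te Echo time, ms (consistent with kappa's scale).
#' @param kappa BOLD calibration parameter from the resting fit.
#' @param dhb0 Baseline deoxyhaemoglobin concentration, g/ml.
#' @param cbf_ratio Task/baseline CBF ratio.
#' @param theta Flow-volume/diffusion exponent.
#' @return Task CMRO2, umol/100g/min. The bracket going non-positive marks
#'   a non-physical voxel and raises an error.
#' @export
task_cmro2 <- function(cmro2_0, dbold_frac, te, kappa, dhb0, cbf_ratio,
                       theta = 0.06) {
  bracket <- 1 - dbold_frac / (te * kappa * dhb0)
  if (any(bracket <= 0))
    stop("calibration bracket non-positive: non-physical voxel")
  cmro2_0 * bracket * cbf_ratio^(1 - theta)
}

#' Task-state OEF (Fick) and effective diffusivity (lookup inversion)
#'
#' Computes the task oxygen extraction fraction from the Fick principle,
#' \eqn{OEF = CMRO_2 / (CBF \cdot C_aO_2)} (with the ml-to-umol conversion
#' applied to the denominator), then inverts the lookup table for the
#' effective diffusivity at constant haemoglobin concentration and P50.
#'
#' @param cmro2_task Task CMRO2, umol/100g/min.
#' @param cbf_task Task CBF, ml/100g/min.
#' @param cao2 Arterial oxygen content, ml/ml (task assumed equal to rest
#'   for air-breathing task runs).
#' @param lut An `oxygen_lut`.
#' @param molar_volume Molar volume of O2, ml/mmol.
#' @return List with `oef` and `dc` (diffusivity carries the `at_bound`
#'   attribute from [invert_lookup_for_dc()]).
#' @export
task_oef_and_dc <- function(cmro2_task, cbf_task, cao2, lut,
                            molar_volume = 25.45) {
  if (any(cmro2_task <= 0) || any(cbf_task <= 0) || any(cao2 <= 0))
    stop("inputs must be strictly positive")
  oef <- cmro2_task / ml_to_umol(cbf_task * cao2,
                                 molar_volume = molar_volume)
  if (any(oef >= 1)) stop("task OEF >= 1: non-physical")
  dc <- invert_lookup_for_dc(oef, cbf_task, lut)
  list(oef = oef, dc = dc)
}

#' Summarise task-evoked physiological changes
#'
#' Convenience wrapper composing the task pipeline for one voxel or ROI:
#' percent BOLD and CBF changes, task CMRO2 via the modified calibration
#' model, task OEF via Fick, task diffusivity via lookup inversion, the
#' CBF:CMRO2 coupling ratio and the flow-volume coupling exponent implied
#' by the diffusivity change.
#'
#' @param rest List with the resting-state quantities `cbf0`, `oef0`, `dc`,
#'   `kappa`, `cmro2_0`, `cao2_0`, `sao2_0`, `hb` (e.g. drawn from a
#'   [qdcm_fit()] voxel or ROI mean).
#' @param pct_bold Task BOLD change, percent of baseline signal.
#' @param pct_cbf Task CBF change, percent.
#' @param lut An `oxygen_lut`.
#' @param acq An [acq_params()] object (TE2 and theta are used).
#' @param molar_volume Molar volume of O2, ml/mmol.
#' @return List of class `task_result`: `pct_cbf`, `pct_bold`, `pct_cmro2`,
#'   `pct_dc`, `coupling_ratio` (n = %CBF / %CMRO2), `eta` (flow-volume
#'   exponent implied by the diffusivity change), `oef_task`, `dc_task`,
#'   `cmro2_task`.
#' @export
task_summary <- function(rest, pct_bold, pct_cbf, lut, acq = acq_params(),
                         molar_volume = 25.45) {
  cbf_ratio <- 1 + pct_cbf / 100
  dhb0 <- dhb_baseline(rest$hb, rest$oef0, rest$sao2_0)
  cmro2_task <- task_cmro2(rest$cmro2_0, pct_bold / 100, acq$te2,
                           rest$kappa, dhb0, cbf_ratio, acq$theta)
  td <- task_oef_and_dc(cmro2_task, rest$cbf0 * cbf_ratio, rest$cao2_0,
                        lut, molar_volume)
  pct_cmro2 <- 100 * (cmro2_task / rest$cmro2_0 - 1)
  pct_dc <- 100 * (as.numeric(td$dc) / rest$dc - 1)
  structure(list(pct_cbf = pct_cbf, pct_bold = pct_bold,
                 pct_cmro2 = pct_cmro2, pct_dc = pct_dc,
                 coupling_ratio = pct_cbf / pct_cmro2,
                 eta = flow_volume_exponent(cbf_ratio, 1 + pct_dc / 100),
                 oef_task = td$oef, dc_task = as.numeric(td$dc),
                 cmro2_task = cmro2_task),
            class = "task_result")
}

#' @export
print.task_result <- function(x, ...) {
  cat("Task-evoked changes\n")
  cat(sprintf("  %%CBF %.1f, %%BOLD %.2f, %%CMRO2 %.1f, %%Dc %.1f\n",
              x$pct_cbf, x$pct_bold, x$pct_cmro2, x$pct_dc))
  cat(sprintf("  CBF:CMRO2 coupling n = %.2f, flow-volume eta = %.2f\n",
              x$coupling_ratio, x$eta))
  invisible(x)
}

#' Simulate rest+activation signals for a known metabolic change
#'
#' Forward-generates the boxcar-task ASL and BOLD timeseries of a voxel in
#' which flow and oxygen metabolism rise by known ratios during the on
#' blocks, for validating the task quantification by inversion. During
#' activation the venous oxygen content follows the Fick principle
#' (\eqn{OEF = OEF_0 \cdot r_{CMRO_2}/r_{CBF}} at constant arterial
#' content) and the deoxyhaemoglobin concentration is recomputed from the
#' task venous saturation, so the generated BOLD signal reflects a genuine
#' (non-isometabolic) metabolic change.
#'
#' @param rest List with `cbf0`, `oef0`, `kappa`, `m0`, `hb`, `sao2_0`,
#'   `pao2_0` (air-breathing baseline).
#' @param design Boxcar (0/1) per volume.
#' @param cbf_ratio,cmro2_ratio On-block flow and metabolism ratios.
#' @param acq An [acq_params()] object.
#' @return List with `asl`, `bold` (per volume), `bold_frac` equal to
#'   `bold`, and the generating ratios.
#' @export
simulate_task_series <- function(rest, design, cbf_ratio, cmro2_ratio,
                                 acq = acq_params()) {
  design <- as.numeric(design > 0)
  rf <- 1 + (cbf_ratio - 1) * design
  rm <- 1 + (cmro2_ratio - 1) * design
  oef_t <- rest$oef0 * rm / rf
  if (any(oef_t >= 1)) stop("task OEF >= 1 in simulation")
  svo2 <- rest$sao2_0 * (1 - oef_t)
  dhb <- rest$hb * (1 - svo2)
  dhb0 <- dhb_baseline(rest$hb, rest$oef0, rest$sao2_0)
  bold <- acq$te2 * rest$kappa * dhb0 * (1 - rf^acq$theta * dhb / dhb0)
  t1b <- t1_blood_from_oxygenation(rest$pao2_0, rest$sao2_0)
  asl <- asl_difference_signal(rest$cbf0 * rf, rep(t1b, length(rf)),
                               rest$m0, acq)
  list(asl = asl, bold = bold, bold_frac = bold, cbf_ratio = cbf_ratio,
       cmro2_ratio = cmro2_ratio, oef_task = oef_t)
}
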