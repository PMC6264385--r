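#' Acquisition parameters for the dual-excitation pCASL/BOLD sequence
#'
#' @param te1 First (ASL-weighted) echo time, ms.
#' @param te2 Second (BOLD-weighted) echo time, ms.
#' @param tr Effective repetition time (label + both readouts), s.
#' @param tau pCASL labelling duration, s.
#' @param pld Post-labelling delay, s.
#' @param alpha Labelling inversion efficiency.
#' @param alpha_inv Background-suppression efficiency factor.
#' @param lambda_bp Brain/blood partition coefficient.
#' @param theta Empirical exponent combining hypercapnic venous blood volume
#'   change and extravascular diffusion effects in the BOLD model.
#' @return An object of class `acq_params` (a named list).
#' @export
acq_params <- function(te1 = 10, te2 = 30, tr = 4.4, tau = 1.5, pld = 1.5,
                       alpha = 0.85, alpha_inv = 0.88, lambda_bp = 0.9,
                       theta = 0.06) {
  if (any(c(te1, te2, tr, tau, lambda_bp) <= 0) || pld < 0)
    stop("timings and partition coefficient must be positive (pld >= 0)")
  if (alpha <= 0 || alpha > 1 || alpha_inv <= 0 || alpha_inv > 1)
    stop("alpha and alpha_inv must lie in (0, 1]")
  if (theta < 0 || theta > 0.5) stop("theta must lie in [0, 0.5]")
  structure(list(te1 = te1, te2 = te2, tr = tr, tau = tau, pld = pld,
                 alpha = alpha, alpha_inv = alpha_inv,
                 lambda_bp = lambda_bp, theta = theta),
            class = "acq_params")
}

#' CBF timecourse driven by CO2 reactivity
#'
#' \deqn{CBF(t) = CBF_0\,(1 + CVR/100 \cdot \Delta P_aCO_2(t))}
#' with the CO2 excursion taken relative to the air-breathing baseline.
#' Hyperoxic vasoconstriction is not modelled; an arbitrary externally
#' computed CBF timecourse can be passed to the forward model instead.
#'
#' @param cbf0 Baseline CBF, ml/100g/min.
#' @param cvr Cerebrovascular reactivity, percent CBF change per mmHg CO2.
#' @param delta_paco2 CO2 excursion from baseline per volume, mmHg.
#' @param floor Lower clip for non-physical negative flows, ml/100g/min.
#' @return CBF per volume, ml/100g/min; clipped values are flagged via
#'   `attr(, "clipped")`.
#' @export
cbf_timecourse <- function(cbf0, cvr, delta_paco2, floor = 0.5) {
  if (cbf0 <= 0) stop("cbf0 must be strictly positive")
  cbf <- cbf0 * (1 + cvr / 100 * delta_paco2)
  clipped <- cbf < floor
  if (any(clipped)) {
    warning("CBF timecourse clipped at floor in ", sum(clipped), " volumes")
    cbf[clipped] <- floor
  }
  structure(cbf, clipped = any(clipped))
}

#' Deoxyhaemoglobin concentration ratio
#'
#' Evaluates the venous deoxyhaemoglobin dilution model
#' \deqn{\frac{[dHb]}{[dHb]_0} = \frac{CBF_0}{CBF} - \frac{1}{[dHb]_0}
#'   \left\{\frac{1}{\phi}\left(C_aO_2 - \frac{CBF_0}{CBF} C_aO_2|_0\right)
#'   + [Hb]\left(\frac{CBF_0}{CBF} - 1\right)\right\},}
#' which equals 1 at baseline, falls during hypercapnia (deoxyhaemoglobin
#' washout) and falls during hyperoxia (arterial content gain).
#' \eqn{[dHb]_0 = [Hb](1 - S_vO_2|_0)} with the baseline venous saturation
#' \eqn{S_vO_2|_0 = S_aO_2|_0 (1 - OEF_0)}.
#'
#' @param cbf CBF per volume, ml/100g/min.
#' @param cbf0 Baseline CBF, ml/100g/min.
#' @param cao2 Arterial oxygen content per volume, ml/ml.
#' @param cao2_0 Baseline arterial oxygen content, ml/ml.
#' @param hb Haemoglobin concentration, g/ml.
#' @param oef0 Baseline oxygen extraction fraction.
#' @param sao2_0 Baseline arterial saturation.
#' @param phi Oxygen binding capacity, ml/g.
#' @param floor Optional small positive clamp: when supplied, non-positive
#'   ratios are floored instead of raising an error (used inside the
#'   fitter, where trial parameters may transiently leave the physical
#'   region).
#' @return `[dHb]/[dHb]0` per volume; an error is raised if the model drives
#'   the ratio non-positive (inconsistent inputs) and no `floor` is given.
#' @export
dhb_ratio <- function(cbf, cbf0, cao2, cao2_0, hb, oef0, sao2_0 = 0.98,
                      phi = 1.34, floor = NULL) {
  if (any(cbf <= 0) || cbf0 <= 0) stop("flows must be strictly positive")
  dhb0 <- dhb_baseline(hb, oef0, sao2_0)
  f <- cbf0 / cbf
  ratio <- f - (1 / dhb0) * ((cao2 - f * cao2_0) / phi + hb * (f - 1))
  if (any(ratio <= 0)) {
    if (is.null(floor))
      stop("deoxyhaemoglobin ratio driven non-positive: inconsistent inputs")
    ratio <- pmax(ratio, floor)
  }
  ratio
}

#' Baseline deoxyhaemoglobin concentration
#'
#' \eqn{[dHb]_0 = [Hb](1 - S_aO_2|_0 (1 - OEF_0))}, g/ml.
#'
#' @inheritParams dhb_ratio
#' @return Baseline deoxyhaemoglobin concentration, g/ml.
#' @export
dhb_baseline <- function(hb, oef0, sao2_0 = 0.98) {
  if (hb <= 0) stop("hb must be positive")
  if (any(oef0 <= 0) || any(oef0 >= 1)) stop("oef0 must lie in (0, 1)")
  hb * (1 - sao2_0 * (1 - oef0))
}

#' Fractional BOLD signal change
#'
#' Simplified calibration model
#' \deqn{\frac{\Delta S}{S_0} = TE\,\kappa\,[dHb]_0
#'   \left\{1 - \left(\frac{CBF}{CBF_0}\right)^{\theta}
#'   \frac{[dHb]}{[dHb]_0}\right\},}
#' zero at baseline by construction. \eqn{\kappa} is a composite calibration
#' parameter absorbing venous-weighted blood volume and water diffusion
#' effects; with TE in ms and `[dHb]0` in g/ml its units are
#' 1/(ms g/ml).
#'
#' @param kappa Composite calibration parameter.
#' @param te Echo time, ms.
#' @param dhb0 Baseline deoxyhaemoglobin concentration, g/ml.
#' @param dhb_ratio Deoxyhaemoglobin ratio per volume.
#' @param cbf_ratio CBF/CBF0 per volume.
#' @param theta Flow-volume/diffusion exponent.
#' @return Fractional signal change per volume.
#' @export
bold_signal <- function(kappa, te, dhb0, dhb_ratio, cbf_ratio, theta = 0.06) {
  if (any(!is.finite(c(kappa, te, dhb0, theta)))) stop("inputs must be finite")
  te * kappa * dhb0 * (1 - cbf_ratio^theta * dhb_ratio)
}

#' pCASL tag/control difference signal
#'
#' Simplified single-compartment pCASL kinetic model
#' \deqn{\Delta S = \frac{2\,\alpha\,\alpha_{inv}\,CBF\,T_{1b}\,M_0\,
#'   (1 - e^{-\tau/T_{1b}})\,e^{-PLD/T_{1b}}}{6000\,\lambda},}
#' with CBF in ml/100g/min and the blood T1 allowed to vary per volume
#' (hyperoxia shortens T1 and attenuates the difference signal).
#'
#' @param cbf CBF per volume, ml/100g/min.
#' @param t1_blood Arterial blood T1 per volume, s.
#' @param m0 Equilibrium magnetisation (same arbitrary units as the data).
#' @param acq An [acq_params()] object.
#' @return Tag/control difference signal per volume (same units as `m0`).
#' @export
asl_difference_signal <- function(cbf, t1_blood, m0, acq = acq_params()) {
  if (any(cbf < 0)) stop("cbf must be non-negative")
  if (any(t1_blood <= 0)) stop("t1_blood must be strictly positive")
  2 * acq$alpha * acq$alpha_inv * cbf * t1_blood * m0 *
    (1 - exp(-acq$tau / t1_blood)) * exp(-acq$pld / t1_blood) /
    (6000 * acq$lambda_bp)
}

#' Forward model of the ASL and BOLD timeseries
#'
#' Composes the physiological building blocks into the predicted
#' dual-excitation signals for one voxel: the CO2-driven CBF timecourse, the
#' deoxyhaemoglobin ratio, the BOLD signal at the second echo, and the pCASL
#' difference signal at the first echo with the per-volume blood T1. The
#' baseline extraction fraction is tied to (CBF0, Dc) through the oxygen
#' lookup table.
#'
#' @param state Named list with elements `cbf0`, `dc`, `kappa`, `cvr`, `m0`.
#' @param arterial An `arterial_ts` object aligned to the MR volumes.
#' @param lut An `oxygen_lut` built with the subject's Hb and P50.
#' @param acq An [acq_params()] object.
#' @param cbf Optional externally supplied CBF timecourse overriding the
#'   CVR-driven model, ml/100g/min per volume.
#' @param dhb_floor Small positive clamp passed to [dhb_ratio()]; trial
#'   parameter values explored by the fitter can transiently predict a
#'   non-physical deoxyhaemoglobin ratio, which is floored rather than
#'   raising an error (physical parameter sets never reach the floor).
#' @return List with elements `asl` (difference signal per volume), `bold`
#'   (fractional BOLD change per volume), `oef0`, `cbf` and `dhb0`.
#' @export
forward_model <- function(state, arterial, lut, acq = acq_params(),
                          cbf = NULL, dhb_floor = 1e-6) {
  stopifnot(inherits(arterial, "arterial_ts"), inherits(lut, "oxygen_lut"))
  hb <- attr(arterial, "constants")$hb
  oef0 <- lut_oef(lut, state$cbf0, state$dc)
  if (is.null(cbf)) {
    dpaco2 <- arterial$paco2 - attr(arterial, "paco2_0")
    cbf <- cbf_timecourse(state$cbf0, state$cvr, dpaco2)
  }
  dhb0 <- dhb_baseline(hb, oef0, sao2_0 = attr(arterial, "sao2_0"))
  dr <- dhb_ratio(cbf = cbf, cbf0 = state$cbf0, cao2 = arterial$cao2,
                  cao2_0 = attr(arterial, "cao2_0"), hb = hb, oef0 = oef0,
                  sao2_0 = attr(arterial, "sao2_0"), floor = dhb_floor)
  bold <- bold_signal(state$kappa, acq$te2, dhb0, dr, cbf / state$cbf0,
                      acq$theta)
  asl <- asl_difference_signal(cbf, arterial$t1_blood, state$m0, acq)
  list(asl = as.numeric(asl), bold = as.numeric(bold), oef0 = oef0,
       cbf = as.numeric(cbf), dhb0 = dhb0)
}
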