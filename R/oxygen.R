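#' Plasma oxygen tension from bound oxygen content (Hill relation)
#'
#' Inverts the Hill dissociation curve for the plasma tension in equilibrium
#' with the haemoglobin-bound oxygen content,
#' \deqn{P = P_{50}\left(\frac{C_t}{\phi [Hb] - C_t}\right)^{1/h}.}
#' The bound content approaches the singularity at full saturation
#' \eqn{C_t \to \phi[Hb]}; the model keeps the capillary inlet at 0.95 of
#' that maximum precisely to stay away from it.
#'
#' @param ct Haemoglobin-bound oxygen content, ml O2/ml blood. Vectorised.
#' @param hb Haemoglobin concentration, g/ml.
#' @param p50 Half-saturation tension, mmHg.
#' @param h Hill coefficient.
#' @param phi Oxygen binding capacity, ml/g.
#' @return Plasma oxygen tension, mmHg.
#' @export
hill_pressure <- function(ct, hb, p50 = 27.1, h = 2.8, phi = 1.34) {
  cmax <- phi * hb
  if (any(ct < 0)) stop("ct must be non-negative")
  if (any(ct >= cmax))
    stop("ct >= phi*hb: bound content at or above full saturation (singular)")
  p50 * (ct / (cmax - ct))^(1 / h)
}

#' Bound oxygen content from plasma tension (Hill relation)
#'
#' Forward Hill curve: saturation \eqn{S = P^h/(P^h + P_{50}^h)} times the
#' binding capacity \eqn{\phi [Hb]}.
#'
#' @inheritParams hill_pressure
#' @param p Plasma oxygen tension, mmHg. Vectorised.
#' @return Bound oxygen content, ml O2/ml blood.
#' @export
hill_content <- function(p, hb, p50 = 27.1, h = 2.8, phi = 1.34) {
  if (any(p < 0)) stop("p must be non-negative")
  phi * hb * p^h / (p^h + p50^h)
}

#' Oxygen transport model parameters
#'
#' @param dc Effective oxygen diffusivity of the capillary network,
#'   ml O2/100g/mmHg/min (the product of effective permeability and
#'   capillary volume).
#' @param cbf Cerebral blood flow, ml/100g/min (same per-100g basis as
#'   `dc`, so `dc/cbf` has units 1/mmHg).
#' @param hb Haemoglobin concentration, g/ml.
#' @param p50 Half-saturation tension, mmHg.
#' @param h Hill coefficient.
#' @param phi Oxygen binding capacity, ml/g.
#' @param inlet_fraction Capillary inlet bound-oxygen content as a fraction
#'   of the maximum \eqn{\phi[Hb]} (arterial end assumed at 0.95 of
#'   maximum).
#' @param pm Mitochondrial oxygen tension, mmHg (0 under the minimal-tension
#'   assumption; expose for sensitivity analyses).
#' @return A named list of validated parameters, class `oxygen_params`.
#' @export
oxygen_params <- function(dc, cbf, hb = 0.143, p50 = 27.1, h = 2.8,
                          phi = 1.34, inlet_fraction = 0.95, pm = 0) {
  if (dc < 0 || cbf <= 0 || hb <= 0 || p50 <= 0 || h <= 0 || phi <= 0)
    stop("dc must be >= 0 and cbf, hb, p50, h, phi strictly positive")
  if (inlet_fraction <= 0 || inlet_fraction >= 1)
    stop("inlet_fraction must lie in (0, 1)")
  if (pm < 0) stop("pm must be non-negative")
  structure(list(dc = dc, cbf = cbf, hb = hb, p50 = p50, h = h, phi = phi,
                 inlet_fraction = inlet_fraction, pm = pm),
            class = "oxygen_params")
}

#' Solve the capillary oxygen content profile
#'
#' Integrates the steady-state oxygen loss equation along the fractional
#' capillary coordinate \eqn{x \in [0,1]},
#' \deqn{\frac{dC_t}{dx} = -\frac{D_C}{CBF}\,(P(C_t) - P_m),}
#' with the Hill relation supplying \eqn{P(C_t)} and inlet content
#' \eqn{C_t(0) = 0.95\,\phi[Hb]}. A stiff-capable adaptive solver
#' (`deSolve::ode`, lsoda) is used with relative tolerance `1e-8`.
#'
#' @param params An [oxygen_params()] object (or arguments to build one via
#'   `...`).
#' @param n_out Number of equally spaced output points along the capillary.
#' @param rtol,atol Solver tolerances.
#' @param ... Passed to [oxygen_params()] when `params` is missing.
#' @return A `capillary_profile`: data frame with columns `x`, `ct`
#'   (bound O2 content) and `p` (plasma tension), parameters in
#'   `attr(, "params")`. If extraction drives the content to the numerical
#'   floor before the venous end (complete-extraction regime), the profile
#'   is clamped and flagged via `attr(, "floored")`.
#' @examples
#' prof <- solve_capillary_profile(oxygen_params(dc = 0.092, cbf = 55.6))
#' oef_from_profile(prof)   # ~0.40 at grey-matter mean parameters
#' @export
solve_capillary_profile <- function(params, n_out = 101, rtol = 1e-8,
                                    atol = 1e-12, ...) {
  if (missing(params)) params <- oxygen_params(...)
  stopifnot(inherits(params, "oxygen_params"))
  cmax <- params$phi * params$hb
  c0 <- params$inlet_fraction * cmax
  floor_ct <- 1e-9 * cmax
  rhs <- function(x, y, p) {
    ct <- max(y[1], floor_ct)
    pres <- params$p50 * (ct / (cmax - ct))^(1 / params$h)
    list(-(params$dc / params$cbf) * (pres - params$pm))
  }
  xs <- seq(0, 1, length.out = n_out)
  if (params$dc == 0) {
    ct <- rep(c0, n_out)
  } else {
    sol <- deSolve::ode(y = c(ct = c0), times = xs, func = rhs, parms = NULL,
                        method = "lsoda", rtol = rtol, atol = atol)
    ct <- sol[, "ct"]
  }
  floored <- any(ct <= floor_ct)
  ct <- pmin(pmax(ct, floor_ct), c0)
  out <- data.frame(x = xs, ct = ct,
                    p = hill_pressure(pmin(ct, cmax * (1 - 1e-12)),
                                      hb = params$hb, p50 = params$p50,
                                      h = params$h, phi = params$phi))
  structure(out, class = c("capillary_profile", "data.frame"),
            params = params, floored = floored)
}

#' Oxygen extraction fraction of a capillary profile
#'
#' \deqn{OEF = \frac{C_t(0) - C_t(1)}{C_t(0)}}: the fraction of the oxygen
#' content at the arterial end of the capillary removed by transit.
#'
#' @param profile A `capillary_profile` from [solve_capillary_profile()].
#' @return OEF fraction in \[0, 1).
#' @export
oef_from_profile <- function(profile) {
  ct <- profile$ct
  (ct[1] - ct[length(ct)]) / ct[1]
}

#' Oxygen extraction fraction for given diffusivity and flow
#'
#' Convenience wrapper: solves the capillary profile and returns its OEF.
#'
#' @inheritParams oxygen_params
#' @param ... Passed to [oxygen_params()].
#' @return OEF fraction.
#' @export
capillary_oef <- function(dc, cbf, ...) {
  oef_from_profile(solve_capillary_profile(oxygen_params(dc = dc, cbf = cbf,
                                                         ...)))
}

#' Convert an oxygen volume quantity to micromoles
#'
#' Divides by the molar volume of O2 gas; with the default body-temperature
#' (310 K) molar volume of 25.45 ml/mmol, 1 ml O2 = 39.3 umol and the
#' grey-matter diffusivity 0.092 ml/100g/mmHg/min converts to
#' 3.6 umol/100g/mmHg/min.
#'
#' @param value Quantity on an ml O2 basis. Vectorised.
#' @param molar_volume Molar volume of O2, ml/mmol (22.414 for STPD).
#' @return Same quantity on a umol basis.
#' @export
ml_to_umol <- function(value, molar_volume = 25.45) {
  if (any(value < 0)) stop("value must be non-negative")
  value * 1000 / molar_volume
}

#' Cerebral metabolic rate of oxygen via the Fick principle
#'
#' \deqn{CMRO_2 = CBF \cdot C_aO_2 \cdot OEF}, converted from
#' ml O2/100g/min to umol/100g/min.
#'
#' @param cbf Cerebral blood flow, ml/100g/min.
#' @param cao2 Arterial oxygen content, ml O2/ml blood.
#' @param oef Oxygen extraction fraction in (0, 1).
#' @param molar_volume Molar volume of O2, ml/mmol.
#' @return CMRO2, umol/100g/min.
#' @examples
#' fick_cmro2(55.6, 0.189, 0.38)   # ~157 umol/100g/min
#' @export
fick_cmro2 <- function(cbf, cao2, oef, molar_volume = 25.45) {
  if (any(cbf < 0) || any(cao2 < 0)) stop("cbf and cao2 must be non-negative")
  if (any(oef < 0) || any(oef >= 1)) stop("oef must lie in [0, 1)")
  ml_to_umol(cbf * cao2 * oef, molar_volume = molar_volume)
}

#' Flow-volume coupling exponent
#'
#' Solves \eqn{CBV/CBV_0 = (CBF/CBF_0)^\eta} for \eqn{\eta}:
#' \deqn{\eta = \ln(CBV/CBV_0) / \ln(CBF/CBF_0).}
#'
#' @param flow_ratio CBF ratio (task/baseline), must differ from 1.
#' @param volume_ratio CBV ratio (task/baseline).
#' @return The coupling exponent eta.
#' @examples
#' flow_volume_exponent(1.21, 1.125)    # ~0.62
#' flow_volume_exponent(1.19, 1.067^2)  # ~0.75 (diameter^2 at fixed length)
#' @export
flow_volume_exponent <- function(flow_ratio, volume_ratio) {
  if (any(flow_ratio <= 0) || any(volume_ratio <= 0))
    stop("ratios must be strictly positive")
  if (any(flow_ratio == 1))
    stop("flow_ratio = 1: coupling exponent undefined")
  log(volume_ratio) / log(flow_ratio)
}
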