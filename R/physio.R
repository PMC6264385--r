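#' Blood gas and haematology constants
#'
#' Collects the physical constants used throughout the oxygen transport and
#' signal models, together with the subject-specific haemoglobin
#' concentration. Units follow the conventions of the calibrated-fMRI
#' literature: `[Hb]` is stored internally in g/ml (clinical g/dl values are
#' accepted by [hb_to_g_ml()]).
#'
#' @param hb Haemoglobin concentration in g/ml (typical adult grey matter
#'   studies: 0.12-0.17). Values that look like g/dl are rejected; convert
#'   first with [hb_to_g_ml()].
#' @param phi Oxygen binding capacity of haemoglobin, ml O2 per g Hb.
#' @param h Hill coefficient of the haemoglobin dissociation curve.
#' @param epsilon Plasma oxygen solubility, ml O2/mmHg/dl.
#' @param hco3 Bicarbonate concentration, mmol/L, used by the
#'   Henderson-Hasselbalch pH estimate.
#' @param molar_volume Molar volume of O2 gas, ml/mmol, used to convert
#'   oxygen volumes to micromoles. The default (25.45) is the ideal-gas
#'   molar volume at body temperature (310 K); the STPD value 22.414 can be
#'   substituted if volumes are reported at standard conditions.
#' @return An object of class `blood_constants` (a named list).
#' @examples
#' bc <- blood_constants(hb = 0.143)
#' bc$phi * bc$hb   # haemoglobin-bound O2 capacity, ml/ml
#' @export
blood_constants <- function(hb = 0.143, phi = 1.34, h = 2.8,
                            epsilon = 0.0031, hco3 = 24,
                            molar_volume = 25.45) {
  vals <- c(hb = hb, phi = phi, h = h, epsilon = epsilon, hco3 = hco3,
            molar_volume = molar_volume)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all blood constants must be finite and strictly positive")
  if (hb <= 0.05 || hb >= 0.25)
    stop("hb = ", hb, " g/ml is outside (0.05, 0.25); ",
         "if the value is in g/dl convert with hb_to_g_ml()")
  structure(list(hb = hb, phi = phi, h = h, epsilon = epsilon, hco3 = hco3,
                 molar_volume = molar_volume),
            class = "blood_constants")
}

#' Normalise a haemoglobin concentration to g/ml
#'
#' Accepts either g/ml (0.05-0.25) or the customary clinical g/dl (5-25)
#' and returns g/ml. Anything outside both windows is rejected as a probable
#' unit error.
#'
#' @param hb Haemoglobin concentration, g/ml or g/dl.
#' @return Haemoglobin concentration in g/ml.
#' @export
hb_to_g_ml <- function(hb) {
  if (!is.finite(hb) || hb <= 0) stop("hb must be finite and positive")
  if (hb > 0.05 && hb < 0.25) return(hb)
  if (hb > 5 && hb < 25) return(hb / 100)
  stop("hb = ", hb, " is not interpretable as g/ml (0.05-0.25) or g/dl (5-25)")
}

#' Severinghaus oxygen dissociation curve
#'
#' Converts arterial oxygen tension to haemoglobin saturation with the
#' closed-form Severinghaus relation
#' \deqn{S = \left(\frac{23400}{P^3 + 150 P} + 1\right)^{-1}.}
#'
#' @param pao2 Arterial O2 tension, mmHg. Vectorised; all values must be
#'   strictly positive.
#' @return Saturation fraction in (0, 1).
#' @examples
#' severinghaus_sao2(c(26.9, 100, 116))
#' @export
severinghaus_sao2 <- function(pao2) {
  if (any(!is.finite(pao2)) || any(pao2 <= 0))
    stop("pao2 must be finite and strictly positive")
  1 / (23400 / (pao2^3 + 150 * pao2) + 1)
}

#' Numeric inverse of the Severinghaus curve
#'
#' Root-finds the oxygen tension giving a target saturation; used for
#' round-trip checks and for back-computing tensions from saturation data.
#'
#' @param sao2 Saturation fraction in (0, 1). Vectorised.
#' @param interval Search interval for the tension, mmHg.
#' @return Oxygen tension, mmHg.
#' @export
severinghaus_pao2 <- function(sao2, interval = c(1e-3, 5000)) {
  if (any(!is.finite(sao2)) || any(sao2 <= 0) || any(sao2 >= 1))
    stop("sao2 must lie strictly inside (0, 1)")
  vapply(sao2, function(s)
    stats::uniroot(function(p) severinghaus_sao2(p) - s,
                   interval = interval, tol = 1e-12)$root,
    numeric(1))
}

#' Blood pH from arterial CO2 tension (Henderson-Hasselbalch)
#'
#' \deqn{pH = 6.1 + \log_{10}\{[HCO_3^-]/(0.03\,P_{CO_2})\}}
#'
#' @param paco2 Arterial CO2 tension, mmHg. Vectorised.
#' @param hco3 Bicarbonate concentration, mmol/L.
#' @return pH (dimensionless).
#' @examples
#' ph_from_paco2(41.6)   # ~7.384 at the default HCO3- of 24 mmol/L
#' @export
ph_from_paco2 <- function(paco2, hco3 = 24) {
  if (any(!is.finite(paco2)) || any(paco2 <= 0))
    stop("paco2 must be finite and strictly positive")
  if (!is.finite(hco3) || hco3 <= 0) stop("hco3 must be positive")
  6.1 + log10(hco3 / (0.03 * paco2))
}

#' Haemoglobin half-saturation tension from pH
#'
#' Linear acid-shift relation \eqn{P_{50} = 221.87 - 26.37 \times pH}.
#' Values of pH outside the physiological window (6.5, 8.0) trigger a
#' warning but are still evaluated.
#'
#' @param ph Blood pH.
#' @return P50, mmHg.
#' @export
p50_from_ph <- function(ph) {
  if (any(!is.finite(ph))) stop("ph must be finite")
  if (any(ph <= 6.5 | ph >= 8.0))
    warning("pH outside the physiological range (6.5, 8.0); ",
            "P50 extrapolated from the linear relation")
  221.87 - 26.37 * ph
}

#' Arterial oxygen content
#'
#' \deqn{C_aO_2 = \phi\,[Hb]\,S_aO_2 + \varepsilon\,P_aO_2}
#' with the plasma solubility \eqn{\varepsilon} quoted per dl and rescaled
#' internally so that the result is in ml O2 per ml blood.
#'
#' @param pao2 Arterial O2 tension, mmHg. Vectorised.
#' @param sao2 Arterial saturation fraction. Vectorised.
#' @param hb Haemoglobin concentration, g/ml.
#' @param constants A [blood_constants()] object supplying phi and epsilon.
#' @return Arterial oxygen content, ml O2/ml blood.
#' @export
cao2_from_state <- function(pao2, sao2, hb = constants$hb,
                            constants = blood_constants(hb = 0.143)) {
  if (any(!is.finite(pao2)) || any(pao2 < 0)) stop("pao2 must be >= 0")
  if (any(sao2 < 0) || any(sao2 > 1)) stop("sao2 must lie in [0, 1]")
  if (hb <= 0.05 || hb >= 0.25)
    stop("hb = ", hb, " g/ml out of range; g/dl input? see hb_to_g_ml()")
  constants$phi * hb * sao2 + (constants$epsilon / 100) * pao2
}

#' Longitudinal relaxation time of arterial blood
#'
#' Linear model of the blood relaxation rate in oxygen tension and
#' desaturation,
#' \deqn{R_{1,blood} = 1.527\times10^{-4} P_aO_2 + 0.1713\,(1 - S_aO_2) + 0.5848,}
#' returned as \eqn{T_1 = 1/R_1} in seconds. Hyperoxia shortens the
#' arterial-blood T1, which attenuates the ASL difference signal.
#'
#' @param pao2 Arterial O2 tension, mmHg. Vectorised.
#' @param sao2 Arterial saturation fraction. Vectorised.
#' @return T1 of arterial blood, seconds.
#' @export
t1_blood_from_oxygenation <- function(pao2, sao2) {
  if (any(!is.finite(pao2)) || any(pao2 < 0)) stop("pao2 must be >= 0")
  if (any(sao2 < 0) || any(sao2 > 1)) stop("sao2 must lie in [0, 1]")
  1 / (1.527e-4 * pao2 + 0.1713 * (1 - sao2) + 0.5848)
}

#' End-tidal gas trace
#'
#' Container for simultaneously recorded end-tidal CO2 and O2 partial
#' pressures. Arterial tensions are assumed equal to end-tidal tensions
#' downstream.
#'
#' @param time Sample times, seconds since trace start; strictly increasing.
#' @param petco2 End-tidal CO2, mmHg; plausible range (10, 120).
#' @param peto2 End-tidal O2, mmHg; plausible range (40, 700).
#' @return An object of class `end_tidal_trace` (a data frame).
#' @export
end_tidal_trace <- function(time, petco2, peto2) {
  n <- length(time)
  if (length(petco2) != n || length(peto2) != n)
    stop("time, petco2 and peto2 must have equal length")
  if (any(!is.finite(time)) || any(diff(time) <= 0))
    stop("time must be finite and strictly increasing")
  if (any(!is.finite(petco2)) || any(petco2 <= 10) || any(petco2 >= 120))
    stop("petco2 outside plausible end-tidal range (10, 120) mmHg")
  if (any(!is.finite(peto2)) || any(peto2 <= 40) || any(peto2 >= 700))
    stop("peto2 outside plausible end-tidal range (40, 700) mmHg")
  structure(data.frame(time = time, petco2 = petco2, peto2 = peto2),
            class = c("end_tidal_trace", "data.frame"))
}

# Linear resampling of a trace column to arbitrary times; end-tidal plateaus
# are slow relative to the TR so linear interpolation is sufficient.
resample_trace <- function(trace, times) {
  data.frame(
    time = times,
    petco2 = stats::approx(trace$time, trace$petco2, xout = times,
                           rule = 2)$y,
    peto2 = stats::approx(trace$time, trace$peto2, xout = times,
                          rule = 2)$y)
}

#' Per-volume arterial state from gas tensions
#'
#' Derives the full arterial timeseries used by the forward models:
#' saturation (Severinghaus), oxygen content, blood T1, and the baseline
#' scalars pH and P50 computed from the mean CO2 tension over designated
#' air-breathing volumes (a single resting P50 is used, matching common
#' practice).
#'
#' @param paco2,pao2 Arterial tensions per MR volume, mmHg.
#' @param constants A [blood_constants()] object.
#' @param baseline Integer indices of air-breathing (baseline) volumes. If
#'   `NULL`, detected with [baseline_volumes()].
#' @param time Optional volume times, seconds.
#' @param lag Optional trace alignment lag, seconds (stored for audit).
#' @return An object of class `arterial_ts`: a data frame with columns
#'   `time`, `paco2`, `pao2`, `sao2`, `cao2`, `t1_blood`, with baseline
#'   summaries in attributes (`p50`, `ph`, `paco2_0`, `pao2_0`, `sao2_0`,
#'   `cao2_0`, `t1_blood_0`, `baseline`, `constants`).
#' @export
arterial_state <- function(paco2, pao2, constants = blood_constants(),
                           baseline = NULL, time = NULL, lag = NA_real_) {
  n <- length(paco2)
  if (length(pao2) != n) stop("paco2 and pao2 must have equal length")
  if (is.null(time)) time <- seq_len(n)
  if (is.null(baseline)) baseline <- baseline_volumes(paco2, pao2)
  if (!length(baseline)) stop("no baseline (air-breathing) volumes identified")
  sao2 <- severinghaus_sao2(pao2)
  cao2 <- cao2_from_state(pao2, sao2, hb = constants$hb,
                          constants = constants)
  t1b <- t1_blood_from_oxygenation(pao2, sao2)
  paco2_0 <- mean(paco2[baseline])
  ph <- ph_from_paco2(paco2_0, hco3 = constants$hco3)
  p50 <- p50_from_ph(ph)
  if (p50 <= 20 || p50 >= 35)
    warning("baseline P50 = ", round(p50, 2), " mmHg outside (20, 35)")
  out <- data.frame(time = time, paco2 = paco2, pao2 = pao2, sao2 = sao2,
                    cao2 = cao2, t1_blood = t1b)
  structure(out,
            class = c("arterial_ts", "data.frame"),
            p50 = p50, ph = ph, lag = lag,
            paco2_0 = paco2_0, pao2_0 = mean(pao2[baseline]),
            sao2_0 = mean(sao2[baseline]), cao2_0 = mean(cao2[baseline]),
            t1_blood_0 = mean(t1b[baseline]),
            baseline = baseline, constants = constants)
}

#' Identify air-breathing (baseline) volumes
#'
#' Flags volumes whose CO2 and O2 tensions are close to the scan-start
#' level: within `co2_tol` (default 1 mmHg) and `o2_tol` (default 15 mmHg)
#' of the median over the first `n_ref` volumes. Explicit windows can be
#' supplied downstream to override this heuristic.
#'
#' @param paco2,pao2 Per-volume tensions, mmHg.
#' @param co2_tol,o2_tol Deviation tolerances, mmHg.
#' @param n_ref Number of leading volumes defining the reference level.
#' @return Integer vector of baseline volume indices.
#' @export
baseline_volumes <- function(paco2, pao2, co2_tol = 1, o2_tol = 15,
                             n_ref = 10) {
  n_ref <- min(n_ref, length(paco2))
  ref_co2 <- stats::median(paco2[seq_len(n_ref)])
  ref_o2 <- stats::median(pao2[seq_len(n_ref)])
  which(abs(paco2 - ref_co2) < co2_tol & abs(pao2 - ref_o2) < o2_tol)
}

#' Align an end-tidal trace to the MR timeseries
#'
#' Finds the delay between the gas analyser recording and the MR acquisition
#' by maximising the normalised cross-correlation between the CO2 trace and
#' the mean grey-matter ASL signal, shifts the trace (not the MR data) by
#' that lag, resamples it to volume times, and returns the per-volume
#' arterial state.
#'
#' @param trace An [end_tidal_trace()] object spanning the acquisition.
#' @param asl_gm_mean Mean grey-matter ASL signal, one value per volume.
#' @param tr Effective repetition time, seconds.
#' @param max_lag Maximum lag searched, seconds (either sign).
#' @param constants A [blood_constants()] object.
#' @param baseline Optional explicit baseline volume indices.
#' @return An `arterial_ts` object (see [arterial_state()]) with the applied
#'   lag in seconds stored in `attr(, "lag")`.
#' @export
align_traces <- function(trace, asl_gm_mean, tr, max_lag = 30,
                         constants = blood_constants(), baseline = NULL) {
  stopifnot(inherits(trace, "end_tidal_trace"))
  n <- length(asl_gm_mean)
  if (n < 8) stop("too few volumes for alignment")
  tv <- (seq_len(n) - 0.5) * tr
  dt <- stats::median(diff(trace$time))
  lags <- seq(-max_lag, max_lag, by = dt)
  asl_c <- asl_gm_mean - mean(asl_gm_mean)
  score <- vapply(lags, function(l) {
    co2 <- stats::approx(trace$time + l, trace$petco2, xout = tv, rule = 2)$y
    co2 <- co2 - mean(co2)
    denom <- sqrt(sum(co2^2) * sum(asl_c^2))
    if (denom == 0) return(NA_real_)
    sum(co2 * asl_c) / denom
  }, numeric(1))
  if (all(!is.finite(score))) stop("degenerate signals: cross-correlation undefined")
  best <- which.max(score)
  lag <- lags[best]
  if (best == 1L || best == length(lags))
    warning("best lag at the search boundary (", lag,
            " s); trace alignment may be unreliable")
  if (score[best] < 0.3)
    warning("weak trace/ASL correlation (r = ", round(score[best], 2),
            "); alignment lag unreliable")
  res <- resample_trace(
    end_tidal_trace(trace$time + lag, trace$petco2, trace$peto2), tv)
  arterial_state(paco2 = res$petco2, pao2 = res$peto2,
                 constants = constants, baseline = baseline, time = tv,
                 lag = lag)
}

#' @export
print.arterial_ts <- function(x, ...) {
  cat("Arterial timeseries:", nrow(x), "volumes\n")
  cat(sprintf("  baseline PaCO2 %.1f mmHg, PaO2 %.1f mmHg (%d air volumes)\n",
              attr(x, "paco2_0"), attr(x, "pao2_0"),
              length(attr(x, "baseline"))))
  cat(sprintf("  pH %.3f, P50 %.2f mmHg, CaO2,0 %.4f ml/ml, T1b,0 %.3f s\n",
              attr(x, "ph"), attr(x, "p50"), attr(x, "cao2_0"),
              attr(x, "t1_blood_0")))
  if (is.finite(attr(x, "lag")))
    cat(sprintf("  trace alignment lag %.1f s\n", attr(x, "lag")))
  invisible(x)
}
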