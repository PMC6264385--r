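#' Dual-excitation series container
#'
#' Raw interleaved tag/control data for both echoes, as time-by-voxel
#' matrices (one row per repetition), together with the calibration volume
#' and analysis mask.
#'
#' @param te1 Matrix (volumes x voxels) of first-echo (ASL-weighted) data,
#'   tag/control interleaved along rows.
#' @param te2 Matrix (volumes x voxels) of second-echo (BOLD-weighted) data.
#' @param m0 Equilibrium-magnetisation calibration values, one per voxel.
#' @param mask Logical vector, voxels to analyse.
#' @param dim Spatial dimensions of the voxel grid (for writing maps).
#' @param tr Effective repetition time, s.
#' @param tag_first Logical; `TRUE` when the first volume is a tag.
#' @return An object of class `dexi_series`.
#' @export
dexi_series <- function(te1, te2, m0, mask = rep(TRUE, ncol(te1)),
                        dim = c(ncol(te1), 1, 1), tr = 4.4,
                        tag_first = TRUE) {
  te1 <- as.matrix(te1); te2 <- as.matrix(te2)
  if (!all(dim(te1) == dim(te2))) stop("te1 and te2 shapes must match")
  if (nrow(te1) %% 2 != 0) stop("interleaved series needs an even volume count")
  if (length(m0) != ncol(te1) || length(mask) != ncol(te1))
    stop("m0 and mask must have one entry per voxel")
  if (prod(dim) != ncol(te1)) stop("dim inconsistent with voxel count")
  if (any(m0[mask] <= 0)) stop("mask must lie within positive m0 support")
  structure(list(te1 = te1, te2 = te2, m0 = as.numeric(m0),
                 mask = as.logical(mask), dim = dim, tr = tr,
                 tag_first = tag_first),
            class = "dexi_series")
}

# Alternating sign vector: +1 at control volumes, -1 at tags, so that the
# surround-subtracted output is (control - tag), positive for perfused tissue.
interleave_sign <- function(n, tag_first = TRUE) {
  s <- rep_len(c(-1, 1), n)
  if (!tag_first) -s else s
}

#' Surround subtraction: isolate the ASL component
#'
#' Sliding tag/control differencing: each volume is differenced against the
#' mean of its two temporal neighbours (opposite condition), which cancels
#' the slowly varying BOLD contamination to first order and yields one
#' perfusion-weighted difference estimate per volume. Series ends use the
#' single available neighbour (half-weight edge handling).
#'
#' @param x Numeric vector or (volumes x voxels) matrix, tag/control
#'   interleaved.
#' @param tag_first Logical; `TRUE` when row 1 is a tag volume.
#' @return Same shape as `x`: per-volume tag/control difference
#'   (control - tag).
#' @export
surround_subtract <- function(x, tag_first = TRUE) {
  vec <- is.null(dim(x))
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < 3) stop("surround subtraction needs at least 3 volumes")
  s <- interleave_sign(n, tag_first)
  out <- x
  mid <- 2:(n - 1)
  out[mid, ] <- s[mid] * (x[mid, , drop = FALSE] -
                          (x[mid - 1, , drop = FALSE] +
                           x[mid + 1, , drop = FALSE]) / 2)
  out[1, ] <- s[1] * (x[1, ] - x[2, ])
  out[n, ] <- s[n] * (x[n, ] - x[n - 1, ])
  if (vec) drop(out) else out
}

#' Surround averaging: isolate the BOLD component
#'
#' Each volume is averaged with the mean of its two temporal neighbours,
#' removing the alternating tag/control (ASL) component while preserving
#' slow signal changes. Series ends use the single available neighbour.
#'
#' @inheritParams surround_subtract
#' @return Same shape as `x`, ASL component removed.
#' @export
surround_average <- function(x, tag_first = TRUE) {
  vec <- is.null(dim(x))
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < 3) stop("surround averaging needs at least 3 volumes")
  out <- x
  mid <- 2:(n - 1)
  out[mid, ] <- (x[mid, , drop = FALSE] +
                 (x[mid - 1, , drop = FALSE] +
                  x[mid + 1, , drop = FALSE]) / 2) / 2
  out[1, ] <- (x[1, ] + x[2, ]) / 2
  out[n, ] <- (x[n, ] + x[n - 1, ]) / 2
  if (vec) drop(out) else out
}

#' Separate a dual-excitation series into ASL and BOLD timeseries
#'
#' Applies surround subtraction to the first echo and surround averaging to
#' the second, normalises the BOLD series to fractional change about its
#' baseline-period mean, and checks the tag/control polarity (a negative
#' mean difference signal inside the mask indicates a wrong `tag_first`
#' flag and triggers a warning).
#'
#' @param series A [dexi_series()].
#' @param baseline Integer indices of baseline (air-breathing) volumes used
#'   to normalise the BOLD series; defaults to the first 20 volumes.
#' @return A list of class `qdcm_data`: `asl` (volumes x voxels difference
#'   signal), `bold` (volumes x voxels fractional change), `bold_raw`,
#'   `m0`, `mask`, `dim`, `tr`, `times`, `baseline`.
#' @export
preprocess_dexi <- function(series, baseline = NULL) {
  stopifnot(inherits(series, "dexi_series"))
  n <- nrow(series$te1)
  if (is.null(baseline)) baseline <- seq_len(min(20, n))
  asl <- surround_subtract(series$te1, series$tag_first)
  if (mean(asl[, series$mask]) < 0)
    warning("negative mean difference signal in mask: ",
            "tag/control ordering flag may be wrong")
  bold_raw <- surround_average(series$te2, series$tag_first)
  base_mean <- colMeans(bold_raw[baseline, , drop = FALSE])
  bold <- sweep(bold_raw, 2, base_mean, "/") - 1
  bold[, base_mean <= 0] <- NA_real_
  structure(list(asl = asl, bold = bold, bold_raw = bold_raw,
                 m0 = series$m0, mask = series$mask, dim = series$dim,
                 tr = series$tr, times = (seq_len(n) - 0.5) * series$tr,
                 baseline = baseline),
            class = "qdcm_data")
}

#' Initial perfusion, grey-matter partial volume and diffusivity prior
#'
#' Inverts the pCASL kinetic model at the baseline blood T1 to obtain an
#' initial perfusion estimate, normalises it by the median of its 100
#' brightest voxels to a pseudo grey-matter partial-volume map (clipped to
#' \[0, 1\]), and scales that map by 0.15 ml/100g/mmHg/min to form the
#' spatially varying diffusivity prior used in regularisation (diffusivity
#' is assumed to scale with capillary density and hence grey-matter partial
#' volume). With fewer than 100 masked voxels the top 10% are used instead.
#'
#' @param asl_baseline_mean Mean baseline difference signal per voxel.
#' @param m0 Calibration values per voxel.
#' @param t1_blood_0 Baseline arterial blood T1, s.
#' @param acq An [acq_params()] object.
#' @param mask Logical vector of analysable voxels.
#' @param dc_scale Diffusivity assigned to a pure grey-matter voxel,
#'   ml/100g/mmHg/min.
#' @return List with `cbf_init`, `gm_pv` and `dc_prior` vectors (NA outside
#'   the mask) and the normalising median in `attr(, "norm")`.
#' @export
initial_perfusion_and_gm_pv <- function(asl_baseline_mean, m0, t1_blood_0,
                                        acq = acq_params(),
                                        mask = rep(TRUE,
                                                   length(asl_baseline_mean)),
                                        dc_scale = 0.15) {
  v <- length(asl_baseline_mean)
  if (length(m0) != v || length(mask) != v)
    stop("asl_baseline_mean, m0 and mask must have equal length")
  scale <- 2 * acq$alpha * acq$alpha_inv * t1_blood_0 *
    (1 - exp(-acq$tau / t1_blood_0)) * exp(-acq$pld / t1_blood_0) /
    (6000 * acq$lambda_bp)
  cbf_init <- rep(NA_real_, v)
  cbf_init[mask] <- pmax(asl_baseline_mean[mask] / (scale * m0[mask]), 0)
  nm <- sum(mask)
  k <- if (nm >= 100) 100 else {
    warning("fewer than 100 masked voxels; normalising by the top 10%")
    max(1L, ceiling(nm * 0.1))
  }
  top <- sort(cbf_init[mask], decreasing = TRUE)[seq_len(k)]
  norm <- stats::median(top)
  if (!is.finite(norm) || norm <= 0)
    stop("degenerate perfusion estimate: cannot normalise")
  gm_pv <- pmin(pmax(cbf_init / norm, 0), 1)
  structure(list(cbf_init = cbf_init, gm_pv = gm_pv,
                 dc_prior = dc_scale * gm_pv),
            norm = norm)
}

#' Gaussian smoothing of a 3D map (phantom helper)
#'
#' Separable Gaussian kernel smoothing in voxel units, provided for phantom
#' experiments; in-vivo smoothing, motion correction and registration are
#' upstream responsibilities.
#'
#' @param vol 3D numeric array.
#' @param fwhm Full width at half maximum, voxels.
#' @return Smoothed array of the same shape.
#' @export
smooth_gaussian <- function(vol, fwhm = 1.5) {
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  half <- max(1L, ceiling(3 * sigma))
  k <- exp(-(seq(-half, half))^2 / (2 * sigma^2))
  k <- k / sum(k)
  smooth_axis <- function(a, axis) {
    ap <- aperm(a, c(axis, setdiff(1:3, axis)))
    d <- dim(ap)
    m <- matrix(ap, nrow = d[1])
    n <- d[1]
    out <- matrix(0, n, ncol(m))
    for (j in seq_along(k)) {
      idx <- pmin(pmax(seq_len(n) + (j - half - 1L), 1L), n)
      out <- out + k[j] * m[idx, , drop = FALSE]
    }
    aperm(array(out, d), order(c(axis, setdiff(1:3, axis))))
  }
  for (ax in 1:3) if (dim(vol)[ax] > 1) vol <- smooth_axis(vol, ax)
  vol
}
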