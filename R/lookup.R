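# Polynomial rolling hash (mod 2^31-1), used to fingerprint lookup-table
# build settings so a table can be matched to the configuration that
# produced it.
fnv1a <- function(s) {
  bytes <- utf8ToInt(s)
  h <- 0
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Build the CBF/diffusivity to OEF lookup table
#'
#' Solves the capillary oxygen-exchange equation over a grid of cerebral
#' blood flow and effective diffusivity values at fixed haemoglobin
#' concentration and P50, storing the oxygen extraction fraction at every
#' node. At fixed blood constants the extraction depends on flow and
#' diffusivity only through the ratio \eqn{D_C/CBF}, so the whole grid is
#' obtained from a single master integration in the rescaled coordinate
#' \eqn{s = (D_C/CBF)\,x} evaluated at every grid ratio; the direct
#' per-parameter solver [solve_capillary_profile()] remains an independent
#' route for verification.
#'
#' @param cbf_grid Strictly increasing CBF axis, ml/100g/min. Default: 96
#'   log-spaced points spanning 5-150, covering grey and white matter with
#'   margin for pathology.
#' @param dc_grid Strictly increasing diffusivity axis, ml/100g/mmHg/min.
#'   Default: 96 log-spaced points spanning 0.005-0.35.
#' @param hb Haemoglobin concentration, g/ml.
#' @param p50 Half-saturation tension, mmHg.
#' @param h,phi,inlet_fraction,pm As in [oxygen_params()].
#' @param rtol Solver relative tolerance.
#' @return An object of class `oxygen_lut`: list with `cbf_grid`, `dc_grid`,
#'   `oef` (matrix, rows = dc, cols = cbf), the build settings and a
#'   settings hash. OEF increases along the diffusivity axis and decreases
#'   along the flow axis; a violation aborts the build.
#' @export
build_lookup <- function(cbf_grid = lut_default_grid("cbf"),
                         dc_grid = lut_default_grid("dc"),
                         hb = 0.143, p50 = 27.1, h = 2.8, phi = 1.34,
                         inlet_fraction = 0.95, pm = 0, rtol = 1e-8) {
  if (any(diff(cbf_grid) <= 0) || any(diff(dc_grid) <= 0))
    stop("cbf_grid and dc_grid must be strictly increasing")
  if (any(cbf_grid <= 0) || any(dc_grid < 0)) stop("grids must be positive")
  cmax <- phi * hb
  c0 <- inlet_fraction * cmax
  floor_ct <- 1e-9 * cmax
  # master trajectory: dC/ds = -(P(C) - pm), OEF(dc, cbf) = 1 - C(dc/cbf)/C0
  r <- outer(dc_grid, 1 / cbf_grid)          # ratio at every node
  s_nodes <- sort(unique(as.vector(r)))
  rhs <- function(s, y, p) {
    ct <- max(y[1], floor_ct)
    pres <- p50 * (ct / (cmax - ct))^(1 / h)
    list(-(pres - pm))
  }
  sol <- deSolve::ode(y = c(ct = c0), times = c(0, s_nodes), func = rhs,
                      parms = NULL, method = "lsoda", rtol = rtol,
                      atol = 1e-12 * cmax)
  ct_end <- pmin(pmax(sol[-1, "ct"], floor_ct), c0)
  oef_by_s <- 1 - ct_end / c0
  oef <- matrix(oef_by_s[match(as.vector(r), s_nodes)],
                nrow = length(dc_grid), ncol = length(cbf_grid),
                dimnames = list(NULL, NULL))
  # strict monotonicity is required away from the complete-extraction
  # plateau, where OEF saturates at 1 to solver precision and ties appear
  sat <- 1 - 1e-6
  bad_dc <- apply(oef, 2, function(col)
    any(diff(col) <= 0 & col[-length(col)] < sat))
  bad_cbf <- apply(oef, 1, function(row)
    any(diff(row) >= 0 & row[-1] < sat))
  if (any(bad_dc))
    stop("lookup build failed: OEF not increasing in diffusivity")
  if (any(bad_cbf))
    stop("lookup build failed: OEF not decreasing in flow")
  settings <- list(cbf_grid = range(cbf_grid), n_cbf = length(cbf_grid),
                   dc_grid = range(dc_grid), n_dc = length(dc_grid),
                   hb = hb, p50 = p50, h = h, phi = phi,
                   inlet_fraction = inlet_fraction, pm = pm, rtol = rtol)
  structure(list(cbf_grid = cbf_grid, dc_grid = dc_grid, oef = oef,
                 hb = hb, p50 = p50, h = h, phi = phi,
                 inlet_fraction = inlet_fraction, pm = pm,
                 settings = settings,
                 hash = fnv1a(paste(deparse(settings), collapse = ""))),
            class = "oxygen_lut")
}

#' Default lookup-table axes
#'
#' @param which `"cbf"` or `"dc"`.
#' @param n Number of grid points.
#' @return Log-spaced axis covering 5-150 ml/100g/min (CBF) or 0.005-0.35
#'   ml/100g/mmHg/min (diffusivity).
#' @export
lut_default_grid <- function(which = c("cbf", "dc"), n = 96) {
  which <- match.arg(which)
  rng <- if (which == "cbf") c(5, 150) else c(0.005, 0.35)
  exp(seq(log(rng[1]), log(rng[2]), length.out = n))
}

#' Interpolate OEF from a lookup table
#'
#' Bilinear interpolation of the stored OEF surface at arbitrary
#' (CBF, diffusivity) points. Queries are clamped to the table axes.
#'
#' @param lut An `oxygen_lut` from [build_lookup()].
#' @param cbf CBF query, ml/100g/min. Vectorised (recycled against `dc`).
#' @param dc Diffusivity query, ml/100g/mmHg/min.
#' @return OEF fraction(s).
#' @export
lut_oef <- function(lut, cbf, dc) {
  stopifnot(inherits(lut, "oxygen_lut"))
  k <- max(length(cbf), length(dc))
  cbf <- rep_len(pmin(pmax(cbf, lut$cbf_grid[1]), max(lut$cbf_grid)), k)
  dc <- rep_len(pmin(pmax(dc, lut$dc_grid[1]), max(lut$dc_grid)), k)
  pracma::interp2(x = lut$cbf_grid, y = lut$dc_grid, Z = lut$oef,
                  xp = cbf, yp = dc, method = "linear")
}

#' Refine a lookup table by interpolation
#'
#' Resamples the OEF surface onto denser axes (bilinear), mirroring the
#' high-resolution 2D table used during fitting so that repeated queries
#' fall on a fine grid.
#'
#' @param lut An `oxygen_lut`.
#' @param n_cbf,n_dc Target axis lengths.
#' @return A new `oxygen_lut` with refined axes (settings inherit the
#'   parent hash).
#' @export
resample_lut <- function(lut, n_cbf = 512, n_dc = 512) {
  cbf_grid <- exp(seq(log(lut$cbf_grid[1]), log(max(lut$cbf_grid)),
                      length.out = n_cbf))
  dc_grid <- exp(seq(log(lut$dc_grid[1]), log(max(lut$dc_grid)),
                     length.out = n_dc))
  grid <- expand.grid(dc = dc_grid, cbf = cbf_grid)
  oef <- matrix(lut_oef(lut, grid$cbf, grid$dc), nrow = n_dc, ncol = n_cbf)
  out <- lut
  out$cbf_grid <- cbf_grid
  out$dc_grid <- dc_grid
  out$oef <- oef
  out$settings$resampled_from <- lut$hash
  out
}

#' Invert the lookup table for effective diffusivity
#'
#' Given an extraction fraction and flow, root-finds the diffusivity whose
#' table OEF matches, exploiting monotonicity of OEF in diffusivity at fixed
#' flow. Requests outside the achievable range return the nearest axis
#' endpoint flagged via `attr(, "at_bound")` (`oef <= 0` returns 0 exactly:
#' no exchange).
#'
#' @param oef Target OEF fraction. Vectorised (recycled against `cbf`).
#' @param cbf CBF, ml/100g/min.
#' @param lut An `oxygen_lut`.
#' @param tol Root tolerance on the diffusivity axis (relative).
#' @return Diffusivity value(s), ml/100g/mmHg/min; attribute `at_bound` is a
#'   logical vector marking out-of-range requests.
#' @export
invert_lookup_for_dc <- function(oef, cbf, lut, tol = 1e-10) {
  stopifnot(inherits(lut, "oxygen_lut"))
  k <- max(length(oef), length(cbf))
  oef <- rep_len(oef, k)
  cbf <- rep_len(cbf, k)
  dc_lo <- lut$dc_grid[1]
  dc_hi <- max(lut$dc_grid)
  at_bound <- logical(k)
  dc <- numeric(k)
  for (i in seq_len(k)) {
    if (oef[i] <= 0) {
      dc[i] <- 0
      next
    }
    lo <- lut_oef(lut, cbf[i], dc_lo)
    hi <- lut_oef(lut, cbf[i], dc_hi)
    if (oef[i] <= lo) {
      dc[i] <- dc_lo
      at_bound[i] <- TRUE
    } else if (oef[i] >= hi) {
      dc[i] <- dc_hi
      at_bound[i] <- TRUE
    } else {
      dc[i] <- stats::uniroot(function(d) lut_oef(lut, cbf[i], d) - oef[i],
                              interval = c(dc_lo, dc_hi),
                              tol = tol * dc_hi)$root
    }
  }
  structure(dc, at_bound = at_bound)
}

#' Write / read a lookup table container
#'
#' Serialises the table with its axes, settings and hash so a fit can record
#' exactly which table it used. The container is a binary artefact produced
#' at run time.
#'
#' @param lut An `oxygen_lut`.
#' @param path Destination / source file path.
#' @return `write_lut` returns `path` invisibly; `read_lut` returns the
#'   `oxygen_lut`.
#' @export
write_lut <- function(lut, path) {
  stopifnot(inherits(lut, "oxygen_lut"))
  saveRDS(lut, path)
  invisible(path)
}

#' @rdname write_lut
#' @export
read_lut <- function(path) {
  lut <- readRDS(path)
  if (!inherits(lut, "oxygen_lut")) stop("not an oxygen_lut container")
  lut
}

#' @export
print.oxygen_lut <- function(x, ...) {
  cat("Oxygen extraction lookup table\n")
  cat(sprintf("  CBF axis: %d points, %.1f-%.1f ml/100g/min\n",
              length(x$cbf_grid), x$cbf_grid[1], max(x$cbf_grid)))
  cat(sprintf("  Dc axis:  %d points, %.3f-%.3f ml/100g/mmHg/min\n",
              length(x$dc_grid), x$dc_grid[1], max(x$dc_grid)))
  cat(sprintf("  [Hb] %.3f g/ml, P50 %.1f mmHg, Pm %.1f mmHg, hash %s\n",
              x$hb, x$p50, x$pm, x$hash))
  invisible(x)
}
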