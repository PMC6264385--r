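#' Read end-tidal trace files
#'
#' Accepts either a single three-column delimited file (`time_s`, `petco2`,
#' `peto2`) or two two-column files (`time_s`, value) — one per gas. Column
#' order is positional; a header line is detected and skipped
#' automatically.
#'
#' @param path Path to the combined trace file, or the CO2 trace when
#'   `o2_path` is given.
#' @param o2_path Optional path to a separate O2 trace; it is linearly
#'   resampled onto the CO2 trace's time base if the sampling differs.
#' @param sep Field separator (default: any whitespace).
#' @return An [end_tidal_trace()].
#' @export
read_endtidal <- function(path, o2_path = NULL, sep = "") {
  rd <- function(p, ncol_min) {
    x <- utils::read.table(p, sep = sep, header = FALSE,
                           comment.char = "#",
                           colClasses = NA, stringsAsFactors = FALSE,
                           skip = 0)
    if (!is.numeric(x[[1]])) x <- x[-1, , drop = FALSE]
    x[] <- lapply(x, function(col) as.numeric(as.character(col)))
    if (ncol(x) < ncol_min) stop("too few columns in ", p)
    x
  }
  if (is.null(o2_path)) {
    x <- rd(path, 3)
    end_tidal_trace(x[[1]], x[[2]], x[[3]])
  } else {
    co2 <- rd(path, 2)
    o2 <- rd(o2_path, 2)
    peto2 <- stats::approx(o2[[1]], o2[[2]], xout = co2[[1]], rule = 2)$y
    end_tidal_trace(co2[[1]], co2[[2]], peto2)
  }
}

#' Read a dataset manifest
#'
#' A YAML manifest names the input files and subject parameters for a fit:
#' keys `te1`, `te2`, `m0`, `mask` (NIfTI paths), `trace` (end-tidal file;
#' optionally `trace_o2` for a two-file dialect), `hb` (g/dl or g/ml —
#' normalised to g/ml), and optional acquisition overrides under `acq`
#' (any argument of [acq_params()]).
#'
#' @param path Path to the YAML manifest.
#' @return A validated list of class `qdcm_manifest` with `hb` in g/ml and
#'   `acq` instantiated.
#' @export
read_manifest <- function(path) {
  m <- yaml::read_yaml(path)
  needed <- c("te1", "te2", "m0", "trace", "hb")
  missing_keys <- setdiff(needed, names(m))
  if (length(missing_keys))
    stop("manifest missing required key(s): ",
         paste(missing_keys, collapse = ", "))
  base <- dirname(normalizePath(path))
  resolve <- function(p) {
    if (!file.exists(p)) p <- file.path(base, p)
    p
  }
  for (key in intersect(c("te1", "te2", "m0", "mask", "trace", "trace_o2"),
                        names(m))) {
    m[[key]] <- resolve(m[[key]])
    if (!file.exists(m[[key]]))
      stop("manifest file for key '", key, "' not found: ", m[[key]])
  }
  m$hb <- hb_to_g_ml(m$hb)
  m$acq <- do.call(acq_params, if (is.null(m$acq)) list() else m$acq)
  structure(m, class = "qdcm_manifest")
}

#' Read dual-excitation NIfTI volumes into a series
#'
#' Loads the 4D first- and second-echo images, the calibration volume and
#' mask named by a manifest, flattening each 3D volume to a voxel vector
#' (row per repetition).
#'
#' @param manifest A [read_manifest()] result.
#' @return A [dexi_series()]; the first input's NIfTI header is kept in
#'   `attr(, "reference")` so output maps preserve the affine.
#' @export
read_dexi <- function(manifest) {
  stopifnot(inherits(manifest, "qdcm_manifest"))
  te1_img <- RNifti::readNifti(manifest$te1)
  te2_img <- RNifti::readNifti(manifest$te2)
  m0_img <- RNifti::readNifti(manifest$m0)
  d <- dim(te1_img)
  if (length(d) != 4) stop("te1 image must be 4D")
  flat <- function(img) t(matrix(img, prod(dim(img)[1:3]), dim(img)[4]))
  mask <- if (!is.null(manifest$mask))
    as.vector(RNifti::readNifti(manifest$mask)) > 0
  else as.vector(m0_img) > 0
  series <- dexi_series(te1 = flat(te1_img), te2 = flat(te2_img),
                        m0 = as.vector(m0_img), mask = mask,
                        dim = d[1:3],
                        tr = manifest$acq$tr,
                        tag_first = !identical(manifest$tag_first, FALSE))
  attr(series, "reference") <- te1_img
  series
}

#' Write fitted parameter maps and provenance
#'
#' Writes one NIfTI map per fitted parameter (cbf0, oef0, dc, kappa, cvr,
#' cmro2_0) plus a QC map (1 = converged, 2 = at bound, 3 = skipped,
#' 0 = outside mask), copying the affine from a reference image when one is
#' available, and a JSON provenance record (configuration, lookup-table
#' hash, package version). Re-writing is idempotent.
#'
#' @param fit A [qdcm_fit()] result.
#' @param out_dir Output directory (created if needed).
#' @param reference Optional NIfTI image supplying header/affine (e.g.
#'   `attr(series, "reference")` from [read_dexi()]).
#' @param seed Optional RNG seed to record.
#' @return Invisibly, the vector of files written.
#' @export
write_maps <- function(fit, out_dir, reference = NULL, seed = NULL) {
  stopifnot(inherits(fit, "qdcm_fit"))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  files <- character(0)
  as_vol <- function(v) array(v, dim = fit$dim)
  write1 <- function(name, v) {
    path <- file.path(out_dir, paste0(name, ".nii.gz"))
    vol <- as_vol(v)
    img <- if (!is.null(reference))
      RNifti::asNifti(vol, reference = reference) else RNifti::asNifti(vol)
    RNifti::writeNifti(img, path)
    path
  }
  for (nm in names(fit$maps)) files <- c(files, write1(nm, fit$maps[[nm]]))
  qc <- integer(length(fit$mask))
  qc[fit$voxels] <- ifelse(fit$qc$skipped[fit$voxels], 3L,
                           ifelse(fit$qc$at_bound[fit$voxels], 2L, 1L))
  files <- c(files, write1("qc", qc))
  prov <- list(
    package = "qdcm",
    version = as.character(utils::packageVersion("qdcm")),
    lut_hash = fit$lut_hash,
    reg = unclass(fit$reg),
    acq = unclass(fit$acq),
    p50 = attr(fit$arterial, "p50"),
    hb = attr(fit$arterial, "constants")$hb,
    lag_s = attr(fit$arterial, "lag"),
    n_voxels = length(fit$voxels),
    seed = seed,
    config_hash = fnv1a(paste(deparse(list(unclass(fit$reg),
                                           unclass(fit$acq))),
                              collapse = "")))
  prov_path <- file.path(out_dir, "provenance.json")
  jsonlite::write_json(prov, prov_path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(c(files, prov_path))
}

#' Write the per-volume arterial state for audit
#'
#' @param arterial An `arterial_ts`.
#' @param path Output delimited file (TSV).
#' @return Invisibly, `path`.
#' @export
write_arterial <- function(arterial, path) {
  df <- as.data.frame(arterial)
  utils::write.table(df, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
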