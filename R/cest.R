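#' Estimate the B0 offset from a low-power z-spectrum
#'
#' WASSR-style estimator: the water direct-saturation minimum of the
#' low-power spectrum is located by natural cubic-spline interpolation on a
#' 0.001 ppm grid over the sweep.  The shift is clamped to the sweep
#' half-width; a minimum found at (or within 0.05 ppm of) the sweep edge is
#' flagged with low fit quality, since the true minimum may lie outside the
#' sweep.
#'
#' @param low_power_spectrum a [zspectrum()] with at least 5 offsets
#'   spanning 0 ppm.
#' @param grid_step_ppm search grid resolution.
#' @return A list: `shift_ppm`, `fit_quality` (`"ok"` or `"near_edge"`).
#' @export
estimate_b0_offset <- function(low_power_spectrum, grid_step_ppm = 0.001) {
  z <- low_power_spectrum
  stopifnot(inherits(z, "zspectrum"))
  if (length(z$offsets_ppm) < 5L) stop("need at least 5 low-power offsets")
  if (min(z$offsets_ppm) > 0 || max(z$offsets_ppm) < 0) {
    stop("low-power offsets must span 0 ppm")
  }
  # fmm end conditions track a dip sitting between the outermost samples,
  # where a natural spline (zero end curvature) pins the minimum to the edge
  sf <- splinefun(z$offsets_ppm, z$s_sat, method = "fmm")
  grid <- seq(min(z$offsets_ppm), max(z$offsets_ppm), by = grid_step_ppm)
  vals <- sf(grid)
  shift <- grid[which.min(vals)] # ties: leftmost; resolve plateau by midpoint
  plateau <- grid[abs(vals - min(vals)) <= .Machine$double.eps * max(abs(vals))]
  if (length(plateau) > 1L) shift <- plateau[ceiling(length(plateau) / 2)]
  half_width <- min(abs(min(z$offsets_ppm)), abs(max(z$offsets_ppm)))
  shift <- min(max(shift, -half_width), half_width)
  quality <- if (abs(shift) >= half_width - 0.05) "near_edge" else "ok"
  list(shift_ppm = shift, fit_quality = quality)
}

#' Recentre a z-spectrum for a B0 offset
#'
#' Resamples the saturated signal on the shifted frequency axis with a
#' natural cubic spline, so that the water centre moves back to 0 ppm.  The
#' offset grid is unchanged; queries beyond the measured range are held flat
#' at the nearest endpoint.
#'
#' @param spectrum a [zspectrum()].
#' @param shift_ppm estimated B0 shift (ppm), e.g. from
#'   [estimate_b0_offset()].
#' @return The corrected [zspectrum()].
#' @export
correct_zspectrum <- function(spectrum, shift_ppm) {
  stopifnot(inherits(spectrum, "zspectrum"))
  rng <- range(spectrum$offsets_ppm)
  if (abs(shift_ppm) > diff(rng)) stop("shift exceeds the spectral range")
  sf <- splinefun(spectrum$offsets_ppm, spectrum$s_sat, method = "natural")
  x <- pmin(pmax(spectrum$offsets_ppm + shift_ppm, rng[1]), rng[2])
  zspectrum(spectrum$offsets_ppm, pmax(sf(x), 0), spectrum$s0)
}

#' MTR asymmetry at an offset
#'
#' Computes MTRasym(offset) = (S_sat(-offset) - S_sat(+offset)) / S0 on a
#' (corrected) z-spectrum, interpolating with a natural cubic spline when
#' +-offset are not sample points.  The denominator is the unsaturated S0.
#' Positive values mean more saturation downfield (+offset) than upfield,
#' the signature of amide proton transfer at +3.5 ppm.
#'
#' @param spectrum a [zspectrum()].
#' @param offset_ppm asymmetry offset; default 3.5 ppm (amide).
#' @return MTRasym in percent.
#' @export
compute_mtrasym <- function(spectrum, offset_ppm = 3.5) {
  stopifnot(inherits(spectrum, "zspectrum"))
  rng <- range(spectrum$offsets_ppm)
  if (-offset_ppm < rng[1] || offset_ppm > rng[2]) {
    stop(sprintf("+-%g ppm outside the spectral range [%g, %g]",
                 offset_ppm, rng[1], rng[2]))
  }
  sf <- splinefun(spectrum$offsets_ppm, spectrum$s_sat, method = "natural")
  100 * (sf(-offset_ppm) - sf(offset_ppm)) / spectrum$s0
}

#' Full CEST processing chain for one spectrum
#'
#' Estimate the B0 shift from the low-power series, recentre the main
#' spectrum, and compute MTRasym(3.5 ppm).
#'
#' @param spectrum main [zspectrum()].
#' @param low_power_spectrum low-power B0 [zspectrum()].
#' @param offset_ppm asymmetry offset (default 3.5).
#' @return A list: `mtrasym_pct`, `shift_ppm`, `fit_quality`,
#'   `corrected_spectrum`.
#' @export
process_cest_spectrum <- function(spectrum, low_power_spectrum, offset_ppm = 3.5) {
  b0 <- estimate_b0_offset(low_power_spectrum)
  corr <- correct_zspectrum(spectrum, b0$shift_ppm)
  list(mtrasym_pct = compute_mtrasym(corr, offset_ppm),
       shift_ppm = b0$shift_ppm, fit_quality = b0$fit_quality,
       corrected_spectrum = corr)
}

#' Voxelwise CEST processing over a volume
#'
#' Applies [process_cest_spectrum()] at every voxel of a 4D saturated series
#' (last axis indexed by offset) with a matching low-power series, producing
#' an MTRasym map (percent) and a B0 map (ppm).
#'
#' @param sat 4D array (x, y, z, offset) of saturated signals.
#' @param offsets_ppm offsets of the main series.
#' @param s0 3D array (or scalar) of unsaturated reference signals.
#' @param low_power 4D array of the low-power series.
#' @param low_power_offsets_ppm its offsets.
#' @param mask logical 3D array; default all voxels.
#' @return List of 3D maps `mtrasym_pct` and `b0_ppm`.
#' @export
cest_process_volume <- function(sat, offsets_ppm, s0, low_power,
                                low_power_offsets_ppm, mask = NULL) {
  dims <- dim(sat)[1:3]
  if (length(s0) == 1L) s0 <- array(s0, dims)
  if (is.null(mask)) mask <- array(TRUE, dims)
  stopifnot(identical(dim(mask), dims), identical(dim(s0)[1:3], dims),
            dim(sat)[4] == length(offsets_ppm),
            dim(low_power)[4] == length(low_power_offsets_ppm))
  mtr <- array(NA_real_, dims)
  b0m <- array(NA_real_, dims)
  nvox <- prod(dims)
  Sm <- matrix(sat, nvox)
  Sl <- matrix(low_power, nvox)
  for (i in which(mask)) {
    res <- process_cest_spectrum(
      zspectrum(offsets_ppm, Sm[i, ], s0[i]),
      zspectrum(low_power_offsets_ppm, Sl[i, ], s0[i]))
    mtr[i] <- res$mtrasym_pct
    b0m[i] <- res$shift_ppm
  }
  list(mtrasym_pct = mtr, b0_ppm = b0m)
}
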