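#' Acquisition b-value scheme
#'
#' The ten diffusion weightings (s/mm2) of the chest SEM-DWI protocol this
#' package targets: 0, 25, 50, 100, 150, 200, 400, 600, 800, 1000.
#'
#' @return Numeric vector of b-values in s/mm2.
#' @export
protocol_bvalues <- function() {
  c(0, 25, 50, 100, 150, 200, 400, 600, 800, 1000)
}

#' Specify a synthetic multi-b-value DWI phantom
#'
#' Describes a rectangular voxel grid with per-voxel ground-truth diffusion
#' parameters for both the mono-exponential (ADC) and stretched-exponential
#' (DDC, alpha) signal models, an unweighted signal S0 and a Rician noise
#' level.  Scalar maps are expanded to the full grid.
#'
#' @param grid_shape integer vector of 3 positive grid dimensions (voxels).
#' @param b_values strictly increasing non-negative diffusion weightings
#'   (s/mm2); must start at 0.
#' @param true_adc_map per-voxel ADC (mm2/s), scalar or array of `grid_shape`.
#' @param true_ddc_map per-voxel DDC (mm2/s), scalar or array.
#' @param true_alpha_map per-voxel heterogeneity index alpha in (0, 1],
#'   scalar or array.
#' @param s0_map per-voxel unweighted signal (> 0, arbitrary units).
#' @param snr S0-relative signal-to-noise ratio; `Inf` for noiseless.
#' @param seed integer master seed for the Rician noise draw.
#' @return An object of class `dwi_phantom_spec`.
#' @export
dwi_phantom_spec <- function(grid_shape = c(8L, 8L, 4L),
                             b_values = protocol_bvalues(),
                             true_adc_map = 1.5e-3,
                             true_ddc_map = 2.0e-3,
                             true_alpha_map = 0.7,
                             s0_map = 1000,
                             snr = Inf,
                             seed = 1L) {
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3L || any(grid_shape < 1L)) {
    stop("grid_shape must be 3 positive integers")
  }
  b_values <- as.numeric(b_values)
  if (any(diff(b_values) <= 0)) stop("b_values must be strictly increasing")
  if (b_values[1] != 0) stop("b_values must start at 0 (unweighted reference)")
  expand <- function(x, name) {
    if (length(x) == 1L) x <- array(x, dim = grid_shape)
    if (!identical(dim(x), grid_shape)) {
      stop(sprintf("%s must be scalar or an array of dim %s", name,
                   paste(grid_shape, collapse = "x")))
    }
    x
  }
  adc <- expand(true_adc_map, "true_adc_map")
  ddc <- expand(true_ddc_map, "true_ddc_map")
  alpha <- expand(true_alpha_map, "true_alpha_map")
  s0 <- expand(s0_map, "s0_map")
  bad <- which(alpha <= 0 | alpha > 1)
  if (length(bad)) {
    stop(sprintf("alpha must lie in (0, 1]; offending voxel index %d (value %g)",
                 bad[1], alpha[bad[1]]))
  }
  for (nm in c("adc", "ddc", "s0")) {
    v <- get(nm)
    bad <- which(!(v > 0))
    if (length(bad)) {
      stop(sprintf("%s must be > 0 everywhere; offending voxel index %d",
                   nm, bad[1]))
    }
  }
  if (!(snr > 0)) stop("snr must be > 0 (use Inf for noiseless)")
  structure(list(grid_shape = grid_shape, b_values = b_values,
                 true_adc_map = adc, true_ddc_map = ddc,
                 true_alpha_map = alpha, s0_map = s0,
                 snr = snr, seed = as.integer(seed)),
            class = "dwi_phantom_spec")
}

#' Generate a synthetic DWI signal volume
#'
#' Evaluates the mono-exponential model S0 * exp(-b * ADC) (`model = "mem"`)
#' or the stretched-exponential model S0 * exp(-(b * DDC)^alpha)
#' (`model = "sem"`) at every voxel and b-value, then corrupts the signal
#' with Rician noise: sqrt((S + n1)^2 + n2^2) with n1, n2 ~ N(0, S0/snr),
#' the magnitude-MRI noise model.  With `snr = Inf` the volume is noiseless.
#' The draw is deterministic given the spec seed and does not depend on the
#' model choice, so an alpha = 1 SEM phantom is bit-identical to the MEM
#' phantom with ADC = DDC.
#'
#' @param spec a [dwi_phantom_spec()].
#' @param model `"sem"` (default) or `"mem"`.
#' @return A list of class `dwi_phantom` with elements `signal` (4D array,
#'   grid x b), `b_values`, the ground-truth maps, `model`, `snr`, `seed`.
#' @export
generate_dwi_phantom <- function(spec, model = c("sem", "mem")) {
  stopifnot(inherits(spec, "dwi_phantom_spec"))
  model <- match.arg(model)
  nb <- length(spec$b_values)
  dims4 <- c(spec$grid_shape, nb)
  nvox <- prod(spec$grid_shape)
  s0 <- as.vector(spec$s0_map)
  decay <- if (model == "mem") {
    exp(-outer(as.vector(spec$true_adc_map), spec$b_values))
  } else {
    exp(-outer(as.vector(spec$true_ddc_map), spec$b_values) ^
          as.vector(spec$true_alpha_map))
  }
  signal <- s0 * decay # nvox x nb
  if (is.finite(spec$snr)) {
    sigma <- s0 / spec$snr
    signal <- with_stream_seed(spec$seed, "dwi_noise", {
      n1 <- matrix(rnorm(nvox * nb, sd = sigma), nvox, nb)
      n2 <- matrix(rnorm(nvox * nb, sd = sigma), nvox, nb)
      sqrt((signal + n1)^2 + n2^2)
    })
  }
  structure(list(signal = array(signal, dim = dims4),
                 b_values = spec$b_values,
                 true_adc_map = spec$true_adc_map,
                 true_ddc_map = spec$true_ddc_map,
                 true_alpha_map = spec$true_alpha_map,
                 s0_map = spec$s0_map,
                 model = model, snr = spec$snr, seed = spec$seed),
            class = "dwi_phantom")
}
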