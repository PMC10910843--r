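#' SUV volume container
#'
#' A 3D grid of standardised uptake values with its voxel size.  Negative
#' values (possible after noise or scatter correction) are clipped to 0 on
#' construction.
#'
#' @param suv 3D numeric array of SUV values.
#' @param voxel_size_mm voxel edge lengths (mm), length 3.
#' @return An object of class `suv_volume`.
#' @export
suv_volume <- function(suv, voxel_size_mm = c(2.6, 2.6, 2.0)) {
  if (length(dim(suv)) != 3L) stop("suv must be a 3D array")
  voxel_size_mm <- as.numeric(voxel_size_mm)
  if (length(voxel_size_mm) != 3L || any(voxel_size_mm <= 0)) {
    stop("voxel_size_mm must be 3 positive reals")
  }
  suv[suv < 0] <- 0
  structure(list(suv = suv, voxel_size_mm = voxel_size_mm,
                 voxel_volume_ml = prod(voxel_size_mm) / 1000),
            class = "suv_volume")
}

#' Specify a synthetic spherical PET lesion phantom
#'
#' A uniform-uptake sphere in a uniform background on the PET reconstruction
#' grid (default voxel size 2.6 x 2.6 x 2.0 mm), with optional additive
#' Gaussian noise on the SUV scale.  Voxel membership is decided by the
#' voxel-centre position.
#'
#' @param grid_shape 3 positive integers (voxels).
#' @param voxel_size_mm voxel edge lengths (mm).
#' @param lesion_center_mm sphere centre in mm (grid coordinates, voxel i
#'   spans \[(i-1), i\] * voxel size); default grid centre.
#' @param lesion_radius_mm sphere radius (mm).
#' @param lesion_suv,background_suv uptake levels, `lesion_suv > background_suv >= 0`.
#' @param noise_sd additive Gaussian noise SD (SUV units).
#' @param voi_margin_mm margin added to the radius for the returned VOI mask.
#' @param seed integer master seed.
#' @return An object of class `pet_phantom_spec`.
#' @export
pet_phantom_spec <- function(grid_shape = c(48L, 48L, 48L),
                             voxel_size_mm = c(2.6, 2.6, 2.0),
                             lesion_center_mm = NULL,
                             lesion_radius_mm = 12,
                             lesion_suv = 10,
                             background_suv = 0.5,
                             noise_sd = 0,
                             voi_margin_mm = 6,
                             seed = 1L) {
  grid_shape <- as.integer(grid_shape)
  voxel_size_mm <- as.numeric(voxel_size_mm)
  if (length(grid_shape) != 3L || any(grid_shape < 1L)) stop("grid_shape must be 3 positive integers")
  if (length(voxel_size_mm) != 3L || any(voxel_size_mm <= 0)) stop("voxel_size_mm must be 3 positive reals")
  extent <- grid_shape * voxel_size_mm
  if (is.null(lesion_center_mm)) lesion_center_mm <- extent / 2
  lesion_center_mm <- as.numeric(lesion_center_mm)
  if (!(lesion_suv > background_suv && background_suv >= 0)) {
    stop("need lesion_suv > background_suv >= 0")
  }
  if (lesion_radius_mm <= 0) stop("lesion_radius_mm must be > 0")
  if (any(lesion_center_mm - lesion_radius_mm < 0) ||
      any(lesion_center_mm + lesion_radius_mm > extent)) {
    stop("sphere extends outside the grid")
  }
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  structure(list(grid_shape = grid_shape, voxel_size_mm = voxel_size_mm,
                 lesion_center_mm = lesion_center_mm,
                 lesion_radius_mm = lesion_radius_mm,
                 lesion_suv = lesion_suv, background_suv = background_suv,
                 noise_sd = noise_sd, voi_margin_mm = voi_margin_mm,
                 seed = as.integer(seed)),
            class = "pet_phantom_spec")
}

#' Generate a spherical PET lesion phantom
#'
#' @param spec a [pet_phantom_spec()].
#' @return A list of class `pet_phantom`: `volume` (a [suv_volume()]), `voi`
#'   (logical 3D mask: sphere plus margin), `lesion_mask` (true sphere
#'   membership), `analytic_volume_ml` = 4/3 pi r^3 in ml, and the spec.
#' @export
generate_pet_phantom <- function(spec) {
  stopifnot(inherits(spec, "pet_phantom_spec"))
  d <- spec$grid_shape
  cx <- (seq_len(d[1]) - 0.5) * spec$voxel_size_mm[1]
  cy <- (seq_len(d[2]) - 0.5) * spec$voxel_size_mm[2]
  cz <- (seq_len(d[3]) - 0.5) * spec$voxel_size_mm[3]
  dx2 <- (cx - spec$lesion_center_mm[1])^2
  dy2 <- (cy - spec$lesion_center_mm[2])^2
  dz2 <- (cz - spec$lesion_center_mm[3])^2
  r2 <- outer(outer(dx2, dy2, "+"), dz2, "+")
  lesion <- r2 <= spec$lesion_radius_mm^2
  voi <- r2 <= (spec$lesion_radius_mm + spec$voi_margin_mm)^2
  suv <- array(spec$background_suv, dim = d)
  suv[lesion] <- spec$lesion_suv
  if (spec$noise_sd > 0) {
    suv <- with_stream_seed(spec$seed, "pet_noise", {
      suv + array(rnorm(prod(d), sd = spec$noise_sd), dim = d)
    })
  }
  structure(list(volume = suv_volume(suv, spec$voxel_size_mm),
                 voi = voi, lesion_mask = lesion,
                 analytic_volume_ml = 4 / 3 * pi * spec$lesion_radius_mm^3 / 1000,
                 spec = spec),
            class = "pet_phantom")
}
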