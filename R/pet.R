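#' Maximum SUV inside a volume of interest
#'
#' @param vol a [suv_volume()].
#' @param voi logical 3D mask, same grid, non-empty.
#' @return A list: `suvmax` and `index` (linear index of the maximum; ties
#'   resolved to the lowest linear index).
#' @export
compute_suvmax <- function(vol, voi) {
  stopifnot(inherits(vol, "suv_volume"))
  if (!identical(dim(voi), dim(vol$suv))) stop("VOI grid does not match volume")
  idx <- which(voi)
  if (!length(idx)) stop("VOI is empty")
  vals <- vol$suv[idx]
  k <- which.max(vals) # first (lowest linear index) on ties
  list(suvmax = vals[k], index = idx[k])
}

# 26-connected component of `mask` containing linear index `seed`
connected_component_26 <- function(mask, seed) {
  dims <- dim(mask)
  offs <- as.matrix(expand.grid(di = -1:1, dj = -1:1, dk = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  visited <- array(FALSE, dims)
  visited[seed] <- TRUE
  frontier <- seed
  while (length(frontier)) {
    fi <- arrayInd(frontier, dims)
    cand <- fi[rep(seq_len(nrow(fi)), nrow(offs)), , drop = FALSE] +
      offs[rep(seq_len(nrow(offs)), each = nrow(fi)), , drop = FALSE]
    keep <- cand[, 1] >= 1 & cand[, 1] <= dims[1] &
      cand[, 2] >= 1 & cand[, 2] <= dims[2] &
      cand[, 3] >= 1 & cand[, 3] <= dims[3]
    cand <- cand[keep, , drop = FALSE]
    lin <- unique((cand[, 3] - 1L) * dims[1] * dims[2] +
                    (cand[, 2] - 1L) * dims[1] + cand[, 1])
    lin <- lin[mask[lin] & !visited[lin]]
    visited[lin] <- TRUE
    frontier <- lin
  }
  which(visited)
}

#' Segment a lesion at a fractional SUVmax isocontour
#'
#' Implements the 40 percent SUVmax rule: voxels of the VOI with SUV at or
#' above `threshold * SUVmax`, restricted to the 26-connected component that
#' contains the SUVmax voxel (disconnected hot noise is excluded).  MTV is
#' the member count times the voxel volume (ml); TLG = SUVmean * MTV (g,
#' assuming unit tissue density).
#'
#' @param vol a [suv_volume()].
#' @param voi logical 3D mask, non-empty.
#' @param threshold isocontour fraction of SUVmax; default 0.4.
#' @return A list of class `lesion_segmentation`: `voxels` (linear indices),
#'   `mask`, `suvmax`, `suvmean`, `mtv_ml`, `tlg_g`, `threshold`.
#' @export
segment_lesion_40pct <- function(vol, voi, threshold = 0.4) {
  stopifnot(inherits(vol, "suv_volume"), threshold > 0, threshold <= 1)
  mx <- compute_suvmax(vol, voi)
  above <- voi & (vol$suv >= threshold * mx$suvmax)
  members <- connected_component_26(above, mx$index)
  mask <- array(FALSE, dim(vol$suv))
  mask[members] <- TRUE
  suvmean <- mean(vol$suv[members])
  mtv <- length(members) * vol$voxel_volume_ml
  structure(list(voxels = members, mask = mask,
                 suvmax = mx$suvmax, suvmean = suvmean,
                 mtv_ml = mtv, tlg_g = suvmean * mtv,
                 threshold = threshold),
            class = "lesion_segmentation")
}
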