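#' VOI-mean aggregation of parameter maps
#'
#' Averages each named parameter map over the VOI, using only voxels with a
#' valid (finite) fit, and records the fraction of VOI voxels that were
#' valid.  A map with no valid voxel yields `NA` and is flagged.
#'
#' @param maps named list of 3D numeric arrays on a common grid.
#' @param voi logical 3D mask, non-empty.
#' @return A list: `features` (named numeric vector of VOI means),
#'   `valid_fraction` (named), `flagged` (character vector of map names with
#'   zero valid voxels).
#' @export
aggregate_parameter_maps <- function(maps, voi) {
  stopifnot(is.list(maps), length(maps) > 0, !is.null(names(maps)))
  dims <- dim(maps[[1]])
  for (nm in names(maps)) {
    if (!identical(dim(maps[[nm]]), dims)) {
      stop(sprintf("map '%s' is not on the common grid", nm))
    }
  }
  if (!identical(dim(voi), dims)) stop("VOI grid does not match maps")
  idx <- which(voi)
  if (!length(idx)) stop("VOI is empty")
  feats <- vf <- setNames(numeric(length(maps)), names(maps))
  flagged <- character(0)
  for (nm in names(maps)) {
    v <- maps[[nm]][idx]
    ok <- is.finite(v)
    vf[nm] <- mean(ok)
    if (!any(ok)) {
      feats[nm] <- NA_real_
      flagged <- c(flagged, nm)
    } else {
      feats[nm] <- mean(v[ok])
    }
  }
  list(features = feats, valid_fraction = vf, flagged = flagged)
}

#' Intraclass correlation for two raters
#'
#' Two-way random-effects, absolute-agreement, single-measurement ICC
#' (ICC(A,1) in the McGraw-Wong taxonomy), the standard model for agreement
#' in magnitude between two raters drawn from a population of raters, with
#' the F-based 95 percent confidence interval.  The agreement band follows
#' the conventional thresholds: below 0.40 poor, 0.40-0.60 fair, 0.60-0.75
#' good, 0.75 and above excellent (left-closed intervals).
#'
#' @param rater1,rater2 same-length numeric measurement vectors (n >= 5).
#' @param conf_level confidence level for the interval.
#' @return A list of class `icc_result`: `icc`, `ci_low`, `ci_high`, `band`,
#'   `degenerate` (TRUE when total variance is zero, in which case ICC is
#'   reported as 1).
#' @export
compute_icc <- function(rater1, rater2, conf_level = 0.95) {
  x <- cbind(as.numeric(rater1), as.numeric(rater2))
  if (any(!is.finite(x))) stop("ratings must be finite")
  n <- nrow(x)
  k <- 2L
  if (n < 5L) stop("need at least 5 paired ratings")
  band_of <- function(r) {
    if (r < 0.40) "poor" else if (r < 0.60) "fair" else if (r < 0.75) "good" else "excellent"
  }
  grand <- mean(x)
  if (isTRUE(all.equal(var(as.vector(x)), 0))) {
    return(structure(list(icc = 1, ci_low = 1, ci_high = 1,
                          band = "excellent", degenerate = TRUE),
                     class = "icc_result"))
  }
  row_m <- rowMeans(x)
  col_m <- colMeans(x)
  SSR <- k * sum((row_m - grand)^2)
  SSC <- n * sum((col_m - grand)^2)
  SST <- sum((x - grand)^2)
  SSE <- SST - SSR - SSC
  MSR <- SSR / (n - 1)
  MSC <- SSC / (k - 1)
  MSE <- SSE / ((n - 1) * (k - 1))
  icc <- (MSR - MSE) / (MSR + (k - 1) * MSE + (k / n) * (MSC - MSE))
  alpha <- 1 - conf_level
  a <- (k * icc) / (n * (1 - icc))
  b <- 1 + (k * icc * (n - 1)) / (n * (1 - icc))
  v <- (a * MSC + b * MSE)^2 /
    ((a * MSC)^2 / (k - 1) + (b * MSE)^2 / ((n - 1) * (k - 1)))
  FL <- qf(1 - alpha / 2, n - 1, v)
  FU <- qf(1 - alpha / 2, v, n - 1)
  lb <- n * (MSR - FL * MSE) /
    (FL * (k * MSC + (k * n - k - n) * MSE) + n * MSR)
  ub <- n * (FU * MSR - MSE) /
    (k * MSC + (k * n - k - n) * MSE + n * FU * MSR)
  structure(list(icc = icc, ci_low = min(lb, icc), ci_high = max(ub, icc),
                 band = band_of(icc), degenerate = FALSE),
            class = "icc_result")
}

#' Average two raters' feature tables
#'
#' Element-wise mean of the quantitative features of two per-lesion tables,
#' aligned by `id`; the averaged table is what downstream analysis consumes
#' once inter-rater agreement has been established.
#'
#' @param r1,r2 data.frames with an `id` column and identical column sets.
#' @return A data.frame in `r1` row order with quantitative columns averaged
#'   and non-numeric columns taken from `r1` (verified identical in `r2`).
#' @export
merge_raters <- function(r1, r2) {
  if (!identical(sort(names(r1)), sort(names(r2)))) {
    stop("rater tables must have identical columns")
  }
  if (!setequal(r1$id, r2$id) || anyDuplicated(r1$id) || anyDuplicated(r2$id)) {
    off <- union(setdiff(r1$id, r2$id), setdiff(r2$id, r1$id))
    stop("id mismatch between raters: ",
         paste(if (length(off)) off else "(duplicated ids)", collapse = ", "))
  }
  r2 <- r2[match(r1$id, r2$id), names(r1), drop = FALSE]
  out <- r1
  for (nm in names(r1)) {
    if (nm == "id") next
    if (is.numeric(r1[[nm]])) {
      out[[nm]] <- (r1[[nm]] + r2[[nm]]) / 2
    } else if (!identical(as.character(r1[[nm]]), as.character(r2[[nm]]))) {
      stop(sprintf("non-numeric column '%s' differs between raters", nm))
    }
  }
  out
}
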