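#' Validate a diffusion signal series
#'
#' @param b_values strictly increasing non-negative b-values (s/mm2).
#' @param signals same-length signal intensities.
#' @param min_points minimum usable points (3 for the mono-exponential model,
#'   4 for the stretched-exponential model).
#' @return Invisibly TRUE; errors otherwise.
#' @keywords internal
check_series <- function(b_values, signals, min_points) {
  if (length(b_values) != length(signals)) {
    stop("b_values and signals must have equal length")
  }
  if (any(diff(b_values) <= 0)) stop("b_values must be strictly increasing")
  if (any(b_values < 0)) stop("b_values must be non-negative")
  if (length(b_values) < min_points) {
    stop(sprintf("need at least %d points, got %d", min_points, length(b_values)))
  }
  invisible(TRUE)
}

# Weighted log-linear mono-exponential fit, vectorised across voxels.
# S: nvox x nb matrix.  Weights are squared signals (the variance-stabilising
# choice for log-transformed data); non-positive signals are floored at
# machine-eps * rowmax and their weight set to 0.
mem_fit_batch <- function(S, b) {
  smax <- apply(S, 1L, max)
  floorv <- .Machine$double.eps * pmax(smax, 1)
  w <- S^2
  w[S <= 0] <- 0
  Sf <- pmax(S, floorv)
  y <- log(Sf)
  B <- matrix(b, nrow(S), length(b), byrow = TRUE)
  sw <- rowSums(w)
  ok <- sw > 0 & rowSums(w > 0) >= 2
  sw[!ok] <- NA_real_
  mb <- rowSums(w * B) / sw
  my <- rowSums(w * y) / sw
  vb <- rowSums(w * (B - mb)^2)
  cb <- rowSums(w * (B - mb) * (y - my))
  slope <- ifelse(vb > 0, cb / vb, 0)
  adc <- -slope
  conv <- ok & adc > 0
  adc[adc < 0] <- 0
  s0 <- exp(my - slope * mb)
  fitted <- s0 * exp(-adc * B)
  rn <- sqrt(rowSums((S - fitted)^2))
  list(adc = adc, s0 = s0, residual_norm = rn, converged = conv)
}

#' Fit the mono-exponential diffusion model to one voxel
#'
#' Estimates (S0, ADC) of S_b = S0 exp(-b ADC) by weighted least squares on
#' the log-signal, with weights equal to the squared signal.  Non-positive
#' signals are floored at machine epsilon times the series maximum and given
#' zero weight.  Noiseless mono-exponential data are recovered exactly.
#' An all-constant series yields ADC = 0 with `converged = FALSE`.
#'
#' @param b_values strictly increasing b-values (s/mm2), at least 3.
#' @param signals signal intensities.
#' @return A list of class `diffusion_fit`: `adc` (mm2/s), `s0_hat`,
#'   `residual_norm`, `converged`.
#' @export
fit_mem_voxel <- function(b_values, signals) {
  check_series(b_values, signals, 3L)
  f <- mem_fit_batch(matrix(as.numeric(signals), 1L), as.numeric(b_values))
  structure(list(adc = f$adc[1], s0_hat = f$s0[1],
                 residual_norm = f$residual_norm[1],
                 converged = f$converged[1]),
            class = "diffusion_fit")
}

# Batched bounded Levenberg-Marquardt for S = s0 * exp(-(b*ddc)^alpha).
# P: nvox x 3 start matrix (s0, ddc, alpha).  Analytic Jacobian; 3x3 normal
# equations solved in closed form per voxel; per-voxel damping; bounds
# enforced by projection.
sem_lm_batch <- function(S, b, P, ddc_bounds, alpha_bounds,
                         maxit = 200L, ftol = 1e-15, ptol = 1e-12) {
  nvox <- nrow(S)
  nb <- length(b)
  lo <- c(1e-12, ddc_bounds[1], alpha_bounds[1])
  hi <- c(Inf, ddc_bounds[2], alpha_bounds[2])
  clampP <- function(P) {
    for (j in 1:3) P[, j] <- pmin(pmax(P[, j], lo[j]), hi[j])
    P
  }
  P <- clampP(P)
  # row-wise power with per-voxel exponent: U^alpha
  powA <- function(U, alpha) {
    A <- exp(log(pmax(U, .Machine$double.xmin)) * alpha)
    A[U == 0] <- 0
    A
  }
  sse_of <- function(P) {
    U <- outer(P[, 2], b)
    A <- powA(U, P[, 3])
    Fv <- P[, 1] * exp(-A)
    rowSums((S - Fv)^2)
  }
  lambda <- rep(1e-3, nvox)
  sse <- sse_of(P)
  active <- rep(TRUE, nvox)
  converged <- rep(FALSE, nvox)
  for (it in seq_len(maxit)) {
    idx <- which(active)
    if (!length(idx)) break
    Pa <- P[idx, , drop = FALSE]
    Sa <- S[idx, , drop = FALSE]
    U <- outer(Pa[, 2], b)
    logU <- log(pmax(U, .Machine$double.xmin))
    A <- powA(U, Pa[, 3])
    E <- exp(-A)
    Fv <- Pa[, 1] * E
    R <- Sa - Fv
    J1 <- E
    J2 <- -Pa[, 1] * E * Pa[, 3] * A / pmax(Pa[, 2], 1e-300)
    J3 <- -Pa[, 1] * E * A * logU
    J3[U == 0] <- 0
    a11 <- rowSums(J1 * J1); a12 <- rowSums(J1 * J2); a13 <- rowSums(J1 * J3)
    a22 <- rowSums(J2 * J2); a23 <- rowSums(J2 * J3); a33 <- rowSums(J3 * J3)
    g1 <- rowSums(J1 * R); g2 <- rowSums(J2 * R); g3 <- rowSums(J3 * R)
    lam <- lambda[idx]
    d11 <- a11 * (1 + lam); d22 <- a22 * (1 + lam) + 1e-300
    d33 <- a33 * (1 + lam) + 1e-300
    det <- d11 * (d22 * d33 - a23^2) - a12 * (a12 * d33 - a23 * a13) +
      a13 * (a12 * a23 - d22 * a13)
    det[abs(det) < 1e-300] <- 1e-300
    s1 <- (g1 * (d22 * d33 - a23^2) + g2 * (a13 * a23 - a12 * d33) +
             g3 * (a12 * a23 - a13 * d22)) / det
    s2 <- (g1 * (a23 * a13 - a12 * d33) + g2 * (d11 * d33 - a13^2) +
             g3 * (a12 * a13 - d11 * a23)) / det
    s3 <- (g1 * (a12 * a23 - d22 * a13) + g2 * (a12 * a13 - d11 * a23) +
             g3 * (d11 * d22 - a12^2)) / det
    Pn <- clampP(cbind(Pa[, 1] + s1, Pa[, 2] + s2, Pa[, 3] + s3))
    sse_new <- {
      Un <- outer(Pn[, 2], b)
      An <- powA(Un, Pn[, 3])
      rowSums((Sa - Pn[, 1] * exp(-An))^2)
    }
    better <- sse_new <= sse[idx]
    step_rel <- apply(abs(Pn - Pa) / pmax(abs(Pa), 1e-12), 1L, max)
    sse_rel <- abs(sse_new - sse[idx]) / pmax(sse[idx], 1e-300)
    upd <- idx[better]
    if (length(upd)) {
      P[upd, ] <- Pn[better, , drop = FALSE]
      sse[upd] <- sse_new[better]
      lambda[upd] <- pmax(lambda[upd] / 3, 1e-12)
    }
    lambda[idx[!better]] <- lambda[idx[!better]] * 10
    done <- (better & (step_rel < ptol | sse_rel < ftol)) |
      (!better & lambda[idx] > 1e13)
    converged[idx[done & better]] <- TRUE
    active[idx[done]] <- FALSE
  }
  list(P = P, sse = sse, converged = converged)
}

sem_fit_batch <- function(S, b, ddc_bounds = c(1e-6, 1e-2),
                          alpha_bounds = c(0.01, 1),
                          alpha_starts = c(0.7, 0.35, 1.0)) {
  mem <- mem_fit_batch(S, b)
  ddc0 <- pmin(pmax(mem$adc, ddc_bounds[1]), ddc_bounds[2])
  s00 <- pmax(mem$s0, .Machine$double.eps)
  best <- NULL
  for (a0 in alpha_starts) {
    P0 <- cbind(s00, ddc0, rep(a0, nrow(S)))
    fit <- sem_lm_batch(S, b, P0, ddc_bounds, alpha_bounds)
    if (is.null(best)) {
      best <- fit
    } else {
      imp <- fit$sse < best$sse
      best$P[imp, ] <- fit$P[imp, , drop = FALSE]
      best$sse[imp] <- fit$sse[imp]
      best$converged[imp] <- fit$converged[imp]
    }
  }
  list(s0 = unname(best$P[, 1]), ddc = unname(best$P[, 2]),
       alpha = unname(best$P[, 3]),
       residual_norm = unname(sqrt(best$sse)), converged = best$converged)
}

#' Fit the stretched-exponential diffusion model to one voxel
#'
#' Estimates (S0, DDC, alpha) of S_b = S0 exp(-(b DDC)^alpha) by bounded
#' damped least squares (Levenberg-Marquardt with projection onto the
#' bounds), with DDC constrained to `ddc_bounds` (default 1e-6..1e-2 mm2/s)
#' and alpha to `alpha_bounds` (default 0.01..1; alpha = 1 is the
#' mono-exponential limit).  Initialisation takes S0 and DDC from the
#' mono-exponential fit and runs three alpha starts (0.7, 0.35, 1.0),
#' keeping the best optimum, which makes the fit robust to the shallow
#' DDC-alpha trade-off valley.  Never throws on non-convergence: the best
#' iterate is returned with `converged = FALSE`.
#'
#' @param b_values strictly increasing b-values (s/mm2), at least 4.
#' @param signals signal intensities.
#' @param ddc_bounds,alpha_bounds parameter box constraints.
#' @return A list of class `diffusion_fit`: `ddc` (mm2/s), `alpha`, `s0_hat`,
#'   `residual_norm`, `converged`.
#' @export
fit_sem_voxel <- function(b_values, signals,
                          ddc_bounds = c(1e-6, 1e-2),
                          alpha_bounds = c(0.01, 1)) {
  check_series(b_values, signals, 4L)
  f <- sem_fit_batch(matrix(as.numeric(signals), 1L), as.numeric(b_values),
                     ddc_bounds, alpha_bounds)
  structure(list(ddc = f$ddc[1], alpha = f$alpha[1], s0_hat = f$s0[1],
                 residual_norm = f$residual_norm[1],
                 converged = f$converged[1]),
            class = "diffusion_fit")
}

#' Fit a diffusion model voxelwise over a volume
#'
#' Runs the mono-exponential or stretched-exponential fit for every voxel
#' inside `mask` and assembles parameter maps on the input grid; voxels
#' outside the mask are `NA`.
#'
#' @param signal 4D array (x, y, z, b) of signals, or a `dwi_phantom`.
#' @param b_values b-values matching the 4th dimension (taken from the
#'   phantom when `signal` is one).
#' @param mask logical 3D array; default all voxels.
#' @param model `"mem"` or `"sem"`.
#' @param ... passed to the voxel fitters (bounds).
#' @return A named list of 3D maps: `adc` or `ddc`+`alpha`, plus `s0`,
#'   `residual_norm`, `converged` (logical).
#' @export
fit_volume <- function(signal, b_values = NULL, mask = NULL,
                       model = c("sem", "mem"), ...) {
  model <- match.arg(model)
  if (inherits(signal, "dwi_phantom")) {
    if (is.null(b_values)) b_values <- signal$b_values
    signal <- signal$signal
  }
  if (length(dim(signal)) != 4L) stop("signal must be a 4D array (x, y, z, b)")
  dims <- dim(signal)[1:3]
  if (is.null(b_values)) stop("b_values required")
  if (length(b_values) != dim(signal)[4]) {
    stop(sprintf("4th signal axis (%d) does not match b_values (%d)",
                 dim(signal)[4], length(b_values)))
  }
  if (is.null(mask)) mask <- array(TRUE, dims)
  if (!identical(dim(mask), dims)) {
    stop(sprintf("mask dim (%s) does not match signal grid (%s)",
                 paste(dim(mask), collapse = "x"), paste(dims, collapse = "x")))
  }
  idx <- which(mask)
  empty_map <- function() array(NA_real_, dims)
  maps <- list(s0 = empty_map(), residual_norm = empty_map(),
               converged = array(NA, dims))
  if (model == "mem") {
    maps <- c(list(adc = empty_map()), maps)
  } else {
    maps <- c(list(ddc = empty_map(), alpha = empty_map()), maps)
  }
  if (!length(idx)) return(maps)
  nvox <- prod(dims)
  S <- matrix(signal, nvox)[idx, , drop = FALSE]
  if (model == "mem") {
    f <- mem_fit_batch(S, as.numeric(b_values))
    maps$adc[idx] <- f$adc
  } else {
    f <- sem_fit_batch(S, as.numeric(b_values), ...)
    maps$ddc[idx] <- f$ddc
    maps$alpha[idx] <- f$alpha
  }
  maps$s0[idx] <- f$s0
  maps$residual_norm[idx] <- f$residual_norm
  maps$converged[idx] <- f$converged
  maps
}
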