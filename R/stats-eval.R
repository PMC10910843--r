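#' Calibration curve of predicted probabilities
#'
#' Quantile-binned observed event rate against mean predicted probability,
#' a logistic recalibration fit (labels regressed on the linear predictor
#' logit(p): slope 1 / intercept 0 means perfect calibration), and an
#' optional bootstrap-averaged lowess-smoothed curve.  Degenerate 0/1
#' probabilities are clipped into (0, 1) and flagged; when there are fewer
#' distinct probabilities than requested bins, bins are merged and flagged.
#'
#' @param probabilities predicted event probabilities.
#' @param labels event labels (see [roc_analysis()]).
#' @param n_bins number of quantile bins (default 10).
#' @param n_boot bootstrap replicates for the smoothed curve (0 to skip).
#' @param positive label treated as event.
#' @param seed integer seed for the bootstrap.
#' @return An object of class `calibration_curve`: `bins` (data.frame with
#'   n, predicted, observed), `slope`, `intercept`, `smoothed` (data.frame
#'   p/observed or NULL), `flags`.
#' @export
calibration_curve <- function(probabilities, labels, n_bins = 10L,
                              n_boot = 1000L, positive = "malignant",
                              seed = 1L) {
  y <- as_binary_labels(labels, positive)
  p <- as.numeric(probabilities)
  stopifnot(length(p) == length(y))
  flags <- character(0)
  if (any(p <= 0 | p >= 1)) {
    flags <- c(flags, "degenerate_probabilities_clipped")
    p <- pmin(pmax(p, 1e-10), 1 - 1e-10)
  }
  breaks <- unique(quantile(p, probs = seq(0, 1, length.out = n_bins + 1L)))
  if (length(breaks) < n_bins + 1L) flags <- c(flags, "bins_merged")
  if (length(breaks) < 2L) breaks <- c(breaks - 1e-10, breaks + 1e-10)
  bin <- cut(p, breaks, include.lowest = TRUE)
  bins <- data.frame(
    n = as.integer(table(bin)),
    predicted = as.numeric(tapply(p, bin, mean)),
    observed = as.numeric(tapply(y, bin, mean)))
  bins <- bins[bins$n > 0, , drop = FALSE]
  lp <- qlogis(p)
  recal <- suppressWarnings(glm(y ~ lp, family = binomial()))
  smoothed <- NULL
  if (n_boot > 0L) {
    grid <- seq(min(p), max(p), length.out = 50L)
    acc <- matrix(NA_real_, n_boot, length(grid))
    smoothed <- with_stream_seed(seed, "calibration_boot", {
      for (bi in seq_len(n_boot)) {
        idx <- sample.int(length(p), replace = TRUE)
        lw <- lowess(p[idx], y[idx], f = 2 / 3)
        acc[bi, ] <- approx(lw$x, lw$y, xout = grid, rule = 2,
                            ties = "ordered")$y
      }
      data.frame(p = grid,
                 observed = pmin(pmax(colMeans(acc), 0), 1))
    })
  }
  structure(list(bins = bins,
                 slope = unname(coef(recal)[2]),
                 intercept = unname(coef(recal)[1]),
                 smoothed = smoothed, flags = flags),
            class = "calibration_curve")
}

#' Decision curve analysis
#'
#' Net benefit of acting on the model at each probability threshold pt:
#' NB(pt) = TP/N - (FP/N) * pt / (1 - pt), where a subject is treated when
#' the predicted probability is at least pt.  The treat-all and treat-none
#' reference policies are included (treat-none is identically 0).
#'
#' @param probabilities predicted event probabilities.
#' @param labels event labels.
#' @param thresholds threshold grid in (0, 1); default 0.01..0.99 step 0.01.
#' @param positive label treated as event.
#' @return An object of class `dca_curve`: data.frame `curve` with columns
#'   threshold, net_benefit_model, net_benefit_all, net_benefit_none, and
#'   `prevalence`.
#' @export
decision_curve <- function(probabilities, labels,
                           thresholds = seq(0.01, 0.99, by = 0.01),
                           positive = "malignant") {
  y <- as_binary_labels(labels, positive)
  p <- as.numeric(probabilities)
  stopifnot(length(p) == length(y), all(p >= 0 & p <= 1))
  thresholds <- thresholds[thresholds > 0 & thresholds < 1]
  N <- length(y)
  prev <- mean(y)
  nb <- vapply(thresholds, function(pt) {
    treat <- p >= pt
    tp <- sum(treat & y == 1L) / N
    fp <- sum(treat & y == 0L) / N
    tp - fp * pt / (1 - pt)
  }, numeric(1))
  nb_all <- prev - (1 - prev) * thresholds / (1 - thresholds)
  structure(list(curve = data.frame(threshold = thresholds,
                                    net_benefit_model = nb,
                                    net_benefit_all = nb_all,
                                    net_benefit_none = 0),
                 prevalence = prev),
            class = "dca_curve")
}
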