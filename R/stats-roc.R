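# DeLong structural components: V10 (one per positive), V01 (one per
# negative).  mean(V10) = mean(V01) = AUC (Mann-Whitney with half-credit for
# ties).
delong_components <- function(scores, labels) {
  X <- scores[labels == 1L]
  Y <- scores[labels == 0L]
  cmp <- outer(X, Y, function(x, y) (x > y) + 0.5 * (x == y))
  list(v10 = rowMeans(cmp), v01 = colMeans(1 - cmp), auc = mean(cmp))
}

as_binary_labels <- function(labels, positive = "malignant") {
  if (is.logical(labels)) return(as.integer(labels))
  if (is.numeric(labels)) {
    u <- sort(unique(labels))
    if (!all(u %in% c(0, 1))) stop("numeric labels must be 0/1")
    return(as.integer(labels))
  }
  as.integer(as.character(labels) == positive)
}

#' Empirical ROC curve with DeLong inference and Youden cutoff
#'
#' Builds the empirical ROC over all distinct score thresholds, computes the
#' trapezoidal AUC (identical to the tie-corrected Mann-Whitney statistic),
#' a DeLong-variance 95 percent confidence interval, and the cutoff
#' maximising Youden's J = sensitivity + specificity - 1 (ties resolved
#' towards the higher specificity).  With `direction = "auto"` the score
#' orientation giving AUC >= 0.5 is used and recorded, so markers that run
#' low-in-disease (e.g. ADC) are handled like high-in-disease ones.
#'
#' @param scores numeric marker values or predicted probabilities.
#' @param labels event labels: logical, 0/1, or characters compared against
#'   `positive`.
#' @param positive label treated as event.
#' @param direction `">="` (event at high scores), `"<="`, or `"auto"`.
#' @param conf_level confidence level for the AUC interval.
#' @return An object of class `roc_curve`: `thresholds`, `sensitivities`,
#'   `specificities`, `auc`, `auc_var`, `auc_ci`, `youden_cutoff`,
#'   `sens_at_cutoff`, `spec_at_cutoff`, `direction`, `n_pos`, `n_neg`.
#' @export
roc_analysis <- function(scores, labels, positive = "malignant",
                         direction = c("auto", ">=", "<="),
                         conf_level = 0.95) {
  direction <- match.arg(direction)
  y <- as_binary_labels(labels, positive)
  stopifnot(length(scores) == length(y), !any(is.na(scores)))
  if (!any(y == 1L) || !any(y == 0L)) stop("both classes must be present")
  orient <- function(s, dir) if (dir == ">=") s else -s
  if (direction == "auto") {
    direction <- if (delong_components(scores, y)$auc >= 0.5) ">=" else "<="
  }
  s <- orient(scores, direction)
  dc <- delong_components(s, y)
  auc <- dc$auc
  auc_var <- var(dc$v10) / length(dc$v10) + var(dc$v01) / length(dc$v01)
  z <- qnorm(1 - (1 - conf_level) / 2)
  ci <- pmin(pmax(auc + c(-1, 1) * z * sqrt(auc_var), 0), 1)
  thr <- c(Inf, sort(unique(s), decreasing = TRUE))
  sens <- vapply(thr, function(t) mean(s[y == 1L] >= t), numeric(1))
  spec <- vapply(thr, function(t) mean(s[y == 0L] < t), numeric(1))
  J <- sens + spec - 1
  best <- which(J == max(J))
  if (length(best) > 1L) best <- best[which.max(spec[best])]
  structure(list(thresholds = orient(thr, direction),
                 sensitivities = sens, specificities = spec,
                 auc = auc, auc_var = auc_var, auc_ci = ci,
                 youden_cutoff = orient(thr[best], direction),
                 sens_at_cutoff = sens[best], spec_at_cutoff = spec[best],
                 direction = direction,
                 n_pos = sum(y == 1L), n_neg = sum(y == 0L)),
            class = "roc_curve")
}

#' DeLong test for two correlated AUCs
#'
#' Compares the AUCs of two markers measured on the same subjects using
#' DeLong's structural-components estimate of the variance of the AUC
#' difference, with a two-sided normal p-value.  Identical score orderings
#' (zero variance of the difference) give Z = 0, p = 1 by convention.
#'
#' @param scores1,scores2 paired marker values on the same subjects.
#' @param labels shared event labels.
#' @param positive label treated as event.
#' @param direction orientation handling per marker, as in [roc_analysis()].
#' @return A list: `auc1`, `auc2`, `auc_diff`, `var_diff`, `z`, `p_value`.
#' @export
delong_test <- function(scores1, scores2, labels, positive = "malignant",
                        direction = "auto") {
  y <- as_binary_labels(labels, positive)
  stopifnot(length(scores1) == length(y), length(scores2) == length(y))
  if (!any(y == 1L) || !any(y == 0L)) stop("both classes must be present")
  fix <- function(s) {
    if (direction == "<=" ||
        (direction == "auto" && delong_components(s, y)$auc < 0.5)) -s else s
  }
  d1 <- delong_components(fix(scores1), y)
  d2 <- delong_components(fix(scores2), y)
  m <- length(d1$v10)
  n <- length(d1$v01)
  s10 <- var(d1$v10 - d2$v10)
  s01 <- var(d1$v01 - d2$v01)
  var_diff <- s10 / m + s01 / n
  diff <- d1$auc - d2$auc
  if (var_diff <= 0) {
    z <- 0
    p <- 1
  } else {
    z <- diff / sqrt(var_diff)
    p <- 2 * pnorm(-abs(z))
  }
  list(auc1 = d1$auc, auc2 = d2$auc, auc_diff = diff,
       var_diff = var_diff, z = z, p_value = p)
}
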