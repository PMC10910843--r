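#' Marginal distribution helpers for the cohort simulator
#'
#' Cohort parameters are simulated through a Gaussian copula; each marginal
#' is described by its family and the transform applied to a standard-normal
#' latent variable.  `marginal_normal()` takes a mean and SD (the form in
#' which normally distributed imaging parameters are reported);
#' `marginal_lognormal()` takes a median and quartiles (the reporting
#' convention for right-skewed parameters) and converts them to
#' (meanlog, sdlog); `marginal_truncnorm01()` is a normal clipped into
#' (0, 1], for the heterogeneity index alpha.
#'
#' @param mean,sd normal mean and standard deviation.
#' @param median,q1,q3 median and lower/upper quartiles.
#' @return A list describing the marginal.
#' @name marginals
NULL

#' @rdname marginals
#' @export
marginal_normal <- function(mean, sd) {
  stopifnot(sd >= 0)
  list(family = "normal", mean = mean, sd = sd)
}

#' @rdname marginals
#' @export
marginal_lognormal <- function(median, q1, q3) {
  stopifnot(median > 0, q1 > 0, q3 >= q1)
  list(family = "lognormal", meanlog = log(median),
       sdlog = log(q3 / q1) / (2 * qnorm(0.75)))
}

#' @rdname marginals
#' @export
marginal_truncnorm01 <- function(median, q1, q3) {
  stopifnot(q3 >= q1)
  list(family = "truncnorm01", mean = median, sd = (q3 - q1) / (2 * qnorm(0.75)))
}

marginal_quantile <- function(m, z) {
  switch(m$family,
         normal = m$mean + m$sd * z,
         lognormal = exp(m$meanlog + m$sdlog * z),
         truncnorm01 = pmin(pmax(m$mean + m$sd * z, 1e-6), 1),
         stop("unknown marginal family: ", m$family))
}

cohort_parameter_names <- function() {
  c("suvmax", "mtv_ml", "tlg_g", "adc", "ddc", "alpha", "mtrasym_pct")
}

#' Default per-group parameter distributions
#'
#' Location/scale of the seven imaging parameters in the benign and
#' malignant groups of the training cohort this package emulates:
#' SUVmax 4.38 (2.78, 5.44) vs 9.63 (6.23, 13.23); MTV 4.05 (2.33, 6.78) vs
#' 14.46 (4.77, 38.82) ml; TLG 6.29 (1.86, 12.96) vs 62.16 (11.33, 155.71) g;
#' ADC 1.79 +- 0.19 vs 1.42 +- 0.28 (x 10^-3 mm2/s); DDC 3.00 (2.78, 3.32)
#' vs 1.93 (1.57, 2.60); alpha 0.48 (0.42, 0.52) vs 0.63 (0.50, 0.78);
#' MTRasym 1.07 (0.35, 1.75) vs 2.58 (0.62, 3.87) percent.  Right-skewed
#' median/IQR parameters get log-normal marginals, ADC a normal marginal,
#' alpha a truncated normal on (0, 1].
#'
#' @return Named list (one entry per parameter) of `list(benign=, malignant=)`
#'   marginals.
#' @export
default_parameter_table <- function() {
  list(
    suvmax = list(benign = marginal_lognormal(4.38, 2.78, 5.44),
                  malignant = marginal_lognormal(9.63, 6.23, 13.23)),
    mtv_ml = list(benign = marginal_lognormal(4.05, 2.33, 6.78),
                  malignant = marginal_lognormal(14.46, 4.77, 38.82)),
    tlg_g = list(benign = marginal_lognormal(6.29, 1.86, 12.96),
                 malignant = marginal_lognormal(62.16, 11.33, 155.71)),
    adc = list(benign = marginal_normal(1.79, 0.19),
               malignant = marginal_normal(1.42, 0.28)),
    ddc = list(benign = marginal_lognormal(3.00, 2.78, 3.32),
               malignant = marginal_lognormal(1.93, 1.57, 2.60)),
    alpha = list(benign = marginal_truncnorm01(0.48, 0.42, 0.52),
                 malignant = marginal_truncnorm01(0.63, 0.50, 0.78)),
    mtrasym_pct = list(benign = marginal_lognormal(1.07, 0.35, 1.75),
                       malignant = marginal_lognormal(2.58, 0.62, 3.87))
  )
}

#' Default inter-parameter correlation matrix
#'
#' Within-group latent (copula) correlations.  Two blocks reflect how these
#' parameters arise: the metabolic block (TLG is SUVmean x MTV, so MTV-TLG
#' 0.85, SUVmax-TLG 0.65, SUVmax-MTV 0.45) and the diffusion block (ADC and
#' DDC both track cellularity, 0.75; alpha couples negatively to both,
#' -0.35/-0.3).  A moderate negative ADC-SUVmax and ADC-MTRasym coupling
#' (-0.3) ties the blocks together and makes multivariate predictor
#' selection non-trivial.  This redundancy structure is what lets a
#' three-predictor model subsume the remaining parameters, mirroring the
#' multivariate outcome the package emulates.
#'
#' @return A 7x7 correlation matrix named by [cohort_parameter_names()].
#' @export
default_correlation_matrix <- function() {
  p <- cohort_parameter_names()
  R <- diag(length(p))
  dimnames(R) <- list(p, p)
  set <- function(a, b, v) {
    R[a, b] <<- v
    R[b, a] <<- v
  }
  set("suvmax", "mtv_ml", 0.45)
  set("suvmax", "tlg_g", 0.65)
  set("mtv_ml", "tlg_g", 0.85)
  set("adc", "ddc", 0.75)
  set("adc", "alpha", -0.35)
  set("ddc", "alpha", -0.30)
  set("adc", "suvmax", -0.3)
  set("adc", "mtrasym_pct", -0.3)
  R
}

default_clinical_table <- function() {
  list(
    age = list(benign = marginal_normal(57.54, 7.98),
               malignant = marginal_normal(61.59, 11.96)),
    diameter_mm = list(benign = marginal_lognormal(16.50, 9.25, 31.00),
                       malignant = marginal_lognormal(31.50, 24.00, 46.25)),
    p_male = c(benign = 16 / 28, malignant = 36 / 56),
    p_smoking = c(benign = 11 / 28, malignant = 25 / 56)
  )
}

#' Specify a synthetic two-group lesion cohort
#'
#' @param n_benign,n_malignant group sizes (default 41/79, the full cohort
#'   this package emulates).
#' @param parameters per-parameter, per-group marginals as produced by
#'   [default_parameter_table()].
#' @param correlation latent correlation matrix over
#'   [cohort_parameter_names()]; symmetric positive semi-definite, unit
#'   diagonal.
#' @param clinical clinical covariate distributions (age, diameter,
#'   sex/smoking probabilities per group).
#' @param seed integer master seed.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_benign = 41L, n_malignant = 79L,
                        parameters = default_parameter_table(),
                        correlation = default_correlation_matrix(),
                        clinical = default_clinical_table(),
                        seed = 1L) {
  n_benign <- as.integer(n_benign)
  n_malignant <- as.integer(n_malignant)
  stopifnot(n_benign >= 1L, n_malignant >= 1L)
  pnames <- cohort_parameter_names()
  if (!setequal(names(parameters), pnames)) {
    stop("parameters must be named exactly: ", paste(pnames, collapse = ", "))
  }
  correlation <- as.matrix(correlation)
  if (!isTRUE(all.equal(correlation, t(correlation), tolerance = 1e-10))) {
    stop("correlation matrix must be symmetric")
  }
  if (any(abs(diag(correlation) - 1) > 1e-10)) {
    stop("correlation matrix must have unit diagonal")
  }
  ev <- eigen(correlation, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) stop("correlation matrix must be positive semi-definite")
  structure(list(n_benign = n_benign, n_malignant = n_malignant,
                 parameters = parameters[pnames], correlation = correlation,
                 clinical = clinical, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Generate a synthetic per-lesion feature table
#'
#' Draws `n_benign + n_malignant` lesion records.  Within each group the
#' seven imaging parameters are generated from a Gaussian copula with the
#' spec's latent correlation matrix and transformed through the per-group
#' marginals; clinical covariates (age, diameter, sex, smoking) are drawn
#' independently.  Reproducible given the spec seed.
#'
#' @param spec a [cohort_spec()].
#' @return A data.frame with columns `id, set, label, age, sex, smoking,
#'   diameter_mm, suvmax, mtv_ml, tlg_g, adc, ddc, alpha, mtrasym_pct`.
#'   `set` is `NA` until [split_cohort()] assigns it.
#' @export
generate_cohort_table <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  pnames <- cohort_parameter_names()
  L <- chol(spec$correlation + diag(1e-10, length(pnames)))
  draw_group <- function(n, group) {
    Z <- matrix(rnorm(n * length(pnames)), n) %*% L
    colnames(Z) <- pnames
    out <- as.data.frame(lapply(setNames(pnames, pnames), function(p) {
      marginal_quantile(spec$parameters[[p]][[group]], Z[, p])
    }))
    out$age <- marginal_quantile(spec$clinical$age[[group]], rnorm(n))
    out$diameter_mm <- marginal_quantile(spec$clinical$diameter_mm[[group]], rnorm(n))
    out$sex <- ifelse(rbinom(n, 1, spec$clinical$p_male[[group]]) == 1, "male", "female")
    out$smoking <- ifelse(rbinom(n, 1, spec$clinical$p_smoking[[group]]) == 1,
                          "always", "never")
    out$label <- group
    out
  }
  tab <- with_stream_seed(spec$seed, "cohort", {
    rbind(draw_group(spec$n_benign, "benign"),
          draw_group(spec$n_malignant, "malignant"))
  })
  tab$id <- sprintf("L%03d", seq_len(nrow(tab)))
  tab$set <- NA_character_
  tab[, c("id", "set", "label", "age", "sex", "smoking", "diameter_mm",
          "suvmax", "mtv_ml", "tlg_g", "adc", "ddc", "alpha", "mtrasym_pct")]
}

#' Cohort in which only SUVmax, ADC and MTRasym carry independent signal
#'
#' Generates the three signal parameters independently from their per-group
#' marginals (each must carry signal of its own, which is the premise of the
#' selection-consistency experiment), then derives MTV, TLG, DDC
#' and alpha as the *same* noisy function of the raw signal values in both
#' groups: log MTV and log TLG are linear in log SUVmax, DDC and alpha are
#' linear in ADC, each plus independent Gaussian noise.  The derived
#' parameters are therefore marginally associated with malignancy (they
#' inherit the group separation of their parents) but conditionally
#' uninformative given the trio -- the ground truth against which predictor
#' selection consistency is judged.
#'
#' @param n_benign,n_malignant group sizes.
#' @param parameters per-group marginals for the signal trio (defaults from
#'   [default_parameter_table()]).
#' @param seed integer master seed.
#' @return A cohort data.frame with the standard schema.
#' @export
generate_trio_cohort <- function(n_benign = 250L, n_malignant = 250L,
                                 parameters = default_parameter_table(),
                                 seed = 1L) {
  trio <- c("suvmax", "adc", "mtrasym_pct")
  clin <- default_clinical_table()
  draw_group <- function(n, group) {
    Z <- matrix(rnorm(n * 3), n)
    colnames(Z) <- trio
    out <- as.data.frame(lapply(setNames(trio, trio), function(p) {
      marginal_quantile(parameters[[p]][[group]], Z[, p])
    }))
    # derived, conditionally null given the trio (identical map both groups).
    # Linear parent + independent additive noise makes the projection
    # residual pure noise, so the score test for entry is exactly null once
    # the parent is in the model; noise scales keep negatives negligible
    # slope/noise ratios keep the parent-child correlation moderate
    # (~0.6, like the ADC pair) so the parent, not the child, enters first
    out$mtv_ml <- pmax(12 + 1.0 * out$suvmax + rnorm(n, sd = 3.5), 0.05)
    out$tlg_g <- pmax(40 + 4.0 * out$suvmax + rnorm(n, sd = 12), 0.05)
    out$ddc <- pmax(0.3 + 1.3 * out$adc + rnorm(n, sd = 0.35), 0.05)
    out$alpha <- pmin(pmax(0.95 - 0.22 * out$adc + rnorm(n, sd = 0.10), 1e-6), 1)
    out$age <- marginal_quantile(clin$age[[group]], rnorm(n))
    out$diameter_mm <- marginal_quantile(clin$diameter_mm[[group]], rnorm(n))
    out$sex <- ifelse(rbinom(n, 1, clin$p_male[[group]]) == 1, "male", "female")
    out$smoking <- ifelse(rbinom(n, 1, clin$p_smoking[[group]]) == 1, "always", "never")
    out$label <- group
    out
  }
  tab <- with_stream_seed(seed, "trio_cohort", {
    rbind(draw_group(n_benign, "benign"), draw_group(n_malignant, "malignant"))
  })
  tab$id <- sprintf("L%03d", seq_len(nrow(tab)))
  tab$set <- NA_character_
  tab[, c("id", "set", "label", "age", "sex", "smoking", "diameter_mm",
          "suvmax", "mtv_ml", "tlg_g", "adc", "ddc", "alpha", "mtrasym_pct")]
}
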