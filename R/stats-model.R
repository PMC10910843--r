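# Encode the outcome and the candidate columns for logistic modelling.
# Continuous candidates are z-scored with *training* statistics; binary
# (two-level) candidates are encoded 0/1 and left unscaled.
encode_candidates <- function(table, candidates, positive = "malignant",
                              scaling = NULL) {
  y <- NULL
  if ("label" %in% names(table)) {
    y <- as.integer(as.character(table$label) == positive)
  }
  X <- list()
  new_scaling <- list()
  for (v in candidates) {
    if (!v %in% names(table)) stop(sprintf("missing feature '%s'", v))
    col <- table[[v]]
    if (!is.numeric(col)) {
      lev <- sort(unique(as.character(col)))
      if (length(lev) > 2L) stop(sprintf("candidate '%s' must be numeric or binary", v))
      col <- as.integer(as.character(col) == lev[length(lev)])
    }
    if (is.null(scaling)) {
      if (length(unique(col)) > 2L) {
        m <- mean(col); s <- sd(col)
        if (s == 0) s <- 1
        new_scaling[[v]] <- c(mean = m, sd = s)
        col <- (col - m) / s
      } else {
        new_scaling[[v]] <- c(mean = 0, sd = 1)
      }
    } else {
      sc <- scaling[[v]]
      if (is.null(sc)) stop(sprintf("no training scaling stored for '%s'", v))
      col <- (col - sc["mean"]) / sc["sd"]
    }
    X[[v]] <- as.numeric(col)
  }
  list(y = y, X = as.data.frame(X, optional = TRUE),
       scaling = if (is.null(scaling)) new_scaling else scaling)
}

glm_quiet <- function(formula, data) {
  sep <- FALSE
  fit <- withCallingHandlers(
    glm(formula, data = data, family = binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1|did not converge",
                conditionMessage(w))) {
        sep <<- TRUE
      }
      invokeRestart("muffleWarning")
    })
  if (any(abs(coef(fit)[-1]) > 15, na.rm = TRUE)) sep <- TRUE
  attr(fit, "separation") <- sep
  fit
}

model_formula <- function(vars) {
  stats::as.formula(paste("y ~", if (length(vars)) {
    paste(sprintf("`%s`", vars), collapse = " + ")
  } else "1"))
}

#' Forward stepwise logistic regression (forward LR)
#'
#' The classical forward-LR procedure for building a multivariable
#' malignancy model: at each step the candidate with the smallest Rao score
#' test p-value enters if below `entry` (default 0.05); after every entry,
#' members whose likelihood-ratio p-value exceeds `removal` (default 0.10)
#' are dropped; the procedure stops when neither rule fires.  The final
#' model is refit by maximum likelihood.  Continuous candidates are z-scored
#' on the training data, so the reported odds ratios are per one standard
#' deviation, with Wald 95 percent confidence intervals.
#'
#' Perfect separation is detected (fitted probabilities pinned at 0/1 or
#' runaway coefficients) and the final fit falls back to a lightly
#' ridge-penalised logistic regression, flagged in the result.
#'
#' @param table training data.frame with a `label` column.
#' @param candidates character vector of candidate feature columns.
#' @param entry,removal entry (score test) and removal (LR test) p-value
#'   thresholds.
#' @param positive label treated as the event (default `"malignant"`).
#' @return An object of class `spl_logistic`: `predictors`, `coefficients`
#'   (intercept first, per-SD scale), `or_table` (per-SD OR with 95 percent
#'   CI and Wald p), `trace` (selection history), `scaling` (training
#'   means/SDs, frozen for test-set scoring), `separation` flag.
#' @export
forward_logistic_selection <- function(table, candidates,
                                       entry = 0.05, removal = 0.10,
                                       positive = "malignant") {
  enc <- encode_candidates(table, candidates, positive)
  dat <- cbind(y = enc$y, enc$X)
  selected <- character(0)
  trace <- data.frame(step = integer(0), action = character(0),
                      variable = character(0), p_value = numeric(0))
  step_no <- 0L
  repeat {
    changed <- FALSE
    fit0 <- glm_quiet(model_formula(selected), dat)
    pool <- setdiff(candidates, selected)
    if (length(pool)) {
      pvals <- vapply(pool, function(v) {
        fit1 <- glm_quiet(model_formula(c(selected, v)), dat)
        an <- anova(fit0, fit1, test = "Rao")
        p <- an[2, "Pr(>Chi)"]
        if (is.na(p)) 1 else p
      }, numeric(1))
      if (min(pvals) < entry) {
        v <- pool[which.min(pvals)]
        selected <- c(selected, v)
        step_no <- step_no + 1L
        trace <- rbind(trace, data.frame(step = step_no, action = "add",
                                         variable = v, p_value = min(pvals)))
        changed <- TRUE
      }
    }
    # removal pass (likelihood-ratio) after each entry
    repeat {
      if (length(selected) == 0L) break
      fit_full <- glm_quiet(model_formula(selected), dat)
      pvals <- vapply(selected, function(v) {
        fit_m <- glm_quiet(model_formula(setdiff(selected, v)), dat)
        an <- anova(fit_m, fit_full, test = "LRT")
        p <- an[2, "Pr(>Chi)"]
        if (is.na(p)) 0 else p
      }, numeric(1))
      if (max(pvals) > removal) {
        v <- selected[which.max(pvals)]
        selected <- setdiff(selected, v)
        step_no <- step_no + 1L
        trace <- rbind(trace, data.frame(step = step_no, action = "remove",
                                         variable = v, p_value = max(pvals)))
        changed <- TRUE
      } else break
    }
    if (!changed || step_no > 10L * length(candidates)) break
  }
  fit <- glm_quiet(model_formula(selected), dat)
  separation <- isTRUE(attr(fit, "separation"))
  if (separation && length(selected) &&
      requireNamespace("glmnet", quietly = TRUE)) {
    Xm <- as.matrix(dat[, selected, drop = FALSE])
    rf <- glmnet::glmnet(cbind(Xm, 0), dat$y, family = "binomial",
                         alpha = 0, lambda = 1e-3, standardize = FALSE)
    cf <- as.numeric(coef(rf))[seq_len(length(selected) + 1L)]
    coefs <- setNames(cf, c("(Intercept)", selected))
    ses <- rep(NA_real_, length(selected))
  } else {
    coefs <- coef(fit)
    ses <- if (length(selected)) {
      sqrt(diag(stats::vcov(fit)))[selected]
    } else numeric(0)
  }
  z <- qnorm(0.975)
  or_table <- if (length(selected)) {
    beta <- coefs[selected]
    data.frame(variable = selected, coefficient = unname(beta),
               or = unname(exp(beta)),
               ci_low = unname(exp(beta - z * ses)),
               ci_high = unname(exp(beta + z * ses)),
               p_value = unname(2 * pnorm(-abs(beta / ses))),
               row.names = NULL)
  } else {
    data.frame(variable = character(0), coefficient = numeric(0),
               or = numeric(0), ci_low = numeric(0), ci_high = numeric(0),
               p_value = numeric(0))
  }
  structure(list(predictors = selected, coefficients = coefs,
                 or_table = or_table, trace = trace,
                 scaling = enc$scaling, positive = positive,
                 separation = separation),
            class = "spl_logistic")
}

#' Univariate per-SD logistic screening
#'
#' Fits one logistic model per candidate (z-scored on the given data), the
#' univariate half of the usual two-stage predictor screen, reporting per-SD
#' odds ratios with Wald confidence intervals and p-values.
#'
#' @inheritParams forward_logistic_selection
#' @return A data.frame: variable, coefficient, or, ci_low, ci_high, p_value.
#' @export
univariate_logistic <- function(table, candidates, positive = "malignant") {
  enc <- encode_candidates(table, candidates, positive)
  dat <- cbind(y = enc$y, enc$X)
  z <- qnorm(0.975)
  rows <- lapply(candidates, function(v) {
    fit <- glm_quiet(model_formula(v), dat)
    beta <- coef(fit)[v]
    se <- sqrt(diag(stats::vcov(fit)))[v]
    data.frame(variable = v, coefficient = unname(beta),
               or = unname(exp(beta)),
               ci_low = unname(exp(beta - z * se)),
               ci_high = unname(exp(beta + z * se)),
               p_value = unname(2 * pnorm(-abs(beta / se))),
               row.names = NULL)
  })
  do.call(rbind, rows)
}

#' Predict malignancy probabilities from a fitted model
#'
#' Applies the stored training standardisation to the new rows and returns
#' the logistic probabilities of the positive (malignant) class.
#'
#' @param object an `spl_logistic` model.
#' @param newdata data.frame containing the model's predictors.
#' @param ... unused.
#' @return Numeric vector of probabilities in (0, 1).
#' @export
predict.spl_logistic <- function(object, newdata, ...) {
  if (!length(object$predictors)) {
    return(rep(plogis(object$coefficients[["(Intercept)"]]), nrow(newdata)))
  }
  enc <- encode_candidates(newdata, object$predictors,
                           positive = object$positive,
                           scaling = object$scaling)
  lp <- object$coefficients[["(Intercept)"]] +
    as.matrix(enc$X) %*% object$coefficients[object$predictors]
  as.numeric(plogis(lp))
}
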