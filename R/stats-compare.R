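#' Stratified training/test split
#'
#' Randomly assigns the given fraction of each label class (rounded to the
#' nearest integer) to the training set and the remainder to the test set;
#' the split is disjoint, exhaustive and reproducible given the seed.
#'
#' @param table per-lesion feature table with a `label` column.
#' @param fraction training fraction within each class (default 0.7).
#' @param seed integer seed.
#' @return A list with data.frames `training` and `test`, each with its
#'   `set` column filled in.
#' @export
split_cohort <- function(table, fraction = 0.7, seed = 1L) {
  stopifnot(is.data.frame(table), "label" %in% names(table))
  classes <- unique(table$label)
  if (length(classes) < 2L) stop("both classes must be present")
  if (!(fraction > 0 && fraction < 1)) {
    stop("fraction must be in (0, 1): both sets must be non-empty")
  }
  train_idx <- with_stream_seed(seed, "split", {
    unlist(lapply(classes, function(cl) {
      idx <- which(table$label == cl)
      if (length(idx) < 2L) stop(sprintf("class '%s' has < 2 members", cl))
      n_tr <- round(fraction * length(idx))
      n_tr <- min(max(n_tr, 1L), length(idx) - 1L)
      sample(idx, n_tr)
    }))
  })
  training <- table[sort(train_idx), , drop = FALSE]
  test <- table[setdiff(seq_len(nrow(table)), train_idx), , drop = FALSE]
  training$set <- "training"
  test$set <- "test"
  list(training = training, test = test)
}

#' Compare a variable between the benign and malignant groups
#'
#' Test choice follows the usual reporting convention: categorical variables
#' get a Pearson chi-square test with count summaries; continuous variables
#' get an independent-samples t test (with mean +- SD summaries) when both
#' groups pass Shapiro-Wilk normality at 0.05, and a Mann-Whitney U test
#' (with median \[IQR\] summaries) otherwise.  A degenerate-variance t-test
#' path falls back to Mann-Whitney.
#'
#' @param table data.frame with the variable and a `label` column.
#' @param variable column name to compare.
#' @param group grouping column (default `"label"`).
#' @return A list of class `group_comparison`: `variable`, `test_used`,
#'   `statistic`, `p_value`, `summaries` (per group), `fallback` flag.
#' @export
compare_groups <- function(table, variable, group = "label") {
  stopifnot(is.data.frame(table), variable %in% names(table),
            group %in% names(table))
  g <- as.character(table[[group]])
  lev <- sort(unique(g))
  if (length(lev) != 2L) stop("exactly two groups required")
  x <- table[[variable]]
  fallback <- FALSE
  if (!is.numeric(x)) {
    tab <- table(factor(x), factor(g))
    ht <- suppressWarnings(chisq.test(tab, correct = FALSE))
    summaries <- lapply(lev, function(l) table(factor(x[g == l])))
    names(summaries) <- lev
    test_used <- "chi_square"
    stat <- unname(ht$statistic)
    p <- ht$p.value
  } else {
    x1 <- x[g == lev[1]]
    x2 <- x[g == lev[2]]
    normal_ok <- function(v) {
      if (length(unique(v)) < 3L || length(v) < 3L) return(FALSE)
      shapiro.test(v)$p.value > 0.05
    }
    use_t <- normal_ok(x1) && normal_ok(x2)
    if (use_t && (sd(x1) == 0 || sd(x2) == 0)) {
      use_t <- FALSE
      fallback <- TRUE
    }
    if (use_t) {
      ht <- t.test(x1, x2, var.equal = TRUE)
      test_used <- "t_test"
      summaries <- lapply(list(x1, x2), function(v) c(mean = mean(v), sd = sd(v)))
    } else {
      ht <- suppressWarnings(wilcox.test(x1, x2))
      test_used <- "mann_whitney"
      summaries <- lapply(list(x1, x2), function(v) {
        c(median = median(v), q1 = unname(quantile(v, 0.25)),
          q3 = unname(quantile(v, 0.75)))
      })
    }
    names(summaries) <- lev
    stat <- unname(ht$statistic)
    p <- ht$p.value
  }
  structure(list(variable = variable, test_used = test_used,
                 statistic = stat, p_value = p, summaries = summaries,
                 fallback = fallback),
            class = "group_comparison")
}
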