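test_that("stratified split is disjoint, exhaustive, reproducible and near the target fraction", {
  tab <- generate_cohort_table(cohort_spec(n_benign = 41, n_malignant = 79,
                                           seed = 4))
  sp <- split_cohort(tab, 0.7, seed = 10)
  expect_equal(nrow(sp$training) + nrow(sp$test), 120)
  expect_length(intersect(sp$training$id, sp$test$id), 0)
  nb <- sum(sp$training$label == "benign")
  nm <- sum(sp$training$label == "malignant")
  expect_true(abs(nb - 0.7 * 41) <= 1)
  expect_true(abs(nm - 0.7 * 79) <= 1)
  sp2 <- split_cohort(tab, 0.7, seed = 10)
  expect_identical(sp$training$id, sp2$training$id)
  expect_error(split_cohort(tab, 1.0), "non-empty")
  one <- tab[c(1, 42, 43), ]
  expect_error(split_cohort(one, 0.7), "< 2 members")
})

test_that("group comparison picks the conventional test per variable type", {
  tab <- generate_cohort_table(cohort_spec(n_benign = 28, n_malignant = 56,
                                           seed = 6))
  expect_identical(compare_groups(tab, "adc")$test_used, "t_test")
  expect_identical(compare_groups(tab, "suvmax")$test_used, "mann_whitney")
  expect_identical(compare_groups(tab, "sex")$test_used, "chi_square")
  # identical balanced categories in both groups: chi-square p = 1
  even <- data.frame(label = rep(c("benign", "malignant"), each = 20),
                     smoking = rep(c("never", "always"), 20))
  expect_equal(compare_groups(even, "smoking")$p_value, 1)
  # degenerate variance falls back to the rank test
  dg <- data.frame(label = rep(c("benign", "malignant"), each = 10),
                   x = c(rep(1, 10), 2:11))
  cmp <- compare_groups(dg, "x")
  expect_identical(cmp$test_used, "mann_whitney")
})

test_that("ADC separates the groups with high power at cohort scale", {
  n_sig <- 0
  for (s in 1:100) {
    tab <- generate_cohort_table(cohort_spec(n_benign = 28, n_malignant = 56,
                                             seed = 600 + s))
    cmp <- compare_groups(tab, "adc")
    if (cmp$p_value < 0.001) n_sig <- n_sig + 1
  }
  expect_gte(n_sig, 95)
})

test_that("rank test on fully separated small samples equals the exact permutation value", {
  # a gross outlier fails the normality gate so the rank path is taken;
  # the groups remain fully separated
  x1 <- c(1, 1.1, 1.2, 1.3, 1.35, 1.4, 1.5, 8)
  x2 <- c(10, 11, 12, 13, 14, 15, 16, 17)
  tab <- data.frame(label = rep(c("benign", "malignant"), each = 8),
                    x = c(x1, x2))
  cmp <- compare_groups(tab, "x")
  expect_identical(cmp$test_used, "mann_whitney")
  expect_equal(unname(cmp$statistic), 0) # U = 0 for full separation
  expect_equal(cmp$p_value, 2 / choose(16, 8)) # exact two-sided enumeration
})

test_that("forward selection keeps a single strong predictor with a sensible OR", {
  set.seed(41)
  n <- 300
  x <- rnorm(n)
  y <- rbinom(n, 1, plogis(1.2 * x))
  tab <- data.frame(label = ifelse(y == 1, "malignant", "benign"), marker = x)
  m <- forward_logistic_selection(tab, "marker")
  expect_identical(m$predictors, "marker")
  expect_gt(m$or_table$or, 1) # positive coefficient, OR > 1
  expect_true(m$or_table$ci_low < m$or_table$or &
                m$or_table$or < m$or_table$ci_high)
  # a pure-noise candidate pool mostly yields an empty model
  empties <- 0
  for (s in 1:40) {
    set.seed(700 + s)
    nul <- data.frame(label = rep(c("benign", "malignant"), each = 100),
                      a = rnorm(200), b = rnorm(200))
    m0 <- forward_logistic_selection(nul, c("a", "b"))
    if (length(m0$predictors) == 0) empties <- empties + 1
  }
  expect_gte(empties / 40, 1 - 0.05 * 2 - 0.1) # (1 - 0.05 k) bound + slack
})

test_that("selection is invariant to affine rescaling of candidates", {
  tab <- generate_cohort_table(cohort_spec(n_benign = 100, n_malignant = 100,
                                           seed = 8))
  cands <- c("suvmax", "adc", "mtrasym_pct", "ddc")
  m1 <- forward_logistic_selection(tab, cands)
  tab2 <- tab
  tab2$adc <- tab2$adc * 1000 - 5
  tab2$suvmax <- tab2$suvmax / 7
  m2 <- forward_logistic_selection(tab2, cands)
  expect_identical(m1$predictors, m2$predictors)
  expect_equal(m1$coefficients, m2$coefficients, tolerance = 1e-6)
})

test_that("model prediction applies the logistic link with frozen training scaling", {
  model <- structure(list(
    predictors = c("u", "v"),
    coefficients = c("(Intercept)" = 0, u = 0.5, v = -0.5),
    scaling = list(u = c(mean = 0, sd = 1), v = c(mean = 0, sd = 1)),
    positive = "malignant", separation = FALSE), class = "spl_logistic")
  nd <- data.frame(u = c(1, 0, 10), v = c(1, 0, -10))
  p <- predict(model, nd)
  expect_equal(p[1], 0.5) # beta . x = 0
  expect_equal(p[2], 0.5)
  expect_equal(p[3], plogis(10), tolerance = 1e-12)
  # large coefficients drive probabilities to the feature-sign limits
  model$coefficients <- c("(Intercept)" = 0, u = 50, v = 0)
  expect_equal(predict(model, data.frame(u = c(-1, 1), v = 0)), c(0, 1),
               tolerance = 1e-6)
  expect_error(predict(model, data.frame(u = 1)), "missing feature 'v'")
})

test_that("empirical ROC matches brute-force pair counting and handles the null", {
  r <- roc_analysis(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1), direction = ">=")
  expect_equal(r$auc, 0.75) # 3 of 4 positive-negative pairs ordered
  # perfect separation
  rp <- roc_analysis(c(1, 2, 3, 10, 11, 12), rep(c(0, 1), each = 3),
                     direction = ">=")
  expect_equal(rp$auc, 1)
  expect_equal(rp$sens_at_cutoff, 1)
  expect_equal(rp$spec_at_cutoff, 1)
  # label-independent scores: AUC near 1/2
  set.seed(51)
  y <- rbinom(1000, 1, 0.5)
  rn <- roc_analysis(rnorm(1000), y, direction = ">=")
  expect_lt(abs(rn$auc - 0.5), 0.06)
  # oracle equality over 100 random samples, with and without ties
  set.seed(52)
  for (i in 1:100) {
    n <- sample(10:200, 1)
    yy <- rbinom(n, 1, 0.5)
    if (length(unique(yy)) < 2) next
    s <- rnorm(n) + yy
    if (i %% 2 == 0) s <- round(s) # tied scores
    expect_equal(roc_analysis(s, yy, direction = ">=")$auc,
                 brute_force_auc(s, yy), tolerance = 1e-12)
  }
  expect_error(roc_analysis(1:5, rep(1, 5)), "both classes")
})

test_that("ROC inference agrees with the pROC reference implementation", {
  skip_if_not_installed("pROC")
  set.seed(53)
  y <- rbinom(80, 1, 0.5)
  s <- rnorm(80) + 0.8 * y
  r <- roc_analysis(s, y, direction = ">=")
  ref <- pROC::roc(y, s, direction = "<", quiet = TRUE)
  expect_equal(r$auc, as.numeric(pROC::auc(ref)), tolerance = 1e-12)
  ci <- as.numeric(pROC::ci.auc(ref, method = "delong"))
  expect_equal(r$auc_ci[1], ci[1], tolerance = 1e-6)
  expect_equal(r$auc_ci[2], ci[3], tolerance = 1e-6)
  # Youden cutoff: same J as pROC's best threshold
  best <- pROC::coords(ref, "best", best.method = "youden",
                       ret = c("sensitivity", "specificity"))
  expect_equal(r$sens_at_cutoff + r$spec_at_cutoff,
               best$sensitivity[1] + best$specificity[1], tolerance = 1e-9)
})

test_that("DeLong test has the rank-invariance and zero-variance conventions", {
  set.seed(54)
  y <- rbinom(60, 1, 0.5)
  s <- rnorm(60) + y
  same <- delong_test(s, s, y, direction = ">=")
  expect_equal(same$z, 0)
  expect_equal(same$p_value, 1)
  # a monotone transform preserves the ordering: identical AUCs, Z = 0
  mono <- delong_test(s, exp(s / 2) + 5, y, direction = ">=")
  expect_equal(mono$auc_diff, 0)
  expect_equal(mono$z, 0)
  expect_equal(mono$p_value, 1)
})

test_that("DeLong agrees with pROC and with a paired-bootstrap variance", {
  skip_if_not_installed("pROC")
  set.seed(55)
  y <- rep(c(0, 1), c(15, 15))
  s1 <- rnorm(30) + 1.2 * y
  s2 <- 0.7 * s1 + 0.8 * rnorm(30) + 0.5 * y
  dt <- delong_test(s1, s2, y, direction = ">=")
  ref <- pROC::roc.test(pROC::roc(y, s1, direction = "<", quiet = TRUE),
                        pROC::roc(y, s2, direction = "<", quiet = TRUE),
                        method = "delong", paired = TRUE)
  expect_equal(dt$p_value, ref$p.value, tolerance = 1e-9)
  expect_equal(abs(dt$z), abs(unname(ref$statistic)), tolerance = 1e-9)
  # 10,000-replicate paired bootstrap of the AUC difference
  set.seed(56)
  pos <- which(y == 1)
  neg <- which(y == 0)
  d <- replicate(10000, {
    idx <- c(sample(neg, replace = TRUE), sample(pos, replace = TRUE))
    brute_force_auc(s1[idx], y[idx]) - brute_force_auc(s2[idx], y[idx])
  })
  expect_equal(dt$var_diff, var(d), tolerance = 0.1)
})

test_that("calibration curve recovers slope 1 for self-consistent probabilities", {
  set.seed(57)
  p <- plogis(rnorm(5000))
  yl <- rbinom(5000, 1, p)
  cal <- calibration_curve(p, yl, n_boot = 0)
  expect_true(cal$slope > 0.9 && cal$slope < 1.1)
  expect_equal(sum(cal$bins$n), 5000)
  expect_true(all(cal$bins$observed >= 0 & cal$bins$observed <= 1))
  # constant probabilities at the prevalence collapse to one merged bin
  cal2 <- calibration_curve(rep(0.5, 100), rbinom(100, 1, 0.5), n_boot = 0)
  expect_true("bins_merged" %in% cal2$flags)
  expect_equal(cal2$bins$predicted[1], 0.5)
  # degenerate 0/1 probabilities are clipped and flagged
  cal3 <- calibration_curve(c(rep(0, 10), rep(1, 10)), rep(c(0, 1), each = 10),
                            n_boot = 0)
  expect_true("degenerate_probabilities_clipped" %in% cal3$flags)
  # bootstrap-smoothed curve is reproducible given the seed
  c4 <- calibration_curve(p[1:500], yl[1:500], n_boot = 50, seed = 9)
  c5 <- calibration_curve(p[1:500], yl[1:500], n_boot = 50, seed = 9)
  expect_identical(c4$smoothed, c5$smoothed)
})

test_that("decision curve reproduces its closed forms", {
  set.seed(58)
  y <- rbinom(400, 1, 0.5)
  p <- plogis(rnorm(400) + y)
  dc <- decision_curve(p, y)
  expect_true(all(dc$curve$net_benefit_none == 0))
  # treat-all closed form at pt = 0.25 with prevalence pi
  pi_hat <- mean(y)
  row <- dc$curve[abs(dc$curve$threshold - 0.25) < 1e-9, ]
  expect_equal(row$net_benefit_all, pi_hat - (1 - pi_hat) * 0.25 / 0.75,
               tolerance = 1e-12)
  # perfect probabilities: model net benefit = prevalence at every threshold
  dcp <- decision_curve(as.numeric(y), y)
  expect_true(all(abs(dcp$curve$net_benefit_model - pi_hat) < 1e-12))
  expect_true(all(dcp$curve$net_benefit_model >=
                    pmax(dcp$curve$net_benefit_all, 0) - 1e-12))
  # pt = 1 never enters the grid
  expect_lt(max(dc$curve$threshold), 1)
})
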