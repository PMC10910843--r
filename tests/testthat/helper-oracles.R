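# Shared independent oracles used across test files.

# Brute-force AUC: fraction of correctly ordered positive-negative pairs,
# half credit for ties.
brute_force_auc <- function(scores, labels) {
  X <- scores[labels == 1]
  Y <- scores[labels == 0]
  mean(outer(X, Y, function(x, y) (x > y) + 0.5 * (x == y)))
}

# Profiled-S0 grid search for the stretched-exponential fit: for every
# (DDC, alpha) grid point the optimal S0 is linear, so the grid gives the
# global optimum of the reduced 2-D problem up to grid resolution.
sem_grid_best_sse <- function(b, s, n_grid = 200) {
  dg <- exp(seq(log(1e-6), log(1e-2), length.out = n_grid))
  ag <- seq(0.01, 1, length.out = n_grid)
  best <- Inf
  for (a in ag) {
    E <- exp(-outer(dg, b)^a)
    s0 <- (E %*% s) / rowSums(E^2)
    sse <- rowSums((matrix(s, n_grid, length(b), byrow = TRUE) -
                      as.vector(s0) * E)^2)
    best <- min(best, min(sse))
  }
  best
}

# The combined-model fit used in workflow-level tests: forward-LR over the
# full candidate roster, as the clinical workflow prescribes.
full_candidate_roster <- function() {
  c("age", "sex", "smoking", "diameter_mm",
    "suvmax", "mtv_ml", "tlg_g", "adc", "ddc", "alpha", "mtrasym_pct")
}
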