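test_that("DWI phantom signals follow the diffusion models exactly when noiseless", {
  b <- protocol_bvalues()
  spec <- dwi_phantom_spec(grid_shape = c(2, 2, 1), true_adc_map = 1.5e-3,
                           true_ddc_map = 3.00e-3, true_alpha_map = 0.48,
                           s0_map = 1000, snr = Inf)
  mem <- generate_dwi_phantom(spec, "mem")
  # direct scalar evaluation of the mono-exponential law
  expect_equal(mem$signal[1, 1, 1, which(b == 1000)], 1000 * exp(-1.5),
               tolerance = 1e-12)
  sem <- generate_dwi_phantom(spec, "sem")
  # hand evaluation of the stretched-exponential law at b = 800
  expect_equal(sem$signal[1, 1, 1, which(b == 800)],
               1000 * exp(-(800 * 3.00e-3)^0.48), tolerance = 1e-12)
  # noiseless decay is monotone non-increasing in b at every voxel
  sig <- matrix(sem$signal, 4)
  expect_true(all(apply(sig, 1, function(v) all(diff(v) <= 0))))
})

test_that("SEM phantom at alpha = 1 is bit-identical to MEM phantom with ADC = DDC", {
  spec <- dwi_phantom_spec(grid_shape = c(4, 4, 2), true_adc_map = 1.5e-3,
                           true_ddc_map = 1.5e-3, true_alpha_map = 1,
                           snr = 40, seed = 7)
  expect_identical(generate_dwi_phantom(spec, "sem")$signal,
                   generate_dwi_phantom(spec, "mem")$signal)
  # and the draw is deterministic given the seed
  expect_identical(generate_dwi_phantom(spec, "sem")$signal,
                   generate_dwi_phantom(spec, "sem")$signal)
})

test_that("Rician noise has the magnitude-MRI moments", {
  # high-SNR limit: mean converges to the noiseless signal
  spec <- dwi_phantom_spec(grid_shape = c(100, 100, 1), b_values = c(0, 500),
                           true_adc_map = 1e-3, s0_map = 1000, snr = 100,
                           seed = 3)
  ph <- generate_dwi_phantom(spec, "mem")
  expect_equal(mean(ph$signal[, , 1, 2]), 1000 * exp(-0.5), tolerance = 1e-2)
  # zero-signal limit: mean converges to sigma * sqrt(pi / 2)
  spec0 <- dwi_phantom_spec(grid_shape = c(100, 100, 1), b_values = c(0, 1000),
                            true_adc_map = 0.05, s0_map = 1000, snr = 20,
                            seed = 4)
  ph0 <- generate_dwi_phantom(spec0, "mem") # signal at b=1000 ~ 2e-19
  sigma <- 1000 / 20
  expect_equal(mean(ph0$signal[, , 1, 2]), sigma * sqrt(pi / 2),
               tolerance = 0.01)
})

test_that("phantom specs reject invalid inputs with informative errors", {
  expect_error(dwi_phantom_spec(b_values = c(0, 100, 100)), "increasing")
  expect_error(dwi_phantom_spec(true_alpha_map = 1.2), "alpha")
  expect_error(dwi_phantom_spec(true_ddc_map = -1e-3), "> 0")
  expect_error(zspectrum_phantom_spec(offsets_ppm = seq(-2, 2, 0.5)), "3.5")
  expect_error(pet_phantom_spec(lesion_radius_mm = 100), "outside")
  expect_error(pet_phantom_spec(lesion_suv = 1, background_suv = 2),
               "lesion_suv")
})

test_that("z-spectrum phantom has symmetric-pool MTRasym of zero and bounded values", {
  spec <- zspectrum_phantom_spec(amide_pool = c(0, 3.5, 1.5),
                                 b0_shift_ppm = 0.4)
  expect_equal(true_mtrasym(spec), 0)
  ph <- generate_zspectrum_phantom(spec)
  expect_true(all(ph$spectrum$s_sat >= 0 & ph$spectrum$s_sat <= ph$spectrum$s0))
  # a narrow amide pool's analytic asymmetry is approximately its amplitude
  spec2 <- zspectrum_phantom_spec(amide_pool = c(0.02, 3.5, 0.4))
  expect_equal(true_mtrasym(spec2), 2.0, tolerance = 1e-2)
  # amplitude calibration inverts the analytic asymmetry exactly
  amp <- amide_amplitude_for_mtrasym(2.58, width = 1.5)
  spec3 <- zspectrum_phantom_spec(amide_pool = c(amp, 3.5, 1.5))
  expect_equal(true_mtrasym(spec3), 2.58, tolerance = 1e-12)
  # the analytic value is invariant to the simulated B0 shift
  spec4 <- zspectrum_phantom_spec(amide_pool = c(amp, 3.5, 1.5),
                                  b0_shift_ppm = 0.3)
  expect_equal(true_mtrasym(spec4), true_mtrasym(spec3))
})

test_that("PET sphere phantom matches its analytic volume", {
  # r = 12.4 mm: analytic volume ~ 7.99 ml, the scale of a median lesion
  spec <- pet_phantom_spec(lesion_radius_mm = 12.4)
  expect_equal(spec$lesion_radius_mm^3 * 4 / 3 * pi / 1000, 7.986, # nolint
               tolerance = 1e-3)
  ph <- generate_pet_phantom(pet_phantom_spec(lesion_radius_mm = 15,
                                              background_suv = 0, noise_sd = 0))
  # brute-force voxel-centre count agrees with the analytic volume within 5%
  vox_ml <- prod(ph$volume$voxel_size_mm) / 1000
  expect_equal(sum(ph$lesion_mask) * vox_ml, ph$analytic_volume_ml,
               tolerance = 0.05)
  # noiseless, zero background: every nonzero voxel equals lesion_suv
  expect_true(all(ph$volume$suv[ph$volume$suv > 0] == 10))
})

test_that("cohort generator reproduces sizes, degenerate specs and medians", {
  tab <- generate_cohort_table(cohort_spec(n_benign = 28, n_malignant = 56,
                                           seed = 1))
  expect_equal(nrow(tab), 84)
  expect_equal(sum(tab$label == "benign"), 28)
  # reproducibility
  tab2 <- generate_cohort_table(cohort_spec(n_benign = 28, n_malignant = 56,
                                            seed = 1))
  expect_identical(tab, tab2)
  # zero-scale marginals collapse each group onto its location
  pars <- default_parameter_table()
  pars$adc <- list(benign = marginal_normal(1.79, 0),
                   malignant = marginal_normal(1.42, 0))
  tabz <- generate_cohort_table(cohort_spec(n_benign = 5, n_malignant = 5,
                                            parameters = pars, seed = 2))
  expect_true(all(tabz$adc[tabz$label == "benign"] == 1.79))
  expect_true(all(tabz$adc[tabz$label == "malignant"] == 1.42))
  # large-sample medians converge to the specified group medians
  big <- generate_cohort_table(cohort_spec(n_benign = 1e5, n_malignant = 1e5,
                                           seed = 3))
  expect_equal(median(big$suvmax[big$label == "malignant"]), 9.63,
               tolerance = 0.02)
  expect_equal(median(big$ddc[big$label == "benign"]), 3.00, tolerance = 0.02)
  expect_equal(mean(big$adc[big$label == "benign"]), 1.79, tolerance = 0.01)
})

test_that("cohort latent correlation converges to the specified matrix", {
  R <- default_correlation_matrix()
  big <- generate_cohort_table(cohort_spec(n_benign = 2e4, n_malignant = 2e4,
                                           seed = 9))
  pars <- cohort_parameter_names <- c("suvmax", "mtv_ml", "tlg_g", "adc",
                                      "ddc", "alpha", "mtrasym_pct")
  g <- big[big$label == "malignant", pars]
  # Spearman rank correlation is invariant to the monotone marginal
  # transforms; convert to the latent Pearson scale for a Gaussian copula
  rs <- stats::cor(g, method = "spearman")
  latent <- 2 * sin(pi * rs / 6)
  expect_lt(norm(latent - R, "F"), 0.15)
  small <- generate_cohort_table(cohort_spec(n_benign = 500, n_malignant = 500,
                                             seed = 9))
  gs <- small[small$label == "malignant", pars]
  latent_small <- 2 * sin(pi * stats::cor(gs, method = "spearman") / 6)
  expect_lt(norm(latent - R, "F"), norm(latent_small - R, "F"))
})

test_that("invalid correlation matrices are rejected", {
  R <- default_correlation_matrix()
  R[1, 2] <- 0.9 # asymmetric
  expect_error(cohort_spec(correlation = R), "symmetric")
  R <- diag(7)
  dimnames(R) <- list(cohort_names <- c("suvmax", "mtv_ml", "tlg_g", "adc",
                                        "ddc", "alpha", "mtrasym_pct"),
                      cohort_names)
  R["suvmax", "adc"] <- R["adc", "suvmax"] <- 1
  R["suvmax", "ddc"] <- R["ddc", "suvmax"] <- 1
  R["adc", "ddc"] <- R["ddc", "adc"] <- -1 # not PSD
  expect_error(cohort_spec(correlation = R), "semi-definite")
})

test_that("seed streams are independent of generator ordering", {
  s1 <- derive_seed(42, "dwi_noise")
  s2 <- derive_seed(42, "cohort")
  expect_true(s1 != s2)
  expect_identical(derive_seed(42, "dwi_noise"), s1)
  # generating another phantom in between does not perturb a stream
  a <- generate_dwi_phantom(dwi_phantom_spec(snr = 30, seed = 5))
  invisible(generate_cohort_table(cohort_spec(n_benign = 5, n_malignant = 5,
                                              seed = 5)))
  b <- generate_dwi_phantom(dwi_phantom_spec(snr = 30, seed = 5))
  expect_identical(a$signal, b$signal)
})
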