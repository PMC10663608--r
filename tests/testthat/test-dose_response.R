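test_that("compute_ratios divides channels and validates the denominator", {
  rec <- data.frame(vesicle_id = c("a", "b"),
                    receptor_fluor = c(100, 100),
                    antibody_fluor = c(50, 0))
  expect_equal(compute_ratios(rec), c(0.5, 0))
  rec$receptor_fluor[2] <- 0
  expect_error(compute_ratios(rec), "b")
})

test_that("constitutive estimate is the zero-ligand mean with its SEM", {
  rec <- data.frame(vesicle_id = letters[1:5],
                    ligand_conc_nM = c(0, 0, 0, 10, 10),
                    receptor_fluor = 1,
                    antibody_fluor = c(0.2, 0.2, 0.2, 0.9, 1.1))
  e0 <- estimate_constitutive(rec)
  expect_equal(e0$E0, 0.2)
  expect_equal(e0$se, 0)
  expect_equal(e0$n, 3)

  # sampling check against a configured offset
  cfg <- generative_config(ligand_concentrations = c(0, 10),
                           vesicles_per_concentration = 500,
                           E0 = 0.2, seed = 3)
  est <- estimate_constitutive(simulate_dose_response(cfg))
  expect_lt(abs(est$E0 - 0.2), 3 * est$se)

  rec_nz <- rec[rec$ligand_conc_nM > 0, ]
  expect_error(estimate_constitutive(rec_nz), "zero-ligand")
})

test_that("fit_hill recovers exact model data and flags degeneracies", {
  L <- c(0.1, 1, 10, 100, 1000)
  fit <- fit_hill(L, 1 * L / (L + 10), e0_mode = "none")
  expect_true(fit$converged)
  expect_equal(fit$E_top, 1, tolerance = 1e-6)
  expect_equal(fit$EC50, 10, tolerance = 1e-6)
  expect_identical(fit$hill_slope, 1)

  flat <- fit_hill(L, rep(0, 5), e0_mode = "none")
  expect_equal(flat$E_top, 0)
  expect_false(flat$ec50_identifiable)

  expect_error(fit_hill(c(1, 10), c(0.1, 0.5), e0_mode = "none"),
               "3 distinct positive")
})

test_that("fit_hill matches a grid-search SSE oracle on noisy data", {
  # generative world chosen so E_top = 0.8, EC50 = 5 nM
  cfg <- generative_config(K_L = 15, K_resp = 0.5, R_max = 1.2, E0 = 0.15,
                           cv_antibody = 0.2,
                           ligand_concentrations = c(0, 0.5, 1.5, 5, 15, 50, 500),
                           vesicles_per_concentration = 200, seed = 11)
  tab <- simulate_dose_response(cfg)
  corrected <- compute_ratios(tab) - estimate_constitutive(tab)$E0
  fit <- fit_hill(tab$ligand_conc_nM, corrected, e0_mode = "none")
  oracle <- grid_search_hill(tab$ligand_conc_nM, corrected)
  expect_equal(fit$E_top, oracle$top, tolerance = 5e-4)
  expect_equal(fit$EC50, oracle$half, tolerance = 5e-4)
  # and the fit sits near the generative truth
  expect_lt(abs(fit$E_top - 0.8), 4 * fit$E_top_se)
  expect_lt(abs(fit$EC50 - 5), 4 * fit$EC50_se)
})

test_that("fit_hill is invariant to record order and supports free/supplied E0", {
  cfg <- quick_config(seed = 21)
  tab <- simulate_dose_response(cfg)
  f1 <- fit_hill(tab)
  f2 <- fit_hill(tab[rev(seq_len(nrow(tab))), ])
  expect_equal(f1$E_top, f2$E_top, tolerance = 1e-9)
  expect_equal(f1$EC50, f2$EC50, tolerance = 1e-9)

  ffree <- fit_hill(tab, e0_mode = "free")
  expect_true(ffree$converged)
  expect_lt(abs(ffree$E0 - cfg$E0), 4 * max(ffree$E0_se, 1e-3))

  fsup <- fit_hill(tab, E0 = cfg$E0)
  expect_lt(abs(fsup$E_top - f1$E_top), 0.05)
})

test_that("corrected response at zero ligand has mean 0 within its SEM", {
  cfg <- quick_config(seed = 31, vesicles_per_concentration = 300)
  tab <- simulate_dose_response(cfg)
  e0 <- estimate_constitutive(tab)
  corrected <- compute_ratios(tab) - e0$E0
  z <- corrected[tab$ligand_conc_nM == 0]
  expect_lt(abs(mean(z)), 1e-12)  # exact: E0 is that group's mean
})

test_that("per-concentration aggregation computes mean/SEM/n", {
  rec <- data.frame(vesicle_id = as.character(1:4),
                    ligand_conc_nM = c(1, 1, 1, 5),
                    receptor_fluor = 1,
                    antibody_fluor = c(1, 2, 3, 7))
  agg <- aggregate_dose_response(rec)
  expect_equal(agg$mean_ratio, c(2, 7))
  expect_equal(agg$sem_ratio[1], sd(c(1, 2, 3)) / sqrt(3))
  expect_equal(agg$sem_ratio[2], 0)  # n = 1 convention
  expect_equal(agg$n_vesicles, c(3L, 1L))

  cfg <- quick_config(cv_antibody = 0)
  agg2 <- aggregate_dose_response(simulate_dose_response(cfg))
  expect_equal(agg2$mean_ratio, true_ratio(cfg, agg2$ligand_conc_nM),
               tolerance = 1e-12)
})

test_that("operational-model algebra: tau <-> (E_top, EC50) round trip", {
  p <- etop_ec50_from_tau(1, 10, 1)
  expect_equal(p$E_top, 0.5)
  expect_equal(p$EC50, 5)

  lim <- etop_ec50_from_tau(1e9, 10, 1)
  expect_equal(lim$E_top, 1, tolerance = 1e-8)
  expect_lt(lim$EC50, 1e-7)

  set.seed(4)
  tau <- 10^runif(50, -2, 2); K_L <- 10^runif(50, -1, 3); R_max <- runif(50, 0.1, 2)
  h <- etop_ec50_from_tau(tau, K_L, R_max)
  t1 <- tau_from_hill(E_top = h$E_top, R_max = R_max, via = "etop")
  t2 <- tau_from_hill(EC50 = h$EC50, K_L = K_L, via = "ec50")
  expect_equal(t1, tau, tolerance = 1e-9)
  expect_equal(t2, tau, tolerance = 1e-9)
  # E_top/R_max = 1/(1+K_resp) with K_resp = 1/tau (efficiency identity)
  expect_equal(h$E_top / R_max, 1 / (1 + 1 / tau), tolerance = 1e-12)

  expect_error(etop_ec50_from_tau(-1, 10, 1), "> 0")
})

test_that("fret_unmix subtracts bleed-through linearly", {
  expect_equal(fret_unmix(0.33 * 100 + 0.07 * 50, 100, 50), 0)
  expect_equal(fret_unmix(40, 100, 0), 7)
  expect_equal(fret_unmix(0, 0, 0), 0)
  expect_error(fret_unmix(1, 1, 1, donor_bleed = -0.1), ">= 0")
})
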