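test_that("beta_lig: self-comparison, direct substitution, gain cancellation", {
  mc <- fast_mc()
  fA <- fit_from_params(1, 1); fB <- fit_from_params(1, 10)

  self <- beta_lig(fA, fB, fA, fB, settings = mc)
  expect_equal(self$value, 0)

  ref <- fit_from_params(1, 1)
  b <- beta_lig(fA, fB, ref, ref, settings = mc)  # EC50,B tenfold in lig only
  expect_equal(b$value, 1)
  expect_gt(b$se, 0)

  # multiplying E_top,A by the same constant in lig and ref leaves beta unchanged
  gain <- 3.7
  fA_g <- fit_from_params(gain * 1, 1)
  ref_gA <- fit_from_params(gain * 1, 1)
  b_g <- beta_lig(fA_g, fB, ref_gA, ref, settings = mc)
  expect_equal(b_g$value, b$value, tolerance = 1e-12)
})

test_that("beta_mut: direct substitution and antisymmetry", {
  mc <- fast_mc()
  wtA <- fit_from_params(1, 2); wtB <- fit_from_params(0.5, 8)
  mutA <- fit_from_params(1, 4)  # EC50,A doubled only

  same <- beta_mut(wtA, wtB, wtA, wtB, settings = mc)
  expect_equal(same$value, 0)

  b <- beta_mut(mutA, wtB, wtA, wtB, settings = mc)
  expect_equal(b$value, -log10(2), tolerance = 1e-12)

  swapped <- beta_mut(wtB, mutA, wtB, wtA, settings = mc,
                      response_A = "Y1173", response_B = "Y1068")
  expect_equal(swapped$value, -b$value, tolerance = 1e-12)
})

test_that("bias is undefined for unusable fits", {
  mc <- fast_mc()
  good <- fit_from_params(1, 1)
  bad <- fit_from_params(0, 1)
  expect_error(beta_lig(bad, good, good, good, settings = mc), "nonpositive")
  nc <- fit_from_params(1, 1); nc$converged <- FALSE
  expect_error(beta_lig(nc, good, good, good, settings = mc), "converge")
})

test_that("absolute coefficient from transducer constants", {
  b <- beta_star_from_kresp(0.40, 0.86, ligand = "rho-mEGF")
  expect_equal(round(b$value, 2), 0.33)
  expect_gt(b$value, 0)  # response A (Y1068) preferred

  expect_equal(beta_star_from_kresp(0.5, 0.5)$value, 0)
  expect_equal(beta_star_from_kresp(0.86, 0.40)$value,
               -beta_star_from_kresp(0.40, 0.86)$value)
  expect_error(beta_star_from_kresp(-1, 1), "> 0")
})

test_that("transfer onto the absolute scale adds the reference coefficient", {
  mc <- fast_mc()
  bstar_ref <- beta_star_from_kresp(0.40, 0.86, se_A = 0.03, se_B = 0.08,
                                    ligand = "rho-mEGF", settings = mc)

  # unbiased ligand inherits the reference's absolute coefficient
  rel0 <- bias_coefficient(0, 0.02, "ligand", "Y1068", "Y1173",
                           "EGF", "rho-mEGF")
  t0 <- beta_star_transfer(rel0, bstar_ref, settings = mc)
  expect_equal(t0$value, bstar_ref$value)

  relh <- bias_coefficient(0.5, 0.02, "ligand", "Y1068", "Y1173",
                           "TGFa", "rho-mEGF")
  ref0 <- beta_star_from_kresp(1, 1, ligand = "rho-mEGF", settings = mc)
  expect_equal(beta_star_transfer(relh, ref0, settings = mc)$value, 0.5)

  # metadata guard: relative coefficient must point at the supplied reference
  rel_bad <- bias_coefficient(0.1, 0.02, "ligand", "Y1068", "Y1173",
                              "TGFa", "EGF")
  expect_error(beta_star_transfer(rel_bad, bstar_ref, settings = mc),
               "reference mismatch")
})

test_that("transfer route agrees with direct K_resp route on simulated data", {
  # two ligands with known transducer constants; relative bias from Hill
  # fits chained through the reference's absolute coefficient must land on
  # log10(K_B/K_A) of the test ligand (Eq.-19-style identity on data).
  mc <- fast_mc()
  make_fits <- function(K_A, K_B, seed) {
    cfgA <- generative_config(K_resp = K_A, R_max = 1, seed = seed,
                              vesicles_per_concentration = 150)
    cfgB <- generative_config(K_resp = K_B, R_max = 0.5, seed = seed + 1,
                              vesicles_per_concentration = 150)
    list(A = fit_hill(simulate_dose_response(cfgA, py_site = "Y1068")),
         B = fit_hill(simulate_dose_response(cfgB, py_site = "Y1173")))
  }
  test_k <- c(A = 0.3, B = 0.9); ref_k <- c(A = 0.4, B = 0.86)
  ft <- make_fits(test_k["A"], test_k["B"], 51)
  fr <- make_fits(ref_k["A"], ref_k["B"], 61)
  rel <- beta_lig(ft$A, ft$B, fr$A, fr$B, ligand = "LigX", reference = "Ref",
                  settings = mc)
  bstar_ref <- beta_star_from_kresp(ref_k["A"], ref_k["B"], 0.02, 0.05,
                                    ligand = "Ref", settings = mc)
  chained <- beta_star_transfer(rel, bstar_ref, settings = mc)
  direct <- log10(test_k["B"] / test_k["A"])
  expect_lt(abs(chained$value - direct), 3 * chained$se)
})

test_that("tau route equals the Hill-parameter route exactly", {
  expect_equal(beta_from_tau(1, 1, 1, 1), 0)
  expect_equal(beta_from_tau(10, 1, 1, 1), 1)
  expect_error(beta_from_tau(0, 1, 1, 1), "> 0")

  set.seed(8)
  n <- 200
  tauA_l <- 10^runif(n, -2, 2); tauB_l <- 10^runif(n, -2, 2)
  tauA_r <- 10^runif(n, -2, 2); tauB_r <- 10^runif(n, -2, 2)
  K_L <- 10^runif(n, -1, 3)
  RmA <- runif(n, 0.1, 2); RmB <- runif(n, 0.1, 2)
  hAl <- etop_ec50_from_tau(tauA_l, K_L, RmA)
  hBl <- etop_ec50_from_tau(tauB_l, K_L, RmB)
  hAr <- etop_ec50_from_tau(tauA_r, K_L, RmA)
  hBr <- etop_ec50_from_tau(tauB_r, K_L, RmB)
  via_hill <- (log10(hAl$E_top) - log10(hAl$EC50) -
               log10(hBl$E_top) + log10(hBl$EC50)) -
              (log10(hAr$E_top) - log10(hAr$EC50) -
               log10(hBr$E_top) + log10(hBr$EC50))
  via_tau <- beta_from_tau(tauA_l, tauB_l, tauA_r, tauB_r)
  expect_lt(max(abs(via_hill - via_tau)), 1e-10)
})

test_that("log additivity: reference chaining is exact", {
  mc <- fast_mc()
  f1A <- fit_from_params(1.0, 2); f1B <- fit_from_params(0.4, 9)
  f2A <- fit_from_params(0.8, 3); f2B <- fit_from_params(0.5, 6)
  f3A <- fit_from_params(0.6, 5); f3B <- fit_from_params(0.7, 4)
  b13 <- beta_lig(f1A, f1B, f3A, f3B, settings = mc)$value
  b12 <- beta_lig(f1A, f1B, f2A, f2B, settings = mc)$value
  b23 <- beta_lig(f2A, f2B, f3A, f3B, settings = mc)$value
  expect_equal(b13, b12 + b23, tolerance = 1e-12)
})

test_that("bias_plot pairs shared concentrations and reports the rest", {
  pA <- data.frame(ligand_conc_nM = c(1, 10), mean_ratio = c(0.2, 0.5),
                   sem_ratio = c(0.01, 0.02), n_vesicles = c(5L, 5L))
  pB <- data.frame(ligand_conc_nM = c(1, 10), mean_ratio = c(0.1, 0.4),
                   sem_ratio = c(0.01, 0.02), n_vesicles = c(4L, 6L))
  bp <- bias_plot(pA, pB)
  expect_equal(bp$mean_A, c(0.2, 0.5))
  expect_equal(bp$mean_B, c(0.1, 0.4))

  ident <- bias_plot(pA, pA)
  expect_equal(ident$mean_A, ident$mean_B)

  pC <- data.frame(ligand_conc_nM = c(3, 30), mean_ratio = c(0.1, 0.4),
                   sem_ratio = 0, n_vesicles = 2L)
  expect_error(bias_plot(pA, pC), "available")
})

test_that("unbiased ligands give overlapping bias curves within SEM", {
  cfgA1 <- quick_config(seed = 71, vesicles_per_concentration = 200)
  cfgB1 <- quick_config(seed = 72, K_resp = 0.86, R_max = 0.39,
                        vesicles_per_concentration = 200)
  cfgA2 <- quick_config(seed = 73, vesicles_per_concentration = 200)
  cfgB2 <- quick_config(seed = 74, K_resp = 0.86, R_max = 0.39,
                        vesicles_per_concentration = 200)
  bp1 <- bias_plot(aggregate_dose_response(simulate_dose_response(cfgA1)),
                   aggregate_dose_response(simulate_dose_response(cfgB1)))
  bp2 <- bias_plot(aggregate_dose_response(simulate_dose_response(cfgA2)),
                   aggregate_dose_response(simulate_dose_response(cfgB2)))
  dz <- (bp1$mean_B - bp2$mean_B) /
    sqrt(bp1$sem_B^2 + bp2$sem_B^2)
  expect_true(all(abs(dz) < 4))
})
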