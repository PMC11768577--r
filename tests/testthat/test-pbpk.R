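ref_phys <- scale_physiology(reference_subject())

test_that("zero dose gives an all-zero profile", {
  prof <- simulate_pbpk(ref_phys,
                        regimen = dose_regimen(dose_amount = 1e-12),
                        t_grid = seq(0, 24, 0.5))
  expect_lt(max(prof$plasma_conc), 1e-6)
})

test_that("mass balance holds below 1e-6 across randomized subjects", {
  coh <- sample_cohort(default_cohort_spec(seed = 21))
  for (i in c(2, 17, 33)) {
    prof <- simulate_pbpk(scale_physiology(coh[i, ]),
                          t_grid = seq(0, 24, 0.5))
    expect_lt(mass_balance(prof), 1e-6)
  }
  # zero-clearance compound never eliminates anything
  cmp0 <- salbutamol_compound()
  cmp0$hepatic_clearance <- 1e-9; cmp0$renal_clearance <- 0
  prof0 <- simulate_pbpk(ref_phys, compound = cmp0,
                         regimen = dose_regimen(n_doses = 1),
                         t_grid = seq(0, 24, 0.5))
  expect_lt(max(prof0$cumulative_eliminated), 1e-3)
  expect_lt(mass_balance(prof0), 1e-6)
})

test_that("kinetics are linear: doubling the dose doubles the profile", {
  p1 <- simulate_pbpk(ref_phys, regimen = dose_regimen(dose_amount = 4),
                      t_grid = seq(0, 24, 0.5))
  p2 <- simulate_pbpk(ref_phys, regimen = dose_regimen(dose_amount = 8),
                      t_grid = seq(0, 24, 0.5))
  expect_lt(max(abs(p2$plasma_conc - 2 * p1$plasma_conc)) /
              max(p1$plasma_conc), 1e-6)
})

test_that("IV-bolus clearance identity: AUC = dose / (CLh + CLr)", {
  cmp <- salbutamol_compound()
  grid <- sort(unique(c(seq(0, 0.02, 1e-4), seq(0.02, 0.5, 0.002),
                        seq(0.5, 96, 0.05))))
  prof <- simulate_pbpk(ref_phys, regimen = dose_regimen(n_doses = 1),
                        t_grid = grid, route = "iv_bolus")
  auc <- auc_trapezoid(prof$times, prof$plasma_conc)   # ug.h/L
  want <- 4000 / (cmp$hepatic_clearance + cmp$renal_clearance)
  expect_lt(abs(auc - want) / want, 0.01)
})

test_that("steady-state clearance from repeated IV dosing", {
  cmp <- salbutamol_compound()
  # dense output right after the dose resolves the venous mixing spike
  grid <- sort(unique(c(seq(0, 114, 0.05), seq(108, 108.1, 1e-4),
                        seq(108, 114, 0.005))))
  prof <- simulate_pbpk(ref_phys,
                        regimen = dose_regimen(interval = 6, n_doses = 20),
                        t_grid = grid, route = "iv_bolus")
  sel <- prof$times >= 108 & prof$times <= 114
  auc_ss <- auc_trapezoid(prof$times[sel], prof$plasma_conc[sel])
  cl <- 4000 / auc_ss
  expect_lt(abs(cl - (cmp$hepatic_clearance + cmp$renal_clearance)) /
              (cmp$hepatic_clearance + cmp$renal_clearance), 0.02)
})

test_that("CAT absorption: Peff limits, fraction absorbed, radius effect", {
  cmp <- salbutamol_compound()
  cmp0 <- cmp; cmp0$effective_permeability <- 0
  expect_equal(cat_absorption_state(cmp0)$fa, 0)
  fa <- cat_absorption_state(cmp)$fa
  expect_lt(fold_error(0.852, fa)$raw, 2)      # within 2-fold of 85.2%
  # doubling the radii strictly decreases absorption
  fa2 <- cat_absorption_state(cmp, r_si = 3, r_colon = 5)$fa
  expect_lt(fa2, fa)
  # simulated cumulative absorption matches the analytic chain value
  prof <- simulate_pbpk(ref_phys, regimen = dose_regimen(n_doses = 1),
                        t_grid = seq(0, 96, 0.25))
  expect_equal(max(prof$cumulative_absorbed) / 4000, fa, tolerance = 1e-3)
  expect_error(cat_absorption_state(cmp, regimen = structure(
    list(route = "iv"), class = "dose_regimen")), "oral")
  # calibration mode hits a target exactly
  s <- calibrate_cat_peff(0.852)
  expect_equal(cat_absorption_state(cmp, peff_scale = s)$fa, 0.852,
               tolerance = 1e-6)
})

test_that("single-dose validation against reference exposure and half-life", {
  prof <- simulate_pbpk(ref_phys, regimen = dose_regimen(n_doses = 1),
                        t_grid = seq(0, 48, 0.25))
  res <- nca_summary(prof$times, prof$plasma_conc / 1000, dose = 4)
  expect_lt(fold_error(0.0318, res$auc_inf)$raw, 2)   # ug.h/mL, 2-fold rule
  expect_lt(fold_error(2.78, res$t_half)$raw, 2)
  expect_lt(fold_error(3.36, res$t_half)$raw, 2)
})

test_that("halving integrator tolerance does not worsen mass balance", {
  p_loose <- simulate_pbpk(ref_phys, t_grid = seq(0, 24, 0.5), rtol = 1e-6,
                           atol = 1e-8)
  p_tight <- simulate_pbpk(ref_phys, t_grid = seq(0, 24, 0.5), rtol = 1e-10,
                           atol = 1e-12)
  expect_lte(mass_balance(p_tight), mass_balance(p_loose) + 1e-12)
})

test_that("observation sampling interpolates, flags LLOQ, reproduces noise", {
  prof <- simulate_pbpk(ref_phys, t_grid = seq(0, 24, 0.25))
  obs <- sample_observations(prof, prof$times)
  expect_equal(obs$conc, prof$plasma_conc)
  expect_error(sample_observations(prof, c(1, 30)), "span")
  lq <- sample_observations(prof, c(0.25, 12), lloq = 1e9)
  expect_true(all(lq$below_lloq))
  expect_equal(nrow(lq), 2)                      # flagged, not dropped
  n1 <- sample_observations(prof, c(2, 6, 10), noise = list(a = 1, b = 0.1),
                            seed = 3)
  n2 <- sample_observations(prof, c(2, 6, 10), noise = list(a = 1, b = 0.1),
                            seed = 3)
  expect_identical(n1, n2)
})

test_that("the 40-subject dataset emulates the study design", {
  coh <- sample_cohort(default_cohort_spec(seed = 1))
  ds <- pbpk_dataset(coh[1:3, ])
  expect_equal(sum(ds$EVID == 0), 3 * 21)
  expect_equal(sum(ds$EVID == 1), 3 * 4)        # 4 mg q6h over 24 h
  expect_equal(unique(ds$TIME[ds$EVID == 1]), c(0, 6, 12, 18))
  expect_true(all(ds$DV[ds$EVID == 0] >= 0))
  expect_true(all(c("AGE", "WT", "BSA", "SEX", "RACE", "HEALTH",
                    "CYP2D6", "CYP2C19") %in% names(ds)))
})
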