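# reference model for estimator checks, with distinct absorption /
# distribution / elimination time scales
est_theta <- c(Mtt = 2, Ktr = 1.5, ka = 3, Cl = 20, V1 = 30, Q = 10, V2 = 80)

test_that("noiseless homogeneous data recovers the fixed effects closely", {
  pop0 <- population_model(est_theta, omega = rep(0, 7),
                           error = c(a = 1e-7, b = 1e-5))
  ds <- simulate_dataset(pop0,
                         list(covariates = data.frame(ID = 1:6),
                              schedule = default_schedule(),
                              regimen = dose_regimen()),
                         seed = 3)
  st <- quick_settings(k1 = 100, k2 = 80)
  # estimator consistency from a perturbed user-supplied start: the
  # global transit/absorption exchange ambiguity is a separate concern,
  # handled by the initialization tie-break
  init <- population_model(est_theta * c(1.3, 0.8, 1.25, 1.1, 0.85, 1.3, 0.8),
                           omega = 0.3 * est_theta,
                           error = c(a = 1e-4, b = 0.1))
  fit <- saem_fit(ds, init = init, settings = st, seed = 8)
  for (p in c("Mtt", "Ktr", "ka", "Cl", "V1")) {
    expect_lt(abs(fit$model$theta[[p]] / est_theta[[p]] - 1), 0.02)
  }
  # residual error collapses toward zero, omegas decay toward zero
  # (geometric annealing: small but nonzero at a finite budget)
  expect_lt(fit$model$error[["b"]], 0.02)
  expect_lt(max(fit$model$omega / est_theta), 0.1)
})

test_that("estimates are invariant to subject order under the same seed", {
  pop <- population_model(est_theta, omega = 0.2 * est_theta,
                          error = c(a = 1e-4, b = 0.05))
  ds <- simulate_dataset(pop,
                         list(covariates = data.frame(ID = 1:6),
                              schedule = c(0.5, 1, 2, 4, 6, 9, 12, 18, 24),
                              regimen = dose_regimen()),
                         seed = 4)
  ids <- unique(ds$ID)
  perm <- unlist(lapply(rev(ids), function(i) which(ds$ID == i)))
  ds_perm <- ds[perm, ]
  st <- quick_settings(k1 = 20, k2 = 10)
  f1 <- saem_fit(ds, settings = st, seed = 5)
  f2 <- saem_fit(ds_perm, settings = st, seed = 5)
  expect_equal(f1$model$theta, f2$model$theta, tolerance = 1e-12)
  expect_equal(f1$model$omega, f2$model$omega, tolerance = 1e-12)
  # and bitwise reproducibility of a repeated identical call
  f3 <- saem_fit(ds, settings = st, seed = 5)
  expect_identical(f1$model$theta, f3$model$theta)
})

test_that("BICc penalty arithmetic", {
  expect_equal(bicc(-100, 40, 838, 0, 0), -100)
  base <- bicc(-100, 40, 838, 10, 2)
  expect_equal(bicc(-100, 40, 838, 11, 2) - base, log(40))
  expect_equal(bicc(-100, 40, 838, 10, 3) - base, log(838))
  expect_error(bicc(-100, 0, 10, 1, 1))
})

test_that("IS likelihood: exact with no IIV, Gaussian oracle with small IIV", {
  schedule <- c(2, 6, 12)
  # no latent variables: -2LL is the exact Gaussian value
  pop0 <- population_model(est_theta, omega = rep(0, 7),
                           error = c(a = 5e-4, b = 0.1))
  ds0 <- simulate_dataset(pop0,
                          list(covariates = data.frame(ID = 1:3),
                               schedule = schedule,
                               regimen = dose_regimen()),
                          seed = 9)
  fit0 <- as_saem_fit(pop0, ds0, quick_settings())
  got <- loglik_importance(fit0, n_is = 10, seed = 1)
  obs <- ds0[ds0$EVID == 0, ]
  f <- predict_conc(est_theta, dose_regimen(), schedule, engine = "grid",
                    dt = 0.05)
  want <- -2 * sum(vapply(split(obs, obs$ID), function(o)
    sum(dnorm(o$DV, f, residual_sd(f, pop0$error), log = TRUE)), 0))
  expect_equal(got$minus2ll, want, tolerance = 1e-10)

  # one subject, one observation, small IIV on Cl: linearized marginal
  pop1 <- population_model(est_theta,
                           omega = c(0, 0, 0, 0.4, 0, 0, 0),
                           error = c(a = 5e-4, b = 0))
  ds1 <- simulate_dataset(pop1,
                          list(covariates = data.frame(ID = 1),
                               schedule = 6, regimen = dose_regimen()),
                          seed = 2)
  fit1 <- as_saem_fit(pop1, ds1, quick_settings())
  got1 <- loglik_importance(fit1, n_is = 4000, seed = 3)
  fCl <- function(cl) {
    th <- est_theta; th["Cl"] <- cl
    predict_conc(th, dose_regimen(), 6, engine = "grid", dt = 0.05)
  }
  f0 <- fCl(est_theta[["Cl"]])
  fp <- (fCl(est_theta[["Cl"]] + 0.5) - fCl(est_theta[["Cl"]] - 0.5)) / 1
  y <- ds1$DV[ds1$EVID == 0]
  want1 <- -2 * dnorm(y, f0, sqrt(5e-4^2 + (fp * 0.4)^2), log = TRUE)
  expect_equal(got1$minus2ll, want1,
               tolerance = max(0.02, 3 * got1$mc_se / abs(want1)))

  # Monte-Carlo error shrinks as draws grow
  se_small <- loglik_importance(fit1, n_is = 200, seed = 4)$mc_se
  se_big <- loglik_importance(fit1, n_is = 1600, seed = 4)$mc_se
  expect_lt(se_big, se_small)
})

test_that("EBEs shrink fully at zero IIV and recover rich-data individuals", {
  pop0 <- population_model(est_theta, omega = rep(0, 7),
                           error = c(a = 1e-4, b = 0.02))
  ds0 <- simulate_dataset(pop0,
                          list(covariates = data.frame(ID = 1:3),
                               schedule = c(1, 4, 8, 16),
                               regimen = dose_regimen()),
                          seed = 6)
  eb0 <- compute_ebes(as_saem_fit(pop0, ds0, quick_settings()), quiet = TRUE)
  expect_true(all(eb0$eta == 0))

  # near-noiseless rich data: EBE parameters match the simulated truth on
  # the well-identified parameters
  pop <- population_model(est_theta,
                          omega = c(0, 0, 0, 0.15, 0.1, 0, 0) * est_theta,
                          error = c(a = 1e-6, b = 1e-4))
  ds <- simulate_dataset(pop,
                         list(covariates = data.frame(ID = 1:4),
                              schedule = default_schedule(),
                              regimen = dose_regimen()),
                         seed = 7)
  eb <- compute_ebes(as_saem_fit(pop, ds, quick_settings(dt = 0.02)),
                     quiet = TRUE)
  truth <- attr(ds, "params")
  expect_lt(max(abs(eb$params[, "Cl"] / truth[, "Cl"] - 1)), 0.01)
  expect_lt(max(abs(eb$params[, "V1"] / truth[, "V1"] - 1)), 0.02)
})

test_that("duplicating the dataset shrinks standard errors by about sqrt(2)", {
  pop <- population_model(est_theta,
                          omega = c(0, 0, 0, 0.2, 0, 0, 0) * est_theta,
                          error = c(a = 2e-4, b = 0.05))
  sched <- c(0.5, 1, 1.5, 3, 4.5, 6, 8, 10, 13, 16, 20, 24)
  ds1 <- simulate_dataset(pop,
                          list(covariates = data.frame(ID = 1:8),
                               schedule = sched, regimen = dose_regimen()),
                          seed = 12)
  ds2b <- ds1
  ds2b$ID <- ds2b$ID + 8   # exact copy of each subject: information doubles
  ds2 <- rbind(ds1, ds2b)
  f1 <- as_saem_fit(pop, ds1, quick_settings())
  f2 <- as_saem_fit(pop, ds2, quick_settings())
  se1 <- standard_errors(f1, n_is = 80, seed = 5)
  se2 <- standard_errors(f2, n_is = 80, seed = 5)
  for (p in c("omega_Cl", "a", "b")) {
    r <- se2$se[se2$parameter == p] / se1$se[se1$parameter == p]
    expect_true(is.finite(r))
    expect_lt(abs(r - 1 / sqrt(2)), 0.3)
    expect_lt(r, 0.95)
  }
  expect_true(all(se1$rse_percent[is.finite(se1$rse_percent)] >= 0))
})
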