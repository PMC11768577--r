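test_that("transit input integrates to the dose and peaks where expected", {
  # normalization for random admissible (Mtt, Ktr)
  set.seed(7)
  for (i in 1:12) {
    Mtt <- runif(1, 0.2, 15); Ktr <- runif(1, 0.05, 5)
    tot <- integrate(function(t) transit_input_rate(t, 100, Mtt, Ktr),
                     0, 200 * Mtt + 200, rel.tol = 1e-9)$value
    expect_equal(tot, 100, tolerance = 1e-6)
  }
  # zero at t = 0 when n > 0, singular case handled
  expect_equal(transit_input_rate(0, 1, 9.5, 0.15), 0)
  expect_true(is.finite(transit_input_rate(0, 1, 0.5, 0.5)))
  # reference values: n = 0.425, peak input at n/Ktr
  Mtt <- 9.50; Ktr <- 0.15
  n <- Ktr * Mtt - 1
  expect_equal(n, 0.425)
  tgrid <- seq(0.01, 40, by = 0.001)
  tpk <- tgrid[which.max(transit_input_rate(tgrid, 1, Mtt, Ktr))]
  expect_equal(tpk, n / Ktr, tolerance = 1e-2)
  expect_equal(n / Ktr, 2.8333, tolerance = 1e-4)
  expect_error(transit_input_rate(1, 1, 1, -1), "Ktr")
})

test_that("predict_conc agrees with its tightened-tolerance ODE oracle", {
  tt <- default_schedule()
  c_ref <- predict_conc(ref_theta, dose_regimen(), tt, engine = "lsoda",
                        rtol = 1e-10, atol = 1e-14)
  c_def <- predict_conc(ref_theta, dose_regimen(), tt, engine = "lsoda")
  expect_lt(max(abs(c_def - c_ref)) / max(c_ref), 1e-6)
  # compiled fast engine tracks the reference within its own tolerance
  c_grid <- predict_conc(ref_theta, dose_regimen(), tt, engine = "grid",
                         dt = 0.01)
  expect_lt(max(abs(c_grid - c_ref)) / max(c_ref), 2e-4)
})

test_that("predict_conc limits: zero dose, dose linearity, one-compartment", {
  tt <- c(0.5, 1, 2, 4, 8, 12)
  expect_equal(predict_conc(ref_theta,
                            data.frame(time = 0, amt = 0), tt),
               rep(0, length(tt)))
  c1 <- predict_conc(ref_theta, dose_regimen(), tt)
  c2 <- predict_conc(ref_theta, dose_regimen(dose_amount = 8), tt)
  expect_equal(c2, 2 * c1, tolerance = 1e-6)

  # Q -> 0, negligible transit delay: one-compartment oral closed form
  ka <- 1.2; ke <- 0.3; V <- 50; dose <- 4
  p <- c(Mtt = 0.002, Ktr = 1000, ka = ka, Cl = ke * V, V1 = V,
         Q = 1e-9, V2 = 100)
  tt2 <- seq(0.5, 24, by = 0.5)
  got <- predict_conc(p, data.frame(time = 0, amt = dose), tt2,
                      engine = "lsoda")
  want <- one_cpt_oral(tt2, dose, ka, ke, V)
  expect_lt(max(abs(got - want)) / max(want), 0.005)
})

test_that("residual error model forms", {
  expect_equal(residual_sd(0, c(a = 0.2, b = 0.5)), 0.2)
  expect_equal(residual_sd(3, c(a = 0, b = 0.5)), 1.5)
  a <- 0.19e-4; b <- 0.15e-2; f <- 0.005
  expect_equal(residual_sd(f, c(a = a, b = b)), sqrt(a^2 + b^2 * f^2))
  expect_equal(residual_sd(f, c(a = a, b = b), form = "combined1"),
               a + b * f)
  expect_error(residual_sd(1, c(a = 0, b = 0)), "not both zero")
})

test_that("individual parameters assemble covariate effects additively", {
  pop <- default_poppk_model()
  expect_equal(as.vector(individual_params(pop, eta = rep(0, 7))),
               unname(pop$theta))
  # continuous link at its reference contributes nothing
  pop$links <- list(covariate_link("Cl", "WT", "continuous", beta = 1.5,
                                   ref = 60))
  expect_equal(individual_params(pop, list(WT = 60), rep(0, 7))[["Cl"]],
               pop$theta[["Cl"]])
  expect_equal(individual_params(pop, list(WT = 70), rep(0, 7))[["Cl"]],
               pop$theta[["Cl"]] + 15)
  # categorical: positive beta for females raises female Cl
  pop$links <- list(covariate_link("Cl", "SEX", "categorical", beta = 20,
                                   ref = 0, category = 1))
  cl_f <- individual_params(pop, list(SEX = 1), rep(0, 7))[["Cl"]]
  cl_m <- individual_params(pop, list(SEX = 0), rep(0, 7))[["Cl"]]
  expect_gt(cl_f, cl_m)
  expect_error(individual_params(pop, list(AGE = 1), rep(0, 7)), "unknown")
})

test_that("simulate_dataset is seeded, order-invariant and moment-faithful", {
  pop <- default_poppk_model()
  des <- list(covariates = data.frame(ID = 1:6),
              schedule = default_schedule(), regimen = dose_regimen())
  d1 <- simulate_dataset(pop, des, seed = 42)
  d2 <- simulate_dataset(pop, des, seed = 42)
  expect_identical(d1, d2)
  expect_false(identical(d1$DV, simulate_dataset(pop, des, seed = 43)$DV))

  # omega = 0 and no noise reproduces predict_conc exactly
  pop0 <- population_model(pop$theta, omega = rep(0, 7), error = pop$error)
  d0 <- simulate_dataset(pop0, des, seed = 1, noise = FALSE)
  obs <- d0[d0$EVID == 0 & d0$ID == 3, ]
  expect_equal(obs$DV,
               predict_conc(pop$theta, dose_regimen(), obs$TIME,
                            engine = "grid", dt = 0.01),
               tolerance = 1e-12)

  # sample moments of individual parameters track the IIV model
  des_big <- list(covariates = data.frame(ID = 1:400),
                  schedule = c(1, 6), regimen = dose_regimen(n_doses = 1))
  db <- simulate_dataset(pop, des_big, seed = 7, noise = FALSE)
  pars <- attr(db, "params")
  expect_equal(mean(pars[, "Mtt"]), pop$theta[["Mtt"]], tolerance = 0.1)
  expect_equal(sd(pars[, "Mtt"]), pop$omega[["Mtt"]], tolerance = 0.15)
  expect_equal(sd(pars[, "Cl"]), pop$omega[["Cl"]], tolerance = 0.15)
  expect_true(all(pars > 0))
})
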