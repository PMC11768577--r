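test_that("geometric statistics against a log-domain oracle", {
  gs <- geometric_stats(c(2, 8))
  expect_equal(gs$geometric_mean, 4)
  gs2 <- geometric_stats(rep(3.7, 5))
  expect_equal(gs2$geometric_sd, 1)
  # lognormal moment check
  set.seed(14)
  v <- rlnorm(1e4, 0, 0.5)
  gs3 <- geometric_stats(v)
  expect_equal(gs3$geometric_mean, 1, tolerance = 0.02)
  expect_equal(gs3$geometric_sd, exp(0.5), tolerance = 0.02)
  # brute-force log-domain oracle on random vectors
  for (i in 1:10) {
    x <- runif(sample(2:30, 1), 0.1, 50)
    gs4 <- geometric_stats(x)
    expect_equal(gs4$geometric_mean, exp(mean(log(x))), tolerance = 1e-12)
    expect_equal(gs4$geometric_sd, exp(sd(log(x))), tolerance = 1e-12)
  }
  expect_error(geometric_stats(c(1, 0)), "positive")
})

test_that("subgroup summaries partition counts and match the full pool", {
  set.seed(20)
  n <- 30
  params <- data.frame(Cl = runif(n, 50, 150), V1 = runif(n, 40, 120))
  covs <- data.frame(SEX = rep(c(0, 1), 15), BSA = runif(n, 0.9, 2.4))
  # one group holding everyone equals plain geometric stats
  sg <- summarize_subgroups(params, covs,
                            list(covariate = "BSA", breaks = c(0, 3)),
                            parameters = "Cl")
  expect_equal(sg$n, n)
  expect_equal(sg$geometric_mean, geometric_stats(params$Cl)$geometric_mean)
  # disjoint BSA ranges: group sizes sum to the filtered total
  sg2 <- summarize_subgroups(params, covs,
                             list(covariate = "BSA",
                                  breaks = c(0.9, 1.6, 2.4)),
                             parameters = "Cl",
                             filter = covs$SEX == 0)
  expect_equal(sum(sg2$n), sum(covs$SEX == 0))
  # empty subgroup reported with n = 0 and missing stats
  sg3 <- summarize_subgroups(params, covs,
                             list(covariate = "BSA",
                                  breaks = c(0, 0.1, 3)),
                             parameters = "Cl")
  expect_true(any(sg3$n == 0 & is.na(sg3$geometric_mean)))
  expect_error(summarize_subgroups(params, covs,
                                   list(covariate = "XX")), "unknown")
})

test_that("a positive female Cl effect shows up in the subgroup summary", {
  pop <- population_model(c(Mtt = 2, Ktr = 1.5, ka = 3, Cl = 20, V1 = 30,
                            Q = 10, V2 = 80),
                          omega = c(0.2, 0.15, 0.3, 1.5, 2, 1, 8),
                          error = c(a = 1e-4, b = 0.02),
                          links = list(covariate_link(
                            "Cl", "SEX", "categorical", beta = 8,
                            ref = 0, category = 1)))
  covs <- data.frame(ID = 1:30, SEX = rep(c(0, 1), 15))
  ds <- simulate_dataset(pop, list(covariates = covs,
                                   schedule = c(1, 3, 6, 12, 24),
                                   regimen = dose_regimen()),
                         seed = 6)
  pars <- attr(ds, "params")
  sg <- summarize_subgroups(pars, covs, list(covariate = "SEX"),
                            parameters = "Cl")
  gm_f <- sg$geometric_mean[sg$group == "1"]
  gm_m <- sg$geometric_mean[sg$group == "0"]
  expect_gt(gm_f, gm_m)
})

test_that("terminal-phase curves separate groups by clearance", {
  th_lo <- c(Mtt = 2, Ktr = 1.5, ka = 3, Cl = 15, V1 = 30, Q = 10, V2 = 80)
  th_hi <- th_lo; th_hi["Cl"] <- 30
  sched <- seq(12, 24, 2)
  mk <- function(th, ids) {
    simulate_dataset(population_model(th, omega = rep(0, 7),
                                      error = c(a = 1e-6, b = 1e-4)),
                     list(covariates = data.frame(ID = ids),
                          schedule = sched,
                          regimen = dose_regimen(n_doses = 1)),
                     seed = 2, noise = FALSE)
  }
  ds <- rbind(mk(th_lo, 1:3), mk(th_hi, 4:6))
  grp <- data.frame(ID = 1:6, group = rep(c("lo", "hi"), each = 3))
  tc <- terminal_phase_curves(ds, grp, c(12, 24))
  slope <- function(g) {
    sub <- tc[tc$group == g, ]
    coef(lm(mean_log_conc ~ TIME, sub))[[2]]
  }
  expect_lt(slope("hi"), slope("lo"))   # faster clearance declines steeper
  # identical groups give identical curves
  ds2 <- rbind(mk(th_lo, 1:2), mk(th_lo, 3:4))
  grp2 <- data.frame(ID = 1:4, group = rep(c("a", "b"), each = 2))
  tc2 <- terminal_phase_curves(ds2, grp2, c(12, 24))
  expect_equal(tc2$mean_log_conc[tc2$group == "a"],
               tc2$mean_log_conc[tc2$group == "b"])
  expect_error(terminal_phase_curves(ds, grp, c(30, 40)), "window")
})
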