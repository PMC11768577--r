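test_that("likelihood-ratio thresholds match chi-square quantiles", {
  # the chi-square upper-0.05 quantile at 1 df is 3.84 at 2 d.p.
  expect_equal(lrt_threshold(0.05, 1), 3.84)
  expect_equal(lrt_threshold(0.001, 1), 10.83)
  expect_lt(lrt_threshold(0.9999, 1), 0.01)
  expect_error(lrt_threshold(0), "alpha")
  expect_error(lrt_threshold(1.2), "alpha")
})

test_that("screening flags true relationships and respects degenerate input", {
  set.seed(31)
  n <- 40
  eta <- matrix(rnorm(n * 7), n, 7, dimnames = list(NULL, names(ref_theta)))
  covs <- data.frame(AGE = runif(n, 5, 65), WT = runif(n, 30, 100),
                     SEX = rbinom(n, 1, 0.5))
  # exact dependence: p ~ 0
  covs$WT <- 30 + 10 * eta[, "Cl"]
  scr <- screen_covariates(eta, covs, continuous = c("AGE", "WT"),
                           categorical = "SEX")
  wt_cl <- scr[scr$parameter == "Cl" & scr$covariate == "WT" &
                 scr$test == "pearson", ]
  expect_lt(wt_cl$p_value, 1e-10)
  expect_true(wt_cl$flagged)
  # constant covariate is skipped with a note
  covs$AGE <- 40
  scr2 <- screen_covariates(eta, covs, continuous = c("AGE", "WT"),
                            categorical = "SEX")
  expect_true(any(scr2$note == "constant covariate"))
  # single-subject category: insufficient df
  covs$SEX <- c(1, rep(0, n - 1))
  scr3 <- screen_covariates(eta, covs, continuous = "WT",
                            categorical = "SEX")
  expect_true(all(is.na(scr3$p_value[scr3$covariate == "SEX"]) |
                    is.finite(scr3$p_value[scr3$covariate == "SEX"])))
})

test_that("screening type-I rate is near alpha under the null", {
  set.seed(97)
  n_rep <- 1000
  hits <- logical(n_rep)
  for (r in seq_len(n_rep)) {
    eta <- rnorm(40)
    x <- rnorm(40)
    hits[r] <- cor.test(x, eta)$p.value < 0.05 ||
      suppressWarnings(cor.test(x, eta, method = "spearman"))$p.value < 0.05
  }
  # either-test flagging is slightly anti-conservative vs a single test
  expect_gt(mean(hits), 0.03)
  expect_lt(mean(hits), 0.11)
})

test_that("VIF filter: orthogonal, collinear and duplicated covariates", {
  set.seed(8)
  n <- 60
  x1 <- rnorm(n); x2 <- rnorm(n)
  res <- vif_filter(data.frame(x1 = x1, x2 = x2))
  expect_true(all(res$vif < 1.5))
  expect_length(res$excluded, 0)

  # weight and BSA from a study-like cohort are heavily collinear
  coh <- sample_cohort(default_cohort_spec(seed = 2))
  res2 <- vif_filter(coh[, c("weight", "bsa", "age")], threshold = 15,
                     p_values = c(weight = 0.001, bsa = 0.2, age = 0.5))
  expect_true("bsa" %in% res2$excluded)   # less significant of the pair

  # exact duplicate: infinite VIF, one copy excluded
  res3 <- vif_filter(data.frame(a = x1, b = x1, c = x2))
  expect_true(length(res3$excluded) >= 1)
  expect_false(all(c("a", "b") %in% res3$retained))
  expect_error(vif_filter(data.frame(a = x1)), "at least 2")
})

make_cov_dataset <- function(beta_cl = 0, n = 20, seed = 1) {
  # moderate IIV so a gender effect of 2 omega is strong but realistic
  pop <- population_model(ref_theta, omega = 0.25 * ref_theta,
                          error = c(a = 2e-5, b = 0.02))
  if (beta_cl != 0)
    pop$links <- list(covariate_link("Cl", "SEX", "categorical",
                                     beta = beta_cl, ref = 0, category = 1))
  set.seed(seed)
  covs <- data.frame(ID = 1:n, SEX = rep(c(0, 1), length.out = n),
                     WT = round(runif(n, 40, 95), 1))
  ds <- simulate_dataset(pop, list(covariates = covs,
                                   schedule = default_schedule(),
                                   regimen = dose_regimen()),
                         seed = seed)
  # truth-anchored starting values: these tests exercise the covariate
  # search, not the initialization machinery
  init <- population_model(pop$theta, omega = pop$omega, error = pop$error)
  attr(init, "individual_fits") <- attr(ds, "params")
  list(ds = ds, pop = pop, covs = covs, init = init)
}

test_that("stepwise search finds a strong gender effect and rejects nulls", {
  st <- quick_settings(k1 = 25, k2 = 15)
  cand <- list(covariate_link("Cl", "SEX", "categorical", ref = 0,
                              category = 1),
               covariate_link("Cl", "WT", "continuous", ref = NA))
  # power: beta = 2 * omega_Cl; 28 subjects so the effect clears the
  # backward-elimination threshold (~0.69 * n of -2LL improvement)
  hits <- 0; n_rep <- 3
  for (r in seq_len(n_rep)) {
    sim <- make_cov_dataset(beta_cl = 2 * 0.25 * ref_theta[["Cl"]],
                            n = 28, seed = 100 + r)
    base <- saem_fit(sim$ds, init = sim$init, settings = st, seed = 50 + r)
    res <- stepwise_search(base, cand, sim$ds, settings = st, n_is = 150,
                           seed = 60 + r)
    labs <- vapply(res$model$links, link_label, "")
    if ("Cl~SEX==1" %in% labs) hits <- hits + 1
  }
  expect_gte(hits, 2)

  # null: no effects simulated, final model stays empty mostly
  clean <- 0
  for (r in seq_len(n_rep)) {
    sim <- make_cov_dataset(beta_cl = 0, seed = 200 + r)
    base <- saem_fit(sim$ds, init = sim$init, settings = st, seed = 70 + r)
    res <- stepwise_search(base, cand, sim$ds, settings = st, n_is = 150,
                           seed = 80 + r)
    if (length(res$model$links) == 0) clean <- clean + 1
  }
  expect_gte(clean, 2)
})

test_that("stepwise search edge cases and trace bookkeeping", {
  sim <- make_cov_dataset(beta_cl = 0, n = 8, seed = 5)
  st <- quick_settings(k1 = 20, k2 = 10)
  base <- saem_fit(sim$ds, init = sim$init, settings = st, seed = 3)
  # empty candidate set: base model back, empty trace
  res <- stepwise_search(base, list(), sim$ds, settings = st, n_is = 100)
  expect_length(res$model$links, 0)
  expect_equal(nrow(res$trace), 0)
  # duplicated candidates never enter twice
  cand <- list(covariate_link("Cl", "WT", "continuous", ref = NA),
               covariate_link("Cl", "WT", "continuous", ref = NA))
  res2 <- stepwise_search(base, cand, sim$ds, settings = st, n_is = 100)
  labs <- vapply(res2$model$links, link_label, "")
  expect_lte(sum(labs == "Cl~WT"), 1)
})

test_that("COSSAC-like search agrees with stepwise on a strong effect", {
  st <- quick_settings(k1 = 25, k2 = 15)
  sim <- make_cov_dataset(beta_cl = 2 * 0.25 * ref_theta[["Cl"]], seed = 301)
  base <- saem_fit(sim$ds, init = sim$init, settings = st, seed = 91)
  cand <- list(covariate_link("Cl", "SEX", "categorical", ref = 0,
                              category = 1),
               covariate_link("V1", "WT", "continuous", ref = NA))
  res <- cossac_search(base, cand, sim$ds, settings = st, n_is = 150,
                       seed = 92)
  labs <- vapply(res$model$links, link_label, "")
  expect_true("Cl~SEX==1" %in% labs)
  expect_s3_class(res$screening, "screening_table")
})

test_that("Wald tests: zero effect and strong effect behave as expected", {
  sim <- make_cov_dataset(beta_cl = 2 * 0.25 * ref_theta[["Cl"]], seed = 401)
  st <- quick_settings(k1 = 25, k2 = 15)
  fit <- saem_fit(sim$ds, init = sim$init,
                  links = list(covariate_link("Cl", "SEX", "categorical",
                                              ref = 0, category = 1)),
                  settings = st, seed = 93)
  wt <- wald_tests(fit)
  expect_equal(nrow(wt), 1)
  expect_lt(wt$p_value, 0.05)
  expect_gt(wt$beta, 0)
  # no links: empty table
  fit0 <- as_saem_fit(default_poppk_model(), sim$ds)
  expect_equal(nrow(wald_tests(fit0)), 0)
})
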