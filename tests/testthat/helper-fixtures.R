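# shared fixtures built in code; everything is seeded

ref_theta <- c(Mtt = 9.50, Ktr = 0.15, ka = 2.91, Cl = 140, V1 = 77.5,
               Q = 48.9, V2 = 130)

small_parametric_dataset <- function(n = 8, seed = 5, pop = default_poppk_model(),
                                     schedule = default_schedule()) {
  simulate_dataset(pop,
                   list(covariates = data.frame(ID = seq_len(n)),
                        schedule = schedule, regimen = dose_regimen()),
                   seed = seed)
}

quick_settings <- function(k1 = 40, k2 = 25, dt = 0.05)
  saem_settings(k1 = k1, k2 = k2, dt = dt, keep_draws = 10)

# closed-form one-compartment oral model (first-order in/out)
one_cpt_oral <- function(t, dose, ka, ke, V)
  ifelse(t <= 0, 0, ka * dose / (V * (ka - ke)) * (exp(-ke * t) - exp(-ka * t)))
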