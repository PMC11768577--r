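# salbupk

An end-to-end, fully in-silico population pharmacokinetic (popPK) study
of **oral salbutamol** (a short-acting beta-2 agonist given as a 4 mg
immediate-release tablet), for pharmacometricians and PBPK/popPK
methodologists. No trial data exist at study scale for this route, so
the package manufactures and then analyzes its own:

1. **Virtual cohort** (`sample_cohort`) — 40 subjects aged 5-65
   (American/Asian/Chinese; healthy, obese, and Child-Pugh A cirrhosis
   groups), with anthropometrics, body surface area (Du Bois), and
   scaled organ volumes/flows.
2. **Whole-body PBPK simulator** (`simulate_pbpk`) — 13 perfusion-limited
   tissues, lung in series, portal routing to the liver, well-stirred
   hepatic extraction, first-order renal elimination, and a
   9-compartment compartmental-absorption-and-transit (CAT) gut model
   with segmental absorption `ka_i = 2 P_eff / R_i`. Validated by the
   directional fold-error rule `max(obs/pred, pred/obs) < 2`.
3. **NCA** (`nca_summary`) — linear-trapezoidal AUC and an
   adjusted-R^2-selected terminal slope.
4. **popPK model** (`predict_conc`, `simulate_dataset`) — two-compartment
   disposition with a gamma-density transit-absorption input
   (`n = Ktr*Mtt - 1` transit compartments), additive-normal IIV, and
   combined residual error `sd = sqrt(a^2 + b^2 f^2)`:

   Y_ij = f(t_ij, theta + eta_i) + sqrt(a^2 + b^2 f^2) * eps_ij,
   eta_i ~ N(0, diag(omega^2)), eps_ij ~ N(0, 1)

5. **SAEM estimation** (`saem_fit`) — Metropolis-within-Gibbs conditional
   sampling, exploratory/smoothing phases with simulated annealing,
   importance-sampling -2LL (`loglik_importance`), BICc, empirical
   Bayes estimates, and Hessian-based RSEs.
6. **Covariate search** (`screen_covariates`, `vif_filter`,
   `stepwise_search`, `cossac_search`) — Pearson/Spearman/ANOVA
   screening at p < 0.05, VIF > 15 collinearity filtering, forward
   inclusion at a -2LL drop > qchisq(0.95, 1), backward elimination at
   a rise < qchisq(0.999, 1).
7. **Diagnostics** (`npde`, `vpc`, `gof_tables`) and **subgroup
   summaries** (`summarize_subgroups`, `terminal_phase_curves`).

The numbered scripts under `analysis/` walk the whole study in order
(cohort, PBPK validation, dataset, base fit, covariate search,
diagnostics, subgroups) and write their tables under `results/`.

## Worked example

Single 4 mg oral dose in the reference 30-year-old, 75 kg male:

```r
library(salbupk)
phys <- scale_physiology(reference_subject())
prof <- simulate_pbpk(phys, regimen = dose_regimen(n_doses = 1),
                      t_grid = seq(0, 48, 0.25))
nca  <- nca_summary(prof$times, prof$plasma_conc / 1000, dose = 4)
fold_error(0.0318, nca$auc_inf)   # observed reference AUCinf, ug.h/mL
```

This prints (ug/mL, h):

```
Cmax 0.00649 at Tmax 1.25; AUCinf 0.0446; t1/2 3.88
$fold_error [1] 1.4    $reliable [1] TRUE
```

i.e. the simulator's exposure is within 1.4-fold of the observed
reference value — inside the conventional 2-fold acceptance band used
for PBPK validation. The fraction absorbed of the CAT chain is 0.968,
within 2-fold of the 85.2% reference. Fitting the packaged final popPK
model back to data simulated from itself (40 subjects, 4 mg q6h, ~840
observations; `analysis/04_base_fit.R`) recovers the population
absorption rate constant ka near the generating 2.91 1/h; the
seed-to-seed scatter of that estimate is of order 10-20%, the
information limit of this absorption-limited design (clearance and
central volume carry very large uncertainty, mirroring the huge
published relative standard errors for those terms).

## Layout

```
R/                 package code (cohort, pbpk, nca, model, saem,
                   covsearch, diagnostics, subgroups, io)
src/               compiled structural-model predictor (Rcpp)
inst/extdata/      compound, Kp, physiology and reference-value tables
analysis/          numbered study scripts writing results/
scripts/           acceptance.R
tests/testthat/    unit, property and acceptance tests
vignettes/         methods vignette (models, assumptions, numerics)
```
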