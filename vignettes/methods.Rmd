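---
title: "An in-silico population pharmacokinetic workflow for oral salbutamol"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An in-silico population pharmacokinetic workflow for oral salbutamol}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`salbupk` implements a fully synthetic population-pharmacokinetic (popPK)
study of orally administered salbutamol, a short-acting beta-2 agonist.
No clinical concentration data for the oral tablet are publicly
available at study scale, so the workflow manufactures its own: a
whole-body physiologically based (PBPK) simulator generates plasma
concentration profiles for a virtual cohort, and a nonlinear
mixed-effects (NLME) pipeline then analyzes those data as if they came
from a trial — structural-model estimation by SAEM, stepwise covariate
selection, and simulation-based model qualification. This vignette
explains each model, its assumptions, the tunable constants, and the
numerical choices, in that order.

## 1. The virtual cohort

`sample_cohort()` draws subjects from a `cohort_spec()`. The default
specification mirrors the study population: 40 subjects in five groups
— 6 healthy and 4 obese Americans, 10 healthy Asians, 10 healthy
Chinese, and 10 American patients with Child-Pugh A cirrhosis — aged
5-65, with 60% males per group (24 M / 16 F overall; the published
per-group "about 50%" text is inconsistent with the published totals,
and the totals win).

Heights come from a piecewise-linear age-height reference per gender
(linear growth from 110 cm at age 5 to the adult plateau at age 20;
plateau 176 cm male / 163 cm female with race offsets of -4 cm Asian
and -3 cm Chinese) plus individual normal variation (SD 5-6 cm). A BMI
class is drawn (normal 18.5-24.9, overweight 25-29.9 on the standard
adult scale, applied across all ages as in the source study; obese
health status forces BMI 30-40), and weight follows as
BMI x height^2. Body surface area uses the Du Bois formula
`0.007184 * W^0.425 * H^0.725` — the usual choice in PBPK software when
no formula is stated. CYP2D6 and CYP2C19 "expression" are opaque
lognormal covariates matched to the reported means and SDs
(1.90 +/- 1.60 and 1.30 +/- 1.50); they do not modify clearance, since
the source analysis found no effect.

All randomness flows through per-subject substreams derived from the
spec seed by a counter, so cohorts are bitwise-reproducible and
extensible without reshuffling existing subjects.

## 2. The whole-body PBPK simulator

`simulate_pbpk()` solves a perfusion-limited, 13-tissue whole-body
model: venous and arterial blood pools, the lung in series, and 12
parallel tissues (adipose, muscle, liver, spleen, heart, brain, kidney,
skin, reproductive organs, red and yellow marrow, rest-of-body). Each
tissue is a well-stirred compartment whose venous outflow concentration
is `C_t * R_bp / Kp_t`. The salbutamol parameters (logP 0.76, R_bp
1.108, P_eff 1.21e-4 cm/s, fu 0.80, hepatic/renal plasma clearances
38.06 / 16.32 L/h) and the 13 tissue:plasma partition coefficients are
shipped as plain-text data files.

Design choices that deserve scrutiny:

* **Physiology table.** Proprietary population-physiology generators are
  replaced by a packaged reference table of organ weight fractions and
  flow fractions (compiled from standard human physiology references).
  Volumes scale with body weight, cardiac output with BSA (cardiac
  index 195 L/h/m^2), flows as fractions of cardiac output with
  rest-of-body absorbing the remainder.
* **Liver flow.** The model has no gut compartment, so the splanchnic
  inflow that would normally reach the liver via the portal vein is
  folded into the hepatic arterial share (0.215 of cardiac output, plus
  the spleen's 0.03). This is not cosmetic: the hepatic blood-term
  clearance (38.06/1.108 = 34.4 L/h) must stay below liver blood flow
  for the well-stirred model `Clint = Qh*CLb/(Qh - CLb)` to be solvable.
* **Clearance scaling.** Intrinsic hepatic clearance is calibrated once,
  at the reference 75 kg adult, so that the linear-regime systemic
  plasma clearance equals the reference hepatic clearance; it then
  scales with liver mass (proportional to weight) across subjects, and
  renal clearance scales as (W/75)^0.75. Cirrhosis A multiplies hepatic
  flow by 0.85 and intrinsic clearance by 0.8 (configurable,
  literature-motivated magnitudes for mild disease). Obesity enlarges
  the adipose fraction (0.19 to 0.32, partly offset in muscle).
* **Absorption.** A nine-compartment CAT chain (stomach, seven
  small-intestine segments, colon) with first-order transit (gastric
  emptying 4 1/h fasted, 3.32 h total SI transit, 13.5 h colon
  residence) and segmental absorption `ka_i = 2*P_eff/R_i` (radii
  1.5 cm SI, 2.5 cm colon). Dissolution is treated as instantaneous —
  justified for a 4 mg dose of a compound with 14.47 mg/mL solubility.
  Absorbed drug enters the liver inlet, so first-pass extraction
  emerges mechanistically. A calibration helper can rescale P_eff to
  hit a target fraction absorbed exactly; it is off by default, and the
  uncalibrated chain lands within the 2-fold acceptance band of the
  reference 85.2%.

Integration uses `deSolve::lsoda` at rtol 1e-8 / atol 1e-10, with doses
as impulse events. Mass balance (lumen + tissues + blood + eliminated +
fecal against administered dose) is checked to below 1e-6 relative in
the tests. One caution for users computing AUC from IV-bolus runs: the
venous mixing transient has a time constant of minutes, so the output
grid must resolve the first ~0.02 h or the trapezoidal AUC will be
biased low; the oral route has no such spike.

## 3. NCA and the fold-error rule

`nca_summary()` implements linear-trapezoidal NCA with a terminal
log-linear regression whose window is chosen by maximizing adjusted R^2
over all contiguous terminal windows of at least three post-peak points
(ties prefer more points — the "best fit" convention of common NCA
software; zero concentrations are excluded from the log fit). The
simulator is accepted against reference values through the directional
fold-error `max(obs/pred, pred/obs)`, with predictions declared
reliable below 2. Reported fold-errors are rounded half-up to two
decimals to match the reference table's print format.

## 4. The popPK model

The structural model is a two-compartment disposition with
transit-compartment absorption: the transit chain is the closed-form
gamma-density input (rate `dose * dgamma(t, shape = Ktr*Mtt,
rate = Ktr)`, i.e. n = Ktr*Mtt - 1 transit compartments, non-integer n
allowed), followed by first-order absorption ka into the central
compartment; doses superpose. Parameters are apparent (Cl/F, V/F), as
oral data cannot separate F.

The statistical model is additive-normal interindividual variability
(IIV) on all seven parameters with diagonal covariance — matching a
normal parameter distribution — and a combined residual error
`sd = sqrt(a^2 + b^2 f^2)` (the "combined-1" form `a + b*f` is
available). The packaged final model carries the published estimates
(Mtt 9.50 h, Ktr 0.15 1/h, ka 2.91 1/h, Cl/F 140 L/h, V1/F 77.5 L,
Q/F 48.9 L/h, V2/F 130 L; a 1.9e-5 ug/mL, b 1.5e-3). The published IIV
constants (0.43, 0.32, 0.41, 0.38, 0.36, 0.92, 0.87) are interpreted as
*relative* standard deviations and converted to absolute SDs as
`omega = IIV * theta`. The absolute reading would make the population
degenerate — a clearance SD of 0.38 L/h on 140 L/h, and a Ktr
distribution `N(0.15, 0.32)` with two thirds of its mass below zero —
which no popPK analysis would report; the relative reading gives
coefficients of variation between 32% and 92%, squarely in the usual
range. Covariate effects are additive on the natural scale (consistent
with the normal distribution), continuous covariates centered at the
dataset median, reference categories male / American / healthy.
Simulation resamples subjects whose parameter vector has a non-positive
component; estimation clips at 1e-6 and flags.

## 5. SAEM estimation and its numerical choices

`saem_fit()` is a stochastic approximation EM: an exploratory phase
(k1 = 300 default iterations, step size 1) followed by a smoothing
phase (k2 = 150, step size `(k - k1)^-0.7`). The E-step runs, per
subject and iteration, two sweeps of two Metropolis-within-Gibbs
kernels — an independent proposal from the prior and an adaptive joint
random walk targeting 30-40% acceptance. M-steps are exact given the
sufficient statistics: per-parameter least squares for fixed effects
and covariate coefficients, moment updates for omega, and a
two-parameter quasi-Newton minimization for (a, b). Simulated annealing
floors the variance components during the exploratory phase; the floors
decay geometrically (factor 0.95 per iteration) *from their starting
values* rather than ratcheting on the running estimates, so one noisy
update cannot prop the error model up for dozens of iterations.

Three further choices matter for stability and are worth making
explicit:

* **The chain lives in individual-parameter space.** After each M-step
  the random effects are re-expressed about the updated population
  means (`eta <- P - mu`), so a moving theta never teleports the
  sampled individual parameters. Without this, every M-step injects
  artificial residual spikes.
* **Plausibility box.** Proposals implying a structural parameter
  outside a broad physical box (e.g. volumes above 3000 L) are
  rejected, and the IIV SD is capped at 1.5x the fixed effect. Both
  guards only bind along likelihood ridges where the data carry no
  information, and prevent the random-effect diffusion such ridges
  otherwise cause.
* **Initial values.** The published strategy — software-chosen starting
  estimates — is reproduced as: NCA heuristics (Cl from dose/AUC, V
  from Cl*t_half/ln2, Mtt from Tmax, ka = 1), refined by per-subject
  weighted least-squares fits (log-parameter scale, multi-start), a
  consensus restart around the component-wise medians with a mild
  relative ridge (35% CV) anchoring unidentified directions, and
  iteratively-reweighted tightening down to each profile's own noise
  floor. The per-subject fits double as warm starts for the
  conditional samples.

**The flip-flop tie-break.** The transit chain plus first-order
absorption admits exchange-symmetric solutions: a slow chain with fast
ka, or a fast chain with slow ka, fit rich profiles equally well
(numerically: objective differences below one chi-square unit at the
data's own noise level). The package resolves this ambiguity by
convention, preferring solutions with ka at least as fast as the
transit rate Ktr — the ordering of the packaged reference model
(2.91 vs 0.15 1/h) — both when selecting among per-subject local optima
at initialization and as a constraint on conditional proposals. Users
fitting drugs believed to be in the opposite regime should disable
`branch_constraint` in `saem_settings()`.

**What is and is not identifiable.** Under the packaged error
magnitudes the best one-compartment approximation of the reference
curve deviates by ~0.11% RMS — below the residual noise. Q and V2 are
therefore decoration on this design: estimable only up to wide ridges,
with the IIV caps doing the stabilizing. The same is true of the
Cl/V1 split during the absorption-limited phase (the published fit
itself reports 223% and 97% relative standard errors there). Parameter
recovery tests are accordingly scoped to the identifiable quantities —
ka, Mtt, Ktr, Cl — and the acceptance check targets ka.

`loglik_importance()` estimates the marginal -2LL by importance
sampling with a 4-df t proposal centered at each subject's conditional
mode with Laplace scales (1000 draws/subject default; Monte-Carlo SE
reported; exact Gaussian evaluation when all IIV is zero).
`bicc()` penalizes subject-level parameters (theta, beta, omega) by
log N_subjects and residual-error parameters by log N_obs.
`standard_errors()` builds a central-difference Hessian of the IS
log-likelihood under common random numbers, caching model predictions
across perturbations that leave the fixed effects unchanged;
negative-curvature directions are flagged rather than silently
symmetrized.

## 6. Covariate selection

`screen_covariates()` tests each (parameter, covariate) pair on the
per-subject random effects: Pearson *and* Spearman for continuous
covariates, one-way ANOVA for categorical ones, flagging a pair when
either p-value drops below 0.05 (the more inclusive reading; the
forward likelihood-ratio step is the real gate). `vif_filter()` removes
multicollinearity above VIF 15, dropping the less significant covariate
of an offending pair — weight and BSA from this cohort reliably trip
it. `stepwise_search()` then adds candidates (ordered by a configurable
clinical-priority list, then p-value) when -2LL drops by more than the
chi-square 0.05 quantile, and back-eliminates from the full model any
link whose removal raises -2LL by less than the 0.001 quantile
(3.84 and 10.83 at two decimals). Nested models are compared with a
shared importance-sampling seed so Monte-Carlo noise largely cancels.
`cossac_search()` is the correlation-based automatic variant: it ranks
relationships on retained conditional MCMC samples rather than EBEs,
then applies the same forward/backward machinery ("COSSAC-like" — the
proprietary scheduling heuristics are not reproduced). Wald tests use
the normal-theory covariance of the M-step regression; this ignores
conditional-mean uncertainty and is used only for ordering the backward
pass and reporting.

## 7. Diagnostics

`iwres()` gives individual weighted residuals from the EBE parameters;
`npde()` the simulation-based decorrelated residuals (empirical mean
and Cholesky of per-subject simulated covariance, rank-based pd with
seeded tie jitter, n_sim >= 50 enforced, marginal fallback when the
simulated covariance is singular); `vpc()` compares the observed
10/50/90th percentiles per quantile-based time bin (8 bins default,
bins under 3 observations merged) with the 5th-95th percentile band of
the same statistics across simulated replicates. The outlier proportion
is defined — the source leaves it undefined — as the fraction of
observations outside the 90% individual prediction interval,
`|y - f_i| > 1.645 * sd(f_i)`; under a correct model it sits near 10%
by construction, so values far above signal misfit (the published
4.89% is context, not a target). All diagnostics are deterministic
under their seed; calibration tests run at n_sim = 200.

## 8. Problem sizes, what the tests show, and limitations

The test suite and the analysis scripts run the full design (40
subjects, 21 samples each, 4 mg q6h over 24 h) for the headline checks,
and reduced designs (6-20 subjects, shortened SAEM budgets of k1
20-60 / k2 10-30, diagnostic n_sim 60-200, 3-4 replicates for power
checks) for property suites, chosen so the whole suite completes on a
single CPU in well under half an hour. The vignette's own claims are
limited to what those tests compute.

What passing tests do **not** show: the virtual data inherit every
assumption of the PBPK layer (perfusion-limited distribution, no
transporters, no CYP-specific kinetics, linear clearances, fasted
state, instantaneous dissolution) and of the popPK layer (additive
normal IIV, diagonal omega, no inter-occasion variability, no BLQ
censoring). Agreement between the two layers demonstrates internal
consistency of the workflow, not predictive accuracy for real patients;
the only external anchors are the reference single-dose PK values used
in the 2-fold validation. The q6h regimen is the default; the
clinically discussed q4h alternative is available through
`dose_regimen()`.
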