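PK_PARAM_NAMES <- c("Mtt", "Ktr", "ka", "Cl", "V1", "Q", "V2")

# plausibility box (h, 1/h, 1/h, L/h, L, L/h, L) used to keep estimation
# searches out of physically meaningless territory along flat ridges;
# oral absorption rate constants above ~12/h are not resolvable at
# 15-minute sampling and only feed ridge diffusion
PK_PARAM_BOX <- matrix(
  c(0.05, 0.005, 0.01, 0.5, 0.5, 1e-3, 0.5,
    48,   50,    12,   2e3, 3e3, 500,  3e3), 2, 7, byrow = TRUE,
  dimnames = list(c("lower", "upper"), PK_PARAM_NAMES))

#' Transit-compartment input rate
#'
#' Closed-form gamma-density input of the transit chain: with n =
#' Ktr*Mtt - 1 transit compartments (non-integer allowed, n > -1), the
#' rate of drug delivery into the absorption compartment at time t after
#' a dose is
#' `bio_f * dose * Ktr * (Ktr*t)^n * exp(-Ktr*t) / Gamma(n+1)`,
#' i.e. `bio_f * dose * dgamma(t, shape = Ktr*Mtt, rate = Ktr)`.
#' The rate integrates to `bio_f * dose` over (0, Inf).
#'
#' @param t time since the dose (h), vectorized; negative times give 0.
#' @param dose dose amount.
#' @param Mtt mean transit time (h).
#' @param Ktr transit rate constant (1/h).
#' @param bio_f bioavailable fraction entering the chain (default 1; the
#'   apparent parameterization absorbs F into Cl/F and V/F).
#' @return input rate, in dose units per hour.
#' @export
transit_input_rate <- function(t, dose, Mtt, Ktr, bio_f = 1) {
  shape <- Ktr * Mtt
  if (!(shape > 0)) stop("requires Ktr*Mtt > 0 (n > -1)")
  r <- ifelse(t > 0, dgamma(t, shape = shape, rate = Ktr), 0)
  r[!is.finite(r)] <- 0   # shape < 1 is singular exactly at t = 0
  bio_f * dose * r
}

as_struct_params <- function(params) {
  p <- unlist(params)[PK_PARAM_NAMES]
  if (anyNA(p)) stop("params must contain ", paste(PK_PARAM_NAMES, collapse = ", "))
  if (any(p[c("Mtt", "Ktr", "ka", "Cl", "V1", "V2")] <= 0) || p["Q"] < 0)
    stop("structural parameters must be positive (Q >= 0)")
  p
}

#' Predict concentrations under the two-compartment transit-absorption model
#'
#' Solves dAa/dt = sum_d input_d(t) - ka*Aa;
#' dAc/dt = ka*Aa - (Cl/V1 + Q/V1)*Ac + (Q/V2)*Ap;
#' dAp/dt = (Q/V1)*Ac - (Q/V2)*Ap; conc = Ac/V1.
#' Doses are superposed through their transit-input rates. The apparent
#' (oral) parameterization is used: bio_f is fixed at 1 and F is absorbed
#' into Cl/F, V/F.
#'
#' @param params named vector/list with `Mtt`, `Ktr`, `ka`, `Cl`, `V1`,
#'   `Q`, `V2` (h, 1/h, 1/h, L/h, L, L/h, L).
#' @param doses data.frame with columns `time` (h) and `amt` (mg), or a
#'   regimen list as from [dose_regimen()].
#' @param times observation times (h).
#' @param engine `"lsoda"` (adaptive stiff-safe reference route) or
#'   `"grid"` (compiled fixed-step route used in estimation loops).
#' @param rtol,atol tolerances for the lsoda route.
#' @param dt step for the grid route (h).
#' @return concentrations (mg/L = ug/mL) at `times`.
#' @export
predict_conc <- function(params, doses, times, engine = c("lsoda", "grid"),
                         rtol = 1e-8, atol = 1e-12, dt = 0.01) {
  engine <- match.arg(engine)
  p <- as_struct_params(params)
  doses <- as_dose_table(doses)
  if (nrow(doses) == 0 || all(doses$amt == 0)) return(numeric(length(times)) * 0)
  ord <- order(times)
  tt <- times[ord]
  if (engine == "grid") {
    out <- pred_2cpt_transit_cpp(unname(p), doses$time, doses$amt, tt, dt)
  } else {
    shape <- p["Ktr"] * p["Mtt"]
    rate_in <- function(t) {
      r <- 0
      for (d in seq_len(nrow(doses))) {
        u <- t - doses$time[d]
        if (u > 0) {
          g <- dgamma(u, shape = shape, rate = p[["Ktr"]])
          if (is.finite(g)) r <- r + doses$amt[d] * g
        }
      }
      r
    }
    deriv <- function(t, y, parms) {
      list(c(rate_in(t) - p[["ka"]] * y[1],
             p[["ka"]] * y[1] - (p[["Cl"]] + p[["Q"]]) / p[["V1"]] * y[2] +
               p[["Q"]] / p[["V2"]] * y[3],
             p[["Q"]] / p[["V1"]] * y[2] - p[["Q"]] / p[["V2"]] * y[3]))
    }
    t_solve <- sort(unique(c(0, doses$time, tt[tt >= 0])))
    sol <- deSolve::lsoda(c(0, 0, 0), t_solve, deriv, parms = NULL,
                          rtol = rtol, atol = atol)
    conc <- sol[, 3] / p[["V1"]]
    out <- approx(t_solve, conc, xout = pmax(tt, 0), rule = 2)$y
    out[tt <= 0] <- 0
  }
  out[order(ord)] <- out
  out
}

#' Dosing regimen
#'
#' @param dose_amount dose (mg); `interval` (h); `n_doses` number of doses;
#'   `route` only `"oral_ir_tablet"` is modeled; `prandial_state` fasted/fed
#'   (fed is a placeholder flag).
#' @return a `dose_regimen` list.
#' @export
dose_regimen <- function(dose_amount = 4, interval = 6, n_doses = 4,
                         route = "oral_ir_tablet",
                         prandial_state = c("fasted", "fed")) {
  stopifnot(dose_amount > 0, interval > 0, n_doses >= 1)
  structure(list(dose_amount = dose_amount, interval = interval,
                 n_doses = n_doses, route = match.arg(route, "oral_ir_tablet"),
                 prandial_state = match.arg(prandial_state)),
            class = "dose_regimen")
}

as_dose_table <- function(doses) {
  if (inherits(doses, "dose_regimen"))
    return(data.frame(time = (seq_len(doses$n_doses) - 1) * doses$interval,
                      amt = doses$dose_amount))
  stopifnot(is.data.frame(doses), all(c("time", "amt") %in% names(doses)))
  doses
}

#' Combined residual-error standard deviation
#'
#' Observation model Y = f + sd(f) * eps with eps standard normal and
#' sd(f) = sqrt(a^2 + b^2 f^2) ("combined2", the default) or
#' sd(f) = a + b*f ("combined1").
#'
#' @param f predicted concentration(s), non-negative.
#' @param error list/vector with constants `a` (concentration units) and
#'   `b` (unitless); not both zero.
#' @param form error-model form.
#' @return residual SD at each `f`.
#' @export
residual_sd <- function(f, error, form = c("combined2", "combined1")) {
  form <- match.arg(form)
  a <- error[["a"]]; b <- error[["b"]]
  if (a < 0 || b < 0 || (a == 0 && b == 0))
    stop("error constants must be non-negative and not both zero")
  if (form == "combined2") sqrt(a^2 + b^2 * f^2) else a + b * f
}

#' Population PK model
#'
#' Container for the NLME model: fixed effects `theta` (one per structural
#' parameter), diagonal IIV standard deviations `omega` (additive normal
#' random effects, matching a normal parameter distribution), covariate
#' links, and the combined residual-error constants.
#'
#' @param theta named numeric over `Mtt, Ktr, ka, Cl, V1, Q, V2`.
#' @param omega named numeric, same names, `>= 0`.
#' @param error c(a =, b =).
#' @param links list of links from [covariate_link()].
#' @param error_form `"combined2"` or `"combined1"`.
#' @return object of class `pop_model`.
#' @export
population_model <- function(theta, omega = setNames(rep(0, 7), PK_PARAM_NAMES),
                             error = c(a = 1e-5, b = 0.1), links = list(),
                             error_form = "combined2") {
  theta <- as_struct_params(theta)
  omega <- unlist(omega)
  if (is.null(names(omega))) {
    if (length(omega) != 7) stop("unnamed omega must have length 7")
    names(omega) <- PK_PARAM_NAMES
  } else {
    omega <- omega[PK_PARAM_NAMES]
    omega[is.na(omega)] <- 0
    names(omega) <- PK_PARAM_NAMES
  }
  if (any(omega < 0)) stop("omega must be non-negative")
  residual_sd(1, error, error_form)  # validates the error constants
  structure(list(theta = theta, omega = omega, error = c(a = unname(error[["a"]]),
                 b = unname(error[["b"]])), links = links,
                 error_form = error_form, distribution = "normal"),
            class = "pop_model")
}

#' Covariate link
#'
#' Additive effect on the natural parameter scale: a continuous covariate
#' contributes `beta * (cov - ref)` (centered at `ref`, typically the
#' dataset median); a categorical covariate contributes `beta` for the
#' non-reference category coded by `category`.
#'
#' @param parameter structural parameter name.
#' @param covariate dataset column name.
#' @param kind `"continuous"` or `"categorical"`.
#' @param beta effect size (parameter units).
#' @param ref centering value (continuous) or reference code (categorical).
#' @param category the non-reference category code the effect applies to
#'   (categorical only).
#' @export
covariate_link <- function(parameter, covariate,
                           kind = c("continuous", "categorical"),
                           beta = 0, ref = 0, category = 1) {
  kind <- match.arg(kind)
  stopifnot(parameter %in% PK_PARAM_NAMES)
  structure(list(parameter = parameter, covariate = covariate, kind = kind,
                 beta = beta, ref = ref, category = category),
            class = "covariate_link")
}

link_label <- function(l) paste0(l$parameter, "~", l$covariate,
                                 if (l$kind == "categorical") paste0("==", l$category) else "")

# covariate contribution to one subject's parameter vector
link_shift <- function(links, covariates) {
  shift <- setNames(rep(0, 7), PK_PARAM_NAMES)
  for (l in links) {
    x <- covariates[[l$covariate]]
    if (is.null(x)) stop("unknown covariate: ", l$covariate)
    eff <- if (l$kind == "continuous") l$beta * (x - l$ref) else
      l$beta * as.numeric(x == l$category)
    shift[l$parameter] <- shift[l$parameter] + eff
  }
  shift
}

#' Individual parameters from population model, covariates and random effects
#'
#' `p_i = theta + sum(link effects) + eta` on the natural scale. During
#' estimation (`mode = "estimate"`) non-positive values are clipped at
#' 1e-6 and flagged via attribute `clipped`; simulation code resamples
#' instead (see [simulate_dataset()]).
#'
#' @param pop a `pop_model`.
#' @param covariates one-row data.frame (or list) of covariate values.
#' @param eta named/unnamed numeric of length 7 (eta scale).
#' @param mode `"estimate"` or `"raw"` (no clipping).
#' @return named structural parameter vector.
#' @export
individual_params <- function(pop, covariates = list(), eta = rep(0, 7),
                              mode = c("estimate", "raw")) {
  mode <- match.arg(mode)
  eta <- unname(unlist(eta))
  if (length(eta) != 7) stop("eta must have length 7")
  p <- pop$theta + link_shift(pop$links, covariates) + eta
  clipped <- p <= 0
  if (mode == "estimate" && any(clipped)) p[clipped] <- 1e-6
  attr(p, "clipped") <- any(clipped)
  p
}

#' Simulate a NONMEM-style popPK dataset from a population model
#'
#' Draws per-subject random effects eta ~ N(0, diag(omega^2)) (subjects
#' whose parameter vector has a non-positive component are re-drawn), and
#' per-observation residual noise under the model's error form. Fully
#' deterministic under `seed`; per-subject substreams make the result
#' invariant to subject order.
#'
#' @param pop a `pop_model`.
#' @param design list with `covariates` (data.frame, one row per subject,
#'   must contain `ID`), `schedule` (observation times, h) and `regimen`
#'   (a [dose_regimen()]).
#' @param seed integer seed.
#' @param noise simulate residual error (TRUE) or return noiseless
#'   individual predictions.
#' @return data.frame of event records: ID, TIME, DV, AMT, EVID, MDV plus
#'   the covariate columns; DV in ug/mL. Attribute `"eta"` carries the
#'   simulated random effects, `"params"` the individual parameters.
#' @export
simulate_dataset <- function(pop, design, seed = 1, noise = TRUE) {
  covs <- design$covariates
  stopifnot(is.data.frame(covs), "ID" %in% names(covs),
            length(design$schedule) >= 1)
  doses <- as_dose_table(design$regimen)
  n <- nrow(covs)
  etas <- matrix(0, n, 7, dimnames = list(covs$ID, PK_PARAM_NAMES))
  pars <- etas
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    set.seed(derive_seed(seed, covs$ID[i], 1))
    for (try in 1:100) {
      eta <- rnorm(7, 0, pop$omega)
      p <- individual_params(pop, covs[i, , drop = FALSE], eta, mode = "raw")
      if (all(p > 0)) break
      if (try == 100) stop("could not draw positive parameters for subject ",
                           covs$ID[i])
    }
    etas[i, ] <- eta; pars[i, ] <- p
    f <- predict_conc(p, doses, design$schedule, engine = "grid", dt = 0.01)
    dv <- f
    if (noise && !(pop$error[["a"]] == 0 && pop$error[["b"]] == 0)) {
      sdv <- residual_sd(f, pop$error, pop$error_form)
      dv <- f + sdv * rnorm(length(f))
    }
    obs <- data.frame(ID = covs$ID[i], TIME = design$schedule, DV = dv,
                      AMT = 0, EVID = 0L, MDV = 0L)
    dsr <- data.frame(ID = covs$ID[i], TIME = doses$time, DV = NA_real_,
                      AMT = doses$amt, EVID = 1L, MDV = 1L)
    sub <- rbind(dsr, obs)
    sub <- sub[order(sub$TIME, -sub$EVID), ]
    for (cn in setdiff(names(covs), "ID")) sub[[cn]] <- covs[[cn]][i]
    rows[[i]] <- sub
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "eta") <- etas
  attr(out, "params") <- pars
  out
}

#' Packaged population model: published oral-salbutamol popPK estimates
#'
#' The final two-compartment transit-absorption model for 4 mg oral
#' salbutamol: fixed effects (Mtt 9.50 h, Ktr 0.15 1/h, ka 2.91 1/h,
#' Cl/F 140 L/h, V1/F 77.5 L, Q/F 48.9 L/h, V2/F 130 L), additive-normal
#' IIV, and combined residual-error constants a = 1.9e-5 ug/mL,
#' b = 1.5e-3. The published IIV constants (0.43, 0.32, 0.41, 0.38,
#' 0.36, 0.92, 0.87) are read as relative standard deviations
#' (coefficients of variation of the normal parameter distribution) and
#' converted to absolute SDs as `omega = IIV * theta`: the absolute
#' reading would give a near-degenerate population (e.g. Cl SD of
#' 0.38 L/h on 140 L/h, and a Ktr distribution truncated at zero for
#' two thirds of its mass), which no popPK analysis would report.
#' Covariate links are not shipped (no published effect sizes); they are
#' discovered by the covariate-search layer.
#'
#' @return a `pop_model`.
#' @export
default_poppk_model <- function() {
  theta <- c(Mtt = 9.50, Ktr = 0.15, ka = 2.91, Cl = 140, V1 = 77.5,
             Q = 48.9, V2 = 130)
  iiv <- c(Mtt = 0.43, Ktr = 0.32, ka = 0.41, Cl = 0.38, V1 = 0.36,
           Q = 0.92, V2 = 0.87)
  population_model(theta, omega = iiv * theta,
                   error = c(a = 0.19e-4, b = 0.15e-2))
}

#' Default rich sampling schedule (~21 samples over 24 h)
#' @return numeric vector of observation times (h).
#' @export
default_schedule <- function() {
  c(0.25, 0.5, 1, 1.5, 2, 3, 4, 5, 6, 6.5, 7, 8, 9, 10, 12, 12.5, 14,
    16, 18, 20, 24)
}
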