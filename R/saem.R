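#' SAEM settings
#'
#' @param k1 exploratory iterations (step size 1, simulated annealing on
#'   the variance components).
#' @param k2 smoothing iterations (step size `(k - k1)^-0.7`).
#' @param n_sweeps MCMC kernel sweeps per subject per iteration; each
#'   sweep runs an independent prior-proposal kernel and an adaptive
#'   joint random-walk kernel (target acceptance 0.3-0.4).
#' @param dt inner-loop integration step (h) for the compiled predictor.
#' @param anneal annealing factor (variance floors decay by this per
#'   exploratory iteration).
#' @param keep_draws number of final iterations from which conditional
#'   eta draws are retained (used by the correlation-based covariate
#'   search).
#' @return list of settings.
#' @export
saem_settings <- function(k1 = 300, k2 = 150, n_sweeps = 2, dt = 0.02,
                          anneal = 0.95, keep_draws = 50,
                          warm_start_eta = TRUE, map_every = 0,
                          branch_constraint = TRUE) {
  list(k1 = k1, k2 = k2, n_sweeps = n_sweeps, dt = dt, anneal = anneal,
       keep_draws = keep_draws, warm_start_eta = warm_start_eta,
       map_every = map_every, branch_constraint = branch_constraint)
}

# absorption faster than transit (ka >= Ktr): the package's resolution of
# the transit-chain flip-flop ambiguity, applied throughout estimation
in_branch_ok <- function(p, constrain) !constrain || p[[3]] >= p[[2]]

# individual weighted least-squares fits (log scale) used to place the
# chain at each subject's conditional mode before SAEM starts; rich
# near-noiseless profiles make those modes extremely sharp, which plain
# random-walk sampling is slow to locate from a distant start
warm_start_etas <- function(data, mu, pred) {
  n <- length(data)
  eta <- matrix(0, n, 7)
  lo <- log(PK_PARAM_BOX[1, ]); hi <- log(PK_PARAM_BOX[2, ])
  for (i in seq_len(n)) {
    y <- data[[i]]$y
    w2 <- (0.02 * max(abs(y)))^2 + (0.1 * pmax(y, 0))^2
    cur <- pmin(pmax(pmax(mu[i, ], 1e-6), PK_PARAM_BOX[1, ]),
                PK_PARAM_BOX[2, ])
    ok <- FALSE
    # first pass at a coarse weighting floor, then iteratively-reweighted
    # tightening down to the profile's own residual scale
    for (pass in 1:3) {
      obj <- function(lp) {
        f <- tryCatch(pred(i, exp(lp)), error = function(e) NULL)
        if (is.null(f)) return(1e10)
        sum((y - f)^2 / w2)
      }
      opt <- tryCatch(nlminb(log(cur), obj, lower = lo, upper = hi,
                             control = list(iter.max = 300)),
                      error = function(e) NULL)
      if (is.null(opt) || !is.finite(opt$objective)) break
      cur <- exp(opt$par)
      ok <- TRUE
      f <- pred(i, cur)
      w2 <- max(mean((y - f)^2), (1e-5 * max(abs(y)))^2)
    }
    if (ok) eta[i, ] <- cur - mu[i, ]
  }
  eta
}

# split a NONMEM-style event-record table into per-subject pieces
parse_pk_dataset <- function(ds) {
  req <- c("ID", "TIME", "DV", "AMT", "EVID")
  miss <- setdiff(req, names(ds))
  if (length(miss)) stop("dataset missing columns: ", paste(miss, collapse = ", "))
  covcols <- setdiff(names(ds), c(req, "MDV"))
  lapply(split(ds, ds$ID), function(sub) {
    obs <- sub[sub$EVID == 0, ]
    dos <- sub[sub$EVID == 1, ]
    if (nrow(obs) == 0 || nrow(dos) == 0)
      stop("every subject needs at least one dose and one observation (ID ",
           sub$ID[1], ")")
    ord <- order(obs$TIME)
    list(id = sub$ID[1], times = obs$TIME[ord], y = obs$DV[ord],
         doses = data.frame(time = dos$TIME, amt = dos$AMT),
         cov = sub[1, covcols, drop = FALSE])
  })
}

make_pred <- function(data, dt) {
  function(i, p) {
    pred_2cpt_transit_cpp(pmax(unname(p), 1e-6), data[[i]]$doses$time,
                          data[[i]]$doses$amt, data[[i]]$times, dt)
  }
}

# per-parameter design matrices implied by the covariate links
build_designs <- function(links, covtab, n) {
  X <- list()
  for (p in PK_PARAM_NAMES) {
    cols <- list(`(intercept)` = rep(1, n))
    for (l in links) {
      if (l$parameter != p) next
      x <- covtab[[l$covariate]]
      if (is.null(x)) stop("unknown covariate: ", l$covariate)
      v <- if (l$kind == "continuous") x - l$ref else as.numeric(x == l$category)
      cols[[link_label(l)]] <- v
    }
    X[[p]] <- do.call(cbind, cols)
  }
  X
}

#' Initial estimates from per-subject non-compartmental analysis
#'
#' Heuristics: Cl/F from total dose over AUC, V from Cl * t_half / ln 2
#' (split evenly over V1 and V2), Mtt from the median Tmax, ka = 1 1/h,
#' Q = Cl/3; IIV standard deviations start at 30% of the fixed effect and
#' the error constants at 10% of the observation SD (additive) and 0.3
#' (proportional).
#'
#' The NCA values anchor a set of per-subject weighted least-squares
#' fits (log-parameter scale, several starts); their component-wise
#' medians and spreads give the population starting values. The transit
#' chain plus first-order absorption admits exchange-symmetric
#' ("flip-flop") solutions that rich profiles cannot distinguish
#' statistically; among near-equivalent local optima the fit in the
#' conventional branch (ka at least as fast as the transit rate Ktr, as
#' in the reference parameterization) is preferred. The per-subject fits
#' are attached as attribute `"individual_fits"` and reused by
#' [saem_fit()] to warm-start the conditional samples.
#'
#' @param dataset event-record data.frame.
#' @param refine run the per-subject refinement (default TRUE; FALSE
#'   returns the raw NCA heuristics).
#' @param dt integration step for the refinement fits.
#' @return a `pop_model` usable as `init` for [saem_fit()].
#' @export
init_from_nca <- function(dataset, refine = TRUE, dt = 0.05) {
  data <- parse_pk_dataset(dataset)
  per <- lapply(data, function(s) {
    # residual noise can push near-zero observations slightly negative
    y <- pmax(s$y, 0)
    n <- nca_summary(s$times, y, dose = sum(s$doses$amt))
    # under repeated dosing, take Tmax within the first dosing interval
    int1 <- if (nrow(s$doses) > 1) min(diff(sort(s$doses$time))) else
      max(s$times)
    in1 <- s$times <= int1
    c(cl = if (is.finite(n$cl_over_f)) n$cl_over_f else
        sum(s$doses$amt) / n$auc_last,
      thalf = if (is.finite(n$t_half)) n$t_half else NA,
      tmax = s$times[in1][which.max(y[in1])])
  })
  per <- do.call(rbind, per)
  cl0 <- median(per[, "cl"], na.rm = TRUE)
  th0 <- median(per[, "thalf"], na.rm = TRUE)
  if (!is.finite(th0)) th0 <- 3
  th0 <- min(max(th0, 0.5), 12)           # truncated profiles give crude tails
  v0 <- cl0 * th0 / log(2)
  mtt0 <- min(max(0.5, 0.75 * median(per[, "tmax"], na.rm = TRUE)), 12)
  yall <- unlist(lapply(data, `[[`, "y"))
  theta <- c(Mtt = mtt0, Ktr = 2 / mtt0, ka = 1, Cl = cl0, V1 = v0 / 2,
             Q = cl0 / 3, V2 = v0 / 2)
  a0 <- max(0.1 * sd(yall), 1e-10)
  if (!refine)
    return(population_model(theta, omega = 0.3 * abs(theta),
                            error = c(a = a0, b = 0.3)))
  ind <- individual_ls_fits(data, theta, dt = dt)
  theta1 <- apply(ind$params, 2, median)
  names(theta1) <- PK_PARAM_NAMES
  # consensus restart: weakly determined components (deep ridges in the
  # individual surfaces) are re-anchored at the first-pass medians
  ind <- individual_ls_fits(data, theta1, dt = dt, consensus = TRUE)
  theta1 <- apply(ind$params, 2, median)
  names(theta1) <- PK_PARAM_NAMES
  spread <- apply(ind$params, 2, mad)
  omega1 <- pmin(pmax(spread, 0.05 * abs(theta1)), 0.5 * abs(theta1))
  b0 <- min(max(median(ind$rel_resid), 1e-3), 0.3)
  out <- population_model(theta1, omega = omega1,
                          error = c(a = max(0.02 * sd(yall), 1e-10), b = b0))
  attr(out, "individual_fits") <- ind$params
  out
}

# per-subject weighted least-squares fits on the log-parameter scale,
# multi-start around theta0, with the flip-flop branch tie-break: among
# local optima within a chi-square-scale slack of the best, prefer
# ka >= Ktr (absorption at least as fast as the transit rate). In the
# consensus pass a mild relative ridge toward theta0 (prior_cv) anchors
# directions the profile does not identify; identified directions
# overpower it. The first pass is unpenalized so the consensus itself
# is data-driven.
individual_ls_fits <- function(data, theta0, dt = 0.05, consensus = FALSE,
                               prior_cv = 0.35) {
  pred <- make_pred(data, dt)
  n <- length(data)
  params <- matrix(NA_real_, n, 7, dimnames = list(NULL, PK_PARAM_NAMES))
  rel_resid <- numeric(n)
  lo <- log(PK_PARAM_BOX[1, ]); hi <- log(PK_PARAM_BOX[2, ])
  svars <- if (consensus) list(c(1, 1, 1, 1, 1, 1, 1)) else
    list(c(1, 1, 1, 1, 1, 1, 1),
         c(1, 1, 1, 1, 0.1, 1, 1),
         c(1, 1, 1, 1, 0.3, 1, 0.3),
         c(1, 1, 1, 1, 0.1, 0.5, 0.3),   # volume-scale variants only: a
         # perturbed-ka start would place solutions along the flat
         # absorption ridge wherever it happened to begin
         c(2, 0.5, 1, 1, 0.2, 1, 0.5))
  for (i in seq_len(n)) {
    y <- data[[i]]$y
    w2 <- (0.02 * max(abs(y)))^2 + (0.1 * pmax(y, 0))^2
    pen <- if (consensus)
      function(p) sum(((p - theta0) / (prior_cv * theta0))^2) else
      function(p) 0
    obj <- function(lp) {
      p <- exp(lp)
      f <- tryCatch(pred(i, p), error = function(e) NULL)
      if (is.null(f)) return(1e10)
      sum((y - f)^2 / w2) + pen(p)
    }
    sols <- list()
    for (sv in svars) {
      opt <- tryCatch(nlminb(pmin(pmax(log(theta0 * sv), lo), hi), obj,
                             lower = lo, upper = hi,
                             control = list(iter.max = 300)),
                      error = function(e) NULL)
      if (!is.null(opt) && is.finite(opt$objective))
        sols[[length(sols) + 1]] <- opt
    }
    if (!length(sols)) { params[i, ] <- theta0; next }
    objs <- vapply(sols, `[[`, 0, "objective")
    pars <- lapply(sols, function(o) setNames(exp(o$par), PK_PARAM_NAMES))
    in_branch <- vapply(pars, function(p) p["ka"] >= p["Ktr"], TRUE)
    slack <- 0.25 * length(y)
    pick <- which.min(objs)
    if (any(in_branch) && min(objs[in_branch]) <= min(objs) + slack)
      pick <- which(in_branch)[which.min(objs[in_branch])]
    # iteratively-reweighted tightening: re-fit at the residual scale the
    # fit itself achieves, down to the data's own noise floor
    cur <- pars[[pick]]
    s2 <- NULL
    for (pass in 1:2) {
      f <- pred(i, cur)
      s2 <- max(mean((y - f)^2), (1e-5 * max(abs(y)))^2)
      objt <- function(lp) {
        pt <- exp(lp)
        ft <- tryCatch(pred(i, pt), error = function(e) NULL)
        if (is.null(ft)) return(1e10)
        sum((y - ft)^2 / s2) + pen(pt)
      }
      opt <- tryCatch(nlminb(log(cur), objt, lower = lo, upper = hi,
                             control = list(iter.max = 400)),
                      error = function(e) NULL)
      if (!is.null(opt) && is.finite(opt$objective))
        cur <- setNames(exp(opt$par), PK_PARAM_NAMES)
    }
    params[i, ] <- cur
    rel_resid[i] <- sqrt(s2) / max(mean(y[y > 0]), 1e-12)
  }
  list(params = params, rel_resid = rel_resid)
}

#' Fit the population model by SAEM
#'
#' Stochastic approximation EM with Metropolis-within-Gibbs conditional
#' sampling of the additive-normal random effects: an exploratory phase
#' (`k1` iterations, step size 1, simulated annealing keeping the
#' variance components from collapsing early) followed by a smoothing
#' phase (`k2` iterations, step size `(k - k1)^-0.7`). M-steps are exact
#' sufficient-statistic updates: per-parameter least squares for the
#' fixed effects and covariate coefficients, moment updates for the
#' diagonal omega, and a two-parameter minimization for the combined
#' residual-error constants. Fully deterministic under `seed`, with
#' per-subject, per-iteration RNG substreams keyed by subject ID so the
#' result is invariant to subject ordering.
#'
#' @param dataset NONMEM-style event records (ID, TIME, DV, AMT, EVID,
#'   covariates), DV in ug/mL.
#' @param init a `pop_model` with initial values (default: NCA-informed
#'   heuristics via [init_from_nca()]).
#' @param links optional list of [covariate_link()]s; overrides
#'   `init$links`. Continuous links with `ref = NA` are centered at the
#'   dataset median.
#' @param settings from [saem_settings()].
#' @param seed integer.
#' @return object of class `saem_fit`: `model` (estimated `pop_model`),
#'   `coefs` (per-parameter fixed-effect/covariate coefficients), `eta`
#'   (final conditional draws), `eta_draws` (retained conditional
#'   samples), `trace` (per-iteration estimates), `flags` (convergence /
#'   clipping / omega-collapse diagnostics), plus the parsed data.
#' @export
saem_fit <- function(dataset, init = NULL, links = NULL,
                     settings = saem_settings(), seed = 1) {
  data <- parse_pk_dataset(dataset)
  if (is.null(init)) init <- init_from_nca(dataset)
  if (is.null(links)) links <- init$links
  covtab <- do.call(rbind, lapply(data, function(s) s$cov))
  links <- lapply(links, function(l) {
    if (l$kind == "continuous" && (is.null(l$ref) || is.na(l$ref)))
      l$ref <- median(covtab[[l$covariate]])
    l
  })
  n <- length(data)
  X <- build_designs(links, covtab, n)
  ids <- vapply(data, `[[`, 0, "id")
  pred <- make_pred(data, settings$dt)
  err_form <- init$error_form

  coefs <- lapply(PK_PARAM_NAMES, function(p) {
    cf <- numeric(ncol(X[[p]]))
    cf[1] <- init$theta[[p]]
    for (j in seq_along(links)) {
      l <- links[[j]]
      if (l$parameter == p && link_label(l) %in% colnames(X[[p]]))
        cf[match(link_label(l), colnames(X[[p]]))] <- l$beta
    }
    setNames(cf, colnames(X[[p]]))
  })
  names(coefs) <- PK_PARAM_NAMES
  mu <- vapply(PK_PARAM_NAMES, function(p) drop(X[[p]] %*% coefs[[p]]),
               numeric(n))
  omega <- init$omega
  a <- init$error[["a"]]; b <- init$error[["b"]]
  eta <- matrix(0, n, 7, dimnames = list(ids, PK_PARAM_NAMES))
  if (isTRUE(settings$warm_start_eta)) {
    indf <- attr(init, "individual_fits")
    if (!is.null(indf) && nrow(indf) == n) eta[] <- indf - mu
    else eta[] <- warm_start_etas(data, mu, pred)
  }
  scale_s <- rep(0.4, n)
  S1 <- S2 <- NULL
  R2 <- F1 <- F2 <- NULL
  K <- settings$k1 + settings$k2
  npar <- sum(vapply(coefs, length, 0L)) + 7 + 2
  trace <- matrix(NA_real_, K, npar)
  colnames(trace) <- c(unlist(lapply(PK_PARAM_NAMES, function(p)
    paste0(p, ifelse(colnames(X[[p]]) == "(intercept)", "",
                     paste0(":", colnames(X[[p]])))))),
    paste0("omega_", PK_PARAM_NAMES), "a", "b")
  eta_draws <- list()
  clipped_any <- FALSE
  P <- mu
  Fi <- vector("list", n)
  # annealing floors decay on a fixed schedule from the initial values so
  # a single noisy error-update cannot ratchet the floor upward
  a_floor <- a; b_floor <- b

  for (k in seq_len(K)) {
    gam <- if (k <= settings$k1) 1 else (k - settings$k1)^(-0.7)
    active <- omega > 1e-12
    # exploratory-phase mode seeking: relocate each subject's random
    # effects at the conditional mode under the current population model;
    # rich low-noise profiles have conditional spikes that plain
    # random-walk kernels take very long to reach from a distant start
    do_map <- settings$map_every > 0 && k <= settings$k1 &&
      k %% settings$map_every == 1 && any(active)
    for (i in seq_len(n)) {
      set.seed(derive_seed(seed, k, round(ids[i] * 13)))
      y <- data[[i]]$y
      if (do_map) {
        bc <- isTRUE(settings$branch_constraint)
        nllmap <- function(e) {
          v <- -cond_logpost(e, active, mu[i, ], omega,
                             c(a = a, b = b), err_form, y,
                             function(p) pred(i, p))
          if (bc) {
            p <- mu[i, ]; p[active] <- p[active] + e
            v <- v + 1e6 * max(0, p[[2]] - p[[3]])^2
          }
          v
        }
        elo <- PK_PARAM_BOX[1, active] - mu[i, active]
        ehi <- PK_PARAM_BOX[2, active] - mu[i, active]
        opt <- tryCatch(nlminb(pmin(pmax(eta[i, active], elo), ehi), nllmap,
                               lower = elo, upper = ehi,
                               control = list(iter.max = 100)),
                        error = function(e) NULL)
        if (!is.null(opt) && is.finite(opt$objective))
          eta[i, active] <- opt$par
      }
      p0 <- mu[i, ] + eta[i, ]
      if (any(p0 <= 0)) clipped_any <- TRUE
      f0 <- pred(i, p0)
      ll0 <- sum(dnorm(y, f0, residual_sd(f0, c(a = a, b = b), err_form),
                       log = TRUE))
      if (any(active)) {
        n_acc <- 0L; n_try <- 0L
        for (sw in seq_len(settings$n_sweeps)) {
          # kernel 1: independent proposal from the prior
          etap <- eta[i, ]
          etap[active] <- rnorm(sum(active), 0, omega[active])
          p1 <- mu[i, ] + etap
          if (all(p1 >= PK_PARAM_BOX[1, ] & p1 <= PK_PARAM_BOX[2, ]) &&
              in_branch_ok(p1, settings$branch_constraint)) {
            f1 <- pred(i, p1)
            ll1 <- sum(dnorm(y, f1, residual_sd(f1, c(a = a, b = b), err_form),
                             log = TRUE))
            if (is.finite(ll1) && log(runif(1)) < ll1 - ll0) {
              eta[i, ] <- etap; f0 <- f1; ll0 <- ll1
            }
          }
          # kernel 2: adaptive joint random walk
          etap <- eta[i, ]
          etap[active] <- eta[i, active] +
            scale_s[i] * omega[active] * rnorm(sum(active))
          n_try <- n_try + 1L
          p1 <- mu[i, ] + etap
          if (all(p1 >= PK_PARAM_BOX[1, ] & p1 <= PK_PARAM_BOX[2, ]) &&
              in_branch_ok(p1, settings$branch_constraint)) {
            lp0 <- sum(dnorm(eta[i, active], 0, omega[active], log = TRUE))
            lp1 <- sum(dnorm(etap[active], 0, omega[active], log = TRUE))
            f1 <- pred(i, p1)
            ll1 <- sum(dnorm(y, f1, residual_sd(f1, c(a = a, b = b), err_form),
                             log = TRUE))
            if (is.finite(ll1) && log(runif(1)) < ll1 + lp1 - ll0 - lp0) {
              eta[i, ] <- etap; f0 <- f1; ll0 <- ll1
              n_acc <- n_acc + 1L
            }
          }
        }
        acc <- n_acc / n_try
        scale_s[i] <- min(50, max(1e-3, scale_s[i] * exp(0.4 * (acc - 0.35))))
      }
      P[i, ] <- mu[i, ] + eta[i, ]
      Fi[[i]] <- f0
    }
    # stochastic-approximation sufficient statistics
    if (is.null(S1)) {
      S1 <- P; S2 <- P^2
      R2 <- lapply(seq_len(n), function(i) (data[[i]]$y - Fi[[i]])^2)
      F1 <- lapply(Fi, identity); F2 <- lapply(Fi, function(f) f^2)
    } else {
      S1 <- (1 - gam) * S1 + gam * P
      S2 <- (1 - gam) * S2 + gam * P^2
      for (i in seq_len(n)) {
        R2[[i]] <- (1 - gam) * R2[[i]] + gam * (data[[i]]$y - Fi[[i]])^2
        F1[[i]] <- (1 - gam) * F1[[i]] + gam * Fi[[i]]
        F2[[i]] <- (1 - gam) * F2[[i]] + gam * Fi[[i]]^2
      }
    }
    # M-step: fixed effects + covariate coefficients, then omega
    for (p in seq_along(PK_PARAM_NAMES)) {
      pn <- PK_PARAM_NAMES[p]
      cf <- qr.coef(qr(X[[pn]]), S1[, p])
      cf[is.na(cf)] <- 0
      if (cf[1] <= 0) {          # keep the fixed effect in the positive domain
        cf[1] <- max(1e-6, 0.5 * coefs[[pn]][[1]])
        clipped_any <- TRUE
      }
      coefs[[pn]] <- setNames(cf, colnames(X[[pn]]))
      mu[, p] <- drop(X[[pn]] %*% cf)
      om2 <- mean(S2[, p] - 2 * mu[, p] * S1[, p] + mu[, p]^2)
      om2 <- max(om2, 0)
      if (k <= settings$k1) om2 <- max(om2, settings$anneal * omega[p]^2)
      # guard against random-effect diffusion along non-identifiable
      # ridges: the IIV SD is capped at 1.5x the fixed effect (the
      # largest reference relative IIV is 0.92)
      omega[p] <- min(sqrt(om2), 1.5 * abs(cf[1]) + 1e-9)
    }
    # M-step: residual-error constants
    r2 <- unlist(R2); f1s <- unlist(F1); f2s <- unlist(F2)
    obj <- function(lab) {
      aa <- exp(lab[1]); bb <- exp(lab[2])
      s2 <- if (err_form == "combined2") aa^2 + bb^2 * f2s else
        (aa + bb * f1s)^2
      sum(log(s2) + r2 / s2)
    }
    opt <- nlminb(log(pmax(c(a, b), 1e-12)), obj,
                  lower = log(1e-12), upper = log(1e6))
    ab <- exp(opt$par)
    if (k <= settings$k1) {
      a_floor <- a_floor * settings$anneal
      b_floor <- b_floor * settings$anneal
      ab <- pmax(ab, c(a_floor, b_floor))
    }
    a <- ab[1]; b <- ab[2]
    # the chain lives in individual-parameter space: re-express the
    # random effects about the updated population means so the sampled
    # individual parameters do not jump when theta moves
    eta <- P - mu
    trace[k, ] <- c(unlist(coefs), omega, a, b)
    if (k > K - settings$keep_draws && (K - k) %% 2 == 0)
      eta_draws[[length(eta_draws) + 1]] <- eta
  }

  theta <- vapply(coefs, `[[`, 0, 1)
  names(theta) <- PK_PARAM_NAMES
  fitted_links <- lapply(links, function(l) {
    l$beta <- coefs[[l$parameter]][[link_label(l)]]
    l
  })
  # convergence: relative fixed-effect movement over the last 20% of
  # the smoothing phase
  tail_it <- max(2, ceiling(0.2 * settings$k2))
  tail_tr <- trace[(K - tail_it + 1):K, seq_len(npar - 9), drop = FALSE]
  mov <- apply(tail_tr, 2, function(v)
    (max(v) - min(v)) / max(abs(median(v)), 1e-12))
  model <- population_model(theta, omega = omega, error = c(a = a, b = b),
                            links = fitted_links, error_form = err_form)
  structure(list(
    model = model, coefs = coefs, designs = X, data = data, eta = eta,
    eta_draws = eta_draws, trace = trace, settings = settings, seed = seed,
    flags = list(converged = max(mov) <= 0.05, max_movement = max(mov),
                 clipped = clipped_any,
                 omega_collapsed = PK_PARAM_NAMES[omega < 1e-8])),
    class = "saem_fit")
}

#' Wrap a known population model as a fit object
#'
#' Builds the `saem_fit` structure around a given `pop_model` and
#' dataset without estimating anything (random effects at zero).
#' Useful for computing likelihoods, EBEs and simulation-based
#' diagnostics of a reference model.
#'
#' @param model a `pop_model` (continuous link refs must be set).
#' @param dataset event-record data.frame.
#' @param settings SAEM settings (only `dt` is used downstream).
#' @param seed stored seed.
#' @return an object of class `saem_fit`.
#' @export
as_saem_fit <- function(model, dataset, settings = saem_settings(),
                        seed = 1) {
  data <- parse_pk_dataset(dataset)
  covtab <- do.call(rbind, lapply(data, function(s) s$cov))
  n <- length(data)
  X <- build_designs(model$links, covtab, n)
  coefs <- lapply(PK_PARAM_NAMES, function(p) {
    cf <- numeric(ncol(X[[p]]))
    cf[1] <- model$theta[[p]]
    for (l in model$links)
      if (l$parameter == p)
        cf[match(link_label(l), colnames(X[[p]]))] <- l$beta
    setNames(cf, colnames(X[[p]]))
  })
  names(coefs) <- PK_PARAM_NAMES
  structure(list(model = model, coefs = coefs, designs = X, data = data,
                 eta = matrix(0, n, 7,
                              dimnames = list(NULL, PK_PARAM_NAMES)),
                 eta_draws = list(), trace = NULL, settings = settings,
                 seed = seed, flags = list(converged = NA)),
            class = "saem_fit")
}

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# conditional log-posterior of eta for one subject (up to a constant)
cond_logpost <- function(eta_act, active, mu_i, omega, err, err_form, y, predfun) {
  eta <- numeric(7); eta[active] <- eta_act
  f <- predfun(mu_i + eta)
  sum(dnorm(y, f, residual_sd(f, err, err_form), log = TRUE)) +
    sum(dnorm(eta_act, 0, omega[active], log = TRUE))
}

#' Marginal -2 log-likelihood by importance sampling
#'
#' Per-subject marginal likelihoods by importance sampling with a
#' location-scale t (4 df) proposal centered at the subject's
#' conditional mode (Laplace scales from a numeric Hessian, with the
#' population omega as fallback). With all omega zero there are no
#' latent variables and the exact Gaussian log-likelihood is returned.
#'
#' @param fit a `saem_fit` (or a list with `model` and `data`).
#' @param n_is importance-sampling draws per subject.
#' @param seed integer; per-subject substreams keyed by ID.
#' @return list with `minus2ll`, `mc_se` (Monte-Carlo SE of -2LL), `ess`
#'   (min effective sample size fraction) and per-subject log-likelihoods.
#' @export
loglik_importance <- function(fit, n_is = 1000, seed = 1) {
  model <- fit$model; data <- fit$data
  pred <- make_pred(data, fit$settings$dt %||% 0.02)
  omega <- model$omega; err <- model$error; err_form <- model$error_form
  active <- omega > 1e-12
  na <- sum(active)
  n <- length(data)
  ll <- se2 <- numeric(n)
  essf <- rep(1, n)
  ebes <- compute_ebes(fit, quiet = TRUE)
  for (i in seq_len(n)) {
    y <- data[[i]]$y
    mu_i <- ebes$mu[i, ]
    predfun <- function(p) pred(i, p)
    if (na == 0) {
      f <- predfun(mu_i)
      ll[i] <- sum(dnorm(y, f, residual_sd(f, err, err_form), log = TRUE))
      next
    }
    mode <- ebes$eta[i, active]
    # Laplace scale from a diagonal numeric Hessian at the mode
    hstep <- pmax(0.05 * omega[active], 1e-6)
    sc <- omega[active]
    g0 <- cond_logpost(mode, active, mu_i, omega, err, err_form, y, predfun)
    for (j in seq_len(na)) {
      ej <- numeric(na); ej[j] <- hstep[j]
      gp <- cond_logpost(mode + ej, active, mu_i, omega, err, err_form, y, predfun)
      gm <- cond_logpost(mode - ej, active, mu_i, omega, err, err_form, y, predfun)
      h <- -(gp - 2 * g0 + gm) / hstep[j]^2
      if (is.finite(h) && h > 0) sc[j] <- min(1 / sqrt(h), 3 * omega[active][j])
    }
    set.seed(derive_seed(seed, 31L, round(data[[i]]$id * 13)))
    tdr <- matrix(stats::rt(n_is * na, df = 4), n_is, na)
    lw <- numeric(n_is)
    for (kk in seq_len(n_is)) {
      eta_act <- mode + sc * tdr[kk, ]
      eta <- numeric(7); eta[active] <- eta_act
      f <- predfun(mu_i + eta)
      ly <- sum(dnorm(y, f, residual_sd(f, err, err_form), log = TRUE))
      lp <- sum(dnorm(eta_act, 0, omega[active], log = TRUE))
      lq <- sum(stats::dt(tdr[kk, ], df = 4, log = TRUE) - log(sc))
      lw[kk] <- ly + lp - lq
    }
    lw[!is.finite(lw)] <- -Inf
    ll[i] <- logsumexp(lw) - log(n_is)
    v <- exp(lw - max(lw))
    essf[i] <- sum(v)^2 / sum(v^2) / n_is
    se2[i] <- var(v) / n_is / mean(v)^2
  }
  if (any(essf < 0.05))
    warning("effective sample size below 5% of draws for ",
            sum(essf < 0.05), " subject(s)")
  list(minus2ll = -2 * sum(ll), mc_se = 2 * sqrt(sum(se2)),
       ess_min = min(essf), ll_by_subject = ll)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Corrected Bayesian information criterion
#'
#' `BICc = -2LL + P_subject * log(N_subjects) + P_obs * log(N_obs)`:
#' subject-level parameters (fixed effects, covariate coefficients,
#' IIV variances) are penalized by the number of subjects, residual-error
#' parameters by the number of observations.
#'
#' @param minus2ll -2 log-likelihood.
#' @param n_subjects,n_obs counts.
#' @param p_subject,p_obs parameter counts for each level.
#' @return BICc value.
#' @export
bicc <- function(minus2ll, n_subjects, n_obs, p_subject, p_obs) {
  stopifnot(n_subjects > 0, n_obs > 0)
  minus2ll + p_subject * log(n_subjects) + p_obs * log(n_obs)
}

# parameter counts of a fitted model for the BICc penalty
model_dim <- function(model) {
  list(p_subject = 7 + length(model$links) + sum(model$omega > 1e-12),
       p_obs = sum(model$error > 1e-12))
}

#' Empirical Bayes estimates (conditional modes)
#'
#' Per subject, maximizes `p(y_i | eta) p(eta)` over the active random
#' effects by quasi-Newton optimization with multi-start (zero, the last
#' conditional MCMC draw, and its half); failed subjects are flagged and
#' fall back to eta = 0.
#'
#' @param fit a `saem_fit`.
#' @param quiet suppress per-subject failure warnings.
#' @return list with `eta` (n x 7), `params` (individual parameters),
#'   `mu` (population-predicted parameters incl. covariates), `flags`.
#' @export
compute_ebes <- function(fit, quiet = FALSE) {
  model <- fit$model; data <- fit$data
  pred <- make_pred(data, fit$settings$dt %||% 0.02)
  omega <- model$omega
  active <- omega > 1e-12
  n <- length(data)
  X <- fit$designs
  mu <- vapply(PK_PARAM_NAMES, function(p)
    drop(X[[p]] %*% fit$coefs[[p]]), numeric(n))
  if (n == 1) mu <- matrix(mu, 1, 7, dimnames = list(NULL, PK_PARAM_NAMES))
  eta <- matrix(0, n, 7, dimnames = list(names(data), PK_PARAM_NAMES))
  failed <- logical(n)
  if (any(active)) {
    for (i in seq_len(n)) {
      y <- data[[i]]$y
      predfun <- function(p) pred(i, p)
      nll <- function(e) -cond_logpost(e, active, mu[i, ], omega, model$error,
                                       model$error_form, y, predfun)
      # primary start at the conditional draw; zero and half-way starts
      # are a fallback when the first optimization fails or stalls
      starts <- list(fit$eta[i, active], numeric(sum(active)),
                     0.5 * fit$eta[i, active])
      best <- NULL
      for (s in starts) {
        opt <- tryCatch(nlminb(s, nll), error = function(e) NULL)
        if (!is.null(opt) && is.finite(opt$objective) &&
            (is.null(best) || opt$objective < best$objective)) best <- opt
        if (!is.null(best) && is.finite(best$objective) &&
            best$objective <= nll(s) + 1e-8) break
      }
      if (is.null(best)) {
        failed[i] <- TRUE
        if (!quiet) warning("EBE optimization failed for subject ",
                            data[[i]]$id, "; eta set to 0")
      } else eta[i, active] <- best$par
    }
  }
  params <- mu + eta
  list(eta = eta, params = params, mu = mu, flags = list(failed = failed))
}

#' Standard errors and RSE% by numeric Hessian of the IS log-likelihood
#'
#' Central-difference Hessian of the importance-sampling log-likelihood
#' at the estimates, using one fixed set of per-subject proposal draws
#' (common random numbers) so the surface is smooth in the parameters.
#' Model predictions are cached across perturbations that leave the
#' fixed-effect part unchanged. RSE = 100 * SE / |estimate|;
#' negative-curvature directions are flagged and reported as missing.
#'
#' @param fit a `saem_fit`.
#' @param n_is importance draws per subject (common across perturbations).
#' @param seed integer.
#' @param rel_step relative finite-difference step.
#' @return data.frame with `parameter`, `estimate`, `se`, `rse_percent`,
#'   `flag`.
#' @export
standard_errors <- function(fit, n_is = 100, seed = 1, rel_step = 0.05) {
  model <- fit$model; data <- fit$data
  pred <- make_pred(data, fit$settings$dt %||% 0.02)
  err_form <- model$error_form
  omega0 <- model$omega
  active <- omega0 > 1e-12
  na <- sum(active)
  n <- length(data)
  X <- fit$designs
  # parameter vector: per-parameter coefficients, active omegas, a, b
  cf_len <- vapply(fit$coefs, length, 0L)
  psi <- c(unlist(fit$coefs), omega0[active], model$error)
  pnames <- c(unlist(lapply(PK_PARAM_NAMES, function(p) {
    cn <- names(fit$coefs[[p]])
    ifelse(cn == "(intercept)", p, paste0(p, ":", cn))
  })), paste0("omega_", PK_PARAM_NAMES[active]), "a", "b")
  names(psi) <- pnames
  d <- length(psi)
  ncf <- sum(cf_len)
  ebes <- compute_ebes(fit, quiet = TRUE)
  # fixed proposal draws at the base estimates
  draws <- lapply(seq_len(n), function(i) {
    set.seed(derive_seed(seed, 67L, round(data[[i]]$id * 13)))
    sweep(matrix(stats::rt(n_is * na, df = 4), n_is, na), 2,
          pmax(omega0[active], 1e-4), "*") +
      matrix(ebes$eta[i, active], n_is, na, byrow = TRUE)
  })
  lq <- lapply(seq_len(n), function(i) {
    sc <- pmax(omega0[active], 1e-4)
    rowSums(stats::dt(sweep(draws[[i]] -
      matrix(ebes$eta[i, active], n_is, na, byrow = TRUE), 2, sc, "/"),
      df = 4, log = TRUE)) - sum(log(sc))
  })
  fcache <- new.env(parent = emptyenv())
  mu_for <- function(cf_vec) {
    cfl <- split(unname(cf_vec), rep(seq_along(cf_len), cf_len))
    m <- vapply(seq_along(PK_PARAM_NAMES), function(p)
      drop(X[[PK_PARAM_NAMES[p]]] %*% cfl[[p]]), numeric(n))
    if (n == 1) m <- matrix(m, 1, 7)
    m
  }
  ll_of <- function(psi_v) {
    cf_vec <- psi_v[seq_len(ncf)]
    om <- omega0; om[active] <- psi_v[ncf + seq_len(na)]
    ab <- c(a = psi_v[[d - 1]], b = psi_v[[d]])
    if (any(om[active] <= 0) || any(ab < 0)) return(NA_real_)
    key <- paste(format(cf_vec, digits = 17), collapse = ",")
    fs <- fcache[[key]]
    if (is.null(fs)) {
      mu <- mu_for(cf_vec)
      fs <- lapply(seq_len(n), function(i) {
        apply(draws[[i]], 1, function(ea) {
          eta <- numeric(7); eta[active] <- ea
          pred(i, mu[i, ] + eta)
        })
      })
      fcache[[key]] <- fs
    }
    tot <- 0
    for (i in seq_len(n)) {
      y <- data[[i]]$y
      fm <- fs[[i]]                       # n_obs x n_is
      sdm <- residual_sd(fm, ab, err_form)
      ly <- colSums(dnorm(y, fm, sdm, log = TRUE))
      lp <- rowSums(dnorm(draws[[i]], 0, rep(om[active], each = n_is),
                          log = TRUE))
      tot <- tot + logsumexp(ly + lp - lq[[i]]) - log(n_is)
    }
    tot
  }
  h <- pmax(rel_step * abs(psi), 1e-6)
  H <- matrix(NA_real_, d, d)
  l0 <- ll_of(psi)
  ev <- function(delta) ll_of(psi + delta)
  for (j in seq_len(d)) {
    ej <- numeric(d); ej[j] <- h[j]
    H[j, j] <- (ev(ej) - 2 * l0 + ev(-ej)) / h[j]^2
    if (j > 1) for (m in seq_len(j - 1)) {
      em <- numeric(d); em[m] <- h[m]
      H[j, m] <- H[m, j] <-
        (ev(ej + em) - ev(ej - em) - ev(-ej + em) + ev(-ej - em)) /
        (4 * h[j] * h[m])
    }
  }
  info <- -H
  se <- rep(NA_real_, d)
  flag <- rep("", d)
  cv <- tryCatch(solve(info), error = function(e) NULL)
  if (is.null(cv)) {
    flag[] <- "singular information matrix"
  } else {
    dg <- diag(cv)
    ok <- is.finite(dg) & dg > 0
    se[ok] <- sqrt(dg[ok])
    flag[!ok] <- "negative curvature"
  }
  data.frame(parameter = pnames, estimate = unname(psi), se = se,
             rse_percent = 100 * se / abs(psi), flag = flag,
             row.names = NULL)
}
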