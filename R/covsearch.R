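#' Statistical screening of covariate-random-effect relationships
#'
#' For each (structural parameter, covariate) pair: Pearson and Spearman
#' correlation tests for continuous covariates, a one-way ANOVA F-test
#' for categorical covariates, all computed on the per-subject random
#' effects (EBEs by default, or conditional-sample means for the
#' correlation-based search). A pair is flagged when any of its test
#' p-values falls below `alpha`; the forward likelihood-ratio step is the
#' real gate downstream.
#'
#' @param ebes matrix of per-subject eta values (n x 7, columns named by
#'   structural parameter).
#' @param covariates data.frame of per-subject covariates.
#' @param continuous,categorical character vectors naming the covariate
#'   columns of each kind (defaults: standard dataset columns present).
#' @param alpha significance threshold.
#' @return `screening_table` data.frame with columns `parameter`,
#'   `covariate`, `test`, `statistic`, `p_value`, `flagged`, `note`.
#' @export
screen_covariates <- function(ebes, covariates,
                              continuous = intersect(
                                c("AGE", "WT", "BSA", "CYP2D6", "CYP2C19"),
                                names(covariates)),
                              categorical = intersect(
                                c("SEX", "RACE", "HEALTH"),
                                names(covariates)),
                              alpha = 0.05) {
  stopifnot(nrow(ebes) == nrow(covariates))
  rows <- list()
  add <- function(parameter, covariate, test, statistic, p, note = "") {
    rows[[length(rows) + 1]] <<- data.frame(
      parameter = parameter, covariate = covariate, test = test,
      statistic = statistic, p_value = p,
      flagged = is.finite(p) && p < alpha, note = note)
  }
  for (p in colnames(ebes)) {
    eta <- ebes[, p]
    if (sd(eta) < 1e-12) next     # no variability to explain
    for (cv in continuous) {
      x <- covariates[[cv]]
      if (sd(x) < 1e-12) {
        add(p, cv, "pearson", NA_real_, NA_real_, "constant covariate")
        next
      }
      pe <- cor.test(x, eta, method = "pearson")
      sp <- suppressWarnings(cor.test(x, eta, method = "spearman"))
      add(p, cv, "pearson", unname(pe$estimate), pe$p.value)
      add(p, cv, "spearman", unname(sp$estimate), sp$p.value)
    }
    for (cv in categorical) {
      x <- factor(covariates[[cv]])
      tab <- table(x)
      if (length(tab) < 2 || all(tab < 2)) {
        add(p, cv, "anova", NA_real_, NA_real_, "insufficient df")
        next
      }
      av <- anova(aov(eta ~ x))
      add(p, cv, "anova", av$`F value`[1], av$`Pr(>F)`[1])
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("screening_table", class(out))
  out
}

#' Variance-inflation-factor collinearity filter
#'
#' VIF_j = 1 / (1 - R^2_j) from regressing covariate j on the remaining
#' covariates. Among covariates exceeding the threshold, the one with
#' the less significant screening p-value is excluded, iteratively.
#'
#' @param covariates data.frame/matrix of continuous covariates (n rows).
#' @param threshold VIF threshold (default 15).
#' @param p_values optional named vector of screening p-values (smaller =
#'   more significant) used to choose which collinear covariate to drop;
#'   without it the largest-VIF covariate is dropped.
#' @return list with `retained`, `excluded`, and the final `vif` values.
#' @export
vif_filter <- function(covariates, threshold = 15, p_values = NULL) {
  X <- as.data.frame(covariates)
  if (ncol(X) < 2) stop("need at least 2 covariates")
  if (nrow(X) <= ncol(X)) stop("need more subjects than covariates")
  excluded <- character(0)
  compute_vif <- function(X) {
    vapply(names(X), function(j) {
      fit <- lm(X[[j]] ~ ., data = X[setdiff(names(X), j)])
      r2 <- summary(fit)$r.squared
      if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
    }, 0)
  }
  repeat {
    vif <- compute_vif(X)
    bad <- names(vif)[vif > threshold]
    if (!length(bad) || ncol(X) <= 1) break
    drop <- if (!is.null(p_values) && any(bad %in% names(p_values))) {
      pv <- p_values[bad]
      pv[is.na(pv)] <- 1
      bad[which.max(pv)]      # least significant goes
    } else names(which.max(vif))
    excluded <- c(excluded, drop)
    X <- X[setdiff(names(X), drop)]
    if (ncol(X) < 2) { vif <- setNames(rep(1, ncol(X)), names(X)); break }
  }
  list(retained = names(X), excluded = excluded, vif = vif)
}

#' Likelihood-ratio threshold for covariate selection
#'
#' Upper-alpha chi-square quantile, reported at 2 decimals: 3.84 at
#' alpha = 0.05 (forward inclusion) and 10.83 at alpha = 0.001
#' (backward elimination), both at 1 df.
#'
#' @param alpha significance level in (0, 1).
#' @param df degrees of freedom.
#' @return the rounded quantile.
#' @export
lrt_threshold <- function(alpha, df = 1) {
  if (!is.finite(alpha) || alpha <= 0 || alpha >= 1) stop("invalid alpha")
  round_half_up(qchisq(1 - alpha, df), 2)
}

refit_with_links <- function(base_fit, links, dataset, settings) {
  init <- base_fit$model
  init$links <- list()
  # nested refits warm-start from the base fit's individual parameters
  n <- length(base_fit$data)
  mu <- vapply(PK_PARAM_NAMES, function(p)
    drop(base_fit$designs[[p]] %*% base_fit$coefs[[p]]), numeric(n))
  if (n == 1) mu <- matrix(mu, 1, 7)
  attr(init, "individual_fits") <- mu + base_fit$eta
  saem_fit(dataset, init = init, links = links, settings = settings,
           seed = base_fit$seed + 1)
}

minus2ll_of <- function(fit, n_is, seed) {
  loglik_importance(fit, n_is = n_is, seed = seed)$minus2ll
}

#' Stepwise forward-inclusion / backward-elimination covariate search
#'
#' Forward: candidates (ordered by clinical priority then screening
#' p-value) are added one at a time; a candidate enters when it lowers
#' -2LL by more than `lrt_threshold(0.05, 1)`; the search stops when no
#' remaining candidate improves the model. Backward: from the full
#' model, links are removed starting with the highest Wald p-value; a
#' link is dropped when its removal raises -2LL by less than
#' `lrt_threshold(0.001, 1)`. -2LL differences are computed by
#' importance sampling with a shared seed across nested models so the
#' Monte-Carlo noise largely cancels.
#'
#' @param base_fit converged `saem_fit` without the candidate links.
#' @param candidates list of [covariate_link()]s (beta values ignored).
#' @param dataset the event-record dataset used for refitting.
#' @param settings SAEM settings for the refits (defaults to the base
#'   fit's settings with a reduced iteration budget).
#' @param n_is importance-sampling draws for each -2LL evaluation.
#' @param priority character vector of covariate names in decreasing
#'   clinical priority, used to order candidates before p-values.
#' @param screening optional `screening_table` used for the ordering.
#' @param seed RNG seed for the likelihood evaluations.
#' @return list with `model` (final `pop_model`), `fit` (final
#'   `saem_fit`), and `trace` (data.frame of attempted steps).
#' @export
stepwise_search <- function(base_fit, candidates, dataset,
                            settings = NULL, n_is = 300,
                            priority = c("WT", "BSA", "SEX", "HEALTH",
                                         "AGE", "RACE", "CYP2D6", "CYP2C19"),
                            screening = NULL, seed = 77) {
  if (is.null(settings)) {
    settings <- base_fit$settings
    settings$k1 <- max(30, round(settings$k1 / 4))
    settings$k2 <- max(20, round(settings$k2 / 4))
  }
  # de-duplicate and order candidates
  labs <- vapply(candidates, link_label, "")
  candidates <- candidates[!duplicated(labs)]
  labs <- labs[!duplicated(labs)]
  pr <- match(vapply(candidates, `[[`, "", "covariate"), priority)
  pv <- rep(1, length(candidates))
  if (!is.null(screening)) {
    for (j in seq_along(candidates)) {
      sel <- screening$parameter == candidates[[j]]$parameter &
        screening$covariate == candidates[[j]]$covariate
      if (any(sel)) pv[j] <- min(screening$p_value[sel], na.rm = TRUE)
    }
  }
  ord <- order(ifelse(is.na(pr), 99, pr), pv)
  candidates <- candidates[ord]

  trace <- list()
  note_step <- function(action, label, before, after, accepted, reason) {
    trace[[length(trace) + 1]] <<- data.frame(
      action = action, link = label, minus2ll_before = before,
      minus2ll_after = after, accepted = accepted, reason = reason)
  }
  current <- list()
  cur_fit <- base_fit
  cur_ll <- minus2ll_of(base_fit, n_is, seed)
  thr_f <- lrt_threshold(0.05, 1)
  thr_b <- lrt_threshold(0.001, 1)

  # forward inclusion
  remaining <- candidates
  repeat {
    improved <- FALSE
    for (j in seq_along(remaining)) {
      cand <- remaining[[j]]
      trial <- c(current, list(cand))
      fit_j <- tryCatch(refit_with_links(base_fit, trial, dataset, settings),
                        error = function(e) NULL)
      if (is.null(fit_j)) {
        note_step("add", link_label(cand), cur_ll, NA, FALSE, "refit failed")
        next
      }
      ll_j <- minus2ll_of(fit_j, n_is, seed)
      if (cur_ll - ll_j > thr_f) {
        note_step("add", link_label(cand), cur_ll, ll_j, TRUE,
                  sprintf("-2LL drop %.2f > %.2f", cur_ll - ll_j, thr_f))
        current <- trial; cur_fit <- fit_j; cur_ll <- ll_j
        remaining <- remaining[-j]
        improved <- TRUE
        break
      }
      note_step("add", link_label(cand), cur_ll, ll_j, FALSE,
                sprintf("-2LL drop %.2f <= %.2f", cur_ll - ll_j, thr_f))
    }
    if (!improved || !length(remaining)) break
  }

  # backward elimination, highest Wald p-value first
  repeat {
    if (!length(current)) break
    wt <- wald_tests(cur_fit)
    ordw <- order(-ifelse(is.na(wt$p_value), 1, wt$p_value))
    removed <- FALSE
    for (j in ordw) {
      lab <- wt$link[j]
      keep <- current[vapply(current, link_label, "") != lab]
      fit_j <- if (length(keep))
        tryCatch(refit_with_links(base_fit, keep, dataset, settings),
                 error = function(e) NULL) else base_fit
      if (is.null(fit_j)) next
      ll_j <- minus2ll_of(fit_j, n_is, seed)
      if (ll_j - cur_ll < thr_b) {
        note_step("remove", lab, cur_ll, ll_j, TRUE,
                  sprintf("-2LL rise %.2f < %.2f", ll_j - cur_ll, thr_b))
        current <- keep; cur_fit <- fit_j; cur_ll <- ll_j
        removed <- TRUE
        break
      }
      note_step("remove", lab, cur_ll, ll_j, FALSE,
                sprintf("-2LL rise %.2f >= %.2f", ll_j - cur_ll, thr_b))
    }
    if (!removed) break
  }

  trace <- if (length(trace)) do.call(rbind, trace) else
    data.frame(action = character(0), link = character(0),
               minus2ll_before = numeric(0), minus2ll_after = numeric(0),
               accepted = logical(0), reason = character(0))
  list(model = cur_fit$model, fit = cur_fit, minus2ll = cur_ll,
       trace = trace)
}

#' Correlation-based automatic covariate search (COSSAC-like)
#'
#' Ranks all random-effect-covariate relationships by correlation/ANOVA
#' p-values computed on retained conditional MCMC samples (not EBEs),
#' then runs the same forward/backward likelihood-ratio machinery as
#' [stepwise_search()], accepting a step only when -2LL (and hence BICc
#' at fixed dimension change) improves beyond the thresholds. With
#' degenerate conditional samples (all-zero IIV) the base model is
#' returned with a warning.
#'
#' @inheritParams stepwise_search
#' @param covariates data.frame of per-subject covariates (defaults to
#'   those stored in the fit's dataset).
#' @return as [stepwise_search()], plus the conditional-sample
#'   `screening` table.
#' @export
cossac_search <- function(base_fit, candidates, dataset, settings = NULL,
                          n_is = 300, seed = 77, covariates = NULL) {
  if (is.null(covariates))
    covariates <- do.call(rbind, lapply(base_fit$data, function(s) s$cov))
  draws <- base_fit$eta_draws
  if (!length(draws) || all(vapply(draws, function(m) max(abs(m)), 0) < 1e-10)) {
    warning("conditional samples degenerate; returning the base model")
    return(list(model = base_fit$model, fit = base_fit,
                minus2ll = minus2ll_of(base_fit, n_is, seed),
                trace = data.frame(), screening = NULL))
  }
  eta_bar <- Reduce(`+`, draws) / length(draws)
  colnames(eta_bar) <- PK_PARAM_NAMES
  scr <- screen_covariates(eta_bar, covariates)
  # candidates sorted purely by conditional-sample p-value
  labs <- vapply(candidates, link_label, "")
  pv <- vapply(seq_along(candidates), function(j) {
    sel <- scr$parameter == candidates[[j]]$parameter &
      scr$covariate == candidates[[j]]$covariate
    if (any(sel)) min(scr$p_value[sel], na.rm = TRUE) else 1
  }, 0)
  res <- stepwise_search(base_fit, candidates[order(pv)], dataset,
                         settings = settings, n_is = n_is,
                         priority = character(0), screening = scr,
                         seed = seed)
  res$screening <- scr
  res
}

#' Wald tests for fitted covariate coefficients
#'
#' z = beta / SE(beta) with a two-sided normal p-value. The SE comes
#' from the normal-theory covariance of the M-step regression,
#' `omega_p^2 (X'X)^-1`, a fast approximation that ignores uncertainty
#' in the conditional means.
#'
#' @param fit a `saem_fit` with covariate links.
#' @return data.frame with `link`, `beta`, `se`, `z`, `p_value`.
#' @export
wald_tests <- function(fit) {
  links <- fit$model$links
  if (!length(links))
    return(data.frame(link = character(0), beta = numeric(0),
                      se = numeric(0), z = numeric(0), p_value = numeric(0)))
  rows <- lapply(links, function(l) {
    X <- fit$designs[[l$parameter]]
    j <- match(link_label(l), colnames(X))
    xtxi <- tryCatch(solve(crossprod(X)), error = function(e) NULL)
    se <- if (is.null(xtxi)) NA_real_ else
      fit$model$omega[[l$parameter]] * sqrt(xtxi[j, j])
    beta <- l$beta
    z <- if (is.finite(se) && se > 0) beta / se else NA_real_
    data.frame(link = link_label(l), beta = beta, se = se, z = z,
               p_value = if (is.finite(z)) 2 * pnorm(-abs(z)) else NA_real_)
  })
  do.call(rbind, rows)
}
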