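#' Individual weighted residuals
#'
#' IWRES = (y - f_i) / sd(f_i) with f_i predicted from each subject's
#' empirical Bayes parameters and sd from the fitted residual-error
#' model. Standard normal under a correct model.
#'
#' @param fit a `saem_fit`.
#' @param ebes optional result of [compute_ebes()] (recomputed if NULL).
#' @return data.frame with `ID`, `TIME`, `DV`, `ipred`, `iwres`.
#' @export
iwres <- function(fit, ebes = NULL) {
  if (is.null(ebes)) ebes <- compute_ebes(fit, quiet = TRUE)
  pred <- make_pred(fit$data, fit$settings$dt %||% 0.02)
  rows <- lapply(seq_along(fit$data), function(i) {
    s <- fit$data[[i]]
    f <- pred(i, ebes$params[i, ])
    sdv <- residual_sd(f, fit$model$error, fit$model$error_form)
    data.frame(ID = s$id, TIME = s$times, DV = s$y, ipred = f,
               iwres = (s$y - f) / sdv)
  })
  do.call(rbind, rows)
}

# simulate replicate observation matrices at the observed design
simulate_replicates <- function(fit, n_sim, seed) {
  model <- fit$model
  pred <- make_pred(fit$data, fit$settings$dt %||% 0.02)
  ebes <- NULL
  X <- fit$designs
  n <- length(fit$data)
  mu <- vapply(PK_PARAM_NAMES, function(p)
    drop(X[[p]] %*% fit$coefs[[p]]), numeric(n))
  if (n == 1) mu <- matrix(mu, 1, 7)
  lapply(seq_len(n), function(i) {
    nt <- length(fit$data[[i]]$times)
    out <- matrix(NA_real_, nt, n_sim)
    set.seed(derive_seed(seed, 101L, round(fit$data[[i]]$id * 13)))
    for (r in seq_len(n_sim)) {
      for (try in 1:100) {
        eta <- rnorm(7, 0, model$omega)
        p <- mu[i, ] + eta
        if (all(p > 0)) break
      }
      f <- pred(i, p)
      sdv <- residual_sd(f, model$error, model$error_form)
      out[, r] <- f + sdv * rnorm(nt)
    }
    out
  })
}

#' Normalized prediction distribution errors
#'
#' Simulates `n_sim` replicate datasets at the observed design; per
#' subject, observed and simulated vectors are decorrelated with the
#' empirical simulated mean and the Cholesky factor of the simulated
#' covariance; the decorrelated prediction discrepancies are converted
#' to normal scores, npde = qnorm(pd), with rank ties broken by seeded
#' uniform jitter. Standard normal under a correct model.
#'
#' @param fit a `saem_fit`.
#' @param n_sim simulated replicates (>= 50).
#' @param seed integer.
#' @return `npde_result` data.frame: `ID`, `TIME`, `DV`, `npde`,
#'   `decorrelated` (FALSE when the simulated covariance was singular
#'   and the marginal fallback was used).
#' @export
npde <- function(fit, n_sim = 500, seed = 1) {
  if (n_sim < 50) stop("n_sim must be at least 50")
  sims <- simulate_replicates(fit, n_sim, seed)
  rows <- lapply(seq_along(fit$data), function(i) {
    s <- fit$data[[i]]
    S <- sims[[i]]                       # nt x n_sim
    Em <- rowMeans(S)
    Vc <- stats::cov(t(S))
    ok <- TRUE
    L <- tryCatch(chol(Vc), error = function(e) NULL)
    if (is.null(L)) {
      ok <- FALSE
      ys <- (s$y - Em) / pmax(sqrt(diag(Vc)), 1e-12)
      Ss <- (S - Em) / pmax(sqrt(diag(Vc)), 1e-12)
    } else {
      ys <- drop(backsolve(L, s$y - Em, transpose = TRUE))
      Ss <- backsolve(L, S - Em, transpose = TRUE)
    }
    set.seed(derive_seed(seed, 103L, round(s$id * 13)))
    pd <- vapply(seq_along(ys), function(j) {
      r <- sum(Ss[j, ] < ys[j]) + sum(Ss[j, ] == ys[j]) * runif(1)
      (r + runif(1)) / (n_sim + 1)
    }, 0)
    data.frame(ID = s$id, TIME = s$times, DV = s$y,
               npde = qnorm(pmin(pmax(pd, 1 / (2 * n_sim)),
                                 1 - 1 / (2 * n_sim))),
               decorrelated = ok)
  })
  out <- do.call(rbind, rows)
  attr(out, "n_sim") <- n_sim
  attr(out, "seed") <- seed
  class(out) <- c("npde_result", class(out))
  out
}

#' Visual predictive check tables
#'
#' Observed 10th/50th/90th percentiles per time bin against the 90%
#' prediction band (5th-95th percentile across `n_sim` simulated
#' replicates) of each percentile. A percentile point outside its band
#' is flagged as an outlier. Bins with fewer than 3 observations are
#' merged with their neighbour.
#'
#' @param fit a `saem_fit`.
#' @param n_sim simulated replicates.
#' @param bins number of quantile-based time bins, or a vector of bin
#'   edges.
#' @param seed integer.
#' @return `vpc_result` data.frame, one row per bin x percentile:
#'   `bin`, `t_mid`, `percentile`, `observed`, `band_lower`,
#'   `band_upper`, `outlier`, `n_obs`.
#' @export
vpc <- function(fit, n_sim = 500, bins = 8, seed = 1) {
  probs <- c(0.1, 0.5, 0.9)
  times <- unlist(lapply(fit$data, `[[`, "times"))
  yobs <- unlist(lapply(fit$data, `[[`, "y"))
  if (length(bins) == 1) {
    edges <- unique(quantile(times, probs = seq(0, 1, length.out = bins + 1)))
  } else edges <- sort(unique(bins))
  if (min(times) < min(edges) || max(times) > max(edges))
    stop("bins must cover the observation times")
  bin_of <- function(tt) pmin(pmax(findInterval(tt, edges,
                                                rightmost.closed = TRUE), 1),
                              length(edges) - 1)
  bi <- bin_of(times)
  # merge undersized bins leftward
  repeat {
    cnt <- tabulate(bi, nbins = length(edges) - 1)
    small <- which(cnt > 0 & cnt < 3)
    if (!length(small)) break
    j <- small[1]
    edges <- edges[-max(2, j)]
    if (length(edges) < 2) stop("cannot form bins with >= 3 observations")
    bi <- bin_of(times)
  }
  sims <- simulate_replicates(fit, n_sim, seed)
  simmat <- do.call(rbind, sims)        # (total obs) x n_sim, row order = times
  ubins <- sort(unique(bi))
  rows <- list()
  for (b in ubins) {
    sel <- bi == b
    obs_q <- quantile(yobs[sel], probs)
    rep_q <- apply(simmat[sel, , drop = FALSE], 2, quantile, probs = probs)
    band <- apply(rep_q, 1, quantile, probs = c(0.05, 0.95))
    for (k in seq_along(probs)) {
      rows[[length(rows) + 1]] <- data.frame(
        bin = b, t_mid = median(times[sel]),
        percentile = 100 * probs[k], observed = unname(obs_q[k]),
        band_lower = band[1, k], band_upper = band[2, k],
        outlier = obs_q[k] < band[1, k] | obs_q[k] > band[2, k],
        n_obs = sum(sel))
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "n_sim") <- n_sim
  attr(out, "seed") <- seed
  class(out) <- c("vpc_result", class(out))
  out
}

#' Goodness-of-fit tables and the outlier proportion
#'
#' Observed-vs-predicted tables (population prediction at eta = 0 and
#' individual prediction from the EBEs), the IWRES table, empirical vs
#' standard-normal density grids for IWRES (and NPDE when supplied), and
#' the outlier proportion: the fraction of observations outside the 90%
#' individual prediction interval, |y - f_i| > qnorm(0.95) * sd(f_i).
#'
#' @param fit a `saem_fit`.
#' @param npde_result optional result of [npde()] for the density table.
#' @param ebes optional precomputed [compute_ebes()] result.
#' @return list with `obs_vs_pred`, `residuals`, `density`,
#'   `outlier_proportion`.
#' @export
gof_tables <- function(fit, npde_result = NULL, ebes = NULL) {
  if (is.null(ebes)) ebes <- compute_ebes(fit, quiet = TRUE)
  pred <- make_pred(fit$data, fit$settings$dt %||% 0.02)
  iw <- iwres(fit, ebes)
  ppred <- unlist(lapply(seq_along(fit$data), function(i)
    pred(i, ebes$mu[i, ])))
  obs_vs_pred <- data.frame(ID = iw$ID, TIME = iw$TIME, DV = iw$DV,
                            pred = ppred, ipred = iw$ipred)
  z <- qnorm(0.95)
  outlier_proportion <- mean(abs(iw$iwres) > z)
  grid <- seq(-4, 4, length.out = 101)
  dens_iwres <- stats::density(iw$iwres, from = -4, to = 4, n = 101)
  density <- data.frame(x = grid, theoretical = dnorm(grid),
                        iwres = dens_iwres$y)
  if (!is.null(npde_result)) {
    dens_npde <- stats::density(npde_result$npde[is.finite(npde_result$npde)],
                                from = -4, to = 4, n = 101)
    density$npde <- dens_npde$y
  }
  list(obs_vs_pred = obs_vs_pred,
       residuals = iw[, c("ID", "TIME", "ipred", "iwres")],
       density = density,
       outlier_proportion = outlier_proportion)
}
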