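#' Linear trapezoidal AUC
#'
#' Area under the concentration-time curve by the linear trapezoidal rule
#' with equal weighting of all points.
#'
#' @param times numeric, strictly increasing sampling times (h).
#' @param conc numeric, non-negative concentrations at `times`.
#' @return The trapezoidal integral over the full sampled range.
#' @export
auc_trapezoid <- function(times, conc) {
  if (length(times) < 2L) stop("need at least 2 points")
  if (length(conc) != length(times)) stop("times and conc lengths differ")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  if (any(conc < 0)) stop("concentrations must be non-negative")
  sum(diff(times) * (head(conc, -1) + conc[-1]) / 2)
}

#' Terminal slope (lambda_z) by best adjusted-R-squared window
#'
#' Searches all contiguous terminal windows of at least 3 post-peak points
#' (the point at Cmax itself excluded) and fits a log-linear regression in
#' each; the window maximizing adjusted R-squared is selected, with ties
#' broken in favour of more points. Zero concentrations are excluded from
#' the log regression.
#'
#' @param times,conc the profile.
#' @param min_points minimum window size (default 3).
#' @return list with `lambda_z` (1/h), `adj_r2`, `n_points`, `intercept`
#'   (log scale) and `ok` (FALSE when no admissible window exists or the
#'   best fit has non-positive slope magnitude).
#' @export
fit_lambda_z <- function(times, conc, min_points = 3L) {
  stopifnot(length(times) == length(conc))
  imax <- which.max(conc)[1]
  keep <- seq_along(times) > imax & conc > 0
  tt <- times[keep]; cc <- conc[keep]
  n <- length(tt)
  fail <- list(lambda_z = NA_real_, adj_r2 = NA_real_,
               n_points = NA_integer_, intercept = NA_real_, ok = FALSE)
  if (n < min_points) return(fail)
  best <- NULL
  for (start in seq_len(n - min_points + 1L)) {
    idx <- start:n                      # terminal windows end at the last point
    y <- log(cc[idx]); x <- tt[idx]
    fit <- lm(y ~ x)
    r2a <- summary(fit)$adj.r.squared
    slope <- coef(fit)[[2]]
    if (!is.finite(r2a) || slope >= -1e-12 || sd(y) < 1e-12) next
    if (is.null(best) || r2a > best$adj_r2 + 1e-12 ||
        (abs(r2a - best$adj_r2) <= 1e-12 && length(idx) > best$n_points)) {
      best <- list(lambda_z = -slope, adj_r2 = r2a,
                   n_points = length(idx), intercept = coef(fit)[[1]],
                   ok = TRUE)
    }
  }
  if (is.null(best)) fail else best
}

#' Non-compartmental analysis summary
#'
#' Cmax/Tmax by direct maximum (first occurrence on ties), AUC by the
#' linear trapezoidal rule, lambda_z by [fit_lambda_z()], and the derived
#' extrapolated quantities. When no admissible terminal fit exists the
#' extrapolated fields are `NA` and `auc_last` is still reported.
#'
#' @param times,conc the profile (conc in ug/mL).
#' @param dose dose amount (mg) used for `cl_over_f`.
#' @return list with fields `cmax`, `tmax`, `auc_last`, `auc_inf`,
#'   `lambda_z`, `lambda_z_adj_r2`, `t_half`, `cl_over_f`, `vz_over_f`,
#'   `n_terminal_points`.
#' @export
nca_summary <- function(times, conc, dose = NA_real_) {
  imax <- which.max(conc)[1]
  auc_last <- auc_trapezoid(times, conc)
  lz <- fit_lambda_z(times, conc)
  out <- list(cmax = conc[imax], tmax = times[imax], auc_last = auc_last,
              auc_inf = NA_real_, lambda_z = NA_real_,
              lambda_z_adj_r2 = NA_real_, t_half = NA_real_,
              cl_over_f = NA_real_, vz_over_f = NA_real_,
              n_terminal_points = NA_integer_)
  if (isTRUE(lz$ok)) {
    clast <- conc[length(conc)]
    out$lambda_z <- lz$lambda_z
    out$lambda_z_adj_r2 <- lz$adj_r2
    out$n_terminal_points <- lz$n_points
    out$auc_inf <- auc_last + clast / lz$lambda_z
    out$t_half <- log(2) / lz$lambda_z
    if (is.finite(dose)) {
      out$cl_over_f <- dose / out$auc_inf   # mg / (ug.h/mL) = L/h
      out$vz_over_f <- out$cl_over_f / lz$lambda_z
    }
  }
  out
}

#' Packaged reference PK values for single-dose oral salbutamol
#'
#' Observed (literature reference) and whole-body-model predicted values
#' for fraction absorbed, bioavailability, Cmax, Tmax and AUCinf after a
#' single 4 mg oral dose in the reference adult; the pairs feeding the
#' fold-error validation rule.
#'
#' @return data.frame with `metric`, `observed`, `predicted`.
#' @export
reference_pk_values <- function() {
  read.csv(system.file("extdata", "reference_pk_values.csv",
                       package = "salbupk"))
}

#' Directional fold-error
#'
#' The larger of observed/predicted and predicted/observed; predictions
#' with fold-error below 2 are conventionally regarded as reliable in
#' PBPK validation.
#'
#' @param observed,predicted strictly positive values.
#' @param digits decimal places for the reported (half-up rounded) value;
#'   `NULL` for no rounding.
#' @return list with `fold_error`, `reliable` (fold-error < 2) and the
#'   unrounded `raw`.
#' @export
fold_error <- function(observed, predicted, digits = 2) {
  if (any(observed <= 0) || any(predicted <= 0))
    stop("fold_error requires strictly positive inputs")
  fe <- pmax(observed / predicted, predicted / observed)
  rep_fe <- if (is.null(digits)) fe else round_half_up(fe, digits)
  list(fold_error = rep_fe, reliable = unname(fe < 2), raw = unname(fe))
}
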