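#' Geometric mean and geometric SD
#'
#' gm = exp(mean(log v)), gsd = exp(sd(log v)).
#'
#' @param values strictly positive numeric vector.
#' @return list with `geometric_mean` and `geometric_sd` (`NA` gsd for a
#'   single value).
#' @export
geometric_stats <- function(values) {
  if (any(values <= 0)) stop("geometric statistics require positive values")
  lv <- log(values)
  list(geometric_mean = exp(mean(lv)),
       geometric_sd = if (length(lv) > 1) exp(sd(lv)) else NA_real_)
}

#' Subgroup summaries of individual PK parameters
#'
#' Applies an optional filter (e.g. healthy adults), groups subjects by a
#' covariate (categorical levels or numeric range cuts), and reports the
#' geometric mean and SD of each requested parameter per subgroup.
#'
#' @param params matrix/data.frame of individual parameters (one row per
#'   subject, columns named by parameter).
#' @param covariates data.frame of per-subject covariates, same row
#'   order.
#' @param grouping list with `covariate` (column name) and either
#'   `breaks` (numeric cut points for a continuous covariate) or nothing
#'   (categorical levels used as-is).
#' @param parameters parameter columns to summarize.
#' @param filter optional logical vector selecting subjects first.
#' @return data.frame with `parameter`, `covariate`, `group`, `n`,
#'   `geometric_mean`, `geometric_sd` (stats `NA` for empty groups).
#' @export
summarize_subgroups <- function(params, covariates, grouping,
                                parameters = colnames(params),
                                filter = NULL) {
  params <- as.data.frame(params)
  stopifnot(nrow(params) == nrow(covariates))
  if (!grouping$covariate %in% names(covariates))
    stop("unknown grouping covariate: ", grouping$covariate)
  keep <- if (is.null(filter)) rep(TRUE, nrow(params)) else filter
  x <- covariates[[grouping$covariate]][keep]
  g <- if (!is.null(grouping$breaks))
    cut(x, breaks = grouping$breaks, include.lowest = TRUE) else factor(x)
  rows <- list()
  for (p in parameters) {
    v <- params[[p]][keep]
    for (lev in levels(g)) {
      sel <- !is.na(g) & g == lev
      if (!any(sel)) {
        rows[[length(rows) + 1]] <- data.frame(
          parameter = p, covariate = grouping$covariate, group = lev,
          n = 0L, geometric_mean = NA_real_, geometric_sd = NA_real_)
        next
      }
      gs <- geometric_stats(v[sel])
      rows[[length(rows) + 1]] <- data.frame(
        parameter = p, covariate = grouping$covariate, group = lev,
        n = sum(sel), geometric_mean = gs$geometric_mean,
        geometric_sd = gs$geometric_sd)
    }
  }
  do.call(rbind, rows)
}

#' Group-mean log-concentration curves over the terminal phase
#'
#' Per-group arithmetic mean of log concentration at the shared
#' observation times within a terminal window; used to compare apparent
#' elimination across subgroups (steeper decline = faster clearance).
#'
#' @param dataset event-record data.frame (EVID = 0 rows used).
#' @param group per-subject grouping: data.frame with `ID` and `group`.
#' @param t_window two times (h) delimiting the terminal window.
#' @return data.frame with `group`, `TIME`, `mean_log_conc`, `n`.
#' @export
terminal_phase_curves <- function(dataset, group, t_window) {
  stopifnot(length(t_window) == 2, t_window[1] < t_window[2])
  obs <- dataset[dataset$EVID == 0 & dataset$TIME >= t_window[1] &
                   dataset$TIME <= t_window[2] & dataset$DV > 0, ]
  if (nrow(obs) == 0) stop("no observations in the terminal window")
  obs$group <- group$group[match(obs$ID, group$ID)]
  if (any(is.na(obs$group))) stop("group missing for some subjects")
  empty <- setdiff(unique(group$group), unique(obs$group))
  if (length(empty))
    stop("group(s) without observations in window: ",
         paste(empty, collapse = ", "))
  agg <- aggregate(log(obs$DV), by = list(group = obs$group, TIME = obs$TIME),
                   FUN = mean)
  n <- aggregate(obs$DV, by = list(group = obs$group, TIME = obs$TIME),
                 FUN = length)
  data.frame(group = agg$group, TIME = agg$TIME, mean_log_conc = agg$x,
             n = n$x)[order(agg$group, agg$TIME), ]
}
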