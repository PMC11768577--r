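#' Read a NONMEM-style event-record dataset
#'
#' Requires columns ID, TIME, DV, AMT, EVID (MDV inferred when absent:
#' 1 for dose records, 0 otherwise). Every subject must carry at least
#' one dose and one observation; non-monotone times within a subject are
#' sorted with a warning. Covariates must be constant within subject.
#'
#' @param path CSV file path.
#' @return validated event-record data.frame (DV in ug/mL).
#' @export
read_pk_dataset <- function(path) {
  ds <- read.csv(path)
  req <- c("ID", "TIME", "DV", "AMT", "EVID")
  miss <- setdiff(req, names(ds))
  if (length(miss))
    stop("dataset is missing column(s): ", paste(miss, collapse = ", "))
  if (!"MDV" %in% names(ds)) ds$MDV <- as.integer(ds$EVID != 0)
  if (any(ds$TIME < 0)) stop("negative times")
  covcols <- setdiff(names(ds), c(req, "MDV"))
  for (id in unique(ds$ID)) {
    sub <- ds[ds$ID == id, ]
    if (!any(sub$EVID == 1) || !any(sub$EVID == 0))
      stop("subject ", id, " lacks a dose or an observation")
    for (cc in covcols)
      if (length(unique(sub[[cc]])) > 1)
        stop("covariate ", cc, " varies within subject ", id)
    if (is.unsorted(sub$TIME)) {
      warning("times not monotone within subject ", id, "; sorting")
      ds[ds$ID == id, ] <- sub[order(sub$TIME, -sub$EVID), ]
    }
  }
  ds
}

#' Write an event-record dataset to CSV
#' @param dataset event-record data.frame.
#' @param path output CSV path.
#' @export
write_pk_dataset <- function(dataset, path) {
  write.csv(dataset, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Packaged end-to-end fixtures
#'
#' Three seeded synthetic datasets binding the workflow stages:
#' (a) `pbpk` - the 40-subject PBPK-derived dataset (default cohort,
#' 4 mg q6h, 21-point schedule over 24 h, ~840 observations);
#' (b) `parametric` - a dataset simulated directly from the packaged
#' population model under the same design, for estimator tests;
#' (c) `mini` - a tiny triangular profile with hand-checkable NCA values
#' (AUC 2.0, Cmax 2 at 1 h).
#'
#' @param seed integer driving all randomness.
#' @param n_subjects cohort size scaling for reduced runs.
#' @return list with elements `pbpk`, `parametric`, `mini`, `cohort`.
#' @export
make_fixtures <- function(seed = 1, n_subjects = 40) {
  spec <- default_cohort_spec(seed = seed)
  if (n_subjects != 40) {
    f <- n_subjects / 40
    spec$groups$n <- pmax(1, round(spec$groups$n * f))
  }
  cohort <- sample_cohort(spec)
  pbpk <- pbpk_dataset(cohort)
  covs <- data.frame(ID = cohort$id)
  parametric <- simulate_dataset(default_poppk_model(),
                                 list(covariates = covs,
                                      schedule = default_schedule(),
                                      regimen = dose_regimen()),
                                 seed = derive_seed(seed, 5))
  mini <- data.frame(ID = 1, TIME = c(0, 0, 1, 2),
                     DV = c(NA, 0, 2, 0), AMT = c(4, 0, 0, 0),
                     EVID = c(1L, 0L, 0L, 0L), MDV = c(1L, 0L, 0L, 0L))
  list(pbpk = pbpk, parametric = parametric, mini = mini, cohort = cohort)
}

#' Default pipeline configuration
#'
#' Reduced demo settings (12 subjects, shortened SAEM) so the complete
#' workflow runs in minutes; the study-scale run uses `n_subjects = 40`
#' and the default SAEM budget.
#'
#' @param seed master seed; every stage derives its own substream.
#' @param n_subjects cohort size.
#' @param regimen a [dose_regimen()].
#' @param schedule observation times (h).
#' @param saem SAEM settings.
#' @param n_sim_diag simulated replicates for VPC/NPDE.
#' @return a `run_config` list.
#' @export
default_config <- function(seed = 1, n_subjects = 12,
                           regimen = dose_regimen(),
                           schedule = default_schedule(),
                           saem = saem_settings(k1 = 100, k2 = 50),
                           n_sim_diag = 200) {
  structure(list(seed = as.integer(seed), n_subjects = n_subjects,
                 regimen = regimen, schedule = schedule, saem = saem,
                 n_sim_diag = n_sim_diag), class = "run_config")
}

#' Run the complete in-silico popPK workflow
#'
#' cohort -> PBPK simulation -> dataset -> NCA -> base SAEM fit ->
#' covariate screening/search -> diagnostics -> subgroup summaries.
#' Every stage writes its table under `out_dir` together with a log of
#' seeds and settings; a rerun with the same config reproduces the same
#' artifacts.
#'
#' @param config a [default_config()].
#' @param out_dir output directory (created if needed).
#' @return invisibly, a list with all stage results.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  logf <- file.path(out_dir, "run_log.txt")
  note <- function(...) cat(..., "\n", file = logf, append = TRUE)
  cat("", file = logf)
  note("salbupk", as.character(utils::packageVersion("salbupk")),
       "| master seed", config$seed)

  spec <- default_cohort_spec(seed = config$seed)
  if (config$n_subjects != 40)
    spec$groups$n <- pmax(1, round(spec$groups$n * config$n_subjects / 40))
  cohort <- sample_cohort(spec)
  write.csv(cohort, file.path(out_dir, "cohort.csv"), row.names = FALSE)
  note("cohort:", nrow(cohort), "subjects")

  dataset <- pbpk_dataset(cohort, regimen = config$regimen,
                          schedule = config$schedule)
  write_pk_dataset(dataset, file.path(out_dir, "dataset.csv"))
  note("dataset:", sum(dataset$EVID == 0), "observations")

  ncares <- do.call(rbind, lapply(split(dataset[dataset$EVID == 0, ],
                                        dataset$ID[dataset$EVID == 0]),
    function(obs) {
      dose <- sum(dataset$AMT[dataset$ID == obs$ID[1] & dataset$EVID == 1])
      as.data.frame(nca_summary(obs$TIME, pmax(obs$DV, 0), dose = dose))
    }))
  ncares$ID <- unique(dataset$ID[dataset$EVID == 0])
  write.csv(ncares, file.path(out_dir, "nca.csv"), row.names = FALSE)

  init <- init_from_nca(dataset)
  fit <- saem_fit(dataset, init = init, settings = config$saem,
                  seed = derive_seed(config$seed, 11))
  est <- data.frame(parameter = names(fit$model$theta),
                    estimate = unname(fit$model$theta),
                    iiv_sd = unname(fit$model$omega))
  write.csv(est, file.path(out_dir, "estimates.csv"), row.names = FALSE)
  write.csv(as.data.frame(fit$trace), file.path(out_dir, "trace.csv"),
            row.names = FALSE)
  note("base fit converged:", fit$flags$converged)

  ebes <- compute_ebes(fit, quiet = TRUE)
  write.csv(data.frame(ID = vapply(fit$data, `[[`, 0, "id"), ebes$eta),
            file.path(out_dir, "ebes.csv"), row.names = FALSE)
  covtab <- do.call(rbind, lapply(fit$data, function(s) s$cov))
  scr <- screen_covariates(ebes$eta, covtab)
  write.csv(scr, file.path(out_dir, "screening.csv"), row.names = FALSE)

  cand <- list()
  for (j in which(scr$flagged))
    cand[[length(cand) + 1]] <- covariate_link(
      scr$parameter[j], scr$covariate[j],
      kind = if (scr$test[j] == "anova") "categorical" else "continuous",
      ref = if (scr$test[j] == "anova") 0 else NA)
  search <- if (length(cand)) {
    stepwise_search(fit, cand, dataset, screening = scr,
                    seed = derive_seed(config$seed, 13))
  } else list(model = fit$model, fit = fit,
              trace = data.frame(), minus2ll = NA)
  if (nrow(search$trace))
    write.csv(search$trace, file.path(out_dir, "covsearch_trace.csv"),
              row.names = FALSE)
  note("covariate links selected:",
       length(search$model$links))

  final_fit <- search$fit
  np <- npde(final_fit, n_sim = config$n_sim_diag,
             seed = derive_seed(config$seed, 17))
  write.csv(np, file.path(out_dir, "npde.csv"), row.names = FALSE)
  vp <- vpc(final_fit, n_sim = config$n_sim_diag,
            seed = derive_seed(config$seed, 19))
  write.csv(vp, file.path(out_dir, "vpc.csv"), row.names = FALSE)
  gof <- gof_tables(final_fit, np)
  write.csv(gof$obs_vs_pred, file.path(out_dir, "gof_obs_vs_pred.csv"),
            row.names = FALSE)
  note("outlier proportion:", signif(gof$outlier_proportion, 3))

  ebes_f <- compute_ebes(final_fit, quiet = TRUE)
  adult_healthy <- cohort$age >= 20 & cohort$health_status == "healthy"
  sg <- rbind(
    summarize_subgroups(ebes_f$params, covtab,
                        list(covariate = "SEX"),
                        parameters = c("Mtt", "Cl"),
                        filter = adult_healthy),
    summarize_subgroups(ebes_f$params, covtab,
                        list(covariate = "BSA", breaks = c(0.94, 1.6, 2.37)),
                        parameters = c("V1", "Cl"),
                        filter = adult_healthy))
  write.csv(sg, file.path(out_dir, "subgroups.csv"), row.names = FALSE)

  invisible(list(cohort = cohort, dataset = dataset, nca = ncares,
                 fit = fit, screening = scr, search = search,
                 npde = np, vpc = vp, gof = gof, subgroups = sg))
}
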