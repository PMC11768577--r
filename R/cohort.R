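#' Cohort specification for the virtual population
#'
#' @param groups data.frame with columns `race` (american/asian/chinese),
#'   `health_status` (healthy/obese/cirrhosis_a), `n` (>= 1) and
#'   `gender_fraction_male`.
#' @param age_range two ages in years, within \[5, 65\].
#' @param bmi_class_mix named proportions over `normal`, `overweight`,
#'   `obese`, summing to 1; applied to subjects whose health status is not
#'   `obese` (those are renormalized over normal/overweight; obese health
#'   status always draws an obese BMI).
#' @param seed default RNG seed for [sample_cohort()].
#' @return a `cohort_spec` object.
#' @export
cohort_spec <- function(groups, age_range = c(5, 65),
                        bmi_class_mix = c(normal = 0.70, overweight = 0.20,
                                          obese = 0.10),
                        seed = 1L) {
  stopifnot(is.data.frame(groups),
            all(c("race", "health_status", "n", "gender_fraction_male")
                %in% names(groups)))
  if (nrow(groups) == 0 || any(groups$n < 1)) stop("group sizes must be >= 1")
  if (!all(groups$race %in% c("american", "asian", "chinese")))
    stop("unknown race")
  if (!all(groups$health_status %in% c("healthy", "obese", "cirrhosis_a")))
    stop("unknown health status")
  if (age_range[1] < 5 || age_range[2] > 65 || age_range[1] > age_range[2])
    stop("age range must lie within [5, 65]")
  if (abs(sum(bmi_class_mix) - 1) > 1e-9)
    stop("bmi_class_mix proportions must sum to 1")
  structure(list(groups = groups, age_range = age_range,
                 bmi_class_mix = bmi_class_mix, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Default 40-subject cohort specification
#'
#' Composition matching the study population: 20 American (6 healthy,
#' 4 obese, 10 cirrhosis A), 10 Asian and 10 Chinese healthy subjects;
#' ages 5-65; 60% male in each group (24 M / 16 F overall).
#' @return a `cohort_spec`.
#' @export
default_cohort_spec <- function(seed = 1L) {
  cohort_spec(data.frame(
    race = c("american", "american", "asian", "chinese", "american"),
    health_status = c("healthy", "obese", "healthy", "healthy", "cirrhosis_a"),
    n = c(6, 4, 10, 10, 10),
    gender_fraction_male = rep(0.6, 5)), seed = seed)
}

# piecewise-linear age-height reference (cm): linear growth from age 5 to
# 20, flat after; race offsets applied to the adult plateau
height_reference <- function(age, gender, race) {
  adult <- ifelse(gender == "male", 176, 163)
  offset <- c(american = 0, asian = -4, chinese = -3)[race]
  adult <- adult + offset
  child5 <- 110
  ifelse(age >= 20, adult, child5 + (age - 5) / 15 * (adult - child5))
}

#' Body surface area (Du Bois - Du Bois)
#'
#' BSA = 0.007184 * weight^0.425 * height^0.725.
#'
#' @param weight kg; `height` cm; both positive.
#' @param height cm.
#' @return BSA in m^2.
#' @export
derive_bsa <- function(weight, height) {
  if (any(weight <= 0) || any(height <= 0)) stop("non-positive input")
  0.007184 * weight^0.425 * height^0.725
}

# lognormal parameters matching a target arithmetic mean and SD
lnorm_pars <- function(m, s) {
  sigma2 <- log(1 + (s / m)^2)
  c(mu = log(m) - sigma2 / 2, sigma = sqrt(sigma2))
}

#' Sample a virtual cohort
#'
#' Deterministic under the spec's seed, with per-subject substreams so the
#' cohort is extensible without reshuffling earlier subjects. Gender counts
#' per group are `round(gender_fraction_male * n)` males. Heights come
#' from gender/age/race reference curves plus individual variation; BMI is
#' drawn within the class sampled from `bmi_class_mix` (scale: 18.5-24.9
#' normal, 25-29.9 overweight, >= 30 obese) and weight = BMI * height^2.
#' CYP2D6/CYP2C19 expression are opaque lognormal covariates
#' (means 1.90/1.30, SDs 1.60/1.50).
#'
#' @param spec a [cohort_spec()].
#' @return data.frame of `VirtualSubject` rows: id, age, gender, race,
#'   health_status, weight, height, bsa, bmi, cyp2d6_expr, cyp2c19_expr.
#' @export
sample_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  cyp2d6 <- lnorm_pars(1.90, 1.60)
  cyp2c19 <- lnorm_pars(1.30, 1.50)
  mix <- spec$bmi_class_mix
  out <- list(); id <- 0L
  for (g in seq_len(nrow(spec$groups))) {
    grp <- spec$groups[g, ]
    n_male <- round(grp$gender_fraction_male * grp$n)
    for (i in seq_len(grp$n)) {
      id <- id + 1L
      set.seed(derive_seed(spec$seed, id))
      gender <- if (i <= n_male) "male" else "female"
      age <- runif(1, spec$age_range[1], spec$age_range[2])
      height <- height_reference(age, gender, grp$race) +
        rnorm(1, 0, ifelse(age < 20, 5, 6))
      if (grp$health_status == "obese") {
        bmi <- runif(1, 30, 40)
      } else {
        m2 <- mix[c("normal", "overweight")]
        cls <- sample(names(m2), 1, prob = m2 / sum(m2))
        bmi <- if (cls == "normal") runif(1, 18.5, 24.9) else runif(1, 25, 29.9)
      }
      weight <- bmi * (height / 100)^2
      out[[id]] <- data.frame(
        id = id, age = age, gender = gender, race = grp$race,
        health_status = grp$health_status, weight = weight, height = height,
        bsa = derive_bsa(weight, height), bmi = bmi,
        cyp2d6_expr = rlnorm(1, cyp2d6["mu"], cyp2d6["sigma"]),
        cyp2c19_expr = rlnorm(1, cyp2c19["mu"], cyp2c19["sigma"]))
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Packaged reference physiology table
#'
#' Tissue volumes as fractions of body weight and blood flows as fractions
#' of cardiac output for the 13 modeled tissues, compiled from standard
#' adult human physiology compilations. The lung receives the whole
#' cardiac output in series; the liver flow fraction is the total hepatic
#' inflow net of the spleen (the splanchnic beds are not modeled
#' separately, so their flow is folded into the hepatic term);
#' rest-of-body receives the flow remainder.
#'
#' @return data.frame with `tissue`, `vol_frac_bw`, `flow_frac_co`.
#' @export
reference_physiology <- function() {
  read.csv(system.file("extdata", "physiology_reference.csv",
                       package = "salbupk"))
}

#' Reference adult subject (30-year-old healthy American male, 75 kg)
#' @return one-row `VirtualSubject` data.frame.
#' @export
reference_subject <- function() {
  data.frame(id = 0L, age = 30, gender = "male", race = "american",
             health_status = "healthy", weight = 75, height = 178,
             bsa = derive_bsa(75, 178), bmi = 75 / 1.78^2,
             cyp2d6_expr = 1.90, cyp2c19_expr = 1.30)
}

#' Scale the reference physiology to a subject
#'
#' Tissue volumes scale proportionally to body weight (obese subjects get
#' an enlarged adipose fraction, 0.32 vs 0.19, partly offset in muscle);
#' cardiac output scales with BSA (cardiac index 195 L/h/m^2); flows are
#' fractions of cardiac output with rest-of-body taking the remainder.
#' Cirrhosis A applies multiplicative reductions to hepatic blood flow
#' (default x0.85) and hepatic intrinsic clearance (default x0.8).
#' Clearance scalars: hepatic intrinsic clearance scales with liver mass
#' (proportional to weight), renal clearance allometrically as
#' (weight/75)^0.75.
#'
#' @param subject one-row data.frame as from [sample_cohort()].
#' @param cirrhosis_flow_mult,cirrhosis_clint_mult cirrhosis-A modifiers.
#' @return a `physiology_set` list: `tissues` (tissue, volume L, flow L/h),
#'   `cardiac_output`, `v_venous`, `v_arterial` (L), `clint_multiplier`,
#'   `hepatic_scale`, `renal_scale`, `subject`.
#' @export
scale_physiology <- function(subject, cirrhosis_flow_mult = 0.85,
                             cirrhosis_clint_mult = 0.8) {
  ref <- reference_physiology()
  wt <- subject$weight; bsa <- subject$bsa
  stopifnot(wt > 0, bsa > 0)
  vf <- setNames(ref$vol_frac_bw, ref$tissue)
  if (subject$health_status == "obese") {
    vf["adipose"] <- 0.32
    vf["muscle"] <- 0.31
  }
  co <- 195 * bsa
  ff <- setNames(ref$flow_frac_co, ref$tissue)
  cirr <- subject$health_status == "cirrhosis_a"
  if (cirr) ff["liver"] <- ff["liver"] * cirrhosis_flow_mult
  named <- names(ff)[!is.na(ff)]
  flows <- setNames(rep(NA_real_, length(ff)), names(ff))
  flows[named] <- ff[named] * co
  flows["rest_of_body"] <- co - sum(flows[named])
  flows["lung"] <- co
  tis <- data.frame(tissue = names(vf), volume = unname(vf * wt),
                    flow = unname(flows[names(vf)]))
  structure(list(
    tissues = tis, cardiac_output = co,
    v_venous = 0.045 * wt, v_arterial = 0.023 * wt,
    clint_multiplier = if (cirr) cirrhosis_clint_mult else 1,
    hepatic_scale = wt / 75, renal_scale = (wt / 75)^0.75,
    subject = subject), class = "physiology_set")
}
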