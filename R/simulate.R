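#' Configuration for the synthetic-cohort generator
#'
#' Collects every knob of [generate_cohort()] with defaults that emulate the
#' motivating screenee cohort: the reference food-group partial-correlation
#' network, log-normal intake marginals moment-matched to the published
#' daily-intake means/SDs, marker-category prevalences matching the published
#' population counts, and an exponential proportional-hazards event model
#' whose category log-hazards equal the published risk points times the
#' per-year age coefficient (default 0.0556).
#'
#' @param n_subjects Number of subjects.
#' @param seed Integer RNG seed; identical config + seed reproduces the
#'   cohort exactly.
#' @param target_pcor 16 x 16 symmetric partial-correlation matrix (zero
#'   diagonal) imposed on the latent Gaussian of the intakes.
#' @param intake_marginals data.frame with `label`, `mean`, `sd` (g/day) per
#'   food group; mapped to log-normal marginals by moment matching.
#' @param marker_mixture Named list `bp`, `chol`, `glucose`, `gfr` of
#'   category-prevalence vectors (each summing to 1).
#' @param beta_age Log-hazard per year of age.
#' @param category_log_hazards Named list (same shape as `marker_mixture`)
#'   of per-category log-hazards; default = published risk point x
#'   `beta_age`.
#' @param baseline_hazard Exponential baseline event rate per year.
#' @param enrollment_span Years over which entry dates are uniform.
#' @param censoring_horizon Administrative end of follow-up, years after the
#'   first enrollment; must exceed `enrollment_span`.
#' @param energy_bounds_violation_rate,missingness_rate,prior_cancer_rate,early_case_rate
#'   Fractions in `[0, 1]` used to plant violations that exercise the
#'   exclusion cascade (all 0 by default: a clean analysis-ready cohort).
#' @return List of class `simulation_config`.
#' @export
simulation_config <- function(n_subjects = 5606,
                              seed = 1,
                              target_pcor = reference_network()$weights,
                              intake_marginals = reference_intake_marginals(),
                              marker_mixture = NULL,
                              beta_age = 0.0556,
                              category_log_hazards = NULL,
                              baseline_hazard = 1e-4,
                              enrollment_span = 6.75,
                              censoring_horizon = 9.25,
                              energy_bounds_violation_rate = 0,
                              missingness_rate = 0,
                              prior_cancer_rate = 0,
                              early_case_rate = 0) {
  if (is.null(marker_mixture)) {
    counts <- list(
      bp = c(normal = 1662, elevated = 2225, hypertension = 1719),
      chol = c(elevated = 2793, low = 1492, normal = 1141),
      glucose = c(normal = 5029, prediabetes_diabetes = 577),
      gfr = c(lt60 = 268, b60_89 = 4459, ge90 = 739)
    )
    marker_mixture <- lapply(counts, function(x) x / sum(x))
  }
  if (is.null(category_log_hazards)) {
    pts <- reference_risk_points("main")$points
    category_log_hazards <- lapply(pts, function(p) p * beta_age)
  }
  cfg <- structure(
    list(
      n_subjects = n_subjects, seed = as.integer(seed),
      target_pcor = target_pcor, intake_marginals = intake_marginals,
      marker_mixture = marker_mixture, beta_age = beta_age,
      category_log_hazards = category_log_hazards,
      baseline_hazard = baseline_hazard,
      enrollment_span = enrollment_span,
      censoring_horizon = censoring_horizon,
      energy_bounds_violation_rate = energy_bounds_violation_rate,
      missingness_rate = missingness_rate,
      prior_cancer_rate = prior_cancer_rate,
      early_case_rate = early_case_rate
    ),
    class = "simulation_config"
  )
  validate_simulation_config(cfg)
}

#' @rdname simulation_config
#' @param config A `simulation_config` to validate.
#' @export
validate_simulation_config <- function(config) {
  stopifnot(config$n_subjects >= 1)
  .check_pcor_matrix(config$target_pcor)
  rates <- c(
    config$energy_bounds_violation_rate, config$missingness_rate,
    config$prior_cancer_rate, config$early_case_rate
  )
  if (any(rates < 0 | rates > 1)) stop("rates must lie in [0, 1]")
  for (m in names(config$marker_mixture)) {
    pr <- config$marker_mixture[[m]]
    if (any(pr < 0) || abs(sum(pr) - 1) > 1e-8) {
      stop("mixture prevalences for ", m, " must be nonnegative and sum to 1")
    }
  }
  if (config$baseline_hazard <= 0) stop("baseline_hazard must be positive")
  if (config$censoring_horizon <= config$enrollment_span) {
    stop("censoring_horizon must exceed enrollment_span")
  }
  invisible(config)
}

# log-normal parameters matched to a mean/sd pair on the natural scale
.lognormal_params <- function(mean, sd) {
  cv2 <- (sd / mean)^2
  list(meanlog = log(mean / sqrt(1 + cv2)), sdlog = sqrt(log(1 + cv2)))
}

.draw_categories <- function(n, prev) {
  factor(sample(names(prev), n, replace = TRUE, prob = prev),
         levels = names(prev))
}

#' Per-subject event rate of the generator's hazard model
#'
#' Closed-form exponential event rate
#' \eqn{\lambda = \lambda_0 \exp(\beta_{age} \cdot age + \sum_m h_m)} for a
#' subject with the given marker categories; its reciprocal is the expected
#' (uncensored) event time, strictly decreasing in every category
#' log-hazard.
#'
#' @param config A `simulation_config`.
#' @param age Age in years.
#' @param bp,chol,glucose,gfr Category names for the four markers.
#' @return Event rate per year.
#' @export
subject_event_rate <- function(config, age, bp, chol, glucose, gfr) {
  h <- config$category_log_hazards
  lp <- config$beta_age * age +
    h$bp[[bp]] + h$chol[[chol]] + h$glucose[[glucose]] + h$gfr[[gfr]]
  unname(config$baseline_hazard * exp(lp))
}

#' Generate a synthetic screenee cohort
#'
#' Draws one subject per row with: food-group intakes from a Gaussian copula
#' whose latent partial-correlation matrix equals `config$target_pcor` and
#' whose marginals are log-normal (so log-intakes are exactly multivariate
#' Gaussian with the target partial correlations); comorbidity marker values
#' drawn per the configured category mixture and made consistent with the
#' classification rules (creatinine is inverted through the MDRD equation so
#' the eGFR lands in the drawn band); demographic covariates with
#' cohort-like frequencies; and exponential event times under the
#' proportional-hazards model of [subject_event_rate()] with uniform
#' enrollment and administrative censoring. Optional rates plant energy
#' violations, missing values, prior cancers and early (within one year)
#' diagnoses to exercise the exclusion cascade.
#'
#' @param config A `simulation_config`.
#' @return data.frame, one row per subject, with the documented cohort
#'   columns (`id`, demographics, `energy`, `intake_*`, marker measurements
#'   and flags, `prior_cancer`, `followup_years`, `cancer_event`,
#'   `time_to_diagnosis_years`). The config is attached as attribute
#'   `"config"`.
#' @export
#' @examples
#' cohort <- generate_cohort(simulation_config(n_subjects = 200, seed = 7))
#' nrow(cohort)
generate_cohort <- function(config) {
  validate_simulation_config(config)
  n <- config$n_subjects
  set.seed(config$seed)

  # demographics, calibrated to cohort-like frequencies
  age <- stats::qnorm(stats::runif(n, stats::pnorm(30, 52.5, 8.2),
                                   stats::pnorm(80, 52.5, 8.2)), 52.5, 8.2)
  sex <- factor(ifelse(stats::runif(n) < 0.37, "male", "female"),
                levels = c("female", "male"))
  marital_status <- factor(
    ifelse(stats::runif(n) < 0.86, "married", "other"),
    levels = c("married", "other")
  )
  education <- .draw_categories(n, c(lt_high_school = 0.13, high_school = 0.38,
                                     college = 0.49))
  employment <- .draw_categories(n, c(employed = 0.92, unemployed = 0.08))
  income <- .draw_categories(n, c(lt2m = 0.22, m2_4m = 0.40, ge4m = 0.38))
  smoking <- .draw_categories(n, c(never = 0.66, past = 0.22, current = 0.12))
  drinking <- .draw_categories(n, c(never = 0.39, past = 0.07, current = 0.54))
  physical_activity <- .draw_categories(n, c(no = 0.44, yes = 0.56))
  bmi <- pmin(pmax(stats::rnorm(n, 23.9, 3.1), 15), 40)
  energy <- exp(stats::rnorm(n, log(1800), 0.22))
  energy <- pmin(pmax(energy, 520), 3950)

  # intakes: Gaussian copula over the latent partial-correlation network
  sigma <- latent_pcor_to_covariance(config$target_pcor)
  r <- stats::cov2cor(sigma)
  z <- matrix(stats::rnorm(n * ncol(r)), n) %*% chol(r)
  marg <- config$intake_marginals
  intakes <- matrix(0, n, nrow(marg))
  for (g in seq_len(nrow(marg))) {
    lp <- .lognormal_params(marg$mean[g], marg$sd[g])
    intakes[, g] <- exp(lp$meanlog + lp$sdlog * z[, g])
  }
  colnames(intakes) <- paste0(
    "intake_", food_groups()$key[match(marg$label, food_groups()$label)]
  )

  # markers consistent with their drawn clinical category
  mix <- config$marker_mixture
  bp_cat <- .draw_categories(n, mix$bp)
  bp_flag <- bp_cat == "hypertension" & stats::runif(n) < 0.6
  sbp <- ifelse(bp_cat == "normal", stats::runif(n, 95, 119.5),
         ifelse(bp_cat == "elevated", stats::runif(n, 120, 139.5),
         ifelse(bp_flag, stats::runif(n, 112, 160), stats::runif(n, 140, 180))))
  dbp <- ifelse(bp_cat == "normal", stats::runif(n, 55, 79.5),
         ifelse(bp_cat == "elevated", stats::runif(n, 60, 89.5),
         ifelse(bp_flag, stats::runif(n, 60, 90), stats::runif(n, 70, 100))))

  chol_cat <- .draw_categories(n, mix$chol)
  chol_flag <- chol_cat == "elevated" & stats::runif(n) < 0.4
  tc <- ifelse(chol_cat == "low", stats::runif(n, 120, 179.5),
        ifelse(chol_cat == "normal", stats::runif(n, 180, 200),
        ifelse(chol_flag, stats::runif(n, 150, 280), stats::runif(n, 200.5, 300))))

  glu_cat <- .draw_categories(n, mix$glucose)
  glu_flag <- glu_cat == "prediabetes_diabetes" & stats::runif(n) < 0.5
  fg <- ifelse(glu_cat == "normal", stats::runif(n, 78, 109.5),
        ifelse(glu_flag, stats::runif(n, 90, 250), stats::runif(n, 110, 220)))

  gfr_cat <- .draw_categories(n, mix$gfr)
  gfr_val <- ifelse(gfr_cat == "ge90", stats::runif(n, 90, 125),
             ifelse(gfr_cat == "b60_89", stats::runif(n, 60, 89.9),
                    stats::runif(n, 30, 59.9)))
  fcoef <- ifelse(sex == "female", 0.742, 1)
  scr <- (175 * age^(-0.203) * fcoef / gfr_val)^(1 / 1.154)

  # event times: exponential proportional hazards, administrative censoring
  h <- config$category_log_hazards
  lp <- config$beta_age * age +
    unname(h$bp[as.character(bp_cat)]) +
    unname(h$chol[as.character(chol_cat)]) +
    unname(h$glucose[as.character(glu_cat)]) +
    unname(h$gfr[as.character(gfr_cat)])
  rate <- config$baseline_hazard * exp(lp)
  t_event <- stats::rexp(n, rate)
  entry <- stats::runif(n, 0, config$enrollment_span)
  censor_time <- config$censoring_horizon - entry
  event <- t_event <= censor_time
  followup <- pmin(t_event, censor_time)

  # planted violations for the exclusion cascade
  prior_cancer <- stats::runif(n) < config$prior_cancer_rate
  plant_early <- stats::runif(n) < config$early_case_rate
  if (any(plant_early)) {
    t_early <- stats::runif(n, 0.05, 0.95)
    event[plant_early] <- TRUE
    followup[plant_early] <- t_early[plant_early]
  }
  plant_energy <- stats::runif(n) < config$energy_bounds_violation_rate
  if (any(plant_energy)) {
    low_side <- stats::runif(n) < 0.5
    bad <- ifelse(low_side, stats::runif(n, 100, 499), stats::runif(n, 4001, 8000))
    energy[plant_energy] <- bad[plant_energy]
  }

  out <- data.frame(
    id = seq_len(n), age = age, sex = sex, marital_status = marital_status,
    education = education, employment = employment, income = income,
    smoking = smoking, drinking = drinking,
    physical_activity = physical_activity, bmi = bmi, energy = energy,
    stringsAsFactors = FALSE
  )
  out <- cbind(out, as.data.frame(intakes))
  out$sbp <- sbp
  out$dbp <- dbp
  out$total_cholesterol <- tc
  out$fasting_glucose <- fg
  out$serum_creatinine <- scr
  out$dx_hypertension <- bp_flag
  out$rx_hypertension <- bp_flag & stats::runif(n) < 0.8
  out$dx_dyslipidemia <- chol_flag
  out$rx_dyslipidemia <- chol_flag & stats::runif(n) < 0.8
  out$dx_diabetes <- glu_flag
  out$rx_diabetes <- glu_flag & stats::runif(n) < 0.8
  out$prior_cancer <- prior_cancer
  out$followup_years <- followup
  out$cancer_event <- event
  out$time_to_diagnosis_years <- ifelse(event, followup, NA_real_)

  plant_missing <- stats::runif(n) < config$missingness_rate
  if (any(plant_missing)) {
    blankable <- c("marital_status", "education", "income", "smoking",
                   "drinking", "total_cholesterol", "serum_creatinine")
    which_col <- sample(blankable, n, replace = TRUE)
    for (cc in blankable) {
      hit <- plant_missing & which_col == cc
      if (any(hit)) out[[cc]][hit] <- NA
    }
  }

  attr(out, "config") <- config
  out
}
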