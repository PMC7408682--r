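#' Clinical category of blood pressure
#'
#' Joint-National-Committee style bands: normal (<120/80), elevated
#' (120-139/80-89, the guideline's "prehypertension"), hypertension
#' (>=140/90, or receiving therapy, or previously diagnosed).
#'
#' @param sbp,dbp Systolic / diastolic blood pressure, mmHg. Vectorized.
#' @param treated_or_diagnosed Logical: antihypertensive therapy or a prior
#'   hypertension diagnosis (either suffices).
#' @return Factor with levels `normal`, `elevated`, `hypertension`
#'   (reference level first).
#' @export
#' @examples
#' classify_blood_pressure(c(118, 130, 118), c(78, 78, 78), c(FALSE, FALSE, TRUE))
classify_blood_pressure <- function(sbp, dbp, treated_or_diagnosed) {
  stopifnot(length(sbp) == length(dbp))
  treated_or_diagnosed <- rep_len(treated_or_diagnosed, length(sbp))
  ok <- !is.na(sbp) & !is.na(dbp)
  if (any(ok & (sbp <= dbp | dbp <= 0))) stop("require sbp > dbp > 0")
  if (any(ok & (sbp > 300 | dbp > 200))) stop("non-physiological blood pressure")
  cat <- ifelse(
    treated_or_diagnosed | sbp >= 140 | dbp >= 90, "hypertension",
    ifelse(sbp >= 120 | dbp >= 80, "elevated", "normal")
  )
  factor(cat, levels = c("normal", "elevated", "hypertension"))
}

#' Clinical category of total cholesterol
#'
#' low (<180), normal (180-200, both ends included per the published closed
#' range), elevated (>200, or lipid-lowering drugs, or prior dyslipidemia
#' diagnosis). The reference level is `elevated`, matching the reference
#' category of the risk-point model.
#'
#' @param tc Total cholesterol, mg/dL. Vectorized.
#' @param treated_or_diagnosed Logical: drugs or prior dyslipidemia diagnosis.
#' @return Factor with levels `elevated`, `low`, `normal`.
#' @export
classify_cholesterol <- function(tc, treated_or_diagnosed) {
  treated_or_diagnosed <- rep_len(treated_or_diagnosed, length(tc))
  if (any(!is.na(tc) & tc <= 0)) stop("total cholesterol must be positive")
  cat <- ifelse(
    treated_or_diagnosed | tc > 200, "elevated",
    ifelse(tc < 180, "low", "normal")
  )
  factor(cat, levels = c("elevated", "low", "normal"))
}

#' Clinical category of fasting glucose
#'
#' normal (<110) versus prediabetes-and-diabetes (>=110, or antidiabetic
#' treatment, or prior diabetes diagnosis).
#'
#' @param fg Fasting glucose, mg/dL. Vectorized.
#' @param treated_or_diagnosed Logical: treatment or prior diabetes diagnosis.
#' @return Factor with levels `normal`, `prediabetes_diabetes`.
#' @export
classify_glucose <- function(fg, treated_or_diagnosed) {
  treated_or_diagnosed <- rep_len(treated_or_diagnosed, length(fg))
  if (any(!is.na(fg) & fg <= 0)) stop("fasting glucose must be positive")
  cat <- ifelse(treated_or_diagnosed | fg >= 110, "prediabetes_diabetes", "normal")
  factor(cat, levels = c("normal", "prediabetes_diabetes"))
}

#' Estimated glomerular filtration rate (MDRD study equation)
#'
#' Four-variable MDRD equation:
#' \eqn{175 \cdot \mathrm{SCr}^{-1.154} \cdot \mathrm{age}^{-0.203} \cdot
#' 0.742^{[\mathrm{female}]}} (times 1.212 if the Black-race coefficient is
#' requested; off by default for this East-Asian cohort setting).
#'
#' @param serum_creatinine Serum creatinine, mg/dL. Vectorized.
#' @param age Age in years.
#' @param female Logical.
#' @param race_black Logical, apply the 1.212 race coefficient.
#' @return eGFR in mL/min/1.73 m^2.
#' @export
#' @examples
#' mdrd_gfr(1.0, 50, female = FALSE)  # ~79.1
mdrd_gfr <- function(serum_creatinine, age, female, race_black = FALSE) {
  if (any(!is.na(serum_creatinine) & serum_creatinine <= 0)) {
    stop("serum creatinine must be positive")
  }
  if (any(!is.na(age) & age <= 0)) stop("age must be positive")
  g <- 175 * serum_creatinine^(-1.154) * age^(-0.203) *
    ifelse(female, 0.742, 1)
  ifelse(rep(race_black, length.out = length(g)), g * 1.212, g)
}

#' GFR category
#'
#' Bands >=90 (`ge90`), 60-89 (`b60_89`), <60 (`lt60`) mL/min/1.73 m^2; the
#' reference level is `lt60`, matching the reference category of the
#' risk-point model.
#'
#' @param gfr eGFR values from [mdrd_gfr()].
#' @return Factor with levels `lt60`, `b60_89`, `ge90`.
#' @export
gfr_category <- function(gfr) {
  cat <- ifelse(gfr >= 90, "ge90", ifelse(gfr >= 60, "b60_89", "lt60"))
  factor(cat, levels = c("lt60", "b60_89", "ge90"))
}

# covariates required complete for the fully adjusted models
.model_covariates <- function() {
  c("age", "sex", "marital_status", "education", "employment", "income",
    "smoking", "drinking", "physical_activity", "bmi")
}

.marker_inputs <- function() {
  c("sbp", "dbp", "total_cholesterol", "fasting_glucose", "serum_creatinine",
    "dx_hypertension", "rx_hypertension", "dx_dyslipidemia",
    "rx_dyslipidemia", "dx_diabetes", "rx_diabetes")
}

#' Attach comorbidity categories to a cohort table
#'
#' Computes the MDRD eGFR and the four marker categories (`bp_category`,
#' `chol_category`, `glucose_category`, `gfr_category`) plus a BMI category
#' (<23 / 23-24.9 / >=25 kg/m^2). Self-reported treatment and diagnosis
#' flags are combined as "treated or diagnosed" per condition.
#'
#' @param cohort data.frame in the cohort column layout of
#'   [generate_cohort()].
#' @return The cohort with category columns appended.
#' @export
classify_cohort <- function(cohort) {
  need <- c("age", "sex", .marker_inputs())
  miss <- setdiff(need, names(cohort))
  if (length(miss)) stop("cohort lacks columns: ", paste(miss, collapse = ", "))
  out <- cohort
  out$gfr <- mdrd_gfr(cohort$serum_creatinine, cohort$age,
                      female = cohort$sex == "female")
  out$bp_category <- classify_blood_pressure(
    cohort$sbp, cohort$dbp, cohort$dx_hypertension | cohort$rx_hypertension
  )
  out$chol_category <- classify_cholesterol(
    cohort$total_cholesterol, cohort$dx_dyslipidemia | cohort$rx_dyslipidemia
  )
  out$glucose_category <- classify_glucose(
    cohort$fasting_glucose, cohort$dx_diabetes | cohort$rx_diabetes
  )
  out$gfr_category <- gfr_category(out$gfr)
  out$bmi_category <- factor(
    ifelse(cohort$bmi < 23, "lt23", ifelse(cohort$bmi < 25, "b23_24.9", "ge25")),
    levels = c("lt23", "b23_24.9", "ge25")
  )
  out
}

#' Apply the subject exclusion cascade
#'
#' Sequential gates in the recruitment-flowchart order: (1) missing dietary
#' intake or unrealistic energy intake (<500 or >4000 kcal/day); (2) prior
#' cancer diagnosis; (3) missing demographics or comorbidity measurements;
#' (4) cancer diagnosed within `latency_years` of enrollment (reverse
#' causality). Each subject is counted at its first failing gate.
#' `latency_years = 0` keeps early cases, reproducing the
#' everyone-regardless-of-diagnosis-time sensitivity cohort.
#'
#' @param cohort Cohort data.frame.
#' @param latency_years Early-case exclusion window in years (default 1).
#' @return List with `cohort` (retained rows) and `report` (class
#'   `exclusion_report`: n_input, per-gate counts, n_final).
#' @export
apply_exclusions <- function(cohort, latency_years = 1) {
  stopifnot(latency_years >= 0)
  n_input <- nrow(cohort)
  intake_cols <- intersect(intake_columns(), names(cohort))
  bad_energy <- is.na(cohort$energy) | cohort$energy < 500 | cohort$energy > 4000
  if (length(intake_cols)) {
    bad_energy <- bad_energy | rowSums(is.na(cohort[intake_cols])) > 0
  }
  keep <- !bad_energy
  n_energy <- sum(bad_energy)

  prior <- keep & !is.na(cohort$prior_cancer) & cohort$prior_cancer
  n_prior <- sum(prior)
  keep <- keep & !prior

  check_cols <- intersect(c(.model_covariates(), .marker_inputs()), names(cohort))
  missing_row <- rowSums(is.na(cohort[check_cols])) > 0
  n_missing <- sum(keep & missing_row)
  keep <- keep & !missing_row

  early <- keep & !is.na(cohort$cancer_event) & cohort$cancer_event &
    !is.na(cohort$time_to_diagnosis_years) &
    cohort$time_to_diagnosis_years <= latency_years
  n_early <- sum(early)
  keep <- keep & !early

  report <- structure(
    list(
      n_input = n_input, n_energy_excluded = n_energy,
      n_prior_cancer_excluded = n_prior, n_missing_excluded = n_missing,
      n_early_case_excluded = n_early, n_final = sum(keep),
      latency_years = latency_years
    ),
    class = "exclusion_report"
  )
  list(cohort = cohort[keep, , drop = FALSE], report = report)
}

#' @export
print.exclusion_report <- function(x, ...) {
  cat(sprintf("Exclusion cascade (latency %.2g y): %d -> %d subjects\n",
              x$latency_years, x$n_input, x$n_final))
  cat(sprintf("  missing diet / unrealistic energy: %d\n", x$n_energy_excluded))
  cat(sprintf("  prior cancer:                      %d\n", x$n_prior_cancer_excluded))
  cat(sprintf("  missing covariates:                %d\n", x$n_missing_excluded))
  cat(sprintf("  cancer within latency window:      %d\n", x$n_early_case_excluded))
  invisible(x)
}
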