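test_that("identical config and seed reproduce the cohort exactly", {
  a <- generate_cohort(simulation_config(n_subjects = 300, seed = 5))
  b <- generate_cohort(simulation_config(n_subjects = 300, seed = 5))
  expect_identical(a, b)
  c <- generate_cohort(simulation_config(n_subjects = 300, seed = 6))
  expect_false(identical(a$age, c$age))
})

test_that("a zero target network yields near-independent intakes", {
  n <- 2000
  cfg <- simulation_config(
    n_subjects = n, seed = 17, target_pcor = matrix(0, 16, 16)
  )
  x <- log(as.matrix(generate_cohort(cfg)[intake_columns()]))
  pc <- partial_correlations(x)
  expect_lt(max(abs(pc[upper.tri(pc)])), 3 / sqrt(n))
})

test_that("the latent network's strongest edge survives the copula transform", {
  ch <- generate_cohort(simulation_config(n_subjects = 5000, seed = 42))
  x <- log(as.matrix(ch[intake_columns()]))
  pc <- partial_correlations(x)
  i <- match("intake_oils_fats", colnames(x))
  j <- match("intake_sugars_sweets", colnames(x))
  expect_lt(abs(pc[i, j] - 0.70), 0.05)
})

test_that("intake marginals match the configured log-normal moments", {
  ch <- generate_cohort(simulation_config(n_subjects = 20000, seed = 8))
  marg <- reference_intake_marginals()
  m_obs <- colMeans(ch[intake_columns()])
  # relative error of the mean: generous bound for heavy-tailed groups
  expect_lt(max(abs(m_obs - marg$mean) / marg$mean), 0.10)
  expect_true(all(as.matrix(ch[intake_columns()]) >= 0))
})

test_that("marker values are consistent with their drawn categories", {
  ch <- classify_cohort(generate_cohort(simulation_config(n_subjects = 3000, seed = 12)))
  mix <- simulation_config(n_subjects = 10, seed = 1)$marker_mixture
  cols <- c(bp = "bp_category", chol = "chol_category",
            glucose = "glucose_category", gfr = "gfr_category")
  for (m in names(mix)) {
    col <- cols[[m]]
    prop <- prop.table(table(ch[[col]]))[names(mix[[m]])]
    expect_lt(max(abs(prop - mix[[m]])), 0.04)
  }
})

test_that("expected event time strictly decreases in a category log-hazard", {
  cfg <- simulation_config(n_subjects = 10, seed = 1)
  base <- 1 / subject_event_rate(cfg, 50, "normal", "elevated", "normal", "lt60")
  up <- cfg
  up$category_log_hazards$bp[["normal"]] <- up$category_log_hazards$bp[["normal"]] + 0.3
  raised <- 1 / subject_event_rate(up, 50, "normal", "elevated", "normal", "lt60")
  expect_lt(raised, base)
  # and monotone across published point-loaded categories
  r_low <- subject_event_rate(cfg, 50, "normal", "elevated", "normal", "lt60")
  r_high <- subject_event_rate(cfg, 50, "hypertension", "normal",
                               "prediabetes_diabetes", "ge90")
  expect_gt(r_high / r_low, exp(0.0556 * 29) * 0.999)
})

test_that("age-only simulations recover the age coefficient with nominal coverage", {
  covered <- 0
  zero_h <- lapply(
    reference_risk_points()$points,
    function(p) stats::setNames(rep(0, length(p)), names(p))
  )
  for (rep in 1:100) {
    cfg <- simulation_config(
      n_subjects = 1500, seed = 7000 + rep,
      category_log_hazards = zero_h, baseline_hazard = 5e-4
    )
    ch <- generate_cohort(cfg)
    fit <- fit_cox(ch, "age")
    b <- fit$coef[["age"]]
    s <- fit$se[["age"]]
    if (b - 1.96 * s <= 0.0556 && 0.0556 <= b + 1.96 * s) covered <- covered + 1
  }
  expect_gte(covered, 90)
})

test_that("planted exclusion violations appear at their binomial rates", {
  n <- 4000
  cfg <- simulation_config(
    n_subjects = n, seed = 31,
    energy_bounds_violation_rate = 0.05, missingness_rate = 0.05,
    prior_cancer_rate = 0.04, early_case_rate = 0.02
  )
  ch <- generate_cohort(cfg)
  res <- apply_exclusions(ch, latency_years = 1)
  r <- res$report
  expect_identical(
    r$n_final,
    r$n_input - r$n_energy_excluded - r$n_prior_cancer_excluded -
      r$n_missing_excluded - r$n_early_case_excluded
  )
  # gate 1 count is a plain binomial draw
  expect_lt(abs(r$n_energy_excluded - n * 0.05), 4 * sqrt(n * 0.05 * 0.95))
  # later gates see only survivors of earlier gates
  m2 <- r$n_input - r$n_energy_excluded
  expect_lt(abs(r$n_prior_cancer_excluded - m2 * 0.04), 4 * sqrt(m2 * 0.04 * 0.96))
  m3 <- m2 - r$n_prior_cancer_excluded
  expect_lt(abs(r$n_missing_excluded - m3 * 0.05), 4 * sqrt(m3 * 0.05 * 0.95))
})

test_that("cancer events always carry a diagnosis time within follow-up", {
  ch <- generate_cohort(simulation_config(n_subjects = 2000, seed = 77,
                                          early_case_rate = 0.02))
  ev <- ch$cancer_event
  expect_true(all(!is.na(ch$time_to_diagnosis_years[ev])))
  expect_true(all(ch$time_to_diagnosis_years[ev] <= ch$followup_years[ev]))
  expect_true(all(is.na(ch$time_to_diagnosis_years[!ev])))
  expect_true(all(ch$followup_years > 0))
})
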