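test_that("a label-permuted covariate has a near-zero coefficient", {
  set.seed(14)
  n <- 800
  df <- data.frame(
    followup_years = rexp(n, 0.2),
    cancer_event = runif(n) < 0.4,
    x = sample(rep(0:1, n / 2))
  )
  fit <- fit_cox(df, "x")
  expect_lt(abs(fit$coef[["x"]]), 2.5 * fit$se[["x"]])
})

test_that("the partial-likelihood maximum matches the hand-derived value", {
  # events at t=1 (x=0) and t=2 (x=1), censored x=0 and x=1 afterwards:
  # d/db log PL = 0 at exp(b) = 1/sqrt(2), i.e. b = -log(2)/2
  df <- data.frame(
    followup_years = c(1, 2, 3, 4),
    cancer_event = c(TRUE, TRUE, FALSE, FALSE),
    x = c(0, 1, 0, 1)
  )
  fit <- fit_cox(df, "x")
  expect_equal(unname(fit$coef[["x"]]), -log(2) / 2, tolerance = 1e-6)
})

test_that("simulated marker effects are covered by their Wald intervals", {
  truth <- c(age = 0.0556,
             bp_categoryhypertension = 8 * 0.0556,
             gfr_categoryge90 = 9 * 0.0556)
  covered <- c(age = 0, bp_categoryhypertension = 0, gfr_categoryge90 = 0)
  for (rep in 1:100) {
    ch <- classify_cohort(generate_cohort(simulation_config(
      n_subjects = 2500, seed = 8000 + rep, baseline_hazard = 4e-4
    )))
    fit <- fit_cox(ch, cox_terms("adjusted"))
    for (term in names(truth)) {
      lo <- fit$coef[[term]] - 1.96 * fit$se[[term]]
      hi <- fit$coef[[term]] + 1.96 * fit$se[[term]]
      if (lo <= truth[[term]] && truth[[term]] <= hi) {
        covered[[term]] <- covered[[term]] + 1
      }
    }
  }
  expect_true(all(covered >= 90))
})

test_that("coefficients and points are invariant to a time-unit change", {
  ch <- classify_cohort(small_cohort(n = 2500, seed = 15, baseline_hazard = 4e-4))
  f1 <- fit_cox(ch, cox_terms("adjusted"))
  ch2 <- ch
  ch2$followup_years <- ch2$followup_years * 365.25
  f2 <- fit_cox(ch2, cox_terms("adjusted"))
  expect_equal(f1$coef, f2$coef, tolerance = 1e-8)
  expect_identical(
    suppressMessages(sullivan_points(f1)$points),
    suppressMessages(sullivan_points(f2)$points)
  )
})

test_that("sullivan points divide by the age coefficient and round half away", {
  fake <- structure(list(
    coef = c(
      age = 0.0556,
      bp_categoryelevated = log(1.12), bp_categoryhypertension = log(1.56),
      chol_categorylow = log(1.31), chol_categorynormal = log(1.51),
      glucose_categoryprediabetes_diabetes = log(1.32),
      gfr_categoryb60_89 = log(1.11), gfr_categoryge90 = log(1.65)
    )
  ), class = "cox_fit")
  pts <- sullivan_points(fake)
  expect_identical(pts$points$glucose[["prediabetes_diabetes"]], 5L)
  expect_identical(pts$points$bp[["elevated"]], 2L)
  expect_identical(pts$points$bp[["normal"]], 0L)
  expect_identical(pts$points$gfr[["ge90"]], 9L)
  # beta_j equal to beta_age gives point 1
  fake$coef[["bp_categoryelevated"]] <- 0.0556
  expect_identical(sullivan_points(fake)$points$bp[["elevated"]], 1L)
  # negative age coefficient is an error
  fake$coef[["age"]] <- -0.01
  expect_error(sullivan_points(fake), "not positive")
  # negative points are retained, with a message
  fake$coef[["age"]] <- 0.0556
  fake$coef[["bp_categoryelevated"]] <- -0.2
  expect_message(p2 <- sullivan_points(fake), "negative")
  expect_identical(p2$points$bp[["elevated"]], -4L)
})

test_that("comorbidity scores add points over the included markers", {
  tbl <- reference_risk_points()
  all_ref <- list(bp = "normal", chol = "elevated", glucose = "normal", gfr = "lt60")
  expect_identical(comorbidity_score(all_ref, tbl), 0L)
  worst <- list(bp = "hypertension", chol = "normal",
                glucose = "prediabetes_diabetes", gfr = "ge90")
  expect_identical(comorbidity_score(worst, tbl), 30L)
  expect_identical(max_score(tbl), 30L)
  nochol <- reference_risk_points("no_cholesterol")
  expect_identical(comorbidity_score(worst[c("bp", "glucose", "gfr")], nochol), 23L)
  expect_identical(max_score(nochol), 23L)
  # additivity: total = sum of single-marker scores
  ch <- classify_cohort(small_cohort(n = 200, seed = 44))
  total <- comorbidity_score(ch, tbl)
  parts <- Reduce(`+`, lapply(c("bp", "chol", "glucose", "gfr"), function(m) {
    comorbidity_score(ch, new_risk_point_table_for_test(tbl, m))
  }))
  expect_identical(total, parts)
  expect_error(
    comorbidity_score(list(bp = "severe", chol = "elevated",
                           glucose = "normal", gfr = "lt60"), tbl),
    "unknown"
  )
})

test_that("strata follow the published inclusive labels", {
  s <- stratify(c(0, 8, 9, 10, 11, 15, 16, 30))
  expect_identical(
    as.character(s),
    c("0-8", "0-8", "9-10", "9-10", "11-15", "11-15", "16-30", "16-30")
  )
  expect_identical(levels(s), c("0-8", "9-10", "11-15", "16-30"))
  expect_length(stratify(integer(0)), 0)
  expect_error(stratify(31), "exceeds the top stratum")
  expect_error(stratify(5, cutpoints = c(10, 3)), "strictly increasing")
})

test_that("an age coefficient consistent with the published points exists", {
  ref <- reference_marker_hr()
  scan <- risk_point_consistency(ref$hr, ref$point)
  expect_gte(scan$n_matched, 6)
  expect_identical(scan$n_categories, 7L)
  expect_true(scan$beta_age >= 0.04 && scan$beta_age <= 0.07)
  # 0.0556 itself reproduces six of the seven printed points
  expect_gte(sum(round(log(ref$hr) / 0.0556) == ref$point), 6)
})
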