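test_that("blood-pressure categories follow the guideline bands", {
  expect_identical(
    as.character(classify_blood_pressure(
      c(118, 130, 118, 142, 120, 119), c(78, 78, 78, 88, 79, 90),
      c(FALSE, FALSE, TRUE, FALSE, FALSE, FALSE)
    )),
    c("normal", "elevated", "hypertension", "hypertension", "elevated",
      "hypertension")
  )
  expect_error(classify_blood_pressure(80, 90, FALSE), "sbp > dbp")
  expect_error(classify_blood_pressure(320, 90, FALSE), "non-physiological")
})

test_that("cholesterol categories use the closed 180-200 normal band", {
  expect_identical(
    as.character(classify_cholesterol(
      c(179, 180, 200, 201, 150), c(FALSE, FALSE, FALSE, FALSE, TRUE)
    )),
    c("low", "normal", "normal", "elevated", "elevated")
  )
  expect_error(classify_cholesterol(-1, FALSE), "positive")
})

test_that("glucose splits at 110 with the treatment flag dominating", {
  expect_identical(
    as.character(classify_glucose(c(109, 110, 95), c(FALSE, FALSE, TRUE))),
    c("normal", "prediabetes_diabetes", "prediabetes_diabetes")
  )
})

test_that("MDRD eGFR matches direct evaluation and its categories", {
  g_male <- mdrd_gfr(1.0, 50, female = FALSE)
  expect_equal(g_male, 79.1, tolerance = 0.01)
  expect_identical(as.character(gfr_category(g_male)), "b60_89")
  g_female <- mdrd_gfr(1.0, 50, female = TRUE)
  expect_equal(g_female, g_male * 0.742, tolerance = 1e-12)
  expect_identical(as.character(gfr_category(g_female)), "lt60")
  # monotone in creatinine
  expect_lt(mdrd_gfr(2.0, 50, FALSE), mdrd_gfr(1.0, 50, FALSE))
  expect_error(mdrd_gfr(0, 50, FALSE), "positive")
})

test_that("MDRD agrees with an independent reimplementation to 1e-9", {
  set.seed(13)
  scr <- runif(1000, 0.4, 3)
  age <- runif(1000, 20, 85)
  fem <- runif(1000) < 0.5
  expect_lt(max(abs(mdrd_gfr(scr, age, fem) - oracle_mdrd(scr, age, fem))), 1e-9)
})

test_that("classification is total and monotone in the continuous input", {
  sbp <- seq(95, 200, by = 0.5)
  cats <- classify_blood_pressure(sbp, rep(70, length(sbp)), FALSE)
  expect_true(!anyNA(cats))
  expect_true(!is.unsorted(as.integer(cats)))
  tc <- seq(100, 300, by = 0.5)
  expect_true(!is.unsorted(as.integer(ordered(
    classify_cholesterol(tc, FALSE), c("low", "normal", "elevated")
  ))))
})

test_that("exclusion gates count planted violations exactly", {
  ch <- small_cohort(n = 60, seed = 3)
  ch$cancer_event[] <- FALSE # start from an event-free slate, then plant
  ch$time_to_diagnosis_years[] <- NA_real_
  ch$energy[1:4] <- c(450, 4200, 100, NA) # 4 energy violations
  ch$prior_cancer[5:7] <- TRUE # 3 prior cancers
  ch$prior_cancer[1] <- TRUE # overlaps gate 1: counted there only
  ch$education[8:9] <- NA # 2 missing
  ch$cancer_event[10:12] <- TRUE # 3 early cases
  ch$time_to_diagnosis_years[10:12] <- c(0.4, 0.8, 0.99)
  ch$followup_years[10:12] <- pmax(ch$followup_years[10:12], 1)
  res <- apply_exclusions(ch, latency_years = 1)
  r <- res$report
  expect_identical(r$n_energy_excluded, 4L)
  expect_identical(r$n_prior_cancer_excluded, 3L)
  expect_identical(r$n_missing_excluded, 2L)
  expect_identical(r$n_early_case_excluded, 3L)
  expect_identical(r$n_final, 60L - 12L)
  # latency 0 keeps the early cases and changes nothing else
  r0 <- apply_exclusions(ch, latency_years = 0)$report
  expect_identical(r0$n_early_case_excluded, 0L)
  expect_identical(r0$n_final, r$n_final + 3L)
  expect_identical(r0$n_energy_excluded, r$n_energy_excluded)
})

test_that("n_final is stable when one subject fails several gates", {
  ch <- small_cohort(n = 30, seed = 4)
  ch$energy[1] <- 100
  ch$prior_cancer[1] <- TRUE
  ch$education[1] <- NA
  r <- apply_exclusions(ch)$report
  expect_identical(r$n_final, 29L)
  expect_identical(r$n_energy_excluded, 1L)
  expect_identical(r$n_prior_cancer_excluded, 0L)
})

test_that("a clean cohort passes every gate", {
  ch <- small_cohort(n = 50, seed = 6)
  r <- apply_exclusions(ch)$report
  expect_identical(r$n_final, r$n_input)
  expect_identical(
    r$n_energy_excluded + r$n_prior_cancer_excluded +
      r$n_missing_excluded + r$n_early_case_excluded, 0L
  )
})
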