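test_that("Kaplan-Meier matches the brute-force product-limit oracle", {
  # hand-derived toy: events at 1 and 3, censoring at 2
  km <- kaplan_meier(c(1, 2, 3), c(TRUE, FALSE, TRUE))
  ev <- km$curves[km$curves$n_event > 0, ]
  expect_equal(ev$survival[ev$time == 1], 2 / 3, tolerance = 1e-12)
  expect_equal(ev$survival[ev$time == 3], 0, tolerance = 1e-12)
  # random small samples, exact equality with the oracle
  for (seed in 1:20) {
    set.seed(seed)
    n <- sample(5:40, 1)
    t <- sample(1:15, n, replace = TRUE)
    e <- runif(n) < 0.6
    if (!any(e)) e[1] <- TRUE
    km <- kaplan_meier(t, e)
    orc <- oracle_km(t, e)
    got <- km$curves[km$curves$n_event > 0, ]
    expect_equal(got$time, orc$time)
    expect_equal(got$survival, orc$survival, tolerance = 1e-12)
  }
})

test_that("all-censored data give a flat curve with undefined median", {
  km <- kaplan_meier(c(2, 4, 6), c(FALSE, FALSE, FALSE))
  expect_true(all(km$curves$survival == 1))
  expect_true(is.na(km$medians[["all"]]))
})

test_that("without censoring the curve is the empirical survival function", {
  t <- c(1, 2, 2, 3, 5)
  km <- kaplan_meier(t, rep(TRUE, 5))
  ev <- km$curves[km$curves$n_event > 0, ]
  expect_equal(ev$survival, c(4 / 5, 2 / 5, 1 / 5, 0), tolerance = 1e-12)
  expect_equal(km$medians[["all"]], 2)
})

test_that("empty strata are dropped with a warning", {
  expect_warning(
    km <- kaplan_meier(c(1, 2), c(TRUE, TRUE),
                       factor(c("a", "a"), levels = c("a", "b"))),
    "empty"
  )
  expect_identical(unique(km$curves$stratum), "a")
})

test_that("the reference stratum has HR exactly 1 and CIs behave under the null", {
  set.seed(33)
  cover <- 0
  for (rep in 1:100) {
    n <- 400
    df <- data.frame(
      followup_years = rexp(n, 0.15),
      cancer_event = runif(n) < 0.5,
      score = sample(0:30, n, replace = TRUE)
    )
    df$stratum <- stratify(df$score)
    a <- association(df, "crude")
    if (rep == 1) {
      expect_identical(a$table$hr[1], 1)
      expect_true(is.na(a$table$lo[1]))
    }
    top <- nrow(a$table)
    if (a$table$lo[top] <= 1 && 1 <= a$table$hi[top]) cover <- cover + 1
  }
  expect_gte(cover, 90)
})

test_that("dose-dependent simulations give increasing HRs and tiny p-trend", {
  ch <- classify_cohort(generate_cohort(simulation_config(
    n_subjects = 20000, seed = 777
  )))
  x <- as.matrix(ch[intake_columns()])
  colnames(x) <- food_groups()$label
  ch$dietary_score <- dietary_score(x, eigenvector_centrality(reference_network()))
  ch$eating_behavior <- tertile_classes(ch$dietary_score)
  ch$score <- comorbidity_score(ch, reference_risk_points())
  ch$stratum <- stratify(ch$score)
  a <- association(ch, "fully_adjusted", "all")
  expect_gt(a$table$hr[4], a$table$hr[1])
  expect_lt(a$p_trend, 0.001)
  # the trend coefficient agrees in sign with the top-stratum log-HR
  expect_gt(a$table$hr[4], 1)
  # subgroup fits drop sex and agree in direction for the top stratum
  am <- association(ch, "fully_adjusted", "male")
  af <- association(ch, "fully_adjusted", "female")
  expect_gt(am$table$hr[4], 1)
  expect_gt(af$table$hr[4], 1)
})

test_that("trend test needs at least two strata and a score column", {
  df <- data.frame(
    followup_years = rexp(50, 0.2), cancer_event = rep(TRUE, 50),
    score = rep(3, 50), stratum = factor(rep("0-8", 50))
  )
  expect_error(trend_test(df, "crude"), "two strata")
})

test_that("the sensitivity suite runs both variants end to end", {
  ch <- small_cohort(n = 1500, seed = 61, early_case_rate = 0.01)
  res <- suppressWarnings(sensitivity_suite(
    ch, models = "crude", subgroups = "all", n_penalties = 20
  ))
  expect_named(res, c("no_cholesterol", "include_early"))
  expect_false("chol" %in% res$no_cholesterol$risk_points$included_markers)
  expect_identical(
    sort(res$no_cholesterol$risk_points$included_markers),
    c("bp", "gfr", "glucose")
  )
  # keeping early cases enlarges the analysis cohort
  expect_gt(res$include_early$exclusions$n_final,
            res$no_cholesterol$exclusions$n_final)
  for (v in res) expect_s3_class(v$associations[["crude.all"]], "association_result")
})
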