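# Independent oracles kept deliberately separate from the package code paths.

# MDRD re-implementation through logs (vs the package's power-law products)
oracle_mdrd <- function(scr, age, female) {
  g <- exp(log(175) - 1.154 * log(scr) - 0.203 * log(age))
  ifelse(female, g * 0.742, g)
}

# brute-force Kaplan-Meier product-limit estimator at the event times
oracle_km <- function(times, events) {
  ts <- sort(unique(times[events]))
  surv <- numeric(length(ts))
  s <- 1
  for (i in seq_along(ts)) {
    at_risk <- sum(times >= ts[i])
    d <- sum(times == ts[i] & events)
    s <- s * (1 - d / at_risk)
    surv[i] <- s
  }
  data.frame(time = ts, survival = surv)
}

# partial correlations by the regression definition: correlate residuals of
# i and j after regressing each on all remaining variables
oracle_pcor_entry <- function(x, i, j) {
  others <- setdiff(seq_len(ncol(x)), c(i, j))
  ri <- stats::resid(stats::lm(x[, i] ~ x[, others]))
  rj <- stats::resid(stats::lm(x[, j] ~ x[, others]))
  stats::cor(ri, rj)
}

# random valid partial-correlation matrix whose implied precision is PD:
# built from a random diagonally dominant precision matrix
random_pcor <- function(p, seed, density = 0.3) {
  set.seed(seed)
  om <- diag(p)
  for (i in seq_len(p - 1)) {
    for (j in seq(i + 1, p)) {
      if (stats::runif(1) < density) {
        om[i, j] <- om[j, i] <- stats::runif(1, -0.9, 0.9) / p
      }
    }
  }
  pc <- -stats::cov2cor(om)
  diag(pc) <- 0
  pc
}

# small clean synthetic cohort for pipeline-level tests
small_cohort <- function(n = 1200, seed = 99, ...) {
  generate_cohort(simulation_config(n_subjects = n, seed = seed, ...))
}

# single-marker view of a risk point table (for additivity checks)
new_risk_point_table_for_test <- function(tbl, marker) {
  structure(
    list(points = tbl$points[marker], included_markers = marker),
    class = "risk_point_table"
  )
}
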