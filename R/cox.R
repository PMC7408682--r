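.marker_category_cols <- function() {
  c(bp = "bp_category", chol = "chol_category",
    glucose = "glucose_category", gfr = "gfr_category")
}

#' Model formula presets for the comorbidity Cox models
#'
#' `"adjusted"`: the four marker categories plus age. `"fully_adjusted"`:
#' additionally sex, marital status, education, employment, income, smoking,
#' drinking, physical activity, BMI category and eating behavior; each
#' marker's coefficients are thereby mutually adjusted for the other chronic
#' conditions in one joint model, which also yields the single per-year age
#' coefficient used to scale the risk points.
#'
#' @param preset `"adjusted"` or `"fully_adjusted"`.
#' @param markers Marker short names to include (subset of
#'   `c("bp", "chol", "glucose", "gfr")`).
#' @return Character vector of model terms.
#' @export
cox_terms <- function(preset = c("adjusted", "fully_adjusted"),
                      markers = c("bp", "chol", "glucose", "gfr")) {
  preset <- match.arg(preset)
  markers <- match.arg(markers, several.ok = TRUE)
  base <- c("age", unname(.marker_category_cols()[markers]))
  if (preset == "adjusted") return(base)
  c(base, "sex", "marital_status", "education", "employment", "income",
    "smoking", "drinking", "physical_activity", "bmi_category",
    "eating_behavior")
}

#' Fit a Cox proportional-hazards model
#'
#' Thin wrapper around [survival::coxph()] (Efron ties correction by
#' default) returning the pieces the risk-point construction needs:
#' coefficients, standard errors from the observed information,
#' log-likelihood and event count.
#'
#' @param data data.frame containing `time_col`, `event_col` and every term.
#' @param terms Character vector of right-hand-side terms, e.g. from
#'   [cox_terms()], or a preset name.
#' @param ties `"efron"` or `"breslow"`.
#' @param time_col,event_col Follow-up time (years, > 0) and event indicator
#'   columns.
#' @return Object of class `cox_fit`: list with `coef`, `se`,
#'   `log_likelihood`, `n_events`, `ties`, `terms` and the underlying
#'   `$model`.
#' @export
fit_cox <- function(data, terms, ties = c("efron", "breslow"),
                    time_col = "followup_years", event_col = "cancer_event") {
  ties <- match.arg(ties)
  if (length(terms) == 1 && terms %in% c("adjusted", "fully_adjusted")) {
    terms <- cox_terms(terms)
  }
  miss <- setdiff(c(terms, time_col, event_col), names(data))
  if (length(miss)) stop("data lacks columns: ", paste(miss, collapse = ", "))
  if (anyNA(data[c(terms, time_col, event_col)])) {
    stop("model covariates must be complete; run apply_exclusions() first")
  }
  if (any(data[[time_col]] <= 0)) stop("follow-up times must be positive")
  if (sum(data[[event_col]]) < 1) stop("need at least one event")
  fml <- stats::reformulate(terms, response = sprintf(
    "survival::Surv(%s, %s)", time_col, event_col
  ))
  fit <- survival::coxph(fml, data = data, ties = ties,
                         model = FALSE, x = FALSE, y = TRUE)
  if (any(is.na(stats::coef(fit)))) {
    bad <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop("Cox fit dropped terms (separation or collinearity): ",
         paste(bad, collapse = ", "))
  }
  structure(
    list(
      coef = stats::coef(fit),
      se = sqrt(diag(stats::vcov(fit))),
      log_likelihood = fit$loglik[length(fit$loglik)],
      n_events = fit$nevent, ties = ties, terms = terms, model = fit
    ),
    class = "cox_fit"
  )
}

#' @export
print.cox_fit <- function(x, ...) {
  cat(sprintf("Cox fit (%s ties): %d events, loglik %.2f\n",
              x$ties, x$n_events, x$log_likelihood))
  hr <- exp(x$coef)
  ci <- exp(cbind(x$coef - 1.96 * x$se, x$coef + 1.96 * x$se))
  print(round(data.frame(coef = x$coef, HR = hr, lo = ci[, 1], hi = ci[, 2]), 3))
  invisible(x)
}

# round half away from zero (round() rounds half to even)
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' @keywords internal
new_risk_point_table <- function(points) {
  stopifnot(is.list(points), length(names(points)) == length(points))
  for (m in names(points)) {
    if (any(points[[m]] != round(points[[m]]))) stop("points must be integers")
  }
  structure(
    list(points = lapply(points, function(p) stats::setNames(as.integer(p), names(p))),
         included_markers = names(points)),
    class = "risk_point_table"
  )
}

#' @export
print.risk_point_table <- function(x, ...) {
  cat("Comorbidity risk points (markers: ",
      paste(x$included_markers, collapse = ", "), ")\n", sep = "")
  for (m in x$included_markers) {
    p <- x$points[[m]]
    cat(sprintf("  %-8s %s\n", m,
                paste(sprintf("%s=%d", names(p), p), collapse = "  ")))
  }
  cat(sprintf("  max attainable score: %d\n", max_score(x)))
  invisible(x)
}

#' Maximum attainable comorbidity score of a point table
#'
#' @param table A `risk_point_table`.
#' @return Integer: sum over markers of the marker's maximum point.
#' @export
max_score <- function(table) {
  sum(vapply(table$points[table$included_markers], max, integer(1)))
}

#' Convert Cox coefficients to integer risk points (Sullivan system)
#'
#' Each comorbidity category's regression coefficient is divided by the
#' coefficient for a one-year increase in age and rounded to the nearest
#' integer (half away from zero). Reference categories get 0. Negative
#' points are retained (with a message), not clamped.
#'
#' @param fit A `cox_fit` whose terms include `age` and the marker category
#'   factors.
#' @param markers Marker short names to convert (default: all four).
#' @return A `risk_point_table`.
#' @export
#' @examples
#' # beta_age = 0.0556; a category with HR 1.32 gets round(log(1.32)/0.0556) = 5
sullivan_points <- function(fit, markers = c("bp", "chol", "glucose", "gfr")) {
  if (!"age" %in% names(fit$coef)) stop("fit must contain an age term")
  beta_age <- fit$coef[["age"]]
  if (beta_age <= 0) {
    stop("age coefficient is not positive; risk points are undefined")
  }
  cols <- .marker_category_cols()
  pts <- list()
  for (m in markers) {
    col <- cols[[m]]
    lv <- .marker_levels()[[m]]
    p <- stats::setNames(integer(length(lv)), lv)
    for (cat in lv[-1]) { # first level is the reference
      term <- paste0(col, cat)
      if (!term %in% names(fit$coef)) {
        stop("fit lacks coefficient for ", term)
      }
      p[[cat]] <- as.integer(round_half_away(fit$coef[[term]] / beta_age))
    }
    if (any(p < 0)) {
      message("negative risk point(s) for ", m, ": ",
              paste(sprintf("%s=%d", names(p)[p < 0], p[p < 0]), collapse = ", "))
    }
    pts[[m]] <- p
  }
  tbl <- new_risk_point_table(pts)
  tbl$beta_age <- beta_age
  tbl
}

.marker_levels <- function() {
  list(
    bp = c("normal", "elevated", "hypertension"),
    chol = c("elevated", "low", "normal"),
    glucose = c("normal", "prediabetes_diabetes"),
    gfr = c("lt60", "b60_89", "ge90")
  )
}

#' Comorbidity risk score of classified subjects
#'
#' Sums the subject's per-marker risk points over the table's included
#' markers (so a cholesterol-excluded table yields the sensitivity score).
#'
#' @param profile data.frame with the marker category columns
#'   (`bp_category`, ...) from [classify_cohort()], or a named list/vector
#'   of single categories.
#' @param table A `risk_point_table`.
#' @return Integer vector of scores.
#' @export
#' @examples
#' comorbidity_score(
#'   list(bp = "hypertension", chol = "normal",
#'        glucose = "prediabetes_diabetes", gfr = "ge90"),
#'   reference_risk_points()
#' ) # 30
comorbidity_score <- function(profile, table) {
  cols <- .marker_category_cols()
  if (!is.data.frame(profile)) {
    profile <- as.data.frame(
      stats::setNames(lapply(table$included_markers,
                             function(m) as.character(profile[[m]])),
                      cols[table$included_markers]),
      stringsAsFactors = FALSE
    )
  }
  total <- integer(nrow(profile))
  for (m in table$included_markers) {
    cat <- as.character(profile[[cols[[m]]]])
    p <- table$points[[m]]
    unknown <- !cat %in% names(p)
    if (any(unknown)) {
      stop("unknown ", m, " category: ", paste(unique(cat[unknown]), collapse = ", "))
    }
    total <- total + p[cat]
  }
  unname(total)
}

#' Stratify comorbidity scores into labelled integer bins
#'
#' Bins are defined by inclusive upper bounds, e.g. `c(8, 10, 15, 30)` gives
#' strata `0-8`, `9-10`, `11-15`, `16-30`. The lowest bin is unbounded
#' below, so a (rare) negative total from negative refit points falls into
#' it; a score above the top bound is a configuration error and fails
#' loudly.
#'
#' @param scores Integer scores.
#' @param cutpoints Strictly increasing inclusive upper bounds covering the
#'   observed range; defaults to the published main-analysis strata.
#' @return Factor of stratum labels (lowest stratum = reference level).
#' @export
#' @examples
#' stratify(c(8, 9, 16))
stratify <- function(scores, cutpoints = default_cutpoints("main")) {
  if (length(scores) == 0) {
    return(factor(character(0), levels = .stratum_labels(cutpoints)))
  }
  if (is.unsorted(cutpoints, strictly = TRUE)) {
    stop("cutpoints must be strictly increasing")
  }
  if (any(scores > max(cutpoints))) {
    stop(sprintf("score %d exceeds the top stratum bound %d: check cutpoints",
                 max(scores), max(cutpoints)))
  }
  labels <- .stratum_labels(cutpoints)
  idx <- findInterval(scores, cutpoints + 0.5) + 1L
  factor(labels[idx], levels = labels)
}

.stratum_labels <- function(cutpoints) {
  lower <- c(0L, utils::head(cutpoints, -1) + 1L)
  sprintf("%d-%d", lower, cutpoints)
}

#' Scan for the per-year age coefficient implied by published points
#'
#' For each candidate age coefficient, converts published category hazard
#' ratios into points via `round(log(HR) / beta_age)` and counts matches
#' with the published integer points. Two-decimal rounding of the printed
#' HRs typically leaves one category ambiguous.
#'
#' @param hr Hazard ratios per category.
#' @param points Published integer points, same length/order.
#' @param beta_range Search interval for the age coefficient.
#' @param step Grid step.
#' @return List with `beta_age` (best match), `n_matched`, `n_categories`,
#'   and the full `grid`.
#' @export
#' @examples
#' ref <- reference_marker_hr()
#' risk_point_consistency(ref$hr, ref$point)$n_matched  # >= 6 of 7
risk_point_consistency <- function(hr, points,
                                   beta_range = c(0.04, 0.07),
                                   step = 1e-4) {
  stopifnot(length(hr) == length(points))
  betas <- seq(beta_range[1], beta_range[2], by = step)
  matched <- vapply(betas, function(b) {
    sum(round_half_away(log(hr) / b) == points)
  }, numeric(1))
  best <- which.max(matched)
  list(
    beta_age = betas[best], n_matched = matched[best],
    n_categories = length(points),
    grid = data.frame(beta_age = betas, n_matched = matched)
  )
}
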