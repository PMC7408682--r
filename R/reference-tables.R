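#' Food groups of the dietary network
#'
#' The 16 food groups used throughout the package, in the canonical order of
#' the reference network. `key` is the syntactic column stem used in cohort
#' tables (intake columns are named `intake_<key>`).
#'
#' @return A data.frame with columns `label` (display name) and `key`
#'   (syntactic identifier).
#' @export
#' @examples
#' food_groups()
food_groups <- function() {
  data.frame(
    label = c(
      "Cereals and grains", "Potatoes and starches", "Sugars and sweets",
      "Legumes", "Seeds and nuts", "Vegetables", "Mushrooms", "Fruits",
      "Meat and poultry", "Eggs", "Fish and shellfish", "Seaweed",
      "Milk and dairy", "Oils and fats", "Beverages", "Seasonings"
    ),
    key = c(
      "cereals_grains", "potatoes_starches", "sugars_sweets", "legumes",
      "seeds_nuts", "vegetables", "mushrooms", "fruits", "meat_poultry",
      "eggs", "fish_shellfish", "seaweed", "milk_dairy", "oils_fats",
      "beverages", "seasonings"
    ),
    stringsAsFactors = FALSE
  )
}

#' @rdname food_groups
#' @export
intake_columns <- function() paste0("intake_", food_groups()$key)

# Upper-triangle edge list of the published regularized partial-correlation
# network of the 16 food groups (g/day scale, EBIC graphical lasso, gamma 0.5).
# Blanks in the published adjacency are structural zeros.
.ref_edges <- function() {
  e <- rbind(
    c("Potatoes and starches", "Sugars and sweets", 0.05),
    c("Potatoes and starches", "Legumes", 0.22),
    c("Cereals and grains", "Seeds and nuts", -0.08),
    c("Potatoes and starches", "Seeds and nuts", 0.05),
    c("Sugars and sweets", "Seeds and nuts", 0.05),
    c("Legumes", "Seeds and nuts", 0.08),
    c("Cereals and grains", "Vegetables", 0.08),
    c("Cereals and grains", "Mushrooms", -0.05),
    c("Sugars and sweets", "Mushrooms", -0.12),
    c("Legumes", "Mushrooms", 0.07),
    c("Seeds and nuts", "Mushrooms", 0.12),
    c("Vegetables", "Mushrooms", 0.18),
    c("Cereals and grains", "Fruits", -0.07),
    c("Sugars and sweets", "Fruits", 0.04),
    c("Legumes", "Fruits", -0.08),
    c("Seeds and nuts", "Fruits", 0.08),
    c("Vegetables", "Fruits", 0.08),
    c("Cereals and grains", "Meat and poultry", 0.11),
    c("Potatoes and starches", "Meat and poultry", -0.05),
    c("Legumes", "Meat and poultry", -0.04),
    c("Vegetables", "Meat and poultry", -0.07),
    c("Mushrooms", "Meat and poultry", 0.05),
    c("Fruits", "Meat and poultry", 0.15),
    c("Legumes", "Eggs", -0.07),
    c("Seeds and nuts", "Eggs", 0.09),
    c("Fruits", "Eggs", 0.06),
    c("Meat and poultry", "Eggs", 0.17),
    c("Potatoes and starches", "Fish and shellfish", 0.08),
    c("Legumes", "Fish and shellfish", 0.09),
    c("Seeds and nuts", "Fish and shellfish", 0.06),
    c("Vegetables", "Fish and shellfish", 0.10),
    c("Mushrooms", "Fish and shellfish", 0.15),
    c("Meat and poultry", "Fish and shellfish", 0.23),
    c("Potatoes and starches", "Seaweed", 0.04),
    c("Legumes", "Seaweed", 0.10),
    c("Vegetables", "Seaweed", 0.23),
    c("Mushrooms", "Seaweed", 0.07),
    c("Fruits", "Seaweed", 0.06),
    c("Meat and poultry", "Seaweed", -0.06),
    c("Fish and shellfish", "Seaweed", 0.19),
    c("Cereals and grains", "Milk and dairy", -0.09),
    c("Sugars and sweets", "Milk and dairy", 0.05),
    c("Seeds and nuts", "Milk and dairy", 0.07),
    c("Fruits", "Milk and dairy", 0.18),
    c("Eggs", "Milk and dairy", 0.12),
    c("Cereals and grains", "Oils and fats", 0.07),
    c("Sugars and sweets", "Oils and fats", 0.70),
    c("Seeds and nuts", "Oils and fats", -0.05),
    c("Mushrooms", "Oils and fats", 0.12),
    c("Fruits", "Oils and fats", -0.08),
    c("Meat and poultry", "Oils and fats", 0.20),
    c("Eggs", "Oils and fats", 0.08),
    c("Seaweed", "Oils and fats", -0.05),
    c("Milk and dairy", "Oils and fats", -0.04),
    c("Sugars and sweets", "Beverages", 0.08),
    c("Mushrooms", "Beverages", 0.05),
    c("Fruits", "Beverages", 0.08),
    c("Meat and poultry", "Beverages", 0.10),
    c("Fish and shellfish", "Beverages", 0.10),
    c("Milk and dairy", "Beverages", 0.08),
    c("Potatoes and starches", "Seasonings", 0.37),
    c("Legumes", "Seasonings", 0.23),
    c("Seeds and nuts", "Seasonings", 0.06),
    c("Vegetables", "Seasonings", 0.34),
    c("Fruits", "Seasonings", 0.19),
    c("Meat and poultry", "Seasonings", 0.07),
    c("Eggs", "Seasonings", 0.04),
    c("Fish and shellfish", "Seasonings", 0.11),
    c("Oils and fats", "Seasonings", 0.05)
  )
  data.frame(
    from = e[, 1], to = e[, 2], weight = as.numeric(e[, 3]),
    stringsAsFactors = FALSE
  )
}

#' Reference food-group partial-correlation network
#'
#' The published regularized partial-correlation matrix of the 16 food groups
#' from the motivating Korean cancer-screenee cohort analysis (EBIC graphical
#' lasso, gamma = 0.5; entries shrunk to zero by the penalty are exact zeros).
#' This matrix is the default latent network of the synthetic-cohort
#' generator and the input of the reference centrality computation.
#'
#' @return A `pcor_network` object (see [estimate_ggm()]) with the 16 x 16
#'   symmetric matrix in `$weights`.
#' @export
#' @examples
#' net <- reference_network()
#' max(abs(net$weights))  # 0.70, oils and fats ~ sugars and sweets
reference_network <- function() {
  labels <- food_groups()$label
  w <- matrix(0, 16, 16, dimnames = list(labels, labels))
  e <- .ref_edges()
  for (k in seq_len(nrow(e))) {
    w[e$from[k], e$to[k]] <- e$weight[k]
    w[e$to[k], e$from[k]] <- e$weight[k]
  }
  new_pcor_network(w, labels,
    selected_penalty = NA_real_, ebic_gamma = 0.5,
    ebic_value = NA_real_, n_samples = NA_integer_
  )
}

#' Reference intake marginals of the 16 food groups
#'
#' Published mean and standard deviation of daily intake (g/day) per food
#' group in the motivating screenee cohort; used to calibrate the log-normal
#' intake marginals of the synthetic-cohort generator.
#'
#' @return data.frame with columns `label`, `key`, `mean`, `sd` (g/day).
#' @export
reference_intake_marginals <- function() {
  fg <- food_groups()
  data.frame(
    label = fg$label, key = fg$key,
    mean = c(582.77, 44.49, 5.02, 59.84, 5.52, 312.12, 9.05, 220.65,
             58.62, 17.33, 39.99, 2.25, 108.63, 3.83, 75.15, 17.42),
    sd = c(213.71, 43.74, 5.24, 67.42, 9.98, 204.07, 13.48, 255.47,
           51.63, 18.04, 34.98, 2.37, 137.91, 3.81, 110.42, 14.80),
    stringsAsFactors = FALSE
  )
}

#' Published eigenvector centralities of the 16 food groups
#'
#' The max-normalized node weights reported for the reference network;
#' kept for comparison with [eigenvector_centrality()] output.
#'
#' @return Named numeric vector, one entry per food group.
#' @export
reference_centralities <- function() {
  stats::setNames(
    c(0.09, 0.68, 0.51, 0.59, 0.32, 0.76, 0.50, 0.27, 0.48, 0.30,
      0.70, 0.45, 0.13, 0.61, 0.25, 1.00),
    food_groups()$label
  )
}

#' Reference comorbidity risk points
#'
#' Published integer risk points per comorbidity category: the main point
#' table (all four markers), the cholesterol-excluded sensitivity table, and
#' the table refit with early cancer cases included. Reference categories
#' carry 0 points.
#'
#' @param variant One of `"main"`, `"no_cholesterol"`, `"include_early"`.
#' @return A `risk_point_table` (see [sullivan_points()]).
#' @export
#' @examples
#' max_score(reference_risk_points())                    # 30
#' max_score(reference_risk_points("no_cholesterol"))    # 23
reference_risk_points <- function(variant = c("main", "no_cholesterol",
                                              "include_early")) {
  variant <- match.arg(variant)
  pts <- switch(variant,
    main = list(
      bp = c(normal = 0, elevated = 2, hypertension = 8),
      chol = c(elevated = 0, low = 5, normal = 8),
      glucose = c(normal = 0, prediabetes_diabetes = 5),
      gfr = c(lt60 = 0, b60_89 = 2, ge90 = 9)
    ),
    no_cholesterol = list(
      bp = c(normal = 0, elevated = 2, hypertension = 8),
      glucose = c(normal = 0, prediabetes_diabetes = 5),
      gfr = c(lt60 = 0, b60_89 = 2, ge90 = 10)
    ),
    include_early = list(
      bp = c(normal = 0, elevated = 1, hypertension = 7),
      chol = c(elevated = 0, low = 5, normal = 6),
      glucose = c(normal = 0, prediabetes_diabetes = 2),
      gfr = c(lt60 = 0, b60_89 = 2, ge90 = 9)
    )
  )
  new_risk_point_table(pts)
}

#' Published fully adjusted hazard ratios per comorbidity category
#'
#' Hazard ratios (with 95% CI bounds) from the fully adjusted Cox model of
#' the motivating cohort, one row per non-reference comorbidity category,
#' together with the published integer risk point. Used by
#' [risk_point_consistency()] to locate the per-year age coefficient
#' implied by the published point table.
#'
#' @return data.frame with columns `marker`, `category`, `hr`, `lo`, `hi`,
#'   `point`.
#' @export
reference_marker_hr <- function() {
  data.frame(
    marker = c("bp", "bp", "chol", "chol", "glucose", "gfr", "gfr"),
    category = c("elevated", "hypertension", "low", "normal",
                 "prediabetes_diabetes", "b60_89", "ge90"),
    hr = c(1.12, 1.56, 1.31, 1.51, 1.32, 1.11, 1.65),
    lo = c(0.74, 1.02, 0.91, 1.03, 0.87, 0.62, 0.80),
    hi = c(1.70, 2.39, 1.88, 2.19, 2.00, 2.02, 3.43),
    point = c(2, 8, 5, 8, 5, 2, 9),
    stringsAsFactors = FALSE
  )
}

#' Default stratum cutpoints for the comorbidity risk score
#'
#' Upper bounds (inclusive) of the published score strata for each analysis
#' variant; [stratify()] turns them into labelled integer bins.
#'
#' @param variant One of `"main"`, `"no_cholesterol"`, `"include_early"`.
#' @return Integer vector of inclusive upper bounds.
#' @export
default_cutpoints <- function(variant = c("main", "no_cholesterol",
                                          "include_early")) {
  switch(match.arg(variant),
    main = c(8L, 10L, 15L, 30L),
    no_cholesterol = c(2L, 8L, 10L, 23L),
    include_early = c(4L, 8L, 10L, 24L)
  )
}
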