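#' Run the full analysis on one cohort
#'
#' The core pipeline behind [run_pipeline()] and [sensitivity_suite()]:
#' exclusion cascade -> marker classification -> dietary network (EBIC
#' graphical lasso) -> centrality weights -> dietary scores and tertile
#' eating behavior -> joint comorbidity Cox model -> Sullivan risk points ->
#' comorbidity scores and strata -> Kaplan-Meier curves, stratum hazard
#' ratios and mean-score trend tests for all / male / female.
#'
#' @param cohort Raw cohort data.frame (see [generate_cohort()] for the
#'   column layout).
#' @param latency_years Early-case exclusion window (0 keeps early cases).
#' @param markers Markers contributing to the risk score (the cholesterol-
#'   excluded sensitivity analysis passes `c("bp", "glucose", "gfr")`).
#' @param cutpoints Inclusive upper bounds of the score strata.
#' @param ebic_gamma EBIC gamma for network selection.
#' @param n_penalties Size of the graphical-lasso penalty grid.
#' @param log_intake Estimate the network on log-transformed intakes
#'   (default TRUE; intakes are strongly right-skewed and the graphical
#'   model assumes joint normality).
#' @param centrality_weights `"signed"` or `"absolute"` edge weights for the
#'   centrality computation.
#' @param models Association covariate presets to run.
#' @param subgroups Subgroups to run.
#' @param ties Ties method for all Cox fits.
#' @return List of class `cohort_analysis` with components `exclusions`,
#'   `network`, `centrality`, `cox_fit`, `risk_points`, `cohort` (analysis
#'   rows with `dietary_score`, `eating_behavior`, `score`, `stratum`),
#'   `km`, `associations` (one `association_result` per model x subgroup)
#'   and `settings`.
#' @export
analyze_cohort <- function(cohort,
                           latency_years = 1,
                           markers = c("bp", "chol", "glucose", "gfr"),
                           cutpoints = default_cutpoints("main"),
                           ebic_gamma = 0.5,
                           n_penalties = 100,
                           log_intake = TRUE,
                           centrality_weights = c("signed", "absolute"),
                           models = c("crude", "adjusted", "fully_adjusted"),
                           subgroups = c("all", "male", "female"),
                           ties = "efron") {
  centrality_weights <- match.arg(centrality_weights)
  excl <- apply_exclusions(cohort, latency_years = latency_years)
  dat <- classify_cohort(excl$cohort)
  if (nrow(dat) == 0) stop("no subjects left after exclusions")

  fg <- food_groups()
  icols <- intake_columns()
  x <- as.matrix(dat[icols])
  colnames(x) <- fg$label
  net <- estimate_ggm(if (log_intake) log(x + 1e-8) else x, gamma = ebic_gamma,
                      n_penalties = n_penalties)
  cw <- eigenvector_centrality(net, weights = centrality_weights)
  dat$dietary_score <- dietary_score(x, cw)
  dat$eating_behavior <- tertile_classes(dat$dietary_score)

  fit <- fit_cox(dat, cox_terms("fully_adjusted", markers), ties = ties)
  points <- sullivan_points(fit, markers)
  dat$score <- comorbidity_score(dat, points)
  if (max(dat$score) > max(cutpoints)) {
    warning(sprintf(
      "refit points give scores up to %d; widening the top stratum bound from %d",
      max(dat$score), max(cutpoints)
    ))
    cutpoints[length(cutpoints)] <- max(dat$score)
  }
  dat$stratum <- stratify(dat$score, cutpoints)

  km <- kaplan_meier(dat$followup_years, dat$cancer_event, dat$stratum)
  assoc <- list()
  for (sg in subgroups) {
    for (md in models) {
      assoc[[paste(md, sg, sep = ".")]] <- association(dat, md, sg, ties = ties)
    }
  }
  structure(
    list(
      exclusions = excl$report, network = net, centrality = cw,
      cox_fit = fit, risk_points = points, cohort = dat, km = km,
      associations = assoc,
      settings = list(
        latency_years = latency_years, markers = markers,
        cutpoints = cutpoints, ebic_gamma = ebic_gamma,
        n_penalties = n_penalties, log_intake = log_intake,
        centrality_weights = centrality_weights, ties = ties
      )
    ),
    class = "cohort_analysis"
  )
}

#' @export
print.cohort_analysis <- function(x, ...) {
  print(x$exclusions)
  print(x$network)
  print(x$risk_points)
  main <- x$associations[["fully_adjusted.all"]]
  if (!is.null(main)) print(main)
  invisible(x)
}

#' Sensitivity analyses: cholesterol-excluded score and early cases kept
#'
#' Reruns the full pipeline twice: (i) with total cholesterol dropped from
#' the risk score (points refit from the three-marker joint model,
#' cholesterol-variant strata); (ii) with `latency_years = 0` so subjects
#' diagnosed within the first year stay in (early-case-variant strata,
#' points refit).
#'
#' @param cohort Raw cohort data.frame.
#' @param cutpoints_no_chol,cutpoints_include_early Stratum bounds per
#'   variant.
#' @param ... Passed to [analyze_cohort()].
#' @return Named list of two `cohort_analysis` objects
#'   (`no_cholesterol`, `include_early`).
#' @export
sensitivity_suite <- function(cohort,
                              cutpoints_no_chol = default_cutpoints("no_cholesterol"),
                              cutpoints_include_early = default_cutpoints("include_early"),
                              ...) {
  list(
    no_cholesterol = analyze_cohort(
      cohort, markers = c("bp", "glucose", "gfr"),
      cutpoints = cutpoints_no_chol, ...
    ),
    include_early = analyze_cohort(
      cohort, latency_years = 0,
      cutpoints = cutpoints_include_early, ...
    )
  )
}

#' Pipeline run configuration
#'
#' A serializable bundle of every pipeline setting. Round-trips through JSON
#' via [jsonlite::toJSON()] / [run_config_from_json()].
#'
#' @param seed Integer seed (also the simulation seed).
#' @param n_subjects Cohort size when simulating.
#' @param input_csv Optional path to a cohort CSV; when NULL a cohort is
#'   simulated with the default [simulation_config()].
#' @param ebic_gamma,n_penalties,latency_years,log_intake,centrality_weights,ties
#'   Pipeline settings, see [analyze_cohort()].
#' @param cutpoints Named list of stratum bounds per variant.
#' @param markers Markers in the main score.
#' @param run_sensitivity Run the two sensitivity variants.
#' @param out_dir Optional directory for artifacts.
#' @return List of class `run_config`.
#' @export
run_config <- function(seed = 1, n_subjects = 5606, input_csv = NULL,
                       ebic_gamma = 0.5, n_penalties = 100,
                       latency_years = 1, log_intake = TRUE,
                       centrality_weights = "signed", ties = "efron",
                       cutpoints = list(
                         main = default_cutpoints("main"),
                         no_cholesterol = default_cutpoints("no_cholesterol"),
                         include_early = default_cutpoints("include_early")
                       ),
                       markers = c("bp", "chol", "glucose", "gfr"),
                       run_sensitivity = TRUE, out_dir = NULL) {
  structure(
    list(
      seed = as.integer(seed), n_subjects = as.integer(n_subjects),
      input_csv = input_csv, ebic_gamma = ebic_gamma,
      n_penalties = as.integer(n_penalties),
      latency_years = latency_years, log_intake = log_intake,
      centrality_weights = centrality_weights, ties = ties,
      cutpoints = cutpoints, markers = markers,
      run_sensitivity = run_sensitivity, out_dir = out_dir
    ),
    class = "run_config"
  )
}

#' @rdname run_config
#' @param path JSON file written by [write_run_config()].
#' @export
run_config_from_json <- function(path) {
  x <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  cfg <- run_config()
  for (nm in names(x)) {
    cfg[[nm]] <- if (nm == "cutpoints") lapply(x[[nm]], as.integer) else x[[nm]]
  }
  cfg$seed <- as.integer(cfg$seed)
  cfg$n_subjects <- as.integer(cfg$n_subjects)
  cfg
}

#' @rdname run_config
#' @param config A `run_config`.
#' @export
write_run_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Run the whole pipeline end to end
#'
#' Simulates (or loads) a cohort, runs [analyze_cohort()] for the main
#' analysis and optionally [sensitivity_suite()], persists every
#' intermediate artifact when `out_dir` is set, and returns a deterministic
#' run report (identical config + seed gives an identical report).
#'
#' @param config A [run_config()].
#' @return List of class `run_report`: `config` (settings echoed back),
#'   `exclusions`, `n_markers`, `n_food_groups`, `selected_penalty`,
#'   `ebic`, `centrality`, `risk_points`, `beta_age`, `n_strata`,
#'   `associations` (per model x subgroup, with p-trend), `km_medians`,
#'   `sensitivity` (same shape per variant), plus `analysis` (the full
#'   `cohort_analysis`, not serialized).
#' @export
run_pipeline <- function(config = run_config()) {
  cohort <- if (is.null(config$input_csv)) {
    generate_cohort(simulation_config(
      n_subjects = config$n_subjects, seed = config$seed
    ))
  } else {
    read_cohort_csv(config$input_csv)
  }
  main <- analyze_cohort(
    cohort, latency_years = config$latency_years, markers = config$markers,
    cutpoints = config$cutpoints$main, ebic_gamma = config$ebic_gamma,
    n_penalties = config$n_penalties, log_intake = config$log_intake,
    centrality_weights = config$centrality_weights, ties = config$ties
  )
  sens <- NULL
  if (isTRUE(config$run_sensitivity)) {
    sens <- sensitivity_suite(
      cohort,
      cutpoints_no_chol = config$cutpoints$no_cholesterol,
      cutpoints_include_early = config$cutpoints$include_early,
      ebic_gamma = config$ebic_gamma, n_penalties = config$n_penalties,
      log_intake = config$log_intake,
      centrality_weights = config$centrality_weights, ties = config$ties
    )
  }
  report <- structure(
    list(
      config = unclass(config)[setdiff(names(config), "out_dir")],
      exclusions = unclass(main$exclusions),
      n_markers = length(config$markers),
      n_food_groups = length(main$centrality$weight),
      selected_penalty = main$network$selected_penalty,
      ebic = main$network$ebic_value,
      centrality = as.list(round(main$centrality$weight, 6)),
      risk_points = lapply(main$risk_points$points, as.list),
      beta_age = unname(main$cox_fit$coef[["age"]]),
      n_strata = nlevels(main$cohort$stratum),
      associations = lapply(main$associations, .serialize_association),
      km_medians = as.list(main$km$medians),
      sensitivity = if (is.null(sens)) NULL else lapply(sens, function(a) {
        list(
          risk_points = lapply(a$risk_points$points, as.list),
          max_score = max_score(a$risk_points),
          n_final = a$exclusions$n_final,
          associations = lapply(a$associations, .serialize_association)
        )
      }),
      analysis = main
    ),
    class = "run_report"
  )
  if (!is.null(config$out_dir)) .persist_artifacts(report, sens, config$out_dir)
  report
}

.serialize_association <- function(a) {
  list(model = a$model, subgroup = a$subgroup, p_trend = a$p_trend,
       table = a$table)
}

#' @export
print.run_report <- function(x, ...) {
  cat("Pipeline run report\n===================\n")
  print(x$analysis)
  if (!is.null(x$sensitivity)) {
    cat(sprintf("Sensitivity variants run: %s\n",
                paste(names(x$sensitivity), collapse = ", ")))
  }
  invisible(x)
}

.persist_artifacts <- function(report, sens, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  a <- report$analysis
  write_cohort_csv(a$cohort, file.path(out_dir, "analysis_cohort.csv"))
  write_adjacency_csv(a$network, file.path(out_dir, "network_adjacency.csv"))
  write_graphml(a$network, file.path(out_dir, "network.graphml"))
  utils::write.csv(
    data.frame(label = a$centrality$labels, weight = a$centrality$weight),
    file.path(out_dir, "centrality_weights.csv"), row.names = FALSE
  )
  write_risk_points_csv(a$risk_points, file.path(out_dir, "risk_points.csv"))
  utils::write.csv(a$km$curves, file.path(out_dir, "km_curves.csv"),
                   row.names = FALSE)
  for (nm in names(a$associations)) {
    utils::write.csv(a$associations[[nm]]$table,
                     file.path(out_dir, sprintf("association_%s.csv", nm)),
                     row.names = FALSE)
  }
  ser <- report[setdiff(names(report), "analysis")]
  jsonlite::write_json(ser, file.path(out_dir, "run_report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = 10,
                       null = "null", force = TRUE)
  invisible(out_dir)
}
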