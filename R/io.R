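#' Read and write cohort tables
#'
#' Plain-CSV round trip for the cohort column layout of
#' [generate_cohort()]. Factor columns are restored with their reference
#' levels first so downstream Cox fits keep the intended reference
#' categories.
#'
#' @param cohort Cohort data.frame.
#' @param path File path.
#' @return `read_cohort_csv`: the cohort data.frame.
#' @export
write_cohort_csv <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = c("NA", ""))
  fct <- list(
    sex = c("female", "male"),
    marital_status = c("married", "other"),
    education = c("lt_high_school", "high_school", "college"),
    employment = c("employed", "unemployed"),
    income = c("lt2m", "m2_4m", "ge4m"),
    smoking = c("never", "past", "current"),
    drinking = c("never", "past", "current"),
    physical_activity = c("no", "yes"),
    eating_behavior = c("light", "normal", "heavy"),
    bmi_category = c("lt23", "b23_24.9", "ge25"),
    bp_category = c("normal", "elevated", "hypertension"),
    chol_category = c("elevated", "low", "normal"),
    glucose_category = c("normal", "prediabetes_diabetes"),
    gfr_category = c("lt60", "b60_89", "ge90")
  )
  for (nm in intersect(names(fct), names(x))) {
    x[[nm]] <- factor(x[[nm]], levels = fct[[nm]])
  }
  x
}

#' Write a network as a CSV adjacency matrix
#'
#' Square symmetric layout with food-group labels as row and column names;
#' structural zeros stay 0.
#'
#' @param network A `pcor_network`.
#' @param path File path.
#' @export
write_adjacency_csv <- function(network, path) {
  utils::write.csv(as.data.frame(network$weights), path, row.names = TRUE)
  invisible(path)
}

#' Write a network as GraphML
#'
#' Minimal GraphML with one `weight` attribute per edge (signed partial
#' correlation); nonzero upper-triangle entries become undirected edges.
#'
#' @param network A `pcor_network`.
#' @param path File path.
#' @export
write_graphml <- function(network, path) {
  w <- network$weights
  labels <- network$labels
  esc <- function(s) {
    s <- gsub("&", "&amp;", s, fixed = TRUE)
    s <- gsub("<", "&lt;", s, fixed = TRUE)
    gsub(">", "&gt;", s, fixed = TRUE)
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<graphml xmlns="http://graphml.graphdrawing.org/xmlns">',
    '  <key id="w" for="edge" attr.name="weight" attr.type="double"/>',
    '  <key id="lab" for="node" attr.name="label" attr.type="string"/>',
    '  <graph id="diet" edgedefault="undirected">'
  ), con)
  for (i in seq_along(labels)) {
    writeLines(sprintf('    <node id="n%d"><data key="lab">%s</data></node>',
                       i, esc(labels[i])), con)
  }
  idx <- which(upper.tri(w) & w != 0, arr.ind = TRUE)
  for (k in seq_len(nrow(idx))) {
    writeLines(sprintf(
      '    <edge source="n%d" target="n%d"><data key="w">%g</data></edge>',
      idx[k, 1], idx[k, 2], w[idx[k, 1], idx[k, 2]]
    ), con)
  }
  writeLines(c("  </graph>", "</graphml>"), con)
  invisible(path)
}

#' Write a risk point table as CSV
#'
#' One row per marker category with its integer point.
#'
#' @param table A `risk_point_table`.
#' @param path File path.
#' @export
write_risk_points_csv <- function(table, path) {
  rows <- do.call(rbind, lapply(table$included_markers, function(m) {
    p <- table$points[[m]]
    data.frame(marker = m, category = names(p), point = as.integer(p),
               stringsAsFactors = FALSE)
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}
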