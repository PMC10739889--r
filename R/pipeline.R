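#' Run the full zygote polarity analysis
#'
#' Chains every stage: normalized-profile extraction, feature-matrix
#' assembly, unsupervised compartmentalization (boundary location, feature
#' groups, compositions), supervised random-forest classification of the
#' apical/basal regions with Gini importance aggregated per structure, and
#' division-plane measurement against the compartment boundary.
#'
#' @param x A `zp_dataset` or a manifest path.
#' @param L Standard profile length (default 110).
#' @param k Normalized time points (default 10).
#' @param n_trees,m_try Random-forest parameters (defaults 500, 10).
#' @param seed Random-forest seed (default 20231218).
#' @return A `zp_analysis` list: `profiles`, `compartment`
#'   (`zp_compartment`), `classification` (`zp_classification`),
#'   `division_planes` (tibble), `division_summary`
#'   (from [boundary_vs_plane()], `NULL` when no planes are annotated).
#' @export
run_pipeline <- function(x, L = 110, k = 10, n_trees = 500, m_try = 10,
                         seed = 20231218) {
  if (is.character(x)) x <- read_dataset(x)
  profiles <- extract_profiles(x, L = L, k = k)
  compartment <- compartmentalize(profiles)
  labels <- tidy(compartment)$region
  classification <- classify_regions(compartment$feature_matrix, labels,
                                     n_trees = n_trees, m_try = m_try,
                                     seed = seed)
  planes <- measure_division_planes(x)
  division_summary <- if (nrow(planes) > 0) {
    boundary_vs_plane(compartment$boundary$boundary_pct, planes$pct_from_tip)
  }
  structure(
    list(profiles = profiles, compartment = compartment,
         classification = classification, division_planes = planes,
         division_summary = division_summary),
    class = "zp_analysis"
  )
}

#' @export
print.zp_analysis <- function(x, ...) {
  cat("<zp_analysis>\n")
  print(x$compartment)
  cat(sprintf("  random forest OOB error: %.1f%%\n",
              x$classification$oob_error_pct))
  if (!is.null(x$division_summary)) {
    s <- x$division_summary
    cat(sprintf(
      "  division plane: %.1f%% +/- %.2f%% from tip (n = %d); half-boundary %.1f%%, delta %.1f\n",
      s$mean, s$sd, s$n, s$half_boundary, s$delta))
  }
  invisible(x)
}

#' Write the analysis report as CSV tables and a JSON summary
#'
#' Emits `profiles.csv` (long format), `feature_matrix.csv` (positions x
#' features with metadata header columns), `importance.csv`,
#' `importance_by_structure.csv`, `composition_by_probe.csv`,
#' `composition_by_timepoint.csv`, `division_planes.csv`, and
#' `report.json` (boundary, OOB error, confusion, parameters).
#'
#' @param analysis A `zp_analysis`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(analysis, dir) {
  stopifnot(inherits(analysis, "zp_analysis"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wcsv <- function(d, name) {
    write.csv(d, file.path(dir, name), row.names = FALSE)
  }
  wcsv(analysis$profiles, "profiles.csv")
  fm <- analysis$compartment$feature_matrix
  wcsv(cbind(position = seq_len(nrow(fm$values)), as.data.frame(fm$values)),
       "feature_matrix.csv")
  wcsv(analysis$classification$importance, "importance.csv")
  wcsv(analysis$classification$importance_by_structure,
       "importance_by_structure.csv")
  wcsv(analysis$compartment$composition$by_probe, "composition_by_probe.csv")
  wcsv(analysis$compartment$composition$by_timepoint,
       "composition_by_timepoint.csv")
  if (nrow(analysis$division_planes) > 0) {
    wcsv(analysis$division_planes, "division_planes.csv")
  }
  b <- analysis$compartment$boundary
  report <- list(
    boundary_index = b$boundary_index,
    boundary_pct = round(b$boundary_pct, 1),
    contiguity_violations = b$contiguity_violations,
    position_labels = analysis$compartment$position_labels,
    feature_groups = analysis$compartment$feature_groups,
    oob_error_pct = analysis$classification$oob_error_pct,
    confusion = analysis$classification$confusion,
    rf_params = analysis$classification$rf_params,
    division_summary = analysis$division_summary
  )
  jsonlite::write_json(report, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, matrix = "rowmajor")
  invisible(dir)
}
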