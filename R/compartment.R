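#' Assemble normalized profiles into a position-by-feature matrix
#'
#' Each (probe, replicate, timepoint) profile becomes one feature column;
#' rows are axial positions (row 1 = tip).  Columns are ordered by probe
#' (declared order), then replicate, then timepoint.  Columns are re-z-scored
#' (mean 0, population sd 1) before clustering; this is idempotent on
#' already-normalized profiles.  The full zygote design (4 probes x 10 time
#' points x 3 replicates of 110-point profiles) yields a 110 x 120 matrix.
#'
#' @param profiles Long tibble from [extract_profiles()] with columns
#'   `probe`, `replicate_id`, `timepoint`, `position`, `intensity`.
#' @param probe_order Declared probe ordering; defaults to the order of
#'   appearance (with [zygote_probes] members first).
#' @return A `zp_feature_matrix`: list with `values` (L x F numeric matrix)
#'   and `features` (tibble: `column`, `probe`, `replicate_id`, `timepoint`).
#' @export
assemble_feature_matrix <- function(profiles, probe_order = NULL) {
  needed <- c("probe", "replicate_id", "timepoint", "position", "intensity")
  if (!all(needed %in% names(profiles))) {
    abort(paste0("`profiles` must have columns: ",
                 paste(needed, collapse = ", ")),
          class = "zp_parameter_error")
  }
  if (is.null(probe_order)) {
    seen <- unique(profiles$probe)
    probe_order <- c(intersect(zygote_probes, seen),
                     setdiff(seen, zygote_probes))
  }
  meta <- unique(profiles[, c("probe", "replicate_id", "timepoint")])
  if (anyDuplicated(profiles[, c("probe", "replicate_id", "timepoint",
                                 "position")])) {
    abort("duplicate (probe, timepoint, replicate) profile detected",
          class = "zp_parameter_error")
  }
  counts <- count(profiles, .data$probe, .data$replicate_id, .data$timepoint)
  L <- unique(counts$n)
  if (length(L) != 1) {
    abort("all profiles must have the same standard length L",
          class = "zp_parameter_error")
  }
  # grid completeness: every probe x replicate x timepoint cell present
  reps <- sort(unique(meta$replicate_id))
  tps <- sort(unique(meta$timepoint))
  full <- expand.grid(probe = probe_order, replicate_id = reps,
                      timepoint = tps, stringsAsFactors = FALSE)
  key <- function(d) paste(d$probe, d$replicate_id, d$timepoint, sep = "\r")
  missing <- setdiff(key(full), key(meta))
  if (length(missing) > 0) {
    abort(c("incomplete profile grid; missing (probe, replicate, timepoint):",
            setNames(gsub("\r", " / ", missing), rep("x", length(missing)))),
          class = "zp_parameter_error")
  }
  features <- as_tibble(full[order(match(full$probe, probe_order),
                                   full$replicate_id, full$timepoint), ])
  features$column <- seq_len(nrow(features))
  features <- features[, c("column", "probe", "replicate_id", "timepoint")]
  values <- matrix(NA_real_, L, nrow(features))
  prof_split <- split(profiles, key(profiles))
  for (j in seq_len(nrow(features))) {
    p <- prof_split[[paste(features$probe[j], features$replicate_id[j],
                           features$timepoint[j], sep = "\r")]]
    values[, j] <- zscore_values(p$intensity[order(p$position)],
                                 what = "feature column")
  }
  colnames(values) <- sprintf("%s_%s_T%d", features$probe,
                              features$replicate_id, features$timepoint)
  structure(list(values = values, features = features),
            class = "zp_feature_matrix")
}

#' @export
print.zp_feature_matrix <- function(x, ...) {
  cat(sprintf("<zp_feature_matrix> %d positions x %d features (%d probes)\n",
              nrow(x$values), ncol(x$values),
              length(unique(x$features$probe))))
  invisible(x)
}

check_finite_matrix <- function(m) {
  if (!all(is.finite(m))) {
    abort("feature matrix contains non-finite entries",
          class = "zp_parameter_error")
  }
}

#' Cluster axial positions by Ward (ward.D2) hierarchical clustering
#'
#' Rows of the feature matrix (axial positions) are clustered with Euclidean
#' distance and Ward's minimum-variance linkage in the variant that squares
#' dissimilarities internally (`ward.D2`), then cut into `k_clusters`.
#'
#' @param fm A `zp_feature_matrix`.
#' @param k_clusters Number of clusters to cut (default 2).
#' @return List with `labels` (integer per position, by [stats::cutree()]
#'   numbering) and `linkage` (the `hclust` tree).
#' @export
cluster_positions <- function(fm, k_clusters = 2) {
  stopifnot(inherits(fm, "zp_feature_matrix"))
  k_clusters <- check_scalar_count(k_clusters, "k_clusters", min = 1L)
  check_finite_matrix(fm$values)
  if (nrow(fm$values) < k_clusters) {
    abort("fewer positions than clusters", class = "zp_parameter_error")
  }
  hc <- hclust(dist(fm$values, method = "euclidean"), method = "ward.D2")
  list(labels = unname(cutree(hc, k = k_clusters)), linkage = hc)
}

#' Cluster feature columns into Group 1 (basal-high) and Group 2 (apical-high)
#'
#' Columns of the feature matrix are clustered as in [cluster_positions()].
#' For `k_groups = 2` the groups are named by where their profiles peak:
#' the group with the larger mean value over basal-cluster positions is
#' "Group 1", the other "Group 2".
#'
#' @param fm A `zp_feature_matrix`.
#' @param k_groups Number of feature groups (default 2).
#' @param position_labels Optional position cluster labels used to orient the
#'   group naming; when `NULL`, groups keep `cutree` numbering.
#' @return List with `groups` (integer per column: 1 = basal-high),
#'   `linkage` (the `hclust` tree).
#' @export
cluster_features <- function(fm, k_groups = 2, position_labels = NULL) {
  stopifnot(inherits(fm, "zp_feature_matrix"))
  k_groups <- check_scalar_count(k_groups, "k_groups", min = 1L)
  check_finite_matrix(fm$values)
  if (ncol(fm$values) < k_groups) {
    abort("fewer items than groups: cannot cut feature tree",
          class = "zp_parameter_error")
  }
  hc <- hclust(dist(t(fm$values), method = "euclidean"), method = "ward.D2")
  g <- unname(cutree(hc, k = k_groups))
  if (!is.null(position_labels) && k_groups == 2) {
    apical_label <- position_labels[1]
    basal_rows <- which(position_labels != apical_label)
    if (length(basal_rows) > 0) {
      basal_mean <- vapply(1:2, function(gi) {
        mean(fm$values[basal_rows, g == gi, drop = FALSE])
      }, numeric(1))
      if (basal_mean[2] > basal_mean[1]) g <- 3L - g  # swap so 1 = basal-high
    }
  }
  list(groups = g, linkage = hc)
}

#' Locate the apical/basal boundary from ordered position labels
#'
#' Positions are ordered tip to base.  The boundary is the two-segment split
#' `[1..s | s+1..L]` minimizing the number of positions whose cluster label
#' disagrees with the segment assignment, ties broken toward the smaller
#' `s`.  When the labels are contiguous this reduces to the obvious split;
#' otherwise the residual disagreement count is reported.
#'
#' @param position_labels Vector with exactly two distinct values, ordered
#'   tip to base.
#' @return List: `boundary_index` (count `s` of tip-side positions),
#'   `boundary_pct` (`100 * s / L`, percent from tip),
#'   `contiguity_violations`, and `apical_label` (the tip-segment label).
#' @export
locate_boundary <- function(position_labels) {
  lab <- position_labels
  L <- length(lab)
  u <- unique(lab)
  if (length(u) != 2) {
    abort("position labels must contain exactly two distinct values",
          class = "zp_parameter_error")
  }
  a <- u[1]
  is_a <- lab == a
  cum_a <- cumsum(is_a)
  total_a <- cum_a[L]
  s <- seq_len(L - 1)
  # apical = a: violations = non-a in [1..s] + a in (s..L]
  viol_a_first <- (s - cum_a[s]) + (total_a - cum_a[s])
  # apical = b (the other label)
  viol_b_first <- cum_a[s] + ((L - total_a) - (s - cum_a[s]))
  viol <- pmin(viol_a_first, viol_b_first)
  best <- min(viol)
  s_star <- which(viol == best)[1]
  apical_label <- if (viol_a_first[s_star] <= viol_b_first[s_star]) a else u[2]
  list(boundary_index = as.integer(s_star),
       boundary_pct = 100 * s_star / L,
       contiguity_violations = as.integer(best),
       apical_label = apical_label)
}

#' Composition of feature groups by probe and by time point
#'
#' @param feature_groups Integer group id per feature column.
#' @param features Feature metadata tibble (`probe`, `timepoint`, ...).
#' @return List of two tibbles, `by_probe` and `by_timepoint`, with counts
#'   and within-group fractions (fractions per group sum to 1).
#' @export
group_composition <- function(feature_groups, features) {
  stopifnot(length(feature_groups) == nrow(features))
  d <- mutate(features, group = feature_groups)
  comp <- function(var) {
    out <- count(d, .data$group, .data[[var]], name = "n")
    out <- mutate(group_by(out, .data$group), fraction = n / sum(n))
    ungroup(out)
  }
  list(by_probe = comp("probe"), by_timepoint = comp("timepoint"))
}

#' Compartmentalize the zygote from normalized profiles
#'
#' End-to-end unsupervised analysis: assembles the feature matrix, clusters
#' positions (two clusters: apical, basal), locates the boundary as a
#' percentage of cell length from the tip, clusters features into
#' basal-high/apical-high groups and computes group compositions.
#'
#' @param profiles Long profile tibble from [extract_profiles()].
#' @param k_clusters Number of position clusters (default 2).
#' @param probe_order Optional declared probe order.
#' @return A `zp_compartment` object; see [tidy.zp_compartment()] and
#'   [glance.zp_compartment()].
#' @export
compartmentalize <- function(profiles, k_clusters = 2, probe_order = NULL) {
  fm <- assemble_feature_matrix(profiles, probe_order = probe_order)
  pos <- cluster_positions(fm, k_clusters = k_clusters)
  bnd <- if (k_clusters == 2) locate_boundary(pos$labels) else NULL
  feat <- cluster_features(fm, k_groups = 2, position_labels = pos$labels)
  comp <- group_composition(feat$groups, fm$features)
  structure(
    list(feature_matrix = fm, position_labels = pos$labels,
         position_linkage = pos$linkage, boundary = bnd,
         feature_groups = feat$groups, feature_linkage = feat$linkage,
         composition = comp),
    class = "zp_compartment"
  )
}

#' @export
print.zp_compartment <- function(x, ...) {
  L <- nrow(x$feature_matrix$values)
  cat(sprintf("<zp_compartment> %d positions x %d features\n",
              L, ncol(x$feature_matrix$values)))
  if (!is.null(x$boundary)) {
    cat(sprintf(
      "  apical/basal boundary: position %d of %d (%.1f%% from tip), %d contiguity violation(s)\n",
      x$boundary$boundary_index, L, x$boundary$boundary_pct,
      x$boundary$contiguity_violations))
  }
  invisible(x)
}

#' Tidy a compartmentalization result
#'
#' @param x A `zp_compartment`.
#' @param ... Unused.
#' @return Tibble with one row per axial position: `position`, `cluster`
#'   (cutree id), and `region` ("apical"/"basal" for two clusters).
#' @exportS3Method generics::tidy
tidy.zp_compartment <- function(x, ...) {
  out <- tibble(position = seq_along(x$position_labels),
                cluster = x$position_labels)
  if (!is.null(x$boundary)) {
    out$region <- ifelse(out$cluster == x$boundary$apical_label,
                         "apical", "basal")
  }
  out
}

#' Summarize a compartmentalization result in one row
#'
#' @param x A `zp_compartment`.
#' @param ... Unused.
#' @return One-row tibble: `n_positions`, `n_features`, `boundary_index`,
#'   `boundary_pct`, `contiguity_violations`.
#' @exportS3Method generics::glance
glance.zp_compartment <- function(x, ...) {
  tibble(
    n_positions = nrow(x$feature_matrix$values),
    n_features = ncol(x$feature_matrix$values),
    boundary_index = x$boundary$boundary_index %||% NA_integer_,
    boundary_pct = x$boundary$boundary_pct %||% NA_real_,
    contiguity_violations = x$boundary$contiguity_violations %||% NA_integer_
  )
}
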