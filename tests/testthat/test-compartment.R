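# Small random profile set covering a full (probe x replicate x timepoint)
# grid, with normalized intensities.
random_profiles <- function(probes = c("a", "b"), reps = c("r1", "r2"),
                            k = 3, L = 12, seed = 1) {
  set.seed(seed)
  grid <- expand.grid(probe = probes, replicate_id = reps,
                      timepoint = 0:(k - 1), stringsAsFactors = FALSE)
  dplyr::bind_rows(lapply(seq_len(nrow(grid)), function(i) {
    tibble::tibble(probe = grid$probe[i], replicate_id = grid$replicate_id[i],
                   timepoint = grid$timepoint[i], position = 1:L,
                   intensity = zscore_profile(rnorm(L))$intensity)
  }))
}

test_that("feature matrix assembly orders, scales and validates the grid", {
  prof <- random_profiles()
  fm <- assemble_feature_matrix(prof, probe_order = c("a", "b"))
  expect_identical(dim(fm$values), c(12L, 12L))
  expect_identical(fm$features$probe, rep(c("a", "b"), each = 6))
  expect_identical(fm$features$timepoint[1:3], 0:2)
  expect_lt(max(abs(colMeans(fm$values))), 1e-9)
  expect_lt(max(abs(apply(fm$values, 2, function(v) mean(v^2)) - 1)), 1e-9)
  # duplicate triple
  expect_error(assemble_feature_matrix(dplyr::bind_rows(prof, prof[1:12, ])),
               "duplicate")
  # missing grid cell, reported by name
  expect_error(assemble_feature_matrix(prof[-(1:12), ], probe_order = c("a", "b")),
               "missing.*probe")
})

test_that("column re-scaling is idempotent on normalized profiles", {
  prof <- random_profiles(seed = 3)
  fm <- assemble_feature_matrix(prof)
  wide <- tidyr::pivot_wider(prof, names_from = c(probe, replicate_id, timepoint),
                             values_from = intensity)
  expect_lt(max(abs(sort(fm$values[1, ]) -
                    sort(unlist(wide[1, -1], use.names = FALSE)))), 1e-12)
})

test_that("position clustering separates duplicated row blocks exactly", {
  set.seed(2)
  u <- rnorm(6); v <- rnorm(6)
  prof <- random_profiles(L = 20, seed = 2)
  fm <- assemble_feature_matrix(prof)
  fm$values <- rbind(matrix(rep(u, each = 10), 10), matrix(rep(v, each = 10), 10))
  cl <- cluster_positions(fm, 2)
  expect_identical(cl$labels[1:10], rep(cl$labels[1], 10))
  expect_identical(cl$labels[11:20], rep(cl$labels[11], 10))
  expect_false(cl$labels[1] == cl$labels[11])
})

test_that("ward.D2 clustering matches the exhaustive Lance-Williams reference", {
  for (seed in 1:10) {
    set.seed(seed)
    x <- matrix(rnorm(12 * 6), 12, 6)
    fm <- structure(list(values = x,
                         features = tibble::tibble(column = 1:6)),
                    class = "zp_feature_matrix")
    cl <- cluster_positions(fm, 2)
    ref <- lw_ward2_reference(x)
    expect_equal(sort(cl$linkage$height), sort(ref$heights), tolerance = 1e-8)
    expect_equal(as.matrix(stats::cophenetic(cl$linkage)),
                 ref$cophenetic, tolerance = 1e-8, ignore_attr = TRUE)
    ref2 <- lw_ward2_cut2(x)
    expect_identical(length(unique(cl$labels[ref2 == 1])), 1L)
    expect_identical(length(unique(cl$labels[ref2 == 2])), 1L)
    expect_false(cl$labels[which(ref2 == 1)[1]] ==
                   cl$labels[which(ref2 == 2)[1]])
  }
})

test_that("clustering is invariant to row permutation up to label swap", {
  set.seed(9)
  x <- matrix(rnorm(20 * 5), 20, 5)
  fm <- structure(list(values = x, features = tibble::tibble(column = 1:5)),
                  class = "zp_feature_matrix")
  base <- cluster_positions(fm, 2)$labels
  perm <- sample(20)
  fmp <- fm; fmp$values <- x[perm, ]
  permuted <- cluster_positions(fmp, 2)$labels
  unperm <- integer(20); unperm[perm] <- permuted
  agree <- mean(unperm == base)
  expect_true(agree == 1 || agree == 0 ||
                all(unperm == (3 - base)))  # same partition either labelling
})

test_that("ward merge heights are monotone non-decreasing", {
  set.seed(12)
  x <- matrix(rnorm(30 * 8), 30, 8)
  fm <- structure(list(values = x, features = tibble::tibble(column = 1:8)),
                  class = "zp_feature_matrix")
  h <- cluster_positions(fm, 2)$linkage$height
  expect_true(all(diff(h) >= -1e-12))
})

test_that("boundary location minimizes two-segment disagreement", {
  r <- locate_boundary(rep(c("apical", "basal"), c(48, 62)))
  expect_identical(r$boundary_index, 48L)
  expect_equal(round(r$boundary_pct, 1), 43.6)
  expect_identical(r$contiguity_violations, 0L)
  expect_identical(r$apical_label, "apical")
  r2 <- locate_boundary(rep(1:2, c(55, 55)))
  expect_equal(r2$boundary_pct, 50)
  # non-contiguous labels: against the exhaustive reference
  lab <- c("A", "A", "B", "A", "B", "B", "B", "B")
  ref <- boundary_reference(lab)
  r3 <- locate_boundary(lab)
  expect_identical(r3$boundary_index, as.integer(ref$boundary_index))
  expect_identical(r3$contiguity_violations, as.integer(ref$violations))
  expect_identical(r3$contiguity_violations, 1L)
  expect_error(locate_boundary(rep("A", 5)), "two distinct")
})

test_that("boundary search equals exhaustive split enumeration (random cases)", {
  set.seed(4)
  for (i in 1:200) {
    L <- sample(2:12, 1)
    lab <- sample(c("x", "y"), L, replace = TRUE)
    if (length(unique(lab)) < 2) next
    got <- locate_boundary(lab)
    ref <- boundary_reference(lab)
    expect_identical(got$boundary_index, as.integer(ref$boundary_index))
    expect_identical(got$contiguity_violations, as.integer(ref$violations))
  }
})

test_that("feature groups split planted apical/basal columns with Group 1 basal-high", {
  L <- 40
  apical_template <- c(rep(2, 16), rep(0, 24))
  basal_template <- c(rep(0, 16), rep(2, 24))
  set.seed(6)
  prof <- dplyr::bind_rows(lapply(0:5, function(t) {
    dplyr::bind_rows(
      tibble::tibble(probe = "microtubules", replicate_id = "r1", timepoint = t,
                     position = 1:L,
                     intensity = zscore_profile(apical_template + rnorm(L, 0, 0.05))$intensity),
      tibble::tibble(probe = "vacuolar_membranes", replicate_id = "r1", timepoint = t,
                     position = 1:L,
                     intensity = zscore_profile(basal_template + rnorm(L, 0, 0.05))$intensity))
  }))
  cm <- compartmentalize(prof)
  td <- tidy(cm)
  expect_identical(td$region, rep(c("apical", "basal"), c(16, 24)))
  g <- cm$feature_groups
  vac_cols <- cm$feature_matrix$features$probe == "vacuolar_membranes"
  expect_true(all(g[vac_cols] == 1))   # basal-high group is Group 1
  expect_true(all(g[!vac_cols] == 2))
  comp <- cm$composition$by_probe
  expect_true(all(abs(tapply(comp$fraction, comp$group, sum) - 1) < 1e-12))
  expect_identical(comp$fraction[comp$group == 1 &
                                   comp$probe == "vacuolar_membranes"], 1)
  # single feature column cannot form two groups
  fm1 <- cm$feature_matrix
  fm1$values <- fm1$values[, 1, drop = FALSE]
  expect_error(cluster_features(fm1, 2), "fewer items than groups")
})

test_that("glance summarizes the compartment result", {
  prof <- random_profiles(L = 16, seed = 10)
  cm <- compartmentalize(prof)
  g <- glance(cm)
  expect_identical(g$n_positions, 16L)
  expect_identical(g$n_features, 12L)
  expect_equal(g$boundary_pct, 100 * g$boundary_index / 16)
})
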