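# Separable toy design: apical rows high on the first half of the features.
separable_fm <- function(n_apical = 13, n_basal = 17, F = 12, noise = 0.1,
                         seed = 1) {
  set.seed(seed)
  L <- n_apical + n_basal
  x <- matrix(rnorm(L * F, 0, noise), L, F)
  x[1:n_apical, 1:(F / 2)] <- x[1:n_apical, 1:(F / 2)] + 1
  colnames(x) <- sprintf("f%d", 1:F)
  features <- tibble::tibble(column = 1:F,
                             probe = rep(c("p1", "p2"), each = F / 2),
                             replicate_id = "r1",
                             timepoint = rep(0:(F / 2 - 1), 2))
  fm <- structure(list(values = x, features = features),
                  class = "zp_feature_matrix")
  list(fm = fm, labels = rep(c("apical", "basal"), c(n_apical, n_basal)))
}

test_that("OOB error from a confusion matrix is the off-diagonal share", {
  expect_equal(oob_error_from_confusion(matrix(c(47, 1, 1, 61), 2,
                                               byrow = TRUE)), 1.8)
  expect_equal(oob_error_from_confusion(matrix(c(48, 0, 0, 62), 2)), 0)
  expect_equal(oob_error_from_confusion(matrix(c(0, 62, 48, 0), 2)), 100)
  # invariant to simultaneous row/col permutation of the class order
  m <- matrix(c(40, 3, 5, 52), 2, byrow = TRUE)
  p <- m[2:1, 2:1]
  expect_equal(oob_error_from_confusion(m), oob_error_from_confusion(p))
  expect_error(oob_error_from_confusion(matrix(0, 2, 2)), "empty")
  expect_error(oob_error_from_confusion(matrix(1, 2, 3)), "square")
})

test_that("random forest separates a separable design with low OOB error", {
  for (seed in 1:10) {
    d <- separable_fm(seed = seed)
    res <- classify_regions(d$fm, d$labels, n_trees = 300, m_try = 3,
                            seed = seed)
    expect_lte(res$oob_error_pct, 2)
    expect_equal(sum(res$confusion), 30)
    expect_equal(res$oob_error_pct,
                 round(100 * (sum(res$confusion) - sum(diag(res$confusion))) /
                         sum(res$confusion), 1))
  }
})

test_that("permuted labels give chance-level OOB error", {
  d <- separable_fm(n_apical = 13, n_basal = 17, seed = 2)
  set.seed(99)
  perm <- sample(d$labels)
  res <- classify_regions(d$fm, perm, n_trees = 300, m_try = 3, seed = 5)
  majority_err <- 100 * min(table(perm)) / length(perm)
  expect_lt(abs(res$oob_error_pct - majority_err), 15)
})

test_that("the forest is deterministic for a fixed seed", {
  d <- separable_fm(seed = 3)
  a <- classify_regions(d$fm, d$labels, n_trees = 100, m_try = 3, seed = 7)
  b <- classify_regions(d$fm, d$labels, n_trees = 100, m_try = 3, seed = 7)
  expect_identical(a$confusion, b$confusion)
  expect_identical(a$importance, b$importance)
  c2 <- classify_regions(d$fm, d$labels, n_trees = 100, m_try = 3, seed = 8)
  expect_false(identical(a$importance, c2$importance))
})

test_that("degenerate label sets and parameters are rejected", {
  d <- separable_fm()
  expect_error(classify_regions(d$fm, rep("apical", 30)), "2 classes")
  expect_error(classify_regions(d$fm, d$labels, m_try = 13), "m_try exceeds")
  expect_error(classify_regions(d$fm, d$labels[-1]), "one entry per position")
})

test_that("percent importances sum to 100 and aggregate per structure", {
  d <- separable_fm(seed = 4)
  res <- classify_regions(d$fm, d$labels, n_trees = 200, m_try = 3, seed = 1)
  expect_lt(abs(sum(res$importance$mean_decrease_gini_pct) - 100), 1e-9)
  agg <- res$importance_by_structure
  expect_identical(nrow(agg), 2L)  # one value per (probe, replicate)
  # uniform importances aggregate to equal shares
  imp <- tibble::tibble(probe = rep(c("a", "b"), each = 6),
                        replicate_id = rep(c("r1", "r2"), 6),
                        timepoint = rep(0:2, 4),
                        mean_decrease_gini_pct = 100 / 12)
  agg_u <- aggregate_importance(imp)
  expect_true(all(abs(agg_u$mean_decrease_gini_pct - 100 / 12) < 1e-12))
  # importance concentrated on one probe stays on that probe
  imp2 <- imp
  imp2$mean_decrease_gini_pct <- ifelse(imp2$probe == "a", 100 / 6, 0)
  agg2 <- aggregate_importance(imp2)
  expect_true(all(agg2$mean_decrease_gini_pct[agg2$probe == "b"] == 0))
  expect_true(all(agg2$mean_decrease_gini_pct[agg2$probe == "a"] > 0))
})

test_that("a pure-noise feature does not outrank the planted signal", {
  wins <- 0
  for (seed in 1:50) {
    set.seed(seed)
    L <- 40
    x <- cbind(signal = c(rnorm(20, 1, 0.2), rnorm(20, 0, 0.2)),
               noise = rnorm(L))
    features <- tibble::tibble(column = 1:2, probe = c("sig", "noi"),
                               replicate_id = "r1", timepoint = 0L)
    fm <- structure(list(values = x, features = features),
                    class = "zp_feature_matrix")
    res <- classify_regions(fm, rep(c("apical", "basal"), each = 20),
                            n_trees = 100, m_try = 1, seed = seed)
    imp <- res$importance
    if (imp$mean_decrease_gini[imp$probe == "sig"] >
        imp$mean_decrease_gini[imp$probe == "noi"]) wins <- wins + 1
  }
  expect_gte(wins, 48)  # >= 95% of 50 seeded runs
})
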