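# Independent reference implementations used as test oracles.  These are
# deliberately naive (exhaustive / O(n^3)) and share no code with the
# package internals they check.

# Exhaustive Lance-Williams agglomeration for Ward's method in the variant
# that squares dissimilarities internally (ward.D2).  Returns merge heights
# (in merge order) and the cophenetic distance matrix.
lw_ward2_reference <- function(x) {
  n <- nrow(x)
  d2 <- as.matrix(dist(x))^2
  active <- as.list(seq_len(n))
  sizes <- rep(1, n)
  alive <- rep(TRUE, n)
  coph <- matrix(0, n, n)
  heights <- numeric(n - 1)
  for (step in seq_len(n - 1)) {
    best <- Inf; bi <- bj <- 0
    idx <- which(alive)
    for (a in seq_along(idx)) {
      for (b in seq_along(idx)) {
        if (b <= a) next
        i <- idx[a]; j <- idx[b]
        if (d2[i, j] < best) { best <- d2[i, j]; bi <- i; bj <- j }
      }
    }
    h <- sqrt(best)
    heights[step] <- h
    for (p in active[[bi]]) for (q in active[[bj]]) {
      coph[p, q] <- coph[q, p] <- h
    }
    # Lance-Williams update on squared dissimilarities
    ni <- sizes[bi]; nj <- sizes[bj]
    for (k in which(alive)) {
      if (k == bi || k == bj) next
      nk <- sizes[k]
      d2[bi, k] <- d2[k, bi] <-
        ((ni + nk) * d2[bi, k] + (nj + nk) * d2[bj, k] - nk * d2[bi, bj]) /
          (ni + nj + nk)
    }
    active[[bi]] <- c(active[[bi]], active[[bj]])
    sizes[bi] <- ni + nj
    alive[bj] <- FALSE
  }
  # two-cluster partition: membership just before the final merge
  last <- which(alive)
  part <- integer(n)
  part[active[[last]]] <- 1L
  # reconstruct the other cluster from the final merge partner
  list(heights = heights, cophenetic = coph)
}

# Two-cluster labels from the reference agglomeration: run it but stop at
# two clusters.
lw_ward2_cut2 <- function(x) {
  n <- nrow(x)
  d2 <- as.matrix(dist(x))^2
  active <- as.list(seq_len(n))
  sizes <- rep(1, n)
  alive <- rep(TRUE, n)
  for (step in seq_len(n - 2)) {
    best <- Inf; bi <- bj <- 0
    idx <- which(alive)
    for (a in seq_along(idx)) {
      for (b in seq_along(idx)) {
        if (b <= a) next
        i <- idx[a]; j <- idx[b]
        if (d2[i, j] < best) { best <- d2[i, j]; bi <- i; bj <- j }
      }
    }
    ni <- sizes[bi]; nj <- sizes[bj]
    for (k in which(alive)) {
      if (k == bi || k == bj) next
      nk <- sizes[k]
      d2[bi, k] <- d2[k, bi] <-
        ((ni + nk) * d2[bi, k] + (nj + nk) * d2[bj, k] - nk * d2[bi, bj]) /
          (ni + nj + nk)
    }
    active[[bi]] <- c(active[[bi]], active[[bj]])
    sizes[bi] <- ni + nj
    alive[bj] <- FALSE
  }
  out <- integer(n)
  out[active[[which(alive)[1]]]] <- 1L
  out[active[[which(alive)[2]]]] <- 2L
  out
}

# Exhaustive minimal-disagreement two-segment split: tries every split s and
# both label-to-segment assignments; ties toward smaller s, and at equal
# violations the assignment where the tip segment carries labels[1].
boundary_reference <- function(labels) {
  L <- length(labels)
  u <- unique(labels)
  stopifnot(length(u) == 2)
  best <- Inf; best_s <- NA; best_apical <- NA
  for (s in seq_len(L - 1)) {
    for (ap in c(labels[1], setdiff(u, labels[1]))) {
      bs <- setdiff(u, ap)
      v <- sum(labels[1:s] != ap) + sum(labels[(s + 1):L] != bs)
      if (v < best) { best <- v; best_s <- s; best_apical <- ap }
    }
  }
  list(boundary_index = best_s, violations = best,
       apical_label = best_apical)
}

# Pairwise Tukey-Kramer p-values computed directly from the studentized
# range distribution.
tukey_reference <- function(values, groups) {
  g <- factor(groups)
  k <- nlevels(g)
  ns <- tapply(values, g, length)
  ms <- tapply(values, g, mean)
  df <- length(values) - k
  mse <- sum(tapply(values, g, function(v) sum((v - mean(v))^2))) / df
  out <- list()
  lv <- levels(g)
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      se <- sqrt(mse / 2 * (1 / ns[i] + 1 / ns[j]))
      q <- abs(ms[i] - ms[j]) / se
      out[[paste(lv[i], lv[j], sep = "|")]] <-
        ptukey(q, k, df, lower.tail = FALSE)
    }
  }
  out
}
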