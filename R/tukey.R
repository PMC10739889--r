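#' Tukey-Kramer all-pairs comparison with compact letter display
#'
#' One-way layout across `>= 2` groups: all pairwise comparisons by the
#' studentized-range test with the Tukey-Kramer unequal-n correction
#' (via [stats::TukeyHSD()]), plus a compact letter display in which groups
#' sharing a letter are not significantly different at `alpha`.  Letters are
#' built by the insert-and-absorb algorithm on the significance pattern and
#' ordered by decreasing group mean.
#'
#' @param data Data frame with one value per row.
#' @param value,group Column names (tidy-eval) of the response and the
#'   grouping variable.
#' @param alpha Family-wise significance level (default 0.01).
#' @return A `zp_tukey` list: `pairs` (tibble: `group1`, `group2`, `diff`,
#'   `p_adj`), `letters` (tibble: `group`, `mean`, `letters`), `alpha`.
#' @export
#' @examples
#' d <- data.frame(g = rep(c("a", "b"), each = 3),
#'                 y = c(0, 0, 0.001, 10, 10, 10.001))
#' tukey_kramer(d, y, g)
tukey_kramer <- function(data, value, group, alpha = 0.01) {
  v <- dplyr::pull(data, {{ value }})
  g <- factor(dplyr::pull(data, {{ group }}))
  if (nlevels(g) < 2) {
    abort("need at least 2 groups", class = "zp_parameter_error")
  }
  if (any(table(g) < 2)) {
    abort("every group needs at least 2 values", class = "zp_parameter_error")
  }
  fit <- aov(v ~ g)
  tk <- TukeyHSD(fit, conf.level = 1 - alpha)$g
  nm <- strsplit(rownames(tk), "-", fixed = TRUE)
  pairs <- tibble(
    group1 = vapply(nm, `[`, "", 1),
    group2 = vapply(nm, `[`, "", 2),
    diff = unname(tk[, "diff"]),
    p_adj = unname(tk[, "p adj"])
  )
  lv <- levels(g)
  sig <- matrix(FALSE, length(lv), length(lv), dimnames = list(lv, lv))
  for (i in seq_len(nrow(pairs))) {
    if (pairs$p_adj[i] < alpha) {
      sig[pairs$group1[i], pairs$group2[i]] <- TRUE
      sig[pairs$group2[i], pairs$group1[i]] <- TRUE
    }
  }
  means <- tapply(v, g, mean)
  ord <- lv[order(-means)]
  sets <- cld_insert_absorb(ord, sig)
  letter_of <- vapply(ord, function(gi) {
    paste(letters[which(vapply(sets, function(s) gi %in% s, TRUE))],
          collapse = "")
  }, "")
  structure(
    list(pairs = pairs,
         letters = tibble(group = ord, mean = unname(means[ord]),
                          letters = unname(letter_of)),
         alpha = alpha),
    class = "zp_tukey"
  )
}

# Insert-and-absorb compact letter display: start with one set holding all
# groups; for each significant pair split every set containing both; drop
# sets contained in another.  Returns a list of group-name vectors (letter
# sets), ordered by first member's position in `ord`.
cld_insert_absorb <- function(ord, sig) {
  sets <- list(ord)
  for (i in seq_along(ord)) {
    for (j in seq_along(ord)) {
      if (j <= i || !sig[ord[i], ord[j]]) next
      for (k in rev(seq_along(sets))) {
        s <- sets[[k]]
        if (ord[i] %in% s && ord[j] %in% s) {
          sets[[k]] <- NULL
          sets <- c(sets, list(setdiff(s, ord[i])), list(setdiff(s, ord[j])))
        }
      }
      # absorb: drop sets that are subsets of another
      keep <- rep(TRUE, length(sets))
      for (a in seq_along(sets)) {
        for (b in seq_along(sets)) {
          if (a != b && keep[b] &&
              all(sets[[a]] %in% sets[[b]]) &&
              (length(sets[[a]]) < length(sets[[b]]) || a > b)) {
            keep[a] <- FALSE
            break
          }
        }
      }
      sets <- sets[keep]
    }
  }
  first_pos <- vapply(sets, function(s) min(match(s, ord)), numeric(1))
  sets[order(first_pos)]
}

#' @export
print.zp_tukey <- function(x, ...) {
  cat(sprintf("<zp_tukey> Tukey-Kramer, alpha = %g\n", x$alpha))
  print(as.data.frame(x$letters))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.zp_tukey <- function(x, ...) x$pairs
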