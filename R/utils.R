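# Internal numeric helpers shared across modules.

# Round-half-up on a real grid (base round() is round-half-even).
round_half_up <- function(x) floor(x + 0.5)

# Population standard deviation (divisor n).
pop_sd <- function(x) {
  m <- mean(x)
  sqrt(mean((x - m)^2))
}

# Z-score with population sd; errors on zero variance.
zscore_values <- function(x, what = "profile") {
  if (length(x) < 2) {
    abort(sprintf("flat %s: need at least 2 values to z-score", what),
          class = "zp_flat_profile")
  }
  s <- pop_sd(x)
  if (!is.finite(s) || s == 0) {
    abort(sprintf("flat %s: zero variance, cannot z-score", what),
          class = "zp_flat_profile")
  }
  (x - mean(x)) / s
}

# Smallest power of two >= max(1, x); used as an exact float storage scale.
pow2_scale <- function(x) {
  2^max(0, ceiling(log2(max(1, x))))
}

check_scalar_count <- function(x, name, min = 1L) {
  if (length(x) != 1 || !is.numeric(x) || is.na(x) || x != as.integer(x) ||
      x < min) {
    abort(sprintf("`%s` must be a single integer >= %d", name, min),
          class = "zp_parameter_error")
  }
  as.integer(x)
}

# Extract an intensity vector from either a numeric vector or a tibble with
# an `intensity` column (profile tables flow through the pipe as tibbles).
profile_values <- function(profile) {
  if (is.data.frame(profile)) {
    if (!"intensity" %in% names(profile)) {
      abort("profile data frame must have an `intensity` column",
            class = "zp_parameter_error")
    }
    profile$intensity
  } else if (is.numeric(profile)) {
    as.numeric(profile)
  } else {
    abort("profile must be a numeric vector or a data frame",
          class = "zp_parameter_error")
  }
}
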