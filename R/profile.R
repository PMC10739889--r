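#' Axial mean-intensity profile of an oriented cell
#'
#' For every image row between the tip and the base of the oriented mask,
#' the mean intensity over mask pixels in that row is computed (background
#' pixels never enter the mean).  Index 1 of the profile is the apical tip.
#'
#' @param oriented A `zp_oriented` object from [rotate_and_mask()].
#' @return A tibble with columns `position` (1 = tip) and `intensity`;
#'   one row per image row spanned by the mask.
#' @export
axial_profile <- function(oriented) {
  stopifnot(inherits(oriented, "zp_oriented"))
  rows <- oriented$tip_row:oriented$base_row
  m <- oriented$mask[rows, , drop = FALSE]
  counts <- rowSums(m)
  if (any(counts == 0)) {
    abort(sprintf(
      "disconnected mask: %d interior row(s) between tip and base contain no mask pixels",
      sum(counts == 0)), class = "zp_mask_error")
  }
  sums <- rowSums(oriented$image[rows, , drop = FALSE] * m)
  tibble(position = seq_along(rows), intensity = sums / counts)
}

#' Resample a profile to a standard length
#'
#' Linear interpolation onto `L` equally spaced positions spanning the
#' original profile; both endpoints are preserved exactly.  This is the 1-D
#' reduction of bilinear image interpolation, used to standardize cell
#' length (default 110 px, the minimum cell length in the original dataset).
#'
#' @param profile Numeric vector or tibble with an `intensity` column
#'   (e.g. from [axial_profile()]).
#' @param L Standard length, default 110.
#' @return A tibble with `position` (1..L) and `intensity`.
#' @export
resample_profile <- function(profile, L = 110) {
  L <- check_scalar_count(L, "L", min = 2L)
  v <- profile_values(profile)
  n <- length(v)
  if (n < 2) {
    abort("profile must have at least 2 values to resample",
          class = "zp_parameter_error")
  }
  out <- approx(x = seq_len(n), y = v,
                xout = 1 + (seq_len(L) - 1) * (n - 1) / (L - 1))$y
  out[1] <- v[1]
  out[L] <- v[n]
  tibble(position = seq_len(L), intensity = out)
}

#' Z-score a profile to mean 0, standard deviation 1
#'
#' Uses the population standard deviation (divisor `n`), so the output has
#' sd exactly 1.  Intensity normalization makes profiles comparable across
#' probes and replicates whose absolute fluorescence differs.
#'
#' @param profile Numeric vector or tibble with an `intensity` column.
#' @return A tibble with `position` and z-scored `intensity`.
#' @export
zscore_profile <- function(profile) {
  v <- profile_values(profile)
  tibble(position = seq_along(v), intensity = zscore_values(v))
}

# One (probe, replicate, timepoint): MIP -> orient -> profile -> resample
# -> zscore.  Returns the normalized profile tibble.
process_frame <- function(frame3d, mask, apex_hint, L) {
  mip <- max_intensity_projection(frame3d)
  oriented <- rotate_and_mask(mip, mask, apex_hint = apex_hint)
  prof <- axial_profile(oriented)
  zscore_profile(resample_profile(prof, L = L))
}

#' Extract normalized axial profiles for a whole dataset
#'
#' Runs the full image-processing chain for every movie and selected time
#' point: frame selection ([select_normalized_frames()]), maximum intensity
#' projection, ellipse fitting and apex-up rotation, axial averaging, length
#' standardization and z-scoring.
#'
#' @param x A `zp_dataset` (from [simulate_dataset()] or [read_dataset()]) or
#'   a manifest file path.
#' @param L Standard profile length (default 110).
#' @param k Number of normalized time points (default 10).
#' @return A tibble with columns `probe`, `replicate_id`, `timepoint`
#'   (0-based, `T = 0 .. k-1`), `position` (1 = tip) and `intensity`
#'   (z-scored), i.e. one normalized profile per movie and time point.
#' @export
extract_profiles <- function(x, L = 110, k = 10) {
  UseMethod("extract_profiles")
}

#' @export
extract_profiles.character <- function(x, L = 110, k = 10) {
  extract_profiles(read_dataset(x), L = L, k = k)
}

#' @export
extract_profiles.zp_dataset <- function(x, L = 110, k = 10) {
  out <- vector("list", nrow(x$entries) * k)
  j <- 1L
  for (i in seq_len(nrow(x$entries))) {
    e <- x$entries[i, ]
    stack <- e$stack[[1]]
    sel <- select_normalized_frames(e$onset_frame, e$predivision_frame, k = k)
    masks <- e$masks[[1]]
    apex <- e$apex[[1]]
    for (t in seq_len(k)) {
      fr <- sel[t]
      mask <- if (identical(e$masks_per, "raw")) masks[[fr]] else masks[[t]]
      frame3d <- stack$intensity[fr, , , , drop = TRUE]
      dim(frame3d) <- dim(stack$intensity)[2:4]
      hint <- apex_hint_for(apex, fr)
      prof <- process_frame(frame3d, mask, hint, L)
      out[[j]] <- mutate(prof,
        probe = e$probe, replicate_id = e$replicate_id, timepoint = t - 1L,
        .before = 1)
      j <- j + 1L
    }
  }
  bind_rows(out)
}

# Apex annotation may be a single {row, col} point or per-frame lists.
apex_hint_for <- function(apex, frame) {
  r <- apex$row; cc <- apex$col
  if (length(r) > 1) {
    f <- apex$frame %||% seq_along(r)
    i <- match(frame, f)
    if (is.na(i)) i <- which.min(abs(f - frame))
    c(r[i], cc[i])
  } else {
    c(r, cc)
  }
}
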