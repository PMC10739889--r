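#' Select time-normalized frames between two biological events
#'
#' Event-anchored time normalization: the window from the onset of cell
#' elongation to just before the asymmetric cell division is divided into
#' `k - 1` equal intervals, and the raw frame nearest each grid point is
#' selected (round-half-up).  The first and last selected frames are exactly
#' the two anchors, so normalized time point `T = 0` is the onset and
#' `T = k - 1` is the pre-division frame.
#'
#' Movies shorter than `k` frames yield duplicated selections, with a
#' warning, rather than an error: elongation durations vary several-fold
#' between zygotes and short movies must not crash the pipeline.
#'
#' @param onset Frame index of elongation onset (any integer base).
#' @param predivision Frame index just before division; must exceed `onset`.
#' @param k Number of normalized time points (default 10).
#' @return Integer vector of `k` non-decreasing frame indices.
#' @export
#' @examples
#' select_normalized_frames(0, 18, k = 10)
select_normalized_frames <- function(onset, predivision, k = 10) {
  k <- check_scalar_count(k, "k", min = 2L)
  if (length(onset) != 1 || length(predivision) != 1 ||
      !is.finite(onset) || !is.finite(predivision)) {
    abort("`onset` and `predivision` must be single finite indices",
          class = "zp_parameter_error")
  }
  if (predivision <= onset) {
    abort("empty elongation window: predivision_frame must exceed onset_frame",
          class = "zp_parameter_error")
  }
  i <- seq_len(k) - 1
  idx <- as.integer(round_half_up(onset + i * (predivision - onset) / (k - 1)))
  idx[1] <- as.integer(onset)
  idx[k] <- as.integer(predivision)
  if (anyDuplicated(idx)) {
    warn(sprintf(
      "elongation window (%d frames) is shorter than k = %d; %d frame(s) selected more than once",
      as.integer(predivision - onset + 1), k, sum(duplicated(idx))))
  }
  idx
}
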