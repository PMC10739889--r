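#' Relative position of the division plane along the apical-basal axis
#'
#' Linear fraction of the cell length, measured from the apical tip on the
#' oriented division frame, expressed in percent and reported to 1 decimal.
#'
#' @param plane_row Axial (row) coordinate of the annotated division plane
#'   in the tip-oriented frame.
#' @param tip_row,base_row Rows of the cell tip and base at that frame.
#' @return Percent from tip in `[0, 100]`, rounded to 1 decimal.
#' @export
#' @examples
#' division_plane_position(30.5, 10, 110)  # 20.5
division_plane_position <- function(plane_row, tip_row, base_row) {
  if (base_row <= tip_row) {
    abort("base_row must exceed tip_row", class = "zp_parameter_error")
  }
  if (plane_row < tip_row || plane_row > base_row) {
    abort("division plane lies outside the cell extent",
          class = "zp_parameter_error")
  }
  round(100 * (plane_row - tip_row) / (base_row - tip_row), 1)
}

#' Compare division-plane positions with the compartment boundary
#'
#' Summarizes the measured plane positions (mean and sample SD, divisor
#' `n - 1`) and relates them to the apical-compartment boundary: if the
#' plane bisects the apical compartment, the mean should sit at half the
#' boundary percentage.
#'
#' @param boundary_pct Compartment boundary, percent from tip.
#' @param plane_pcts Numeric vector of plane positions (percent from tip).
#' @return One-row tibble: `mean`, `sd` (`NA` when `n = 1`), `n`,
#'   `half_boundary`, `delta` (`mean - half_boundary`).
#' @export
boundary_vs_plane <- function(boundary_pct, plane_pcts) {
  if (length(plane_pcts) < 1) {
    abort("need at least one plane position", class = "zp_parameter_error")
  }
  n <- length(plane_pcts)
  m <- mean(plane_pcts)
  tibble(
    mean = m,
    sd = if (n > 1) sd(plane_pcts) else NA_real_,
    n = n,
    half_boundary = boundary_pct / 2,
    delta = m - boundary_pct / 2
  )
}

#' Measure division-plane positions for all annotated movies in a dataset
#'
#' For every dataset entry carrying a division-plane annotation, the
#' annotated frame is oriented apex-up (same rotation as the profile
#' pipeline), the annotated point is mapped through the rotation, and its
#' axial position is expressed in percent of cell length from the tip.
#'
#' @param dataset A `zp_dataset`.
#' @return Tibble: `probe`, `replicate_id`, `pct_from_tip`.
#' @export
measure_division_planes <- function(dataset) {
  stopifnot(inherits(dataset, "zp_dataset"))
  out <- list()
  for (i in seq_len(nrow(dataset$entries))) {
    e <- dataset$entries[i, ]
    dp <- e$division_plane[[1]]
    if (is.null(dp)) next
    fr <- dp$frame
    stack <- e$stack[[1]]
    frame3d <- stack$intensity[fr, , , , drop = TRUE]
    dim(frame3d) <- dim(stack$intensity)[2:4]
    sel <- select_normalized_frames(e$onset_frame, e$predivision_frame,
                                    k = length(e$masks[[1]]))
    mask <- if (identical(e$masks_per, "raw")) {
      e$masks[[1]][[fr]]
    } else {
      e$masks[[1]][[which.min(abs(sel - fr))]]
    }
    mip <- max_intensity_projection(frame3d)
    oriented <- rotate_and_mask(mip, mask,
                                apex_hint = apex_hint_for(e$apex[[1]], fr))
    pt <- map_to_oriented(oriented, tibble(row = dp$row, col = dp$col))
    out[[length(out) + 1]] <- tibble(
      probe = e$probe, replicate_id = e$replicate_id,
      pct_from_tip = division_plane_position(
        pt$row, oriented$tip_row, oriented$base_row)
    )
  }
  if (length(out) == 0) {
    return(tibble(probe = character(), replicate_id = character(),
                  pct_from_tip = numeric()))
  }
  bind_rows(out)
}
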