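#' Maximum intensity projection along z
#'
#' @param frame 3-d numeric array `(z, row, col)` with at least one slice.
#' @return A numeric matrix `(row, col)`; each pixel is the maximum over z.
#' @export
max_intensity_projection <- function(frame) {
  if (!is.array(frame) || length(dim(frame)) != 3 || dim(frame)[1] < 1) {
    abort("`frame` must be a (z, row, col) array with >= 1 slice",
          class = "zp_parameter_error")
  }
  d <- dim(frame)
  out <- frame[1, , , drop = TRUE]
  dim(out) <- d[2:3]
  if (d[1] > 1) {
    for (z in 2:d[1]) {
      sl <- frame[z, , , drop = TRUE]
      dim(sl) <- d[2:3]
      out <- pmax(out, sl)
    }
  }
  out
}

#' Fit the apical-basal axis of a cell mask by image moments
#'
#' The binary mask is summarized by its moment-equivalent ellipse: the
#' centroid is the mean of foreground pixel coordinates and the axis lengths
#' and orientation come from the eigendecomposition of the central
#' second-moment (covariance) matrix, scaled so the ellipse has the same
#' second moments as the pixel set (semi-axis `= 2 * sqrt(eigenvalue)`).
#' The major axis of this ellipse defines the apical-basal axis.
#'
#' Orientation `theta` is in degrees in `[0, 180)`, measured from the column
#' (horizontal) axis toward increasing row (downward on screen).
#'
#' @param mask Logical matrix with at least 3 foreground pixels.
#' @param eps Relative axis-ratio threshold below which the fit is flagged
#'   degenerate (near-isotropic mask), default 0.05.
#' @return A `zp_axis` list: `centroid_row`, `centroid_col`, `theta`,
#'   `major_len`, `minor_len`, `degenerate`.
#' @export
fit_ellipse_axis <- function(mask, eps = 0.05) {
  if (!is.logical(mask) || length(dim(mask)) != 2) {
    abort("`mask` must be a logical matrix", class = "zp_parameter_error")
  }
  px <- which(mask, arr.ind = TRUE)
  n <- nrow(px)
  if (n == 0) {
    abort("empty mask: cannot fit an axis", class = "zp_mask_error")
  }
  r <- px[, 1]; cc <- px[, 2]
  cen_r <- mean(r); cen_c <- mean(cc)
  # central second moments with x = col, y = row (row increases downward)
  mu20 <- mean((cc - cen_c)^2)
  mu02 <- mean((r - cen_r)^2)
  mu11 <- mean((cc - cen_c) * (r - cen_r))
  theta <- 0.5 * atan2(2 * mu11, mu20 - mu02) * 180 / pi
  if (theta < 0) theta <- theta + 180
  if (theta >= 180) theta <- theta - 180
  ev <- eigen(matrix(c(mu20, mu11, mu11, mu02), 2, 2), symmetric = TRUE)$values
  major <- 4 * sqrt(max(ev[1], 0))
  minor <- 4 * sqrt(max(ev[2], 0))
  degenerate <- FALSE
  if (minor < 1e-9 * max(major, 1)) {
    warn("collinear mask pixels: minor axis clamped to 1 px")
    minor <- 1
    degenerate <- TRUE
  }
  if (major / minor < 1 + eps) degenerate <- TRUE
  structure(
    list(centroid_row = cen_r, centroid_col = cen_c, theta = theta,
         major_len = major, minor_len = minor, degenerate = degenerate),
    class = "zp_axis"
  )
}

#' @export
print.zp_axis <- function(x, ...) {
  cat(sprintf(
    "<zp_axis> theta=%.2f deg  major=%.1f px  minor=%.1f px  centroid=(%.1f, %.1f)%s\n",
    x$theta, x$major_len, x$minor_len, x$centroid_row, x$centroid_col,
    if (x$degenerate) "  [degenerate]" else ""))
  invisible(x)
}

# Rotation matrix for phi degrees acting on (x, y) = (col, row) coordinates.
rot_mat <- function(phi_deg) {
  a <- phi_deg * pi / 180
  matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2, 2)
}

# Bilinear sample of matrix `img` at fractional (row, col) positions;
# positions outside the image return 0.
bilinear_sample <- function(img, rows, cols) {
  h <- nrow(img); w <- ncol(img)
  r0 <- floor(rows); c0 <- floor(cols)
  fr <- rows - r0; fc <- cols - c0
  val <- numeric(length(rows))
  get_px <- function(ri, ci) {
    ok <- ri >= 1 & ri <= h & ci >= 1 & ci <= w
    v <- numeric(length(ri))
    v[ok] <- img[cbind(ri[ok], ci[ok])]
    v
  }
  val <- get_px(r0, c0) * (1 - fr) * (1 - fc) +
    get_px(r0 + 1, c0) * fr * (1 - fc) +
    get_px(r0, c0 + 1) * (1 - fr) * fc +
    get_px(r0 + 1, c0 + 1) * fr * fc
  val
}

# Nearest-neighbour sample of a logical matrix; outside -> FALSE.
nearest_sample <- function(mask, rows, cols) {
  h <- nrow(mask); w <- ncol(mask)
  ri <- round_half_up(rows); ci <- round_half_up(cols)
  ok <- ri >= 1 & ri <= h & ci >= 1 & ci <= w
  v <- logical(length(rows))
  v[ok] <- mask[cbind(ri[ok], ci[ok])]
  v
}

#' Rotate a masked cell so the apical-basal axis is vertical, apex up
#'
#' Rotates the image and mask about the mask centroid by `90 - theta`
#' degrees (plus 180 if needed so the annotated apex maps to the top), on an
#' output canvas expanded to contain the rotated bounding box.  Intensity is
#' interpolated bilinearly, the mask nearest-neighbour and re-binarized, and
#' all intensity outside the rotated mask is set to zero.
#'
#' @param image Numeric matrix (e.g. a maximum intensity projection).
#' @param mask Logical matrix, same dimensions as `image`.
#' @param axis Optional [fit_ellipse_axis()] result; fitted from `mask`
#'   when `NULL`.  A degenerate axis is an error: supply an explicit
#'   orientation by constructing the `zp_axis` yourself.
#' @param apex_hint Numeric `(row, col)` point on or near the apical tip,
#'   used only to disambiguate the 180-degree flip.
#' @return A `zp_oriented` list: `image`, `mask`, `tip_row`, `base_row`,
#'   `angle_deg` (rotation applied), plus the mapping parameters needed by
#'   [map_to_oriented()].
#' @export
rotate_and_mask <- function(image, mask, axis = NULL, apex_hint) {
  stopifnot(is.matrix(image), is.logical(mask),
            all(dim(image) == dim(mask)))
  if (is.null(axis)) axis <- fit_ellipse_axis(mask)
  if (isTRUE(axis$degenerate)) {
    abort(paste0("degenerate axis (near-isotropic mask): cannot orient; ",
                 "supply an explicit angle via `axis`"),
          class = "zp_degenerate_axis")
  }
  if (length(apex_hint) != 2 || !all(is.finite(apex_hint))) {
    abort("`apex_hint` must be a finite (row, col) point",
          class = "zp_parameter_error")
  }
  phi <- 90 - axis$theta
  cen <- c(axis$centroid_col, axis$centroid_row)  # (x, y)
  # flip so the apex maps above the centroid (smaller y)
  apex_xy <- c(apex_hint[2], apex_hint[1])
  if ((rot_mat(phi) %*% (apex_xy - cen))[2] > 0) phi <- phi + 180
  h <- nrow(image); w <- ncol(image)
  corners <- rbind(c(1, 1), c(1, h), c(w, 1), c(w, h))  # (x, y)
  q <- t(rot_mat(phi) %*% (t(corners) - cen))
  qmin <- apply(q, 2, min)
  qmax <- apply(q, 2, max)
  out_w <- as.integer(ceiling(qmax[1] - qmin[1] - 1e-9)) + 1L
  out_h <- as.integer(ceiling(qmax[2] - qmin[2] - 1e-9)) + 1L
  # inverse map: output pixel (x', y') -> source (x, y)
  xs <- seq_len(out_w) + qmin[1] - 1
  ys <- seq_len(out_h) + qmin[2] - 1
  qx <- matrix(xs, out_h, out_w, byrow = TRUE)
  qy <- matrix(ys, out_h, out_w)
  rinv <- rot_mat(-phi)
  src_x <- rinv[1, 1] * qx + rinv[1, 2] * qy + cen[1]
  src_y <- rinv[2, 1] * qx + rinv[2, 2] * qy + cen[2]
  raw <- bilinear_sample(image, as.vector(src_y), as.vector(src_x))
  # coverage-normalized interpolation: weight by the bilinearly sampled
  # mask so cell-edge pixels are not attenuated by the zeroed background
  wt <- bilinear_sample(mask * 1, as.vector(src_y), as.vector(src_x))
  val <- ifelse(wt > 0.2, raw / pmax(wt, 0.2), 0)
  img_rot <- matrix(val, out_h, out_w)
  mask_rot <- matrix(nearest_sample(mask, as.vector(src_y), as.vector(src_x)),
                     out_h, out_w)
  img_rot[!mask_rot] <- 0
  rows_with <- which(rowSums(mask_rot) > 0)
  if (length(rows_with) == 0) {
    abort("rotation produced an empty mask", class = "zp_mask_error")
  }
  structure(
    list(image = img_rot, mask = mask_rot,
         tip_row = min(rows_with), base_row = max(rows_with),
         angle_deg = phi %% 360, axis = axis,
         .cen = cen, .qmin = qmin, .phi = phi),
    class = "zp_oriented"
  )
}

#' Map raw-frame points into an oriented cell's coordinates
#'
#' Applies the same rotation used by [rotate_and_mask()] to annotated points
#' (e.g. a manually marked division-plane position) so they can be measured
#' in the apex-up frame.
#'
#' @param oriented A `zp_oriented` object.
#' @param points Data frame with `row` and `col` columns (raw coordinates).
#' @return A tibble with `row` and `col` in oriented-image coordinates.
#' @export
map_to_oriented <- function(oriented, points) {
  stopifnot(inherits(oriented, "zp_oriented"))
  p <- rbind(points$col, points$row)  # (x, y) columns
  q <- rot_mat(oriented$.phi) %*% (p - oriented$.cen)
  tibble(row = q[2, ] - oriented$.qmin[2] + 1,
         col = q[1, ] - oriented$.qmin[1] + 1)
}

#' @export
print.zp_oriented <- function(x, ...) {
  cat(sprintf(
    "<zp_oriented> %d x %d px  tip_row=%d base_row=%d  rotated %.2f deg\n",
    nrow(x$image), ncol(x$image), x$tip_row, x$base_row, x$angle_deg))
  invisible(x)
}
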