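# Programmatic image fixtures.  The capsule renderer here is written
# independently of the package's synthetic-data module so geometry tests do
# not check the generator against itself.

# Filled axis-aligned rectangle mask centred in a canvas.
rect_mask <- function(canvas = c(101, 101), h = 61, w = 21) {
  m <- matrix(FALSE, canvas[1], canvas[2])
  r0 <- (canvas[1] - h) %/% 2 + 1
  c0 <- (canvas[2] - w) %/% 2 + 1
  m[r0:(r0 + h - 1), c0:(c0 + w - 1)] <- TRUE
  m
}

# Rectangle of half-extents (a, b) rasterized after rotation by `angle_deg`
# (angle of the long axis from the horizontal, toward increasing row).
rotated_rect_mask <- function(canvas = c(151, 151), a = 50, b = 12,
                              angle_deg = 30) {
  cen <- (canvas + 1) / 2
  th <- angle_deg * pi / 180
  r <- matrix(seq_len(canvas[1]), canvas[1], canvas[2]) - cen[1]
  cc <- matrix(seq_len(canvas[2]), canvas[1], canvas[2], byrow = TRUE) - cen[2]
  # coordinates along / across the long axis (x = col, y = row)
  along <- cc * cos(th) + r * sin(th)
  across <- -cc * sin(th) + r * cos(th)
  abs(along) <= a & abs(across) <= b
}

disc_mask <- function(canvas = c(81, 81), radius = 30) {
  cen <- (canvas + 1) / 2
  r <- matrix(seq_len(canvas[1]), canvas[1], canvas[2]) - cen[1]
  cc <- matrix(seq_len(canvas[2]), canvas[1], canvas[2], byrow = TRUE) - cen[2]
  sqrt(r^2 + cc^2) <= radius
}

# Capsule-shaped cell with axial density f(u), u = 0 at the apex, rendered
# at `angle_deg`; returns the 2-d image, mask and exact apex point.
capsule_cell <- function(length_px = 90, width_px = 30, angle_deg = 0,
                         f = function(u) 0.2 + u, canvas = c(162, 162)) {
  cen <- (canvas + 1) / 2
  th <- angle_deg * pi / 180
  dirv <- c(cos(th), sin(th))  # (x, y)
  r <- matrix(seq_len(canvas[1]), canvas[1], canvas[2]) - cen[1]
  cc <- matrix(seq_len(canvas[2]), canvas[1], canvas[2], byrow = TRUE) - cen[2]
  axial <- cc * dirv[1] + r * dirv[2]
  transv <- -cc * dirv[2] + r * dirv[1]
  half <- length_px / 2
  radius <- width_px / 2
  da <- pmax(0, abs(axial) - (half - radius))
  mask <- sqrt(da^2 + transv^2) <= radius
  u <- pmin(1, pmax(0, (axial + half) / length_px))
  img <- matrix(0, canvas[1], canvas[2])
  img[mask] <- f(u[mask])
  apex <- c(cen[1] - half * dirv[2], cen[2] - half * dirv[1])  # (row, col)
  list(image = img, mask = mask, apex = apex)
}

# Foreground connectivity and hole check: every row-run and column-run of
# TRUE pixels must be a single interval (holds for convex shapes; implies
# no interior holes).
runs_contiguous <- function(mask) {
  one_run <- function(v) {
    w <- which(v)
    length(w) == 0 || all(diff(w) == 1)
  }
  all(apply(mask, 1, one_run)) && all(apply(mask, 2, one_run))
}

# Tiny synthetic config used by unit tests (small canvas, quick).
tiny_config <- function(...) {
  probes <- tibble::tibble(
    probe = c("microtubules", "vacuolar_membranes"),
    template = c("apical_band", "basal_gradient"),
    scale = c(NA, 0.015),
    band_sd = c(0.06, NA)
  )
  synthetic_config(probes = probes, n_replicates = 1, k_timepoints = 3,
                   initial_length_px = 40, final_length_px = 60,
                   width_px = 16, z_slices = 3, ...)
}
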