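#' Planted axial density templates
#'
#' Closed-form axial fluorescence densities used by the synthetic-data
#' generator, defined on the relative axial coordinate `u` in `[0, 1]`
#' (0 = apical tip, 1 = basal end) with planted compartment boundary `b`:
#'
#' * `uniform`: constant 1 (dispersed, mitochondria-like).
#' * `apical_band`: Gaussian bump of width `band_sd` centred at `u = b / 2`,
#'   the midpoint of the apical compartment, on top of `baseline`
#'   (subapical cortical microtubule band).
#' * `basal_gradient`: logistic rise of steepness `scale` centred at
#'   `u = b` on top of `baseline`; at `u = b` the value is exactly
#'   `baseline + amplitude / 2` (basal vacuolar / actin enrichment).
#'
#' @param u Relative axial positions in `[0, 1]`.
#' @param template One of `"uniform"`, `"apical_band"`, `"basal_gradient"`.
#' @param b Planted boundary fraction in `(0, 1)`.
#' @param baseline,amplitude Additive baseline and peak amplitude.
#' @param scale Logistic steepness of `basal_gradient`.
#' @param band_sd Gaussian width of `apical_band`.
#' @return Density values, same length as `u`.
#' @export
planted_density <- function(u, template, b = 0.436, baseline = 0.2,
                            amplitude = 1, scale = 0.1, band_sd = 0.1) {
  if (any(u < 0 | u > 1)) {
    abort("`u` must lie in [0, 1]", class = "zp_parameter_error")
  }
  switch(template,
    uniform = rep(1, length(u)),
    apical_band = baseline + amplitude * exp(-(u - b / 2)^2 / (2 * band_sd^2)),
    basal_gradient = baseline + amplitude * stats::plogis((u - b) / scale),
    abort(sprintf("unknown template '%s'", template),
          class = "zp_parameter_error")
  )
}

default_probe_table <- function() {
  tibble(
    probe = zygote_probes,
    template = c("basal_gradient", "uniform", "apical_band",
                 "basal_gradient"),
    scale = c(0.03, NA, NA, 0.015),
    band_sd = c(NA, NA, 0.06, NA)
  )
}

#' Probe table with a single boundary-signal carrier
#'
#' Variant of the default probe table in which the vacuolar-membrane probe
#' is the only one carrying the compartment-boundary gradient (actin is
#' uniform here); microtubules keep their subapical band and mitochondria
#' stay uniform.  Used for importance-attribution studies where the probe
#' carrying the planted boundary signal must be unique by construction.
#'
#' @return Tibble in the format of the `probes` field of
#'   [synthetic_config()].
#' @export
single_marker_probe_table <- function() {
  tibble(
    probe = zygote_probes,
    template = c("uniform", "uniform", "apical_band", "basal_gradient"),
    scale = c(NA, NA, NA, 0.015),
    band_sd = c(NA, NA, 0.06, NA)
  )
}

#' Configuration for the synthetic zygote dataset generator
#'
#' Defaults emulate the full study design: four probes (actin filaments and
#' vacuolar membranes basally enriched, the vacuolar gradient being the
#' sharpest marker of the compartment boundary; microtubules forming a
#' subapical band at half the apical compartment; mitochondria uniform),
#' three biological replicates, ten normalized time points, a planted
#' boundary at 43.6% of cell length, linear elongation from 90 to 180 px,
#' random in-plane rotation per movie, and Gaussian noise with SD equal to
#' 10% of the peak cell signal.
#'
#' @param probes Tibble with columns `probe`, `template` and optional
#'   per-probe `scale`/`band_sd`; default [zygote_probes] templates above.
#' @param n_replicates Biological replicates per probe (default 3).
#' @param k_timepoints Frames per movie = normalized time points
#'   (default 10).
#' @param boundary_fraction Planted boundary `b` in `(0, 1)`
#'   (default 0.436).
#' @param initial_length_px,final_length_px Cell length at the first and
#'   last frame (defaults 90, 180; must be >= 20).
#' @param width_px Cell width (default 40).
#' @param z_slices Z slices per frame (default 7).
#' @param rotation_angles Per-movie in-plane angles in degrees, recycled
#'   over movies; `NULL` (default) draws each uniformly from `[0, 180)`.
#' @param noise_sd_frac Gaussian noise SD as a fraction of the peak cell
#'   signal (default 0.10).
#' @param poisson Add Poisson shot noise (default `FALSE`).
#' @param division_jitter_pct SD (percentage points) of the planted
#'   division-plane position around half the boundary (default 2.15).
#' @param seed Integer RNG seed (default 1).
#' @return A validated `zp_config` list.
#' @export
synthetic_config <- function(probes = default_probe_table(),
                             n_replicates = 3,
                             k_timepoints = 10,
                             boundary_fraction = 0.436,
                             initial_length_px = 90,
                             final_length_px = 180,
                             width_px = 40,
                             z_slices = 7,
                             rotation_angles = NULL,
                             noise_sd_frac = 0.10,
                             poisson = FALSE,
                             division_jitter_pct = 2.15,
                             seed = 1) {
  cfg <- list(
    probes = probes,
    n_replicates = check_scalar_count(n_replicates, "n_replicates"),
    k_timepoints = check_scalar_count(k_timepoints, "k_timepoints", min = 2L),
    boundary_fraction = boundary_fraction,
    initial_length_px = initial_length_px,
    final_length_px = final_length_px,
    width_px = width_px,
    z_slices = check_scalar_count(z_slices, "z_slices"),
    rotation_angles = rotation_angles,
    noise_sd_frac = noise_sd_frac,
    poisson = isTRUE(poisson),
    division_jitter_pct = division_jitter_pct,
    seed = check_scalar_count(seed, "seed", min = 0L)
  )
  if (!is.data.frame(probes) ||
      !all(c("probe", "template") %in% names(probes))) {
    abort("`probes` must be a data frame with `probe` and `template`",
          class = "zp_config_error")
  }
  if (!(boundary_fraction > 0 && boundary_fraction < 1)) {
    abort("boundary_fraction must lie strictly in (0, 1)",
          class = "zp_config_error")
  }
  if (initial_length_px < 20 || final_length_px < initial_length_px) {
    abort("cell lengths must be >= 20 px with final >= initial",
          class = "zp_config_error")
  }
  if (width_px < 4 || width_px > initial_length_px) {
    abort("width_px must be in [4, initial_length_px]",
          class = "zp_config_error")
  }
  if (noise_sd_frac < 0) {
    abort("noise_sd_frac must be >= 0", class = "zp_config_error")
  }
  structure(cfg, class = "zp_config")
}

# Density function for one probe row of the config table.
probe_density_fun <- function(cfg, probe_row) {
  template <- probe_row$template
  b <- cfg$boundary_fraction
  sc <- probe_row$scale
  bs <- probe_row$band_sd
  function(u) {
    planted_density(u, template, b = b,
                    scale = if (is.null(sc) || is.na(sc)) 0.1 else sc,
                    band_sd = if (is.null(bs) || is.na(bs)) 0.1 else bs)
  }
}

# Render one frame: a capsule of given length/width at `angle_deg`, centred
# on the canvas, carrying axial density f(u) (u = 0 at the apex), extruded
# over z with a hemispheric cross-section so the noiseless MIP equals the
# 2-d render.  Returns the (z, row, col) stack, the 2-d render, the mask,
# and the apex (row, col).
render_cell_frame <- function(length_px, width_px, angle_deg, canvas,
                              density_fun, z_slices) {
  h <- canvas[1]; w <- canvas[2]
  cen <- c((w + 1) / 2, (h + 1) / 2)        # (x, y)
  a_rad <- angle_deg * pi / 180
  dir <- c(cos(a_rad), sin(a_rad))          # axis unit vector, apex at -L/2
  x <- matrix(seq_len(w), h, w, byrow = TRUE) - cen[1]
  y <- matrix(seq_len(h), h, w) - cen[2]
  axial <- x * dir[1] + y * dir[2]
  transv <- -x * dir[2] + y * dir[1]
  half <- length_px / 2
  radius <- width_px / 2
  seg_half <- half - radius
  da <- pmax(0, abs(axial) - seg_half)
  dist <- sqrt(da^2 + transv^2)
  mask <- dist <= radius
  u <- pmin(1, pmax(0, (axial + half) / length_px))
  img <- matrix(0, h, w)
  img[mask] <- density_fun(u[mask])
  zc <- (z_slices + 1) / 2
  thick <- matrix(0, h, w)
  thick[mask] <- (z_slices / 2) * sqrt(pmax(0, 1 - (dist[mask] / radius)^2))
  stack <- array(0, dim = c(z_slices, h, w))
  for (z in seq_len(z_slices)) {
    occ <- abs(z - zc) <= thick & mask
    sl <- matrix(0, h, w)
    sl[occ] <- img[occ]
    stack[z, , ] <- sl
  }
  apex_xy <- cen - half * dir
  list(stack = stack, render = img, mask = mask,
       apex = c(apex_xy[2], apex_xy[1]))
}

#' Simulate a synthetic zygote time-lapse dataset in memory
#'
#' For each (probe, replicate) movie, a capsule-shaped cell elongates
#' linearly from the initial to the final length over `k` frames, rendered
#' at the movie's rotation angle with its planted axial density fixed in
#' relative coordinates across frames (the distribution pattern is
#' maintained through elongation).  Gaussian (optionally Poisson) noise is
#' added voxel-wise; masks are the noiseless support.  A division-plane
#' point is planted on the final frame at half the boundary fraction plus
#' jitter.  Fixing the seed reproduces the dataset exactly.
#'
#' @param config A [synthetic_config()].
#' @return A `zp_dataset`: `entries` tibble (one row per movie, holding the
#'   [zygote_stack()], per-frame masks, apex and division-plane
#'   annotations), `probes`, and `ground_truth` (boundary fraction, angles,
#'   planted division fractions, templates).
#' @export
simulate_dataset <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "zp_config"))
  set.seed(config$seed)
  k <- config$k_timepoints
  n_movies <- nrow(config$probes) * config$n_replicates
  angles <- config$rotation_angles
  if (is.null(angles)) {
    angles <- runif(n_movies) * 180
  } else {
    angles <- rep_len(angles, n_movies)
  }
  canvas_side <- 2L * ceiling(config$final_length_px / 2) + 8L
  canvas <- c(canvas_side, canvas_side)
  lengths <- config$initial_length_px +
    (seq_len(k) - 1) / (k - 1) *
      (config$final_length_px - config$initial_length_px)
  entries <- list()
  gt_movies <- list()
  m <- 0L
  for (p in seq_len(nrow(config$probes))) {
    fdens <- probe_density_fun(config, config$probes[p, ])
    for (r in seq_len(config$n_replicates)) {
      m <- m + 1L
      angle <- angles[m]
      arr <- array(0, dim = c(k, config$z_slices, canvas[1], canvas[2]))
      masks <- vector("list", k)
      apex_row <- apex_col <- numeric(k)
      peak <- 0
      for (t in seq_len(k)) {
        fr <- render_cell_frame(lengths[t], config$width_px, angle, canvas,
                                fdens, config$z_slices)
        arr[t, , , ] <- fr$stack
        masks[[t]] <- fr$mask
        apex_row[t] <- fr$apex[1]
        apex_col[t] <- fr$apex[2]
        peak <- max(peak, max(fr$render))
      }
      if (config$noise_sd_frac > 0) {
        arr <- arr + rnorm(length(arr), sd = config$noise_sd_frac * peak)
      }
      if (config$poisson) {
        arr <- rpois(length(arr), lambda = pmax(arr, 0) * 100) / 100
        dim(arr) <- c(k, config$z_slices, canvas[1], canvas[2])
      }
      arr[arr < 0] <- 0
      # planted division plane on the final raw frame
      frac <- config$boundary_fraction / 2 +
        rnorm(1, sd = config$division_jitter_pct / 100)
      frac <- min(0.95, max(0.02, frac))
      a_rad <- angle * pi / 180
      cen <- c((canvas[2] + 1) / 2, (canvas[1] + 1) / 2)
      plane_xy <- cen + (frac - 0.5) * lengths[k] * c(cos(a_rad), sin(a_rad))
      rep_id <- sprintf("r%d", r)
      entries[[m]] <- tibble(
        probe = config$probes$probe[p],
        replicate_id = rep_id,
        stack = list(zygote_stack(arr, probe = config$probes$probe[p],
                                  replicate_id = rep_id)),
        onset_frame = 1L,
        predivision_frame = k,
        masks_per = "selected",
        masks = list(masks),
        apex = list(list(frame = seq_len(k), row = apex_row, col = apex_col)),
        division_plane = list(list(frame = k, row = plane_xy[2],
                                   col = plane_xy[1]))
      )
      gt_movies[[m]] <- tibble(
        probe = config$probes$probe[p], replicate_id = rep_id,
        angle_deg = angle, division_fraction = frac,
        template = config$probes$template[p]
      )
    }
  }
  structure(
    list(entries = bind_rows(entries),
         probes = config$probes$probe,
         ground_truth = list(
           boundary_fraction = config$boundary_fraction,
           movies = bind_rows(gt_movies),
           config = config)),
    class = "zp_dataset"
  )
}

#' @export
print.zp_dataset <- function(x, ...) {
  cat(sprintf("<zp_dataset> %d movies (%d probes), %d frames each\n",
              nrow(x$entries), length(unique(x$entries$probe)),
              x$entries$predivision_frame[1]))
  invisible(x)
}

#' Write a synthetic dataset to disk
#'
#' Materializes [simulate_dataset()] output as the on-disk contract consumed
#' by [read_manifest()]/[read_dataset()]: multi-page float TIFF stacks with
#' JSON sidecars, PNG masks (one per selected time point), a YAML manifest
#' carrying the event-frame, apex and division-plane annotations, and a
#' ground-truth JSON.
#'
#' @param config A [synthetic_config()].
#' @param dir Output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
generate_dataset <- function(config = synthetic_config(), dir) {
  ds <- simulate_dataset(config)
  dir.create(file.path(dir, "stacks"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "masks"), recursive = TRUE, showWarnings = FALSE)
  entries_yaml <- list()
  for (i in seq_len(nrow(ds$entries))) {
    e <- ds$entries[i, ]
    base <- sprintf("%s_%s", e$probe, e$replicate_id)
    stack_rel <- file.path("stacks", paste0(base, ".tif"))
    write_stack(e$stack[[1]], file.path(dir, stack_rel))
    mask_rel <- vapply(seq_along(e$masks[[1]]), function(t) {
      p <- file.path("masks", sprintf("%s_T%d.png", base, t - 1))
      write_mask(e$masks[[1]][[t]], file.path(dir, p))
      p
    }, "")
    entries_yaml[[i]] <- list(
      stack = stack_rel, probe = e$probe, replicate_id = e$replicate_id,
      onset_frame = e$onset_frame, predivision_frame = e$predivision_frame,
      masks = as.list(mask_rel),
      apex = e$apex[[1]],
      division_plane = e$division_plane[[1]]
    )
  }
  manifest_path <- file.path(dir, "manifest.yaml")
  yaml::write_yaml(list(probes = as.list(ds$probes),
                        entries = entries_yaml), manifest_path)
  gt <- ds$ground_truth
  jsonlite::write_json(
    list(boundary_fraction = gt$boundary_fraction,
         movies = gt$movies,
         seed = gt$config$seed),
    file.path(dir, "ground_truth.json"),
    auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(manifest_path)
}

#' Load a dataset from a manifest into memory
#'
#' @param manifest_path Path to a manifest YAML (see [read_manifest()]).
#' @return A `zp_dataset` with all stacks and masks loaded.
#' @export
read_dataset <- function(manifest_path) {
  man <- read_manifest(manifest_path)
  entries <- list()
  for (i in seq_len(nrow(man))) {
    e <- man[i, ]
    entries[[i]] <- tibble(
      probe = e$probe, replicate_id = e$replicate_id,
      stack = list(read_stack(e$stack_path, probe = e$probe,
                              replicate_id = e$replicate_id)),
      onset_frame = e$onset_frame,
      predivision_frame = e$predivision_frame,
      masks_per = e$masks_per,
      masks = list(lapply(e$mask_paths[[1]], read_mask)),
      apex = e$apex,
      division_plane = e$division_plane
    )
  }
  structure(
    list(entries = bind_rows(entries), probes = attr(man, "probes"),
         ground_truth = NULL),
    class = "zp_dataset"
  )
}

#' Simulate normalized profiles directly (profile-level fast path)
#'
#' Generates z-scored, length-standardized profiles from the planted
#' templates without rendering images: each (probe, replicate, timepoint)
#' profile is the template sampled at the frame's cell length plus Gaussian
#' noise attenuated by row averaging over the cell width
#' (`SD = noise_sd_frac * peak / sqrt(width_px)`), then resampled to `L`
#' and z-scored.  Used for large simulation studies (e.g. boundary-recovery
#' sweeps) where rendering every voxel would dominate the runtime; the
#' imaging steps themselves are exercised by [simulate_dataset()].
#'
#' @param config A [synthetic_config()].
#' @param L Standard profile length (default 110).
#' @return Long profile tibble as from [extract_profiles()].
#' @export
simulate_profiles <- function(config = synthetic_config(), L = 110) {
  stopifnot(inherits(config, "zp_config"))
  set.seed(config$seed)
  k <- config$k_timepoints
  lengths <- round(config$initial_length_px +
    (seq_len(k) - 1) / (k - 1) *
      (config$final_length_px - config$initial_length_px))
  out <- list()
  for (p in seq_len(nrow(config$probes))) {
    fdens <- probe_density_fun(config, config$probes[p, ])
    for (r in seq_len(config$n_replicates)) {
      for (t in seq_len(k)) {
        n <- lengths[t]
        u <- (seq_len(n) - 1) / (n - 1)
        v <- fdens(u)
        if (config$noise_sd_frac > 0) {
          v <- v + rnorm(n, sd = config$noise_sd_frac * max(v) /
                           sqrt(config$width_px))
        }
        prof <- zscore_profile(resample_profile(v, L = L))
        out[[length(out) + 1]] <- mutate(
          prof, probe = config$probes$probe[p],
          replicate_id = sprintf("r%d", r), timepoint = t - 1L, .before = 1)
      }
    }
  }
  bind_rows(out)
}
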