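test_that("planted densities honour their closed forms", {
  u <- seq(0, 1, length.out = 1001)
  expect_true(all(planted_density(u, "uniform") == 1))
  b <- 0.436
  expect_equal(planted_density(b, "basal_gradient", b = b, baseline = 0.2,
                               amplitude = 1),
               0.2 + 0.5)
  band <- planted_density(u, "apical_band", b = b, band_sd = 0.06)
  expect_lt(abs(u[which.max(band)] - b / 2), 1e-3 + 1e-12)
  expect_error(planted_density(1.2, "uniform"), "\\[0, 1\\]")
  expect_error(planted_density(0.5, "nonsense"), "unknown template")
})

test_that("the generator is reproducible and validates its configuration", {
  a <- simulate_dataset(tiny_config(seed = 5))
  b <- simulate_dataset(tiny_config(seed = 5))
  expect_identical(a$entries$stack[[1]]$intensity,
                   b$entries$stack[[1]]$intensity)
  expect_identical(a$ground_truth$movies, b$ground_truth$movies)
  c2 <- simulate_dataset(tiny_config(seed = 6))
  expect_false(identical(a$entries$stack[[1]]$intensity,
                         c2$entries$stack[[1]]$intensity))
  expect_error(synthetic_config(boundary_fraction = 1.2), "strictly in")
  expect_error(synthetic_config(initial_length_px = 10), ">= 20")
  expect_error(synthetic_config(noise_sd_frac = -1), ">= 0")
})

test_that("generated masks are connected with no interior holes", {
  ds <- simulate_dataset(tiny_config(seed = 8))
  for (i in seq_len(nrow(ds$entries))) {
    for (m in ds$entries$masks[[i]]) {
      expect_true(any(m))
      expect_true(runs_contiguous(m))
    }
  }
})

test_that("the noiseless MIP equals the 2-d render and recovers the template", {
  probes <- tibble::tibble(probe = "vacuolar_membranes",
                           template = "basal_gradient",
                           scale = 0.05, band_sd = NA)
  # angle 90: the axis already lies vertical, so orientation is an exact
  # identity and the comparison isolates rendering + normalization
  cfg <- synthetic_config(probes = probes, n_replicates = 1, k_timepoints = 2,
                          initial_length_px = 90, final_length_px = 120,
                          width_px = 30, z_slices = 5, noise_sd_frac = 0,
                          rotation_angles = 90, seed = 2)
  ds <- simulate_dataset(cfg)
  st <- ds$entries$stack[[1]]$intensity
  frame1 <- st[1, , , , drop = TRUE]
  dim(frame1) <- dim(st)[2:4]
  mip <- max_intensity_projection(frame1)
  mask <- ds$entries$masks[[1]][[1]]
  # MIP support equals the mask and carries the axial density
  expect_identical(mip > 0, mask)
  prof <- extract_profiles(ds, L = 110, k = 2)
  p0 <- prof$intensity[prof$timepoint == 0]
  # oracle: template at the mask rows' pixel-centre coordinates, resampled
  n <- sum(apply(mask, 1, any))
  u <- (seq_len(n) - 0.5) / n
  expected <- zscore_profile(resample_profile(
    planted_density(u, "basal_gradient", b = cfg$boundary_fraction,
                    scale = 0.05), 110))$intensity
  expect_lt(max(abs(p0 - expected)), 1e-3)
})

test_that("degenerate templates exercise the contracted error paths", {
  probes <- tibble::tibble(probe = "mitochondria", template = "uniform",
                           scale = NA, band_sd = NA)
  cfg <- synthetic_config(probes = probes, n_replicates = 1, k_timepoints = 2,
                          initial_length_px = 40, final_length_px = 50,
                          width_px = 16, z_slices = 3, noise_sd_frac = 0,
                          rotation_angles = 0, seed = 1)
  ds <- simulate_dataset(cfg)
  # a noiseless uniform cell has a flat profile: z-scoring must refuse it
  expect_error(extract_profiles(ds, L = 30, k = 2), "flat")
})

test_that("noiseless basal gradients yield strictly increasing profiles", {
  probes <- tibble::tibble(probe = "vacuolar_membranes",
                           template = "basal_gradient", scale = 0.1,
                           band_sd = NA)
  cfg <- synthetic_config(probes = probes, n_replicates = 1, k_timepoints = 2,
                          initial_length_px = 60, final_length_px = 80,
                          width_px = 20, z_slices = 3, noise_sd_frac = 0,
                          rotation_angles = 0, seed = 1)
  prof <- extract_profiles(simulate_dataset(cfg), L = 110, k = 2)
  for (t in 0:1) {
    expect_true(all(diff(prof$intensity[prof$timepoint == t]) > 0))
  }
})

test_that("profile-level simulation matches the design grid", {
  prof <- simulate_profiles(synthetic_config(seed = 3), L = 110)
  expect_identical(nrow(prof), 110L * 120L)
  fm <- assemble_feature_matrix(prof)
  expect_identical(dim(fm$values), c(110L, 120L))
  expect_identical(unique(fm$features$probe), zygote_probes)
})
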