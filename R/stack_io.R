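#' Construct a zygote image stack
#'
#' A `zygote_stack` holds one time-lapse movie of a single zygote as a
#' 4-dimensional intensity array indexed `(frame, z, row, col)`, together
#' with probe and acquisition metadata.  Row index increases downward, so an
#' apex-up oriented cell has its tip at small row indices.
#'
#' @param intensity 4-d numeric array `(frame, z, row, col)`; all values
#'   must be finite and non-negative.
#' @param probe Probe label, e.g. one of [zygote_probes] or a free label.
#' @param replicate_id Biological replicate identifier.
#' @param frame_interval_min Acquisition interval in minutes (metadata only).
#' @param z_step_um Z-step in micrometres (metadata only).
#'
#' @return An object of class `zygote_stack`.
#' @export
zygote_stack <- function(intensity, probe = "unknown", replicate_id = "r1",
                         frame_interval_min = NA_real_, z_step_um = NA_real_) {
  if (!is.array(intensity) || length(dim(intensity)) != 4) {
    abort("`intensity` must be a 4-d array (frame, z, row, col)",
          class = "zp_stack_error")
  }
  if (any(dim(intensity) < 1)) {
    abort("all stack extents must be >= 1", class = "zp_stack_error")
  }
  if (!all(is.finite(intensity)) || any(intensity < 0)) {
    abort("stack intensities must be finite and non-negative",
          class = "zp_stack_error")
  }
  structure(
    list(intensity = intensity, probe = probe, replicate_id = replicate_id,
         frame_interval_min = frame_interval_min, z_step_um = z_step_um),
    class = "zygote_stack"
  )
}

#' @export
print.zygote_stack <- function(x, ...) {
  d <- dim(x$intensity)
  cat(sprintf(
    "<zygote_stack> probe=%s replicate=%s  %d frames x %d z x %d x %d px\n",
    x$probe, x$replicate_id, d[1], d[2], d[3], d[4]))
  invisible(x)
}

#' @export
dim.zygote_stack <- function(x) dim(x$intensity)

sidecar_path <- function(path) paste0(path, ".json")

#' Write a zygote stack to a multi-page TIFF
#'
#' Pages are ordered frame-major (all z slices of frame 1, then frame 2, ...).
#' Intensities are stored as 32-bit float scaled into `[0, 1]` by an exact
#' power-of-two factor; the factor and the `(frame, z)` page layout are
#' recorded in a JSON sidecar (`<path>.json`) so that [read_stack()] never
#' has to guess the axis layout.  Samples are quantized to 32-bit
#' resolution (about 5e-10 relative error); integer-valued stacks (the
#' common camera output) are flagged in the sidecar and restored exactly.
#'
#' @param stack A [zygote_stack()].
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "zygote_stack"))
  d <- dim(stack$intensity)
  scale <- pow2_scale(max(stack$intensity))
  pages <- vector("list", d[1] * d[2])
  i <- 1L
  for (t in seq_len(d[1])) {
    for (z in seq_len(d[2])) {
      pages[[i]] <- stack$intensity[t, z, , , drop = TRUE] / scale
      dim(pages[[i]]) <- d[3:4]
      i <- i + 1L
    }
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  meta <- list(
    n_frames = d[1], n_z = d[2], scale = scale,
    integer_valued = all(stack$intensity == round(stack$intensity)),
    probe = stack$probe, replicate_id = stack$replicate_id,
    frame_interval_min = stack$frame_interval_min, z_step_um = stack$z_step_um
  )
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA, null = "null", na = "null")
  invisible(path)
}

#' Read a zygote stack from a multi-page TIFF
#'
#' The page order must encode `(frame, z)` frame-major.  The layout is taken
#' from, in order of precedence: the explicit `n_frames`/`n_z` arguments, the
#' JSON sidecar written by [write_stack()], or -- failing both -- the read
#' aborts with an "axis inference failed" error rather than silently guessing.
#'
#' @param path TIFF path.
#' @param n_frames,n_z Optional explicit page layout (one may be omitted if
#'   the other divides the page count).
#' @param probe,replicate_id Optional metadata overrides (e.g. from a
#'   manifest); defaults come from the sidecar when present.
#' @return A [zygote_stack()].
#' @export
read_stack <- function(path, n_frames = NULL, n_z = NULL,
                       probe = NULL, replicate_id = NULL) {
  if (!file.exists(path)) {
    abort(sprintf("cannot read stack: no such file '%s'", path),
          class = "zp_io_error")
  }
  info <- tiff::readTIFF(path, payload = FALSE)
  bits <- info$bits.per.sample[1]
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  # integer TIFFs come back normalized to [0, 1]; undo that so 8/16-bit
  # data keep their raw counts (32-bit pages are floats, stored as-is)
  if (bits %in% c(8L, 16L)) {
    pages <- lapply(pages, function(p) p * (2^bits - 1))
  }
  n_pages <- length(pages)
  meta <- NULL
  if (file.exists(sidecar_path(path))) {
    meta <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
  }
  n_frames <- n_frames %||% meta$n_frames
  n_z <- n_z %||% meta$n_z
  if (is.null(n_frames) && is.null(n_z)) {
    abort(paste0(
      "axis inference failed: cannot split ", n_pages, " TIFF page(s) into ",
      "(frame, z) without `n_frames`/`n_z` or a sidecar; refusing to guess"),
      class = "zp_axis_error")
  }
  if (is.null(n_frames)) n_frames <- n_pages / n_z
  if (is.null(n_z)) n_z <- n_pages / n_frames
  if (n_frames * n_z != n_pages ||
      n_frames != as.integer(n_frames) || n_z != as.integer(n_z)) {
    abort(sprintf(
      "axis inference failed: %d pages do not factor as %s frames x %s z",
      n_pages, format(n_frames), format(n_z)), class = "zp_axis_error")
  }
  n_frames <- as.integer(n_frames); n_z <- as.integer(n_z)
  dpage <- dim(pages[[1]])
  scale <- meta$scale %||% 1
  arr <- array(0, dim = c(n_frames, n_z, dpage[1], dpage[2]))
  i <- 1L
  for (t in seq_len(n_frames)) {
    for (z in seq_len(n_z)) {
      arr[t, z, , ] <- pages[[i]] * scale
      i <- i + 1L
    }
  }
  if (isTRUE(meta$integer_valued)) arr <- round(arr)
  zygote_stack(
    arr,
    probe = probe %||% meta$probe %||% "unknown",
    replicate_id = replicate_id %||% meta$replicate_id %||% "r1",
    frame_interval_min = meta$frame_interval_min %||% NA_real_,
    z_step_um = meta$z_step_um %||% NA_real_
  )
}

#' Read a binary cell mask
#'
#' Accepts single-page TIFF or PNG images with exactly two spatial axes.
#' Any pixel with a value greater than zero is foreground.
#'
#' @param path Mask image path (`.png`, `.tif`, `.tiff`).
#' @return A logical matrix with at least one `TRUE` pixel.
#' @export
read_mask <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("cannot read mask: no such file '%s'", path),
          class = "zp_io_error")
  }
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path, as.is = TRUE),
    abort(sprintf("unsupported mask format '.%s'", ext), class = "zp_io_error")
  )
  if (length(dim(img)) == 3 && dim(img)[3] >= 1) {
    img <- img[, , 1]  # collapse grey+alpha / RGB to first channel
  }
  if (length(dim(img)) != 2) {
    abort("mask image must have exactly 2 axes", class = "zp_mask_error")
  }
  m <- img > 0
  if (!any(m)) {
    abort(sprintf("empty mask: '%s' contains no foreground pixels", path),
          class = "zp_mask_error")
  }
  m
}

#' Write a binary mask as PNG (or single-page TIFF)
#'
#' @param mask Logical matrix.
#' @param path Output path; format chosen by extension.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  stopifnot(is.logical(mask), length(dim(mask)) == 2)
  img <- matrix(as.numeric(mask), nrow(mask), ncol(mask))
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png = png::writePNG(img, path),
    tif = ,
    tiff = tiff::writeTIFF(img, path, bits.per.sample = 8L),
    abort(sprintf("unsupported mask format '.%s'", ext), class = "zp_io_error")
  )
  invisible(path)
}

#' Read and validate a dataset manifest
#'
#' The manifest is a YAML file declaring, per movie: the stack path, probe,
#' replicate, the manually annotated elongation-onset and pre-division frames
#' (1-based), the mask paths (one per selected time point under `masks:`, or
#' one per raw frame under `raw_masks:`), an apex hint, and optionally a
#' division-plane point annotation.  All invariant violations across all
#' entries are collected and reported together.
#'
#' @param path Manifest YAML path.
#' @return A `zp_manifest`: a tibble with one row per movie and attributes
#'   `probes` (declared probe order) and `root` (directory for relative
#'   paths).
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("cannot read manifest: no such file '%s'", path),
          class = "zp_io_error")
  }
  doc <- yaml::read_yaml(path)
  root <- dirname(path)
  probes <- as.character(doc$probes %||% zygote_probes)
  entries <- doc$entries
  if (is.null(entries) || length(entries) == 0) {
    abort("manifest declares no entries", class = "zp_manifest_error")
  }
  problems <- character()
  note <- function(fmt, ...) {
    problems <<- c(problems, sprintf(fmt, ...))
  }
  rows <- vector("list", length(entries))
  for (i in seq_along(entries)) {
    e <- entries[[i]]
    id <- sprintf("entry %d (%s/%s)", i, e$probe %||% "?",
                  e$replicate_id %||% "?")
    onset <- e$onset_frame %||% NA
    prediv <- e$predivision_frame %||% NA
    if (is.na(onset) || is.na(prediv)) {
      note("%s: missing onset_frame/predivision_frame", id)
    } else if (onset >= prediv) {
      note("%s: onset_frame (%s) must be < predivision_frame (%s)",
           id, onset, prediv)
    }
    if (is.null(e$probe) || !(e$probe %in% probes)) {
      note("%s: probe '%s' not in declared probe set [%s]", id,
           e$probe %||% "", paste(probes, collapse = ", "))
    }
    stack_path <- file.path(root, e$stack %||% "")
    if (is.null(e$stack) || !file.exists(stack_path)) {
      note("%s: stack path '%s' does not exist", id, e$stack %||% "")
    }
    mask_rel <- e$masks %||% e$raw_masks
    masks_per <- if (!is.null(e$masks)) "selected" else "raw"
    if (is.null(mask_rel)) {
      note("%s: no masks or raw_masks declared", id)
      mask_paths <- character()
    } else {
      mask_paths <- file.path(root, unlist(mask_rel))
      missing <- mask_paths[!file.exists(mask_paths)]
      for (m in missing) note("%s: mask path '%s' does not exist", id, m)
    }
    apex <- e$apex
    if (is.null(apex) || is.null(apex$row) || is.null(apex$col)) {
      note("%s: missing apex annotation ({row, col} or per-frame lists)", id)
      apex <- list(row = NA_real_, col = NA_real_)
    }
    dp <- e$division_plane
    rows[[i]] <- tibble(
      probe = as.character(e$probe %||% NA),
      replicate_id = as.character(e$replicate_id %||% sprintf("r%d", i)),
      stack_path = stack_path,
      onset_frame = as.integer(onset),
      predivision_frame = as.integer(prediv),
      masks_per = masks_per,
      mask_paths = list(mask_paths),
      apex = list(apex),
      division_plane = list(dp)
    )
  }
  if (length(problems) > 0) {
    abort(c("invalid manifest:", setNames(problems, rep("x", length(problems)))),
          class = "zp_manifest_error")
  }
  out <- bind_rows(rows)
  dup <- duplicated(out[, c("probe", "replicate_id")])
  if (any(dup)) {
    abort("duplicate (probe, replicate_id) pairs in manifest",
          class = "zp_manifest_error")
  }
  structure(out, probes = probes, root = root,
            class = c("zp_manifest", class(out)))
}
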