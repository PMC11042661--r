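#' Construct a 3D image stack
#'
#' Single-channel voxel grid with anisotropic spacing, the raw input of
#' the surface-reconstruction pipeline. Intensities are arbitrary units
#' (confocal counts); the array is indexed `[x, y, z]`.
#'
#' @param intensities 3D numeric array.
#' @param voxel_spacing length-3 numeric, um per voxel in x, y, z.
#' @param channel_label text label for the fluorescence channel.
#' @return an object of class `image_stack`.
#' @export
image_stack <- function(intensities, voxel_spacing,
                        channel_label = "unknown") {
  if (!is.array(intensities) || length(dim(intensities)) != 3)
    stopf("intensities must be a 3D array")
  if (any(dim(intensities) == 0)) stopf("image stack grid is empty")
  if (!all(is.finite(intensities))) stopf("intensities must be finite")
  if (length(voxel_spacing) != 3 || any(voxel_spacing <= 0))
    stopf("voxel_spacing must be three positive values (um)")
  structure(list(intensities = intensities,
                 voxel_spacing = as.numeric(voxel_spacing),
                 channel_label = channel_label),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$intensities)
  cat(sprintf("<image_stack> %d x %d x %d voxels, %.3g x %.3g x %.3g um, channel '%s'\n",
              d[1], d[2], d[3], x$voxel_spacing[1], x$voxel_spacing[2],
              x$voxel_spacing[3], x$channel_label))
  invisible(x)
}

#' Specify how to render a height field into an image stack
#'
#' @param voxel_spacing um per voxel in x, y, z. The x and y spacings
#'   must match the height field's pixel spacing at render time.
#' @param volume_extent voxels in x, y, z, or `NULL` to size the volume
#'   automatically from the height field (x and y from the grid, z to
#'   fit the slice with a 5-voxel margin).
#' @param foreground_intensity intensity inside the fluorescent sheet.
#' @param background_intensity intensity elsewhere; must be lower than
#'   the foreground.
#' @param noise_sd standard deviation of additive Gaussian noise, same
#'   units as the intensities.
#' @param seed integer seed for the noise.
#' @return an object of class `stack_render_spec`.
#' @export
stack_render_spec <- function(voxel_spacing = c(10, 10, 5),
                              volume_extent = NULL,
                              foreground_intensity = 100,
                              background_intensity = 10,
                              noise_sd = 0,
                              seed = 1L) {
  if (length(voxel_spacing) != 3 || any(voxel_spacing <= 0))
    stopf("voxel_spacing must be three positive values (um)")
  if (foreground_intensity <= background_intensity)
    stopf("foreground_intensity must exceed background_intensity")
  if (noise_sd < 0) stopf("noise_sd must be >= 0")
  structure(list(voxel_spacing = as.numeric(voxel_spacing),
                 volume_extent = volume_extent,
                 foreground_intensity = foreground_intensity,
                 background_intensity = background_intensity,
                 noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "stack_render_spec")
}

#' Render a height field as a synthetic fluorescence stack
#'
#' Emulates a confocal acquisition of a relaxed slice: a fluorescent
#' sheet of the slice's thickness centred on the surface z(x, y), inside
#' a dark volume, plus additive Gaussian noise. Each voxel whose z
#' coordinate lies within thickness/2 of the surface (along z) in a
#' masked column receives the foreground intensity; all other voxels the
#' background. The noiseless structure is deterministic; the noise is
#' reproducible under the spec's seed.
#'
#' @param hf a [height_field()] carrying a finite `thickness`.
#' @param spec a [stack_render_spec()]; its x/y voxel spacing must equal
#'   the height field's pixel spacing.
#' @param margin_voxels minimum clearance (voxels) required between the
#'   sheet and the top/bottom of the volume. Default 3.
#' @return an [image_stack()].
#' @export
render_stack <- function(hf, spec = stack_render_spec(), margin_voxels = 3) {
  stopifnot(inherits(hf, "height_field"), inherits(spec, "stack_render_spec"))
  if (!is.finite(hf$thickness) || hf$thickness <= 0)
    stopf("height field carries no slice thickness; cannot render")
  if (any(abs(spec$voxel_spacing[1:2] - hf$pixel_spacing) > 1e-9))
    stopf("render spec x/y spacing (%g, %g) must match height-field pixel spacing (%g, %g)",
          spec$voxel_spacing[1], spec$voxel_spacing[2],
          hf$pixel_spacing[1], hf$pixel_spacing[2])
  dz <- spec$voxel_spacing[3]
  half <- hf$thickness / 2
  zr <- range(hf$z[hf$mask])

  if (is.null(spec$volume_extent)) {
    nx <- nrow(hf$z); ny <- ncol(hf$z)
    margin <- (margin_voxels + 2) * dz
    z0 <- zr[1] - half - margin
    nz <- ceiling((zr[2] + half + margin - z0) / dz) + 1
  } else {
    ext <- spec$volume_extent
    if (length(ext) != 3) stopf("volume_extent must have three entries")
    nx <- ext[1]; ny <- ext[2]; nz <- ext[3]
    if (nx != nrow(hf$z) || ny != ncol(hf$z))
      stopf("volume_extent x/y (%d, %d) must match height-field grid (%d, %d)",
            nx, ny, nrow(hf$z), ncol(hf$z))
    z0 <- zr[1] - half - (margin_voxels + 2) * dz
    lo_clear <- (zr[1] - half - z0) / dz
    hi_clear <- ((z0 + (nz - 1) * dz) - (zr[2] + half)) / dz
    if (lo_clear < margin_voxels || hi_clear < margin_voxels)
      stopf("surface exits the volume: need >= %d voxels of z margin, have %.1f (bottom) / %.1f (top)",
            margin_voxels, lo_clear, hi_clear)
  }

  zgrid <- z0 + (seq_len(nz) - 1) * dz
  vol <- array(spec$background_intensity, dim = c(nx, ny, nz))
  idx <- which(hf$mask, arr.ind = TRUE)
  zsurf <- hf$z[idx]
  # A voxel integrates fluorescence over its z extent, so voxels
  # straddling the sheet boundary receive a fractional intensity equal
  # to their overlap with [zsurf - half, zsurf + half]. This gives the
  # sheet sub-voxel edge localisation, as the finite axial PSF does in
  # a real acquisition.
  contrast <- spec$foreground_intensity - spec$background_intensity
  vlo <- zgrid - dz / 2
  for (r in seq_len(nrow(idx))) {
    overlap <- pmin(zsurf[r] + half, vlo + dz) - pmax(zsurf[r] - half, vlo)
    f <- pmin(pmax(overlap / dz, 0), 1)
    vol[idx[r, 1], idx[r, 2], ] <- spec$background_intensity + contrast * f
  }
  if (spec$noise_sd > 0) {
    rs <- .Random.seed_save()
    on.exit(.Random.seed_restore(rs))
    set.seed(spec$seed)
    vol <- vol + array(stats::rnorm(length(vol), 0, spec$noise_sd), dim(vol))
  }
  image_stack(vol, spec$voxel_spacing, channel_label = "synthetic")
}
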