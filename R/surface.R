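# Surface reconstruction: from a 3D fluorescence stack of a relaxed
# slice to a height field over the tissue footprint.

#' Segment the tissue footprint of a slice stack
#'
#' Thresholds the maximum-intensity projection along z with Otsu's
#' histogram split, fills holes, drops connected components smaller than
#' `min_object_area`, and keeps the largest remaining component. The
#' result is the 2D tissue mask over which the surface is reconstructed.
#'
#' @param stack an [image_stack()].
#' @param min_object_area smallest object to keep, in um^2 (converted to
#'   pixels with the stack's in-plane spacing). Default 0 (keep all,
#'   then select the largest).
#' @return logical matrix, the tissue mask.
#' @export
segment_tissue <- function(stack, min_object_area = 0) {
  stopifnot(inherits(stack, "image_stack"))
  mip <- apply(stack$intensities, c(1, 2), max)
  rng <- range(mip)
  if (diff(rng) <= 0) stopf("no tissue detected (uniform projection)")
  mipn <- (mip - rng[1]) / diff(rng)
  thr <- EBImage::otsu(EBImage::Image(mipn), range = c(0, 1))
  mask <- mipn > thr
  if (!any(mask)) stopf("no tissue detected")
  mask_img <- EBImage::fillHull(EBImage::Image(mask * 1))
  lab <- EBImage::bwlabel(mask_img)
  labm <- EBImage::imageData(lab)
  sizes <- tabulate(labm[labm > 0])
  min_px <- min_object_area / prod(stack$voxel_spacing[1:2])
  keep <- which(sizes >= min_px)
  if (length(keep) == 0) stopf("no tissue detected (all objects below %g um^2)",
                               min_object_area)
  largest <- keep[which.max(sizes[keep])]
  matrix(labm == largest, nrow(mip), ncol(mip))
}

#' Reconstruct the slice surface as a height field
#'
#' For every masked (x, y) column the surface height is located from the
#' bright (above-threshold) run of voxels along z:
#' \describe{
#'   \item{`centroid`}{intensity-weighted centroid of the bright run --
#'     the mid-surface of the fluorescent sheet; the default, symmetric
#'     under physical flipping and most robust to noise.}
#'   \item{`max`}{z of the brightest voxel in the column.}
#'   \item{`top`}{upper envelope of the bright run.}
#' }
#' The threshold is Otsu's split of the full stack histogram. Columns
#' with no bright voxel are in-filled from neighbouring columns and
#' counted (more than 10\% failures is an error); columns with several
#' separated bright runs use the longest run and are reported as the
#' `multi_run_fraction` (a high fraction indicates a folded slice, which
#' violates the single-valued-surface assumption). The height map is
#' finally smoothed in-plane by a Gaussian of width `smoothing_scale`
#' restricted to the mask.
#'
#' @param stack an [image_stack()].
#' @param mask logical matrix from [segment_tissue()].
#' @param method `"centroid"`, `"max"` or `"top"`.
#' @param smoothing_scale Gaussian sigma in um; `NULL` means 2 in-plane
#'   pixels. Curvature is scale-dependent, so reported indices carry
#'   this value in their provenance.
#' @return a [height_field()] with provenance (method, smoothing,
#'   failed-column and multi-run diagnostics).
#' @export
extract_height_field <- function(stack, mask,
                                 method = c("centroid", "max", "top"),
                                 smoothing_scale = NULL) {
  stopifnot(inherits(stack, "image_stack"))
  method <- match.arg(method)
  if (!any(mask)) stopf("tissue mask is empty")
  dx <- stack$voxel_spacing[1]; dy <- stack$voxel_spacing[2]
  dz <- stack$voxel_spacing[3]
  if (is.null(smoothing_scale)) smoothing_scale <- 2 * dx

  vol <- stack$intensities
  rng <- range(vol)
  if (diff(rng) <= 0) stopf("no tissue detected (uniform stack)")
  # flatten: Otsu is histogram-based, and EBImage thresholds per frame
  flat <- matrix((as.vector(vol) - rng[1]) / diff(rng), ncol = 1)
  thr <- rng[1] + diff(rng) *
    EBImage::otsu(EBImage::Image(flat), range = c(0, 1))

  nz <- dim(vol)[3]
  idx <- which(mask, arr.ind = TRUE)
  z <- matrix(NA_real_, nrow(mask), ncol(mask))
  n_multi <- 0L
  for (r in seq_len(nrow(idx))) {
    col <- vol[idx[r, 1], idx[r, 2], ]
    bright <- col > thr
    if (!any(bright)) next
    rl <- rle(bright)
    ends <- cumsum(rl$lengths)
    starts <- ends - rl$lengths + 1L
    runs <- which(rl$values)
    if (length(runs) > 1) n_multi <- n_multi + 1L
    main <- runs[which.max(rl$lengths[runs])]
    ks <- starts[main]:ends[main]
    # background-subtracted weights: the pedestal under the bright run
    # carries no surface information and would drag the centroid onto
    # the voxel grid
    w <- col[ks] - thr
    z[idx[r, 1], idx[r, 2]] <- switch(method,
      centroid = sum((ks - 1) * w) / sum(w) * dz,
      max = (ks[which.max(col[ks])] - 1) * dz,
      top = (max(ks) - 1) * dz)
  }

  failed <- mask & is.na(z)
  n_failed <- sum(failed)
  if (n_failed > 0.10 * sum(mask))
    stopf("surface extraction failed in %d of %d masked columns (> 10%%)",
          n_failed, sum(mask))
  # in-fill isolated failures from the mean of valid masked neighbours
  guard <- 0L
  while (any(failed) && guard < 100L) {
    fi <- which(failed, arr.ind = TRUE)
    for (r in seq_len(nrow(fi))) {
      i <- fi[r, 1]; j <- fi[r, 2]
      ni <- pmax(1L, i - 1L):pmin(nrow(z), i + 1L)
      nj <- pmax(1L, j - 1L):pmin(ncol(z), j + 1L)
      nb <- z[ni, nj]
      nb <- nb[!is.na(nb)]
      if (length(nb)) z[i, j] <- mean(nb)
    }
    failed <- mask & is.na(z)
    guard <- guard + 1L
  }
  if (any(failed)) stopf("surface extraction could not in-fill %d columns",
                         sum(failed))

  sigma_px <- smoothing_scale / dx
  z <- smooth_masked(z, mask, sigma_px, dx, dy)
  height_field(z, mask, pixel_spacing = c(dx, dy),
               provenance = list(source = "image_stack",
                                 surface_method = method,
                                 smoothing_scale = smoothing_scale,
                                 threshold = thr,
                                 n_failed_columns = n_failed,
                                 multi_run_fraction = n_multi / sum(mask)))
}
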