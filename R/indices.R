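# Residual-solid-stress indices of a relaxed slice surface.
#
# Given the reconstructed (or analytic) height field z(x, y) over the
# tissue mask, three scalar indices summarise the stress-release
# deformation:
#   D_n = mean over masked pixels of |z_k - z_bar|      (um)
#   R_a = A_s / A_p, curved over projected surface area (>= 1)
#   K_m = mean over masked pixels of |(k1 + k2) / 2|    (1/um)
# with z_bar the mean height, A_s = integral of sqrt(1 + zx^2 + zy^2),
# A_p the mask area, and k1, k2 the principal curvatures (reciprocal
# curvature radii) of the Monge patch.

#' @noRd
new_stress_indices <- function(D_n, R_a, K_m, A_s, A_p, z_bar, N,
                               normalization_mode = "none",
                               deformation_map = NULL,
                               curvature_map = NULL,
                               curvature_map_signed = NULL,
                               meta = NULL, provenance = list()) {
  out <- list(D_n = D_n, R_a = R_a, K_m = K_m, A_s = A_s, A_p = A_p,
              z_bar = z_bar, N = N,
              normalization_mode = normalization_mode,
              deformation_map = deformation_map,
              curvature_map = curvature_map,
              curvature_map_signed = curvature_map_signed,
              meta = meta, provenance = provenance)
  if (identical(normalization_mode, "area")) {
    # dimensionless variants for cross-slice comparison: deformation per
    # slice size and curvature times slice size
    out$D_n_norm <- D_n / sqrt(A_p)
    out$K_m_norm <- K_m * sqrt(A_p)
  }
  structure(out, class = "stress_indices")
}

#' @export
print.stress_indices <- function(x, ...) {
  cat("<stress_indices>\n")
  cat(sprintf("  D_n = %.4g um   (normalized deformation)\n", x$D_n))
  cat(sprintf("  R_a = %.6g      (area ratio, >= 1)\n", x$R_a))
  cat(sprintf("  K_m = %.4g um^-1 = %.4g mm^-1 (mean curvature index)\n",
              x$K_m, x$K_m * 1e3))
  cat(sprintf("  A_s = %.6g um^2, A_p = %.6g um^2, N = %d px\n",
              x$A_s, x$A_p, x$N))
  if (identical(x$normalization_mode, "area"))
    cat(sprintf("  area-normalized: D_n/sqrt(A_p) = %.4g, K_m*sqrt(A_p) = %.4g\n",
                x$D_n_norm, x$K_m_norm))
  invisible(x)
}

#' Normalized deformation of a height field
#'
#' The primary solid-stress index: the mean absolute deviation of the
#' surface height from its mean plane, `D_n = mean(|z_k - z_bar|)` over
#' masked pixels, with `z_bar` the mean height. A flat slice gives 0; a
#' slice bowed by released stress gives a value that grows with the
#' deformation amplitude. Also returns the per-pixel deformation map
#' `|z - z_bar|`.
#'
#' @param hf a [height_field()].
#' @return list with `D_n` (um), `z_bar` (um), and `map` (matrix, um,
#'   `NA` off-mask).
#' @export
normalized_deformation <- function(hf) {
  stopifnot(inherits(hf, "height_field"))
  zv <- hf$z[hf$mask]
  z_bar <- mean(zv)
  map <- abs(hf$z - z_bar)
  map[!hf$mask] <- NA_real_
  list(D_n = mean(abs(zv - z_bar)), z_bar = z_bar, map = map)
}

#' Area ratio of a height field
#'
#' Ratio of the true (curved) surface area to its planar projection,
#' `R_a = A_s / A_p`. The surface area is the masked integral of
#' `sqrt(1 + zx^2 + zy^2)` with gradients by centred finite differences
#' (one-sided at the mask boundary); the projected area is the mask
#' pixel count times the pixel area. `R_a >= 1` with equality only for a
#' flat (constant-height) slice.
#'
#' @param hf a [height_field()].
#' @return list with `R_a`, `A_s` (um^2), `A_p` (um^2).
#' @export
area_ratio <- function(hf) {
  stopifnot(inherits(hf, "height_field"))
  dx <- hf$pixel_spacing[1]; dy <- hf$pixel_spacing[2]
  g <- masked_gradient(hf$z, hf$mask, dx, dy)
  zx <- g$zx[hf$mask]; zy <- g$zy[hf$mask]
  # isolated single-pixel rows/cols can lack a neighbour along one axis
  zx[is.na(zx)] <- 0; zy[is.na(zy)] <- 0
  dA <- dx * dy
  A_p <- sum(hf$mask) * dA
  A_s <- sum(sqrt(1 + zx^2 + zy^2)) * dA
  list(R_a = A_s / A_p, A_s = A_s, A_p = A_p)
}

#' Mean-curvature index of a height field
#'
#' Per-pixel Monge-patch mean curvature
#' `H = ((1 + zy^2) zxx - 2 zx zy zxy + (1 + zx^2) zyy) /
#'      (2 (1 + zx^2 + zy^2)^(3/2))`
#' from centred finite differences, averaged as `K_m = mean(|H|)` over
#' the mask eroded by one pixel (the centred second-derivative stencil
#' is undefined on boundary pixels, which are excluded and counted).
#'
#' @param hf a [height_field()].
#' @return list with `K_m` (um^-1), `map` (|H|, um^-1), `map_signed`
#'   (H with sign), and `N_interior` (pixels entering the average).
#' @export
mean_curvature <- function(hf) {
  stopifnot(inherits(hf, "height_field"))
  dx <- hf$pixel_spacing[1]; dy <- hf$pixel_spacing[2]
  g <- masked_gradient(hf$z, hf$mask, dx, dy)
  h <- masked_hessian(hf$z, hf$mask, dx, dy)
  if (!any(h$core))
    stopf("mask too small for the curvature stencil (no interior pixels)")
  H <- monge_mean_curvature(g$zx, g$zy, h$zxx, h$zxy, h$zyy)
  H[!h$core] <- NA_real_
  list(K_m = mean(abs(H[h$core])), map = abs(H), map_signed = H,
       N_interior = sum(h$core))
}

#' All three stress indices of a height field
#'
#' Convenience wrapper computing [normalized_deformation()],
#' [area_ratio()] and [mean_curvature()] and assembling a
#' `stress_indices` object with the per-pixel maps. With
#' `normalization_mode = "area"` the dimensionless variants
#' `D_n / sqrt(A_p)` and `K_m * sqrt(A_p)` are added, which remove the
#' dependence on slice size when comparing slices of different
#' cross-sectional area.
#'
#' @param hf a [height_field()].
#' @param normalization_mode `"none"` or `"area"`.
#' @param meta optional [slice_metadata()] attached to the result.
#' @return a `stress_indices` object.
#' @export
stress_indices <- function(hf, normalization_mode = c("none", "area"),
                           meta = NULL) {
  normalization_mode <- match.arg(normalization_mode)
  nd <- normalized_deformation(hf)
  ar <- area_ratio(hf)
  mc <- mean_curvature(hf)
  new_stress_indices(D_n = nd$D_n, R_a = ar$R_a, K_m = mc$K_m,
                     A_s = ar$A_s, A_p = ar$A_p, z_bar = nd$z_bar,
                     N = sum(hf$mask),
                     normalization_mode = normalization_mode,
                     deformation_map = nd$map,
                     curvature_map = mc$map,
                     curvature_map_signed = mc$map_signed,
                     meta = meta,
                     provenance = hf$provenance)
}

#' Full image-to-indices pipeline for one slice
#'
#' Runs tissue segmentation, height-field extraction and the three index
#' computations on a 3D stack, with errors from each stage prefixed by
#' the stage name.
#'
#' @param stack an [image_stack()].
#' @param config a [run_config()]; controls surface method, smoothing
#'   and normalization.
#' @param meta optional [slice_metadata()].
#' @return a `stress_indices` object with maps and provenance.
#' @export
compute_indices <- function(stack, config = run_config(), meta = NULL) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stopf("[%s] %s", name, conditionMessage(e)))
  }
  mask <- stage("segment_tissue",
                segment_tissue(stack, min_object_area = config$min_object_area))
  hf <- stage("extract_height_field",
              extract_height_field(stack, mask,
                                   method = config$surface_method,
                                   smoothing_scale = config$smoothing_scale))
  stage("indices", stress_indices(hf,
                                  normalization_mode = config$normalization_mode,
                                  meta = meta))
}

#' One summary row per slice for group tables
#'
#' @param x a `stress_indices` object.
#' @param ... unused.
#' @return a one-row `data.frame` with slice metadata (if present) and
#'   the scalar indices; `K_m` is also reported in mm^-1 for
#'   readability.
#' @export
as.data.frame.stress_indices <- function(x, ...) {
  meta <- x$meta
  data.frame(
    slice_id = if (!is.null(meta)) meta$slice_id else NA_character_,
    group = if (!is.null(meta)) meta$group else NA_character_,
    position_ap = if (!is.null(meta) && !is.null(meta$position_ap))
      meta$position_ap else NA_real_,
    D_n = x$D_n, R_a = x$R_a, K_m = x$K_m, K_m_mm = x$K_m * 1e3,
    A_s = x$A_s, A_p = x$A_p, N = x$N,
    D_n_norm = if (!is.null(x$D_n_norm)) x$D_n_norm else x$D_n / sqrt(x$A_p),
    K_m_norm = if (!is.null(x$K_m_norm)) x$K_m_norm else x$K_m * sqrt(x$A_p),
    stringsAsFactors = FALSE)
}
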