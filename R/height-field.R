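#' Construct a height field
#'
#' A height field is the Monge-patch representation of the relaxed slice
#' surface: a single-valued height z(x, y) (um) defined on a logical
#' tissue mask over a regular in-plane grid. It is the central geometric
#' object of the pipeline: the synthetic generator produces it
#' analytically, the surface module reconstructs it from an image stack,
#' and the index module integrates over it.
#'
#' @param z numeric matrix of heights (um); values off the mask are
#'   ignored and stored as `NA`.
#' @param mask logical matrix, same dimensions as `z`.
#' @param pixel_spacing length-2 numeric, in-plane spacing (um) in x and
#'   y.
#' @param thickness slice thickness (um), carried for rendering; may be
#'   `NA` for reconstructed fields.
#' @param provenance free-form list recording how the field was obtained
#'   (surface method, smoothing scale, ...).
#' @return an object of class `height_field`.
#' @export
height_field <- function(z, mask, pixel_spacing, thickness = NA_real_,
                         provenance = list()) {
  if (!is.matrix(z) || !is.matrix(mask) || !all(dim(z) == dim(mask)))
    stopf("z and mask must be matrices of identical dimensions")
  mask <- matrix(as.logical(mask), nrow(z), ncol(z))
  if (!any(mask)) stopf("height field mask is empty")
  if (any(!is.finite(z[mask])))
    stopf("z must be finite on the mask")
  if (length(pixel_spacing) == 1) pixel_spacing <- rep(pixel_spacing, 2)
  if (any(pixel_spacing <= 0)) stopf("pixel_spacing must be > 0")
  z[!mask] <- NA_real_
  structure(list(z = z, mask = mask,
                 pixel_spacing = as.numeric(pixel_spacing),
                 thickness = thickness,
                 provenance = provenance),
            class = "height_field")
}

#' @export
print.height_field <- function(x, ...) {
  cat(sprintf("<height_field> %d x %d grid, %.3g x %.3g um/px, %d masked px\n",
              nrow(x$z), ncol(x$z), x$pixel_spacing[1], x$pixel_spacing[2],
              sum(x$mask)))
  zr <- range(x$z[x$mask])
  cat(sprintf("  z range: [%.2f, %.2f] um\n", zr[1], zr[2]))
  if (length(x$provenance))
    cat("  provenance:", paste(names(x$provenance),
                               vapply(x$provenance, function(v)
                                 paste(format(v), collapse = ","), ""),
                               sep = "=", collapse = " "), "\n")
  invisible(x)
}

#' Physically flip a height field
#'
#' Returns the height field of the same slice viewed after being turned
#' over: heights are negated and the x axis mirrored. Slicing-based
#' stress indices must be identical before and after this operation
#' (they depend only on |z - mean(z)| and |H|), which is the in-silico
#' analogue of re-imaging a flipped slice to rule out buoyancy
#' artifacts.
#'
#' @param hf a `height_field`.
#' @return the flipped `height_field`; flipping twice restores the
#'   original exactly.
#' @export
flip_height_field <- function(hf) {
  stopifnot(inherits(hf, "height_field"))
  idx <- nrow(hf$z):1
  z <- -hf$z[idx, , drop = FALSE]
  mask <- hf$mask[idx, , drop = FALSE]
  prov <- hf$provenance
  prov$flipped <- !isTRUE(prov$flipped)
  height_field(z, mask, hf$pixel_spacing, thickness = hf$thickness,
               provenance = prov)
}
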