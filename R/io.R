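# File I/O: multi-page TIFF stacks with a YAML metadata sidecar, CSV
# compression traces, YAML run configuration. Readers reject malformed
# input rather than repairing it; in particular, a stack with no
# recorded voxel spacing is an error, never a silent default (curvature
# has units, and a guessed spacing corrupts every index).

#' @noRd
sidecar_path <- function(path) paste0(path, ".yaml")

#' Write an image stack as multi-page TIFF plus YAML sidecar
#'
#' Intensities are stored as 32-bit float pages (z slices); the voxel
#' spacing and channel label go in a `<path>.yaml` sidecar, since plain
#' TIFF has no standard slot for z spacing.
#'
#' @param stack an [image_stack()].
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "image_stack"))
  d <- dim(stack$intensities)
  # TIFF float storage is only defined on [0, 1]; store affinely
  # rescaled values and record the transform in the sidecar
  off <- min(stack$intensities)
  scl <- max(stack$intensities) - off
  if (scl == 0) scl <- 1
  pages <- lapply(seq_len(d[3]),
                  function(k) (stack$intensities[, , k] - off) / scl)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  yaml::write_yaml(list(voxel_spacing_um = as.list(stack$voxel_spacing),
                        channel_label = stack$channel_label,
                        value_offset = off, value_scale = scl,
                        axes = "xyz"),
                   sidecar_path(path))
  invisible(path)
}

#' Read an image stack from multi-page TIFF
#'
#' Voxel spacing is taken from the YAML sidecar written by
#' [write_stack()], or from the explicit `spacing` override; a stack
#' without spacing information is rejected. Multi-sample (multi-channel)
#' pages require a `channel` selection.
#'
#' @param path TIFF path.
#' @param spacing optional length-3 numeric (um) overriding the sidecar.
#' @param channel optional channel index for multi-channel files.
#' @return an [image_stack()].
#' @export
read_stack <- function(path, spacing = NULL, channel = NULL) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  if (!is.list(pages)) pages <- list(pages)
  nch <- if (length(dim(pages[[1]])) == 3) dim(pages[[1]])[3] else 1L
  if (nch > 1) {
    if (is.null(channel))
      stopf("multi-channel stack (%d channels); select one with 'channel' (1..%d)",
            nch, nch)
    if (channel < 1 || channel > nch)
      stopf("channel %d out of range 1..%d", channel, nch)
    pages <- lapply(pages, function(p) p[, , channel])
  }
  label <- "unknown"
  off <- 0; scl <- 1
  sc <- sidecar_path(path)
  if (file.exists(sc)) {
    meta <- yaml::read_yaml(sc)
    if (!is.null(meta$channel_label)) label <- meta$channel_label
    if (!is.null(meta$value_offset)) off <- meta$value_offset
    if (!is.null(meta$value_scale)) scl <- meta$value_scale
    if (is.null(spacing)) {
      if (is.null(meta$voxel_spacing_um))
        stopf("sidecar %s has no voxel_spacing_um entry", sc)
      spacing <- as.numeric(unlist(meta$voxel_spacing_um))
    }
  } else if (is.null(spacing)) {
    stopf("no voxel spacing: sidecar %s missing and no 'spacing' given", sc)
  }
  if (length(spacing) != 3 || any(!is.finite(spacing)) || any(spacing <= 0))
    stopf("voxel spacing must be three positive numbers (um)")
  vol <- array(0, dim = c(dim(pages[[1]])[1], dim(pages[[1]])[2],
                          length(pages)))
  for (k in seq_along(pages)) vol[, , k] <- pages[[k]] * scl + off
  image_stack(vol, spacing, channel_label = label)
}

#' Write a compression trace as CSV
#'
#' Header `time_s,displacement_mm,force_N`; geometry is not stored in
#' the CSV (it belongs to the specimen, not the instrument export) and
#' must be supplied again when reading.
#'
#' @param trace a [relaxation_trace()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "relaxation_trace"))
  utils::write.csv(as.data.frame(trace)[c("time_s", "displacement_mm",
                                          "force_N")],
                   path, row.names = FALSE)
  invisible(path)
}

#' Read a compression trace from delimited text
#'
#' Accepts a generic CSV with a mandatory header. Vendor exports with
#' different column names are handled through `col_map`, which maps the
#' canonical names to the file's names. Non-numeric cells, missing
#' columns and non-increasing time are rejected.
#'
#' @param path CSV path.
#' @param specimen_diameter punch diameter (mm).
#' @param specimen_thickness specimen thickness (mm).
#' @param col_map named character vector mapping canonical column names
#'   (`time_s`, `displacement_mm`, `force_N`) to the file's header
#'   names, e.g. `c(time_s = "Time", force_N = "Load")`.
#' @param sep field separator. Default `","`.
#' @return a [relaxation_trace()].
#' @export
read_trace <- function(path, specimen_diameter, specimen_thickness,
                       col_map = NULL, sep = ",") {
  if (!file.exists(path)) stopf("file not found: %s", path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          blank.lines.skip = TRUE,
                          stringsAsFactors = FALSE)
  canonical <- c("time_s", "displacement_mm", "force_N")
  if (!is.null(col_map)) {
    for (nm in names(col_map)) {
      if (!col_map[[nm]] %in% names(df))
        stopf("mapped column '%s' not found in %s", col_map[[nm]], path)
      names(df)[names(df) == col_map[[nm]]] <- nm
    }
  }
  miss <- setdiff(canonical, names(df))
  if (length(miss)) stopf("trace file %s is missing column(s): %s",
                          path, paste(miss, collapse = ", "))
  for (cc in canonical) {
    v <- df[[cc]]
    if (!is.numeric(v)) {
      vn <- suppressWarnings(as.numeric(v))
      if (anyNA(vn)) stopf("non-numeric values in column '%s'", cc)
      df[[cc]] <- vn
    }
  }
  relaxation_trace(df, specimen_diameter, specimen_thickness)
}

#' Per-slice metadata
#'
#' @param slice_id text identifier.
#' @param group group label (age group, condition, ...).
#' @param position_ap anterior-posterior position (um from the anterior
#'   reference), optional; must be >= 0 when given.
#' @param flipped whether the slice was imaged flipped.
#' @return an object of class `slice_metadata`.
#' @export
slice_metadata <- function(slice_id, group, position_ap = NULL,
                           flipped = FALSE) {
  if (!is.null(position_ap) && position_ap < 0)
    stopf("position_ap must be >= 0 (got %g)", position_ap)
  structure(list(slice_id = as.character(slice_id),
                 group = as.character(group),
                 position_ap = position_ap,
                 flipped = isTRUE(flipped)),
            class = "slice_metadata")
}

#' Run configuration for the image-to-indices pipeline
#'
#' @param smoothing_scale in-plane Gaussian smoothing of the
#'   reconstructed surface, in um; `NULL` means two in-plane pixels.
#'   Curvature is scale-dependent, so indices are comparable only within
#'   one smoothing configuration.
#' @param surface_method `"centroid"`, `"max"` or `"top"` (see
#'   [extract_height_field()]).
#' @param normalization_mode `"none"` or `"area"`.
#' @param min_object_area smallest segmented object kept (um^2).
#' @param fit_tol relative tolerance passed to nonlinear fits.
#' @param output_dir directory for report output.
#' @return an object of class `run_config`.
#' @export
run_config <- function(smoothing_scale = NULL,
                       surface_method = c("centroid", "max", "top"),
                       normalization_mode = c("none", "area"),
                       min_object_area = 0,
                       fit_tol = 1e-8,
                       output_dir = ".") {
  surface_method <- match.arg(surface_method)
  normalization_mode <- match.arg(normalization_mode)
  if (!is.null(smoothing_scale) && smoothing_scale < 0)
    stopf("smoothing_scale must be >= 0")
  structure(list(smoothing_scale = smoothing_scale,
                 surface_method = surface_method,
                 normalization_mode = normalization_mode,
                 min_object_area = min_object_area,
                 fit_tol = fit_tol,
                 output_dir = output_dir),
            class = "run_config")
}

#' Write / read a run configuration as YAML
#'
#' @param config a [run_config()].
#' @param path YAML path.
#' @return `write_config` returns `path` invisibly; `read_config`
#'   returns a [run_config()].
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  v <- yaml::read_yaml(path)
  run_config(smoothing_scale = v$smoothing_scale,
             surface_method = v$surface_method,
             normalization_mode = v$normalization_mode,
             min_object_area = v$min_object_area %||% 0,
             fit_tol = v$fit_tol %||% 1e-8,
             output_dir = v$output_dir %||% ".")
}

#' Write / read a height field as TIFF + sidecar
#'
#' The surface goes to a single-page float TIFF, the mask to a second
#' TIFF (`<path>.mask.tif`), spacing and provenance to a YAML sidecar.
#'
#' @param hf a [height_field()].
#' @param path output TIFF path for the z map.
#' @return `write_height_field` returns `path` invisibly;
#'   `read_height_field` returns a [height_field()].
#' @export
write_height_field <- function(hf, path) {
  stopifnot(inherits(hf, "height_field"))
  z <- hf$z
  z[!hf$mask] <- 0
  off <- min(z); scl <- max(z) - off
  if (scl == 0) scl <- 1
  tiff::writeTIFF((z - off) / scl, path, bits.per.sample = 32L,
                  reduce = FALSE)
  tiff::writeTIFF(matrix(as.numeric(hf$mask), nrow(z), ncol(z)),
                  paste0(path, ".mask.tif"), bits.per.sample = 32L,
                  reduce = FALSE)
  yaml::write_yaml(list(pixel_spacing_um = as.list(hf$pixel_spacing),
                        thickness_um = hf$thickness,
                        value_offset = off, value_scale = scl,
                        provenance = hf$provenance),
                   sidecar_path(path))
  invisible(path)
}

#' @rdname write_height_field
#' @export
read_height_field <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  sc <- sidecar_path(path)
  if (!file.exists(sc)) stopf("no pixel spacing: sidecar %s missing", sc)
  meta <- yaml::read_yaml(sc)
  z <- tiff::readTIFF(path) * (meta$value_scale %||% 1) +
    (meta$value_offset %||% 0)
  mask <- tiff::readTIFF(paste0(path, ".mask.tif")) > 0.5
  height_field(z, mask,
               pixel_spacing = as.numeric(unlist(meta$pixel_spacing_um)),
               thickness = meta$thickness_um %||% NA_real_,
               provenance = meta$provenance %||% list())
}
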