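#' Specify the geometry of a synthetic tissue slice
#'
#' Describes a deformed slice surface with an analytically known height
#' function, used as ground truth for the surface-reconstruction and
#' stress-index pipeline. Available shapes:
#' \describe{
#'   \item{`flat`}{z = 0 everywhere (undeformed slice).}
#'   \item{`spherical_cap`}{z = sqrt(R^2 - x^2 - y^2) - sqrt(R^2 - a^2),
#'     a dome of curvature radius R = `amplitude_or_radius` clamped to zero
#'     at the outline radius a. Both principal curvatures equal 1/R.}
#'   \item{`sinusoid`}{z = A sin(2 pi x / lambda), a one-directional ripple.}
#'   \item{`composite`}{z = A sin(2 pi x / lambda) cos(2 pi y / lambda),
#'     an egg-carton surface with curvature of both signs.}
#' }
#' A rigid tilt (plane `tan(tilt) * x`) can be superposed on any shape.
#' The in-plane outline is either a disk of radius `outline_radius` or an
#' irregular "blob": a disk whose boundary radius is perturbed by seeded
#' low-order Fourier modes, emulating the irregular outline of a real
#' slice.
#'
#' @param shape_kind one of `"flat"`, `"spherical_cap"`, `"sinusoid"`,
#'   `"composite"`.
#' @param amplitude_or_radius deformation amplitude A (um) for
#'   sinusoid/composite, curvature radius R (um) for the spherical cap.
#'   Ignored for `flat`.
#' @param wavelength in-plane wavelength lambda (um) for
#'   sinusoid/composite.
#' @param outline `"disk"` or `"blob"`.
#' @param outline_radius characteristic in-plane radius a (um).
#' @param thickness slice thickness (um). Default 250, the standard
#'   vibratome section thickness used for stress-release slices.
#' @param tilt rigid plane tilt (radians) added to the surface.
#' @param seed integer seed for the blob outline perturbation.
#' @return an object of class `slice_shape_spec`.
#' @export
#' @examples
#' spec <- slice_shape_spec("spherical_cap", amplitude_or_radius = 1000,
#'                          outline_radius = 500)
#' hf <- make_height_field(spec, resolution = 10)
slice_shape_spec <- function(shape_kind = c("flat", "spherical_cap",
                                            "sinusoid", "composite"),
                             amplitude_or_radius = 0,
                             wavelength = 800,
                             outline = c("disk", "blob"),
                             outline_radius = 500,
                             thickness = 250,
                             tilt = 0,
                             seed = 1L) {
  shape_kind <- match.arg(shape_kind)
  outline <- match.arg(outline)
  if (!is.numeric(thickness) || thickness <= 0)
    stopf("invalid shape parameters: thickness must be > 0 (got %g)", thickness)
  if (!is.numeric(outline_radius) || outline_radius <= 0)
    stopf("invalid shape parameters: outline radius must be > 0 (got %g)",
          outline_radius)
  if (shape_kind %in% c("sinusoid", "composite") && wavelength <= 0)
    stopf("invalid shape parameters: wavelength must be > 0 (got %g)", wavelength)
  if (shape_kind == "spherical_cap") {
    if (amplitude_or_radius <= 0)
      stopf("invalid shape parameters: cap radius must be > 0 (got %g)",
            amplitude_or_radius)
    if (amplitude_or_radius < outline_radius)
      stopf(paste0("invalid shape parameters: cap radius (%g um) smaller than ",
                   "outline radius (%g um) -- cap would exceed a hemisphere"),
            amplitude_or_radius, outline_radius)
  }
  structure(list(shape_kind = shape_kind,
                 amplitude_or_radius = amplitude_or_radius,
                 wavelength = wavelength,
                 outline = outline,
                 outline_radius = outline_radius,
                 thickness = thickness,
                 tilt = tilt,
                 seed = as.integer(seed)),
            class = "slice_shape_spec")
}

# Closed-form z and its partial derivatives for a shape spec.
# Returns vectorised functions of (x, y); the tilt plane contributes
# tan(tilt) * x to z and tan(tilt) to zx, nothing to second derivatives.
#' @noRd
shape_functions <- function(spec) {
  tl <- tan(spec$tilt)
  zero <- function(x, y) rep(0, length(x))
  base <- switch(spec$shape_kind,
    flat = list(z = zero, zx = zero, zy = zero,
                zxx = zero, zxy = zero, zyy = zero),
    spherical_cap = {
      R <- spec$amplitude_or_radius
      a <- spec$outline_radius
      z0 <- sqrt(R^2 - a^2)
      w <- function(x, y) sqrt(pmax(R^2 - x^2 - y^2, .Machine$double.eps))
      list(
        z   = function(x, y) w(x, y) - z0,
        zx  = function(x, y) -x / w(x, y),
        zy  = function(x, y) -y / w(x, y),
        zxx = function(x, y) { W <- w(x, y); -1 / W - x^2 / W^3 },
        zxy = function(x, y) -x * y / w(x, y)^3,
        zyy = function(x, y) { W <- w(x, y); -1 / W - y^2 / W^3 }
      )
    },
    sinusoid = {
      A <- spec$amplitude_or_radius
      om <- 2 * pi / spec$wavelength
      list(
        z   = function(x, y) A * sin(om * x),
        zx  = function(x, y) A * om * cos(om * x),
        zy  = zero,
        zxx = function(x, y) -A * om^2 * sin(om * x),
        zxy = zero,
        zyy = zero
      )
    },
    composite = {
      A <- spec$amplitude_or_radius
      om <- 2 * pi / spec$wavelength
      list(
        z   = function(x, y) A * sin(om * x) * cos(om * y),
        zx  = function(x, y) A * om * cos(om * x) * cos(om * y),
        zy  = function(x, y) -A * om * sin(om * x) * sin(om * y),
        zxx = function(x, y) -A * om^2 * sin(om * x) * cos(om * y),
        zxy = function(x, y) -A * om^2 * cos(om * x) * sin(om * y),
        zyy = function(x, y) -A * om^2 * sin(om * x) * cos(om * y)
      )
    })
  list(
    z   = function(x, y) base$z(x, y) + tl * x,
    zx  = function(x, y) base$zx(x, y) + tl,
    zy  = base$zy, zxx = base$zxx, zxy = base$zxy, zyy = base$zyy
  )
}

# Outline radius as a function of polar angle. Blob outlines perturb the
# disk radius with seeded Fourier modes k = 2..5, amplitudes ~ 1/k,
# bounded so the total perturbation stays below 25%.
#' @noRd
outline_radius_fun <- function(spec) {
  a <- spec$outline_radius
  if (spec$outline == "disk") return(function(theta) rep(a, length(theta)))
  rs <- .Random.seed_save()
  on.exit(.Random.seed_restore(rs))
  set.seed(spec$seed)
  kk <- 2:5
  amp <- stats::runif(length(kk), 0, 0.12 / (kk / 2))
  phs <- stats::runif(length(kk), 0, 2 * pi)
  function(theta) {
    pert <- rep(0, length(theta))
    for (m in seq_along(kk)) pert <- pert + amp[m] * cos(kk[m] * theta + phs[m])
    a * (1 + pert)
  }
}

# Save/restore the global RNG state so generators are seeded locally
# without disturbing the caller's random stream.
#' @noRd
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
#' @noRd
.Random.seed_restore <- function(rs) {
  if (is.null(rs)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", rs, envir = globalenv())
}

#' Sample an analytic slice surface on a regular grid
#'
#' Evaluates the shape's closed-form height function on a regular grid
#' with the given in-plane resolution and builds the tissue mask from the
#' outline. The result is the ground-truth counterpart of the height
#' field reconstructed from an image stack.
#'
#' @param spec a [slice_shape_spec()].
#' @param resolution in-plane grid spacing (um per pixel).
#' @return a `height_field`: list with `z` (matrix, um; `NA` off-mask),
#'   `mask` (logical matrix), `pixel_spacing` (um, x and y) and
#'   `provenance`. The slice `thickness` (um) is carried along for
#'   rendering.
#' @export
make_height_field <- function(spec, resolution = 10) {
  stopifnot(inherits(spec, "slice_shape_spec"))
  if (resolution <= 0) stopf("resolution must be > 0")
  rfun <- outline_radius_fun(spec)
  rmax <- max(rfun(seq(0, 2 * pi, length.out = 720)))
  L <- 1.1 * rmax
  xs <- seq(-L, L, by = resolution)
  ys <- xs
  gx <- matrix(xs, length(xs), length(ys))
  gy <- matrix(ys, length(xs), length(ys), byrow = TRUE)
  theta <- atan2(gy, gx)
  mask <- sqrt(gx^2 + gy^2) <= matrix(rfun(as.vector(theta)),
                                      length(xs), length(ys))
  fns <- shape_functions(spec)
  z <- matrix(NA_real_, length(xs), length(ys))
  z[mask] <- fns$z(gx[mask], gy[mask])
  height_field(z = z, mask = mask, pixel_spacing = c(resolution, resolution),
               thickness = spec$thickness,
               provenance = list(source = "analytic",
                                 shape_kind = spec$shape_kind,
                                 seed = spec$seed))
}

#' Ground-truth stress indices by quadrature on the analytic surface
#'
#' Computes normalized deformation, area ratio and the mean-curvature
#' index directly from a shape's closed-form height function and its
#' analytic partial derivatives, by dense numerical quadrature on a grid
#' of the given resolution. This never touches image rendering or surface
#' reconstruction, so it serves as an independent oracle for the full
#' pipeline: its values converge to the exact surface integrals as
#' `resolution` decreases.
#'
#' @param spec a [slice_shape_spec()].
#' @param resolution quadrature grid spacing (um); smaller is more
#'   accurate.
#' @return a `stress_indices` object (no maps).
#' @export
#' @examples
#' # a spherical cap of radius R has |H| = 1/R everywhere
#' oi <- oracle_indices(slice_shape_spec("spherical_cap", 1000,
#'                                       outline_radius = 500))
#' all.equal(oi$K_m, 1e-3, tolerance = 1e-6)
oracle_indices <- function(spec, resolution = 2) {
  stopifnot(inherits(spec, "slice_shape_spec"))
  if (resolution <= 0) stopf("resolution must be > 0")
  rfun <- outline_radius_fun(spec)
  rmax <- max(rfun(seq(0, 2 * pi, length.out = 720)))
  L <- 1.02 * rmax
  xs <- seq(-L, L, by = resolution)
  gx <- matrix(xs, length(xs), length(xs))
  gy <- t(gx)
  theta <- atan2(gy, gx)
  inside <- sqrt(gx^2 + gy^2) <= matrix(rfun(as.vector(theta)),
                                        length(xs), length(xs))
  x <- gx[inside]; y <- gy[inside]
  fns <- shape_functions(spec)
  z <- fns$z(x, y)
  zx <- fns$zx(x, y); zy <- fns$zy(x, y)
  H <- monge_mean_curvature(zx, zy, fns$zxx(x, y), fns$zxy(x, y),
                            fns$zyy(x, y))
  N <- length(z)
  dA <- resolution^2
  A_p <- N * dA
  A_s <- sum(sqrt(1 + zx^2 + zy^2)) * dA
  new_stress_indices(D_n = mean(abs(z - mean(z))),
                     R_a = A_s / A_p,
                     K_m = mean(abs(H)),
                     A_s = A_s, A_p = A_p, z_bar = mean(z), N = N,
                     normalization_mode = "none",
                     provenance = list(source = "analytic_quadrature",
                                       resolution = resolution))
}
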