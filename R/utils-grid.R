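# Masked finite-difference and smoothing primitives shared by the surface
# and index modules. All grids are matrices indexed [x, y] with physical
# spacing in micrometres.

#' @keywords internal
#' @noRd
stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# Erode a logical mask by one pixel: keep pixels whose full 3x3
# neighbourhood lies inside the mask (and inside the grid).
#' @noRd
erode_mask1 <- function(mask) {
  nx <- nrow(mask); ny <- ncol(mask)
  out <- matrix(FALSE, nx, ny)
  if (nx < 3 || ny < 3) return(out)
  core <- mask[2:(nx - 1), 2:(ny - 1)]
  for (di in -1:1) for (dj in -1:1) {
    core <- core & mask[(2 + di):(nx - 1 + di), (2 + dj):(ny - 1 + dj)]
  }
  out[2:(nx - 1), 2:(ny - 1)] <- core
  out
}

# First derivatives of z on a mask: centred differences where both
# neighbours are masked, one-sided at the mask boundary, NA where no
# masked neighbour exists along the axis.
#' @noRd
masked_gradient <- function(z, mask, dx, dy) {
  nx <- nrow(z); ny <- ncol(z)
  pad <- function(m, fill) {
    p <- matrix(fill, nx + 2, ny + 2)
    p[2:(nx + 1), 2:(ny + 1)] <- m
    p
  }
  zp <- pad(z, NA_real_)
  mp <- pad(mask, FALSE)
  i <- 2:(nx + 1); j <- 2:(ny + 1)

  # x axis
  m_up <- mp[i + 1, j, drop = FALSE]; m_dn <- mp[i - 1, j, drop = FALSE]
  z_up <- zp[i + 1, j, drop = FALSE]; z_dn <- zp[i - 1, j, drop = FALSE]
  zx <- matrix(NA_real_, nx, ny)
  both <- mask & m_up & m_dn
  fwd  <- mask & m_up & !m_dn
  bwd  <- mask & !m_up & m_dn
  zx[both] <- (z_up[both] - z_dn[both]) / (2 * dx)
  zx[fwd]  <- (z_up[fwd] - z[fwd]) / dx
  zx[bwd]  <- (z[bwd] - z_dn[bwd]) / dx

  # y axis
  m_up <- mp[i, j + 1, drop = FALSE]; m_dn <- mp[i, j - 1, drop = FALSE]
  z_up <- zp[i, j + 1, drop = FALSE]; z_dn <- zp[i, j - 1, drop = FALSE]
  zy <- matrix(NA_real_, nx, ny)
  both <- mask & m_up & m_dn
  fwd  <- mask & m_up & !m_dn
  bwd  <- mask & !m_up & m_dn
  zy[both] <- (z_up[both] - z_dn[both]) / (2 * dy)
  zy[fwd]  <- (z_up[fwd] - z[fwd]) / dy
  zy[bwd]  <- (z[bwd] - z_dn[bwd]) / dy

  list(zx = zx, zy = zy)
}

# Second derivatives on the 1-pixel-eroded mask (centred stencils only).
#' @noRd
masked_hessian <- function(z, mask, dx, dy) {
  nx <- nrow(z); ny <- ncol(z)
  core <- erode_mask1(mask)
  zxx <- zyy <- zxy <- matrix(NA_real_, nx, ny)
  idx <- which(core, arr.ind = TRUE)
  if (nrow(idx) > 0) {
    i <- idx[, 1]; j <- idx[, 2]
    at <- function(di, dj) z[cbind(i + di, j + dj)]
    zxx[idx] <- (at(1, 0) - 2 * at(0, 0) + at(-1, 0)) / dx^2
    zyy[idx] <- (at(0, 1) - 2 * at(0, 0) + at(0, -1)) / dy^2
    zxy[idx] <- (at(1, 1) - at(1, -1) - at(-1, 1) + at(-1, -1)) / (4 * dx * dy)
  }
  list(zxx = zxx, zyy = zyy, zxy = zxy, core = core)
}

# Monge-patch mean curvature from first and second partials.
#' @noRd
monge_mean_curvature <- function(zx, zy, zxx, zxy, zyy) {
  ((1 + zy^2) * zxx - 2 * zx * zy * zxy + (1 + zx^2) * zyy) /
    (2 * (1 + zx^2 + zy^2)^1.5)
}

# First-order extrapolation of z past the mask boundary: grow the
# support ring by ring, predicting each new pixel from its already
# filled neighbours continued along their local gradient. Plain
# normalised convolution flattens a curved surface at the mask edge
# (the kernel only sees the inside), which biases deformation and
# curvature there; linear continuation keeps the edge slope and makes
# the smoothing bias second order.
#' @noRd
extrapolate_masked <- function(z, mask, n_rings, dx, dy) {
  g <- masked_gradient(z, mask, dx, dy)
  zx <- g$zx; zy <- g$zy
  zx[is.na(zx)] <- 0; zy[is.na(zy)] <- 0
  zf <- z
  filled <- mask
  nx <- nrow(z); ny <- ncol(z)
  offs <- expand.grid(di = -1:1, dj = -1:1)
  offs <- offs[!(offs$di == 0 & offs$dj == 0), ]
  for (ring in seq_len(n_rings)) {
    frontier <- !filled & (
      (rbind(filled[-1, , drop = FALSE], FALSE)) |
      (rbind(FALSE, filled[-nx, , drop = FALSE])) |
      (cbind(filled[, -1, drop = FALSE], FALSE)) |
      (cbind(FALSE, filled[, -ny, drop = FALSE])))
    if (!any(frontier)) break
    fi <- which(frontier, arr.ind = TRUE)
    newz <- numeric(nrow(fi)); neww <- numeric(nrow(fi))
    newzx <- numeric(nrow(fi)); newzy <- numeric(nrow(fi))
    for (o in seq_len(nrow(offs))) {
      si <- fi[, 1] + offs$di[o]; sj <- fi[, 2] + offs$dj[o]
      ok <- si >= 1 & si <= nx & sj >= 1 & sj <= ny
      ok[ok] <- filled[cbind(si[ok], sj[ok])]
      if (!any(ok)) next
      src <- cbind(si[ok], sj[ok])
      pred <- zf[src] - offs$di[o] * dx * zx[src] - offs$dj[o] * dy * zy[src]
      newz[ok] <- newz[ok] + pred
      newzx[ok] <- newzx[ok] + zx[src]
      newzy[ok] <- newzy[ok] + zy[src]
      neww[ok] <- neww[ok] + 1
    }
    has <- neww > 0
    tgt <- fi[has, , drop = FALSE]
    zf[tgt] <- newz[has] / neww[has]
    zx[tgt] <- newzx[has] / neww[has]
    zy[tgt] <- newzy[has] / neww[has]
    filled[tgt] <- TRUE
  }
  list(z = zf, support = filled)
}

# Gaussian smoothing restricted to a mask: the surface is first
# continued past the mask edge by linear extrapolation (see above),
# then convolved with a separable Gaussian (normalised over the
# extended support), and returned on the original mask. sigma in
# pixels.
#' @noRd
smooth_masked <- function(z, mask, sigma_px, dx = 1, dy = 1) {
  if (sigma_px <= 0) return(z)
  r_ext <- ceiling(3 * sigma_px) + 1L
  ext <- extrapolate_masked(z, mask, r_ext, dx, dy)
  z <- ext$z
  smooth_mask <- ext$support
  r <- max(1L, ceiling(3 * sigma_px))
  k <- exp(-((-r:r)^2) / (2 * sigma_px^2))
  k <- k / sum(k)
  zf <- z
  zf[!smooth_mask] <- 0
  w <- matrix(as.numeric(smooth_mask), nrow(mask), ncol(mask))
  conv_sep <- function(m) {
    nx <- nrow(m); ny <- ncol(m)
    # along x (rows), replicate-pad by zero: mask weighting handles edges
    out <- matrix(0, nx, ny)
    for (s in -r:r) {
      src <- pmin(pmax(1:nx + s, 1L), nx)
      valid <- (1:nx + s >= 1) & (1:nx + s <= nx)
      contrib <- m[src, , drop = FALSE]
      contrib[!valid, ] <- 0
      out <- out + k[s + r + 1] * contrib
    }
    m2 <- out
    out <- matrix(0, nx, ny)
    for (s in -r:r) {
      src <- pmin(pmax(1:ny + s, 1L), ny)
      valid <- (1:ny + s >= 1) & (1:ny + s <= ny)
      contrib <- m2[, src, drop = FALSE]
      contrib[, !valid] <- 0
      out <- out + k[s + r + 1] * contrib
    }
    out
  }
  num <- conv_sep(zf)
  den <- conv_sep(w)
  out <- matrix(NA_real_, nrow(mask), ncol(mask))
  ok <- mask & den > 1e-12
  out[ok] <- num[ok] / den[ok]
  out
}
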