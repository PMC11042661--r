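# Synthetic shape generator and its quadrature oracle.

test_that("shape specs reject invalid geometry with informative messages", {
  expect_error(slice_shape_spec("flat", thickness = 0), "thickness")
  expect_error(slice_shape_spec("flat", outline_radius = -1),
               "outline radius")
  expect_error(cap_spec(R = 400, a = 500), "hemisphere")
  expect_error(sin_spec(lambda = 0), "wavelength")
  expect_silent(cap_spec(R = 500, a = 500)) # exact hemisphere allowed
})

test_that("analytic height fields match their closed forms", {
  # flat, disk outline: z == 0 on the mask
  hf <- make_height_field(slice_shape_spec("flat"), resolution = 10)
  expect_true(all(hf$z[hf$mask] == 0))
  expect_true(all(is.na(hf$z[!hf$mask])))

  # spherical cap: z = sqrt(R^2 - r^2) - sqrt(R^2 - a^2)
  R <- 1000; a <- 500
  hf <- make_height_field(cap_spec(R, a), resolution = 10)
  n <- nrow(hf$z)
  xs <- matrix((seq_len(n) - (n + 1) / 2) * 10, n, n)
  ys <- t(xs)
  ztrue <- sqrt(R^2 - xs^2 - ys^2) - sqrt(R^2 - a^2)
  expect_lt(max(abs(hf$z[hf$mask] - ztrue[hf$mask])), 1e-9)

  # sinusoid: z = A sin(2 pi x / lambda), independent of y
  hf <- make_height_field(sin_spec(50, 800), resolution = 10)
  n <- nrow(hf$z)
  xs <- matrix((seq_len(n) - (n + 1) / 2) * 10, n, n)
  ztrue <- 50 * sin(2 * pi * xs / 800)
  expect_lt(max(abs(hf$z[hf$mask] - ztrue[hf$mask])), 1e-9)
})

test_that("blob outlines are seeded and reproducible", {
  s1 <- slice_shape_spec("flat", outline = "blob", seed = 11)
  s2 <- slice_shape_spec("flat", outline = "blob", seed = 11)
  s3 <- slice_shape_spec("flat", outline = "blob", seed = 12)
  expect_identical(make_height_field(s1)$mask, make_height_field(s2)$mask)
  expect_false(identical(make_height_field(s1)$mask,
                         make_height_field(s3)$mask))
  # blob stays a perturbed disk: area within 30% of the disk's
  m <- make_height_field(s1)$mask
  expect_lt(abs(sum(m) * 100 / (pi * 500^2) - 1), 0.3)
})

test_that("oracle indices reproduce closed forms for flat, cap, plane", {
  of <- oracle_indices(slice_shape_spec("flat"))
  expect_equal(of$D_n, 0)
  expect_equal(of$R_a, 1)
  expect_equal(of$K_m, 0)

  R <- 1000; a <- 500
  oc <- oracle_indices(cap_spec(R, a), resolution = 2)
  h <- R - sqrt(R^2 - a^2)
  expect_equal(oc$K_m, 1 / R, tolerance = 1e-6)       # sphere: |H| = 1/R
  expect_equal(oc$R_a, 2 * R * h / a^2, tolerance = 2e-3) # cap area 2*pi*R*h
  expect_true(oc$R_a >= 1)

  # tilted flat slice: R_a = 1/cos(theta), D_n > 0, K_m = 0
  th <- 20 * pi / 180
  ot <- oracle_indices(slice_shape_spec("flat", tilt = th), resolution = 2)
  expect_equal(ot$R_a, 1 / cos(th), tolerance = 1e-9)
  expect_equal(ot$K_m, 0)
})

test_that("oracle is resolution-convergent (halving changes < 0.1%)", {
  for (spec in list(cap_spec(), sin_spec())) {
    o1 <- oracle_indices(spec, resolution = 2)
    o2 <- oracle_indices(spec, resolution = 1)
    expect_lt(abs(o2$D_n / o1$D_n - 1), 1e-3)
    expect_lt(abs(o2$R_a / o1$R_a - 1), 1e-3)
    expect_lt(abs(o2$K_m / o1$K_m - 1), 1e-3)
  }
})

test_that("sinusoid oracle agrees with independent 1D quadrature", {
  # On a disk, D_n and K_m of A sin(om x) reduce to disk-weighted means
  # over x; integrate them with R's adaptive quadrature as a second,
  # structurally different oracle.
  A <- 50; lam <- 800; a <- 500
  om <- 2 * pi / lam
  w <- function(x) 2 * sqrt(a^2 - x^2)       # chord length at x
  area <- pi * a^2
  zbar <- integrate(function(x) A * sin(om * x) * w(x), -a, a)$value / area
  dn <- integrate(function(x) abs(A * sin(om * x) - zbar) * w(x),
                  -a, a, subdivisions = 500)$value / area
  km <- integrate(function(x) {
    zx <- A * om * cos(om * x); zxx <- -A * om^2 * sin(om * x)
    abs(zxx / (2 * (1 + zx^2)^1.5)) * w(x)
  }, -a, a, subdivisions = 500)$value / area
  o <- oracle_indices(sin_spec(A, lam, a), resolution = 1)
  expect_equal(o$D_n, dn, tolerance = 2e-3)
  expect_equal(o$K_m, km, tolerance = 2e-3)
})
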