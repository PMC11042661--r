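# Stress indices: closed-form cases and invariance properties.

test_that("flat and two-level height fields give the forced values", {
  hf <- make_height_field(slice_shape_spec("flat"), resolution = 20)
  si <- stress_indices(hf)
  expect_equal(si$D_n, 0)
  expect_equal(si$R_a, 1)
  expect_equal(si$K_m, 0)

  # +h on half the mask, -h on the other half -> D_n = h
  n <- 20; h <- 12
  z <- matrix(rep(c(-h, h), each = n * n / 2), n, n)
  hf2 <- height_field(z, matrix(TRUE, n, n), c(10, 10))
  expect_equal(normalized_deformation(hf2)$D_n, h)
})

test_that("deformation map is non-negative and averages to D_n", {
  hf <- random_hf(8)
  nd <- normalized_deformation(hf)
  expect_true(all(nd$map[hf$mask] >= 0))
  expect_equal(mean(nd$map[hf$mask]), nd$D_n)
})

test_that("tilted plane has R_a = 1/cos(theta)", {
  for (deg in c(5, 15, 30)) {
    th <- deg * pi / 180
    ar <- area_ratio(plane_hf(th))
    expect_equal(ar$R_a, 1 / cos(th), tolerance = 5e-3)
  }
})

test_that("R_a = A_s/A_p to machine precision and >= 1", {
  for (seed in c(2, 9)) {
    si <- stress_indices(random_hf(seed))
    expect_identical(si$R_a, si$A_s / si$A_p)
    expect_gte(si$R_a, 1)
  }
})

test_that("sphere and cylinder patches give closed-form curvature", {
  # sphere patch: every interior pixel |H| = 1/R
  R <- 1000
  hf <- make_height_field(cap_spec(R, 500), resolution = 10)
  mc <- mean_curvature(hf)
  expect_equal(mc$K_m, 1 / R, tolerance = 5e-3)
  inner <- mc$map[!is.na(mc$map)]
  expect_lt(max(abs(inner - 1 / R)) / (1 / R), 0.02)

  # cylinder patch radius R: |H| = 1/(2R)
  n <- 41; spacing <- 10
  xs <- (seq_len(n) - (n + 1) / 2) * spacing
  z <- matrix(sqrt(R^2 - xs^2), n, n)
  hfc <- height_field(z, matrix(TRUE, n, n), c(spacing, spacing))
  mcc <- mean_curvature(hfc)
  expect_equal(mcc$K_m, 1 / (2 * R), tolerance = 5e-3)

  # curvature map identity: mean of |H| over interior equals K_m
  expect_equal(mean(mcc$map[!is.na(mcc$map)]), mcc$K_m)
})

test_that("mask too small for the curvature stencil errors", {
  z <- matrix(0, 2, 2)
  hf <- height_field(z, matrix(TRUE, 2, 2), c(10, 10))
  expect_error(mean_curvature(hf), "stencil")
})

test_that("indices are invariant to height translation", {
  hf <- random_hf(4)
  hf2 <- height_field(hf$z + 137.5, hf$mask, hf$pixel_spacing)
  s1 <- stress_indices(hf); s2 <- stress_indices(hf2)
  expect_equal(s2$D_n, s1$D_n, tolerance = 1e-10)
  expect_equal(s2$R_a, s1$R_a, tolerance = 1e-12)
  expect_equal(s2$K_m, s1$K_m, tolerance = 1e-10)
  expect_equal(s2$z_bar, s1$z_bar + 137.5, tolerance = 1e-10)
})

test_that("indices increase with sinusoid amplitude (oracle and pipeline)", {
  amps <- c(10, 30, 60)
  oracle <- sapply(amps, function(A) {
    o <- oracle_indices(sin_spec(A), resolution = 4)
    c(o$D_n, o$R_a, o$K_m)
  })
  expect_true(all(apply(oracle, 1, diff) > 0))
  pipe <- sapply(amps, function(A) {
    s <- pipeline_indices(sin_spec(A), resolution = 20)
    c(s$D_n, s$R_a, s$K_m)
  })
  expect_true(all(apply(pipe, 1, diff) > 0))
})

test_that("indices are stable under grid coarsening on smooth shapes", {
  o10 <- stress_indices(make_height_field(cap_spec(), resolution = 10))
  o20 <- stress_indices(make_height_field(cap_spec(), resolution = 20))
  expect_lt(abs(o20$D_n / o10$D_n - 1), 0.01)
  expect_lt(abs(o20$R_a / o10$R_a - 1), 0.01)
  expect_lt(abs(o20$K_m / o10$K_m - 1), 0.01)
})

test_that("area normalization adds the dimensionless variants", {
  hf <- random_hf(5)
  si <- stress_indices(hf, normalization_mode = "area")
  expect_equal(si$D_n_norm, si$D_n / sqrt(si$A_p))
  expect_equal(si$K_m_norm, si$K_m * sqrt(si$A_p))
  row <- as.data.frame(si)
  expect_true(all(c("D_n", "R_a", "K_m", "D_n_norm", "K_m_norm") %in%
                    names(row)))
  expect_equal(row$K_m_mm, si$K_m * 1e3)
})

test_that("compute_indices runs the full pipeline and names failing stages", {
  hf <- make_height_field(cap_spec(), resolution = 20)
  st <- render_stack(hf, stack_render_spec(voxel_spacing = c(20, 20, 5)))
  meta <- slice_metadata("s1", "adult", position_ap = 1500)
  si <- compute_indices(st, run_config(), meta)
  oi <- oracle_indices(cap_spec(), resolution = 2)
  expect_lt(abs(si$D_n / oi$D_n - 1), 0.02)
  expect_identical(si$meta$group, "adult")

  blank <- image_stack(array(10, c(16, 16, 8)), c(10, 10, 5))
  expect_error(compute_indices(blank), "segment_tissue")
})
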