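# Tissue segmentation and height-field extraction.

test_that("segmentation recovers the generating outline", {
  # disk outline: mask area within 1% of pi a^2 in pixels
  hf <- make_height_field(cap_spec(a = 500), resolution = 10)
  st <- render_stack(hf, default_render())
  mask <- segment_tissue(st)
  expect_lt(abs(sum(mask) / (pi * 50^2) - 1), 0.01)

  # blob outline at SNR 10: Jaccard vs generating mask >= 0.95
  spec <- slice_shape_spec("spherical_cap", 1000, outline = "blob",
                           outline_radius = 450, seed = 5)
  hf <- make_height_field(spec, resolution = 10)
  st <- render_stack(hf, default_render(noise_sd = 9, seed = 2))
  mask <- segment_tissue(st)
  jac <- sum(mask & hf$mask) / sum(mask | hf$mask)
  expect_gte(jac, 0.95)
})

test_that("an all-background stack yields a no-tissue error", {
  st <- image_stack(array(10, c(16, 16, 8)), c(10, 10, 5))
  expect_error(segment_tissue(st), "no tissue")
})

test_that("noiseless reconstruction is accurate for all three methods", {
  hf <- make_height_field(cap_spec(), resolution = 10)
  st <- render_stack(hf, default_render())
  mask <- segment_tissue(st)
  dz <- st$voxel_spacing[3]
  for (m in c("centroid", "max", "top")) {
    rec <- extract_height_field(st, mask, method = m)
    common <- mask & hf$mask
    d <- (rec$z - mean(rec$z[common])) - (hf$z - mean(hf$z[common]))
    expect_lt(sqrt(mean(d[common]^2)), dz / 2)
  }
})

test_that("flat slab reconstructs as constant height", {
  hf <- make_height_field(slice_shape_spec("flat"), resolution = 20)
  st <- render_stack(hf, stack_render_spec(voxel_spacing = c(20, 20, 5)))
  rec <- extract_height_field(st, segment_tissue(st))
  expect_lt(diff(range(rec$z[rec$mask])), 1e-6)
})

test_that("height field is invariant to uniform intensity scaling", {
  hf <- make_height_field(cap_spec(), resolution = 20)
  st <- render_stack(hf, stack_render_spec(voxel_spacing = c(20, 20, 5),
                                           noise_sd = 4, seed = 3))
  st2 <- image_stack(st$intensities * 7.3, st$voxel_spacing)
  for (m in c("centroid", "max")) {
    r1 <- extract_height_field(st, segment_tissue(st), method = m)
    r2 <- extract_height_field(st2, segment_tissue(st2), method = m)
    expect_equal(r1$z, r2$z, tolerance = 1e-9)
  }
})

test_that("reconstruction error degrades monotonically with noise", {
  hf <- make_height_field(cap_spec(), resolution = 20)
  rmse_at <- function(noise_sd) {
    errs <- vapply(1:4, function(seed) {
      st <- render_stack(hf, stack_render_spec(voxel_spacing = c(20, 20, 5),
                                               noise_sd = noise_sd,
                                               seed = seed))
      rec <- extract_height_field(st, segment_tissue(st))
      common <- rec$mask & hf$mask
      d <- (rec$z - mean(rec$z[common])) - (hf$z - mean(hf$z[common]))
      sqrt(mean(d[common]^2))
    }, 0)
    mean(errs)
  }
  e <- vapply(c(0, 9, 25), rmse_at, 0)
  expect_true(all(diff(e) >= 0))
})

test_that("failed columns are in-filled, excess failures are an error", {
  # stack with a hole: one column entirely at background
  hf <- make_height_field(slice_shape_spec("flat"), resolution = 20)
  st <- render_stack(hf, stack_render_spec(voxel_spacing = c(20, 20, 5)))
  mask <- segment_tissue(st)
  ij <- which(mask, arr.ind = TRUE)[100, ]
  st$intensities[ij[1], ij[2], ] <- 10
  rec <- extract_height_field(st, mask)
  expect_true(is.finite(rec$z[ij[1], ij[2]]))
  expect_equal(rec$provenance$n_failed_columns, 1)

  # kill 20% of columns -> error
  kill <- which(mask, arr.ind = TRUE)
  kill <- kill[seq_len(ceiling(0.2 * nrow(kill))), , drop = FALSE]
  for (r in seq_len(nrow(kill))) st$intensities[kill[r, 1], kill[r, 2], ] <- 10
  expect_error(extract_height_field(st, mask), "10%")
})

test_that("flipping a height field is an involution preserving indices", {
  for (seed in c(3, 17)) {
    hf <- random_hf(seed)
    fl <- flip_height_field(hf)
    expect_equal(flip_height_field(fl)$z, hf$z)
    expect_identical(flip_height_field(fl)$mask, hf$mask)
    si <- stress_indices(hf); sf <- stress_indices(fl)
    expect_equal(sf$D_n, si$D_n, tolerance = 1e-12)
    expect_equal(sf$R_a, si$R_a, tolerance = 1e-12)
    expect_equal(sf$K_m, si$K_m, tolerance = 1e-12)
  }
  # flat field: flip only mirrors
  hf <- make_height_field(slice_shape_spec("flat"), resolution = 20)
  fl <- flip_height_field(hf)
  expect_true(all(fl$z[fl$mask] == 0))
})
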