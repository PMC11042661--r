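# Shared fixtures: standard shapes and a small rendering configuration
# used across the surface / index tests. Everything is generated in
# code; nothing is read from disk.

cap_spec <- function(R = 1000, a = 500, ...) {
  slice_shape_spec("spherical_cap", amplitude_or_radius = R,
                   outline_radius = a, ...)
}

sin_spec <- function(A = 50, lambda = 800, a = 500, ...) {
  slice_shape_spec("sinusoid", amplitude_or_radius = A,
                   wavelength = lambda, outline_radius = a, ...)
}

# default render: 10 um in plane, 5 um z step
default_render <- function(noise_sd = 0, seed = 1L) {
  stack_render_spec(voxel_spacing = c(10, 10, 5), noise_sd = noise_sd,
                    seed = seed)
}

# full image pipeline for a shape spec, returning reconstructed indices
pipeline_indices <- function(spec, resolution = 10, noise_sd = 0,
                             seed = 1L) {
  hf <- make_height_field(spec, resolution = resolution)
  st <- render_stack(hf, stack_render_spec(
    voxel_spacing = c(resolution, resolution, 5),
    noise_sd = noise_sd, seed = seed))
  stress_indices(extract_height_field(st, segment_tissue(st)))
}

# plane height field z = x tan(theta) on a square mask
plane_hf <- function(theta, n = 41, spacing = 10) {
  xs <- (seq_len(n) - (n + 1) / 2) * spacing
  z <- matrix(xs * tan(theta), n, n)
  height_field(z, matrix(TRUE, n, n), c(spacing, spacing))
}

# random smooth composite-shape height field for property tests
random_hf <- function(seed) {
  set.seed(seed)
  spec <- slice_shape_spec("composite",
                           amplitude_or_radius = runif(1, 20, 80),
                           wavelength = runif(1, 600, 1200),
                           outline = "blob",
                           outline_radius = runif(1, 350, 550),
                           tilt = runif(1, -0.1, 0.1),
                           seed = seed)
  make_height_field(spec, resolution = 10)
}

# closed-form Welch t-test, independent of stats::t.test
welch_oracle <- function(a, b) {
  va <- sum((a - mean(a))^2) / (length(a) - 1)
  vb <- sum((b - mean(b))^2) / (length(b) - 1)
  se2 <- va / length(a) + vb / length(b)
  t <- (mean(a) - mean(b)) / sqrt(se2)
  df <- se2^2 / ((va / length(a))^2 / (length(a) - 1) +
                 (vb / length(b))^2 / (length(b) - 1))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

# closed-form one-way ANOVA, independent of stats::aov
anova_oracle <- function(groups) {
  ns <- lengths(groups)
  gm <- mean(unlist(groups))
  ssb <- sum(ns * (vapply(groups, mean, 0) - gm)^2)
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), 0))
  df1 <- length(groups) - 1
  df2 <- sum(ns) - length(groups)
  F <- (ssb / df1) / (ssw / df2)
  list(F = F, p = stats::pf(F, df1, df2, lower.tail = FALSE))
}
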