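# Viscoelastic analysis: conversions, segmentation, modulus and
# relaxation fits.

test_that("stress/strain conversion uses the punch geometry", {
  df <- data.frame(time_s = 0:2, displacement_mm = c(0, 0.05, 0.1),
                   force_N = c(0, 0.005, 0.01))
  tr <- relaxation_trace(df, specimen_diameter = 6, specimen_thickness = 2)
  ss <- to_stress_strain(tr)
  expect_equal(ss$stress_kPa[3], 0.01 / (pi * 0.003^2) / 1000,
               tolerance = 1e-12) # ~0.3537 kPa
  expect_equal(ss$strain[3], 0.05)
  expect_equal(ss$stress_kPa[1], 0)
})

test_that("trace construction rejects malformed input", {
  df <- data.frame(time_s = c(0, 2, 1), displacement_mm = 0, force_N = 0)
  expect_error(relaxation_trace(df, 6, 2), "increasing")
  expect_error(relaxation_trace(data.frame(time_s = 0:2, force_N = 0), 6, 2),
               "displacement_mm")
  df2 <- data.frame(time_s = 0:2, displacement_mm = 0, force_N = 0)
  expect_error(relaxation_trace(df2, -6, 2), "geometry")
})

test_that("step segmentation finds the schedule or errors usefully", {
  tr <- simulate_trace(trace_sim_spec())
  expect_length(segment_steps(tr, 4), 4)
  expect_error(segment_steps(tr, 2), "detected 4 ramps")

  # monotone creep: no staircase
  df <- data.frame(time_s = seq(0, 100, 0.5))
  df$displacement_mm <- df$time_s * 0.001
  df$force_N <- 0.01
  creep <- relaxation_trace(df, 6, 2)
  expect_error(segment_steps(creep, 4), "ramps")
})

test_that("Young's modulus fit recovers lines exactly", {
  # two-point line through (0.05, 0.25), (0.10, 0.50): E = 5, C = 0
  seg <- function(eps, sig) {
    structure(list(step_index = 1, ramp_window = c(0, 1),
                   hold_window = c(1, 10), strain_level = eps,
                   ramp_stress = sig, time_s = seq(0, 9),
                   stress_kPa = rep(sig, 10)), class = "step_segment")
  }
  fit <- suppressWarnings(
    fit_youngs_modulus(list(seg(0.05, 0.25), seg(0.10, 0.50))))
  expect_equal(fit$E, 5, tolerance = 1e-12)
  expect_equal(fit$C, 0, tolerance = 1e-12)

  # constant stress across strains: E = 0
  fit0 <- suppressWarnings(
    fit_youngs_modulus(list(seg(0.05, 1), seg(0.10, 1), seg(0.15, 1))))
  expect_equal(fit0$E, 0, tolerance = 1e-12)
  expect_error(fit_youngs_modulus(list(seg(0.05, 1))), "2 steps")
})

test_that("modulus ratio handles decaying and flat holds", {
  seg <- structure(list(step_index = 1, ramp_window = c(0, 1),
                        hold_window = c(1, 181), strain_level = 0.05,
                        ramp_stress = c(0, 2),
                        time_s = seq(0, 180, 0.5),
                        stress_kPa = 1 + 1 * exp(-seq(0, 180, 0.5) / 5)),
                   class = "step_segment")
  mr <- modulus_ratio(seg)
  expect_equal(mr$R_s, 2, tolerance = 1e-6)

  flat <- seg; flat$stress_kPa <- rep(1.5, length(seg$time_s))
  flat$ramp_stress <- c(0, 1.5)
  expect_equal(modulus_ratio(flat)$R_s, 1, tolerance = 1e-12)
})

test_that("bi-exponential fit recovers known parameters on a clean hold", {
  t <- seq(0, 180, 0.1)
  y <- 1 * exp(-t / 2) + 0.5 * exp(-t / 60) + 0.3
  seg <- structure(list(step_index = 1, ramp_window = c(0, 0),
                        hold_window = c(0, 180), strain_level = 0.05,
                        ramp_stress = y[1], time_s = t, stress_kPa = y),
                   class = "step_segment")
  fr <- fit_relaxation(seg)
  expect_true(fr$converged)
  expect_equal(fr$a1, 1, tolerance = 1e-2)
  expect_equal(fr$a2, 0.5, tolerance = 1e-2)
  expect_equal(fr$tau_fast, 2, tolerance = 1e-2)
  expect_equal(fr$tau_slow, 60, tolerance = 1e-2)
  expect_equal(fr$b, 0.3, tolerance = 1e-2)
  expect_lt(fr$tau_fast, fr$tau_slow)
})

test_that("single-exponential data is flagged degenerate with 1-exp preferred", {
  t <- seq(0, 180, 0.1)
  y <- 0.8 * exp(-t / 20) + 0.5
  seg <- structure(list(step_index = 1, ramp_window = c(0, 0),
                        hold_window = c(0, 180), strain_level = 0.05,
                        ramp_stress = y[1], time_s = t, stress_kPa = y),
                   class = "step_segment")
  fr <- fit_relaxation(seg)
  # a 2-exp fit of 1-exp data collapses: tiny second amplitude or equal taus
  expect_true(fr$degenerate || fr$one_exp$preferred)
  expect_equal(fr$one_exp$tau, 20, tolerance = 1e-3)

  # constant hold: amplitudes vanish, b = level
  yc <- rep(0.7, length(t))
  segc <- seg; segc$stress_kPa <- yc; segc$ramp_stress <- 0.7
  frc <- fit_relaxation(segc)
  expect_equal(frc$a1 + frc$a2, 0, tolerance = 1e-6)
  expect_equal(frc$b, 0.7, tolerance = 1e-6)
})

test_that("tau ordering invariant holds across seeded noisy fits", {
  for (seed in 1:5) {
    tr <- simulate_trace(trace_sim_spec(noise_sd = 0.05, seed = seed))
    vf <- analyze_trace(tr)
    ok <- vf$steps$converged
    expect_true(all(vf$steps$tau_fast_s[ok] <= vf$steps$tau_slow_s[ok]))
  }
})

test_that("noiseless full-trace analysis recovers the generator", {
  tr <- simulate_trace(trace_sim_spec(E_true = 5, Rs_true = 1.8,
                                      tau_fast_true = 2,
                                      tau_slow_true = 60))
  vf <- suppressWarnings(analyze_trace(tr))
  expect_equal(vf$E, 5, tolerance = 1e-3)
  expect_equal(vf$C, 0, tolerance = 1e-6)
  expect_equal(vf$steps$R_s, rep(1.8, 4), tolerance = 1e-3)
  expect_equal(vf$steps$tau_fast_s, rep(2, 4), tolerance = 1e-3)
  expect_equal(vf$steps$tau_slow_s, rep(60, 4), tolerance = 1e-3)
})

test_that("fit residuals on model-generated noise sit at the noise floor", {
  # reduced chi^2 ~ 1: rss / (n - p) ~ noise_sd^2
  sd0 <- 0.03
  chis <- vapply(1:6, function(seed) {
    tr <- simulate_trace(trace_sim_spec(noise_sd = sd0, seed = seed))
    seg <- segment_steps(tr, 4)[[4]]
    fr <- fit_relaxation(seg)
    fr$rss / (length(seg$time_s) - 5) / sd0^2
  }, 0)
  expect_lt(abs(mean(chis) - 1), 0.1)
})
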