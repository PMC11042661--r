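#' Specify a simulated step-hold compression experiment
#'
#' Parameters of a synthetic unconfined-compression test on a
#' cylindrical specimen: consecutive ramp-hold steps of equal strain
#' increments, with per-hold stress following a linear-elastic
#' equilibrium plus a two-exponential relaxation transient,
#' \deqn{\sigma(t) = a_1 e^{-t/\tau_{fast}} + a_2 e^{-t/\tau_{slow}} + b,}
#' where b is the equilibrium stress E * strain (optionally offset), the
#' transient amplitude a1 + a2 is set so that the peak/equilibrium ratio
#' equals `Rs_true`, and the split between fast and slow components is
#' `amp_split`. Defaults follow the standard protocol for brain
#' specimens: 6 mm punch, 2 mm thickness, four 5%-strain steps, 1 s
#' ramps, 3 min holds.
#'
#' @param E_true Young's modulus (kPa).
#' @param Rs_true instantaneous/equilibrium modulus ratio per step
#'   (>= 1).
#' @param tau_fast_true,tau_slow_true relaxation time constants (s);
#'   `tau_fast_true < tau_slow_true`.
#' @param amp_split fraction of the transient carried by the fast
#'   exponential (a1 share). Default 0.5.
#' @param offset_b_frac extra constant offset added to the equilibrium
#'   stress, as a fraction of it. Default 0.
#' @param n_steps number of ramp-hold steps. Default 4.
#' @param strain_per_step strain increment per step. Default 0.05.
#' @param ramp_duration,hold_duration ramp and hold lengths (s).
#'   Defaults 1 and 180.
#' @param sample_rate sampling rate (Hz). Default 10.
#' @param noise_sd additive Gaussian stress noise (kPa).
#' @param specimen_diameter,specimen_thickness punch diameter and slice
#'   thickness (mm). Defaults 6 and 2.
#' @param seed integer seed for the noise.
#' @return an object of class `trace_sim_spec`.
#' @export
trace_sim_spec <- function(E_true = 5, Rs_true = 1.8,
                           tau_fast_true = 2, tau_slow_true = 60,
                           amp_split = 0.5, offset_b_frac = 0,
                           n_steps = 4, strain_per_step = 0.05,
                           ramp_duration = 1, hold_duration = 180,
                           sample_rate = 10, noise_sd = 0,
                           specimen_diameter = 6, specimen_thickness = 2,
                           seed = 1L) {
  if (tau_fast_true >= tau_slow_true)
    stopf("tau_fast_true (%g s) must be smaller than tau_slow_true (%g s)",
          tau_fast_true, tau_slow_true)
  if (Rs_true < 1) stopf("Rs_true must be >= 1 (got %g)", Rs_true)
  if (n_steps * strain_per_step >= 1)
    stopf("cumulative strain %g must stay below 1",
          n_steps * strain_per_step)
  if (amp_split < 0 || amp_split > 1) stopf("amp_split must be in [0, 1]")
  if (any(c(ramp_duration, hold_duration, sample_rate,
            specimen_diameter, specimen_thickness) <= 0))
    stopf("durations, sample rate and geometry must be positive")
  structure(list(E_true = E_true, Rs_true = Rs_true,
                 tau_fast_true = tau_fast_true,
                 tau_slow_true = tau_slow_true,
                 amp_split = amp_split, offset_b_frac = offset_b_frac,
                 n_steps = as.integer(n_steps),
                 strain_per_step = strain_per_step,
                 ramp_duration = ramp_duration,
                 hold_duration = hold_duration,
                 sample_rate = sample_rate, noise_sd = noise_sd,
                 specimen_diameter = specimen_diameter,
                 specimen_thickness = specimen_thickness,
                 seed = as.integer(seed)),
            class = "trace_sim_spec")
}

#' Simulate a step-hold compression trace
#'
#' Generates the time / displacement / force record an unconfined
#' compression test would produce under the model in
#' [trace_sim_spec()]. Displacement follows the ramp-hold staircase;
#' stress during hold i decays from the peak `Rs_true * b_i` to the
#' equilibrium `b_i = (1 + offset_b_frac) * E_true * strain_i`; force is
#' stress times the specimen cross-section. Gaussian noise of
#' `noise_sd` kPa is added to the stress before conversion to force.
#'
#' @param spec a [trace_sim_spec()].
#' @return a [relaxation_trace()] (data frame with columns `time_s`,
#'   `displacement_mm`, `force_N`, plus specimen geometry attributes).
#' @export
simulate_trace <- function(spec) {
  stopifnot(inherits(spec, "trace_sim_spec"))
  dt <- 1 / spec$sample_rate
  step_len <- spec$ramp_duration + spec$hold_duration
  total <- spec$n_steps * step_len
  t <- seq(0, total, by = dt)
  d_step <- spec$strain_per_step * spec$specimen_thickness # mm

  disp <- numeric(length(t))
  sigma <- numeric(length(t)) # kPa

  # model value at the end of a hold (start point of the next ramp)
  hold_sigma <- function(i, tt) {
    b <- (1 + spec$offset_b_frac) * spec$E_true * i * spec$strain_per_step
    amp <- (spec$Rs_true - 1) *
      spec$E_true * i * spec$strain_per_step * (1 + spec$offset_b_frac)
    a1 <- spec$amp_split * amp
    a2 <- (1 - spec$amp_split) * amp
    a1 * exp(-tt / spec$tau_fast_true) + a2 * exp(-tt / spec$tau_slow_true) + b
  }

  sigma_prev_end <- 0
  for (i in seq_len(spec$n_steps)) {
    t0 <- (i - 1) * step_len
    in_ramp <- t >= t0 & t < t0 + spec$ramp_duration
    in_hold <- t >= t0 + spec$ramp_duration & t <= t0 + step_len
    frac <- (t[in_ramp] - t0) / spec$ramp_duration
    disp[in_ramp] <- (i - 1) * d_step + frac * d_step
    disp[in_hold] <- i * d_step
    sigma_peak <- hold_sigma(i, 0)
    sigma[in_ramp] <- sigma_prev_end + frac * (sigma_peak - sigma_prev_end)
    sigma[in_hold] <- hold_sigma(i, t[in_hold] - (t0 + spec$ramp_duration))
    sigma_prev_end <- hold_sigma(i, spec$hold_duration)
  }

  if (spec$noise_sd > 0) {
    rs <- .Random.seed_save()
    on.exit(.Random.seed_restore(rs))
    set.seed(spec$seed)
    sigma <- sigma + stats::rnorm(length(sigma), 0, spec$noise_sd)
  }

  area_m2 <- pi * (spec$specimen_diameter / 2 / 1000)^2
  force <- sigma * 1000 * area_m2 # kPa -> Pa -> N
  relaxation_trace(data.frame(time_s = t, displacement_mm = disp,
                              force_N = force),
                   specimen_diameter = spec$specimen_diameter,
                   specimen_thickness = spec$specimen_thickness)
}
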