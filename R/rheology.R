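# Unconfined-compression viscoelastic analysis: stress/strain
# conversion, ramp-hold segmentation, Young's modulus, the
# instantaneous/equilibrium modulus ratio, and bi-exponential
# stress-relaxation fits.

#' Construct a relaxation trace
#'
#' Time / displacement / force record of a step-hold unconfined
#' compression test on a cylindrical specimen, with the specimen
#' geometry attached (needed to convert force to stress and
#' displacement to strain).
#'
#' @param df data frame with numeric columns `time_s` (strictly
#'   increasing), `displacement_mm`, `force_N`.
#' @param specimen_diameter punch diameter (mm).
#' @param specimen_thickness specimen thickness (mm).
#' @return a `relaxation_trace` (a data frame subclass).
#' @export
relaxation_trace <- function(df, specimen_diameter, specimen_thickness) {
  need <- c("time_s", "displacement_mm", "force_N")
  miss <- setdiff(need, names(df))
  if (length(miss)) stopf("trace is missing column(s): %s",
                          paste(miss, collapse = ", "))
  for (cc in need) if (!is.numeric(df[[cc]]))
    stopf("trace column '%s' is not numeric", cc)
  if (anyNA(df[need])) stopf("trace contains missing values")
  if (any(diff(df$time_s) <= 0)) stopf("time must be strictly increasing")
  if (specimen_diameter <= 0 || specimen_thickness <= 0)
    stopf("specimen geometry must be positive")
  structure(df[need],
            specimen_diameter = specimen_diameter,
            specimen_thickness = specimen_thickness,
            class = c("relaxation_trace", "data.frame"))
}

#' Convert a trace to stress and strain
#'
#' Stress is force over the specimen cross-section,
#' sigma = F / (pi (d/2)^2), reported in kPa; strain is displacement
#' over the specimen thickness. Compression is taken positive
#' throughout.
#'
#' @param trace a [relaxation_trace()].
#' @return data frame with `time_s`, `strain` (dimensionless) and
#'   `stress_kPa`.
#' @export
to_stress_strain <- function(trace) {
  stopifnot(inherits(trace, "relaxation_trace"))
  d <- attr(trace, "specimen_diameter")
  h <- attr(trace, "specimen_thickness")
  area_m2 <- pi * (d / 2 / 1000)^2
  data.frame(time_s = trace$time_s,
             strain = trace$displacement_mm / h,
             stress_kPa = trace$force_N / area_m2 / 1000)
}

#' Segment a step-hold trace into ramp and hold windows
#'
#' Ramps are located by thresholding the displacement rate at half its
#' maximum; each hold spans from a ramp's end to the next ramp's start.
#' The strain level of a step is the median plateau displacement over
#' its hold divided by the specimen thickness.
#'
#' @param trace a [relaxation_trace()].
#' @param n_steps expected number of steps; a mismatch with the detected
#'   ramp count is an error listing the detected ramp times.
#' @return list of `step_segment`s, each with `step_index`,
#'   `ramp_window` and `hold_window` (s), `strain_level`, and the hold
#'   `time_s` / `stress_kPa` series (time re-zeroed at hold start).
#' @export
segment_steps <- function(trace, n_steps = 4) {
  stopifnot(inherits(trace, "relaxation_trace"))
  ss <- to_stress_strain(trace)
  t <- trace$time_s
  rate <- c(0, diff(trace$displacement_mm) / diff(t))
  peak <- max(abs(rate))
  if (peak <= 0)
    stopf("no ramps detected: displacement is constant")
  moving <- abs(rate) > 0.5 * peak
  rl <- rle(moving)
  ends <- cumsum(rl$lengths)
  starts <- ends - rl$lengths + 1L
  ramp_ids <- which(rl$values)
  if (length(ramp_ids) != n_steps)
    stopf("detected %d ramps (expected %d) at t = %s s",
          length(ramp_ids), n_steps,
          paste(signif(t[starts[ramp_ids]], 4), collapse = ", "))
  h <- attr(trace, "specimen_thickness")
  segs <- vector("list", n_steps)
  for (k in seq_len(n_steps)) {
    r0 <- starts[ramp_ids[k]]; r1 <- ends[ramp_ids[k]]
    h1 <- if (k < n_steps) starts[ramp_ids[k + 1]] - 1L else length(t)
    hold_i <- (r1 + 1L):h1
    if (length(hold_i) < 3) stopf("hold window of step %d is too short", k)
    plateau <- stats::median(trace$displacement_mm[hold_i])
    segs[[k]] <- structure(list(
      step_index = k,
      ramp_window = c(t[r0], t[r1]),
      hold_window = c(t[hold_i[1]], t[h1]),
      strain_level = plateau / h,
      ramp_stress = ss$stress_kPa[r0:r1],
      time_s = ss$time_s[hold_i] - ss$time_s[hold_i[1]],
      stress_kPa = ss$stress_kPa[hold_i]),
      class = "step_segment")
  }
  segs
}

# Equilibrium stress of a hold: mean over the final `frac` of the window.
#' @noRd
equilibrium_stress <- function(seg, frac = 0.10) {
  n <- length(seg$stress_kPa)
  mean(seg$stress_kPa[seg$time_s >= (1 - frac) * max(seg$time_s)])
}

#' Young's modulus from the equilibrium stress-strain relation
#'
#' Ordinary least squares of the per-step equilibrium stress (mean of
#' the final 10\% of each hold) against the step strain level,
#' sigma = E * epsilon + C. The slope is the (equilibrium) Young's
#' modulus. A linear model is appropriate for brain-like tissue up to
#' about 20\% strain.
#'
#' @param segments list of `step_segment`s from [segment_steps()].
#' @param eq_frac fraction of the hold tail averaged for the
#'   equilibrium stress. Default 0.10.
#' @param sigma_eq optional per-segment equilibrium stresses (kPa)
#'   replacing the tail means, e.g. the fitted asymptotes from
#'   [fit_relaxation()], which are unbiased when the slow relaxation has
#'   not fully decayed by the end of the hold.
#' @return list with `E` and `C` (kPa), their standard errors, and the
#'   per-step `strain` / `stress_eq` table used for the fit.
#' @export
fit_youngs_modulus <- function(segments, eq_frac = 0.10, sigma_eq = NULL) {
  if (length(segments) < 2)
    stopf("need at least 2 steps for a stress-strain fit")
  strain <- vapply(segments, function(s) s$strain_level, 0)
  s_eq <- if (!is.null(sigma_eq)) {
    if (length(sigma_eq) != length(segments))
      stopf("sigma_eq must have one value per segment")
    sigma_eq
  } else vapply(segments, equilibrium_stress, 0, frac = eq_frac)
  fit <- stats::lm(s_eq ~ strain)
  cf <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  list(E = unname(cf["strain"]), C = unname(cf["(Intercept)"]),
       E_se = unname(se["strain"]), C_se = unname(se["(Intercept)"]),
       table = data.frame(strain = strain, stress_eq_kPa = s_eq))
}

#' Instantaneous/equilibrium modulus ratio of one step
#'
#' `R_s = sigma_max / sigma_equilibrium`, the peak stress reached during
#' the ramp (and early hold) over the equilibrated stress at the end of
#' the hold. Values above 1 quantify rate-dependent stiffening: how much
#' stress the tissue sheds while relaxing to equilibrium.
#'
#' @param seg a `step_segment`.
#' @param eq_frac tail fraction for the equilibrium mean. Default 0.10.
#' @param peak `"ramp_hold"` (default: maximum over ramp and hold) or
#'   `"hold_start"` (first hold sample); the two differ negligibly for
#'   1 s ramps.
#' @return list with `R_s`, `sigma_max`, `sigma_eq` (kPa).
#' @export
modulus_ratio <- function(seg, eq_frac = 0.10,
                          peak = c("ramp_hold", "hold_start")) {
  peak <- match.arg(peak)
  s_eq <- equilibrium_stress(seg, frac = eq_frac)
  if (s_eq <= 0) stopf("equilibrium stress is not positive (%.3g kPa)", s_eq)
  s_max <- switch(peak,
    ramp_hold = max(c(seg$ramp_stress, seg$stress_kPa)),
    hold_start = seg$stress_kPa[1])
  list(R_s = s_max / s_eq, sigma_max = s_max, sigma_eq = s_eq)
}

# Residual sum of squares of the bi-exponential model for a start value.
#' @noRd
biexp_rss <- function(p, t, y) {
  sum((y - (p[1] * exp(-t / p[3]) + p[2] * exp(-t / p[4]) + p[5]))^2)
}

#' Fit the bi-exponential stress-relaxation model to one hold
#'
#' Nonlinear least squares of
#' `sigma(t) = a1 exp(-t/tau_fast) + a2 exp(-t/tau_slow) + b`
#' to the hold-window stress, time re-zeroed at the hold start.
#' Bi-exponential fits are initialization-sensitive, so a multistart
#' strategy is used: `b` starts at the equilibrium stress, the remaining
#' amplitude is split over {0.25, 0.5, 0.75}, and time constants start
#' on a log-spaced grid over [0.01, 1] times the hold duration, crossed
#' pairwise with tau_fast < tau_slow; the best-residual start is refined
#' with Levenberg-Marquardt under non-negativity bounds. Parameters are
#' reported with `tau_fast < tau_slow` regardless of optimizer
#' internals.
#'
#' A single-exponential comparison fit and a BIC-style parsimony score
#' are included: when the data carry only one decay time scale the
#' 2-exponential model is degenerate (a2 ~ 0 or tau_fast ~ tau_slow),
#' which is flagged.
#'
#' @param seg a `step_segment` from [segment_steps()].
#' @param eq_frac tail fraction used for the `b` start. Default 0.10.
#' @return list with `a1`, `a2` (kPa), `tau_fast`, `tau_slow` (s), `b`
#'   (kPa), `rss`, `converged`, `degenerate`, and the single-exponential
#'   comparison (`one_exp`: a, tau, b, rss, preferred).
#' @export
fit_relaxation <- function(seg, eq_frac = 0.10) {
  t <- seg$time_s
  y <- seg$stress_kPa
  hold_dur <- max(t)
  b0 <- equilibrium_stress(seg, frac = eq_frac)
  amp0 <- max(y[1] - b0, 1e-9)

  # a flat hold carries no decay information: the exact solution is
  # zero amplitudes with b at the stress level
  if (diff(range(y)) <= 1e-9 * max(abs(y), 1)) {
    return(list(a1 = 0, a2 = 0, tau_fast = 0.01 * hold_dur,
                tau_slow = 0.1 * hold_dur, b = mean(y), rss = 0,
                converged = TRUE, degenerate = TRUE,
                preferred_model = "one_exp",
                one_exp = list(a = 0, tau = 0.1 * hold_dur, b = mean(y),
                               rss = 0, preferred = TRUE)))
  }

  tau_grid <- exp(seq(log(0.01 * hold_dur), log(1 * hold_dur), length.out = 5))
  starts <- list()
  for (f in c(0.25, 0.5, 0.75))
    for (i in seq_along(tau_grid)) for (j in seq_along(tau_grid))
      if (tau_grid[i] < tau_grid[j])
        starts[[length(starts) + 1]] <-
          c(f * amp0, (1 - f) * amp0, tau_grid[i], tau_grid[j], max(b0, 0))

  rss0 <- vapply(starts, biexp_rss, 0, t = t, y = y)
  order_best <- order(rss0)[seq_len(min(3L, length(starts)))]

  model2 <- function(p) p[1] * exp(-t / p[3]) + p[2] * exp(-t / p[4]) + p[5]
  best <- NULL
  for (k in order_best) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = starts[[k]],
                         lower = c(0, 0, 1e-6, 1e-6, 0),
                         fn = function(p) y - model2(p),
                         control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- fit$deviance
    cf <- fit$par
    if (is.null(best) || rss < best$rss - 1e-12 ||
        (abs(rss - best$rss) <= 1e-12 && max(cf[3:4]) < best$ts_raw)) {
      best <- list(cf = cf, rss = rss, ts_raw = max(cf[3:4]),
                   converged = fit$info %in% 1:4)
    }
  }
  if (is.null(best))
    return(list(a1 = NA_real_, a2 = NA_real_, tau_fast = NA_real_,
                tau_slow = NA_real_, b = NA_real_, rss = NA_real_,
                converged = FALSE, degenerate = TRUE,
                preferred_model = "none", one_exp = NULL))

  cf <- best$cf
  # enforce the reporting order tau_fast < tau_slow
  if (cf[3] <= cf[4]) {
    a1 <- cf[1]; a2 <- cf[2]; tf <- cf[3]; ts <- cf[4]
  } else {
    a1 <- cf[2]; a2 <- cf[1]; tf <- cf[4]; ts <- cf[3]
  }

  one <- tryCatch({
    model1 <- function(p) p[1] * exp(-t / p[2]) + p[3]
    fit1 <- minpack.lm::nls.lm(par = c(amp0, sqrt(tf * ts), max(b0, 0)),
                               lower = c(0, 1e-6, 0),
                               fn = function(p) y - model1(p),
                               control = minpack.lm::nls.lm.control(
                                 maxiter = 200))
    list(a = fit1$par[1], tau = fit1$par[2], b = fit1$par[3],
         rss = fit1$deviance)
  }, error = function(e) NULL)

  n <- length(y)
  degenerate <- (a2 < 1e-3 * (a1 + a2 + 1e-12)) ||
    (a1 < 1e-3 * (a1 + a2 + 1e-12)) || (ts / tf < 1.05)
  preferred <- "two_exp"
  if (!is.null(one)) {
    bic2 <- n * log(best$rss / n) + 5 * log(n)
    bic1 <- n * log(one$rss / n) + 3 * log(n)
    one$preferred <- bic1 <= bic2
    if (one$preferred && degenerate) preferred <- "one_exp"
  }

  list(a1 = unname(a1), a2 = unname(a2), tau_fast = unname(tf),
       tau_slow = unname(ts), b = unname(cf[5]), rss = best$rss,
       converged = isTRUE(best$converged), degenerate = degenerate,
       preferred_model = preferred, one_exp = one)
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

#' Full viscoelastic analysis of one compression trace
#'
#' Segments the trace, fits the bi-exponential relaxation model on
#' every hold, and derives the modulus quantities. By default the
#' instantaneous and equilibrium stresses are taken from the fitted
#' model (`method = "fit"`): the equilibrium stress is the asymptote
#' `b`, which is unbiased even when the slow relaxation has not fully
#' decayed within the hold, and the instantaneous stress is the model
#' evaluated at the ramp end (extrapolating over the short gap between
#' the ramp end and the first hold sample), which is insensitive to
#' single-sample noise peaks. `method = "empirical"` instead uses the
#' tail-mean equilibrium and the observed peak, as in
#' [modulus_ratio()]; steps whose relaxation fit fails fall back to the
#' empirical estimates and are flagged.
#'
#' @param trace a [relaxation_trace()].
#' @param n_steps expected ramp-hold steps. Default 4.
#' @param eq_frac equilibrium tail fraction. Default 0.10.
#' @param method `"fit"` (model-based stresses, default) or
#'   `"empirical"`.
#' @return a `visco_fit`: list with `E`, `C` (and standard errors), the
#'   estimation `method`, and a per-step data frame (`strain`,
#'   `sigma_max`, `sigma_eq`, `R_s`, `a1`, `a2`, `tau_fast`,
#'   `tau_slow`, `b`, `rss`, `converged`).
#' @export
analyze_trace <- function(trace, n_steps = 4, eq_frac = 0.10,
                          method = c("fit", "empirical")) {
  method <- match.arg(method)
  segs <- segment_steps(trace, n_steps = n_steps)
  fits <- lapply(segs, fit_relaxation, eq_frac = eq_frac)
  rows <- vector("list", length(segs))
  sigma_eq_fit <- rep(NA_real_, length(segs))
  for (k in seq_along(segs)) {
    s <- segs[[k]]; fr <- fits[[k]]
    mr <- modulus_ratio(s, eq_frac = eq_frac)
    use_fit <- method == "fit" && isTRUE(fr$converged) && !is.na(fr$b) &&
      fr$b > 0
    if (use_fit) {
      gap <- s$hold_window[1] - s$ramp_window[2]
      sigma_max <- fr$a1 * exp(gap / fr$tau_fast) +
        fr$a2 * exp(gap / fr$tau_slow) + fr$b
      sigma_eq <- fr$b
    } else {
      sigma_max <- mr$sigma_max
      sigma_eq <- mr$sigma_eq
    }
    sigma_eq_fit[k] <- sigma_eq
    rows[[k]] <- data.frame(step = s$step_index, strain = s$strain_level,
                            sigma_max_kPa = sigma_max,
                            sigma_eq_kPa = sigma_eq,
                            R_s = sigma_max / sigma_eq,
                            a1_kPa = fr$a1, a2_kPa = fr$a2,
                            tau_fast_s = fr$tau_fast,
                            tau_slow_s = fr$tau_slow,
                            b_kPa = fr$b, rss = fr$rss,
                            converged = fr$converged,
                            model_based = use_fit)
  }
  em <- fit_youngs_modulus(segs, eq_frac = eq_frac,
                           sigma_eq = sigma_eq_fit)
  structure(list(E = em$E, C = em$C, E_se = em$E_se, C_se = em$C_se,
                 method = method, steps = do.call(rbind, rows)),
            class = "visco_fit")
}

#' @export
print.visco_fit <- function(x, ...) {
  cat(sprintf("<visco_fit> E = %.4g kPa (SE %.2g), C = %.4g kPa\n",
              x$E, x$E_se, x$C))
  print(x$steps, digits = 4)
  invisible(x)
}
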