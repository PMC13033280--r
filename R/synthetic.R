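#' Synthetic CCB-like source model
#'
#' A two-parameter log-polynomial central-axis depth-dose family,
#' `dose(z) = D0 * exp(-a*z - b*z^2)`, emulating the steep near-surface
#' gradient of a Ru-106 CCB plaque (about 2 % per 0.1 mm at the surface,
#' i.e. a = 0.2/mm) with monotone decay out to 10 mm. It is a test-bed
#' family, not a fit to real CCB data: it reproduces the surface gradient
#' and monotone fall-off, nothing more.
#'
#' @param surface_dose_rate D0, Gy/min at z = 0; default 0.1 Gy/min, a
#'   typical CCB surface dose-rate magnitude.
#' @param log_gradient_surface a, relative log-dose slope per mm at the
#'   surface; default 0.2/mm (2 % per 0.1 mm).
#' @param curvature b, second-order log coefficient per mm^2; default 0.01.
#' @param reference_time calendar timestamp the model dose rates refer to.
#' @return an object of class `synthetic_model`.
#' @export
synthetic_model <- function(surface_dose_rate = 0.1,
                            log_gradient_surface = 0.2,
                            curvature = 0.01,
                            reference_time = "2026-01-01") {
  check_that(surface_dose_rate > 0, "surface_dose_rate must be positive")
  a <- log_gradient_surface
  b <- curvature
  check_that(a >= 0, "log_gradient_surface must be >= 0")
  # strictly decreasing log-dose on [0, 10]: a + 2 b z > 0 there
  check_that(a > 0 && a + 2 * b * 10 > 0,
             "parameterization is not strictly decreasing on [0, 10] mm")
  structure(list(surface_dose_rate = surface_dose_rate,
                 log_gradient_surface = a, curvature = b,
                 reference_time = as_timestamp(reference_time)),
            class = "synthetic_model")
}

#' @rdname synthetic_model
#' @param model a `synthetic_model`.
#' @param z depth(s), mm.
#' @return `model_dose()`: dose rate(s) at `z`, Gy/min at the model's
#'   reference time.
#' @export
model_dose <- function(model, z) {
  check_that(inherits(model, "synthetic_model"),
             "model must be a synthetic_model")
  model$surface_dose_rate *
    exp(-model$log_gradient_surface * z - model$curvature * z^2)
}

#' @export
print.synthetic_model <- function(x, ...) {
  cat(sprintf(paste0("Synthetic CCB-like source: D0 = %g Gy/min, ",
                     "a = %g /mm, b = %g /mm^2, ref %s\n"),
              x$surface_dose_rate, x$log_gradient_surface, x$curvature,
              format_timestamp(x$reference_time)))
  invisible(x)
}

# Acquisition time at depth z: linear from 10 s at 2 mm to 60 s at 10 mm
# (signal weakens with depth), clamped at the endpoints.
acquisition_time_at <- function(z, t_min = 10, t_max = 60,
                                z_min = 2, z_max = 10) {
  f <- pmin(pmax((z - z_min) / (z_max - z_min), 0), 1)
  t_min + f * (t_max - t_min)
}

# Mean-one multiplicative lognormal noise factors.
lognormal_noise <- function(n, rel_sigma_pct) {
  if (rel_sigma_pct == 0) return(rep(1, n))
  sl <- rel_sigma_pct / 100
  stats::rlnorm(n, meanlog = -sl^2 / 2, sdlog = sl)
}

#' Simulate a bidirectional measurement session
#'
#' Generates a forward (2 to 10 mm) and reverse (10 back to 2 mm) pass with
#' `n_repeats` readings per depth, acquisition times interpolating linearly
#' from 10 s at 2 mm to 60 s at 10 mm, constant-rate backgrounds measured
#' before and after, multiplicative mean-one lognormal reading noise of the
#' stated relative sigma, and source decay across the session timeline. The
#' ideal reading rate at depth z and time t is
#' `dose(z) * 2^(-(t - t_ref)/T_half) / (N * kq(z))` divided by the session
#' correction factors, plus the background rate — so the processing chain
#' inverts the simulation exactly when the noise is zero.
#'
#' The default noise of 1.5 % per reading is calibrated so that the
#' estimated per-depth repeatability of a 10-repeat bidirectional session
#' falls in the 0.3-0.8 % band typical of this measurement setup.
#'
#' @param model a [synthetic_model()].
#' @param geometry a [detector_geometry()].
#' @param calibration a [calibration_coefficient()].
#' @param kq a [kq_table()] covering the session depths.
#' @param noise_rel relative reading noise, percent (>= 0).
#' @param background_rate constant background, reading units per second.
#' @param seed integer RNG seed (mandatory: sessions are reproducible).
#' @param depths_mm active-volume depths, mm; default 2:10.
#' @param n_repeats readings per series; default 10.
#' @param decay a [decay_parameters()] governing source decay over the
#'   session timeline.
#' @param temperature_C,electrometer_factor session environment; the raw
#'   readings are divided by the corresponding correction factors so that
#'   applying the corrections recovers the ideal reading.
#' @param plaque_id,detector_id labels.
#' @return a [measurement_session()] dated at the model reference time.
#' @export
simulate_session <- function(model, geometry = detector_geometry(),
                             calibration, kq,
                             noise_rel = 1.5, background_rate = 1e-4,
                             seed, depths_mm = 2:10, n_repeats = 10,
                             decay = decay_parameters(),
                             temperature_C = 20, electrometer_factor = 1,
                             plaque_id = "SYN-CCB", detector_id = "uSi-sim") {
  check_that(noise_rel >= 0, "noise_rel must be >= 0")
  check_that(background_rate >= 0, "background_rate must be >= 0")
  check_that(!missing(seed), "a seed is mandatory for simulated sessions")
  set.seed(seed)
  t0 <- model$reference_time
  corr <- electrometer_factor  # temperature coefficient defaults to 0 %/degC
  kqz <- kq_interpolate(kq, depths_mm)
  names(kqz) <- as.character(depths_mm)

  clock <- 0  # seconds since session start
  bg_series <- function(direction) {
    acq <- 60
    reads <- background_rate * acq * lognormal_noise(n_repeats, noise_rel)
    s <- reading_series(NA_real_, reads, acq, t0 + clock, direction)
    clock <<- clock + n_repeats * acq
    s
  }
  meas_series <- function(z, direction) {
    acq <- acquisition_time_at(z)
    t <- t0 + clock
    decay_fac <- 2^(-days_between(t, t0) / decay$half_life_days)
    ideal_rate <- model_dose(model, z) * decay_fac /
      (calibration$value * kqz[[as.character(z)]])
    raw_rate <- ideal_rate / corr + background_rate
    reads <- raw_rate * acq * lognormal_noise(n_repeats, noise_rel)
    s <- reading_series(z, reads, acq, t, direction)
    clock <<- clock + n_repeats * acq
    s
  }

  bg_pre <- bg_series("pre")
  forward <- lapply(sort(depths_mm), meas_series, direction = "forward")
  reverse <- lapply(sort(depths_mm, decreasing = TRUE), meas_series,
                    direction = "reverse")
  bg_post <- bg_series("post")

  measurement_session(forward = forward, reverse = reverse,
                      bg_pre = bg_pre, bg_post = bg_post,
                      temperature_C = temperature_C,
                      electrometer_factor = electrometer_factor,
                      detector_id = detector_id, plaque_id = plaque_id,
                      session_date = t0)
}

#' Simulate a vendor certificate
#'
#' Certificate table `dose(z) * (1 + bias_rel/100)` on a 0-10 mm grid with
#' the vendor's 11 % (k = 2) expanded uncertainty. Deterministic unless an
#' optional per-depth noise is enabled.
#'
#' @param model a [synthetic_model()].
#' @param bias_rel systematic vendor bias, percent; `|bias_rel| < 50`.
#' @param seed RNG seed, only used when `noise_rel > 0`.
#' @param depths_mm certificate grid, mm; default 0:10.
#' @param u_rel_expanded,k_cov certificate uncertainty convention.
#' @param noise_rel optional per-depth multiplicative noise, percent.
#' @param plaque_id plaque label.
#' @return a [certificate()].
#' @export
simulate_certificate <- function(model, bias_rel = 0, seed = NULL,
                                 depths_mm = 0:10,
                                 u_rel_expanded = 11, k_cov = 2,
                                 noise_rel = 0, plaque_id = "SYN-CCB") {
  check_that(abs(bias_rel) < 50, "|bias_rel| must be below 50 %")
  dose <- model_dose(model, depths_mm) * (1 + bias_rel / 100)
  if (noise_rel > 0) {
    check_that(!is.null(seed), "a seed is required for noisy certificates")
    set.seed(seed)
    dose <- dose * lognormal_noise(length(dose), noise_rel)
  }
  certificate(plaque_id = plaque_id, reference_time = model$reference_time,
              depth_mm = depths_mm, dose_rate = dose,
              u_rel_expanded = u_rel_expanded, k_cov = k_cov)
}

#' Default perturbation-factor profiles for chain simulation
#'
#' Smooth depth-parameterized profiles with the qualitative shapes of the
#' alanine-setup perturbations: k_gap below 1 at shallow depth approaching 1
#' with depth, k_al and k_holder rising with depth, k_vol slightly
#' decreasing (near 1 around 1 mm).
#'
#' @return named list of four functions of depth (mm):
#'   `k_gap`, `k_al`, `k_holder`, `k_vol`.
#' @export
ccb_default_factor_profiles <- function() {
  list(k_gap = function(z) 1 - 0.010 * exp(-z / 2),
       k_al = function(z) 1 + 0.012 * z,
       k_holder = function(z) 1 + 0.015 * z,
       k_vol = function(z) 1.002 - 0.002 * z)
}

#' Simulate a staged geometry-dose chain
#'
#' Builds the five staged geometry dose vectors so that the water-point dose
#' g5 equals the model dose and the successive ratios reproduce the supplied
#' factor profiles exactly: g1 = dose/k_tot, g2 = g1*k_gap, g3 = g2*k_al,
#' g4 = g3*k_holder, g5 = g4*k_vol. [perturbation_factors()] on the result
#' recovers the injected profiles.
#'
#' @param model a [synthetic_model()].
#' @param factor_profiles named list of four positive functions of depth:
#'   `k_gap`, `k_al`, `k_holder`, `k_vol`.
#' @param depth_mm chain depth grid, mm.
#' @return a [geometry_dose_chain()].
#' @export
simulate_geometry_chain <- function(model,
                                    factor_profiles = ccb_default_factor_profiles(),
                                    depth_mm = seq(0.25, 7.75, by = 0.5)) {
  need <- c("k_gap", "k_al", "k_holder", "k_vol")
  check_that(all(need %in% names(factor_profiles)),
             "factor_profiles must name k_gap, k_al, k_holder, k_vol")
  f <- lapply(factor_profiles[need], function(fn) fn(depth_mm))
  check_that(all(unlist(f) > 0), "all factor profiles must be positive")
  g5 <- model_dose(model, depth_mm)
  g4 <- g5 / f$k_vol
  g3 <- g4 / f$k_holder
  g2 <- g3 / f$k_al
  g1 <- g2 / f$k_gap
  geometry_dose_chain(depth_mm, g1, g2, g3, g4, g5)
}

#' Simulate per-pellet mean doses of an alanine stack
#'
#' Axial average of the model dose over each pellet slab; radial variation
#' over the 5 mm pellet diameter is ignored (the model is central-axis
#' only). The first pellet's front face sits at `stack_offset_mm`.
#'
#' @param model a [synthetic_model()].
#' @param n_pellets number of pellets (>= 1); default 11.
#' @param pellet_thickness_mm pellet thickness, mm; default 0.5. The 0.44 mm
#'   x 16 pellet layout used in transport modelling is equally valid input.
#' @param pellet_diameter_mm pellet diameter, mm (recorded, not used).
#' @param stack_offset_mm depth of the first pellet's front face, mm.
#' @return data frame with `pellet`, `z_front_mm`, `z_center_mm`,
#'   `mean_dose`.
#' @export
simulate_alanine_stack <- function(model, n_pellets = 11,
                                   pellet_thickness_mm = 0.5,
                                   pellet_diameter_mm = 5,
                                   stack_offset_mm = 0) {
  check_that(n_pellets >= 1, "n_pellets must be >= 1")
  check_that(pellet_thickness_mm > 0, "pellet thickness must be positive")
  t <- pellet_thickness_mm
  z1 <- stack_offset_mm + (seq_len(n_pellets) - 1) * t
  mean_dose <- vapply(z1, function(z) {
    stats::integrate(function(u) model_dose(model, u), z, z + t,
                     rel.tol = 1e-10)$value / t
  }, numeric(1))
  data.frame(pellet = seq_len(n_pellets), z_front_mm = z1,
             z_center_mm = z1 + t / 2, mean_dose = mean_dose)
}
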