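#' Raw reading processing
#'
#' Operations converting raw electrometer reading sessions into corrected,
#' decay-referenced net reading rates per depth with type-A uncertainties:
#' background subtraction, per-series statistics, bidirectional merging,
#' session corrections and decay referencing.
#'
#' @name measurement-processing
NULL

# Mean background rate (reading units / s) of one background series.
background_rate <- function(bg) {
  check_that(inherits(bg, "reading_series") && length(bg$readings) >= 1L,
             "background series must hold at least one reading")
  mean(bg$readings) / bg$acquisition_time_s
}

#' Subtract the average background from a reading series
#'
#' The pre- and post-session background rates are averaged and the mean rate,
#' scaled to the series acquisition time, is subtracted from every reading.
#' Optionally the background is interpolated linearly in time between the two
#' background measurements (drift model) instead of averaged; the plain
#' average is the default. Negative net readings are allowed and flagged via
#' an attribute.
#'
#' @param series a [reading_series()] of plaque measurements.
#' @param bg_pre,bg_post background [reading_series()].
#' @param drift if `TRUE`, interpolate the background rate linearly between
#'   the pre and post timestamps at the series timestamp.
#' @return a net [reading_series()]; attribute `negative_net` is `TRUE` if
#'   any net reading fell below zero.
#' @export
subtract_background <- function(series, bg_pre, bg_post, drift = FALSE) {
  r_pre <- background_rate(bg_pre)
  r_post <- background_rate(bg_post)
  rate <- if (drift) {
    span <- days_between(bg_post$timestamp, bg_pre$timestamp)
    if (span <= 0) (r_pre + r_post) / 2
    else {
      f <- days_between(series$timestamp, bg_pre$timestamp) / span
      f <- min(max(f, 0), 1)
      (1 - f) * r_pre + f * r_post
    }
  } else {
    (r_pre + r_post) / 2
  }
  net <- series$readings - rate * series$acquisition_time_s
  out <- series
  out$readings <- net
  attr(out, "negative_net") <- any(net < 0)
  out
}

#' Per-series reading statistics
#'
#' Mean reading rate and its type-A relative standard uncertainty (standard
#' error of the mean as a percentage of the mean). With a single reading the
#' type-A estimate is undefined and reported as `NA`, never as zero.
#'
#' @param series a (net) [reading_series()].
#' @return list with `mean_rate` (reading units / s) and `u_typeA_rel` (%).
#' @examples
#' s <- reading_series(5, c(9, 10, 11), 1, "2026-01-01", "forward")
#' series_statistics(s)  # mean 10, type-A 5.77 %
#' @export
series_statistics <- function(series) {
  rates <- series$readings / series$acquisition_time_s
  m <- mean(rates)
  u <- if (length(rates) < 2L) NA_real_
  else {
    sem <- stats::sd(rates) / sqrt(length(rates))
    100 * sem / abs(m)
  }
  list(mean_rate = m, u_typeA_rel = u)
}

#' Merge forward and reverse passes
#'
#' Per depth, the combined reading is the unweighted mean of the forward and
#' reverse mean rates. The repeatability estimate combines, in quadrature,
#' the pooled type-A uncertainty of that mean (`sqrt(uA_f^2 + uA_r^2)/2`)
#' with half the relative forward/reverse difference — the latter captures
#' systematic drift over the session that the within-series scatter misses.
#'
#' @param forward,reverse data frames with columns `depth_mm`, `mean_rate`,
#'   `u_typeA_rel` (one row per depth) as produced from [series_statistics()].
#' @return data frame with columns `depth_mm`, `mean_rate`, `u_typeA_rel`
#'   (pooled), `direction_rel` (half forward/reverse relative difference, %)
#'   and `repeatability_rel` (%).
#' @export
merge_bidirectional <- function(forward, reverse) {
  forward <- forward[order(forward$depth_mm), , drop = FALSE]
  reverse <- reverse[order(reverse$depth_mm), , drop = FALSE]
  check_that(nrow(forward) == nrow(reverse) &&
               all(forward$depth_mm == reverse$depth_mm),
             "forward and reverse passes must cover identical depth sets")
  m <- (forward$mean_rate + reverse$mean_rate) / 2
  direction <- 100 * abs(forward$mean_rate - reverse$mean_rate) / (2 * abs(m))
  pooled <- sqrt(forward$u_typeA_rel^2 + reverse$u_typeA_rel^2) / 2
  data.frame(depth_mm = forward$depth_mm,
             mean_rate = m,
             u_typeA_rel = pooled,
             direction_rel = direction,
             repeatability_rel = sqrt(pooled^2 + direction^2))
}

#' Apply electrometer and temperature corrections
#'
#' Multiplies the reading by the electrometer calibration factor and a linear
#' temperature sensitivity model
#' `1 + coefficient_pct_per_C/100 * (temperature_C - reference_temperature_C)`.
#' Silicon diodes carry no documented temperature formula for this setup, so
#' the coefficient defaults to 0 %/degC (no-op); the budget still carries a
#' temperature component.
#'
#' @param reading reading or reading rate.
#' @param electrometer_factor multiplicative correction, > 0.
#' @param temperature_C phantom temperature, Celsius.
#' @param reference_temperature_C reference temperature, Celsius.
#' @param coefficient_pct_per_C linear sensitivity, percent per degC.
#' @return corrected reading.
#' @export
apply_session_corrections <- function(reading, electrometer_factor = 1,
                                      temperature_C = 20,
                                      reference_temperature_C = 20,
                                      coefficient_pct_per_C = 0) {
  check_that(electrometer_factor > 0, "electrometer_factor must be positive")
  tfac <- 1 + coefficient_pct_per_C / 100 *
    (temperature_C - reference_temperature_C)
  check_that(tfac > 0, "temperature factor must be positive")
  reading * electrometer_factor * tfac
}

#' Decay-correct a rate to a reference time
#'
#' Standard exponential decay: `rate * 2^((t_meas - t_ref) / T_half)`.
#' Correcting toward an earlier reference time increases the rate.
#'
#' @param rate measured rate at `t_meas`.
#' @param t_meas,t_ref measurement and reference timestamps.
#' @param decay a [decay_parameters()].
#' @return rate referenced to `t_ref`.
#' @export
decay_correct <- function(rate, t_meas, t_ref, decay = decay_parameters()) {
  check_that(inherits(decay, "decay_parameters"),
             "decay must be a decay_parameters object")
  rate * 2^(days_between(t_meas, t_ref) / decay$half_life_days)
}

#' Water-equivalent depth of the active volume
#'
#' Adds the detector's effective-depth offset (active volume beneath the
#' detector surface) to the nominal plaque-to-detector gap.
#'
#' @param nominal_gap_mm nominal distance from plaque surface centre to the
#'   detector surface, mm (>= 0).
#' @param geometry a [detector_geometry()].
#' @return water-equivalent depth of the active-volume front face, mm.
#' @export
water_equivalent_depth <- function(nominal_gap_mm,
                                   geometry = detector_geometry()) {
  check_that(all(nominal_gap_mm >= 0), "nominal_gap_mm must be >= 0")
  nominal_gap_mm + geometry$effective_depth_offset_mm
}

#' Process a full measurement session
#'
#' Runs the per-depth chain: background subtraction for every series,
#' per-series statistics, optional decay referencing of each series' rate to
#' `reference_time`, bidirectional merging, and session corrections. The ten
#' repeats of each series are reduced to statistics per direction first, then
#' the two directions are merged.
#'
#' @param session a [measurement_session()].
#' @param decay optional [decay_parameters()]; with `reference_time`, every
#'   series rate is decay-corrected to the reference time before merging.
#' @param reference_time reference timestamp (required when `decay` given).
#' @param reference_temperature_C,temperature_coefficient_pct_per_C see
#'   [apply_session_corrections()].
#' @param drift background drift interpolation, see [subtract_background()].
#' @return data frame as [merge_bidirectional()], with the corrected
#'   `mean_rate` per depth.
#' @export
process_session <- function(session, decay = NULL, reference_time = NULL,
                            reference_temperature_C = 20,
                            temperature_coefficient_pct_per_C = 0,
                            drift = FALSE) {
  check_that(inherits(session, "measurement_session"),
             "process_session needs a measurement_session")
  if (!is.null(decay))
    check_that(!is.null(reference_time),
               "reference_time is required for decay correction")

  one_pass <- function(series_list) {
    rows <- lapply(series_list, function(s) {
      net <- subtract_background(s, session$bg_pre, session$bg_post,
                                 drift = drift)
      st <- series_statistics(net)
      rate <- st$mean_rate
      if (!is.null(decay))
        rate <- decay_correct(rate, s$timestamp, reference_time, decay)
      data.frame(depth_mm = s$depth_mm, mean_rate = rate,
                 u_typeA_rel = st$u_typeA_rel)
    })
    do.call(rbind, rows)
  }

  merged <- merge_bidirectional(one_pass(session$forward),
                                one_pass(session$reverse))
  merged$mean_rate <- apply_session_corrections(
    merged$mean_rate,
    electrometer_factor = session$electrometer_factor,
    temperature_C = session$temperature_C,
    reference_temperature_C = reference_temperature_C,
    coefficient_pct_per_C = temperature_coefficient_pct_per_C)
  merged
}
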