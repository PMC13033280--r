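#' Depth-dose curve assembly and comparison
#'
#' Building decay-referenced depth-dose curves from processed sessions,
#' polynomial extrapolation below the shallowest measurable depth,
#' normalization between datasets and agreement testing against vendor
#' certificates at expanded uncertainty.
#'
#' @name curve-analysis
NULL

#' Build a depth-dose curve from a measurement session
#'
#' Applies the full per-depth chain: background subtraction, per-series
#' statistics, decay referencing, bidirectional merging, session corrections,
#' and conversion to absorbed dose rate to water with the interpolated
#' depth-dependent beam-quality correction. The per-depth k = 1 uncertainty
#' comes from the supplied budget (evaluated at each depth); without a
#' budget, the measured repeatability is used.
#'
#' @param session a [measurement_session()].
#' @param calibration a [calibration_coefficient()].
#' @param kq a [kq_table()]; every session depth must lie within its range.
#' @param decay a [decay_parameters()].
#' @param reference_time timestamp the curve is decay-referenced to.
#' @param budget optional [uncertainty_budget()] for the per-depth k = 1
#'   uncertainty.
#' @param origin curve origin label; default derived from the calibration
#'   quality.
#' @param ... passed to [process_session()] (temperature model, drift).
#' @return a [depth_dose_curve()].
#' @export
build_curve <- function(session, calibration, kq, decay = decay_parameters(),
                        reference_time, budget = NULL, origin = NULL, ...) {
  merged <- process_session(session, decay = decay,
                            reference_time = reference_time, ...)
  check_that(nrow(merged) >= 2L,
             "need processed readings at >= 2 depths inside the kq range")
  kqz <- kq_interpolate(kq, merged$depth_mm)
  dose <- dose_from_reading(merged$mean_rate, calibration, kqz)
  u <- if (is.null(budget)) merged$repeatability_rel
  else vapply(merged$depth_mm, function(z) combine_budget(budget, z),
              numeric(1))
  if (is.null(origin))
    origin <- paste0("diode-", calibration$quality)
  depth_dose_curve(depths_mm = merged$depth_mm, dose_rate = dose,
                   reference_time = reference_time, u_rel_k1 = u,
                   source_id = session$plaque_id, origin = origin)
}

#' Extrapolate a curve below the measured range
#'
#' Polynomial regression in log-dose versus depth (default order 2 over all
#' measured depths — the near-exponential beta attenuation makes log-space
#' fits stable), evaluated at shallower target depths. Extrapolated points
#' are flagged and carry no measurement uncertainty (`NA`); measured points
#' are kept untouched, so the extended curve equals the measured curve from
#' the junction onward.
#'
#' @param curve a [depth_dose_curve()] of measured points.
#' @param target_depths depths (mm) below the measured minimum.
#' @param order polynomial order; must be smaller than the number of fitted
#'   points.
#' @param window optional depth range `c(lo, hi)` restricting the fit to
#'   measured depths within it; default all measured depths.
#' @return extended [depth_dose_curve()] with `extrapolated` flags.
#' @export
extrapolate_shallow <- function(curve, target_depths, order = 2,
                                window = NULL) {
  check_that(inherits(curve, "depth_dose_curve"),
             "curve must be a depth_dose_curve")
  check_that(all(target_depths < min(curve$depths_mm)),
             "target depths must lie below the measured range")
  keep <- !curve$extrapolated
  z <- curve$depths_mm[keep]
  d <- curve$dose_rate[keep]
  if (!is.null(window)) {
    inw <- z >= window[1] & z <= window[2]
    z <- z[inw]; d <- d[inw]
  }
  check_that(order < length(z),
             "polynomial order (%d) must be below the number of fitted points (%d)",
             order, length(z))
  fit <- stats::lm(log(d) ~ stats::poly(z, degree = order, raw = TRUE),
                   data = data.frame(z = z, d = d))
  target_depths <- sort(target_depths)
  pred <- exp(stats::predict(fit, newdata = data.frame(z = target_depths)))
  depth_dose_curve(
    depths_mm = c(target_depths, curve$depths_mm),
    dose_rate = c(pred, curve$dose_rate),
    reference_time = curve$reference_time,
    u_rel_k1 = c(rep(NA_real_, length(target_depths)), curve$u_rel_k1),
    source_id = curve$source_id, origin = curve$origin,
    extrapolated = c(rep(TRUE, length(target_depths)), curve$extrapolated))
}

# Linear interpolation of a curve (or certificate table) onto given depths.
interp_curve <- function(depths, dose, xout) {
  if (length(depths) == 1L) return(rep(dose, length(xout)))
  stats::approx(depths, dose, xout = xout)$y
}

#' Normalize one curve to a reference curve
#'
#' Per-depth ratio curve/reference over the overlapping depth range, with the
#' reference interpolated linearly onto the curve's depths. The ratio's
#' relative uncertainty is the quadrature of the two curves' relative
#' uncertainties.
#'
#' @param curve,reference_curve [depth_dose_curve()] objects with overlapping
#'   depth ranges.
#' @return data frame with `depth_mm`, `ratio`, `u_rel` (%).
#' @export
normalize_curves <- function(curve, reference_curve) {
  lo <- max(min(curve$depths_mm), min(reference_curve$depths_mm))
  hi <- min(max(curve$depths_mm), max(reference_curve$depths_mm))
  check_that(lo <= hi, "curves share no overlapping depth range")
  keep <- curve$depths_mm >= lo & curve$depths_mm <= hi
  z <- curve$depths_mm[keep]
  ref <- interp_curve(reference_curve$depths_mm, reference_curve$dose_rate, z)
  uref <- interp_curve(reference_curve$depths_mm, reference_curve$u_rel_k1, z)
  data.frame(depth_mm = z,
             ratio = curve$dose_rate[keep] / ref,
             u_rel = sqrt(curve$u_rel_k1[keep]^2 + uref^2))
}

#' Test agreement with a vendor certificate
#'
#' Per depth, the measured/certificate dose-rate ratio with an agreement flag:
#' agreement holds where `|ratio - 1|` does not exceed the combined expanded
#' uncertainty `k_cov * sqrt(u_meas^2 + u_cert^2) / 100`, both uncertainties
#' entering the quadrature at k = 1 (the certificate's expanded value is
#' first scaled down by its own coverage factor).
#'
#' @param measured a [depth_dose_curve()] with k = 1 uncertainties.
#' @param cert a [certificate()].
#' @param k_cov coverage factor for the comparison (default 2, matching
#'   expanded-uncertainty reporting).
#' @return data frame with `depth_mm`, `measured`, `certificate`, `ratio`,
#'   `u_combined_expanded_rel` (%), `within` (logical).
#' @export
certificate_agreement <- function(measured, cert, k_cov = 2) {
  check_that(inherits(cert, "certificate"), "cert must be a certificate")
  lo <- max(min(measured$depths_mm), min(cert$depth_mm))
  hi <- min(max(measured$depths_mm), max(cert$depth_mm))
  check_that(lo <= hi, "measured curve and certificate share no depths")
  keep <- measured$depths_mm >= lo & measured$depths_mm <= hi
  z <- measured$depths_mm[keep]
  u_meas <- measured$u_rel_k1[keep]
  check_that(!anyNA(u_meas),
             "measured uncertainties are missing at compared depths")
  cval <- interp_curve(cert$depth_mm, cert$dose_rate, z)
  u_cert_k1 <- cert$u_rel_expanded / cert$k_cov
  ratio <- measured$dose_rate[keep] / cval
  u_comb <- k_cov * sqrt(u_meas^2 + u_cert_k1^2)
  data.frame(depth_mm = z, measured = measured$dose_rate[keep],
             certificate = cval, ratio = ratio,
             u_combined_expanded_rel = u_comb,
             within = abs(ratio - 1) <= u_comb / 100)
}

#' Mean relative difference between two calibration routes
#'
#' For two curves of the same plaque processed with different calibrations
#' (e.g. Co-60 versus 6 MeV), the per-depth relative difference
#' `(a/b - 1) * 100` and its unweighted mean over the common depths.
#'
#' @param curve_a,curve_b [depth_dose_curve()] objects sharing depths.
#' @return list with `per_depth` (data frame `depth_mm`, `rel_diff_pct`) and
#'   `mean_rel_diff_pct`.
#' @export
calibration_consistency <- function(curve_a, curve_b) {
  common <- intersect(curve_a$depths_mm, curve_b$depths_mm)
  check_that(length(common) >= 1L, "curves share no common depths")
  ia <- match(common, curve_a$depths_mm)
  ib <- match(common, curve_b$depths_mm)
  d <- (curve_a$dose_rate[ia] / curve_b$dose_rate[ib] - 1) * 100
  list(per_depth = data.frame(depth_mm = common, rel_diff_pct = d),
       mean_rel_diff_pct = mean(d))
}
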