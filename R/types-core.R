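#' Domain objects for Ru-106 plaque dosimetry
#'
#' Constructors for the small S3 objects shared by all processing stages:
#' calibration coefficients, detector geometry, decay parameters, reading
#' series and measurement sessions, beam-quality correction tables,
#' Monte-Carlo dose quartets, geometry-dose chains and vendor certificates.
#' Each constructor validates its invariants and returns a classed list.
#'
#' Depths are always water-equivalent millimetres measured on the plaque
#' central axis from the surface centre to the front face of the detector
#' active volume (plus the effective-depth offset). Dose rates are Gy/min
#' absorbed dose to water at a stated reference time.
#'
#' @name rudose-types
NULL

#' Absorbed-dose-to-water calibration coefficient
#'
#' The coefficient N_D,w converting a detector reading (arbitrary consistent
#' unit) to absorbed dose to water, established in a traceable reference
#' beam, either Co-60 or a 6 MeV clinical electron beam.
#'
#' @param quality reference beam quality, `"Co60"` or `"6MeV"`.
#' @param value Gy per reading unit; must be positive.
#' @param u_rel relative standard uncertainty in percent (k = 1).
#' @param lab provenance label (calibration laboratory).
#' @return an object of class `calibration_coefficient`.
#' @export
calibration_coefficient <- function(quality = c("Co60", "6MeV"),
                                    value, u_rel = 0, lab = "") {
  quality <- match.arg(quality)
  check_that(is.numeric(value) && length(value) == 1L && value > 0,
             "calibration coefficient value must be a single positive number")
  check_that(is.numeric(u_rel) && u_rel >= 0,
             "calibration coefficient u_rel must be >= 0")
  structure(list(quality = quality, value = value, u_rel = u_rel, lab = lab),
            class = "calibration_coefficient")
}

#' Ru-106 decay parameters
#'
#' @param half_life_days half-life in days. Default 371.8 d for Ru-106.
#' @param u_rel relative standard uncertainty in percent.
#' @return an object of class `decay_parameters`.
#' @export
decay_parameters <- function(half_life_days = 371.8, u_rel = 0.04) {
  check_that(is.numeric(half_life_days) && half_life_days > 0,
             "half_life_days must be positive")
  check_that(u_rel >= 0, "u_rel must be >= 0")
  structure(list(half_life_days = half_life_days, u_rel = u_rel),
            class = "decay_parameters")
}

#' Detector geometry for a microSilicon-type diode
#'
#' Active volume: a disc of radius 0.75 mm and thickness 18 um. The
#' effective-depth offset places the active volume beneath the detector
#' surface; 0.9 mm (manufacturer photon specification) is the default, with
#' 0.3 mm (electron specification) supported as an alternative.
#'
#' @param active_radius_mm active-volume radius, mm.
#' @param active_thickness_um active-volume thickness, micrometres.
#' @param effective_depth_offset_mm water-equivalent offset from detector
#'   surface to the active volume, mm.
#' @return an object of class `detector_geometry`.
#' @export
detector_geometry <- function(active_radius_mm = 0.75,
                              active_thickness_um = 18,
                              effective_depth_offset_mm = 0.9) {
  check_that(active_radius_mm > 0 && active_thickness_um > 0 &&
               effective_depth_offset_mm > 0,
             "all detector geometry dimensions must be positive")
  structure(list(active_radius_mm = active_radius_mm,
                 active_thickness_um = active_thickness_um,
                 effective_depth_offset_mm = effective_depth_offset_mm),
            class = "detector_geometry")
}

#' A repeated electrometer reading series at one depth
#'
#' @param depth_mm water-equivalent depth of the active-volume front face;
#'   `NA` for background series.
#' @param readings numeric vector of repeated charge readings (consistent
#'   arbitrary unit), at least one.
#' @param acquisition_time_s acquisition duration per reading, seconds.
#' @param timestamp acquisition time (`POSIXct` or ISO-8601 string).
#' @param direction `"forward"`, `"reverse"`, or for backgrounds `"pre"` /
#'   `"post"`.
#' @return an object of class `reading_series`.
#' @export
reading_series <- function(depth_mm, readings, acquisition_time_s,
                           timestamp,
                           direction = c("forward", "reverse", "pre", "post")) {
  direction <- match.arg(direction)
  check_that(length(readings) >= 1L && is.numeric(readings),
             "a reading series needs at least one numeric reading")
  check_that(is.numeric(acquisition_time_s) && acquisition_time_s > 0,
             "acquisition_time_s must be positive")
  structure(list(depth_mm = depth_mm,
                 readings = as.numeric(readings),
                 acquisition_time_s = acquisition_time_s,
                 timestamp = as_timestamp(timestamp),
                 direction = direction),
            class = "reading_series")
}

#' One plaque/detector measurement session
#'
#' Holds the forward (2 -> 10 mm) and reverse (10 -> 2 mm) reading passes
#' together with pre/post background series and session environment data.
#' Forward and reverse must cover identical depth sets.
#'
#' @param forward,reverse lists of [reading_series()].
#' @param bg_pre,bg_post background [reading_series()] (may read all zero).
#' @param temperature_C phantom temperature, Celsius.
#' @param electrometer_factor multiplicative electrometer correction.
#' @param detector_id,plaque_id labels.
#' @param session_date session timestamp.
#' @return an object of class `measurement_session`.
#' @export
measurement_session <- function(forward, reverse, bg_pre, bg_post,
                                temperature_C = 20,
                                electrometer_factor = 1,
                                detector_id = "", plaque_id = "",
                                session_date = Sys.time()) {
  check_that(length(forward) >= 1L && length(reverse) >= 1L,
             "session needs forward and reverse series")
  fd <- sort(vapply(forward, function(s) s$depth_mm, numeric(1)))
  rd <- sort(vapply(reverse, function(s) s$depth_mm, numeric(1)))
  check_that(length(fd) == length(rd) && all(fd == rd),
             "forward and reverse passes must cover identical depth sets")
  check_that(inherits(bg_pre, "reading_series") &&
               inherits(bg_post, "reading_series"),
             "pre and post background series are required (may be all-zero)")
  check_that(electrometer_factor > 0, "electrometer_factor must be positive")
  structure(list(forward = forward, reverse = reverse,
                 bg_pre = bg_pre, bg_post = bg_post,
                 temperature_C = temperature_C,
                 electrometer_factor = electrometer_factor,
                 detector_id = detector_id, plaque_id = plaque_id,
                 session_date = as_timestamp(session_date)),
            class = "measurement_session")
}

#' Depth-dependent beam quality correction table
#'
#' k_Q,Q0(z) for one (plaque model, calibration quality) pair, valid only for
#' the measurement setup under which the factors were computed.
#'
#' @param plaque_model plaque model label, e.g. `"CCB"`.
#' @param quality calibration quality Q0, `"Co60"` or `"6MeV"` (the field
#'   quality Q is the Ru-106 plaque field).
#' @param depth_mm strictly increasing depths, mm.
#' @param k_value correction factors, all positive.
#' @param u_typeA_rel,u_typeB_rel relative standard uncertainties, percent.
#' @return an object of class `kq_table`.
#' @export
kq_table <- function(plaque_model, quality = c("Co60", "6MeV"),
                     depth_mm, k_value, u_typeA_rel = 0, u_typeB_rel = 0) {
  quality <- match.arg(quality)
  check_that(length(depth_mm) == length(k_value) && length(depth_mm) >= 1L,
             "depth_mm and k_value must have equal nonzero length")
  check_that(all(diff(depth_mm) > 0), "kq table depths must strictly increase")
  check_that(all(k_value > 0), "all k_Q,Q0 values must be positive")
  structure(list(plaque_model = plaque_model,
                 quality_pair = c(Q = paste0("Ru106-", plaque_model), Q0 = quality),
                 depth_mm = as.numeric(depth_mm),
                 k_value = as.numeric(k_value),
                 u_typeA_rel = u_typeA_rel, u_typeB_rel = u_typeB_rel),
            class = "kq_table")
}

#' Monte-Carlo dose quartet for a beam-quality correction factor
#'
#' The four absorbed doses entering a k_Q,Q0 double ratio: dose to water and
#' average dose to the detector active volume, each in the measurement
#' quality Q and the calibration quality Q0 (consistent unit, e.g.
#' pGy/decay).
#'
#' @param dw_Q,ddet_Q,dw_Q0,ddet_Q0 positive doses.
#' @param u_rel named or positional numeric vector of four relative
#'   statistical uncertainties in percent, same order as the doses.
#' @return an object of class `mc_dose_quartet`.
#' @export
mc_dose_quartet <- function(dw_Q, ddet_Q, dw_Q0, ddet_Q0,
                            u_rel = c(0, 0, 0, 0)) {
  d <- c(dw_Q = dw_Q, ddet_Q = ddet_Q, dw_Q0 = dw_Q0, ddet_Q0 = ddet_Q0)
  check_that(all(d > 0), "all four quartet doses must be positive")
  check_that(length(u_rel) == 4L && all(u_rel >= 0),
             "u_rel must be four nonnegative percentages")
  structure(list(dw_Q = dw_Q, ddet_Q = ddet_Q,
                 dw_Q0 = dw_Q0, ddet_Q0 = ddet_Q0,
                 u_rel = as.numeric(u_rel)),
            class = "mc_dose_quartet")
}

#' Per-depth doses for the five staged alanine-setup geometries
#'
#' The staged geometries from which the perturbation chain is formed, in
#' fixed order: g1 full setup (source, pellet stack, holder, air gap); g2
#' air gap filled with PMMA; g3 alanine replaced by water; g4 holder
#' replaced by water; g5 a water point (microSilicon-sized scoring volume)
#' in full water.
#'
#' @param depth_mm shared depth grid, mm.
#' @param g1,g2,g3,g4,g5 positive dose vectors on that grid.
#' @return an object of class `geometry_dose_chain`.
#' @export
geometry_dose_chain <- function(depth_mm, g1, g2, g3, g4, g5) {
  gs <- list(g1 = g1, g2 = g2, g3 = g3, g4 = g4, g5 = g5)
  n <- length(depth_mm)
  check_that(all(vapply(gs, length, integer(1)) == n),
             "all five geometries must share one depth vector")
  check_that(all(unlist(gs) > 0), "all geometry doses must be positive")
  structure(c(list(depth_mm = as.numeric(depth_mm)),
              lapply(gs, as.numeric)),
            class = "geometry_dose_chain")
}

#' Vendor certificate for a sealed Ru-106 plaque
#'
#' The manufacturer depth-dose table with its expanded uncertainty (11 % at
#' k = 2 for the vendor's plastic-scintillator measurement).
#'
#' @param plaque_id plaque label.
#' @param reference_time certificate reference timestamp.
#' @param depth_mm,dose_rate certificate table: depth (mm) and dose rate
#'   (Gy/min) at `reference_time`.
#' @param u_rel_expanded expanded relative uncertainty in percent at
#'   coverage factor `k_cov`.
#' @param k_cov coverage factor of the stated uncertainty (vendor: 2).
#' @return an object of class `certificate`.
#' @export
certificate <- function(plaque_id, reference_time, depth_mm, dose_rate,
                        u_rel_expanded = 11, k_cov = 2) {
  check_that(length(depth_mm) == length(dose_rate) && length(depth_mm) >= 1L,
             "certificate table needs matching depth and dose vectors")
  check_that(all(diff(depth_mm) > 0), "certificate depths must strictly increase")
  check_that(all(dose_rate > 0), "certificate dose rates must be positive")
  check_that(u_rel_expanded >= 0, "u_rel_expanded must be >= 0")
  check_that(k_cov >= 1, "coverage factor must be >= 1")
  structure(list(plaque_id = plaque_id,
                 reference_time = as_timestamp(reference_time),
                 depth_mm = as.numeric(depth_mm),
                 dose_rate = as.numeric(dose_rate),
                 u_rel_expanded = u_rel_expanded, k_cov = k_cov),
            class = "certificate")
}

#' Central-axis depth-dose curve
#'
#' Absorbed dose rate to water versus water-equivalent depth on the plaque
#' central axis, decay-referenced to `reference_time`, with per-depth
#' relative standard uncertainties (k = 1). Points produced by shallow
#' extrapolation are flagged and carry no measurement uncertainty.
#'
#' @param depths_mm strictly increasing depths, mm.
#' @param dose_rate positive dose rates, Gy/min at `reference_time`.
#' @param reference_time calendar timestamp.
#' @param u_rel_k1 relative standard uncertainty per depth, percent
#'   (`NA` for extrapolated points).
#' @param source_id plaque identifier.
#' @param origin one of `"diode-Co60"`, `"diode-6MeV"`, `"alanine"`,
#'   `"certificate"`, `"synthetic"`.
#' @param extrapolated logical flag per depth.
#' @return an object of class `depth_dose_curve`.
#' @export
depth_dose_curve <- function(depths_mm, dose_rate, reference_time,
                             u_rel_k1 = rep(0, length(depths_mm)),
                             source_id = "", origin = "synthetic",
                             extrapolated = rep(FALSE, length(depths_mm))) {
  n <- length(depths_mm)
  check_that(length(dose_rate) == n && length(u_rel_k1) == n &&
               length(extrapolated) == n,
             "curve fields must have one value per depth")
  check_that(all(diff(depths_mm) > 0), "curve depths must strictly increase")
  check_that(all(dose_rate > 0), "dose rates must be positive everywhere")
  check_that(all(is.na(u_rel_k1) | u_rel_k1 >= 0), "u_rel_k1 must be >= 0")
  origins <- c("diode-Co60", "diode-6MeV", "alanine", "certificate", "synthetic")
  check_that(origin %in% origins,
             "origin must be one of %s", paste(origins, collapse = ", "))
  structure(list(depths_mm = as.numeric(depths_mm),
                 dose_rate = as.numeric(dose_rate),
                 reference_time = as_timestamp(reference_time),
                 u_rel_k1 = as.numeric(u_rel_k1),
                 source_id = source_id, origin = origin,
                 extrapolated = as.logical(extrapolated)),
            class = "depth_dose_curve")
}

#' @export
print.depth_dose_curve <- function(x, ...) {
  cat(sprintf("Depth-dose curve [%s] plaque '%s', %d depths (%g-%g mm)\n",
              x$origin, x$source_id, length(x$depths_mm),
              min(x$depths_mm), max(x$depths_mm)))
  cat(sprintf("  reference time: %s\n", format_timestamp(x$reference_time)))
  print(as.data.frame(x), ...)
  invisible(x)
}

#' @export
as.data.frame.depth_dose_curve <- function(x, ...) {
  data.frame(depth_mm = x$depths_mm, dose_rate = x$dose_rate,
             u_rel_k1 = x$u_rel_k1, extrapolated = x$extrapolated)
}

#' @export
plot.depth_dose_curve <- function(x, log = "y",
                                  xlab = "Depth [mm]",
                                  ylab = "Dose rate to water [Gy/min]", ...) {
  graphics::plot(x$depths_mm, x$dose_rate, log = log, type = "b",
                 pch = ifelse(x$extrapolated, 1, 19),
                 xlab = xlab, ylab = ylab, ...)
  u <- x$u_rel_k1 / 100 * x$dose_rate
  ok <- !is.na(u) & u > 0
  if (any(ok))
    graphics::arrows(x$depths_mm[ok], x$dose_rate[ok] - u[ok],
                     x$depths_mm[ok], x$dose_rate[ok] + u[ok],
                     angle = 90, code = 3, length = 0.03)
  invisible(x)
}

#' @export
print.kq_table <- function(x, ...) {
  cat(sprintf("k_Q,Q0 table: %s plaque, Q0 = %s (u_A %g %%, u_B %g %%)\n",
              x$plaque_model, x$quality_pair[["Q0"]],
              x$u_typeA_rel, x$u_typeB_rel))
  print(data.frame(depth_mm = x$depth_mm, k_value = x$k_value), ...)
  invisible(x)
}

#' @export
print.measurement_session <- function(x, ...) {
  cat(sprintf("Measurement session: plaque '%s', detector '%s', %s\n",
              x$plaque_id, x$detector_id, format_timestamp(x$session_date)))
  cat(sprintf("  %d forward + %d reverse series, depths %s mm\n",
              length(x$forward), length(x$reverse),
              paste(sort(vapply(x$forward, function(s) s$depth_mm,
                                numeric(1))), collapse = ", ")))
  invisible(x)
}

#' @export
print.certificate <- function(x, ...) {
  cat(sprintf("Certificate: plaque '%s', %s, u = %g %% (k = %g)\n",
              x$plaque_id, format_timestamp(x$reference_time),
              x$u_rel_expanded, x$k_cov))
  print(data.frame(depth_mm = x$depth_mm, dose_rate = x$dose_rate), ...)
  invisible(x)
}

# ---- timestamps ----------------------------------------------------------

# All timestamps are POSIXct in UTC; files use ISO-8601.
as_timestamp <- function(x) {
  if (inherits(x, "POSIXct")) return(x)
  if (is.character(x)) {
    fmt <- if (grepl("T", x, fixed = TRUE)) "%Y-%m-%dT%H:%M:%S" else
      if (grepl(":", x, fixed = TRUE)) "%Y-%m-%d %H:%M:%S" else "%Y-%m-%d"
    out <- as.POSIXct(x, format = fmt, tz = "UTC")
    if (any(is.na(out))) abort_parse("unparseable timestamp '%s'", x[is.na(out)][1])
    return(out)
  }
  abort_validation("timestamps must be POSIXct or ISO-8601 strings")
}

format_timestamp <- function(t) format(t, "%Y-%m-%dT%H:%M:%S", tz = "UTC")

# Signed time difference in days (t1 - t0).
days_between <- function(t1, t0) {
  as.numeric(difftime(as_timestamp(t1), as_timestamp(t0), units = "days"))
}
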