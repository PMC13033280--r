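#' Dose formalism
#'
#' Conversion of corrected net readings to absorbed dose to water via
#' calibration coefficients and beam-quality correction factors, computation
#' of k_Q,Q0 from Monte-Carlo dose quartets, and the alanine perturbation
#' chain for the PMMA-phantom setup.
#'
#' @name dose-formalism
NULL

#' Absorbed dose to water from a detector reading
#'
#' D_w = M * N_D,w * k_Q,Q0. If `M_net` is a reading rate the result is a
#' dose rate in the same time unit.
#'
#' @param M_net corrected net reading (or rate), > 0.
#' @param N_Dw a [calibration_coefficient()].
#' @param kq scalar beam-quality correction factor, > 0.
#' @return absorbed dose (rate) to water.
#' @export
dose_from_reading <- function(M_net, N_Dw, kq) {
  check_that(inherits(N_Dw, "calibration_coefficient"),
             "N_Dw must be a calibration_coefficient")
  check_that(all(M_net > 0) && all(kq > 0), "M_net and kq must be positive")
  M_net * N_Dw$value * kq
}

#' Interpolate a beam-quality correction table
#'
#' Linear interpolation of k_Q,Q0(z) between adjacent table rows; exact at
#' the nodes. No extrapolation: depths outside the tabulated range raise a
#' range error.
#'
#' @param table a [kq_table()].
#' @param depth_mm depth(s), mm, within the table range.
#' @return interpolated k_Q,Q0 value(s).
#' @export
kq_interpolate <- function(table, depth_mm) {
  check_that(inherits(table, "kq_table"), "table must be a kq_table")
  rng <- range(table$depth_mm)
  out_of_range <- depth_mm < rng[1] | depth_mm > rng[2]
  if (any(out_of_range))
    abort_range("depth %g mm outside k_Q,Q0 table range [%g, %g] mm",
                depth_mm[out_of_range][1], rng[1], rng[2])
  if (length(table$depth_mm) == 1L)
    return(rep(table$k_value, length(depth_mm)))
  stats::approx(table$depth_mm, table$k_value, xout = depth_mm)$y
}

#' Beam-quality correction factor from a Monte-Carlo dose quartet
#'
#' k_Q,Q0 = ((Dw/Ddet)_Q / (Dw/Ddet)_Q0) * r_ratio, where r_ratio is the
#' intrinsic-response ratio R_Q0/R_Q, modelled as exactly unity (any doubt
#' about that assumption is carried as a type-B budget component, not as a
#' free parameter). The statistical uncertainty is the quadrature of the
#' four dose uncertainties.
#'
#' @param quartet an [mc_dose_quartet()].
#' @param r_ratio intrinsic-response ratio; default 1.
#' @return list with `kq` and `u_stat_rel` (%).
#' @export
kq_from_mc <- function(quartet, r_ratio = 1) {
  check_that(inherits(quartet, "mc_dose_quartet"),
             "quartet must be an mc_dose_quartet")
  check_that(r_ratio > 0, "r_ratio must be positive")
  kq <- (quartet$dw_Q / quartet$ddet_Q) /
    (quartet$dw_Q0 / quartet$ddet_Q0) * r_ratio
  list(kq = kq, u_stat_rel = sqrt(sum(quartet$u_rel^2)))
}

#' Absorbed dose to water from an alanine EPR signal
#'
#' D_w = M_al * N_al * k_QRu,Q0, the alanine analogue of
#' [dose_from_reading()] with the alanine Co-60 calibration coefficient and
#' the Ru-106 beam-quality correction.
#'
#' @param M_al alanine EPR signal, > 0.
#' @param N_al alanine [calibration_coefficient()].
#' @param kq_ru beam-quality correction factor Co-60 -> Ru-106, > 0.
#' @return absorbed dose to water.
#' @export
alanine_dose <- function(M_al, N_al, kq_ru) {
  dose_from_reading(M_al, N_al, kq_ru)
}

#' Perturbation factors from a staged geometry-dose chain
#'
#' Successive ratios of the five staged geometries: k_gap = g2/g1 (air gap
#' filled with PMMA), k_al = g3/g2 (alanine replaced by water), k_holder =
#' g4/g3 (PMMA holder replaced by water; > 1 since water attenuates the
#' electrons less), k_vol = g5/g4 (transition to a microSilicon-sized water
#' point). The product telescopes to k_tot = g5/g1, which is verified
#' internally to relative 1e-12.
#'
#' @param chain a [geometry_dose_chain()].
#' @return object of class `perturbation_factors`: data-frame-like list with
#'   `depth_mm`, `k_gap`, `k_al`, `k_holder`, `k_vol`, `k_tot`.
#' @export
perturbation_factors <- function(chain) {
  check_that(inherits(chain, "geometry_dose_chain"),
             "chain must be a geometry_dose_chain")
  k_gap <- chain$g2 / chain$g1
  k_al <- chain$g3 / chain$g2
  k_holder <- chain$g4 / chain$g3
  k_vol <- chain$g5 / chain$g4
  k_tot <- chain$g5 / chain$g1
  stopifnot(all(abs(k_gap * k_al * k_holder * k_vol / k_tot - 1) < 1e-12))
  structure(list(depth_mm = chain$depth_mm,
                 k_gap = k_gap, k_al = k_al, k_holder = k_holder,
                 k_vol = k_vol, k_tot = k_tot),
            class = "perturbation_factors")
}

#' @export
print.perturbation_factors <- function(x, ...) {
  cat("Alanine-setup perturbation factors\n")
  print(as.data.frame(unclass(x)), ...)
  invisible(x)
}

#' @export
plot.perturbation_factors <- function(x, xlab = "Depth [mm]",
                                      ylab = "Perturbation factor", ...) {
  ks <- c("k_gap", "k_al", "k_holder", "k_vol", "k_tot")
  graphics::matplot(x$depth_mm, sapply(ks, function(k) x[[k]]),
                    type = "b", pch = 19, lty = 1,
                    xlab = xlab, ylab = ylab, ...)
  graphics::legend("topleft", legend = ks, col = seq_along(ks),
                   pch = 19, lty = 1, bty = "n")
  invisible(x)
}

#' Alanine beam-quality correction factor from dose ratios
#'
#' k_QRu,Q0 = ((Dw/Dal)_QRu / (Dw/Dal)_Q0) * r_ratio. The intrinsic alanine
#' sensitivity ratio r_ratio is modelled as unity carrying a 0.5 % type-B
#' uncertainty (Ru-106 and Co-60 assumed to affect alanine equally).
#'
#' @param ratio_Ru dose ratio (Dw/Dal) in the Ru-106 field, > 0.
#' @param ratio_Q0 dose ratio (Dw/Dal) in the calibration field, > 0.
#' @param r_ratio intrinsic-sensitivity ratio; default 1.
#' @param u_r_ratio_rel type-B uncertainty of `r_ratio`, percent.
#' @return list with `kq` and `u_r_ratio_rel` (to be carried into budgets).
#' @export
alanine_kq <- function(ratio_Ru, ratio_Q0, r_ratio = 1, u_r_ratio_rel = 0.5) {
  check_that(ratio_Ru > 0 && ratio_Q0 > 0 && r_ratio > 0,
             "dose ratios and r_ratio must be positive")
  list(kq = ratio_Ru / ratio_Q0 * r_ratio, u_r_ratio_rel = u_r_ratio_rel)
}

#' Volume-averaging factor over the detector active volume
#'
#' Ratio of the point dose at `depth_mm` to the mean of the axial dose
#' profile over the active volume (disc of the detector's radius and
#' thickness centred at `depth_mm`). The profile is a function of depth
#' only, so the disc average reduces to the axial slab average, evaluated by
#' adaptive quadrature at relative tolerance 1e-8. In steep gradients the
#' factor moves away from 1.
#'
#' @param dose_profile function of depth (mm) returning dose, positive over
#'   the slab.
#' @param geometry a [detector_geometry()].
#' @param depth_mm centre depth of the scoring volume, mm.
#' @return point dose / volume-averaged dose.
#' @export
volume_average_factor <- function(dose_profile, geometry = detector_geometry(),
                                  depth_mm) {
  half <- geometry$active_thickness_um / 1000 / 2
  z1 <- depth_mm - half
  z2 <- depth_mm + half
  probe <- dose_profile(seq(z1, z2, length.out = 21))
  check_that(all(probe > 0),
             "dose profile must be positive over the scoring volume")
  avg <- stats::integrate(dose_profile, z1, z2, rel.tol = 1e-8)$value /
    (z2 - z1)
  dose_profile(depth_mm) / avg
}
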