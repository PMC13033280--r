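test_that("build_curve recovers a zero-noise synthetic model exactly", {
  model <- syn_model()
  s <- syn_session(model)
  cur <- build_curve(s, syn_cal(), syn_kq(), decay_parameters(),
                     reference_time = model$reference_time)
  expect_s3_class(cur, "depth_dose_curve")
  expect_equal(cur$depths_mm, 2:10)
  expect_equal(cur$dose_rate, model_dose(model, 2:10), tolerance = 1e-10)
  expect_equal(cur$origin, "diode-Co60")
})

test_that("Co60 and 6MeV processing differ only by the N*kQ ratio", {
  model <- syn_model()
  s <- syn_session(model)  # simulated under the Co-60 calibration chain
  cal_co <- syn_cal("Co60")
  cal_6 <- calibration_coefficient("6MeV", 0.055, u_rel = 1.1)
  cur_co <- build_curve(s, cal_co, syn_kq("Co60"), decay_parameters(),
                        reference_time = model$reference_time)
  cur_6 <- build_curve(s, cal_6, syn_kq("6MeV"), decay_parameters(),
                       reference_time = model$reference_time)
  expected_ratio <- (cal_6$value * kq_interpolate(syn_kq("6MeV"), 2:10)) /
    (cal_co$value * kq_interpolate(syn_kq("Co60"), 2:10))
  expect_equal(cur_6$dose_rate / cur_co$dose_rate, expected_ratio,
               tolerance = 1e-12)
})

test_that("curves carry the budget's per-depth combined uncertainty", {
  model <- syn_model()
  s <- syn_session(model)
  b <- diode_budget("Co60")
  cur <- build_curve(s, syn_cal(), syn_kq(), decay_parameters(),
                     reference_time = model$reference_time, budget = b)
  expect_equal(cur$u_rel_k1,
               vapply(2:10, function(z) combine_budget(b, z), numeric(1)))
})

test_that("shallow extrapolation closes over its own model family", {
  t0 <- as_ts("2026-01-01")
  # order-2 log-polynomial data: extrapolation is exact
  z <- 2:10
  d <- 0.1 * exp(-0.2 * z - 0.01 * z^2)
  cur <- depth_dose_curve(z, d, t0)
  ext <- extrapolate_shallow(cur, c(0, 0.5, 1), order = 2)
  expect_equal(ext$dose_rate[1:3],
               0.1 * exp(-0.2 * c(0, 0.5, 1) - 0.01 * c(0, 0.5, 1)^2),
               tolerance = 1e-9)
  expect_true(all(ext$extrapolated[1:3]))
  expect_true(all(is.na(ext$u_rel_k1[1:3])))
  # measured points are untouched: junction continuity
  expect_equal(ext$dose_rate[-(1:3)], cur$dose_rate)
  expect_false(any(ext$extrapolated[-(1:3)]))

  # exponential data, log-linear fit: matches analytic continuation
  d1 <- 2 * exp(-0.3 * z)
  ext1 <- extrapolate_shallow(depth_dose_curve(z, d1, t0), 1, order = 1)
  expect_equal(ext1$dose_rate[1], 2 * exp(-0.3), tolerance = 1e-9)

  # constant curve extends to a constant
  extc <- extrapolate_shallow(depth_dose_curve(z, rep(4, 9), t0), 1, order = 1)
  expect_equal(extc$dose_rate[1], 4, tolerance = 1e-9)

  expect_error(extrapolate_shallow(depth_dose_curve(c(2, 3), c(2, 1), t0),
                                   1, order = 2),
               class = "rudose_validation_error")
})

test_that("normalization is a per-depth ratio with quadrature uncertainty", {
  t0 <- as_ts("2026-01-01")
  z <- 2:10
  a <- depth_dose_curve(z, exp(-0.2 * z), t0, u_rel_k1 = rep(3, 9))
  b <- depth_dose_curve(z, 0.5 * exp(-0.2 * z), t0, u_rel_k1 = rep(4, 9))
  self <- normalize_curves(a, a)
  expect_equal(self$ratio, rep(1, 9))
  ab <- normalize_curves(a, b)
  expect_equal(ab$ratio, rep(2, 9))
  expect_equal(ab$u_rel, rep(5, 9))  # 3 (+) 4 in quadrature
  # antisymmetry: ratio(a,b) * ratio(b,a) = 1 per depth
  ba <- normalize_curves(b, a)
  expect_equal(ab$ratio * ba$ratio, rep(1, 9), tolerance = 1e-12)
  disjoint <- depth_dose_curve(20:22, rep(1, 3), t0)
  expect_error(normalize_curves(a, disjoint),
               class = "rudose_validation_error")
})

test_that("certificate agreement flags respect the combined expanded bound", {
  t0 <- as_ts("2026-01-01")
  z <- 2:10
  d <- exp(-0.2 * z)
  cert <- certificate("P1", t0, z, d, u_rel_expanded = 11, k_cov = 2)
  # identical curves agree everywhere
  same <- certificate_agreement(depth_dose_curve(z, d, t0,
                                                 u_rel_k1 = rep(1, 9)), cert)
  expect_equal(same$ratio, rep(1, 9))
  expect_true(all(same$within))
  # 10 % low with 4 % (k=1) measurement vs 11 % (k=2) certificate: within
  low <- certificate_agreement(depth_dose_curve(z, 0.9 * d, t0,
                                                u_rel_k1 = rep(4, 9)), cert)
  expect_true(all(low$within))
  expect_equal(low$u_combined_expanded_rel,
               rep(2 * sqrt(4^2 + 5.5^2), 9))
  # 25 % low with combined expanded ~15 %: violation
  bad_cert <- certificate("P1", t0, z, d, u_rel_expanded = 13.77, k_cov = 2)
  far <- certificate_agreement(depth_dose_curve(z, 0.75 * d, t0,
                                                u_rel_k1 = rep(2, 9)),
                               bad_cert)
  expect_false(any(far$within))
  # symmetry: swapping which side carries which uncertainty changes nothing
  swapped <- certificate_agreement(
    depth_dose_curve(z, 0.9 * d, t0, u_rel_k1 = rep(5.5, 9)),
    certificate("P1", t0, z, d, u_rel_expanded = 8, k_cov = 2))
  expect_equal(swapped$u_combined_expanded_rel, low$u_combined_expanded_rel)
  expect_identical(swapped$within, low$within)
})

test_that("calibration consistency reports the mean relative difference", {
  t0 <- as_ts("2026-01-01")
  z <- 2:10
  a <- depth_dose_curve(z, exp(-0.2 * z), t0)
  expect_equal(calibration_consistency(a, a)$mean_rel_diff_pct, 0)
  b <- depth_dose_curve(z, 1.0075 * exp(-0.2 * z), t0)
  res <- calibration_consistency(a, b)
  expect_equal(res$mean_rel_diff_pct, (1 / 1.0075 - 1) * 100,
               tolerance = 1e-12)
  expect_equal(round(res$mean_rel_diff_pct, 3), -0.744)
  expect_equal(nrow(res$per_depth), 9)
})
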