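t0 <- "2026-01-01"

mk_series <- function(readings, acq = 10, depth = 5, dir = "forward",
                      ts = t0)
  reading_series(depth, readings, acq, ts, dir)

mk_bg <- function(rate, acq = 60, dir = "pre")
  reading_series(NA_real_, rep(rate * acq, 3), acq, t0, dir)

test_that("background subtraction removes the mean pre/post rate", {
  s <- mk_series(c(10.0, 10.2))
  # zero background leaves the series unchanged
  net0 <- subtract_background(s, mk_bg(0), mk_bg(0, dir = "post"))
  expect_identical(net0$readings, s$readings)
  # bg rates averaging 0.02/s over 10 s remove 0.2 per reading
  net <- subtract_background(s, mk_bg(0.015), mk_bg(0.025, dir = "post"))
  expect_equal(net$readings, c(9.8, 10.0))
  expect_false(attr(net, "negative_net"))
  # readings equal to the mean background cancel to zero
  nets <- subtract_background(mk_series(c(0.2, 0.2)),
                              mk_bg(0.02), mk_bg(0.02, dir = "post"))
  expect_equal(nets$readings, c(0, 0))
  # doubling the background doubles the reduction (linearity)
  net2 <- subtract_background(s, mk_bg(0.03), mk_bg(0.05, dir = "post"))
  expect_equal(s$readings - net2$readings, 2 * (s$readings - net$readings))
})

test_that("series statistics give the SEM-based type-A estimate", {
  st <- series_statistics(mk_series(c(9, 10, 11), acq = 1))
  expect_equal(st$mean_rate, 10)
  expect_equal(st$u_typeA_rel, 100 * (1 / sqrt(3)) / 10, tolerance = 1e-12)
  # identical readings: no spread
  expect_equal(series_statistics(mk_series(c(5, 5, 5)))$u_typeA_rel, 0)
  # a single reading: undefined marker, never zero
  expect_true(is.na(series_statistics(mk_series(7))$u_typeA_rel))
})

test_that("bidirectional merge averages passes and scores the direction term", {
  f <- data.frame(depth_mm = c(2, 3), mean_rate = c(10.0, 4.0),
                  u_typeA_rel = c(0.5, 0.5))
  r <- data.frame(depth_mm = c(2, 3), mean_rate = c(10.2, 4.0),
                  u_typeA_rel = c(0.5, 0.5))
  m <- merge_bidirectional(f, r)
  expect_equal(m$mean_rate, c(10.1, 4.0))
  expect_equal(m$direction_rel[1], 100 * 0.1 / 10.1, tolerance = 1e-12)
  expect_equal(m$direction_rel[2], 0)  # symmetric passes: no direction term
  expect_equal(m$u_typeA_rel, rep(0.5 / sqrt(2), 2), tolerance = 1e-12)
  expect_equal(m$repeatability_rel[2], 0.5 / sqrt(2), tolerance = 1e-12)
  # mismatched depth sets are a contract violation
  r_bad <- r; r_bad$depth_mm <- c(2, 4)
  expect_error(merge_bidirectional(f, r_bad),
               class = "rudose_validation_error")
})

test_that("session corrections apply the linear model", {
  expect_equal(apply_session_corrections(10), 10)
  expect_equal(apply_session_corrections(10, electrometer_factor = 1.002),
               10.02)
  expect_equal(apply_session_corrections(10, temperature_C = 22,
                                         reference_temperature_C = 20,
                                         coefficient_pct_per_C = 0.1),
               10 * 1.002)
  expect_error(apply_session_corrections(10, electrometer_factor = -1),
               class = "rudose_validation_error")
})

test_that("decay correction follows the half-life closed form", {
  dec <- decay_parameters(half_life_days = 371.8)
  t_ref <- as_ts("2026-01-01")
  expect_equal(decay_correct(1, t_ref, t_ref, dec), 1)
  # one half-life after the reference: factor 2
  expect_equal(decay_correct(1, t_ref + 371.8 * 86400, t_ref, dec), 2,
               tolerance = 1e-12)
  expect_equal(decay_correct(1, t_ref + 37.18 * 86400, t_ref, dec), 2^0.1,
               tolerance = 1e-12)
  # round trip to the reference and back is the identity
  t1 <- t_ref + 123456
  there <- decay_correct(5, t1, t_ref, dec)
  expect_equal(decay_correct(there, t_ref, t1, dec), 5, tolerance = 1e-12)
  # correcting toward an earlier reference increases the rate
  expect_gt(there, 5)
})

test_that("water-equivalent depth adds the effective offset", {
  expect_equal(water_equivalent_depth(1.1), 2.0)  # default 0.9 mm offset
  geo_e <- detector_geometry(effective_depth_offset_mm = 0.3)
  expect_equal(water_equivalent_depth(2, geo_e), 2.3)
  expect_error(water_equivalent_depth(-1), class = "rudose_validation_error")
})

test_that("a zero-noise session is inverted exactly by the processing chain", {
  model <- syn_model()
  s <- syn_session(model)
  merged <- process_session(s, decay = decay_parameters(),
                            reference_time = model$reference_time)
  kqz <- kq_interpolate(syn_kq(), merged$depth_mm)
  recovered <- merged$mean_rate * syn_cal()$value * kqz
  expect_equal(recovered, model_dose(model, merged$depth_mm),
               tolerance = 1e-12)
  expect_equal(merged$repeatability_rel, rep(0, nrow(merged)))
})
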