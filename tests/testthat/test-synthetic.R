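test_that("the model family satisfies the surface gradient and closed forms", {
  m <- synthetic_model(surface_dose_rate = 1, log_gradient_surface = 0.2,
                       curvature = 0.01)
  # ~2 % drop per 0.1 mm at the surface
  expect_equal(model_dose(m, 0.1) / model_dose(m, 0), exp(-0.02 - 0.01 * 0.01),
               tolerance = 1e-12)
  expect_equal(model_dose(m, 5), exp(-1.25), tolerance = 1e-12)
  # log-dose strictly decreasing on [0, 10]
  z <- seq(0, 10, by = 0.1)
  expect_true(all(diff(log(model_dose(m, z))) < 0))
  # non-monotone parameterizations are rejected
  expect_error(synthetic_model(log_gradient_surface = 0.1, curvature = -0.02),
               class = "rudose_validation_error")
})

test_that("sessions are seed-deterministic and invert under zero noise", {
  model <- syn_model()
  s1 <- syn_session(model, noise_rel = 1.0, seed = 11)
  s2 <- syn_session(model, noise_rel = 1.0, seed = 11)
  expect_identical(s1, s2)
  s3 <- syn_session(model, noise_rel = 1.0, seed = 12)
  expect_false(identical(s1$forward[[1]]$readings, s3$forward[[1]]$readings))
  # bit-identical synthetic files for identical seeds
  f1 <- tempfile(); f2 <- tempfile()
  write_session(s1, f1); write_session(s2, f2)
  expect_identical(readLines(f1), readLines(f2))

  # zero noise: full processing recovers the model exactly
  cur <- build_curve(syn_session(model), syn_cal(), syn_kq(),
                     decay_parameters(), reference_time = model$reference_time)
  expect_equal(cur$dose_rate, model_dose(model, 2:10), tolerance = 1e-10)
})

test_that("acquisition times interpolate 10 s at 2 mm to 60 s at 10 mm", {
  s <- syn_session()
  acq <- vapply(s$forward, `[[`, numeric(1), "acquisition_time_s")
  depths <- vapply(s$forward, `[[`, numeric(1), "depth_mm")
  expect_equal(acq[depths == 2], 10)
  expect_equal(acq[depths == 10], 60)
  expect_equal(acq[depths == 6], 35)
  expect_length(s$forward[[1]]$readings, 10)
})

test_that("stochastic sessions are unbiased and reproduce the injected noise", {
  model <- syn_model()
  n_sessions <- 60
  ratios <- numeric(n_sessions)
  for (i in seq_len(n_sessions)) {
    s <- syn_session(model, noise_rel = 0.5, seed = 1000 + i)
    cur <- build_curve(s, syn_cal(), syn_kq(), decay_parameters(),
                       reference_time = model$reference_time)
    ratios[i] <- mean(cur$dose_rate / model_dose(model, cur$depths_mm))
  }
  se <- stats::sd(ratios) / sqrt(n_sessions)
  expect_lt(abs(mean(ratios) - 1), 3 * se)
  # type-A estimate converges to sigma/sqrt(n): 0.5 %/sqrt(10) ~ 0.158 %
  s <- syn_session(model, noise_rel = 0.5, seed = 77, n_repeats = 10)
  typeA <- vapply(s$forward, function(ser)
    series_statistics(ser)$u_typeA_rel, numeric(1))
  expect_equal(mean(typeA), 0.5 / sqrt(10), tolerance = 0.35)
})

test_that("certificates carry the vendor convention and the injected bias", {
  model <- syn_model()
  cert <- simulate_certificate(model, bias_rel = 8)
  expect_equal(cert$u_rel_expanded, 11)
  expect_equal(cert$k_cov, 2)
  expect_equal(cert$depth_mm, 0:10)
  expect_equal(cert$dose_rate, model_dose(model, 0:10) * 1.08,
               tolerance = 1e-12)
})

test_that("geometry-chain simulation is inverted exactly by perturbation_factors", {
  model <- syn_model()
  profiles <- ccb_default_factor_profiles()
  depths <- seq(0.25, 7.75, by = 0.5)
  chain <- simulate_geometry_chain(model, profiles, depths)
  pf <- perturbation_factors(chain)
  expect_equal(pf$k_gap, profiles$k_gap(depths), tolerance = 1e-12)
  expect_equal(pf$k_al, profiles$k_al(depths), tolerance = 1e-12)
  expect_equal(pf$k_holder, profiles$k_holder(depths), tolerance = 1e-12)
  expect_equal(pf$k_vol, profiles$k_vol(depths), tolerance = 1e-12)
  # qualitative shapes: k_gap below 1 at shallow depth, k_al/k_holder rising
  expect_lt(pf$k_gap[1], 1)
  expect_true(all(diff(pf$k_al) > 0))
  expect_true(all(diff(pf$k_holder) > 0))
  expect_true(all(diff(pf$k_vol) < 0))
  # factors identically 1: every geometry equals the model
  unit <- lapply(1:4, function(i) function(z) rep(1, length(z)))
  names(unit) <- c("k_gap", "k_al", "k_holder", "k_vol")
  ch1 <- simulate_geometry_chain(model, unit, depths)
  expect_equal(ch1$g1, model_dose(model, depths))
  expect_equal(ch1$g5, ch1$g1)

  # random smooth positive profiles: exact recovery
  set.seed(99)
  for (i in 1:50) {
    p <- stats::runif(4, 0.9, 1.2)
    q <- stats::runif(4, -0.01, 0.01)
    fns <- lapply(1:4, function(j) {
      force(j); function(z) p[j] * exp(q[j] * z)
    })
    names(fns) <- c("k_gap", "k_al", "k_holder", "k_vol")
    pf_i <- perturbation_factors(simulate_geometry_chain(model, fns, depths))
    expect_equal(pf_i$k_al, fns$k_al(depths), tolerance = 1e-12)
    expect_equal(pf_i$k_tot,
                 fns$k_gap(depths) * fns$k_al(depths) *
                   fns$k_holder(depths) * fns$k_vol(depths),
                 tolerance = 1e-12)
  }
})

test_that("alanine stack averages match the analytic slab integral", {
  # flat field: every pellet sees the same dose
  flat <- synthetic_model(surface_dose_rate = 2,
                          log_gradient_surface = 1e-9, curvature = 0)
  st <- simulate_alanine_stack(flat, n_pellets = 5)
  expect_equal(st$mean_dose, rep(2, 5), tolerance = 1e-6)

  # 11 x 0.5 mm pellets span 5.5 mm, first centred at 0.25 mm
  m <- syn_model()
  st11 <- simulate_alanine_stack(m, n_pellets = 11, pellet_thickness_mm = 0.5)
  expect_equal(nrow(st11), 11)
  expect_equal(st11$z_center_mm[1], 0.25)
  expect_equal(st11$z_front_mm[11] + 0.5, 5.5)

  # exponential model: closed-form slab average to 1e-9
  a <- 0.2; D0 <- 0.1
  expo <- synthetic_model(surface_dose_rate = D0, log_gradient_surface = a,
                          curvature = 0)
  st_e <- simulate_alanine_stack(expo, n_pellets = 11,
                                 pellet_thickness_mm = 0.5)
  z1 <- st_e$z_front_mm; z2 <- z1 + 0.5
  analytic <- D0 / (a * 0.5) * (exp(-a * z1) - exp(-a * z2))
  expect_equal(st_e$mean_dose, analytic, tolerance = 1e-9)

  # the 0.44 mm x 16 transport-model layout is accepted configuration
  st16 <- simulate_alanine_stack(m, n_pellets = 16,
                                 pellet_thickness_mm = 0.44)
  expect_equal(st16$z_front_mm[16] + 0.44, 7.04)
})
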