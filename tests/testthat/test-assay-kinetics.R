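test_that("accessible ligand concentrations reproduce the assay configs", {
  # 200 uM lipids, 5% ligand, outer leaflet -> 5 uM
  expect_equal(accessible_concentration(assay_config(200, 0.05, 0.5)), 5)
  # 80 uM lipids, 2% ligand -> 0.8 uM
  expect_equal(accessible_concentration(assay_config(80, 0.02, 0.5)), 0.8)
  expect_equal(accessible_concentration(assay_config(200, 0, 0.5)), 0)
})

test_that("extraction and bound percentages hit their calibration endpoints", {
  expect_equal(as.numeric(extraction_percentage(100, 100, 500)), 100)
  expect_equal(as.numeric(extraction_percentage(500, 100, 500)), 0)
  expect_equal(as.numeric(extraction_percentage(300, 100, 500)), 50)
  expect_error(extraction_percentage(1, 2, 2), "differ")
  expect_warning(extraction_percentage(600, 100, 500), "outside")

  expect_equal(as.numeric(bound_percentage(20, 20, 480)), 0)
  expect_equal(as.numeric(bound_percentage(480, 20, 480)), 100)
  expect_equal(as.numeric(bound_percentage(250, 20, 480)), 50)
  expect_error(bound_percentage(1, 3, 3), "differ")
})

test_that("extraction% and 100 * F_Norm are complements on random inputs", {
  set.seed(12)
  for (i in 1:50) {
    F0 <- runif(1, 0, 200)
    Fmax <- F0 + runif(1, 10, 500)
    F <- runif(1, F0 - 50, Fmax + 50)
    fn <- (F - F0) / (Fmax - F0)
    expect_equal(
      as.numeric(suppressWarnings(extraction_percentage(F, F0, Fmax))) +
        100 * fn,
      100, tolerance = 1e-10)
  }
})

test_that("transport normalization converts F_Norm into delivered ligand", {
  cfg <- assay_config(200, 0.05, 0.5)
  tr <- kinetic_trace(0:2, c(100, 260, 500), F0 = 100, Fmax = 500)
  out <- normalize_transport(tr, cfg)
  expect_equal(out$f_norm, c(0, 0.4, 1))
  expect_equal(out$delivered_uM, c(0, 2, 5))  # 5 x F_Norm; 0.4 -> 2 uM
  # delivered never exceeds the accessible pool while F <= Fmax
  expect_true(all(out$delivered_uM <= accessible_concentration(cfg) + 1e-12))
})

test_that("initial rates convert to per-protein turnover as slope*60/protein", {
  # noiseless linear delivered(t) of slope 0.104 uM/s, 0.2 uM protein
  cfg <- assay_config(200, 0.05, 0.5, protein_conc = 0.2)
  acc <- accessible_concentration(cfg)
  tt <- seq(0, 20, by = 0.5)
  slope_true <- 0.104
  delivered <- pmax(0, slope_true * (tt - 10))
  f <- 100 + delivered / acc * 400  # back to raw intensity, F0=100 Fmax=500
  tr <- kinetic_trace(tt, f, F0 = 100, Fmax = 500,
                      t_inject = c(protein = 10))
  r <- initial_rate(tr, cfg)
  expect_equal(r$initial_rate_uM_s, slope_true, tolerance = 1e-9)
  expect_equal(r$per_protein_rate_min, 31.2, tolerance = 1e-9)
  expect_equal(r$n_points, 8L)
  expect_equal(diff(r$fit_window_s), 3.5)  # 8 points at 0.5 s spacing

  # flat trace -> zero rate
  tr0 <- kinetic_trace(tt, rep(100, length(tt)), F0 = 100, Fmax = 500,
                       t_inject = c(protein = 10))
  expect_equal(initial_rate(tr0, cfg)$initial_rate_uM_s, 0)

  # insufficient post-injection points
  short <- kinetic_trace(seq(0, 12, 0.5), rep(100, 25), F0 = 100,
                         Fmax = 500, t_inject = c(protein = 11))
  expect_error(initial_rate(short, cfg), "insufficient")

  # points sampled too sparsely for the fit window are refused
  sparse <- kinetic_trace(seq(0, 40, 2), rep(100, 21), F0 = 100, Fmax = 500,
                          t_inject = c(protein = 10))
  expect_error(initial_rate(sparse, cfg), "span")
})

test_that("the fitted OLS slope matches its closed-form finite-window expectation", {
  # exponential trace: the OLS slope over the 8 post-injection sample
  # times has the closed-form value cov(t, A(1-exp(-k t)))/var(t)
  cfg <- assay_config(200, 0.05, 0.5, protein_conc = 0.2)
  acc <- accessible_concentration(cfg)
  for (k in c(0.01, 0.05, 0.1)) {
    sim <- simulate_transport_trace(k = k, F0 = 100, Fmax = 500,
                                    t_inject = 10, noise_sd = 0, dt = 0.5,
                                    duration = 60)
    r <- initial_rate(sim$trace, cfg)
    ts <- seq(0.5, 4, by = 0.5)
    expected <- acc * stats::cov(ts, 1 - exp(-k * ts)) / stats::var(ts)
    expect_equal(r$initial_rate_uM_s, expected, tolerance = 1e-9)
    # and that expectation sits within 3% x (finite-window correction)
    # of accessible x k by construction of the correction itself
    corr <- stats::cov(ts, 1 - exp(-k * ts)) / stats::var(ts) / k
    expect_equal(r$initial_rate_uM_s, acc * k * corr, tolerance = 1e-9)
  }
})

test_that("initial rate is invariant under affine rescaling of intensities", {
  cfg <- assay_config(200, 0.05, 0.5)
  sim <- simulate_transport_trace(k = 0.04, F0 = 100, Fmax = 500,
                                  t_inject = 10, noise_sd = 3, dt = 0.5,
                                  duration = 60, seed = 2)
  r1 <- initial_rate(sim$trace, cfg)
  a <- 2.7; b <- -40
  tr2 <- kinetic_trace(sim$trace$time, a * sim$trace$F + b,
                       F0 = a * 100 + b, Fmax = a * 500 + b,
                       t_inject = c(protein = 10))
  r2 <- initial_rate(tr2, cfg)
  expect_equal(r2$initial_rate_uM_s, r1$initial_rate_uM_s, tolerance = 1e-9)
})

test_that("rate-constant fitting recovers the generator's k", {
  # noiseless: exact recovery
  sim <- simulate_transport_trace(k = 0.05, noise_sd = 0, seed = 1)
  expect_equal(fit_transfer_k(sim$trace)$k, 0.05, tolerance = 1e-6)

  # k = 0: estimate ~ 0 within its standard error (flat trace + noise)
  sim0 <- simulate_transport_trace(k = 0, noise_sd = 2, seed = 3)
  f0 <- fit_transfer_k(sim0$trace)
  expect_lt(f0$k, max(3 * f0$k_se, 1e-3))

  # freeing the anchors still recovers k on clean data
  expect_equal(fit_transfer_k(sim$trace, fit_anchors = TRUE)$k, 0.05,
               tolerance = 1e-6)
})

test_that("dissociation traces are min-max normalized", {
  tr <- kinetic_trace(0:4, c(10, 8, 6, 4, 2))
  nd <- normalize_dissociation(tr)
  expect_equal(nd$f_norm, c(1, 0.75, 0.5, 0.25, 0))
  expect_error(normalize_dissociation(kinetic_trace(0:2, rep(5, 3))), "flat")
})
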