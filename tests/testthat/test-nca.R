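test_that("Cmax/Tmax pick the maximum and break ties at the earliest time", {
  expect_equal(pk_cmax(c(0, 12, 14, 16), c(0, 5, 12, 8)),
               list(cmax = 12, tmax = 14))
  expect_equal(pk_cmax(c(0, 13, 14, 20), c(0, 7, 7, 3)),
               list(cmax = 7, tmax = 13))
  expect_error(pk_cmax(c(0, 1, 2), c(0, 0, 0)),
               class = "pkcross_error_undefined_metric")
})

test_that("noiseless delayed-release Tmax equals the model argmax on the grid", {
  cfg <- default_config("dose_proportionality", bsv_cv = 0,
                        residual_prop_cv = 0, residual_add_sd = 0,
                        tlag_jitter_sd = 0)
  s <- generate_study(cfg, seed = 1)
  res <- nca(s)
  pp <- cfg$treatments$dr100$params
  sched <- cfg$treatments$dr100$schedule
  grid_argmax <- sched[which.max(one_cpt_conc(pp, 100, sched))]
  expect_true(all(res$tmax == grid_argmax))
  expect_equal(grid_argmax, 14)
})

test_that("trapezoidal AUC handles rectangles, triangles, and windows", {
  expect_equal(pk_auc(c(0, 10), c(1, 1)), 10)
  expect_equal(pk_auc(c(0, 1, 2), c(0, 2, 0)), 2)
  # interpolated boundaries: constant profile, interior window
  expect_equal(pk_auc(c(0, 10), c(1, 1), 2.5, 7.5), 5)
  expect_error(pk_auc(c(0, 10), c(1, 1), -1, 5), class = "pkcross_error_range")
  expect_error(pk_auc(c(0, 10), c(1, 1), 5, 5), class = "pkcross_error_value")
})

test_that("trapezoidal AUC matches dense quadrature and the analytic bound", {
  tt <- 0:48
  cc <- 10 * exp(-0.1 * tt)
  auc <- pk_auc(tt, cc)

  # oracle 1: integral of the same piecewise-linear interpolant on a
  # refined grid containing the knots (exact for a piecewise line)
  fine <- sort(unique(c(tt, seq(0, 48, by = 1 / 64))))
  cf <- stats::approx(tt, cc, xout = fine)$y
  dense <- sum(diff(fine) * (cf[-length(cf)] + cf[-1]) / 2)
  expect_lt(abs(auc - dense), 1e-9)

  # oracle 2: analytic integral, within the trapezoidal error bound
  # (b - a) h^2 max|f''| / 12
  analytic <- 10 / 0.1 * (1 - exp(-4.8))
  bound <- 48 * 1^2 * (10 * 0.1^2) / 12
  expect_lt(abs(auc - analytic), bound)
  expect_gt(auc, analytic)  # trapezoids overestimate a convex decay
})

test_that("AUC is additive over interior split points", {
  set.seed(11)
  for (rep in 1:20) {
    tt <- sort(runif(12, 0, 48))
    cc <- runif(12, 0, 10)
    a <- runif(1, tt[1], tt[12])
    expect_equal(pk_auc(tt, cc, tt[1], a) + pk_auc(tt, cc, a, tt[12]),
                 pk_auc(tt, cc), tolerance = 1e-12)
  }
})

test_that("AUC is invariant under insertion of a collinear point", {
  tt <- c(0, 2, 6, 10)
  cc <- c(0, 4, 8, 1)
  mid <- 4
  cmid <- stats::approx(tt, cc, xout = mid)$y
  tt2 <- c(0, 2, 4, 6, 10)
  cc2 <- c(0, 4, cmid, 8, 1)
  expect_equal(pk_auc(tt2, cc2), pk_auc(tt, cc), tolerance = 1e-12)
})

test_that("lambda_z is exact on log-linear tails and refuses flat ones", {
  tt <- c(0, 12, 24, 36, 48)
  cc <- c(0, 20, 10 * exp(-0.1 * 24), 10 * exp(-0.1 * 36), 10 * exp(-0.1 * 48))
  fit <- pk_lambda_z(tt, cc)
  expect_equal(fit$lambda_z, 0.1, tolerance = 1e-12)
  expect_equal(fit$n_points, 3L)

  flat <- pk_lambda_z(c(0, 12, 24, 36, 48), c(0, 9, 4, 4, 4))
  expect_true(is.na(flat$lambda_z))
})

test_that("lambda_z needs three usable points strictly after Tmax", {
  out <- pk_lambda_z(c(0, 10, 20, 30, 40), c(0, 8, 4, 2, 1))
  expect_equal(out$lambda_z, log(2) / 10, tolerance = 1e-12)
  expect_false(10 %in% out$tail_times)  # the peak itself is excluded
  # only 2 points after tmax
  expect_true(is.na(pk_lambda_z(c(0, 10, 20, 30), c(0, 8, 4, 2))$lambda_z))
  # interior zeros are excluded from the regression, not the trapezoid
  tt <- c(0, 10, 20, 25, 30, 40)
  cc <- c(0, 8, 4, 0, 2, 1)
  out2 <- pk_lambda_z(tt, cc)
  expect_false(25 %in% out2$tail_times)
})

test_that("lambda_z recovers ke within 1% on a noiseless fast-absorption profile", {
  pp <- one_cpt_params(ka = 2, ke = 0.1192, tlag = 0, scale = 0.2)
  tt <- c(0, 1, 2, 4, 6, 8, 12, 16, 24, 36, 48)
  cc <- one_cpt_conc(pp, 100, tt)
  est <- pk_lambda_z(tt, cc)$lambda_z
  expect_lt(abs(est - 0.1192) / 0.1192, 0.01)
})

test_that("half-life is ln 2 over lambda_z", {
  expect_equal(pk_half_life(log(2)), 1.0)
  expect_equal(pk_half_life(0.1), 6.931, tolerance = 1e-4)
  expect_equal(pk_half_life(0.1192), 5.815, tolerance = 1e-4)
  expect_error(pk_half_life(0), class = "pkcross_error_value")
})

test_that("AUC extrapolation adds Clast over lambda_z", {
  expect_equal(pk_auc_inf(100, 1, 0.1), 110)
  expect_true(is.na(pk_auc_inf(100, 0, 0.1)))   # Clast = 0: metric missing
  expect_true(is.na(pk_auc_inf(100, 1, NA)))    # lambda_z undefined
})

test_that("AUC to an infinity proxy recovers the analytic C0/ke", {
  ke <- 1
  tt <- seq(0, 200 / ke, by = 0.003)
  cc <- 10 * exp(-ke * tt)
  prof <- nca_profile(tt, cc)
  expect_equal(prof$auc_inf, 10 / ke, tolerance = 1e-6)
})

test_that("dose normalisation matches the printed-table arithmetic", {
  expect_equal(dose_normalize(12.31, 100), 0.1231)
  expect_equal(dose_normalize(32.3, 20), 1.615)
  expect_equal(dose_normalize(7.3, 1), 7.3)
  expect_error(dose_normalize(1, 0), class = "pkcross_error_value")
})

test_that("dose-normalised metrics are invariant to profile scaling", {
  tt <- c(0, 2, 4, 8, 12, 24)
  cc <- c(0, 1, 4, 3, 2, 0.5)
  for (k in c(2, 5, 10)) {
    expect_equal(dose_normalize(pk_cmax(tt, k * cc)$cmax, k * 10),
                 dose_normalize(pk_cmax(tt, cc)$cmax, 10))
    expect_equal(dose_normalize(pk_auc(tt, k * cc), k * 10),
                 dose_normalize(pk_auc(tt, cc), 10))
  }
})

test_that("early-exposure fraction behaves on delayed and constant profiles", {
  # fully delayed release: nothing before 10 h
  tt <- c(0, 2, 6, 10, 12, 14, 24)
  cc <- c(0, 0, 0, 0, 5, 8, 2)
  expect_equal(early_exposure_fraction(tt, cc), 0)
  # constant profile on [0, 20]: half the exposure in [0, 10]
  expect_equal(early_exposure_fraction(c(0, 20), c(3, 3)), 50)
  expect_error(early_exposure_fraction(c(0, 20), c(0, 0)),
               class = "pkcross_error_undefined_metric")
  expect_error(early_exposure_fraction(c(0, 5), c(1, 1)),
               class = "pkcross_error_range")
})

test_that("noiseless delayed profiles put under 5% of exposure before 10 h", {
  cfg <- default_config("dose_proportionality", bsv_cv = 0,
                        residual_prop_cv = 0, residual_add_sd = 0,
                        tlag_jitter_sd = 0)
  res <- nca(generate_study(cfg, seed = 1))
  expect_true(all(res$early_fraction < 5))
})

test_that("arm summaries report mean, CV%, median, range, geometric mean", {
  tbl <- tibble::tibble(treatment = "A", cmax = c(10, 12, 14))
  out <- nca_summary(tbl, metrics = "cmax")
  expect_equal(out$mean, 12)
  expect_equal(out$cv_pct, 100 * 2 / 12, tolerance = 1e-12)
  expect_equal(out$median, 12)
  expect_equal(c(out$min, out$max), c(10, 14))

  tbl2 <- tibble::tibble(treatment = "A", cmax = c(2, 2, 2))
  out2 <- nca_summary(tbl2, metrics = "cmax")
  expect_equal(out2$cv_pct, 0)

  tbl3 <- tibble::tibble(treatment = "A", cmax = c(1, 100))
  expect_equal(nca_summary(tbl3, metrics = "cmax")$geo_mean, 10)

  tbl4 <- tibble::tibble(treatment = "A", cmax = c(NA_real_, NA_real_))
  out4 <- nca_summary(tbl4, metrics = "cmax")
  expect_equal(out4$n, 0L)
  expect_true(is.na(out4$mean))
})

test_that("a study-wide NCA on noiseless data recovers the generating truth", {
  cfg <- default_config("dose_proportionality", bsv_cv = 0,
                        residual_prop_cv = 0, residual_add_sd = 0,
                        tlag_jitter_sd = 0)
  res <- nca(generate_study(cfg, seed = 1))
  # lambda_z within 1% of the elimination rate for every profile
  expect_true(all(abs(res$lambda_z - 0.1192) / 0.1192 < 0.01))
  # per-profile half-life identity holds exactly by construction
  expect_equal(res$t_half, log(2) / res$lambda_z)
  # dose-normalised metrics identical across the 20/100 mg arms
  wide <- tidyr::pivot_wider(res[, c("subject", "treatment", "dn_auc_last")],
                             names_from = "treatment",
                             values_from = "dn_auc_last")
  expect_equal(wide$dr20, wide$dr100, tolerance = 1e-12)
})
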