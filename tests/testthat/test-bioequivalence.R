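test_that("ratio of geometric LS means reproduces printed-table arithmetic", {
  expect_equal(round(ratio_of_geometric_means(11.25, 12.99), 3), 0.866)
  expect_equal(round(ratio_of_geometric_means(1.107, 1.498), 3), 0.739)
  expect_equal(ratio_of_geometric_means(7.3, 7.3), 1.0)
  expect_error(ratio_of_geometric_means(-1, 2), class = "pkcross_error_value")
})

test_that("the equivalence verdict is inclusive at the 0.8-1.25 boundaries", {
  expect_true(equivalence_verdict(0.869, 1.102))
  expect_false(equivalence_verdict(0.769, 0.975))
  expect_true(equivalence_verdict(0.8, 1.25))
  expect_false(equivalence_verdict(0.7999, 1.25))
  expect_false(equivalence_verdict(0.8, 1.2501))
  expect_error(equivalence_verdict(1.2, 0.9), class = "pkcross_error_value")
})

test_that("intrasubject CV back-transforms the residual log variance", {
  expect_equal(intra_subject_cv(log(1.04)), 20.0)
  expect_equal(intra_subject_cv(0), 0)
})

test_that("a no-noise 2x2 gives the common ratio with a zero-width CI", {
  # every subject's ln difference (T - R) is exactly 0.1; no period or
  # sequence effects, distinct subject levels
  d <- make_2x2_metric(n_per_seq = 4, treat_effect = 0.1,
                       subj_effects = seq(-0.3, 0.4, by = 0.1))
  res <- crossover_be(d, value, contrasts = c("T", "R"))
  expect_equal(res$ratio, exp(0.1), tolerance = 1e-10)
  expect_equal(res$ci90_high - res$ci90_low, 0, tolerance = 1e-8)
  expect_equal(res$intra_cv_pct, 0, tolerance = 1e-6)
})

test_that("the 2x2 fit matches the closed-form crossover ANOVA oracle", {
  # fixed 8-subject dataset with hand-picked effects and residuals
  set.seed(421)
  d <- make_2x2_metric(
    n_per_seq = 4, mu = 2.5, treat_effect = -0.08, period_effect = 0.05,
    subj_effects = c(0.2, -0.1, 0.4, 0, -0.25, 0.15, -0.3, 0.1),
    resid = round(rnorm(16, 0, 0.15), 4)
  )
  res <- crossover_be(d, value, contrasts = c("T", "R"))
  orc <- oracle_2x2_be(d)
  expect_equal(res$ratio, orc$ratio, tolerance = 1e-8)
  expect_equal(res$ci90_low, orc$ci90[1], tolerance = 1e-8)
  expect_equal(res$ci90_high, orc$ci90[2], tolerance = 1e-8)
  expect_equal(res$intra_cv_pct, intra_subject_cv(orc$sigma2_within),
               tolerance = 1e-8)
  expect_equal(res$df, orc$df)
  expect_equal(res$df, 2 * 4 - 2)  # n - 2 residual df in a balanced 2x2
})

test_that("REML and fixed-subject fits agree on balanced complete data", {
  set.seed(99)
  d <- make_2x2_metric(n_per_seq = 5, treat_effect = 0.12,
                       period_effect = -0.03,
                       subj_effects = rnorm(10, 0, 0.3),
                       resid = rnorm(20, 0, 0.2))
  fx <- crossover_be(d, value, contrasts = c("T", "R"), method = "fixed")
  rm <- crossover_be(d, value, contrasts = c("T", "R"), method = "reml")
  expect_equal(rm$ratio, fx$ratio, tolerance = 1e-6)
  expect_equal(rm$ci90_low, fx$ci90_low, tolerance = 1e-4)
  expect_equal(rm$df, fx$df, tolerance = 1e-3)
  expect_equal(rm$intra_cv_pct, fx$intra_cv_pct, tolerance = 1e-4)
})

test_that("swapping test and reference inverts ratio and CI", {
  set.seed(7)
  d <- make_2x2_metric(n_per_seq = 4, treat_effect = 0.2,
                       subj_effects = rnorm(8, 0, 0.3),
                       resid = rnorm(16, 0, 0.15))
  a <- crossover_be(d, value, contrasts = c("T", "R"))
  b <- crossover_be(d, value, contrasts = c("R", "T"))
  expect_equal(b$ratio, 1 / a$ratio, tolerance = 1e-10)
  expect_equal(b$ci90_low, 1 / a$ci90_high, tolerance = 1e-10)
  expect_equal(b$ci90_high, 1 / a$ci90_low, tolerance = 1e-10)
})

test_that("scaling one treatment scales its LS mean and the ratio exactly", {
  set.seed(13)
  d <- make_2x2_metric(n_per_seq = 4, subj_effects = rnorm(8, 0, 0.3),
                       resid = rnorm(16, 0, 0.1))
  base <- crossover_be(d, value, contrasts = c("T", "R"))
  k <- 3.7
  d2 <- d
  d2$value[d2$treatment == "T"] <- k * d2$value[d2$treatment == "T"]
  scaled <- crossover_be(d2, value, contrasts = c("T", "R"))
  expect_equal(scaled$gls_mean_test, k * base$gls_mean_test,
               tolerance = 1e-10)
  expect_equal(scaled$ratio, k * base$ratio, tolerance = 1e-10)
  expect_equal(scaled$intra_cv_pct, base$intra_cv_pct, tolerance = 1e-10)
})

test_that("a constant period effect leaves the treatment ratio unchanged", {
  set.seed(29)
  subj <- rnorm(8, 0, 0.3); eps <- rnorm(16, 0, 0.12)
  d0 <- make_2x2_metric(n_per_seq = 4, treat_effect = 0.1,
                        period_effect = 0, subj_effects = subj, resid = eps)
  d1 <- make_2x2_metric(n_per_seq = 4, treat_effect = 0.1,
                        period_effect = 0.5, subj_effects = subj, resid = eps)
  r0 <- crossover_be(d0, value, contrasts = c("T", "R"))
  r1 <- crossover_be(d1, value, contrasts = c("T", "R"))
  expect_equal(r1$ratio, r0$ratio, tolerance = 1e-10)
  expect_equal(r1$ci90_low, r0$ci90_low, tolerance = 1e-10)
})

test_that("3x3 Latin-square contrasts come from one fit, no adjustment", {
  s <- generate_study(default_config("evening_food_effect"), seed = 31)
  res <- nca(s)
  be <- be_analysis(res, "auc_last",
                    list(c("fed", "fasted"), c("sprinkled", "fasted"),
                         c("fed", "sprinkled")))
  expect_equal(nrow(be), 3L)
  # one shared residual variance -> identical intrasubject CV per row
  expect_equal(be$intra_cv_pct, rep(be$intra_cv_pct[1], 3))
  # contrast consistency within the single fit:
  # (fed/fasted) / (sprinkled/fasted) = fed/sprinkled
  expect_equal(be$ratio[1] / be$ratio[2], be$ratio[3], tolerance = 1e-10)
  expect_equal(be$df, rep(2 * 18 - 4, 3))  # residual df of the 3x3 model
})

test_that("contrast and transform preconditions are enforced", {
  d <- make_2x2_metric(n_per_seq = 2)
  expect_error(crossover_be(d, value, contrasts = c("T", "X")),
               class = "pkcross_error_contrast")
  expect_error(crossover_be(d, value, contrasts = c("T")),
               class = "pkcross_error_contrast")
  d$value[1] <- 0
  expect_error(crossover_be(d, value, contrasts = c("T", "R")),
               class = "pkcross_error_transform")
})

test_that("unbalanced data fall back to the REML path", {
  set.seed(55)
  d <- make_2x2_metric(n_per_seq = 5, treat_effect = 0.1,
                       subj_effects = rnorm(10, 0, 0.3),
                       resid = rnorm(20, 0, 0.2))
  d <- d[-3, ]  # drop one period observation
  res <- crossover_be(d, value, contrasts = c("T", "R"))
  expect_equal(res$method, "reml")
  expect_true(res$ci90_low < res$ratio & res$ratio < res$ci90_high)
})

test_that("the estimated ratio tracks a known true ratio on synthetic studies", {
  st <- generate_true_ratio_study(true_ratio = 1, n_subjects = 20,
                                  intra_cv = 1, bsv_cv = 10, seed = 17)
  res <- nca(st)
  be <- crossover_be(res, auc_last, contrasts = c("test", "ref"))
  expect_gt(be$ratio, 0.99)
  expect_lt(be$ratio, 1.01)

  # strongly non-equivalent truth is rejected
  st2 <- generate_true_ratio_study(true_ratio = 0.7, n_subjects = 18,
                                   intra_cv = 20, seed = 18)
  be2 <- crossover_be(nca(st2), auc_last, contrasts = c("test", "ref"))
  expect_false(be2$bioequivalent)
})
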