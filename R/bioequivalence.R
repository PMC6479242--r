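#' Ratio of geometric least-squares means
#'
#' @param gls_test,gls_reference Back-transformed (geometric) LS means of
#'   the test and reference treatments; both must be > 0.
#' @return `gls_test / gls_reference`.
#' @examples
#' ratio_of_geometric_means(11.25, 12.99)  # fed vs fasted peak exposure
#' @export
ratio_of_geometric_means <- function(gls_test, gls_reference) {
  if (any(gls_test <= 0) || any(gls_reference <= 0)) {
    pk_abort("geometric means must be > 0.", "pkcross_error_value")
  }
  gls_test / gls_reference
}

#' Average-bioequivalence verdict
#'
#' Two treatments are declared equivalent when the 90% confidence
#' interval of the geometric LS mean ratio lies entirely within the
#' regulatory limits, boundaries included.
#'
#' @param ci_low,ci_high Confidence-interval bounds of the ratio.
#' @param limits Length-2 numeric equivalence limits (default
#'   `c(0.8, 1.25)`).
#' @return Logical.
#' @export
equivalence_verdict <- function(ci_low, ci_high, limits = c(0.8, 1.25)) {
  if (any(ci_low > ci_high)) {
    pk_abort("ci_low must be <= ci_high.", "pkcross_error_value")
  }
  ci_low >= limits[1] & ci_high <= limits[2]
}

#' Intrasubject CV from a within-subject log-scale variance
#'
#' `100 * sqrt(exp(sigma2_within) - 1)`, the standard back-transformation
#' of the residual variance of a crossover model fitted on the natural
#' log scale.
#'
#' @param sigma2_within Within-subject (residual) variance on the log
#'   scale.
#' @return Intrasubject CV in percent.
#' @export
intra_subject_cv <- function(sigma2_within) {
  if (any(sigma2_within < 0)) {
    pk_abort("sigma2_within must be >= 0.", "pkcross_error_value")
  }
  100 * sqrt(exp(sigma2_within) - 1)
}

#' Average-bioequivalence analysis of one exposure metric
#'
#' Fits the crossover model on the natural log of the metric with
#' sequence, period, and treatment effects and a subject effect, then
#' reports, for each requested test/reference contrast: back-transformed
#' geometric LS means, their ratio, the 90% confidence interval
#' (`exp(difference +/- t[0.95, df] * SE)`), the intrasubject CV derived
#' from the residual variance, and the 0.8--1.25 equivalence verdict.
#' All contrasts of a 3-treatment Latin square come from the single model
#' fit, with no multiplicity adjustment.
#'
#' For balanced complete data the model is fitted with subject as a fixed
#' effect (`lm`), which coincides with the REML mixed model there; with
#' unbalanced data it falls back to a subject-random-intercept model
#' (`lmerTest::lmer`) with Satterthwaite degrees of freedom.
#'
#' @param data Data frame with columns `subject`, `sequence`, `period`,
#'   `treatment`, and the metric column named by `value` (one row per
#'   subject x treatment); e.g. a [nca()] result.
#' @param value Metric column (bare name or string); values must be > 0.
#' @param contrasts A `c(test, reference)` character pair, or a list of
#'   such pairs. Default: all ordered pairs against the last treatment
#'   level are not guessed -- the argument is required.
#' @param limits Equivalence limits (default `c(0.8, 1.25)`).
#' @param method `"auto"` (default), `"fixed"`, or `"reml"`.
#' @return A tibble of class `pk_be`, one row per contrast, with columns
#'   `metric`, `test`, `reference`, `gls_mean_test`, `gls_mean_reference`,
#'   `ratio`, `ci90_low`, `ci90_high`, `intra_cv_pct`, `df`, `n_subjects`,
#'   `method`, `bioequivalent`.
#' @examples
#' study <- generate_study(default_config("dose_proportionality"), seed = 7)
#' res <- nca(study)
#' crossover_be(res, dn_auc_last, contrasts = c("dr20", "dr100"))
#' @export
crossover_be <- function(data, value, contrasts,
                         limits = c(0.8, 1.25),
                         method = c("auto", "fixed", "reml")) {
  method <- rlang::arg_match(method)
  value_name <- rlang::as_name(rlang::ensym(value))
  if (!value_name %in% names(data)) {
    pk_abort(sprintf("column `%s` not found.", value_name),
             "pkcross_error_schema")
  }
  if (!is.list(contrasts)) contrasts <- list(contrasts)
  for (ct in contrasts) {
    if (length(ct) != 2L) {
      pk_abort("each contrast must be c(test, reference).",
               "pkcross_error_contrast")
    }
    if (!all(ct %in% data$treatment)) {
      pk_abort(sprintf("treatment(s) %s absent from the data.",
                       paste(setdiff(ct, data$treatment), collapse = ", ")),
               "pkcross_error_contrast")
    }
  }

  d <- tibble::tibble(
    subject = factor(data$subject),
    sequence = factor(data$sequence),
    period = factor(data$period),
    treatment = factor(data$treatment),
    y = data[[value_name]]
  )
  d <- d[!is.na(d$y), ]
  if (any(d$y <= 0)) {
    pk_abort("metric values must be > 0 for the log transform.",
             "pkcross_error_transform")
  }
  d$ln_y <- log(d$y)

  tab <- table(d$subject, d$treatment)
  balanced <- all(tab == 1L)
  if (method == "auto") method <- if (balanced) "fixed" else "reml"

  fit_info <- if (method == "fixed") {
    be_fit_fixed(d)
  } else {
    be_fit_reml(d)
  }

  rows <- purrr::map(contrasts, function(ct) {
    est <- be_contrast(fit_info, ct[1], ct[2])
    half <- qt(0.95, est$df) * est$se
    tibble::tibble(
      metric = value_name,
      test = ct[1], reference = ct[2],
      gls_mean_test = exp(est$lsm_test),
      gls_mean_reference = exp(est$lsm_ref),
      ratio = exp(est$diff),
      ci90_low = exp(est$diff - half),
      ci90_high = exp(est$diff + half),
      intra_cv_pct = intra_subject_cv(fit_info$sigma2_within),
      df = est$df,
      n_subjects = nlevels(droplevels(d$subject)),
      method = method
    )
  })
  out <- dplyr::bind_rows(rows)
  out$bioequivalent <- equivalence_verdict(out$ci90_low, out$ci90_high, limits)
  class(out) <- c("pk_be", class(out))
  out
}

# subject-as-fixed formulation (sequence is aliased with subjects)
be_fit_fixed <- function(d) {
  d <- droplevels(d)
  fit <- lm(ln_y ~ subject + period + treatment, data = d)
  grid <- expand.grid(subject = levels(d$subject), period = levels(d$period))
  list(kind = "fixed", fit = fit, grid = grid, d = d,
       sigma2_within = sum(fit$residuals^2) / fit$df.residual,
       df_resid = fit$df.residual)
}

be_fit_reml <- function(d) {
  d <- droplevels(d)
  fit <- lmerTest::lmer(ln_y ~ sequence + period + treatment + (1 | subject),
                        data = d)
  grid <- expand.grid(sequence = levels(d$sequence), period = levels(d$period))
  list(kind = "reml", fit = fit, grid = grid, d = d,
       sigma2_within = sigma(fit)^2)
}

# LS-mean row vector for one treatment: average model-matrix row over the
# reference grid of the remaining design factors
be_lsm_vector <- function(info, treat) {
  grid <- info$grid
  grid$treatment <- factor(treat, levels = levels(info$d$treatment))
  rhs <- if (info$kind == "fixed") {
    ~ subject + period + treatment
  } else {
    ~ sequence + period + treatment
  }
  mm <- model.matrix(rhs, grid)
  colMeans(mm)
}

be_contrast <- function(info, test, reference) {
  l_test <- be_lsm_vector(info, test)
  l_ref <- be_lsm_vector(info, reference)
  ldiff <- l_test - l_ref
  if (info$kind == "fixed") {
    beta <- coef(info$fit)
    keep <- !is.na(beta)
    # a perfect (zero-residual) fit is legitimate here: degenerate
    # no-noise data yield a zero-width CI
    v <- suppressWarnings(vcov(info$fit))
    lsm_test <- sum(l_test[keep] * beta[keep])
    lsm_ref <- sum(l_ref[keep] * beta[keep])
    se <- sqrt(drop(t(ldiff[keep]) %*% v %*% ldiff[keep]))
    df <- info$df_resid
  } else {
    beta <- lme4::fixef(info$fit)
    lsm_test <- sum(l_test * beta)
    lsm_ref <- sum(l_ref * beta)
    ct <- lmerTest::contest1D(info$fit, ldiff, confint = FALSE)
    se <- ct[["Std. Error"]]
    df <- ct[["df"]]
  }
  list(lsm_test = lsm_test, lsm_ref = lsm_ref,
       diff = lsm_test - lsm_ref, se = se, df = df)
}

#' Bioequivalence analysis of several NCA metrics at once
#'
#' Convenience wrapper running [crossover_be()] for each metric column
#' and stacking the results.
#'
#' @param nca_tbl A `pk_nca` tibble (or any data frame with the design
#'   columns and metric columns).
#' @param metrics Character vector of metric column names.
#' @inheritParams crossover_be
#' @return A `pk_be` tibble with one row per metric x contrast.
#' @export
be_analysis <- function(nca_tbl, metrics, contrasts,
                        limits = c(0.8, 1.25), method = "auto") {
  out <- purrr::map(metrics, function(m) {
    crossover_be(nca_tbl, !!rlang::sym(m), contrasts = contrasts,
                 limits = limits, method = method)
  })
  out <- dplyr::bind_rows(out)
  class(out) <- c("pk_be", class(out))
  out
}
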