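# Nominal sampling schedules (hours post-dose). The predose sample is
# recorded as time 0. The delayed/extended schedule samples twice-hourly
# around the expected release window (8-12 h) and out to 48 h; the
# immediate-release schedule is front-loaded and ends at 24 h.
schedule_delayed <- function() {
  c(0, 2, 4, 6, 8, 8.5, 9, 9.5, 10, 10.5, 11, 11.5, 12, 13, 14, 15, 16,
    17, 18, 19, 20, 22, 24, 36, 48)
}

schedule_ir <- function() {
  c(0, 0.25, 0.5, 1, 1.5, 2, 2.5, 3, 3.5, 4, 5, 6, 8, 10, 12, 14, 17, 20, 24)
}

# Population parameters of the evening-dosed delayed/extended
# formulation: a 10 h absorption lag, monophasic absorption peaking at
# 14 h on the sampling grid, terminal elimination 0.1192 /h, and an
# amplitude giving Cmax ~ 12.3 ng/mL and AUC0-inf ~ 168 ng.h/mL at
# 100 mg.
params_delayed <- function() one_cpt_params(ka = 0.45, ke = 0.1192,
                                            tlag = 10, scale = 0.2)

# Immediate-release reference: peak near 1.5 h, terminal rate 0.191 /h,
# amplitude set so the delayed formulation's dose-normalised AUC0-inf is
# 73.9% of the immediate-release value.
params_ir <- function() one_cpt_params(ka = 1.6, ke = 0.191,
                                       tlag = 0, scale = 0.433656)

#' Default generator configuration for one of the three study templates
#'
#' Returns a `pk_generator_config` describing a synthetic crossover study
#' with the structure of one of three single-dose designs of an
#' evening-dosed delayed-release/extended-release (DR/ER) oral stimulant
#' program:
#'
#' * `"dose_proportionality"`: 2x2 crossover, n = 20, 20 mg (`dr20`) vs
#'   100 mg (`dr100`) of the DR/ER formulation; the two treatments share
#'   the model parameters and differ only in dose.
#' * `"evening_food_effect"`: six-sequence 3x3 Latin square, n = 18,
#'   100 mg under `fed`, `sprinkled`, and `fasted` conditions. The fed
#'   condition delays the lag by 2.5 h and blunts the peak by ~12%
#'   through a slower absorption rate (`ka` x 2/3), leaving elimination
#'   and total exposure unchanged; sprinkled is identical to fasted.
#' * `"relative_bioavailability"`: 2x2 crossover, n = 12, 100 mg DR/ER
#'   (`dr100`) vs 20 mg immediate-release (`ir20`), each on its own
#'   sampling schedule; the DR/ER dose-normalised exposure is 73.9% of
#'   the immediate-release value by construction.
#'
#' Between-subject variability defaults to a 30% lognormal CV on `ka`,
#' `ke`, and `scale` (one draw per subject, shared across periods), a
#' truncated-normal lag jitter (SD 0.5 h, floor 8 h) for the delayed
#' formulation, and residual error of 10% proportional CV plus an
#' additive SD equal to the 0.02 ng/mL LLOQ.
#'
#' @param study One of `"dose_proportionality"`,
#'   `"evening_food_effect"`, `"relative_bioavailability"`.
#' @param n_subjects Optional override of the template sample size; must
#'   be divisible by the number of sequences.
#' @param bsv_cv Between-subject lognormal CV (%), applied to `ka`, `ke`,
#'   `scale`.
#' @param residual_prop_cv Proportional residual error CV (%).
#' @param residual_add_sd Additive residual error SD (ng/mL).
#' @param tlag_jitter_sd SD (h) of the truncated-normal between-subject
#'   lag jitter (delayed formulation only).
#' @param lloq Lower limit of quantitation (ng/mL).
#' @return A list of class `pk_generator_config`.
#' @export
default_config <- function(study = c("dose_proportionality",
                                     "evening_food_effect",
                                     "relative_bioavailability"),
                           n_subjects = NULL,
                           bsv_cv = 30,
                           residual_prop_cv = 10,
                           residual_add_sd = 0.02,
                           tlag_jitter_sd = 0.5,
                           lloq = 0.02) {
  study <- rlang::arg_match(study)
  dr <- params_delayed()
  treatments <- switch(
    study,
    dose_proportionality = list(
      dr20 = list(dose_mg = 20, formulation = "delayed_extended",
                  params = dr, schedule = schedule_delayed()),
      dr100 = list(dose_mg = 100, formulation = "delayed_extended",
                   params = dr, schedule = schedule_delayed())
    ),
    evening_food_effect = list(
      fed = list(dose_mg = 100, formulation = "delayed_extended",
                 params = one_cpt_params(dr$ka * 2 / 3, dr$ke,
                                         dr$tlag + 2.5, dr$scale),
                 schedule = schedule_delayed()),
      sprinkled = list(dose_mg = 100, formulation = "delayed_extended",
                       params = dr, schedule = schedule_delayed()),
      fasted = list(dose_mg = 100, formulation = "delayed_extended",
                    params = dr, schedule = schedule_delayed())
    ),
    relative_bioavailability = list(
      dr100 = list(dose_mg = 100, formulation = "delayed_extended",
                   params = dr, schedule = schedule_delayed()),
      ir20 = list(dose_mg = 20, formulation = "immediate_release",
                  params = params_ir(), schedule = schedule_ir())
    )
  )
  design <- switch(study,
                   dose_proportionality = "two_by_two",
                   evening_food_effect = "latin_square_3x3_6seq",
                   relative_bioavailability = "two_by_two")
  n_default <- switch(study,
                      dose_proportionality = 20L,
                      evening_food_effect = 18L,
                      relative_bioavailability = 12L)
  structure(
    list(study = study, design = design,
         n_subjects = as.integer(n_subjects %||% n_default),
         treatments = treatments,
         bsv_cv = bsv_cv,
         residual = list(prop_cv = residual_prop_cv, add_sd = residual_add_sd),
         tlag_jitter_sd = tlag_jitter_sd,
         lloq = lloq),
    class = "pk_generator_config"
  )
}

#' @exportS3Method base::print
print.pk_generator_config <- function(x, ...) {
  cat(sprintf("<pk_generator_config> %s | %s | n = %d | treatments: %s\n",
              x$study, x$design, x$n_subjects,
              paste(names(x$treatments), collapse = ", ")))
  cat(sprintf("BSV CV %g%% | residual %g%% prop + %g ng/mL add | LLOQ %g\n",
              x$bsv_cv, x$residual$prop_cv, x$residual$add_sd, x$lloq))
  invisible(x)
}

design_sequences <- function(design, codes) {
  switch(design,
         two_by_two = list(codes, rev(codes)),
         latin_square_3x3_6seq = {
           perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                         c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
           lapply(perms, function(p) codes[p])
         },
         pk_abort(paste0("unsupported design: ", design),
                  "pkcross_error_config"))
}

#' Generate a synthetic crossover study
#'
#' Simulates subject-level concentration--time data with the statistical
#' structure the downstream analyses assume. Per subject, one
#' between-subject parameter draw (lognormal multipliers on `ka`, `ke`,
#' `scale`; truncated-normal lag jitter) is shared across periods, so
#' subject acts as the random effect of the crossover model. Each
#' observation is `model value * (1 + eps_prop) + eps_add`, clamped at
#' zero, with the LLOQ rule applied last. Sequences are assigned in
#' balanced Latin-square blocks. The whole study is reproducible from
#' `seed` (subject draws precede observation draws in fixed order).
#'
#' @param config A [default_config()] object (fields may be edited before
#'   the call).
#' @param seed Integer seed for the random stream.
#' @return A [pk_study()].
#' @examples
#' study <- generate_study(default_config("dose_proportionality"), seed = 1)
#' study
#' @export
generate_study <- function(config, seed = 1L) {
  stopifnot(inherits(config, "pk_generator_config"))
  codes <- names(config$treatments)
  seqs <- design_sequences(config$design, codes)
  n <- config$n_subjects
  if (n %% length(seqs) != 0L) {
    pk_abort(sprintf("n_subjects (%d) must be divisible by %d sequences.",
                     n, length(seqs)),
             "pkcross_error_config")
  }
  set.seed(as.integer(seed))

  subjects <- sprintf("S%02d", seq_len(n))
  seq_of_subject <- rep(seq_along(seqs), each = n / length(seqs))

  # --- subject-level draws, fixed order: ka, ke, scale, tlag jitter ---
  sdlog <- cv_to_sdlog(config$bsv_cv)
  mult <- matrix(exp(rnorm(3L * n, 0, sdlog)), nrow = n, ncol = 3L,
                 byrow = TRUE,
                 dimnames = list(NULL, c("ka", "ke", "scale")))
  base_tlag <- max(vapply(config$treatments, function(tr) tr$params$tlag,
                          numeric(1)))
  tlag_delta <- rtrunc_norm_delta(n, sd = config$tlag_jitter_sd,
                                  lower = 8 - base_tlag)

  # --- assemble observation table, fixed order: subject, period, time ---
  obs <- purrr::map_dfr(seq_len(n), function(i) {
    trts <- seqs[[seq_of_subject[i]]]
    purrr::map_dfr(seq_along(trts), function(p) {
      tr <- config$treatments[[trts[p]]]
      pp <- tr$params
      tlag_i <- if (pp$tlag > 0) max(0, pp$tlag + tlag_delta[i]) else pp$tlag
      conc <- one_cpt_conc_(tr$schedule,
                            pp$ka * mult[i, "ka"],
                            pp$ke * mult[i, "ke"],
                            tlag_i,
                            pp$scale * mult[i, "scale"],
                            tr$dose_mg)
      tibble::tibble(
        subject = subjects[i],
        sequence = paste(trts, collapse = "-"),
        period = p,
        treatment = trts[p],
        time_h = tr$schedule,
        conc_true = conc
      )
    })
  })

  m <- nrow(obs)
  eps_prop <- rnorm(m, 0, config$residual$prop_cv / 100)
  eps_add <- rnorm(m, 0, config$residual$add_sd)
  obs$conc_ng_ml <- pmax(0, obs$conc_true * (1 + eps_prop) + eps_add)
  obs$conc_true <- NULL

  finish_study(obs, config)
}

# truncated-normal deviation via inverse-CDF sampling (deterministic in
# the stream, no rejection); sd = 0 returns exact zeros
rtrunc_norm_delta <- function(n, sd, lower) {
  u <- runif(n)
  if (sd <= 0) return(rep(0, n))
  p_lo <- stats::pnorm(lower, 0, sd)
  qnorm(p_lo + u * (1 - p_lo), 0, sd)
}

finish_study <- function(obs, config) {
  treatments <- purrr::imap_dfr(config$treatments, function(tr, code) {
    tibble::tibble(treatment = code, dose_mg = tr$dose_mg,
                   formulation = tr$formulation, tau_h = 24, n_doses = 1L)
  })
  schedule <- purrr::imap_dfr(config$treatments, function(tr, code) {
    tibble::tibble(treatment = code, time_h = tr$schedule)
  })
  pk_study(obs, treatments = treatments, schedule = schedule,
           design = config$design, lloq = config$lloq)
}

#' Generate a two-treatment study with a known true geometric mean ratio
#'
#' Calibration harness for the bioequivalence module: the test
#' treatment's population curve is the reference curve scaled by
#' `true_ratio`, so the true geometric mean ratio of Cmax and AUC equals
#' `true_ratio` exactly. Noise is purely multiplicative and lognormal --
#' a per-subject curve multiplier (between-subject CV `bsv_cv`) and an
#' independent per-profile multiplier whose CV is the target intrasubject
#' CV -- so the log-scale crossover model holds exactly and confidence
#' intervals have nominal coverage by construction.
#'
#' @param true_ratio True test/reference ratio, > 0.
#' @param n_subjects Number of subjects (even; 2x2 design).
#' @param intra_cv Within-subject (residual) CV in percent.
#' @param bsv_cv Between-subject CV in percent.
#' @param seed Integer seed.
#' @return A [pk_study()] with treatments `test` and `ref` (100 mg,
#'   delayed formulation).
#' @export
generate_true_ratio_study <- function(true_ratio, n_subjects = 18,
                                      intra_cv = 20, bsv_cv = 30,
                                      seed = 1L) {
  assert_scalar_number(true_ratio, "true_ratio", positive = TRUE)
  if (n_subjects %% 2L != 0L) {
    pk_abort("n_subjects must be even for the 2x2 design.",
             "pkcross_error_config")
  }
  set.seed(as.integer(seed))
  n <- as.integer(n_subjects)
  pp <- params_delayed()
  sched <- schedule_delayed()
  subjects <- sprintf("S%02d", seq_len(n))
  seqs <- list(c("test", "ref"), c("ref", "test"))
  seq_of_subject <- rep(1:2, each = n / 2L)

  eta <- rnorm(n, 0, cv_to_sdlog(bsv_cv))          # subject draws first
  eps <- matrix(rnorm(2L * n, 0, cv_to_sdlog(intra_cv)), nrow = n)

  base <- one_cpt_conc(pp, 100, sched)
  obs <- purrr::map_dfr(seq_len(n), function(i) {
    trts <- seqs[[seq_of_subject[i]]]
    purrr::map_dfr(1:2, function(p) {
      fac <- exp(eta[i] + eps[i, p]) * ifelse(trts[p] == "test", true_ratio, 1)
      tibble::tibble(
        subject = subjects[i],
        sequence = paste(trts, collapse = "-"),
        period = p, treatment = trts[p],
        time_h = sched, conc_ng_ml = base * fac
      )
    })
  })

  treatments <- tibble::tibble(
    treatment = c("test", "ref"), dose_mg = 100,
    formulation = "delayed_extended", tau_h = 24, n_doses = 1L
  )
  pk_study(obs, treatments = treatments, design = "two_by_two", lloq = 0.02)
}
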