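#' Render a bioequivalence results table
#'
#' Formats a [crossover_be()] result the way regulatory PK reports print
#' it: geometric LS means, intrasubject CV%, and the ratio with its 90%
#' CI as `"0.866 (0.769–0.975)"` (3-decimal rounding applied only at
#' render time; the input tibble carries full precision), with
#' within-limits rows flagged.
#'
#' @param be_tbl A `pk_be` tibble.
#' @param digits Decimal places for the ratio and CI (default 3).
#' @return A tibble with character columns `metric`, `contrast`,
#'   `gls_mean_test`, `gls_mean_reference`, `intra_cv_pct`,
#'   `ratio_ci90`, `within_limits`.
#' @export
render_be_table <- function(be_tbl, digits = 3) {
  stopifnot(is.data.frame(be_tbl))
  if (nrow(be_tbl) == 0L) {
    pk_abort("empty bioequivalence table.", "pkcross_error_value")
  }
  fmt <- function(x) formatC(x, digits = digits, format = "f")
  tibble::tibble(
    metric = as.character(be_tbl$metric),
    contrast = paste(be_tbl$test, "/", be_tbl$reference),
    gls_mean_test = signif(be_tbl$gls_mean_test, 4),
    gls_mean_reference = signif(be_tbl$gls_mean_reference, 4),
    intra_cv_pct = round(be_tbl$intra_cv_pct, 2),
    ratio_ci90 = sprintf("%s (%s–%s)", fmt(be_tbl$ratio),
                         fmt(be_tbl$ci90_low), fmt(be_tbl$ci90_high)),
    within_limits = ifelse(be_tbl$bioequivalent, "yes", "no")
  )
}

#' Parse a rendered ratio/CI cell back to numbers
#'
#' Inverse of the `ratio_ci90` column of [render_be_table()] (to the
#' rendered precision).
#'
#' @param x Character vector like `"0.866 (0.769–0.975)"`.
#' @return A tibble with columns `ratio`, `ci90_low`, `ci90_high`.
#' @export
parse_ratio_ci <- function(x) {
  m <- regmatches(x, gregexpr("[0-9]+\\.?[0-9]*", x))
  purrr::map_dfr(m, function(v) {
    v <- as.numeric(v)
    tibble::tibble(ratio = v[1], ci90_low = v[2], ci90_high = v[3])
  })
}

#' Render an arm-summary table
#'
#' Mean +/- CV% per metric, with median (range) for `tmax`, mirroring the
#' usual PK parameter table layout.
#'
#' @param summary_tbl Output of [nca_summary()].
#' @param digits Significant digits (default 4).
#' @return A tibble with character columns `treatment`, `metric`, `value`.
#' @export
render_arm_table <- function(summary_tbl, digits = 4) {
  by <- setdiff(names(summary_tbl),
                c("metric", "n", "mean", "cv_pct", "median", "min", "max",
                  "geo_mean"))[1]
  tibble::tibble(
    treatment = as.character(summary_tbl[[by]]),
    metric = summary_tbl$metric,
    value = ifelse(
      summary_tbl$metric == "tmax",
      sprintf("%s (%s–%s)", signif(summary_tbl$median, digits),
              signif(summary_tbl$min, digits), signif(summary_tbl$max, digits)),
      sprintf("%s ± %s%%", signif(summary_tbl$mean, digits),
              signif(summary_tbl$cv_pct, 3))
    )
  )
}

#' Run the full synthetic-study analysis pipeline
#'
#' Orchestrates generate -> NCA -> arm summaries -> bioequivalence ->
#' mean-profile model fit -> multiple-dose simulation for one of the
#' three study templates, optionally persisting every intermediate
#' artifact (CSV for tabular data, JSON for parameters and reports) so
#' each stage can be re-read by the module that produced it.
#'
#' The bioequivalence contrasts per template are: dose proportionality --
#' dose-normalised Cmax and AUC0-t, 20 mg vs 100 mg; evening food effect
#' -- Cmax and AUC0-t for fed/fasted, sprinkled/fasted, fed/sprinkled;
#' relative bioavailability -- dose-normalised Cmax and AUC0-t, delayed
#' vs immediate release. The compartmental stage fits the arithmetic
#' mean 100 mg delayed-release profile and simulates `n_doses` once-daily
#' doses at both 20 and 100 mg.
#'
#' @param study Study template label, as in [default_config()].
#' @param seed Integer seed for the generator.
#' @param out_dir Optional directory for artifacts; `NULL` skips writing.
#' @param n_subjects Optional sample-size override.
#' @param n_doses Doses to simulate in the accumulation step (default 20).
#' @param config Optional pre-built [default_config()] overriding
#'   `study`/`n_subjects`.
#' @return A list of class `pk_pipeline` with elements `study`, `nca`,
#'   `arm_summary`, `be`, `be_table`, `fit`, `simulations` (one `pk_sim`
#'   per dose), and `accumulation` (tibble of single-dose vs steady-state
#'   Cmax/Cmin with accumulation ratios).
#' @export
run_pk_pipeline <- function(study = c("dose_proportionality",
                                      "evening_food_effect",
                                      "relative_bioavailability"),
                            seed = 1L, out_dir = NULL, n_subjects = NULL,
                            n_doses = 20, config = NULL) {
  study <- rlang::arg_match(study)
  config <- config %||% default_config(study, n_subjects = n_subjects)
  studydat <- generate_study(config, seed = seed)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_pk_study(studydat, file.path(out_dir, "study.csv"))
  }

  res <- nca(studydat)
  summ <- nca_summary(res)

  contrasts <- switch(study,
    dose_proportionality = list(c("dr20", "dr100")),
    evening_food_effect = list(c("fed", "fasted"), c("sprinkled", "fasted"),
                               c("fed", "sprinkled")),
    relative_bioavailability = list(c("dr100", "ir20"))
  )
  metrics <- switch(study,
    dose_proportionality = c("dn_cmax", "dn_auc_last"),
    evening_food_effect = c("cmax", "auc_last"),
    relative_bioavailability = c("dn_cmax", "dn_auc_last")
  )
  be <- be_analysis(res, metrics, contrasts)
  be_rendered <- render_be_table(be)

  # mean profile of the delayed 100 mg arm (falls back to the first
  # delayed treatment present)
  trt_tbl <- studydat$treatments
  delayed <- trt_tbl$treatment[trt_tbl$formulation == "delayed_extended"]
  fit_trt <- if ("dr100" %in% delayed) "dr100" else
    if ("fasted" %in% delayed) "fasted" else delayed[1]
  fit_dose <- trt_tbl$dose_mg[trt_tbl$treatment == fit_trt]
  mean_profile <- dplyr::summarise(
    dplyr::group_by(
      dplyr::filter(studydat$conc, .data$treatment == fit_trt),
      .data$time_h),
    conc_ng_ml = mean(.data$conc_ng_ml), .groups = "drop"
  )
  fit <- fit_one_cpt(mean_profile, dose_mg = fit_dose)

  sims <- lapply(c(20, 100), function(dose) {
    simulate_regimen(fit$params, dose_mg = dose, tau_h = 24,
                     n_doses = n_doses)
  })
  names(sims) <- c("20", "100")
  accumulation <- purrr::imap_dfr(sims, function(s, dose) {
    tibble::tibble(
      dose_mg = as.numeric(dose),
      cmax_single = s$intervals$cmax[1],
      cmax_ss = s$intervals$cmax[s$n_doses],
      r_cmax = s$r_cmax,
      cmin_single = s$intervals$cmin[1],
      cmin_ss = s$intervals$cmin[s$n_doses],
      r_cmin = s$r_cmin,
      n_to_steady_state = s$n_to_steady_state
    )
  })

  if (!is.null(out_dir)) {
    readr::write_csv(res, file.path(out_dir, "nca.csv"), progress = FALSE)
    readr::write_csv(summ, file.path(out_dir, "arm_summary.csv"),
                     progress = FALSE)
    readr::write_csv(be, file.path(out_dir, "be.csv"), progress = FALSE)
    readr::write_csv(be_rendered, file.path(out_dir, "be_table.csv"),
                     progress = FALSE)
    jsonlite::write_json(
      list(params = unclass(fit$params), rss = fit$rss,
           dose_mg = fit$dose_mg, converged = fit$converged),
      file.path(out_dir, "fit.json"), auto_unbox = TRUE, digits = NA)
    readr::write_csv(accumulation, file.path(out_dir, "accumulation.csv"),
                     progress = FALSE)
  }

  structure(
    list(study = studydat, nca = res, arm_summary = summ, be = be,
         be_table = be_rendered, fit = fit, simulations = sims,
         accumulation = accumulation, config = config, seed = seed),
    class = "pk_pipeline"
  )
}

#' @exportS3Method base::print
print.pk_pipeline <- function(x, ...) {
  cat(sprintf("<pk_pipeline> %s (seed %s)\n", x$config$study, x$seed))
  cat("\nBioequivalence:\n")
  print(x$be_table)
  cat("\nAccumulation:\n")
  print(x$accumulation)
  invisible(x)
}
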