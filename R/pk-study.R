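#' Apply the lower-limit-of-quantitation rule
#'
#' Plasma concentrations below the assay's lower limit of quantitation
#' (LLOQ) are not reliably measurable and are set to exactly zero before
#' any analysis. The substitution is idempotent: applying it twice gives
#' the same result as applying it once.
#'
#' @param conc Numeric vector of concentrations (ng/mL).
#' @param lloq Lower limit of quantitation in ng/mL (default 0.02).
#' @return Numeric vector with every value strictly below `lloq` replaced
#'   by 0.
#' @examples
#' apply_lloq(c(0.01, 0.02, 5), lloq = 0.02)
#' @export
apply_lloq <- function(conc, lloq = 0.02) {
  assert_scalar_number(lloq, "lloq")
  conc[!is.na(conc) & conc < lloq] <- 0
  conc
}

#' Assemble and validate a crossover pharmacokinetic study
#'
#' Bundles a long-format concentration--time table with the treatment
#' regimens and (optionally) the nominal sampling schedule into a
#' validated `pk_study` object, the input container for [nca()] and the
#' bioequivalence tools.
#'
#' Validation enforces: strictly increasing times within each
#' subject/period/treatment profile, no negative times or concentrations,
#' integer periods, each subject dosed at most once per period, and --
#' when the sequence labels are `"-"`-separated treatment codes -- that
#' each subject's treatments follow its randomised sequence. The LLOQ
#' substitution ([apply_lloq()]) is applied on construction, so stored
#' concentrations are the analysis values.
#'
#' @param conc Data frame with columns `subject`, `sequence`, `period`,
#'   `treatment`, `time_h`, `conc_ng_ml` (one row per observation).
#' @param treatments Optional data frame with columns `treatment`,
#'   `dose_mg`, `formulation` (`"delayed_extended"` or
#'   `"immediate_release"`), `tau_h`, `n_doses` describing each regimen.
#'   Needed for dose-normalised metrics.
#' @param schedule Optional data frame with columns `treatment`, `time_h`
#'   giving the nominal sampling schedule; profile times must be a subset.
#' @param design Study design label: `"two_by_two"`,
#'   `"latin_square_3x3_6seq"`, or `"parallel"`.
#' @param lloq Lower limit of quantitation (ng/mL).
#' @return An object of class `pk_study`: a list with elements `conc`
#'   (tibble sorted by subject/period/time), `treatments`, `schedule`,
#'   `design`, and `lloq`.
#' @seealso [read_pk_study()], [generate_study()]
#' @export
pk_study <- function(conc,
                     treatments = NULL,
                     schedule = NULL,
                     design = c("two_by_two", "latin_square_3x3_6seq", "parallel"),
                     lloq = 0.02) {
  design <- rlang::arg_match(design)
  required <- c("subject", "sequence", "period", "treatment", "time_h", "conc_ng_ml")
  missing_cols <- setdiff(required, names(conc))
  if (length(missing_cols) > 0L) {
    pk_abort(paste0("Missing required column(s): ",
                    paste(missing_cols, collapse = ", ")),
             "pkcross_error_schema")
  }
  conc <- tibble::as_tibble(conc)[required]
  conc$subject <- as.character(conc$subject)
  conc$sequence <- as.character(conc$sequence)
  conc$treatment <- as.character(conc$treatment)

  if (!is.numeric(conc$period) || any(is.na(conc$period)) ||
      any(conc$period != round(conc$period)) || any(conc$period < 1)) {
    pk_abort("`period` must contain positive integers.",
             "pkcross_error_integrity")
  }
  conc$period <- as.integer(conc$period)
  suppressWarnings({
    conc$time_h <- as.numeric(conc$time_h)
    conc$conc_ng_ml <- as.numeric(conc$conc_ng_ml)
  })
  if (any(is.na(conc$time_h)) || any(conc$time_h < 0)) {
    pk_abort("`time_h` must be non-negative and non-missing.",
             "pkcross_error_value")
  }
  if (any(is.na(conc$conc_ng_ml)) || any(conc$conc_ng_ml < 0)) {
    pk_abort("`conc_ng_ml` must be non-negative and non-missing.",
             "pkcross_error_value")
  }
  if (anyDuplicated(conc[c("subject", "period", "time_h")]) > 0L) {
    pk_abort("Duplicate (subject, period, time_h) observations.",
             "pkcross_error_integrity")
  }

  conc$conc_ng_ml <- apply_lloq(conc$conc_ng_ml, lloq)
  conc <- dplyr::arrange(conc, .data$subject, .data$period, .data$time_h)

  # one treatment per subject-period
  per <- dplyr::distinct(conc, .data$subject, .data$period, .data$treatment)
  if (anyDuplicated(per[c("subject", "period")]) > 0L) {
    pk_abort("A subject has more than one treatment in the same period.",
             "pkcross_error_integrity")
  }
  # one sequence label per subject
  seq_tbl <- dplyr::distinct(conc, .data$subject, .data$sequence)
  if (anyDuplicated(seq_tbl$subject) > 0L) {
    pk_abort("A subject carries more than one sequence label.",
             "pkcross_error_integrity")
  }
  check_sequence_consistency(per, seq_tbl)

  if (!is.null(treatments)) {
    treatments <- tibble::as_tibble(treatments)
    treat_required <- c("treatment", "dose_mg", "formulation", "tau_h", "n_doses")
    miss <- setdiff(treat_required, names(treatments))
    if (length(miss) > 0L) {
      pk_abort(paste0("`treatments` is missing column(s): ",
                      paste(miss, collapse = ", ")),
               "pkcross_error_schema")
    }
    if (any(treatments$dose_mg <= 0) || any(treatments$tau_h <= 0) ||
        any(treatments$n_doses < 1)) {
      pk_abort("Regimens require dose_mg > 0, tau_h > 0, n_doses >= 1.",
               "pkcross_error_value")
    }
    unknown <- setdiff(unique(conc$treatment), treatments$treatment)
    if (length(unknown) > 0L) {
      pk_abort(paste0("Treatment(s) without a regimen: ",
                      paste(unknown, collapse = ", ")),
               "pkcross_error_integrity")
    }
  }

  if (!is.null(schedule)) {
    schedule <- tibble::as_tibble(schedule)
    if (!all(c("treatment", "time_h") %in% names(schedule))) {
      pk_abort("`schedule` needs columns treatment and time_h.",
               "pkcross_error_schema")
    }
    off <- dplyr::anti_join(
      dplyr::distinct(conc, .data$treatment, .data$time_h),
      schedule,
      by = c("treatment", "time_h")
    )
    if (nrow(off) > 0L) {
      pk_abort("Observed times outside the nominal sampling schedule.",
               "pkcross_error_integrity")
    }
  }

  structure(
    list(conc = conc, treatments = treatments, schedule = schedule,
         design = design, lloq = lloq),
    class = "pk_study"
  )
}

# sequences written as "A-B-C" must match the treatment given in each period
check_sequence_consistency <- function(per, seq_tbl) {
  if (nrow(per) == 0L) return(invisible(NULL))
  n_periods <- max(per$period)
  for (i in seq_len(nrow(seq_tbl))) {
    toks <- strsplit(seq_tbl$sequence[i], "-", fixed = TRUE)[[1]]
    if (length(toks) != n_periods) next  # label not parseable; skip check
    rows <- per[per$subject == seq_tbl$subject[i], ]
    if (any(toks[rows$period] != rows$treatment)) {
      pk_abort(sprintf("Subject %s's treatments do not follow sequence %s.",
                       seq_tbl$subject[i], seq_tbl$sequence[i]),
               "pkcross_error_integrity")
    }
  }
  invisible(NULL)
}

#' @exportS3Method base::print
print.pk_study <- function(x, ...) {
  prof <- dplyr::distinct(x$conc, .data$subject, .data$period, .data$treatment)
  cat(sprintf("<pk_study> design: %s | %d subjects | %d profiles | LLOQ %g ng/mL\n",
              x$design, dplyr::n_distinct(x$conc$subject), nrow(prof), x$lloq))
  if (!is.null(x$treatments)) {
    cat("treatments:\n")
    print(x$treatments)
  }
  invisible(x)
}

#' Split a study into per-profile tables
#'
#' @param study A `pk_study`.
#' @return A tibble with one row per subject x period x treatment profile
#'   and list-columns `time_h` and `conc_ng_ml`.
#' @export
study_profiles <- function(study) {
  stopifnot(inherits(study, "pk_study"))
  dplyr::reframe(
    dplyr::group_by(study$conc, .data$subject, .data$sequence,
                    .data$period, .data$treatment),
    time_h = list(.data$time_h),
    conc_ng_ml = list(.data$conc_ng_ml)
  )
}

#' Read a crossover study from a long-format CSV
#'
#' The CSV holds one row per observation with columns `subject`,
#' `sequence`, `period`, `treatment`, `time_h`, `conc_ng_ml` (UTF-8,
#' comma-separated, dot decimal; times in hours post-dose). Design
#' metadata (treatment regimens, sampling schedule, design label, LLOQ)
#' comes from a JSON side-car config, by default the CSV path with a
#' `.json` extension as written by [write_pk_study()].
#'
#' @param path Path to the CSV file.
#' @param config Path to the JSON design config, or a list with elements
#'   `design`, `lloq`, `treatments`, `schedule`. `NULL` (and no side-car
#'   file) reads concentrations only, with defaults
#'   `design = "two_by_two"`, `lloq = 0.02`.
#' @return A validated [pk_study()].
#' @export
read_pk_study <- function(path, config = NULL) {
  if (!file.exists(path)) {
    pk_abort(paste0("File not found: ", path), "pkcross_error_io")
  }
  if (is.null(config)) {
    side <- sub("\\.csv$", ".json", path)
    if (!identical(side, path) && file.exists(side)) config <- side
  }
  if (is.character(config)) {
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }

  # base read.csv: strtod parsing is correctly rounded, so decimal text
  # written with 17 significant digits round-trips doubles bit-exactly
  conc <- tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  required <- c("subject", "sequence", "period", "treatment", "time_h", "conc_ng_ml")
  missing_cols <- setdiff(required, names(conc))
  if (length(missing_cols) > 0L) {
    pk_abort(paste0("Missing required column(s): ",
                    paste(missing_cols, collapse = ", ")),
             "pkcross_error_schema")
  }
  if (!is.numeric(conc$period)) {
    suppressWarnings(p <- as.numeric(conc$period))
    if (any(is.na(p))) {
      pk_abort("`period` must be integer-valued.", "pkcross_error_integrity")
    }
    conc$period <- p
  }

  treatments <- config$treatments
  if (!is.null(treatments)) treatments <- tibble::as_tibble(treatments)
  schedule <- config$schedule
  if (!is.null(schedule)) schedule <- tibble::as_tibble(schedule)

  pk_study(conc,
           treatments = treatments,
           schedule = schedule,
           design = config$design %||% "two_by_two",
           lloq = config$lloq %||% 0.02)
}

#' Write a crossover study to CSV plus a JSON design config
#'
#' Inverse of [read_pk_study()]: `read_pk_study(write_pk_study(s, path))`
#' reproduces the study exactly (numeric columns round-trip through
#' decimal text losslessly).
#'
#' @param study A `pk_study`.
#' @param path CSV output path.
#' @param config_path JSON config output path; default replaces the
#'   `.csv` extension with `.json`.
#' @return `path`, invisibly.
#' @export
write_pk_study <- function(study, path, config_path = NULL) {
  stopifnot(inherits(study, "pk_study"))
  config_path <- config_path %||% sub("\\.csv$", ".json", path)
  out <- study$conc
  # 17 significant digits round-trip a double through decimal text exactly
  out$time_h <- sprintf("%.17g", out$time_h)
  out$conc_ng_ml <- sprintf("%.17g", out$conc_ng_ml)
  ok <- tryCatch({
    readr::write_csv(out, path, progress = FALSE)
    TRUE
  }, error = function(e) FALSE)
  if (!ok) pk_abort(paste0("Cannot write: ", path), "pkcross_error_io")
  cfg <- list(design = study$design, lloq = study$lloq)
  if (!is.null(study$treatments)) cfg$treatments <- study$treatments
  if (!is.null(study$schedule)) cfg$schedule <- study$schedule
  jsonlite::write_json(cfg, config_path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
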