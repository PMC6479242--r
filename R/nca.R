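#' Peak concentration and its time
#'
#' `Cmax` is the maximum observed concentration and `Tmax` the earliest
#' sampling time attaining it (ties broken by earliest time, the
#' conventional deterministic rule).
#'
#' @param time_h Numeric vector of sampling times (hours post-dose),
#'   strictly increasing.
#' @param conc Numeric vector of concentrations (ng/mL), same length.
#' @return A named list with elements `cmax` and `tmax`.
#' @export
pk_cmax <- function(time_h, conc) {
  check_profile_vectors(time_h, conc)
  if (all(conc <= 0)) {
    pk_abort("Cmax undefined: no positive concentration in profile.",
             "pkcross_error_undefined_metric")
  }
  i <- which.max(conc)  # which.max returns the first (earliest) maximum
  list(cmax = conc[i], tmax = time_h[i])
}

check_profile_vectors <- function(time_h, conc) {
  if (length(time_h) != length(conc)) {
    pk_abort("time and concentration vectors differ in length.",
             "pkcross_error_value")
  }
  if (length(time_h) > 1L && any(diff(time_h) <= 0)) {
    pk_abort("times must be strictly increasing.", "pkcross_error_value")
  }
  if (any(conc < 0) || any(time_h < 0)) {
    pk_abort("negative time or concentration.", "pkcross_error_value")
  }
  invisible(NULL)
}

#' Linear trapezoidal area under the curve
#'
#' Integrates the piecewise-linear interpolant of the concentration--time
#' profile over `[t_start, t_end]`. Boundary values at window edges that
#' are not sampling times are obtained by linear interpolation. `AUC0-t`
#' is the area from 0 to the time of the last quantifiable concentration.
#'
#' @inheritParams pk_cmax
#' @param t_start,t_end Window bounds in hours; must lie within the
#'   observed time range. Defaults integrate the full profile.
#' @return Area in ng.h/mL.
#' @export
pk_auc <- function(time_h, conc, t_start = min(time_h), t_end = max(time_h)) {
  check_profile_vectors(time_h, conc)
  if (t_start >= t_end) {
    pk_abort("t_start must be < t_end.", "pkcross_error_value")
  }
  if (t_start < min(time_h) || t_end > max(time_h)) {
    pk_abort("AUC window outside the observed time range.",
             "pkcross_error_range")
  }
  inside <- time_h > t_start & time_h < t_end
  tt <- c(t_start, time_h[inside], t_end)
  cc <- c(stats::approx(time_h, conc, xout = t_start)$y,
          conc[inside],
          stats::approx(time_h, conc, xout = t_end)$y)
  sum(diff(tt) * (head(cc, -1) + tail(cc, -1)) / 2)
}

#' Terminal elimination rate constant by log-linear regression
#'
#' Estimates the terminal rate constant as minus the least-squares slope
#' of log concentration on time over a terminal window of points strictly
#' after `Tmax`. Zero concentrations are excluded (their log is
#' undefined). By default all candidate windows of at least `min_points`
#' consecutive usable points ending at the last positive concentration
#' are evaluated and the window with the largest adjusted R-squared wins;
#' ties go to the window with more points. A manual window can be forced
#' via `manual_times`.
#'
#' @inheritParams pk_cmax
#' @param min_points Minimum number of regression points (default 3).
#' @param manual_times Optional numeric vector of sampling times to use
#'   as the regression window, overriding automatic selection.
#' @return A named list with `lambda_z` (1/h), `n_points`, `r2_adj`, and
#'   `tail_times` (the times used). If no window yields a positive rate
#'   constant the three estimates are `NA` (the metric is missing).
#' @export
pk_lambda_z <- function(time_h, conc, min_points = 3, manual_times = NULL) {
  check_profile_vectors(time_h, conc)
  undefined <- list(lambda_z = NA_real_, n_points = NA_integer_,
                    r2_adj = NA_real_, tail_times = numeric(0))
  if (all(conc <= 0)) return(undefined)
  tmax <- pk_cmax(time_h, conc)$tmax

  usable <- which(time_h > tmax & conc > 0)
  if (!is.null(manual_times)) {
    idx <- which(time_h %in% manual_times & conc > 0)
    if (length(idx) < 2L) return(undefined)
    return(loglin_fit(time_h[idx], conc[idx]) %||% undefined)
  }
  if (length(usable) < min_points) return(undefined)

  # all suffix windows [s .. last] in one pass via reverse cumulative
  # sums, so profiles with thousands of points stay O(n)
  tt <- time_h[usable]
  y <- log(conc[usable])
  rcum <- function(x) rev(cumsum(rev(x)))
  m <- length(tt)
  n_w <- m - seq_len(m) + 1
  st <- rcum(tt); st2 <- rcum(tt^2)
  sy <- rcum(y); sy2 <- rcum(y^2); sty <- rcum(tt * y)
  sxx <- st2 - st^2 / n_w
  sxy <- sty - st * sy / n_w
  syy <- sy2 - sy^2 / n_w
  keep <- n_w >= min_points
  slope <- sxy / sxx
  r2 <- ifelse(syy > 0, sxy^2 / (sxx * syy), 1)
  r2_adj <- ifelse(n_w > 2, 1 - (1 - r2) * (n_w - 1) / (n_w - 2), r2)
  ok <- keep & is.finite(slope) & slope < 0
  if (!any(ok)) return(undefined)
  best <- max(r2_adj[ok])
  cand <- which(ok & r2_adj >= best - 1e-9)  # numerical ties
  s <- cand[which.max(n_w[cand])]            # tie-break: more points
  list(lambda_z = -slope[s], n_points = as.integer(n_w[s]),
       r2_adj = r2_adj[s], tail_times = tt[s:m])
}

# least-squares slope of ln(conc) on time; NULL when slope not negative
loglin_fit <- function(tt, cc) {
  y <- log(cc)
  n <- length(tt)
  mx <- mean(tt); my <- mean(y)
  sxx <- sum((tt - mx)^2)
  slope <- sum((tt - mx) * (y - my)) / sxx
  if (!is.finite(slope) || slope >= 0) return(NULL)
  resid <- y - my - slope * (tt - mx)
  sst <- sum((y - my)^2)
  r2 <- if (sst > 0) 1 - sum(resid^2) / sst else 1
  r2_adj <- if (n > 2) 1 - (1 - r2) * (n - 1) / (n - 2) else r2
  list(lambda_z = -slope, n_points = as.integer(n), r2_adj = r2_adj,
       tail_times = tt)
}

#' Terminal half-life
#'
#' @param lambda_z Terminal elimination rate constant (1/h), > 0.
#' @return `log(2) / lambda_z`, in hours.
#' @export
pk_half_life <- function(lambda_z) {
  if (any(!is.na(lambda_z) & lambda_z <= 0)) {
    pk_abort("lambda_z must be > 0.", "pkcross_error_value")
  }
  log(2) / lambda_z
}

#' Extrapolate AUC to infinity
#'
#' `AUC0-inf = AUC0-t + Clast / lambda_z`, where `Clast` is the last
#' quantifiable concentration. Returns `NA` (metric missing) when
#' `lambda_z` is undefined or `Clast` is zero.
#'
#' @param auc_last AUC to the last quantifiable concentration (ng.h/mL).
#' @param clast Last quantifiable concentration (ng/mL).
#' @param lambda_z Terminal rate constant (1/h).
#' @return AUC0-inf in ng.h/mL, or `NA`.
#' @export
pk_auc_inf <- function(auc_last, clast, lambda_z) {
  ifelse(is.na(lambda_z) | is.na(clast) | clast <= 0 | lambda_z <= 0,
         NA_real_,
         auc_last + clast / lambda_z)
}

#' Dose-normalise an exposure metric
#'
#' @param value Metric value(s) (e.g. Cmax in ng/mL or AUC in ng.h/mL).
#' @param dose_mg Administered dose in mg, > 0.
#' @return `value / dose_mg`.
#' @export
dose_normalize <- function(value, dose_mg) {
  if (any(!is.finite(dose_mg)) || any(dose_mg <= 0)) {
    pk_abort("dose_mg must be > 0.", "pkcross_error_value")
  }
  value / dose_mg
}

#' Early-exposure fraction of total AUC
#'
#' Percentage of `AUC0-t` accrued in the window `[0, window_end]`; for an
#' evening-dosed delayed-release formulation with a roughly 10-hour lag
#' this quantifies overnight drug release.
#'
#' @inheritParams pk_cmax
#' @param window_end End of the early window in hours (default 10).
#' @return Percentage in `[0, 100]`.
#' @export
early_exposure_fraction <- function(time_h, conc, window_end = 10) {
  check_profile_vectors(time_h, conc)
  if (min(time_h) > 0 || max(time_h) < window_end) {
    pk_abort("profile must span [0, window_end].", "pkcross_error_range")
  }
  total <- pk_auc(time_h, conc)
  if (total <= 0) {
    pk_abort("early-exposure fraction undefined: AUC0-t is zero.",
             "pkcross_error_undefined_metric")
  }
  100 * pk_auc(time_h, conc, 0, window_end) / total
}

#' Noncompartmental work-up of a single profile
#'
#' Vector-level counterpart of [nca()] for one concentration--time
#' profile; useful inside `dplyr::reframe()` or for ad-hoc profiles.
#'
#' @inheritParams pk_cmax
#' @param dose_mg Dose in mg (`NA` skips dose-normalised metrics).
#' @param early_window Early-exposure window end (h).
#' @param lambda_min_points Minimum points for the terminal regression.
#' @param lambda_manual_times Optional forced terminal-window times.
#' @return A named list of NCA metrics (see [nca()]).
#' @export
nca_profile <- function(time_h, conc, dose_mg = NA_real_,
                        early_window = 10, lambda_min_points = 3,
                        lambda_manual_times = NULL) {
  cm <- pk_cmax(time_h, conc)
  pos <- which(conc > 0)
  tlast <- time_h[max(pos)]
  clast <- conc[max(pos)]
  auc_last <- pk_auc(time_h, conc, min(time_h), tlast)
  lz <- pk_lambda_z(time_h, conc, min_points = lambda_min_points,
                    manual_times = lambda_manual_times)
  early <- if (min(time_h) <= 0 && max(time_h) >= early_window && auc_last > 0) {
    early_exposure_fraction(time_h, conc, early_window)
  } else {
    NA_real_
  }
  list(
    cmax = cm$cmax, tmax = cm$tmax, tlast = tlast, clast = clast,
    auc_last = auc_last,
    auc_inf = pk_auc_inf(auc_last, clast, lz$lambda_z),
    lambda_z = lz$lambda_z,
    t_half = if (is.na(lz$lambda_z)) NA_real_ else pk_half_life(lz$lambda_z),
    n_lambda_points = lz$n_points, r2_adj = lz$r2_adj,
    dn_cmax = if (is.na(dose_mg)) NA_real_ else dose_normalize(cm$cmax, dose_mg),
    dn_auc_last = if (is.na(dose_mg)) NA_real_ else dose_normalize(auc_last, dose_mg),
    early_fraction = early
  )
}

#' Noncompartmental analysis of every profile in a study
#'
#' Computes, per subject x period x treatment profile: `Cmax`, `Tmax`,
#' `Tlast`, `Clast`, `AUC0-t` (linear trapezoidal rule), `AUC0-inf`
#' (`AUC0-t + Clast/lambda_z`), the terminal rate constant and half-life
#' with regression diagnostics, dose-normalised `Cmax` and `AUC0-t`
#' (when regimens are attached to the study), and the early-exposure
#' fraction over `[0, early_window]` hours.
#'
#' Profiles with no positive concentration yield a row of `NA` metrics
#' with a warning; profiles whose terminal phase cannot be characterised
#' (< `lambda_min_points` usable points after `Tmax`, or no negative
#' log-linear slope) report `lambda_z`-dependent metrics as missing.
#'
#' @param study A [pk_study()].
#' @param early_window Early-exposure window end, hours (default 10).
#' @param lambda_min_points Minimum points for the terminal regression.
#' @param lambda_manual Optional named list mapping
#'   `"subject/period"` keys to numeric time vectors forcing the terminal
#'   window for specific profiles.
#' @return A tibble of class `pk_nca`, one row per profile.
#' @examples
#' study <- generate_study(default_config("dose_proportionality"), seed = 1)
#' nca(study)
#' @export
nca <- function(study, early_window = 10, lambda_min_points = 3,
                lambda_manual = NULL) {
  stopifnot(inherits(study, "pk_study"))
  profs <- study_profiles(study)
  doses <- if (!is.null(study$treatments)) {
    setNames(study$treatments$dose_mg, study$treatments$treatment)
  } else {
    NULL
  }
  rows <- vector("list", nrow(profs))
  for (i in seq_len(nrow(profs))) {
    tt <- profs$time_h[[i]]
    cc <- profs$conc_ng_ml[[i]]
    dose <- if (is.null(doses)) NA_real_ else unname(doses[profs$treatment[i]])
    key <- paste(profs$subject[i], profs$period[i], sep = "/")
    manual <- if (!is.null(lambda_manual)) lambda_manual[[key]] else NULL
    rows[[i]] <- tryCatch(
      nca_profile(tt, cc, dose_mg = dose, early_window = early_window,
                  lambda_min_points = lambda_min_points,
                  lambda_manual_times = manual),
      pkcross_error_undefined_metric = function(e) {
        warn(sprintf("Profile %s: %s", key, conditionMessage(e)))
        empty_nca_row()
      }
    )
  }
  out <- dplyr::bind_cols(
    profs[c("subject", "sequence", "period", "treatment")],
    dplyr::bind_rows(lapply(rows, tibble::as_tibble))
  )
  out$dose_mg <- if (is.null(doses)) NA_real_ else unname(doses[out$treatment])
  class(out) <- c("pk_nca", class(out))
  out
}

empty_nca_row <- function() {
  list(cmax = NA_real_, tmax = NA_real_, tlast = NA_real_, clast = NA_real_,
       auc_last = NA_real_, auc_inf = NA_real_, lambda_z = NA_real_,
       t_half = NA_real_, n_lambda_points = NA_integer_, r2_adj = NA_real_,
       dn_cmax = NA_real_, dn_auc_last = NA_real_, early_fraction = NA_real_)
}

#' Arm-level descriptive summary of NCA metrics
#'
#' For each treatment arm and metric: n (non-missing), arithmetic mean,
#' CV% (100 x sample SD / mean), median, min, max, and geometric mean --
#' the layout of a standard PK parameter table (mean +/- CV%, median Tmax
#' with range).
#'
#' @param nca_tbl A `pk_nca` tibble from [nca()].
#' @param metrics Character vector of metric columns to summarise.
#' @param by Grouping column (default `"treatment"`).
#' @return A tibble with one row per group x metric.
#' @export
nca_summary <- function(nca_tbl,
                        metrics = c("cmax", "dn_cmax", "auc_last",
                                    "dn_auc_last", "auc_inf", "tmax",
                                    "t_half", "lambda_z"),
                        by = "treatment") {
  stopifnot(is.data.frame(nca_tbl))
  metrics <- intersect(metrics, names(nca_tbl))
  long <- tidyr::pivot_longer(
    dplyr::select(nca_tbl, dplyr::all_of(c(by, metrics))),
    cols = dplyr::all_of(metrics), names_to = "metric", values_to = "value"
  )
  long$metric <- factor(long$metric, levels = metrics)
  out <- dplyr::summarise(
    dplyr::group_by(long, dplyr::across(dplyr::all_of(c(by, "metric")))),
    n = sum(!is.na(.data$value)),
    mean = mean(.data$value, na.rm = TRUE),
    cv_pct = cv_pct(.data$value),
    median = median(.data$value, na.rm = TRUE),
    min = suppressWarnings(min(.data$value, na.rm = TRUE)),
    max = suppressWarnings(max(.data$value, na.rm = TRUE)),
    geo_mean = geo_mean(.data$value),
    .groups = "drop"
  )
  out$metric <- as.character(out$metric)
  out$mean[out$n == 0L] <- NA_real_
  out$median[out$n == 0L] <- NA_real_
  out$min[is.infinite(out$min)] <- NA_real_
  out$max[is.infinite(out$max)] <- NA_real_
  out
}
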