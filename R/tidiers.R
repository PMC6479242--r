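#' Tidy a one-compartment fit
#'
#' @param x A `pk_one_cpt_fit`.
#' @param ... Unused.
#' @return A tibble with one row per parameter (`term`, `estimate`,
#'   `unit`).
#' @export
tidy.pk_one_cpt_fit <- function(x, ...) {
  tibble::tibble(
    term = c("ka", "ke", "tlag", "scale"),
    estimate = c(x$params$ka, x$params$ke, x$params$tlag, x$params$scale),
    unit = c("1/h", "1/h", "h", "(ng/mL)/mg")
  )
}

#' Glance at a one-compartment fit
#'
#' @param x A `pk_one_cpt_fit`.
#' @param ... Unused.
#' @return A one-row tibble: `rss`, `sigma`, `n_obs`, `dose_mg`,
#'   `lambda_z_nca`, `converged`.
#' @export
glance.pk_one_cpt_fit <- function(x, ...) {
  n <- nrow(x$data)
  tibble::tibble(
    rss = x$rss,
    sigma = sqrt(x$rss / max(1, n - 4)),
    n_obs = n,
    dose_mg = x$dose_mg,
    lambda_z_nca = x$lambda_z_nca,
    converged = x$converged
  )
}

#' Tidy a multiple-dose simulation
#'
#' @param x A `pk_sim`.
#' @param ... Unused.
#' @return The per-interval tibble (`dose`, `cmax`, `cmin`).
#' @export
tidy.pk_sim <- function(x, ...) x$intervals

#' Glance at a multiple-dose simulation
#'
#' @param x A `pk_sim`.
#' @param ... Unused.
#' @return A one-row tibble with the accumulation summary.
#' @export
glance.pk_sim <- function(x, ...) {
  tibble::tibble(
    dose_mg = x$dose_mg, tau_h = x$tau_h, n_doses = x$n_doses,
    cmax_single = x$intervals$cmax[1], cmax_ss = x$intervals$cmax[x$n_doses],
    r_cmax = x$r_cmax,
    cmin_single = x$intervals$cmin[1], cmin_ss = x$intervals$cmin[x$n_doses],
    r_cmin = x$r_cmin,
    n_to_steady_state = x$n_to_steady_state
  )
}

#' Tidy a bioequivalence result
#'
#' `pk_be` results are already tidy; the method returns the tibble
#' unclassed, one row per metric x contrast.
#'
#' @param x A `pk_be` tibble.
#' @param ... Unused.
#' @return A plain tibble.
#' @export
tidy.pk_be <- function(x, ...) {
  tibble::as_tibble(unclass(x))
}

#' Glance at a bioequivalence result
#'
#' @param x A `pk_be` tibble.
#' @param ... Unused.
#' @return A one-row tibble: contrast count, subjects, overall verdict.
#' @export
glance.pk_be <- function(x, ...) {
  tibble::tibble(
    n_contrasts = nrow(x),
    n_subjects = x$n_subjects[1],
    method = x$method[1],
    all_bioequivalent = all(x$bioequivalent)
  )
}
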