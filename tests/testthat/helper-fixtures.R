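# Shared fixtures and independent oracles used across test files.

# A tiny hand-written 2-subject, 2-period study table
toy_conc <- function() {
  tibble::tibble(
    subject = rep(c("S1", "S1", "S2", "S2"), each = 4),
    sequence = rep(c("A-B", "A-B", "B-A", "B-A"), each = 4),
    period = rep(c(1L, 2L, 1L, 2L), each = 4),
    treatment = rep(c("A", "B", "B", "A"), each = 4),
    time_h = rep(c(0, 1, 2, 4), times = 4),
    conc_ng_ml = rep(c(0, 4, 6, 2), times = 4)
  )
}

toy_treatments <- function() {
  tibble::tibble(
    treatment = c("A", "B"), dose_mg = c(20, 100),
    formulation = "delayed_extended", tau_h = 24, n_doses = 1L
  )
}

# Balanced 2x2 crossover dataset on the metric scale, built from chosen
# subject/period/treatment log-effects plus residuals
make_2x2_metric <- function(n_per_seq, mu = 3, treat_effect = 0,
                            period_effect = 0, subj_effects = NULL,
                            resid = NULL) {
  n <- 2 * n_per_seq
  subj_effects <- subj_effects %||% rep(0, n)
  seqs <- rep(c("T-R", "R-T"), each = n_per_seq)
  rows <- list()
  k <- 0
  for (i in seq_len(n)) {
    trts <- if (seqs[i] == "T-R") c("T", "R") else c("R", "T")
    for (p in 1:2) {
      k <- k + 1
      ln_y <- mu + subj_effects[i] +
        (p == 2) * period_effect +
        (trts[p] == "T") * treat_effect +
        if (is.null(resid)) 0 else resid[k]
      rows[[k]] <- tibble::tibble(
        subject = sprintf("S%02d", i), sequence = seqs[i],
        period = p, treatment = trts[p], value = exp(ln_y)
      )
    }
  }
  dplyr::bind_rows(rows)
}

# Independent closed-form 2x2 crossover ANOVA oracle (period-difference
# method): treatment effect, 90% CI and within-subject variance from the
# per-subject half differences d_i = (ln y_i2 - ln y_i1) / 2.
oracle_2x2_be <- function(data, test = "T", reference = "R") {
  d <- data
  d$ln_y <- log(d$value)
  wide <- tidyr::pivot_wider(
    d[, c("subject", "sequence", "period", "ln_y")],
    names_from = "period", values_from = "ln_y", names_prefix = "p"
  )
  wide$half_diff <- (wide$p2 - wide$p1) / 2
  # sequence label "T-R" means `test` in period 1
  g1 <- wide$half_diff[wide$sequence == paste(test, reference, sep = "-")]
  g2 <- wide$half_diff[wide$sequence == paste(reference, test, sep = "-")]
  est <- mean(g2) - mean(g1)  # (test - reference) on the log scale
  s2 <- (sum((g1 - mean(g1))^2) + sum((g2 - mean(g2))^2)) /
    (length(g1) + length(g2) - 2)
  se <- sqrt(s2 * (1 / length(g1) + 1 / length(g2)))
  df <- length(g1) + length(g2) - 2
  half <- stats::qt(0.95, df) * se
  list(ratio = exp(est), ci90 = exp(c(est - half, est + half)),
       sigma2_within = 2 * s2, df = df)
}

`%||%` <- rlang::`%||%`
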