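# Shared fixtures and independent oracles, built in code.

# A small hand-written trial: 5 subjects, mixed events/censoring.
toy_trial <- function() {
  subjects <- data.frame(
    subject_id = c("A", "B", "C", "D", "E"),
    arm = c(0, 1, 0, 1, 0),
    ata_positive = c(1, 0, 0, 1, 1),
    baseline_fvc_pct = c(70, 80, 65, 75, 72),
    followup_end_days = c(392, 392, 392, 200, 392),
    death_day = c(NA, NA, 100, NA, NA),
    stringsAsFactors = FALSE)
  visits <- expand.grid(subject_id = subjects$subject_id,
                        visit_week = c(0, 2, 12, 24, 52),
                        stringsAsFactors = FALSE)
  visits <- visits[order(visits$subject_id, visits$visit_week), ]
  attr(visits, "out.attrs") <- NULL
  rownames(visits) <- NULL
  set.seed(42)
  visits$fvc_pct <- round(subjects$baseline_fvc_pct[
    match(visits$subject_id, subjects$subject_id)] -
      2 * visits$visit_week * 7 / 365.25 + rnorm(nrow(visits), 0, 1), 2)
  visits$on_treatment <- 1
  events <- data.frame(
    subject_id = c("A", "A", "E"),
    event_day = c(30, 30, 500),
    category = c("all_cause", "ssc_related", "all_cause"),
    stringsAsFactors = FALSE)
  fvc_trial(subjects, visits, events)
}

# Write an fvc_trial to CSVs in a temp dir; returns the three paths.
write_toy_csvs <- function(trial, dir = withr::local_tempdir(
                             .local_envir = parent.frame())) {
  paths <- file.path(dir, c("subjects.csv", "visits.csv", "events.csv"))
  write_tables(trial, paths[1], paths[2], paths[3])
  paths
}

# Brute-force marginal LMM log-likelihood via dense per-subject covariance
# Z D Z' + sigma2 I (independent of the package's Woodbury evaluation).
brute_lmm_loglik <- function(params, data) {
  s <- data$subjects
  center <- params$center
  tot <- 0
  for (i in seq_len(nrow(s))) {
    sel <- data$long$subject_id == s$subject_id[i]
    if (!any(sel)) next
    t <- data$long$time_years[sel]
    y <- data$long$fvc_pct[sel]
    mu <- params$beta[1] + params$beta[2] * s$ata_positive[i] +
      params$beta[3] * (s$baseline_fvc_pct[i] - center) +
      (params$beta[4] + params$beta[5] * s$arm[i]) * t
    Z <- cbind(1, t)
    V <- Z %*% params$D %*% t(Z) + diag(params$sigma2, length(t))
    r <- y - mu
    tot <- tot - 0.5 * (length(t) * log(2 * pi) +
                          as.numeric(determinant(V)$modulus) +
                          drop(crossprod(r, solve(V, r))))
  }
  tot
}

# Dense-grid 2-D integration oracle for the joint log-likelihood: a 161^2
# Riemann grid per subject, centred at a crude per-subject least-squares
# estimate of (b0, b1) so the mass is covered, then summed directly.
grid_joint_loglik <- function(lmm, hazard, alpha, data, association,
                              npts = 161, half0 = 22, half1 = 18) {
  s <- data$subjects
  tot <- 0
  for (i in seq_len(nrow(s))) {
    sel <- data$long$subject_id == s$subject_id[i]
    t <- data$long$time_years[sel]
    y <- data$long$fvc_pct[sel]
    mu0 <- lmm$beta[1] + lmm$beta[2] * s$ata_positive[i] +
      lmm$beta[3] * (s$baseline_fvc_pct[i] - lmm$center) +
      (lmm$beta[4] + lmm$beta[5] * s$arm[i]) * t
    r <- y - mu0
    ctr <- if (length(t) >= 2) {
      unname(coef(stats::lm(r ~ t)))
    } else c(0, 0)
    g0 <- ctr[1] + seq(-half0, half0, length.out = npts)
    g1 <- ctr[2] + seq(-half1, half1, length.out = npts)
    f <- outer(g0, g1, Vectorize(function(b0, b1) {
      ll <- sum(dnorm(y, mu0 + b0 + b1 * t, sqrt(lmm$sigma2), log = TRUE))
      st <- subject_survival_terms(lmm, hazard, alpha, s$ata_positive[i],
                                   s$baseline_fvc_pct[i], s$arm[i],
                                   s$event_time_years[i], c(b0, b1),
                                   association = association)
      ll + s$event[i] * st["log_hazard"] + st["neg_cum_hazard"] -
        log(2 * pi) - 0.5 * log(det(lmm$D)) -
        0.5 * drop(crossprod(c(b0, b1), solve(lmm$D, c(b0, b1))))
    }))
    m <- max(f)
    tot <- tot + m + log(sum(exp(f - m)) * diff(g0)[1] * diff(g1)[1])
  }
  tot
}

default_truth_params <- function(cfg, center) {
  lmm_params(cfg$beta, cfg$D, cfg$sigma^2, center)
}
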