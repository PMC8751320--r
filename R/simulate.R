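## Two-arm trial simulator.  The generator is the exact probabilistic
## inverse of the model the package fits: linear subject-specific FVC
## trajectories with bivariate-normal random effects, and event times drawn
## by inverting the subject's cumulative hazard at a uniform draw
## (Lambda_i(T) = -log u), with the piecewise-constant baseline hazard and
## the slope or current-value association.

#' Simulator configuration
#'
#' Defaults emulate a SENSCIS-like two-arm trial: 1:1 allocation, 60.8% ATA
#' positive, baseline FVC 72.5 +/- 16.7 % predicted, control-arm decline
#' -2.6 %/yr with a +1.2 %/yr treatment difference, slope association with
#' hazard ratio 1.13 per unit of annual decline, and a constant baseline
#' hazard of 0.10/yr calibrated so that roughly 14% of subjects have a
#' composite event inside the 52-week analysis window.
#'
#' @param n_subjects number of subjects.
#' @param allocation fraction allocated to the active arm (default 0.5;
#'   exactly alternating assignment when 0.5).
#' @param ata_prevalence probability of ATA-positive status.
#' @param female_fraction cosmetic; recorded in the truth object only.
#' @param baseline_fvc_mean,baseline_fvc_sd baseline FVC % predicted.
#' @param beta true fixed effects (named as in [lmm_params()]); the
#'   baseline-FVC effect is applied to FVC0 centered at
#'   `baseline_fvc_mean`.
#' @param D true 2x2 random-effects covariance (default: intercept SD 12,
#'   slope SD 3 %/yr, correlation -0.2).
#' @param sigma residual SD (% predicted).
#' @param knots,log_h0 true baseline hazard (default: no knots, constant
#'   0.10/yr in both strata).
#' @param alpha true association coefficient (default `-log(1.13)` per
#'   %-predicted/yr of slope).
#' @param association `"slope"` or `"current_value"`.
#' @param period `"52w"` (admin censoring at 392 days, visits to week 52) or
#'   `"whole"` (728 days, visits to week 100).
#' @param schedule_weeks visit schedule; default depends on `period`.
#' @param dropout_rate exponential dropout hazard per year (default 0).
#' @param p_death probability a composite event is a death rather than a
#'   hospitalisation.
#' @param p_ssc,p_er_icu,p_icu,p_vent probabilities that a hospitalisation
#'   also qualifies for the narrower endpoint categories.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_subjects = 300,
                       allocation = 0.5,
                       ata_prevalence = 0.608,
                       female_fraction = 0.751,
                       baseline_fvc_mean = 72.5,
                       baseline_fvc_sd = 16.7,
                       beta = c(intercept = 72.5, ata = -1.5,
                                baseline_fvc = 1, slope_control = -2.6,
                                slope_trt_diff = 1.2),
                       D = matrix(c(144, -7.2, -7.2, 9), 2, 2),
                       sigma = 3,
                       knots = numeric(0),
                       log_h0 = log(0.10),
                       alpha = -log(1.13),
                       association = c("slope", "current_value"),
                       period = c("52w", "whole"),
                       schedule_weeks = NULL,
                       dropout_rate = 0,
                       p_death = 0.10, p_ssc = 0.54, p_er_icu = 0.90,
                       p_icu = 0.10, p_vent = 0.05) {
  association <- match.arg(association)
  period <- match.arg(period)
  if (is.null(schedule_weeks)) {
    schedule_weeks <- c(0, 2, 4, 6, 12, 24, 36, 52)
    if (period == "whole") schedule_weeks <- c(schedule_weeks, 68, 84, 100)
  }
  for (p in c(allocation, ata_prevalence, female_fraction, p_death, p_ssc,
              p_er_icu, p_icu, p_vent)) {
    if (!is.finite(p) || p < 0 || p > 1) {
      stop("probabilities must lie in [0, 1]")
    }
  }
  stopifnot(n_subjects >= 1, baseline_fvc_sd > 0, sigma >= 0,
            dropout_rate >= 0, all(diff(schedule_weeks) > 0),
            all(schedule_weeks >= 0))
  beta <- beta[LMM_BETA_NAMES]
  if (any(is.na(beta))) stop("beta must be named as in lmm_params()")
  hz <- piecewise_hazard(knots, matrix(log_h0, nrow = if (
    is.matrix(log_h0)) nrow(log_h0) else 1, ncol = length(knots) + 1L))
  structure(list(n_subjects = as.integer(n_subjects),
                 allocation = allocation, ata_prevalence = ata_prevalence,
                 female_fraction = female_fraction,
                 baseline_fvc_mean = baseline_fvc_mean,
                 baseline_fvc_sd = baseline_fvc_sd,
                 beta = beta, D = D, sigma = sigma,
                 hazard = hz, alpha = alpha, association = association,
                 period = period, schedule_weeks = schedule_weeks,
                 admin_days = if (period == "52w") CAP_52W_DAYS else
                   100 * WEEK_DAYS + POST_TREATMENT_WINDOW_DAYS,
                 dropout_rate = dropout_rate,
                 p_death = p_death, p_ssc = p_ssc, p_er_icu = p_er_icu,
                 p_icu = p_icu, p_vent = p_vent),
            class = "sim_config")
}

#' Read a simulator configuration from a YAML file
#'
#' Fields missing from the file keep their [sim_config()] defaults.  `D`
#' may be given as `d_intercept_sd`, `d_slope_sd`, `d_corr`; the hazard as
#' `knots` and `h0` (heights, recycled across strata).
#'
#' @param path YAML file.
#' @return A `sim_config` object.
#' @export
read_sim_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- list()
  direct <- intersect(names(y), c(
    "n_subjects", "allocation", "ata_prevalence", "female_fraction",
    "baseline_fvc_mean", "baseline_fvc_sd", "sigma", "alpha", "association",
    "period", "schedule_weeks", "dropout_rate", "p_death", "p_ssc",
    "p_er_icu", "p_icu", "p_vent", "knots"))
  args[direct] <- y[direct]
  if (!is.null(y$beta)) args$beta <- unlist(y$beta)
  if (!is.null(y$d_intercept_sd)) {
    r <- if (is.null(y$d_corr)) 0 else y$d_corr
    s1 <- y$d_intercept_sd
    s2 <- if (is.null(y$d_slope_sd)) s1 else y$d_slope_sd
    args$D <- matrix(c(s1^2, r * s1 * s2, r * s1 * s2, s2^2), 2, 2)
  }
  if (!is.null(y$h0)) args$log_h0 <- log(unlist(y$h0))
  do.call(sim_config, args)
}

# Invert Lambda(T) = target for one subject.  `cum` gives the cumulative
# hazard contribution of each full piece; inversion walks the pieces.
invert_hazard_slope <- function(target, mult, h, bnd) {
  # Lambda(t) = mult * sum_j h_j |[bnd_j, bnd_{j+1}) ^ [0, t]|
  acc <- 0
  for (j in seq_along(h)) {
    width <- bnd[j + 1] - bnd[j]
    piece <- mult * h[j] * width
    if (is.finite(piece) && acc + piece < target) {
      acc <- acc + piece
    } else {
      if (mult * h[j] <= 0) return(Inf)
      return(bnd[j] + (target - acc) / (mult * h[j]))
    }
  }
  Inf
}

invert_hazard_current <- function(target, A, C, alpha, h, bnd, horizon) {
  # Lambda(t) = sum_j h_j exp(alpha*(A + C*lo_j)) * (exp(x*s) - 1)/x,
  # x = alpha*C, s = time spent in piece j
  x <- alpha * C
  acc <- 0
  for (j in seq_along(h)) {
    lo <- bnd[j]
    hi <- min(bnd[j + 1], horizon)
    if (hi <= lo) break
    len <- hi - lo
    base <- h[j] * exp(alpha * (A + C * lo))
    piece <- if (abs(x * len) < 1e-10) base * len * (1 + 0.5 * x * len) else
      base * expm1(x * len) / x
    if (is.finite(piece) && acc + piece < target) {
      acc <- acc + piece
    } else {
      rem <- target - acc
      if (base <= 0) return(Inf)
      if (abs(x) < 1e-12) return(lo + rem / base)
      arg <- 1 + rem * x / base
      if (arg <= 0) return(Inf)       # hazard decays; target never reached
      return(lo + log(arg) / x)
    }
  }
  Inf
}

#' Simulate a two-arm trial
#'
#' Draws covariates, random effects, scheduled FVC measurements and event
#' times, and emits the three raw tables consumed by [build_joint_dataset()]
#' plus the simulation truth.  Byte-identical output for identical
#' `(config, seed)`.  Draw order (one seed stream): ATA status, sex,
#' baseline FVC, random effects, visit residuals, event uniforms, event-type
#' uniforms, then dropout (so enabling dropout does not perturb the earlier
#' draws).
#'
#' @param config a [sim_config()] object.
#' @param seed integer seed.
#' @return A list with `trial` (an `fvc_trial`) and `truth` (class
#'   `sim_truth`: true parameters, per-subject latent random effects,
#'   uniforms and pre-censoring latent event times).
#' @export
simulate_trial <- function(config, seed = 1) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_subjects
  set.seed(seed)
  ids <- sprintf("S%04d", seq_len(n))
  arm <- if (config$allocation == 0.5) rep_len(c(0L, 1L), n) else
    stats::rbinom(n, 1, config$allocation)
  ata <- stats::rbinom(n, 1, config$ata_prevalence)
  female <- stats::rbinom(n, 1, config$female_fraction)
  # baseline FVC truncated at the eligibility threshold (>= 40 % predicted),
  # drawn by inverse CDF so one uniform per subject is consumed
  p_lo <- stats::pnorm(40, config$baseline_fvc_mean, config$baseline_fvc_sd)
  fvc0 <- stats::qnorm(p_lo + stats::runif(n) * (1 - p_lo),
                       config$baseline_fvc_mean, config$baseline_fvc_sd)
  z <- matrix(stats::rnorm(2 * n), n, 2)
  b <- if (all(config$D == 0)) 0 * z else z %*% chol(config$D)

  weeks <- config$schedule_weeks
  post <- weeks[weeks > 0]
  eps <- matrix(stats::rnorm(n * length(post), 0, config$sigma), n,
                length(post))
  u <- stats::runif(n)
  u_death <- stats::runif(n)
  u_ssc <- stats::runif(n)
  u_er <- stats::runif(n)
  u_icu <- stats::runif(n)
  u_vent <- stats::runif(n)
  drop_years <- if (config$dropout_rate > 0) {
    stats::rexp(n, config$dropout_rate)
  } else rep(Inf, n)

  beta <- config$beta
  slope <- beta["slope_control"] + beta["slope_trt_diff"] * arm + b[, 2]
  level0 <- beta["intercept"] + beta["ata"] * ata +
    beta["baseline_fvc"] * (fvc0 - config$baseline_fvc_mean) + b[, 1]

  hz <- config$hazard
  bnd <- piece_bounds(hz$knots)
  latent <- numeric(n)
  for (i in seq_len(n)) {
    h <- exp(hz$log_h0[ata[i] + 1L, ])
    target <- -log(u[i])
    latent[i] <- if (config$association == "slope") {
      invert_hazard_slope(target, exp(config$alpha * slope[i]), h, bnd)
    } else {
      invert_hazard_current(target, level0[i], slope[i], config$alpha, h,
                            bnd, horizon = 10)
    }
  }

  admin_days <- config$admin_days
  followup <- pmin(admin_days, drop_years * DAYS_PER_YEAR)
  latent_days <- latent * DAYS_PER_YEAR
  observed <- latent_days <= followup
  is_death <- observed & (u_death < config$p_death)

  subjects <- data.frame(
    subject_id = ids, arm = arm, ata_positive = ata,
    baseline_fvc_pct = round(fvc0, 4),
    followup_end_days = followup,
    death_day = ifelse(is_death, latent_days, NA_real_),
    stringsAsFactors = FALSE)

  hosp <- observed & !is_death
  ev <- data.frame(subject_id = character(0), event_day = numeric(0),
                   category = character(0), stringsAsFactors = FALSE)
  if (any(hosp)) {
    idx <- which(hosp)
    add <- function(sel, cat) {
      sel <- which(sel)
      data.frame(subject_id = ids[idx[sel]],
                 event_day = latent_days[idx[sel]],
                 category = rep(cat, length(sel)), stringsAsFactors = FALSE)
    }
    ev <- rbind(add(rep(TRUE, length(idx)), "all_cause"),
                add(u_ssc[idx] < config$p_ssc, "ssc_related"),
                add(u_er[idx] < config$p_er_icu, "er_or_icu"),
                add(u_icu[idx] < config$p_icu, "icu"),
                add(u_vent[idx] < config$p_vent, "ventilation"))
  }

  treat_end_days <- admin_days - POST_TREATMENT_WINDOW_DAYS
  visit_list <- vector("list", length(weeks))
  for (k in seq_along(weeks)) {
    w <- weeks[k]
    t_years <- weeks_to_years(w)
    # physical floor at 1 % predicted; essentially never active under the
    # default configuration
    value <- if (w == 0) fvc0 else {
      pmax(level0 + slope * t_years + eps[, match(w, post)], 1)
    }
    on_trt <- as.integer(w * WEEK_DAYS <= pmin(treat_end_days, followup))
    visit_list[[k]] <- data.frame(subject_id = ids, visit_week = w,
                                  fvc_pct = round(value, 4),
                                  on_treatment = on_trt,
                                  stringsAsFactors = FALSE)
  }
  visits <- do.call(rbind, visit_list)
  visits <- visits[order(visits$subject_id, visits$visit_week), ]
  rownames(visits) <- NULL

  truth <- structure(list(
    config = config, seed = seed,
    params = list(beta = beta, D = config$D, sigma2 = config$sigma^2,
                  hazard = hz, alpha = config$alpha,
                  center = config$baseline_fvc_mean),
    b = b, u = u, latent_event_years = latent,
    baseline_fvc_pct = fvc0, female = female),
    class = "sim_truth")

  list(trial = fvc_trial(subjects, visits, ev), truth = truth)
}

#' Simulate trials from a fitted joint model
#'
#' Uses the fitted parameters as simulation truth; covariate distributions
#' keep their [sim_config()] defaults.
#'
#' @param object an `fvcjm` object.
#' @param nsim number of trials.
#' @param seed integer; trial r uses `seed + r - 1`.
#' @param n_subjects subjects per simulated trial (default: as fitted).
#' @param ... unused.
#' @return A list of `simulate_trial()` results.
#' @export
simulate.fvcjm <- function(object, nsim = 1, seed = 1,
                           n_subjects = object$n, ...) {
  cfg <- sim_config(
    n_subjects = n_subjects,
    beta = object$lmm$beta,
    D = object$lmm$D,
    sigma = sqrt(object$lmm$sigma2),
    knots = object$hazard$knots,
    log_h0 = object$hazard$log_h0,
    alpha = object$alpha,
    association = object$spec$association,
    period = object$period,
    baseline_fvc_mean = object$lmm$center)
  lapply(seq_len(nsim), function(r) simulate_trial(cfg, seed + r - 1))
}
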