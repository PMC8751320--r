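## Longitudinal sub-model: y_i(t) = beta0 + beta_ata*ATA_i
##   + beta_base*(FVC0_i - c) + (beta_t + beta_tx*arm_i)*t + b0_i + b1_i*t + eps
## with (b0, b1) ~ N(0, D) unstructured and eps ~ N(0, sigma2).
## ML fitting integrates the random effects analytically (marginal Gaussian
## likelihood, evaluated subject-wise from sufficient statistics).

LMM_BETA_NAMES <- c("intercept", "ata", "baseline_fvc", "slope_control",
                    "slope_trt_diff")

#' Longitudinal sub-model parameters
#'
#' @param beta fixed effects: intercept, ATA effect, centered-baseline-FVC
#'   effect, control-arm slope (% predicted/year), treatment slope
#'   difference (% predicted/year).
#' @param D 2x2 positive-semidefinite covariance of the random intercept and
#'   random slope.
#' @param sigma2 residual variance (squared % predicted).
#' @param center centering constant for baseline FVC (% predicted).
#' @return An object of class `lmm_params`.
#' @export
lmm_params <- function(beta, D, sigma2, center = 0) {
  beta <- as.numeric(beta)
  stopifnot(length(beta) == 5L, is.matrix(D), all(dim(D) == 2L),
            isTRUE(all.equal(D, t(D))), sigma2 > 0)
  ev <- eigen(D, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(abs(ev), 1)) stop("D must be PSD")
  names(beta) <- LMM_BETA_NAMES
  structure(list(beta = beta, D = D, sigma2 = sigma2, center = center),
            class = "lmm_params")
}

#' Fixed- and random-effect design rows at one time point
#'
#' @param ata ATA status (0/1).
#' @param baseline_fvc_pct baseline FVC % predicted.
#' @param arm treatment indicator (0/1).
#' @param t_years time since randomisation in years.
#' @param center centering constant subtracted from baseline FVC.
#' @return A list with `fixed` (length 5) and `random` (length 2) rows.
#' @export
design_row <- function(ata, baseline_fvc_pct, arm, t_years, center = 0) {
  stopifnot(t_years >= 0)
  list(fixed = c(1, ata, baseline_fvc_pct - center, t_years, arm * t_years),
       random = c(1, t_years))
}

#' Subject-specific annual FVC slope
#'
#' The trajectory is linear, so the estimated slope -- the annual rate of
#' change in FVC % predicted -- is constant in time:
#' `slope_control + slope_trt_diff * arm + b1`.
#'
#' @param params an `lmm_params` object (or a fitted model's `$params`).
#' @param arm treatment indicator (0/1).
#' @param b1 subject-specific random slope (default 0: the arm mean).
#' @return Slope in % predicted per year.
#' @export
subject_slope <- function(params, arm, b1 = 0) {
  unname(params$beta["slope_control"] + params$beta["slope_trt_diff"] * arm +
           b1)
}

#' Error-free trajectory value at time t
#'
#' @inheritParams subject_slope
#' @param ata,baseline_fvc_pct subject covariates.
#' @param b0 subject-specific random intercept.
#' @param t_years time in years.
#' @return FVC % predicted on the model scale (fixed + random parts, no
#'   residual).
#' @export
current_value <- function(params, ata, baseline_fvc_pct, arm,
                          b0 = 0, b1 = 0, t_years = 0) {
  b <- params$beta
  unname(b["intercept"] + b["ata"] * ata +
           b["baseline_fvc"] * (baseline_fvc_pct - params$center) + b0 +
           subject_slope(params, arm, b1) * t_years)
}

## ---- sufficient statistics ----------------------------------------------

# Per-subject summaries of the longitudinal data, in the row order of
# data$subjects.  Everything the marginal and joint likelihoods need.
jm_suffstats <- function(data, center = NULL) {
  stopifnot(inherits(data, "jm_data"))
  s <- data$subjects
  if (is.null(center)) center <- mean(s$baseline_fvc_pct)
  ids <- s$subject_id
  f <- factor(data$long$subject_id, levels = ids)
  t <- data$long$time_years
  y <- data$long$fvc_pct
  agg <- function(v) {
    out <- rep(0, length(ids))
    if (length(v)) {
      a <- rowsum(v, f)
      out[match(rownames(a), ids)] <- a[, 1]
    }
    out
  }
  list(ids = ids,
       n = length(ids),
       arm = s$arm,
       ata = s$ata_positive,
       fvc0c = s$baseline_fvc_pct - center,
       center = center,
       Tobs = s$event_time_years,
       delta = s$event,
       ni = agg(rep(1, length(t))),
       St = agg(t), Stt = agg(t * t),
       Sy = agg(y), Sty = agg(t * y), Syy = agg(y * y))
}

# theta = (beta[5], log L11, L21, log L22, log sigma); D = L L'
lmm_theta_unpack <- function(theta) {
  beta <- theta[1:5]
  L11 <- exp(theta[6]); L21 <- theta[7]; L22 <- exp(theta[8])
  sigma <- exp(theta[9])
  list(beta = beta,
       D = matrix(c(L11^2, L11 * L21, L11 * L21, L21^2 + L22^2), 2, 2),
       L = matrix(c(L11, L21, 0, L22), 2, 2),
       sigma2 = sigma^2)
}

lmm_theta_pack <- function(beta, D, sigma2) {
  L <- t(chol(D + diag(1e-10, 2)))
  c(beta, log(L[1, 1]), L[2, 1], log(L[2, 2]), 0.5 * log(sigma2))
}

# Marginal log-likelihood of the LMM, vectorised over subjects.
# Uses: log|V_i| = ni*log(sigma2) + log det(D) + log det(P_i) and
# r'V^-1 r = (Srr - (Z'r)' P^-1 (Z'r)/sigma2)/sigma2, with
# P = D^-1 + Z'Z/sigma2 (Woodbury on V = sigma2*I + Z D Z').
lmm_marginal_loglik <- function(theta, ss) {
  p <- lmm_theta_unpack(theta)
  sigma2 <- p$sigma2
  D <- p$D
  detD <- D[1, 1] * D[2, 2] - D[1, 2]^2
  if (!is.finite(detD) || detD <= 0) return(-1e12)
  Di11 <- D[2, 2] / detD; Di12 <- -D[1, 2] / detD; Di22 <- D[1, 1] / detD

  a <- p$beta[1] + p$beta[2] * ss$ata + p$beta[3] * ss$fvc0c
  cc <- p$beta[4] + p$beta[5] * ss$arm
  Sr <- ss$Sy - ss$ni * a - cc * ss$St
  Srt <- ss$Sty - a * ss$St - cc * ss$Stt
  Srr <- ss$Syy - 2 * a * ss$Sy - 2 * cc * ss$Sty + ss$ni * a^2 +
    2 * a * cc * ss$St + cc^2 * ss$Stt

  P11 <- Di11 + ss$ni / sigma2
  P12 <- Di12 + ss$St / sigma2
  P22 <- Di22 + ss$Stt / sigma2
  detP <- P11 * P22 - P12^2
  if (any(!is.finite(detP)) || any(detP <= 0)) return(-1e12)
  # q = (Z'r)' P^-1 (Z'r)
  q <- (P22 * Sr^2 - 2 * P12 * Sr * Srt + P11 * Srt^2) / detP
  logdetV <- ss$ni * log(sigma2) + log(detD) + log(detP)
  quad <- (Srr - q / sigma2) / sigma2
  ll <- -0.5 * (ss$ni * log(2 * pi) + logdetV + quad)
  sum(ll)
}

lmm_check_identifiable <- function(data, ss) {
  long <- data$long
  idx <- match(long$subject_id, ss$ids)
  X <- cbind(intercept = 1, ata = ss$ata[idx], baseline_fvc = ss$fvc0c[idx],
             slope_control = long$time_years,
             slope_trt_diff = ss$arm[idx] * long$time_years)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    drop <- setdiff(colnames(X), colnames(X)[qrX$pivot[seq_len(qrX$rank)]])
    stop("singular longitudinal design; collinear column(s): ",
         paste(drop, collapse = ", "))
  }
  invisible(TRUE)
}

#' Fit the longitudinal mixed-effects sub-model by maximum likelihood
#'
#' Maximises the marginal Gaussian likelihood (random effects integrated
#' analytically) over the fixed effects, the log-Cholesky factor of the
#' random-effects covariance and the log residual standard deviation, by
#' quasi-Newton optimisation.  Baseline FVC is centered at the sample mean,
#' stored in the fit.
#'
#' @param data a `jm_data` object from [build_joint_dataset()].
#' @param se compute standard errors from a numerical Hessian (default TRUE).
#' @param control passed to [stats::optim()] (`reltol` defaults to 1e-10).
#' @return An object of class `fvc_lmm` with elements `params`
#'   (an [lmm_params] object), `theta` (transformed-scale estimate),
#'   `loglik`, `vcov` (transformed scale, if `se`), `se_beta`, `n`, `n_obs`,
#'   `convergence`.
#' @export
fit_lmm <- function(data, se = TRUE, control = list()) {
  ss <- jm_suffstats(data)
  if (sum(ss$ni > 0) < 2L) stop("need at least 2 subjects with measurements")
  lmm_check_identifiable(data, ss)

  # start values: pooled OLS for beta, residual spread split between levels
  long <- data$long
  idx <- match(long$subject_id, ss$ids)
  X <- cbind(1, ss$ata[idx], ss$fvc0c[idx], long$time_years,
             ss$arm[idx] * long$time_years)
  ols <- stats::lm.fit(X, long$fvc_pct)
  s0 <- max(stats::sd(ols$residuals), 1e-3)
  # theta order: beta[5], log L11, L21, log L22, log sigma
  theta0 <- c(ols$coefficients, log(s0), 0, log(max(s0 / 2, 1e-3)),
              log(max(s0 / 2, 1e-3)))
  ctrl <- utils::modifyList(list(rel.tol = 1e-10, iter.max = 500,
                                 eval.max = 2000), control)
  # box constraints on the transformed scale keep the quasi-Newton search
  # away from overflow regions (sigma, D factors between e^-15 and e^15)
  lower <- c(rep(-1e6, 5), -15, -1e4, -15, -15)
  upper <- c(rep(1e6, 5), 15, 1e4, 15, 15)
  opt <- stats::nlminb(theta0, function(th) -lmm_marginal_loglik(th, ss),
                       lower = lower, upper = upper, control = ctrl)
  opt$value <- opt$objective
  p <- lmm_theta_unpack(opt$par)
  vc <- NULL
  se_beta <- rep(NA_real_, 5)
  if (se) {
    H <- stats::optimHess(opt$par, function(th) -lmm_marginal_loglik(th, ss))
    vc <- tryCatch(solve(H), error = function(e) NULL)
    if (!is.null(vc)) se_beta <- sqrt(pmax(diag(vc)[1:5], 0))
  }
  names(se_beta) <- LMM_BETA_NAMES
  structure(list(params = lmm_params(p$beta, p$D, p$sigma2, ss$center),
                 theta = opt$par, loglik = -opt$value, vcov = vc,
                 se_beta = se_beta, n = ss$n, n_obs = sum(ss$ni),
                 convergence = opt$convergence),
            class = "fvc_lmm")
}

#' @export
print.fvc_lmm <- function(x, digits = 4, ...) {
  cat("Linear mixed-effects model of FVC % predicted (ML)\n")
  cat(sprintf("  %d subjects, %d measurements; log-likelihood %.3f\n",
              x$n, x$n_obs, x$loglik))
  est <- rbind(estimate = x$params$beta, se = x$se_beta)
  print(round(est, digits))
  cat(sprintf("  random effects: sd(intercept) %.3f, sd(slope) %.3f, corr %.3f; residual sd %.3f\n",
              sqrt(x$params$D[1, 1]), sqrt(x$params$D[2, 2]),
              stats::cov2cor(x$params$D)[1, 2], sqrt(x$params$sigma2)))
  cat(sprintf("  baseline FVC centered at %.2f\n", x$params$center))
  invisible(x)
}

#' @export
coef.fvc_lmm <- function(object, ...) object$params$beta

#' @export
logLik.fvc_lmm <- function(object, ...) {
  structure(object$loglik, df = 9L, class = "logLik")
}
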