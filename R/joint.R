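## Shared-parameter joint model.  Per subject i with random effects
## b = (b0, b1) ~ N(0, D):
##   longitudinal:  y_ij | b ~ N(a_i + c_i t_ij + b0 + b1 t_ij, sigma2)
##   survival:      h_i(t) = h0_{s_i}(t) exp(alpha * f_i(t, b))
## where f is the subject's annual FVC slope (c_i + b1; primary) or the
## error-free current value m_i(t) (secondary), and h0 is piecewise constant
## and stratified by ATA status.  The marginal likelihood integrates b out
## with 2-D Gauss-Hermite quadrature, centred and scaled per subject at the
## closed-form Gaussian posterior of b given the longitudinal data
## (adaptive quadrature; exact whenever the integrand is Gaussian, e.g. at
## alpha = 0).

#' Joint-model specification
#'
#' @param association association structure: `"slope"` (hazard depends on the
#'   subject's annual rate of FVC decline; primary) or `"current_value"`
#'   (hazard depends on the error-free FVC value at time t).
#' @param n_internal_knots internal knots of the baseline hazard (default 5).
#' @param nodes Gauss-Hermite quadrature nodes per random-effect dimension
#'   (default 9; must be at least 3).
#' @param min_events minimum number of observed events required to attempt a
#'   fit (default 20); endpoints with fewer events are refused as unfittable.
#' @param reltol,maxit optimiser control.
#' @return An object of class `jm_spec`.
#' @export
jm_spec <- function(association = c("slope", "current_value"),
                    n_internal_knots = 5, nodes = 9, min_events = 20,
                    reltol = 1e-8, maxit = 400) {
  association <- match.arg(association)
  stopifnot(nodes >= 3, n_internal_knots >= 0, min_events >= 0)
  structure(list(association = association,
                 n_internal_knots = n_internal_knots,
                 nodes = as.integer(nodes), min_events = min_events,
                 reltol = reltol, maxit = maxit),
            class = "jm_spec")
}

gh_grid <- function(nodes) {
  gh <- pracma::gaussHermite(nodes)
  u1 <- rep(gh$x, times = nodes)
  u2 <- rep(gh$x, each = nodes)
  lw <- rep(log(gh$w), times = nodes) + rep(log(gh$w), each = nodes) +
    u1^2 + u2^2
  list(u1 = u1, u2 = u2, lw = lw, K = nodes * nodes)
}

# Precomputed quantities shared by likelihood evaluations.
joint_env <- function(data, knots, nodes, center = NULL) {
  ss <- jm_suffstats(data, center)
  Tobs <- ss$Tobs
  list(ss = ss, long = data$long, knots = knots, J = length(knots) + 1L,
       E = piece_exposure(knots, Tobs),
       jT = piece_index(knots, Tobs),
       strat = ss$ata + 1L,                      # 1 = ata_neg, 2 = ata_pos
       gh = gh_grid(nodes))
}

joint_par_names <- function(J) {
  c(LMM_BETA_NAMES, "log_chol_D11", "chol_D21", "log_chol_D22", "log_sigma",
    paste0("log_h0_ata_neg_", seq_len(J)),
    paste0("log_h0_ata_pos_", seq_len(J)),
    "alpha")
}

joint_theta_pack <- function(lmm, hazard, alpha) {
  lh <- hazard$log_h0
  c(lmm_theta_pack(lmm$beta, lmm$D, lmm$sigma2), lh[1, ], lh[2, ], alpha)
}

joint_theta_unpack <- function(theta, J) {
  p <- lmm_theta_unpack(theta[1:9])
  lh <- rbind(theta[9 + seq_len(J)], theta[9 + J + seq_len(J)])
  rownames(lh) <- PE_STRATA
  list(lmm = p, log_h0 = lh, alpha = unname(theta[10 + 2 * J]))
}

# Core evaluator: marginal joint log-likelihood, and for the slope
# association also its gradient (quadrature nodes treated as fixed at the
# current parameter point; the neglected node-movement term is of the order
# of the quadrature error).
joint_eval <- function(theta, env, association, want_grad = FALSE) {
  ss <- env$ss
  n <- ss$n
  J <- env$J
  up <- joint_theta_unpack(theta, J)
  beta <- up$lmm$beta
  D <- up$lmm$D
  L <- up$lmm$L
  sigma2 <- up$lmm$sigma2
  h0 <- exp(up$log_h0)
  alpha <- up$alpha

  detD <- D[1, 1] * D[2, 2] - D[1, 2]^2
  if (!is.finite(detD) || detD <= 0) return(list(loglik = -1e12))
  Di11 <- D[2, 2] / detD; Di12 <- -D[1, 2] / detD; Di22 <- D[1, 1] / detD

  a <- beta[1] + beta[2] * ss$ata + beta[3] * ss$fvc0c
  cc <- beta[4] + beta[5] * ss$arm
  Sr <- ss$Sy - ss$ni * a - cc * ss$St
  Srt <- ss$Sty - a * ss$St - cc * ss$Stt
  Srr <- ss$Syy - 2 * a * ss$Sy - 2 * cc * ss$Sty + ss$ni * a^2 +
    2 * a * cc * ss$St + cc^2 * ss$Stt

  # closed-form Gaussian posterior of b given the longitudinal data only
  P11 <- Di11 + ss$ni / sigma2
  P12 <- Di12 + ss$St / sigma2
  P22 <- Di22 + ss$Stt / sigma2
  detP <- P11 * P22 - P12^2
  if (any(!is.finite(detP)) || any(detP <= 0)) return(list(loglik = -1e12))
  S11 <- P22 / detP; S12 <- -P12 / detP; S22 <- P11 / detP
  mu1 <- (S11 * Sr + S12 * Srt) / sigma2
  mu2 <- (S12 * Sr + S22 * Srt) / sigma2
  B11 <- sqrt(S11)
  B21 <- S12 / B11
  B22 <- sqrt(pmax(S22 - B21^2, 1e-300))

  gh <- env$gh
  K <- gh$K
  sq2 <- sqrt(2)
  b0 <- mu1 + sq2 * outer(B11, gh$u1)
  b1 <- mu2 + sq2 * (outer(B21, gh$u1) + outer(B22, gh$u2))

  # conditional longitudinal log-density (n x K)
  SSE <- Srr - 2 * b0 * Sr - 2 * b1 * Srt + b0^2 * ss$ni +
    2 * b0 * b1 * ss$St + b1^2 * ss$Stt
  Lc <- -0.5 * (ss$ni * log(2 * pi * sigma2)) - 0.5 * SSE / sigma2
  # random-effects prior
  Lp <- -log(2 * pi) - 0.5 * log(detD) -
    0.5 * (Di11 * b0^2 + 2 * Di12 * b0 * b1 + Di22 * b1^2)

  # survival factor
  hsel <- t(h0)[, env$strat]                     # J x n heights per subject
  Lam0T <- colSums(t(env$E) * hsel)              # baseline cum. hazard at T
  dloghT <- ifelse(ss$delta == 1,
                   up$log_h0[cbind(env$strat, env$jT)], 0)
  if (association == "slope") {
    sl <- cc + b1                                # n x K
    eta <- alpha * sl
    Lam <- exp(eta) * Lam0T
    Ls <- ss$delta * (dloghT + eta) - Lam
  } else {
    A <- a + b0
    Cm <- cc + b1
    x <- alpha * Cm
    bnd <- piece_bounds(env$knots)
    Lam <- 0
    for (j in seq_len(J)) {
      len <- env$E[, j]
      active <- len > 0
      if (!any(active)) next
      lo <- pmin(ss$Tobs, bnd[j])
      xl <- x * len
      Q <- ifelse(abs(xl) < 1e-10, len * (1 + 0.5 * xl),
                  expm1(xl) / ifelse(x == 0, 1, x))
      Lam <- Lam + (hsel[j, ] * active) * exp(alpha * (A + Cm * lo)) * Q
    }
    mT <- A + Cm * ss$Tobs
    Ls <- ss$delta * (dloghT + alpha * mT) - Lam
  }

  M <- Lc + Lp + Ls + matrix(gh$lw, n, K, byrow = TRUE)
  mc <- max.col(M, ties.method = "first")
  m <- M[cbind(seq_len(n), mc)]
  Pm <- exp(M - m)
  S <- rowSums(Pm)
  log2B <- log(2) - 0.5 * log(detP)
  li <- log2B + m + log(S)
  ll <- sum(li)
  if (!is.finite(ll)) return(list(loglik = -1e12))
  if (!want_grad) return(list(loglik = ll, li = li))

  if (association != "slope") {
    stop("analytic gradient implemented for the slope association only")
  }
  W <- Pm / S                                    # posterior node weights
  wsum <- function(G) rowSums(W * G)             # posterior mean per subject

  Se <- Sr - ss$ni * b0 - b1 * ss$St             # sum of residuals e_ij
  Set <- Srt - b0 * ss$St - b1 * ss$Stt          # sum of t_ij e_ij
  dLam <- ss$delta - Lam

  g_e <- wsum(Se) / sigma2
  g_et <- wsum(Set) / sigma2
  g_dl <- wsum(dLam)
  g_b0 <- c(sum(g_e), sum(ss$ata * g_e), sum(ss$fvc0c * g_e))
  g_bt <- sum(g_et) + alpha * sum(g_dl)
  g_btx <- sum(ss$arm * g_et) + alpha * sum(ss$arm * g_dl)

  g_lsig <- sum(-ss$ni + wsum(SSE) / sigma2)

  w1 <- Di11 * b0 + Di12 * b1                    # D^-1 b
  w2 <- Di12 * b0 + Di22 * b1
  g_l11 <- sum(wsum(w1 * b0) - 1)
  g_l21 <- sum(wsum(w2 * b0)) / L[1, 1]
  g_l22 <- sum(wsum(w2 * (b1 - L[2, 1] * b0 / L[1, 1])) - 1)

  eeta <- wsum(exp(eta))                         # posterior mean of e^eta
  g_lh <- matrix(0, 2, J)
  for (k in 1:2) {
    sel <- env$strat == k
    for (j in seq_len(J)) {
      g_lh[k, j] <- sum(ss$delta[sel] * (env$jT[sel] == j)) -
        h0[k, j] * sum(env$E[sel, j] * eeta[sel])
    }
  }
  g_alpha <- sum(ss$delta * wsum(sl) - wsum(sl * Lam))

  grad <- c(g_b0, g_bt, g_btx, g_l11, g_l21, g_l22, g_lsig,
            g_lh[1, ], g_lh[2, ], g_alpha)
  list(loglik = ll, li = li, grad = grad)
}

#' Joint log-likelihood at given parameter values
#'
#' Evaluates the marginal joint log-likelihood (random effects integrated by
#' adaptive Gauss-Hermite quadrature) at user-supplied sub-model parameters.
#' Mostly useful for testing and diagnostics; fitting is done by [fvcjm()].
#'
#' @param lmm an [lmm_params] object (its `center` is used to centre
#'   baseline FVC).
#' @param hazard a [piecewise_hazard] object.
#' @param alpha association coefficient (log-hazard per % predicted/year for
#'   the slope association; per % predicted for the current value).
#' @param data a `jm_data` object.
#' @param association `"slope"` or `"current_value"`.
#' @param nodes quadrature nodes per dimension.
#' @return The log-likelihood (scalar).
#' @export
joint_loglik <- function(lmm, hazard, alpha, data,
                         association = c("slope", "current_value"),
                         nodes = 9) {
  association <- match.arg(association)
  env <- joint_env(data, hazard$knots, nodes, center = lmm$center)
  theta <- joint_theta_pack(lmm, hazard, alpha)
  res <- joint_eval(theta, env, association)
  res$loglik
}

#' Per-subject survival terms of the joint likelihood
#'
#' For given random effects `b`, returns the log hazard at the subject's
#' event/censoring time and the negative cumulative hazard.  For the slope
#' association the cumulative hazard is `exp(alpha * slope) * Lambda0(T)`;
#' for the current-value association it is the closed-form piecewise
#' integral of `h0(t) exp(alpha * m(t))`.
#'
#' @inheritParams joint_loglik
#' @param ata,baseline_fvc_pct,arm subject covariates.
#' @param T_years event or censoring time (years).
#' @param b numeric length-2 vector of random effects (b0, b1).
#' @return Named vector `c(log_hazard, neg_cum_hazard)`.
#' @export
subject_survival_terms <- function(lmm, hazard, alpha, ata, baseline_fvc_pct,
                                   arm, T_years, b = c(0, 0),
                                   association = c("slope",
                                                   "current_value")) {
  association <- match.arg(association)
  stratum <- PE_STRATA[ata + 1L]
  h <- exp(hazard$log_h0[stratum, ])
  jT <- piece_index(hazard$knots, T_years)
  sl <- subject_slope(lmm, arm, b[2])
  if (association == "slope") {
    eta <- alpha * sl
    logh <- log(h[jT]) + eta
    Lam <- exp(eta) * cum_base_hazard(hazard, stratum, T_years)
  } else {
    A <- current_value(lmm, ata, baseline_fvc_pct, arm, b[1], b[2], 0)
    x <- alpha * sl
    bnd <- piece_bounds(hazard$knots)
    Lam <- 0
    for (j in seq_along(h)) {
      lo <- min(T_years, bnd[j]); hi <- min(T_years, bnd[j + 1])
      if (hi <= lo) next
      len <- hi - lo
      Q <- if (abs(x * len) < 1e-10) len * (1 + 0.5 * x * len) else
        expm1(x * len) / x
      Lam <- Lam + h[j] * exp(alpha * (A + sl * lo)) * Q
    }
    logh <- log(h[jT]) + alpha * (A + sl * T_years)
  }
  c(log_hazard = unname(logh), neg_cum_hazard = -unname(Lam))
}

#' Fit the shared-parameter joint model
#'
#' Two-stage initialisation (standalone mixed-model fit, closed-form
#' piecewise-exponential fit, association coefficient 0) followed by
#' quasi-Newton maximisation of the joint log-likelihood; the slope
#' association uses an analytic gradient.  Standard errors come from a
#' finite-difference Hessian at the optimum.  The fit is deterministic given
#' the data and specification.
#'
#' @param data a `jm_data` object from [build_joint_dataset()].
#' @param association `"slope"` (primary) or `"current_value"`.
#' @param spec a [jm_spec()] object; `association` overrides its field when
#'   given explicitly.
#' @param se compute the Hessian-based covariance of all free parameters.
#' @return An object of class `fvcjm` with components `lmm`
#'   ([lmm_params]), `hazard` ([piecewise_hazard]), `alpha`, `loglik`,
#'   `theta`/`vcov` (transformed scale), `se_alpha`, `se_beta`,
#'   `convergence` diagnostics, `n`, `n_events`, plus the dataset labels.
#' @export
fvcjm <- function(data, association = NULL, spec = jm_spec(), se = TRUE) {
  stopifnot(inherits(data, "jm_data"), inherits(spec, "jm_spec"))
  if (!is.null(association)) {
    spec$association <- match.arg(association, c("slope", "current_value"))
  }
  if (data$n_events < spec$min_events) {
    stop(errorCondition(
      sprintf("unfittable endpoint '%s' (%s): %d events observed, minimum %d -- low numbers of events preclude a stable fit",
              data$endpoint, data$period, data$n_events, spec$min_events),
      class = c("fvcjoint_unfittable_error", "error")))
  }

  lmm0 <- fit_lmm(data, se = FALSE)
  s <- data$subjects
  knots <- choose_knots(s$event_time_years[s$event == 1],
                        spec$n_internal_knots)
  pe0 <- fit_pe(data, knots)
  # smoothed heights so that empty cells start finite
  h_init <- (pe0$events + 0.5) / pmax(pe0$exposure, 1e-8)
  hazard0 <- piecewise_hazard(knots, log(h_init))

  env <- joint_env(data, knots, spec$nodes)
  theta0 <- joint_theta_pack(lmm0$params, hazard0, 0)
  J <- env$J
  nm <- joint_par_names(J)

  negll <- function(th) -joint_eval(th, env, spec$association)$loglik
  gr <- NULL
  if (spec$association == "slope") {
    gr <- function(th) {
      r <- joint_eval(th, env, spec$association, want_grad = TRUE)
      if (!is.finite(r$loglik)) return(rep(0, length(th)))
      -r$grad
    }
  }
  opt <- stats::optim(theta0, negll, gr, method = "BFGS",
                      control = list(reltol = spec$reltol,
                                     maxit = spec$maxit))
  theta <- opt$par
  names(theta) <- nm
  up <- joint_theta_unpack(theta, J)

  vc <- NULL
  se_all <- rep(NA_real_, length(theta))
  if (se) {
    H <- stats::optimHess(theta, negll, gr)
    vc <- tryCatch(solve(H), error = function(e) NULL)
    if (is.null(vc)) {
      # near-singular Hessian (e.g. empty hazard cells): pseudo-inverse
      eg <- eigen(H, symmetric = TRUE)
      pos <- eg$values > max(eg$values) * 1e-10
      vc <- eg$vectors[, pos, drop = FALSE] %*%
        (t(eg$vectors[, pos, drop = FALSE]) / eg$values[pos])
    }
    dimnames(vc) <- list(nm, nm)
    se_all <- sqrt(pmax(diag(vc), 0))
  }
  names(se_all) <- nm

  grad_norm <- if (spec$association == "slope") {
    sqrt(sum(joint_eval(theta, env, spec$association,
                        want_grad = TRUE)$grad^2))
  } else NA_real_
  if (opt$convergence != 0) {
    warning(sprintf("joint-model optimiser did not converge (code %d, gradient norm %.3g)",
                    opt$convergence, grad_norm))
  }

  structure(list(
    lmm = lmm_params(up$lmm$beta, up$lmm$D, up$lmm$sigma2, env$ss$center),
    hazard = piecewise_hazard(knots, up$log_h0),
    alpha = up$alpha,
    loglik = -opt$value,
    theta = theta, vcov = vc,
    se_alpha = unname(se_all["alpha"]),
    se_beta = se_all[1:5],
    spec = spec,
    endpoint = data$endpoint, period = data$period,
    n = data$n, n_events = data$n_events,
    convergence = list(code = opt$convergence, counts = opt$counts,
                       gradient_norm = grad_norm),
    env = env,
    init = list(lmm = lmm0$params, hazard = hazard0)),
    class = "fvcjm")
}

#' Empirical-Bayes random-effects estimate for one subject
#'
#' Posterior mode of `(b0, b1)` given the subject's longitudinal and
#' survival data at the fitted parameters, with the curvature (negative
#' Hessian of the log posterior) at the mode.  With no data the mode is the
#' prior mode (0, 0); with the association coefficient at 0 and no event
#' information it reduces to the usual mixed-model BLUP.
#'
#' @param fit an `fvcjm` object.
#' @param subject_id subject identifier.
#' @return A list with `mode` (length 2) and `curvature` (2x2 matrix).
#' @export
empirical_bayes <- function(fit, subject_id) {
  stopifnot(inherits(fit, "fvcjm"))
  env <- fit$env
  i <- match(subject_id, env$ss$ids)
  if (is.na(i)) stop("unknown subject_id: ", subject_id)
  ss <- env$ss
  D <- fit$lmm$D
  detD <- D[1, 1] * D[2, 2] - D[1, 2]^2
  Di <- matrix(c(D[2, 2], -D[1, 2], -D[1, 2], D[1, 1]), 2, 2) / detD
  sigma2 <- fit$lmm$sigma2
  a <- fit$lmm$beta[1] + fit$lmm$beta[2] * ss$ata[i] +
    fit$lmm$beta[3] * ss$fvc0c[i]
  cc <- fit$lmm$beta[4] + fit$lmm$beta[5] * ss$arm[i]
  Sr <- ss$Sy[i] - ss$ni[i] * a - cc * ss$St[i]
  Srt <- ss$Sty[i] - a * ss$St[i] - cc * ss$Stt[i]

  logpost <- function(b) {
    SSE <- -2 * b[1] * Sr - 2 * b[2] * Srt + ss$ni[i] * b[1]^2 +
      2 * b[1] * b[2] * ss$St[i] + b[2]^2 * ss$Stt[i]
    lp <- -0.5 * SSE / sigma2 - 0.5 * drop(t(b) %*% Di %*% b)
    st <- subject_survival_terms(fit$lmm, fit$hazard, fit$alpha,
                                 ss$ata[i], ss$fvc0c[i] + ss$center,
                                 ss$arm[i], ss$Tobs[i], b,
                                 association = fit$spec$association)
    lp + ss$delta[i] * st["log_hazard"] + st["neg_cum_hazard"]
  }
  opt <- stats::optim(c(0, 0), function(b) -logpost(b), method = "BFGS",
                      control = list(reltol = 1e-12, maxit = 200))
  H <- stats::optimHess(opt$par, function(b) -logpost(b))
  list(mode = opt$par, curvature = H)
}
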