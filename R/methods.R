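## Standard modelling methods for fvcjm fits.

#' @export
print.fvcjm <- function(x, digits = 4, ...) {
  cat("Shared-parameter joint model (", x$spec$association,
      " association)\n", sep = "")
  cat(sprintf("  endpoint: %s (%s); %d subjects, %d events\n",
              x$endpoint, x$period, x$n, x$n_events))
  cat(sprintf("  log-likelihood: %.3f\n", x$loglik))
  cat(sprintf("  association alpha: %.4f (SE %.4f); HR per 1-unit faster annual decline: %.3f\n",
              x$alpha, x$se_alpha, exp(-x$alpha)))
  cat(sprintf("  slope difference (active - control): %.3f %%/yr\n",
              unname(x$lmm$beta["slope_trt_diff"])))
  invisible(x)
}

#' @export
coef.fvcjm <- function(object, ...) {
  c(object$lmm$beta, alpha = object$alpha)
}

#' @export
vcov.fvcjm <- function(object, ...) object$vcov

#' @export
logLik.fvcjm <- function(object, ...) {
  structure(object$loglik, df = length(object$theta), class = "logLik")
}

#' @export
confint.fvcjm <- function(object, parm, level = 0.95, ...) {
  est <- coef(object)
  se <- c(object$se_beta, alpha = object$se_alpha)
  if (missing(parm)) parm <- names(est)
  z <- stats::qnorm(1 - (1 - level) / 2)
  out <- cbind(est[parm] - z * se[parm], est[parm] + z * se[parm])
  colnames(out) <- sprintf("%.1f %%", 100 * c((1 - level) / 2,
                                              1 - (1 - level) / 2))
  out
}

#' @export
summary.fvcjm <- function(object, level = 0.95, ...) {
  est <- coef(object)
  se <- c(object$se_beta, alpha = object$se_alpha)
  zstat <- est / se
  tab <- cbind(estimate = est, se = se, z = zstat,
               p = 2 * stats::pnorm(-abs(zstat)))
  out <- list(coefficients = tab,
              D = object$lmm$D, sigma2 = object$lmm$sigma2,
              hazard = object$hazard,
              hr = hazard_ratio_report(object, level = level),
              loglik = object$loglik, n = object$n,
              n_events = object$n_events,
              endpoint = object$endpoint, period = object$period,
              association = object$spec$association,
              convergence = object$convergence)
  class(out) <- "summary.fvcjm"
  out
}

#' @export
print.summary.fvcjm <- function(x, digits = 4, ...) {
  cat("Shared-parameter joint model (", x$association, " association)\n",
      sep = "")
  cat(sprintf("endpoint: %s (%s); %d subjects, %d events (%.1f%%); log-likelihood %.3f\n\n",
              x$endpoint, x$period, x$n, x$n_events,
              100 * x$n_events / x$n, x$loglik))
  cat("Coefficients (longitudinal fixed effects and association):\n")
  stats::printCoefmat(x$coefficients, digits = digits, P.values = TRUE,
                      has.Pvalue = TRUE)
  cat(sprintf("\nRandom effects: sd(intercept) %.3f, sd(slope) %.3f %%/yr, corr %.3f; residual sd %.3f\n",
              sqrt(x$D[1, 1]), sqrt(x$D[2, 2]),
              stats::cov2cor(x$D)[1, 2], sqrt(x$sigma2)))
  cat("\n")
  print(x$hr)
  invisible(x)
}

#' Predicted FVC trajectories
#'
#' Subject-level predictions use the empirical-Bayes random-effects mode;
#' population-level predictions set the random effects to zero.
#'
#' @param object an `fvcjm` object.
#' @param subject_id subjects to predict for (default: all).
#' @param t_years times at which to predict.
#' @param level `"subject"` (empirical Bayes) or `"population"`.
#' @param ... unused.
#' @return A data frame `subject_id`, `t_years`, `fvc_pred`.
#' @export
predict.fvcjm <- function(object, subject_id = NULL,
                          t_years = seq(0, 1, by = 0.25),
                          level = c("subject", "population"), ...) {
  level <- match.arg(level)
  ss <- object$env$ss
  if (is.null(subject_id)) subject_id <- ss$ids
  out <- lapply(subject_id, function(id) {
    i <- match(id, ss$ids)
    if (is.na(i)) stop("unknown subject_id: ", id)
    b <- if (level == "subject") empirical_bayes(object, id)$mode else c(0, 0)
    data.frame(subject_id = id, t_years = t_years,
               fvc_pred = current_value(object$lmm, ss$ata[i],
                                        ss$fvc0c[i] + ss$center,
                                        ss$arm[i], b[1], b[2], t_years),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' @export
fitted.fvcjm <- function(object, level = c("subject", "population"), ...) {
  level <- match.arg(level)
  long <- object$env$long
  ss <- object$env$ss
  eb <- if (level == "subject") {
    do.call(rbind, lapply(ss$ids, function(id) empirical_bayes(object,
                                                               id)$mode))
  } else matrix(0, ss$n, 2)
  i <- match(long$subject_id, ss$ids)
  current_value(object$lmm, ss$ata[i], ss$fvc0c[i] + ss$center, ss$arm[i],
                eb[i, 1], eb[i, 2], long$time_years)
}

#' @export
residuals.fvcjm <- function(object, level = c("subject", "population"),
                            ...) {
  level <- match.arg(level)
  object$env$long$fvc_pct - fitted(object, level = level)
}

#' Plot the hazard-ratio risk curve
#'
#' @param x an `fvcjm` object.
#' @param decline_grid grid of FVC declines (% predicted per year).
#' @param ... passed to [graphics::plot()].
#' @export
plot.fvcjm <- function(x, decline_grid = seq(0.1, 10, by = 0.1), ...) {
  rc <- risk_curve(x, decline_grid)
  graphics::plot(rc$decline, rc$hr, type = "n",
                 xlab = "Decline in FVC % predicted per year",
                 ylab = "Hazard ratio",
                 ylim = range(c(rc$ci_low, rc$ci_high, 1), finite = TRUE),
                 ...)
  if (all(is.finite(rc$ci_low))) {
    graphics::polygon(c(rc$decline, rev(rc$decline)),
                      c(rc$ci_low, rev(rc$ci_high)),
                      col = "grey85", border = NA)
  }
  graphics::lines(rc$decline, rc$hr, lwd = 2)
  graphics::abline(h = 1, lty = 3)
  invisible(rc)
}
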