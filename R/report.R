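## Hazard-ratio reporting.  Under the slope association the log hazard is
## linear in the subject's annual FVC slope, so the hazard ratio for a
## k-percentage-point FASTER annual decline is exp(-k * alpha): reported
## HRs above 1 mean decline is harmful.

#' Hazard ratios for k-unit declines in the annual FVC slope
#'
#' `HR(k) = exp(-k * alpha_hat)` with Wald confidence limits
#' `exp(-k * (alpha_hat +/- z * SE))` (ordered low < high) and the two-sided
#' Wald p-value for `alpha = 0`.  A "unit" is one percentage point of FVC %
#' predicted per year.
#'
#' @param fit an `fvcjm` object (slope association).
#' @param units vector of decline sizes (default 1, 3, 5).
#' @param level confidence level (default 0.95).
#' @param sig_threshold significance threshold for the flag (default 0.05).
#' @return A data frame of class `fvcjm_hr` with columns `unit`, `hr`,
#'   `ci_low`, `ci_high`, and attributes `alpha`, `se_alpha`, `p_value`,
#'   `significant`, `level`.
#' @export
hazard_ratio_report <- function(fit, units = c(1, 3, 5), level = 0.95,
                                sig_threshold = 0.05) {
  alpha <- fit$alpha
  se <- fit$se_alpha
  z <- stats::qnorm(1 - (1 - level) / 2)
  hr <- exp(-units * alpha)
  lo <- hi <- rep(NA_real_, length(units))
  p <- NA_real_
  if (is.finite(se) && se > 0) {
    a <- exp(-units * (alpha - z * se))
    b <- exp(-units * (alpha + z * se))
    lo <- pmin(a, b)
    hi <- pmax(a, b)
    p <- 2 * stats::pnorm(-abs(alpha) / se)
  } else if (alpha == 0) {
    p <- 1
  }
  out <- data.frame(unit = units, hr = hr, ci_low = lo, ci_high = hi)
  structure(out, class = c("fvcjm_hr", "data.frame"),
            alpha = alpha, se_alpha = se, p_value = p,
            significant = isTRUE(p <= sig_threshold), level = level)
}

#' @export
print.fvcjm_hr <- function(x, digits = 3, ...) {
  cat("Hazard ratios per k-unit decrease in annual FVC % predicted slope\n")
  df <- as.data.frame(x)
  df$hr <- round(df$hr, digits)
  df$ci_low <- round(df$ci_low, digits)
  df$ci_high <- round(df$ci_high, digits)
  print(df, row.names = FALSE)
  p <- attr(x, "p_value")
  cat(sprintf("alpha = %.4f (SE %.4f); Wald p %s%s\n", attr(x, "alpha"),
              attr(x, "se_alpha"),
              if (is.na(p)) "NA" else if (p < 1e-4) "< 0.0001" else
                sprintf("= %.4f", p),
              if (isTRUE(attr(x, "significant"))) " (significant)" else ""))
  invisible(x)
}

#' Pointwise hazard-ratio curve over a grid of FVC declines
#'
#' `HR(d) = exp(-d * alpha_hat)` for declines d on `(0, 10]` by default,
#' with delta-method (Wald, log-scale) confidence bands; monotone in d when
#' `alpha_hat != 0`.
#'
#' @inheritParams hazard_ratio_report
#' @param decline_grid grid of declines in % predicted per year.
#' @return A data frame `decline`, `hr`, `ci_low`, `ci_high`.
#' @export
risk_curve <- function(fit, decline_grid = seq(0.1, 10, by = 0.1),
                       level = 0.95) {
  stopifnot(all(decline_grid > 0))
  hrp <- hazard_ratio_report(fit, units = decline_grid, level = level)
  data.frame(decline = hrp$unit, hr = hrp$hr,
             ci_low = hrp$ci_low, ci_high = hrp$ci_high)
}

#' Publication-style results table
#'
#' Lays the fit out like the trial reports: a longitudinal block (estimated
#' slope difference active vs control with CI and p) and a time-to-event
#' block (event counts, HRs for 1/3/5-unit declines, association p-value).
#'
#' @param fit an `fvcjm` object.
#' @param level confidence level.
#' @return A data frame with columns `section`, `quantity`, `value`.
#' @export
results_table <- function(fit, level = 0.95) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  btx <- unname(fit$lmm$beta["slope_trt_diff"])
  se_btx <- unname(fit$se_beta["slope_trt_diff"])
  p_btx <- if (is.finite(se_btx)) 2 * stats::pnorm(-abs(btx) / se_btx) else NA
  hr <- hazard_ratio_report(fit, level = level)
  fmt <- function(x) sprintf("%.4f", x)
  rows <- rbind(
    c("longitudinal", "slope_difference_trt_vs_control", fmt(btx)),
    c("longitudinal", "slope_difference_ci_low", fmt(btx - z * se_btx)),
    c("longitudinal", "slope_difference_ci_high", fmt(btx + z * se_btx)),
    c("longitudinal", "slope_difference_p", fmt(p_btx)),
    c("time_to_event", "n_subjects", as.character(fit$n)),
    c("time_to_event", "n_events", as.character(fit$n_events)),
    c("time_to_event", "pct_events",
      sprintf("%.1f", 100 * fit$n_events / fit$n)),
    do.call(rbind, lapply(seq_len(nrow(hr)), function(i) rbind(
      c("time_to_event", sprintf("hr_%g_unit", hr$unit[i]), fmt(hr$hr[i])),
      c("time_to_event", sprintf("hr_%g_unit_ci_low", hr$unit[i]),
        fmt(hr$ci_low[i])),
      c("time_to_event", sprintf("hr_%g_unit_ci_high", hr$unit[i]),
        fmt(hr$ci_high[i]))))),
    c("time_to_event", "association_p", fmt(attr(hr, "p_value"))))
  out <- as.data.frame(rows, stringsAsFactors = FALSE)
  names(out) <- c("section", "quantity", "value")
  out
}

#' Serialise a fitted joint model to a plain list / JSON
#'
#' Mirrors a full coefficient listing: every free parameter with its
#' standard error, the sub-model variance components, knots, log-likelihood
#' and convergence diagnostics.
#'
#' @param fit an `fvcjm` object.
#' @param path optional path; when given the list is written as JSON.
#' @return The list, invisibly when `path` is given.
#' @export
fit_to_json <- function(fit, path = NULL) {
  se_all <- if (!is.null(fit$vcov)) sqrt(pmax(diag(fit$vcov), 0)) else
    rep(NA_real_, length(fit$theta))
  out <- list(
    model = "shared-parameter joint model",
    association = fit$spec$association,
    endpoint = fit$endpoint, period = fit$period,
    n = fit$n, n_events = fit$n_events,
    loglik = fit$loglik,
    center_baseline_fvc = fit$lmm$center,
    beta = as.list(fit$lmm$beta),
    se_beta = as.list(fit$se_beta),
    D = fit$lmm$D, sigma2 = fit$lmm$sigma2,
    knots = fit$hazard$knots,
    baseline_hazard = exp(fit$hazard$log_h0),
    alpha = fit$alpha, se_alpha = fit$se_alpha,
    coefficients = data.frame(parameter = names(fit$theta),
                              estimate = unname(fit$theta),
                              se = unname(se_all)),
    convergence = fit$convergence[c("code", "gradient_norm")],
    quadrature_nodes = fit$spec$nodes)
  if (is.null(path)) return(out)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(out)
}
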