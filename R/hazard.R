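## Time-to-event sub-model: piecewise-exponential baseline hazard with five
## internal knots by default, stratified by ATA status (separate piece
## heights per stratum, shared knot locations).

PE_STRATA <- c("ata_neg", "ata_pos")

#' Piecewise-constant baseline hazard
#'
#' @param knots strictly increasing internal knot locations (years).  The
#'   hazard has `length(knots) + 1` pieces per stratum on the half-open
#'   intervals `[0, k1), [k1, k2), ..., [k_J, Inf)`.
#' @param log_h0 matrix of log piece heights (events/year), one row per ATA
#'   stratum (`ata_neg`, `ata_pos`), one column per piece.
#' @return An object of class `piecewise_hazard`.
#' @export
piecewise_hazard <- function(knots, log_h0) {
  knots <- as.numeric(knots)
  if (length(knots) && (any(diff(knots) <= 0) || any(knots <= 0))) {
    stop("knots must be positive and strictly increasing")
  }
  if (!is.matrix(log_h0)) log_h0 <- matrix(log_h0, nrow = 1L)
  if (nrow(log_h0) == 1L) log_h0 <- rbind(log_h0, log_h0)
  stopifnot(nrow(log_h0) == 2L, ncol(log_h0) == length(knots) + 1L)
  rownames(log_h0) <- PE_STRATA
  structure(list(knots = knots, log_h0 = log_h0), class = "piecewise_hazard")
}

#' Place internal knots at event-time quantiles
#'
#' Knots sit at the `j/(n_internal + 1)` empirical quantiles (linear
#' interpolation) of the observed, uncensored event times, pooled across
#' strata.  Coincident quantiles are collapsed with a warning, giving fewer
#' pieces.
#'
#' @param event_times observed event times (years) of subjects with an
#'   event.
#' @param n_internal number of internal knots (default 5).
#' @return Numeric vector of knot locations.
#' @export
choose_knots <- function(event_times, n_internal = 5) {
  event_times <- event_times[is.finite(event_times)]
  if (length(event_times) == 0L) {
    stop(errorCondition("unfittable endpoint: no observed events",
                        class = c("fvcjoint_unfittable_error", "error")))
  }
  if (n_internal == 0L) return(numeric(0))
  probs <- seq_len(n_internal) / (n_internal + 1)
  k <- unname(stats::quantile(event_times, probs, type = 7))
  ku <- unique(k)
  if (length(ku) < length(k)) {
    warning(sprintf("collapsed %d coincident knot(s); %d piece(s) remain",
                    length(k) - length(ku), length(ku) + 1L))
  }
  ku
}

piece_bounds <- function(knots) c(0, knots, Inf)

# n x J matrix of time spent in each hazard piece up to time t (years)
piece_exposure <- function(knots, t) {
  b <- piece_bounds(knots)
  J <- length(b) - 1L
  out <- matrix(0, length(t), J)
  for (j in seq_len(J)) {
    out[, j] <- pmax(0, pmin(t, b[j + 1L]) - b[j])
  }
  out
}

# index of the piece containing t (half-open intervals [b_j, b_{j+1}))
piece_index <- function(knots, t) {
  findInterval(t, piece_bounds(knots), left.open = FALSE)
}

#' Cumulative baseline hazard
#'
#' `Lambda0(t) = sum_j h0_j * |[k_j, k_{j+1}) intersect [0, t]|`:
#' continuous, piecewise linear and nondecreasing, with `Lambda0(0) = 0`.
#'
#' @param pw a `piecewise_hazard` object.
#' @param stratum `"ata_neg"` or `"ata_pos"` (or 0/1).
#' @param t time(s) in years.
#' @return Cumulative hazard at `t` (vectorised).
#' @export
cum_base_hazard <- function(pw, stratum, t) {
  stopifnot(inherits(pw, "piecewise_hazard"))
  if (is.numeric(stratum)) stratum <- PE_STRATA[stratum + 1L]
  stratum <- match.arg(stratum, PE_STRATA)
  h <- exp(pw$log_h0[stratum, ])
  drop(piece_exposure(pw$knots, t) %*% h)
}

#' @export
print.piecewise_hazard <- function(x, digits = 4, ...) {
  cat(sprintf("Piecewise-exponential baseline hazard: %d piece(s), knots at %s years\n",
              ncol(x$log_h0),
              if (length(x$knots)) paste(round(x$knots, 3), collapse = ", ")
              else "(none)"))
  print(round(exp(x$log_h0), digits))
  invisible(x)
}

#' Fit the piecewise-exponential sub-model (no covariates)
#'
#' Closed-form maximum likelihood: within each (stratum, interval) cell the
#' hazard estimate is events/exposure, identical to the Poisson-likelihood
#' formulation.  Cells with zero exposure get hazard 0 and are flagged.
#'
#' @param data a `jm_data` object.
#' @param knots internal knots (years); default chosen by [choose_knots()].
#' @return An object of class `fvc_pe`: `hazard` (a [piecewise_hazard];
#'   zero-hazard cells carry `-Inf` log height), `loglik`, `events` and
#'   `exposure` matrices, and `zero_cells`.
#' @export
fit_pe <- function(data, knots = NULL) {
  stopifnot(inherits(data, "jm_data"))
  s <- data$subjects
  if (is.null(knots)) {
    knots <- choose_knots(s$event_time_years[s$event == 1])
  }
  J <- length(knots) + 1L
  E <- piece_exposure(knots, s$event_time_years)
  jT <- piece_index(knots, s$event_time_years)
  strat <- factor(PE_STRATA[s$ata_positive + 1L], levels = PE_STRATA)

  exposure <- matrix(0, 2, J, dimnames = list(PE_STRATA, NULL))
  events <- matrix(0, 2, J, dimnames = list(PE_STRATA, NULL))
  for (k in 1:2) {
    sel <- as.integer(strat) == k
    if (any(sel)) exposure[k, ] <- colSums(E[sel, , drop = FALSE])
    for (j in seq_len(J)) {
      events[k, j] <- sum(s$event[sel] == 1 & jT[sel] == j)
    }
  }
  h <- ifelse(exposure > 0, events / exposure, 0)
  zero_cells <- which(exposure == 0, arr.ind = TRUE)
  ll <- sum(ifelse(events > 0, events * log(h), 0) - h * exposure)
  structure(list(hazard = piecewise_hazard(knots, log(h)),
                 loglik = ll, events = events, exposure = exposure,
                 zero_cells = zero_cells),
            class = "fvc_pe")
}

#' @export
print.fvc_pe <- function(x, ...) {
  print(x$hazard)
  cat(sprintf("  events %d, total exposure %.2f subject-years; log-likelihood %.3f\n",
              sum(x$events), sum(x$exposure), x$loglik))
  invisible(x)
}

#' @export
logLik.fvc_pe <- function(object, ...) {
  structure(object$loglik, df = length(object$events), class = "logLik")
}
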