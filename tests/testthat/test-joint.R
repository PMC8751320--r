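# Joint model: likelihood assembly, quadrature, estimation, empirical Bayes.

make_small <- function(n = 6, seed = 7) {
  cfg <- sim_config(n_subjects = n)
  sim <- simulate_trial(cfg, seed = seed)
  d <- build_joint_dataset(sim$trial, "all_cause", "52w")
  lp <- lmm_params(cfg$beta, cfg$D, cfg$sigma^2,
                   center = mean(d$subjects$baseline_fvc_pct))
  hz <- piecewise_hazard(c(0.3, 0.6), log(c(0.1, 0.15, 0.08)))
  list(d = d, lp = lp, hz = hz)
}

test_that("survival terms reduce correctly and encode the slope multiplier", {
  s <- make_small()
  # alpha = 0: subject cumulative hazard equals the baseline one
  for (assoc in c("slope", "current_value")) {
    st <- subject_survival_terms(s$lp, s$hz, 0, ata = 1,
                                 baseline_fvc_pct = 70, arm = 0,
                                 T_years = 0.8, b = c(3, -1),
                                 association = assoc)
    expect_equal(unname(st["neg_cum_hazard"]),
                 -cum_base_hazard(s$hz, "ata_pos", 0.8))
  }
  # slope association: a subject declining 1 unit/yr faster has hazard
  # multiplied by exp(-alpha) = 1.13
  alpha <- -log(1.13)
  st1 <- subject_survival_terms(s$lp, s$hz, alpha, 0, 70, 0, 0.8,
                                b = c(0, 0))
  st2 <- subject_survival_terms(s$lp, s$hz, alpha, 0, 70, 0, 0.8,
                                b = c(0, -1))
  expect_equal(exp(st2["log_hazard"] - st1["log_hazard"]), c(log_hazard = 1.13))
  expect_equal(st2["neg_cum_hazard"] / st1["neg_cum_hazard"],
               c(neg_cum_hazard = 1.13))
})

test_that("current-value cumulative hazard matches adaptive numerical integration", {
  s <- make_small()
  alpha <- -0.05
  for (b in list(c(0, 0), c(5, -2), c(-8, 1.5))) {
    st <- subject_survival_terms(s$lp, s$hz, alpha, 1, 75, 1, 0.9, b,
                                 association = "current_value")
    hfun <- function(t) {
      h <- exp(s$hz$log_h0["ata_pos", ])
      j <- findInterval(t, fvcjoint:::piece_bounds(s$hz$knots))
      m <- current_value(s$lp, 1, 75, 1, b[1], b[2], t)
      h[j] * exp(alpha * m)
    }
    num <- integrate(Vectorize(hfun), 0, 0.9, rel.tol = 1e-12,
                     subdivisions = 500)$value
    expect_equal(unname(-st["neg_cum_hazard"]), num, tolerance = 1e-10)
  }
})

test_that("at alpha = 0 the joint loglik factorises exactly", {
  s <- make_small(n = 25, seed = 3)
  jl <- joint_loglik(s$lp, s$hz, 0, s$d, "slope", nodes = 9)
  ll_lmm <- brute_lmm_loglik(s$lp, s$d)
  sub <- s$d$subjects
  ll_surv <- 0
  for (i in seq_len(nrow(sub))) {
    st <- subject_survival_terms(s$lp, s$hz, 0, sub$ata_positive[i],
                                 sub$baseline_fvc_pct[i], sub$arm[i],
                                 sub$event_time_years[i])
    ll_surv <- ll_surv + sub$event[i] * st["log_hazard"] +
      st["neg_cum_hazard"]
  }
  expect_equal(jl, ll_lmm + unname(ll_surv), tolerance = 1e-8)
  # both association structures coincide at alpha = 0
  expect_equal(joint_loglik(s$lp, s$hz, 0, s$d, "current_value", nodes = 9),
               jl, tolerance = 1e-8)
})

test_that("quadrature matches dense-grid integration on a 3-subject toy", {
  cfg <- sim_config(n_subjects = 3)
  sim <- simulate_trial(cfg, seed = 12)
  d <- build_joint_dataset(sim$trial, "all_cause", "52w")
  lp <- lmm_params(cfg$beta, cfg$D, cfg$sigma^2,
                   center = mean(d$subjects$baseline_fvc_pct))
  hz <- piecewise_hazard(0.5, log(c(0.12, 0.09)))
  for (assoc in c("slope", "current_value")) {
    jl <- joint_loglik(lp, hz, -log(1.13), d, assoc, nodes = 15)
    go <- grid_joint_loglik(lp, hz, -log(1.13), d, assoc, npts = 161)
    expect_equal(jl, go, tolerance = 1e-6)
  }
})

test_that("increasing the node count stabilises the loglik monotonically", {
  s <- make_small(n = 10, seed = 19)
  lls <- sapply(c(5, 9, 15, 25), function(k) {
    joint_loglik(s$lp, s$hz, -0.2, s$d, "slope", nodes = k)
  })
  gaps <- abs(diff(lls))
  expect_true(all(diff(gaps) <= 1e-8 | gaps[-1] < 1e-8))
  expect_lt(abs(lls[4] - lls[3]), 1e-5)
})

test_that("the analytic gradient matches central differences", {
  s <- make_small(n = 8, seed = 23)
  env <- fvcjoint:::joint_env(s$d, s$hz$knots, 9)
  th <- fvcjoint:::joint_theta_pack(s$lp, s$hz, -0.12)
  r <- fvcjoint:::joint_eval(th, env, "slope", want_grad = TRUE)
  ng <- sapply(seq_along(th), function(k) {
    h <- 1e-6
    tp <- th; tp[k] <- tp[k] + h
    tm <- th; tm[k] <- tm[k] - h
    (fvcjoint:::joint_eval(tp, env, "slope")$loglik -
       fvcjoint:::joint_eval(tm, env, "slope")$loglik) / (2 * h)
  })
  expect_equal(r$grad, ng, tolerance = 1e-4)
})

test_that("fitting refuses endpoints with too few events", {
  cfg <- sim_config(n_subjects = 40)
  sim <- simulate_trial(cfg, seed = 2)
  d <- build_joint_dataset(sim$trial, "all_cause", "52w")
  expect_error(fvcjm(d, spec = jm_spec(min_events = 100)),
               "unfittable.*minimum 100",
               class = "fvcjoint_unfittable_error")
})

test_that("the joint fit is deterministic and permutation-invariant", {
  cfg <- sim_config(n_subjects = 120)
  sim <- simulate_trial(cfg, seed = 4)
  d <- build_joint_dataset(sim$trial, "all_cause", "52w")
  spec <- jm_spec(min_events = 5)
  f1 <- fvcjm(d, spec = spec, se = FALSE)
  f2 <- fvcjm(d, spec = spec, se = FALSE)
  expect_identical(f1$theta, f2$theta)

  set.seed(99)
  perm <- sample(nrow(sim$trial$subjects))
  trial2 <- fvc_trial(sim$trial$subjects[perm, ], sim$trial$visits,
                      sim$trial$events)
  d2 <- build_joint_dataset(trial2, "all_cause", "52w")
  f3 <- fvcjm(d2, spec = spec, se = FALSE)
  expect_equal(f1$alpha, f3$alpha, tolerance = 1e-6)
  expect_equal(f1$lmm$beta, f3$lmm$beta, tolerance = 1e-6)
  expect_equal(f1$loglik, f3$loglik, tolerance = 1e-6)
})

test_that("the current-value association can be fitted and is recorded", {
  # baseline height compensates exp(alpha * mean FVC) so events still occur
  cfg <- sim_config(n_subjects = 100, association = "current_value",
                    alpha = -0.03, log_h0 = log(0.9))
  sim <- simulate_trial(cfg, seed = 8)
  d <- build_joint_dataset(sim$trial, "all_cause", "52w")
  f <- fvcjm(d, association = "current_value",
             spec = jm_spec(min_events = 5, n_internal_knots = 2),
             se = FALSE)
  expect_equal(f$spec$association, "current_value")
  expect_true(is.finite(f$loglik))
  expect_true(is.finite(f$alpha))
  # joint fit should not be worse than its own initialisation
  init_ll <- joint_loglik(f$init$lmm, f$init$hazard, 0, d, "current_value")
  expect_gte(f$loglik, init_ll - 1e-6)
})

test_that("empirical Bayes reduces to the BLUP, the prior mode and the LS slope", {
  cfg <- sim_config(n_subjects = 150)
  sim <- simulate_trial(cfg, seed = 6)
  # give one subject an event before the first post-baseline visit, so it
  # contributes survival information only
  tr <- sim$trial
  tr$events <- tr$events[tr$events$subject_id != "S0001", ]
  tr$events <- rbind(tr$events,
                     data.frame(subject_id = "S0001", event_day = 5,
                                category = "all_cause"))
  tr$subjects$death_day[tr$subjects$subject_id == "S0001"] <- NA
  tr <- fvc_trial(tr$subjects, tr$visits, tr$events)
  dd <- build_joint_dataset(tr, "all_cause", "52w")
  fit <- fvcjm(dd, se = FALSE, spec = jm_spec(min_events = 5))

  # alpha = 0 and censored subject: EB equals the closed-form BLUP
  fit0 <- fit
  fit0$alpha <- 0
  ss <- fit0$env$ss
  cens <- which(ss$delta == 0 & ss$ni > 0)[1]
  eb <- empirical_bayes(fit0, ss$ids[cens])
  D <- fit0$lmm$D
  sigma2 <- fit0$lmm$sigma2
  Z <- cbind(1, dd$long$time_years[dd$long$subject_id == ss$ids[cens]])
  y <- dd$long$fvc_pct[dd$long$subject_id == ss$ids[cens]]
  a <- fit0$lmm$beta[1] + fit0$lmm$beta[2] * ss$ata[cens] +
    fit0$lmm$beta[3] * ss$fvc0c[cens]
  mu <- a + (fit0$lmm$beta[4] + fit0$lmm$beta[5] * ss$arm[cens]) * Z[, 2]
  blup <- solve(crossprod(Z) / sigma2 + solve(D),
                crossprod(Z, y - mu) / sigma2)
  expect_equal(eb$mode, drop(blup), tolerance = 1e-5)

  # measurement-free subject at alpha = 0: posterior = prior, mode (0, 0)
  expect_equal(fit0$env$ss$ni[match("S0001", fit0$env$ss$ids)], 0)
  eb00 <- empirical_bayes(fit0, "S0001")
  expect_equal(eb00$mode, c(0, 0), tolerance = 1e-5)

  # a subject with very rich data: mode approaches the LS slope fit
  cfg2 <- sim_config(n_subjects = 40, sigma = 0.5,
                     schedule_weeks = c(0, seq(2, 52, by = 2)))
  sim2 <- simulate_trial(cfg2, seed = 44)
  d2 <- build_joint_dataset(sim2$trial, "all_cause", "52w")
  f2 <- fvcjm(d2, se = FALSE, spec = jm_spec(min_events = 1))
  id <- d2$subjects$subject_id[which(d2$subjects$n_obs >= 25)[1]]
  eb2 <- empirical_bayes(f2, id)
  sel <- d2$long$subject_id == id
  i2 <- match(id, d2$subjects$subject_id)
  a2 <- f2$lmm$beta[1] + f2$lmm$beta[2] * d2$subjects$ata_positive[i2] +
    f2$lmm$beta[3] * (d2$subjects$baseline_fvc_pct[i2] - f2$lmm$center)
  c2 <- f2$lmm$beta[4] + f2$lmm$beta[5] * d2$subjects$arm[i2]
  ls <- stats::lm(I(d2$long$fvc_pct[sel] - a2 -
                      c2 * d2$long$time_years[sel]) ~
                    d2$long$time_years[sel])
  expect_equal(unname(eb2$mode[2]), unname(coef(ls)[2]), tolerance = 0.15)
})
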