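# Raw-table reading, validation, endpoint derivation and measurement
# filtering.

test_that("reading the toy CSVs returns typed, validated tables", {
  trial <- toy_trial()
  paths <- write_toy_csvs(trial)
  back <- read_tables(paths[1], paths[2], paths[3])
  expect_s3_class(back, "fvc_trial")
  expect_equal(nrow(back$subjects), 5)
  expect_equal(nrow(back$visits), 25)
  expect_equal(nrow(back$events), 3)
  expect_type(back$subjects$baseline_fvc_pct, "double")
})

test_that("round trip write -> read reproduces the tables", {
  trial <- toy_trial()
  paths <- write_toy_csvs(trial)
  back <- read_tables(paths[1], paths[2], paths[3])
  rownames(trial$visits) <- rownames(back$visits) <- NULL
  expect_equal(back$subjects, trial$subjects)
  expect_equal(back$visits, trial$visits)
  expect_equal(back$events, trial$events)
})

test_that("schema and range violations are reported with row numbers", {
  trial <- toy_trial()
  bad <- trial$subjects[, setdiff(names(trial$subjects), "arm")]
  expect_error(fvc_trial(bad, trial$visits, trial$events),
               "missing mandatory column.*arm",
               class = "fvcjoint_schema_error")

  v <- trial$visits
  v$visit_week[7] <- -2
  expect_error(fvc_trial(trial$subjects, v, trial$events),
               "visit_week.*row\\(s\\) 7",
               class = "fvcjoint_validation_error")

  v <- trial$visits
  v$visit_week[2] <- v$visit_week[1]
  expect_error(fvc_trial(trial$subjects, v, trial$events),
               "duplicate \\(subject_id, visit_week\\)",
               class = "fvcjoint_validation_error")

  e <- trial$events
  e$category[2] <- "ssc_related"
  e$subject_id[2] <- "B"   # ssc event with no matching all_cause record
  e$event_day[2] <- 99
  expect_error(fvc_trial(trial$subjects, trial$visits, e),
               "ssc_related event without matching all_cause")
})

test_that("a visit with missing FVC is retained then dropped from analysis", {
  trial <- toy_trial()
  trial$visits$fvc_pct[trial$visits$subject_id == "B" &
                         trial$visits$visit_week == 12] <- NA
  trial2 <- fvc_trial(trial$subjects, trial$visits, trial$events)
  d <- build_joint_dataset(trial2, "all_cause", "52w")
  bb <- d$long[d$long$subject_id == "B", ]
  expect_false(any(abs(bb$time_years - 12 * 7 / 365.25) < 1e-9))
  expect_equal(nrow(bb), 3)  # weeks 2, 24, 52 (week 0 is covariate only)
})

test_that("endpoint derivation applies the composite-minimum and window rules", {
  trial <- toy_trial()
  ep <- derive_endpoint(trial, "all_cause", "52w")
  # A: hospitalisation day 30
  expect_equal(ep$event_time_years[ep$subject_id == "A"], 30 / 365.25)
  expect_equal(ep$event[ep$subject_id == "A"], 1L)
  # C: death day 100 (no hospitalisation record)
  expect_equal(ep$event_time_years[ep$subject_id == "C"], 100 / 365.25)
  expect_equal(ep$event[ep$subject_id == "C"], 1L)
  # E: hospitalisation at day 500 > followup_end 392 -> censored at 392
  expect_equal(ep$event_time_years[ep$subject_id == "E"], 392 / 365.25)
  expect_equal(ep$event[ep$subject_id == "E"], 0L)
  # D: censored at its own follow-up end (200 < 392)
  expect_equal(ep$event_time_years[ep$subject_id == "D"], 200 / 365.25)

  # death before first hospitalisation wins the composite
  tr2 <- toy_trial()
  tr2$subjects$death_day[tr2$subjects$subject_id == "A"] <- 20
  tr2 <- fvc_trial(tr2$subjects, tr2$visits, tr2$events)
  ep2 <- derive_endpoint(tr2, "all_cause", "52w")
  expect_equal(ep2$event_time_years[ep2$subject_id == "A"], 20 / 365.25)

  # event on day 0 is shifted to half a day
  tr3 <- toy_trial()
  tr3$events$event_day[1] <- 0
  tr3$events$event_day[2] <- 0
  tr3 <- fvc_trial(tr3$subjects, tr3$visits, tr3$events)
  ep3 <- derive_endpoint(tr3, "all_cause", "52w")
  expect_equal(ep3$event_time_years[ep3$subject_id == "A"], 0.5 / 365.25)
})

test_that("endpoint derivation is order-invariant and idempotent", {
  trial <- toy_trial()
  trial$events <- rbind(trial$events,
                        data.frame(subject_id = "A", event_day = 60,
                                   category = "all_cause"))
  ep1 <- derive_endpoint(trial, "all_cause", "52w")
  trial2 <- trial
  trial2$events <- trial2$events[rev(seq_len(nrow(trial2$events))), ]
  ep2 <- derive_endpoint(trial2, "all_cause", "52w")
  expect_equal(ep1, derive_endpoint(trial, "all_cause", "52w"))
  expect_equal(ep1$event_time_years,
               ep2$event_time_years[match(ep1$subject_id, ep2$subject_id)])
})

test_that("on-treatment filtering keeps pre-event post-baseline visits only", {
  trial <- toy_trial()
  trial$visits$on_treatment[trial$visits$subject_id == "B" &
                              trial$visits$visit_week == 12] <- 0
  trial <- fvc_trial(trial$subjects, trial$visits, trial$events)
  ep <- derive_endpoint(trial, "all_cause", "52w")
  long <- filter_on_treatment(trial$visits, ep)
  # A has event at day 30 (~4.3 weeks): only week 2 retained
  expect_equal(long$time_years[long$subject_id == "A"], 2 * 7 / 365.25)
  # B off-treatment week 12 dropped despite being pre-censoring
  expect_equal(sort(long$time_years[long$subject_id == "B"]),
               sort(c(2, 24, 52) * 7 / 365.25))
  # week 0 rows never appear
  expect_true(all(long$time_years > 0))
})

test_that("joint dataset counts events and keeps measurement-free subjects", {
  trial <- toy_trial()
  d <- build_joint_dataset(trial, "all_cause", "52w")
  expect_equal(d$n, 5)
  expect_equal(d$n_events, 2)
  expect_false(d$unfittable)
  expect_true(all(d$subjects$subject_id %in% trial$subjects$subject_id))
  # subject with event before week 2 has 0 or few retained visits but stays
  expect_true("A" %in% d$subjects$subject_id)
  s <- summary(d)
  expect_equal(s$pct_events, 40)

  # endpoint with zero events is flagged unfittable (deaths always count
  # towards the composite, so remove them first)
  tr0 <- trial
  tr0$subjects$death_day <- NA_real_
  tr0 <- fvc_trial(tr0$subjects, tr0$visits, tr0$events)
  d0 <- build_joint_dataset(tr0, "ventilation", "52w")
  expect_true(d0$unfittable)
  expect_equal(d0$n_events, 0L)
})

test_that("whole-trial events and censoring dominate the 52-week analysis", {
  cfg <- sim_config(n_subjects = 150, period = "whole")
  sim <- simulate_trial(cfg, seed = 11)
  d52 <- build_joint_dataset(sim$trial, "all_cause", "52w")
  dwh <- build_joint_dataset(sim$trial, "all_cause", "whole")
  expect_gte(dwh$n_events, d52$n_events)
  expect_true(all(dwh$subjects$event_time_years >=
                    d52$subjects$event_time_years - 1e-12))
  # 52w times are capped at 392 days
  expect_true(all(d52$subjects$event_time_years <= 392 / 365.25 + 1e-12))
})
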