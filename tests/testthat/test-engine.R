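test_that("step_day applies discharges first, then admits within capacity", {
  expect_identical(step_day(24, 2, 3, 25),
                   list(census_after = 25, admitted = 3, canceled = 0))
  expect_identical(step_day(25, 0, 2, 25),
                   list(census_after = 25, admitted = 0, canceled = 2))
  expect_identical(step_day(0, 0, 0, 25),
                   list(census_after = 0, admitted = 0, canceled = 0))
  expect_error(step_day(3, 4, 0, 25), "consistency")
  expect_error(step_day(-1, 0, 0, 25), "non-negative")
})

test_that("replications are bit-identical under a fixed seed", {
  spec <- scenario_spec(replications = 1L)
  a <- run_replication(spec, seed = 123)
  b <- run_replication(spec, seed = 123)
  expect_identical(a, b)
  expect_identical(attr(a, "patients"), attr(b, "patients"))
})

test_that("the ledger conserves patients day by day", {
  spec <- scenario_spec()
  led <- run_replication(spec, seed = 77)
  n <- nrow(led)
  expect_identical(led$census[-1],
                   led$census[-n] + led$admitted[-1] - led$discharged[-1])
  expect_true(all(led$census <= spec$unit$effective_capacity))
  expect_true(all(led$census >= 0))
  expect_identical(led$arrivals, led$admitted + led$canceled)
  # no weekend surgery
  expect_true(all(led$arrivals[led$weekday %in% c("Sat", "Sun")] == 0L))
  # calendar: measured year starts on a Monday, warm-up precedes it
  expect_identical(led$weekday[led$day == 1L], "Mon")
  expect_identical(sum(led$day < 1L), spec$warmup_days)
})

test_that("annual accounting balances demand against outcomes", {
  spec <- scenario_spec()
  for (seed in c(5, 17, 29)) {
    led <- run_replication(spec, seed = seed)
    ct <- attr(led, "counters")
    expect_identical(
      ct$demand_year + ct$pool_carry_in,
      ct$admitted_year + ct$canceled_year + ct$pool_end + ct$post_horizon
    )
    expect_lte(ct$demand_full_weeks, spec$demand$annual_guard)
  }
})

test_that("with no demand the census decays and nothing is canceled", {
  spec <- scenario_spec(weekly_min = 0L, occupancy_level = 0.005)
  expect_identical(spec$demand$b, 0L)
  led <- run_replication(spec, seed = 1)
  yr <- led[led$day >= 1, ]
  expect_true(all(diff(yr$census) <= 0))
  expect_identical(sum(yr$canceled), 0L)
})

test_that("with unlimited beds every scheduled arrival is admitted", {
  spec <- scenario_spec(unit = unit_config(total_beds = 10000),
                        replications = 1L, horizon_days = 28L)
  led <- run_replication(spec, seed = 42)
  expect_identical(sum(led$canceled), 0L)
  expect_identical(led$admitted, led$arrivals)
})

test_that("the engine reproduces a naive event-list re-simulation exactly", {
  total_canceled <- 0L
  for (seed in c(2, 8, 31, 64)) {
    for (policy in c("random", "anticipatory")) {
      spec <- tiny_congested_spec(policy = policy)
      led <- run_replication(spec, seed = seed)
      pat <- attr(led, "patients")
      sched <- pat[!is.na(pat$arrival_day) & pat$arrival_day <= 14, ]
      expect_lte(nrow(sched), 10)
      oracle <- naive_ledger(sched$arrival_day, sched$stay_days,
                             capacity = spec$unit$effective_capacity,
                             first_day = 1L, last_day = 14L)
      expect_identical(led$census, oracle$census)
      expect_identical(led$admitted, oracle$admitted)
      expect_identical(led$discharged, oracle$discharged)
      expect_identical(led$canceled, oracle$canceled)
      total_canceled <- total_canceled + sum(oracle$canceled)
    }
  }
  expect_gt(total_canceled, 0L)  # the fixture really congests somewhere
})

test_that("scenario aggregation averages weekdays and collapses to zero variance when degenerate", {
  spec <- scenario_spec(policy = "anticipatory", replications = 4L,
                        los = los_lognormal(log(3), 0))
  spec$demand$a <- spec$demand$b <- 10L
  s <- run_scenario(spec, seed = 3)
  expect_identical(unname(s$replications), 4L)
  expect_equal(unname(sd(s$reps$cancellations)), 0)
  expect_equal(unname(sd(s$reps$admissions)), 0)

  s2 <- run_scenario(scenario_spec(replications = 6L), seed = 9)
  expect_true(all(s2$weekday_sd >= 0))
  expect_equal(s2$cancellation_pct,
               100 * s2$annual_cancellations / s2$annual_demand)
  # identical master seed reproduces the summary exactly
  s3 <- run_scenario(scenario_spec(replications = 6L), seed = 9)
  expect_identical(s2$weekday_mean, s3$weekday_mean)
  expect_identical(s2$reps, s3$reps)
})

test_that("weekday_spread returns the mean and sample SD of five weekday means", {
  sp <- weekday_spread(c(14.31, 16.94, 19.24, 19.43, 19.45))
  expect_equal(unname(sp["sd"]), sd(c(14.31, 16.94, 19.24, 19.43, 19.45)))
  expect_equal(unname(weekday_spread(rep(4.2, 5))["sd"]), 0)
  expect_error(weekday_spread(1:4), "five")
})
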