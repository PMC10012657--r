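test_that("slot templates place 7 on the extra pair and 5 elsewhere", {
  expect_identical(as.integer(slot_template(c("Tue", "Wed"))), c(5L, 7L, 7L, 5L, 5L))
  expect_identical(as.integer(slot_template(c("Mon", "Fri"))), c(7L, 5L, 5L, 5L, 7L))
  expect_identical(attr(slot_template(c("Fri", "Mon")), "extra_pair"), c("Mon", "Fri"))
  for (i in seq_len(nrow(enumerate_pairs())))
    expect_identical(sum(slot_template(enumerate_pairs()[i, ])), 29L)
  expect_error(slot_template(c("Mon", "Mon")), "distinct")
  expect_error(slot_template(c("Sat", "Sun")), "weekend")
})

test_that("weekly bound calibration matches the discrete-uniform mean target", {
  expect_identical(calibrate_weekly_bound(0.76), 36L)
  expect_identical(calibrate_weekly_bound(0.90), 44L)
  expect_identical(calibrate_weekly_bound(0.86), 42L)
  expect_warning(b <- calibrate_weekly_bound(0.20), "clamping")
  expect_identical(b, 8L)
})

test_that("weekly demand has the calibrated mean and respects the guard", {
  dm <- demand_model(0.76)
  set.seed(11)
  draws <- replicate(3e4, sample_weekly_demand(dm))
  expect_true(all(draws >= 8 & draws <= 36))
  expect_equal(mean(draws), (8 + 36) / 2, tolerance = 0.2 / 22)

  expect_identical(sample_weekly_demand(dm, guard_remaining = 5), 5L)
  dm0 <- demand_model(0.5, a = 8L)
  dm0$a <- dm0$b <- 8L
  expect_identical(sample_weekly_demand(dm0), 8L)
})

test_that("random assignment saturates slots and picks free days uniformly", {
  set.seed(3)
  full <- assign_random(rep(4L, 29), slot_template())
  expect_identical(sum(is.na(full$day)), 0L)
  expect_identical(unname(tabulate(full$day, 5)), c(5L, 7L, 7L, 5L, 5L))
  expect_identical(sum(full$free), 0L)

  over <- assign_random(rep(4L, 31), slot_template())
  expect_identical(sum(is.na(over$day)), 2L)

  expect_identical(assign_random(integer(0), slot_template())$day, integer(0))

  set.seed(5)
  first_day <- replicate(1e5, assign_random(3L, slot_template())$day)
  p <- tabulate(first_day, 5) / 1e5
  expect_true(all(abs(p - 0.2) < 0.005))
})

test_that("anticipatory assignment fills Mon/Tue with shorts and Wed-Fri with longs", {
  tpl <- slot_template()  # [5,7,7,5,5]
  shorts5 <- assign_anticipatory(c(1L, 2L, 2L, 1L, 1L), tpl)
  expect_identical(shorts5$day, rep(1L, 5))

  shorts6 <- assign_anticipatory(rep(2L, 6), tpl)
  expect_identical(shorts6$day, c(rep(1L, 5), 2L))

  longs3 <- assign_anticipatory(c(10L, 5L, 3L), tpl)
  expect_identical(longs3$day, rep(3L, 3))

  # long spill order Wed(7) -> Thu(5) -> Fri(5) -> Tue -> Mon
  longs20 <- assign_anticipatory(rep(9L, 20), tpl)
  expect_identical(unname(tabulate(longs20$day, 5)), c(0L, 3L, 7L, 5L, 5L))
})

test_that("assignment conserves the pool and respects slot capacity", {
  tpl_all <- enumerate_pairs()
  set.seed(21)
  for (rep in 1:40) {
    tpl <- slot_template(tpl_all[sample.int(10, 1), ])
    n <- sample.int(45, 1)
    stays <- sample_stays(los_lognormal(), n)
    for (policy in c("random", "anticipatory")) {
      res <- if (policy == "random") assign_random(stays, tpl)
             else assign_anticipatory(stays, tpl)
      placed <- !is.na(res$day)
      expect_identical(sum(placed) + sum(!placed), n)
      counts <- tabulate(res$day[placed], 5)
      expect_true(all(counts <= as.integer(tpl)))
      expect_identical(sum(placed), min(n, 29L))
      # anticipatory dominance: if Mon+Tue can hold every waiting short,
      # no short is placed Wed-Fri
      if (policy == "anticipatory" && sum(stays <= 2) <= tpl[1] + tpl[2])
        expect_false(any(res$day[placed & stays <= 2] >= 3))
    }
  }
})

test_that("assignment is reproducible under a fixed seed", {
  stays <- rep(c(1L, 8L), 15)
  set.seed(99); a <- assign_random(stays, slot_template())
  set.seed(99); b <- assign_random(stays, slot_template())
  expect_identical(a, b)
  expect_identical(assign_anticipatory(stays, slot_template()),
                   assign_anticipatory(stays, slot_template()))
})
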