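make_summary <- function(means, sds) {
  structure(list(weekday_mean = c(means, Sat = 0, Sun = 0),
                 weekday_sd = c(sds, Sat = 0, Sun = 0)),
            class = "scenario_summary")
}

test_that("all ten weekday pairs are enumerated in lexicographic order", {
  p <- enumerate_pairs()
  expect_identical(dim(p), c(10L, 2L))
  expect_identical(p[1, ], c("Mon", "Tue"))
  expect_identical(p[10, ], c("Thu", "Fri"))
  expect_identical(anyDuplicated(paste(p[, 1], p[, 2])), 0L)
  expect_false(any(p[, 1] == p[, 2]))
})

test_that("the range criterion picks the pair with the smallest ranges", {
  base_m <- c(Mon = 15, Tue = 17, Wed = 18, Thu = 19, Fri = 20)
  base_s <- c(Mon = 3, Tue = 3.5, Wed = 4, Thu = 4, Fri = 4.2)
  summaries <- replicate(10, make_summary(base_m, base_s), simplify = FALSE)
  # give pair 7 (Tue,Fri) strictly flatter mean and SD profiles
  summaries[[7]] <- make_summary(c(Mon = 17, Tue = 17.5, Wed = 18, Thu = 17.8, Fri = 17.2),
                                 c(Mon = 3.6, Tue = 3.7, Wed = 3.8, Thu = 3.7, Fri = 3.6))
  res <- range_criterion(summaries)
  expect_identical(res$optimal_pair, c("Tue", "Fri"))
  expect_identical(which(res$table$optimal), 7L)
  expect_true(all(res$table$mean_range >= 0 & res$table$sd_range >= 0))

  # all-identical summaries: documented tie-break to the first pair
  tied <- range_criterion(replicate(10, make_summary(base_m, base_s),
                                    simplify = FALSE))
  expect_identical(tied$optimal_pair, c("Mon", "Tue"))

  # mean-range ties broken by SD-range
  alt <- replicate(10, make_summary(base_m, base_s), simplify = FALSE)
  alt[[4]] <- make_summary(base_m, base_s * 0.5)
  expect_identical(range_criterion(alt)$optimal_pair,
                   c(enumerate_pairs()[4, ]))

  expect_error(range_criterion(summaries[1:9]), "one summary per")
})

test_that("pair search evaluates every pair under common random numbers", {
  ps <- pair_search("anticipatory", replications = 8L, seed = 4)
  expect_identical(nrow(ps$table), 10L)
  expect_true(sum(ps$table$optimal) == 1L)
  # identical rerun under the same master seed
  ps2 <- pair_search("anticipatory", replications = 8L, seed = 4)
  expect_identical(ps$table, ps2$table)
  # CRN: the Tue+Wed entry equals a plain scenario run with the same seeds
  set.seed(4)
  seeds <- matrix(sample.int(2147483646L, 8L * 10L), ncol = 10L)[, 1]
  ref <- run_scenario(scenario_spec("anticipatory", slot_template(c("Tue", "Wed")),
                                    replications = 8L), rep_seeds = seeds)
  expect_equal(ps$table$mean_range[5],
               unname(diff(range(ref$weekday_mean[1:5]))))
})

test_that("cancellation reductions follow the printed-table arithmetic", {
  expect_equal(round(cancellation_reduction(8.4, 3.6)), 57)
  expect_equal(cancellation_reduction(10, 10), 0)
  # anti-monotone in the second argument
  expect_true(all(diff(cancellation_reduction(8.4, c(8, 6, 4, 2))) > 0))
  expect_error(cancellation_reduction(0, 1), "> 0")
})

test_that("the comparison grid is self-consistent", {
  cmp <- compare_models(occupancy_levels = 0.76, replications = 6L, seed = 2)
  expect_identical(nrow(cmp$grid), 4L)
  expect_identical(cmp$grid$model, c("1A", "1B", "2A", "2B"))
  expect_identical(cmp$grid$extra_pair,
                   c("Tue+Wed", "Mon+Fri", "Tue+Wed", "Wed+Thu"))
  # reductions recomputed from the grid's own cancellation cells
  base <- cmp$grid$cancellations[cmp$grid$model == "1A"]
  for (m in c("2A", "1B", "2B")) {
    got <- cmp$reductions$reduction_pct[cmp$reductions$comparison ==
                                          paste0("1A->", m)]
    expect_equal(got, 100 * (base - cmp$grid$cancellations[cmp$grid$model == m]) / base)
  }
})
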